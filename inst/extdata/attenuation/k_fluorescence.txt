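# K-shell data: edges/yields/lines from standard compilations; K fraction from Cromer-Liberman jump ratio
# element k_edge_keV omega_K k_fraction line_keV line_probability
Cu 8.9790 0.4410 0.875882 8.0480 0.595238
Cu 8.9790 0.4410 0.875882 8.0280 0.303571
Cu 8.9790 0.4410 0.875882 8.9050 0.101190
Zn 9.6590 0.4740 0.874818 8.6390 0.595238
Zn 9.6590 0.4740 0.874818 8.6160 0.303571
Zn 9.6590 0.4740 0.874818 9.5720 0.101190
Br 13.4740 0.6180 0.868263 11.9240 0.588235
Br 13.4740 0.6180 0.868263 11.8780 0.305882
Br 13.4740 0.6180 0.868263 13.2910 0.105882
Cd 26.7110 0.8430 0.844845 23.1740 0.568182
Cd 26.7110 0.8430 0.844845 22.9840 0.301136
Cd 26.7110 0.8430 0.844845 26.0960 0.130682
Te 31.8140 0.8750 0.839354 27.4720 0.561798
Te 31.8140 0.8750 0.839354 27.2020 0.303371
Te 31.8140 0.8750 0.839354 30.9950 0.134831
I 33.1690 0.8820 0.837945 28.6120 0.561798
I 33.1690 0.8820 0.837945 28.3170 0.303371
I 33.1690 0.8820 0.837945 32.2950 0.134831
La 38.9250 0.9060 0.831413 33.4420 0.555556
La 38.9250 0.9060 0.831413 33.0340 0.305556
La 38.9250 0.9060 0.831413 37.8010 0.138889
Ce 40.4430 0.9110 0.829884 34.7190 0.555556
Ce 40.4430 0.9110 0.829884 34.2790 0.305556
Ce 40.4430 0.9110 0.829884 39.2570 0.138889
W 69.5250 0.9580 0.805097 59.3180 0.531915
W 69.5250 0.9580 0.805097 57.9820 0.308511
W 69.5250 0.9580 0.805097 67.2440 0.159574
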