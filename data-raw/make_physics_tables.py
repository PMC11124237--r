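#!/usr/bin/env python
"""One-time generator for the elemental photon-interaction tables bundled
under inst/extdata/attenuation/.

Cross sections per process, 1-300 keV:
  photoelectric : Cromer-Liberman f'' (gemmi 0.7.4), sigma = 2 r0 lambda f''
  incoherent    : Klein-Nishina total cross section per electron (free
                  electrons; incoherent-scattering-function correction omitted)
  coherent      : Thomson differential cross section weighted by the squared
                  atomic form factor f0 (4-Gaussian IT92 fit + damped constant, gemmi),
                  integrated numerically over solid angle
K-shell data: edge energies, fluorescence yields and K-line energies/relative
intensities from standard compilations (X-ray data booklet values); K-shell
photoelectric fraction above the edge derived from the f'' jump ratio.

Run from the repository root:  python data-raw/make_physics_tables.py
"""
import math
import os

import gemmi
import numpy as np

NA = 6.02214076e23
R0 = 2.8179403262e-13   # classical electron radius, cm
HC = 12.398419843320026  # keV * Angstrom
MEC2 = 510.99895         # keV

ELEMENTS = ["H", "Be", "C", "O", "F", "Al", "Cu", "Zn", "Br",
            "Cd", "Te", "I", "La", "Ce", "W"]

# K-edge energies (keV), K fluorescence yields omega_K, and K lines
# (energy keV, relative intensity) -- Ka1, Ka2, Kb1 from standard tables.
KDATA = {
    "Cu": (8.979, 0.441, [(8.048, 100), (8.028, 51), (8.905, 17)]),
    "Zn": (9.659, 0.474, [(8.639, 100), (8.616, 51), (9.572, 17)]),
    "Br": (13.474, 0.618, [(11.924, 100), (11.878, 52), (13.291, 18)]),
    "Cd": (26.711, 0.843, [(23.174, 100), (22.984, 53), (26.096, 23)]),
    "Te": (31.814, 0.875, [(27.472, 100), (27.202, 54), (30.995, 24)]),
    "I":  (33.169, 0.882, [(28.612, 100), (28.317, 54), (32.295, 24)]),
    "La": (38.925, 0.906, [(33.442, 100), (33.034, 55), (37.801, 25)]),
    "Ce": (40.443, 0.911, [(34.719, 100), (34.279, 55), (39.257, 25)]),
    "W":  (69.525, 0.958, [(59.318, 100), (57.982, 58), (67.244, 30)]),
}


def mu_pe(z, weight, e_kev):
    _, fpp = gemmi.cromer_liberman(z, e_kev * 1000.0)
    sigma = 2.0 * R0 * (HC / e_kev * 1e-8) * fpp  # cm^2/atom
    return sigma * NA / weight


def sigma_kn(e_kev):
    """Klein-Nishina total cross section per electron, cm^2."""
    k = e_kev / MEC2
    t1 = (1 + k) / k**2 * (2 * (1 + k) / (1 + 2 * k) - math.log(1 + 2 * k) / k)
    t2 = math.log(1 + 2 * k) / (2 * k)
    t3 = -(1 + 3 * k) / (1 + 2 * k) ** 2
    return 2 * math.pi * R0**2 * (t1 + t2 + t3)


def f0(el, stol2):
    """Atomic X-ray form factor at (sin theta / lambda)^2 in A^-2 (IT92 fit).

    The IT92 constant term (inner-shell electrons) is damped with a
    hydrogenic K-shell form factor so that f0 -> 0 at large momentum
    transfer instead of plateauing at c.
    """
    c = el.it92.get_coefs()  # a1..a4, b1..b4, c
    a, b, const = c[0:4], c[4:8], c[8]
    zk = max(el.atomic_number - 0.3, 1.0)
    ak = 2 * math.pi * 0.529177 / zk  # A
    damp = (1.0 + ak**2 * stol2) ** -2
    return sum(ai * np.exp(-bi * stol2) for ai, bi in zip(a, b)) + const * damp


def mu_coh(el, e_kev):
    lam = HC / e_kev  # Angstrom
    mu = np.linspace(-1.0, 1.0, 2001)  # cos theta
    stol2 = (1 - mu) / (2 * lam**2)    # (sin(theta/2)/lambda)^2
    ff = f0(el, stol2)
    integrand = 0.5 * R0**2 * (1 + mu**2) * ff**2
    sigma = 2 * math.pi * np.trapezoid(integrand, mu)
    return sigma * NA / el.weight


def energy_grid(sym):
    grid = list(np.geomspace(1.0, 300.0, 140))
    if sym in KDATA:
        ek = KDATA[sym][0]
        grid += [ek * (1 - 5e-4), ek * (1 + 5e-4)]
    return np.array(sorted(grid))


def main():
    outdir = os.path.join("inst", "extdata", "attenuation")
    os.makedirs(outdir, exist_ok=True)
    klines = []
    for sym in ELEMENTS:
        el = gemmi.Element(sym)
        z, w = el.atomic_number, el.weight
        es = energy_grid(sym)
        rows = []
        for e in es:
            pe = mu_pe(z, w, e)
            inc = sigma_kn(e) * NA * z / w
            coh = mu_coh(el, e)
            rows.append((e, pe + inc + coh, pe, inc, coh))
        path = os.path.join(outdir, f"{sym}.txt")
        with open(path, "w") as fh:
            fh.write(f"# element {sym} Z={z} A={w}\n")
            fh.write("# mass attenuation coefficients, cm^2/g\n")
            fh.write("# photoelectric: Cromer-Liberman f'' (gemmi 0.7.4); "
                     "incoherent: Klein-Nishina (free electron); "
                     "coherent: Thomson x IT92 form factor (damped constant term)\n")
            fh.write("# energy_keV total photoelectric incoherent coherent\n")
            for r in rows:
                fh.write("%.5e %.4e %.4e %.4e %.4e\n" % r)
        if sym in KDATA:
            ek, wk, lines = KDATA[sym]
            below = mu_pe(z, w, ek * (1 - 5e-4))
            above = mu_pe(z, w, ek * (1 + 5e-4))
            fk = 1.0 - below / above  # K-shell fraction from jump ratio
            tot = sum(i for _, i in lines)
            for le, li in lines:
                klines.append((sym, ek, wk, fk, le, li / tot))
    with open(os.path.join(outdir, "k_fluorescence.txt"), "w") as fh:
        fh.write("# K-shell data: edges/yields/lines from standard "
                 "compilations; K fraction from Cromer-Liberman jump ratio\n")
        fh.write("# element k_edge_keV omega_K k_fraction line_keV "
                 "line_probability\n")
        for sym, ek, wk, fk, le, lp in klines:
            fh.write("%s %.4f %.4f %.6f %.4f %.6f\n" % (sym, ek, wk, fk, le, lp))
    print("wrote tables for", len(ELEMENTS), "elements")


if __name__ == "__main__":
    main()
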