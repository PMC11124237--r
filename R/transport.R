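# Simplified Monte-Carlo photon transport in the pixel array.
#
# The model keeps the effects the pPSF analysis relies on: finite absorption
# efficiency, K-fluorescence escape and crosstalk, Compton scatter crosstalk
# and the reflector dead area of the indirect-conversion detector. It
# deliberately omits electron range (deposits are point-like; no charge
# sharing), optical transport, and coherent scattering: interaction depths
# are sampled with the total attenuation coefficient and the interaction
# branches photoelectric vs incoherent in proportion to their partial cross
# sections, so a coherent event's cross section is effectively redistributed
# over the depositing processes.

ELECTRON_REST_KEV <- 510.99895
MAX_SCATTER_DEPTH <- 5L

# per-material transport tables, cached: linear attenuation and per-element
# photoelectric shares plus K-shell data
transport_tables <- function(material) {
  key <- paste0("tp.", material$name, ".",
                paste(material$elements, signif(material$fractions, 8),
                      collapse = "_"))
  if (!is.null(.pcd[[key]])) return(.pcd[[key]])
  kdata <- lapply(material$elements, function(el)
    tryCatch(fluorescence(el), error = function(e) NULL))
  names(kdata) <- material$elements
  tt <- list(material = material, kdata = kdata)
  .pcd[[key]] <- tt
  tt
}

mu_linear <- function(material, energy, process = "total") {
  mass_attenuation(material, energy, process) * material$density  # 1/cm
}

# Klein-Nishina sampling of the scattering angle cosine (vectorized
# rejection; the differential cross section is bounded by its forward value)
sample_kn_costheta <- function(energy_kev) {
  k <- energy_kev / ELECTRON_REST_KEV
  n <- length(k)
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    m <- length(todo)
    mu <- stats::runif(m, -1, 1)
    u <- stats::runif(m, 0, 2)
    eps <- 1 / (1 + k[todo] * (1 - mu))
    f <- eps^2 * (eps + 1 / eps - (1 - mu^2))
    acc <- u < f
    out[todo[acc]] <- mu[acc]
    todo <- todo[!acc]
  }
  out
}

# rotate unit direction vectors (matrix n x 3) by polar angle acos(cos_t)
# and uniform azimuth
rotate_direction <- function(dir, cos_t) {
  n <- nrow(dir)
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  phi <- stats::runif(n, 0, 2 * pi)
  # orthonormal basis (u, v) perpendicular to dir
  ref <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
  swap <- abs(dir[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  u <- cbind(dir[, 2] * ref[, 3] - dir[, 3] * ref[, 2],
             dir[, 3] * ref[, 1] - dir[, 1] * ref[, 3],
             dir[, 1] * ref[, 2] - dir[, 2] * ref[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(dir[, 2] * u[, 3] - dir[, 3] * u[, 2],
             dir[, 3] * u[, 1] - dir[, 1] * u[, 3],
             dir[, 1] * u[, 2] - dir[, 2] * u[, 1])
  dir * cos_t + (u * cos(phi) + v * sin(phi)) * sin_t
}

random_direction <- function(n) {
  cz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sz <- sqrt(1 - cz^2)
  cbind(sz * cos(phi), sz * sin(phi), cz)
}

#' Sample Poisson arrival times
#'
#' Homogeneous Poisson process over a detector area; the expected number of
#' arrivals is `rate * area * duration * 1e-9`.
#'
#' @param rate total fluence rate, mm^-2 s^-1.
#' @param area irradiated area, mm^2.
#' @param duration exposure duration, ns.
#' @return arrival times in ns, ascending.
#' @export
sample_arrivals <- function(rate, area, duration) {
  if (rate < 0) stop("rate must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  n <- stats::rpois(1, rate * area * duration * 1e-9)
  sort(stats::runif(n, 0, duration))
}

sample_spectrum_energies <- function(spec, n) {
  if (n == 0) return(numeric(0))
  idx <- sample.int(length(spec$energy), n, replace = TRUE,
                    prob = spec$fluence)
  spec$energy[idx]
}

in_dead_area <- function(geom, x_um, y_um) {
  if (geom$septum_um <= 0) return(rep(FALSE, length(x_um)))
  lx <- x_um %% geom$pitch_um
  ly <- y_um %% geom$pitch_um
  s <- geom$septum_um
  (lx < s) | (lx > geom$pitch_um - s) | (ly < s) | (ly > geom$pitch_um - s)
}

#' Transport photons through the sensor
#'
#' Vectorized simplified Monte-Carlo: exponential interaction depths from
#' the total attenuation coefficient; photoelectric absorption with
#' K-fluorescence emission and single-flight escape/reabsorption of the K
#' photon; Klein-Nishina Compton scattering recursed up to depth 5, then
#' forced to absorb or escape on one final flight. Primaries that enter the
#' reflector dead area of an indirect-conversion detector deposit nothing.
#' Uses the current RNG state.
#'
#' @param detector a `detector_model`.
#' @param energy primary photon energies, keV.
#' @param x_um,y_um entry coordinates on the array, um.
#' @param primary primary ids (default `seq_along(energy)`).
#' @return a data.frame of merged deposits: `primary`, `px`, `py` (0-based
#'   pixel indices), `energy` (keV deposited).
#' @export
interact_photons <- function(detector, energy, x_um, y_um,
                             primary = seq_along(energy)) {
  geom <- detector$geometry
  mat <- detector$material
  lim <- c(geom$n_pixels[1] * geom$pitch_um,
           geom$n_pixels[2] * geom$pitch_um,
           geom$thickness_mm * 1000)
  n <- length(energy)
  if (n == 0 || detector$transport == "full-absorption") {
    if (n == 0)
      return(data.frame(primary = integer(0), px = integer(0),
                        py = integer(0), energy = numeric(0)))
    return(data.frame(primary = primary,
                      px = pmin(floor(x_um / geom$pitch_um),
                                geom$n_pixels[1] - 1),
                      py = pmin(floor(y_um / geom$pitch_um),
                                geom$n_pixels[2] - 1),
                      energy = energy))
  }
  tt <- transport_tables(mat)
  dead <- in_dead_area(geom, x_um, y_um)
  keep <- !dead
  st <- list(id = primary[keep], E = energy[keep],
             pos = cbind(x_um[keep], y_um[keep], 0),
             dir = cbind(0, 0, 1)[rep(1, sum(keep)), , drop = FALSE],
             kphoton = rep(FALSE, sum(keep)))
  dep_id <- list(); dep_px <- list(); dep_py <- list(); dep_e <- list()
  push_deposit <- function(id, pos, e) {
    ok <- e > 0
    if (!any(ok)) return()
    i <- length(dep_id) + 1
    dep_id[[i]] <<- id[ok]
    dep_px[[i]] <<- pmin(floor(pos[ok, 1] / geom$pitch_um),
                         geom$n_pixels[1] - 1)
    dep_py[[i]] <<- pmin(floor(pos[ok, 2] / geom$pitch_um),
                         geom$n_pixels[2] - 1)
    dep_e[[i]] <<- e[ok]
  }
  for (gen in 0:MAX_SCATTER_DEPTH) {
    m <- length(st$E)
    if (m == 0) break
    mu <- mu_linear(mat, st$E)                    # 1/cm
    step <- stats::rexp(m, mu) * 1e4              # um
    pos <- st$pos + st$dir * step
    inside <- pos[, 1] >= 0 & pos[, 1] < lim[1] &
      pos[, 2] >= 0 & pos[, 2] < lim[2] &
      pos[, 3] >= 0 & pos[, 3] <= lim[3]
    id <- st$id[inside]; E <- st$E[inside]
    pos <- pos[inside, , drop = FALSE]
    dir <- st$dir[inside, , drop = FALSE]
    kph <- st$kphoton[inside]
    m <- length(E)
    if (m == 0) break
    # K photons deposit fully at their endpoint
    if (any(kph)) push_deposit(id[kph], pos[kph, , drop = FALSE], E[kph])
    act <- !kph
    id <- id[act]; E <- E[act]
    pos <- pos[act, , drop = FALSE]; dir <- dir[act, , drop = FALSE]
    m <- length(E)
    if (m == 0) break
    if (gen == MAX_SCATTER_DEPTH) {               # forced absorption
      push_deposit(id, pos, E)
      break
    }
    pe <- mass_attenuation(mat, E, "photoelectric")
    inc <- mass_attenuation(mat, E, "incoherent")
    is_pe <- stats::runif(m) < pe / (pe + inc)
    # --- photoelectric branch ---
    nxt <- list(id = integer(0), E = numeric(0),
                pos = matrix(0, 0, 3), dir = matrix(0, 0, 3),
                kphoton = logical(0))
    if (any(is_pe)) {
      idp <- id[is_pe]; Ep <- E[is_pe]
      posp <- pos[is_pe, , drop = FALSE]
      mp <- length(Ep)
      # element selection proportional to the elemental photoelectric share
      shares <- vapply(seq_along(mat$elements), function(i)
        mat$fractions[i] * element_mu(mat$elements[i], Ep, "photoelectric"),
        numeric(mp))
      shares <- matrix(shares, nrow = mp)
      cum <- shares / rowSums(shares)
      if (ncol(cum) > 1)
        for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1] + cum[, j]
      uel <- stats::runif(mp)
      elem_idx <- max.col(uel <= cum, ties.method = "first")
      elem <- mat$elements[elem_idx]
      fluo <- rep(FALSE, mp)
      eline <- rep(0, mp)
      ufl <- stats::runif(mp)
      for (el in unique(elem)) {
        kd <- tt$kdata[[el]]
        if (is.null(kd)) next
        sel <- elem == el & Ep > kd$k_edge
        emit <- sel & ufl < kd$k_fraction * kd$omega_k
        ne <- sum(emit)
        if (ne > 0) {
          li <- sample.int(nrow(kd$lines), ne, replace = TRUE,
                           prob = kd$lines$probability)
          fluo[emit] <- TRUE
          eline[emit] <- kd$lines$energy[li]
        }
      }
      push_deposit(idp, posp, Ep - eline)         # local deposit
      if (any(fluo)) {                            # emit K photon
        nf <- sum(fluo)
        nxt$id <- c(nxt$id, idp[fluo])
        nxt$E <- c(nxt$E, eline[fluo])
        nxt$pos <- rbind(nxt$pos, posp[fluo, , drop = FALSE])
        nxt$dir <- rbind(nxt$dir, random_direction(nf))
        nxt$kphoton <- c(nxt$kphoton, rep(TRUE, nf))
      }
    }
    # --- incoherent (Compton) branch ---
    if (any(!is_pe)) {
      idc <- id[!is_pe]; Ec <- E[!is_pe]
      posc <- pos[!is_pe, , drop = FALSE]
      dirc <- dir[!is_pe, , drop = FALSE]
      ct <- sample_kn_costheta(Ec)
      eps <- 1 / (1 + Ec / ELECTRON_REST_KEV * (1 - ct))
      Esc <- Ec * eps
      push_deposit(idc, posc, Ec - Esc)           # recoil electron, local
      cont <- Esc >= 1                            # below table range: done
      if (any(!cont))
        push_deposit(idc[!cont], posc[!cont, , drop = FALSE], Esc[!cont])
      if (any(cont)) {
        nxt$id <- c(nxt$id, idc[cont])
        nxt$E <- c(nxt$E, Esc[cont])
        nxt$pos <- rbind(nxt$pos, posc[cont, , drop = FALSE])
        nxt$dir <- rbind(nxt$dir,
                         rotate_direction(dirc[cont, , drop = FALSE],
                                          ct[cont]))
        nxt$kphoton <- c(nxt$kphoton, rep(FALSE, sum(cont)))
      }
    }
    st <- nxt
  }
  if (length(dep_id) == 0)
    return(data.frame(primary = integer(0), px = integer(0),
                      py = integer(0), energy = numeric(0)))
  d <- data.frame(primary = unlist(dep_id), px = unlist(dep_px),
                  py = unlist(dep_py), energy = unlist(dep_e))
  # merge deposits of one primary in one pixel (simultaneous at ns scale)
  key <- paste(d$primary, d$px, d$py)
  e <- rowsum(d$energy, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- d[first, c("primary", "px", "py")]
  out$energy <- as.numeric(e[match(key[first], rownames(e))])
  rownames(out) <- NULL
  out
}

#' Simulate an exposure of the detector array
#'
#' Operating-beam photons arrive homogeneously over the whole array as a
#' Poisson process with energies drawn from the spectrum; an optional
#' monoenergetic probe beam arrives on the footprint (full pitch) of one
#' target pixel. All random draws come from named substreams of `seed`, so
#' the operating-beam realization — arrivals, energies, entry points and
#' transport — is bit-identical with and without the probe (the
#' common-random-numbers contract used by the pPSF estimator).
#'
#' @param detector a `detector_model`.
#' @param spectrum operating `spectral_fluence` (absolute scale =
#'   fluence rate).
#' @param duration exposure duration, ns.
#' @param seed master seed.
#' @param probe optional `list(energy, rate, pixel)`: probe energy (keV),
#'   probe fluence rate (mm^-2 s^-1) and target pixel (0-based
#'   `c(px, py)`, default the center pixel).
#' @return a data.frame of deposition events: `primary`, `time` (ns),
#'   `px`, `py`, `energy` (keV), `origin` (`"op"` or `"probe"`), with
#'   attributes `duration`, `n_op_primaries`, `n_probe_primaries`.
#' @export
simulate_exposure <- function(detector, spectrum, duration, seed,
                              probe = NULL) {
  geom <- detector$geometry
  lx <- geom$n_pixels[1] * geom$pitch_um
  ly <- geom$n_pixels[2] * geom$pitch_um
  area <- lx * ly * 1e-6  # mm^2
  total <- total_fluence(spectrum)
  times <- with_seed(substream_seed(seed, "op.arrivals"),
                     sample_arrivals(total, area, duration))
  n_op <- length(times)
  energies <- with_seed(substream_seed(seed, "op.energies"),
                        sample_spectrum_energies(spectrum, n_op))
  posxy <- with_seed(substream_seed(seed, "op.positions"),
                     cbind(stats::runif(n_op, 0, lx),
                           stats::runif(n_op, 0, ly)))
  dep <- with_seed(substream_seed(seed, "op.transport"),
                   interact_photons(detector, energies, posxy[, 1],
                                    posxy[, 2]))
  dep$time <- times[dep$primary]
  dep$origin <- rep("op", nrow(dep))
  n_probe <- 0L
  if (!is.null(probe)) {
    pix <- if (is.null(probe$pixel)) (geom$n_pixels - 1) %/% 2 else
      probe$pixel
    if (any(pix < 0) || any(pix >= geom$n_pixels))
      stop("probe pixel outside array")
    pt <- with_seed(substream_seed(seed, "probe.arrivals"),
                    sample_arrivals(probe$rate, geom$pixel_area_mm2,
                                    duration))
    n_probe <- length(pt)
    if (n_probe > 0) {
      pxy <- with_seed(substream_seed(seed, "probe.positions"),
                       cbind(stats::runif(n_probe, pix[1] * geom$pitch_um,
                                          (pix[1] + 1) * geom$pitch_um),
                             stats::runif(n_probe, pix[2] * geom$pitch_um,
                                          (pix[2] + 1) * geom$pitch_um)))
      pdep <- with_seed(substream_seed(seed, "probe.transport"),
                        interact_photons(detector, rep(probe$energy, n_probe),
                                         pxy[, 1], pxy[, 2],
                                         primary = n_op + seq_len(n_probe)))
      pdep$time <- pt[pdep$primary - n_op]
      pdep$origin <- rep("probe", nrow(pdep))
      dep <- rbind(dep, pdep)
    }
  }
  attr(dep, "duration") <- duration
  attr(dep, "n_op_primaries") <- n_op
  attr(dep, "n_probe_primaries") <- n_probe
  attr(dep, "primary_energies") <- energies
  dep
}

#' Write a deposition event list to a columnar text file
#'
#' @param events event data.frame from [simulate_exposure()].
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, c("primary", "px", "py", "energy", "time")],
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
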