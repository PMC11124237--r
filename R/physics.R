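# Bundled photon-interaction physics: elemental mass attenuation
# coefficients by process, K-shell fluorescence data, and material mixtures.
# Tables live under inst/extdata/attenuation/ (see the file headers for
# provenance) on a log energy grid, 1-300 keV, split at K edges.

.pcd <- new.env(parent = emptyenv())

att_dir <- function() system.file("extdata", "attenuation",
                                  package = "pcdpileup", mustWork = TRUE)

#' Elemental attenuation table
#'
#' Loads (and caches) the bundled table for one element: mass attenuation
#' coefficients in cm^2/g for the total, photoelectric, incoherent and
#' coherent processes on an energy grid in keV.
#'
#' @param symbol element symbol, e.g. `"Cd"`.
#' @return a data.frame with columns `energy`, `total`, `photoelectric`,
#'   `incoherent`, `coherent`.
#' @export
element_table <- function(symbol) {
  key <- paste0("el.", symbol)
  if (!is.null(.pcd[[key]])) return(.pcd[[key]])
  path <- file.path(att_dir(), paste0(symbol, ".txt"))
  if (!file.exists(path))
    stop("no bundled attenuation table for element '", symbol, "'")
  d <- utils::read.table(path, col.names = c("energy", "total",
                                             "photoelectric", "incoherent",
                                             "coherent"))
  .pcd[[key]] <- d
  d
}

#' K-shell fluorescence data for an element
#'
#' @param element element symbol.
#' @return a list with `k_edge` (keV), `omega_k` (K fluorescence yield),
#'   `k_fraction` (K-shell share of the photoelectric cross section above
#'   the edge, from the edge jump ratio), and `lines`, a data.frame of
#'   K-line energies (keV) and relative emission probabilities (sum 1).
#' @export
fluorescence <- function(element) {
  if (is.null(.pcd$kfluo)) {
    d <- utils::read.table(file.path(att_dir(), "k_fluorescence.txt"),
                           col.names = c("element", "k_edge", "omega_k",
                                         "k_fraction", "line_kev",
                                         "line_prob"))
    .pcd$kfluo <- d
  }
  d <- .pcd$kfluo[.pcd$kfluo$element == element, ]
  if (nrow(d) == 0)
    stop("no bundled K-shell data for element '", element, "'")
  list(k_edge = d$k_edge[1], omega_k = d$omega_k[1],
       k_fraction = d$k_fraction[1],
       lines = data.frame(energy = d$line_kev, probability = d$line_prob))
}

# log-log interpolation of one elemental process column; the grid is split
# at absorption edges so interpolation never bridges a jump.
element_mu <- function(symbol, energy, process = "total") {
  d <- element_table(symbol)
  if (any(energy < d$energy[1] | energy > d$energy[nrow(d)]))
    stop("energy outside the bundled table range (",
         signif(d$energy[1], 3), "-", signif(d$energy[nrow(d)], 3), " keV)")
  y <- d[[process]]
  if (is.null(y)) stop("unknown process '", process, "'")
  exp(stats::approx(log(d$energy), log(pmax(y, 1e-300)),
                    xout = log(energy), rule = 2)$y)
}

#' Define a material from elemental mass fractions
#'
#' Fractions are normalized to sum to exactly 1 on construction.
#'
#' @param composition named numeric vector of mass fractions by element
#'   symbol, e.g. `c(I = 0.2308, O = 0.6832, H = 0.0861)`.
#' @param density mass density in g/cm^3.
#' @param name optional material name.
#' @return an object of class `material_spec`.
#' @examples
#' water <- mixture(c(H = 2 * 1.008, O = 15.999) / (2 * 1.008 + 15.999), 1.0)
#' @export
mixture <- function(composition, density = NA_real_, name = "mixture") {
  if (length(composition) == 0) stop("empty composition")
  if (is.null(names(composition)) || any(names(composition) == ""))
    stop("composition must be a named vector of mass fractions")
  if (any(composition <= 0)) stop("mass fractions must be strictly positive")
  for (el in names(composition)) element_table(el)  # errors on unknown symbol
  if (!is.na(density) && density <= 0) stop("density must be positive")
  structure(list(name = name,
                 elements = names(composition),
                 fractions = as.numeric(composition) / sum(composition),
                 density = density),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat("<material>", x$name, "  density:", x$density, "g/cm^3\n")
  cat(paste0("  ", x$elements, ": ", signif(x$fractions, 5),
             collapse = "\n"), "\n")
  invisible(x)
}

# Registry of built-in materials (density g/cm^3, mass composition).
# CZT is Cd0.9Zn0.1Te; the scintillator is LaBr3 with 5% of the La sites
# occupied by Ce. Lesion material is an aqueous iodine solution.
builtin_materials <- function() {
  amu <- c(H = 1.008, C = 12.011, O = 15.999, F = 18.998403,
           Zn = 65.38, Br = 79.904, Cd = 112.411, Te = 127.6,
           La = 138.90547, Ce = 140.116)
  czt <- c(Cd = 0.9 * amu[["Cd"]], Zn = 0.1 * amu[["Zn"]],
           Te = amu[["Te"]])
  labr <- c(La = 0.95 * amu[["La"]], Ce = 0.05 * amu[["Ce"]],
            Br = 3 * amu[["Br"]])
  water <- c(H = 2 * amu[["H"]], O = amu[["O"]])
  ptfe <- c(C = 2 * amu[["C"]], F = 4 * amu[["F"]])
  list(
    water       = mixture(water / sum(water), 1.000, "water"),
    CZT         = mixture(czt / sum(czt), 5.78, "CZT"),
    `LaBr3:Ce`  = mixture(labr / sum(labr), 5.29, "LaBr3:Ce"),
    PTFE        = mixture(ptfe / sum(ptfe), 2.20, "PTFE"),
    aluminium   = mixture(c(Al = 1), 2.699, "aluminium"),
    copper      = mixture(c(Cu = 1), 8.96, "copper"),
    beryllium   = mixture(c(Be = 1), 1.848, "beryllium"),
    iodine_lesion = mixture(c(I = 0.2308, O = 0.6832, H = 0.0861), 1.23,
                            "iodine_lesion")
  )
}

#' Look up a built-in material by name
#'
#' @param name one of `"water"`, `"CZT"`, `"LaBr3:Ce"`, `"PTFE"`,
#'   `"aluminium"`, `"copper"`, `"beryllium"`, `"iodine_lesion"`.
#' @return a `material_spec`.
#' @export
material <- function(name) {
  if (is.null(.pcd$materials)) .pcd$materials <- builtin_materials()
  m <- .pcd$materials[[name]]
  if (is.null(m)) stop("unknown material '", name, "'; see ?material")
  m
}

#' Mass attenuation coefficient of a material
#'
#' Mass-fraction-weighted sum of the elemental coefficients, interpolated
#' log-log on the bundled grids (split at absorption edges).
#'
#' @param material a `material_spec` (or built-in material name).
#' @param energy photon energy in keV (vectorized); must lie within the
#'   bundled table range, 1-300 keV.
#' @param process one of `"total"`, `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`.
#' @return mass attenuation coefficient(s) in cm^2/g.
#' @export
mass_attenuation <- function(material, energy, process = "total") {
  if (is.character(material)) material <- material(material)
  mu <- 0
  for (i in seq_along(material$elements))
    mu <- mu + material$fractions[i] *
      element_mu(material$elements[i], energy, process)
  mu
}

#' Photon transmission through a material slab
#'
#' Beer-Lambert probability that a photon passes a slab of the given
#' thickness without any interaction.
#'
#' @inheritParams mass_attenuation
#' @param thickness slab thickness in mm.
#' @return transmission probability in (0, 1] (vectorized over energy).
#' @export
transmission <- function(material, thickness, energy) {
  if (is.character(material)) material <- material(material)
  if (thickness < 0) stop("negative thickness")
  if (is.na(material$density)) stop("material has no density")
  mu <- mass_attenuation(material, energy, "total") * material$density  # 1/cm
  exp(-mu * thickness / 10)
}
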