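#' Ion species
#'
#' Light-weight identity of a primary ion or nuclear fragment: a text symbol,
#' atomic number `Z` and mass number `A`. Kinematics throughout the package are
#' bookkept in kinetic energy per nucleon (MeV/n), so `A` is needed whenever a
#' total energy or a range is formed.
#'
#' @param symbol Short text label, e.g. `"12C"`.
#' @param Z Integer atomic number (>= 1).
#' @param A Integer mass number (>= Z).
#' @return An object of class `ion_species`.
#' @examples
#' carbon <- ion_species("12C", 6, 12)
#' carbon
#' @export
ion_species <- function(symbol, Z, A) {
  stopifnot(is.character(symbol), length(symbol) == 1L)
  Z <- as.integer(Z); A <- as.integer(A)
  if (is.na(Z) || Z < 1L) stop("Z must be a positive integer")
  if (is.na(A) || A < Z) stop("A must be an integer >= Z")
  structure(list(symbol = symbol, Z = Z, A = A), class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s (Z=%d, A=%d)\n", x$symbol, x$Z, x$A))
  invisible(x)
}

#' @export
format.ion_species <- function(x, ...) x$symbol

species_key <- function(species) sprintf("Z%d_A%d", species$Z, species$A)

#' The six primary beam species of the comparison study
#'
#' Protons through carbon-12, selected for stability and abundance:
#' 1H, 4He, 7Li, 10Be, 10B, 12C.
#'
#' @return Named list of [ion_species] objects.
#' @examples
#' names(beam_species())
#' @export
beam_species <- function() {
  list(
    `1H`   = ion_species("1H",   1L, 1L),
    `4He`  = ion_species("4He",  2L, 4L),
    `7Li`  = ion_species("7Li",  3L, 7L),
    `10Be` = ion_species("10Be", 4L, 10L),
    `10B`  = ion_species("10B",  5L, 10L),
    `12C`  = ion_species("12C",  6L, 12L)
  )
}

#' Fragment species used by the fragmentation model
#'
#' @return Named list of [ion_species] objects for the light fragments the
#'   default fragmentation configuration can produce.
#' @export
fragment_species <- function() {
  list(
    `1H`   = ion_species("1H",  1L, 1L),
    `2H`   = ion_species("2H",  1L, 2L),
    `3H`   = ion_species("3H",  1L, 3L),
    `3He`  = ion_species("3He", 2L, 3L),
    `4He`  = ion_species("4He", 2L, 4L),
    `6Li`  = ion_species("6Li", 3L, 6L),
    `7Li`  = ion_species("7Li", 3L, 7L),
    `9Be`  = ion_species("9Be", 4L, 9L),
    `11B`  = ion_species("11B", 5L, 11L)
  )
}

# Atomic rest energy per nucleon (MeV); a single rounded value is used for all
# species since binding-energy differences are irrelevant at this precision.
.M_NUCLEON <- 931.494

#' Relativistic speed from kinetic energy per nucleon
#'
#' @param energy Kinetic energy per nucleon (MeV/n).
#' @return beta = v/c, in (0, 1).
#' @export
beta_from_energy <- function(energy) {
  stopifnot(all(energy > 0))
  gamma <- 1 + energy / .M_NUCLEON
  sqrt(1 - 1 / gamma^2)
}

#' Barkas effective charge
#'
#' Z_eff = Z (1 - exp(-125 beta Z^(-2/3))): at high velocity an ion is fully
#' stripped (Z_eff -> Z); near the end of range electron pickup lowers the net
#' charge and hence the stopping power.
#'
#' @param Z Atomic number.
#' @param energy Kinetic energy per nucleon (MeV/n).
#' @return Effective charge (same length as `energy`).
#' @export
effective_charge <- function(Z, energy) {
  beta <- beta_from_energy(energy)
  Z * (1 - exp(-125 * beta * Z^(-2 / 3)))
}
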