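#' Per-depth scalar profile
#'
#' A depth-indexed curve (dose, dose-averaged LET, RBE or biological dose) on
#' a [depth_grid]. Bins where the quantity is undefined (e.g. LET where the
#' dose is zero) carry `NA`, never a fabricated 0.
#'
#' @param grid A [depth_grid].
#' @param values One value per depth bin; `NA` marks undefined bins.
#' @param quantity Label: `"dose"`, `"LET_d"`, `"RBE"` or `"bio_dose"`.
#' @param units Unit label.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(grid, values, quantity = "dose", units = "relative") {
  stopifnot(inherits(grid, "depth_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_bins)
    stop("values length must equal grid n_bins")
  if (any(values < 0, na.rm = TRUE))
    stop(sprintf("%s values must be non-negative", quantity))
  structure(list(grid = grid, values = values, quantity = quantity,
                 units = units),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  ok <- !is.na(x$values)
  cat(sprintf("<depth_profile> %s [%s]: %d bins (%d defined), max %.4g\n",
              x$quantity, x$units, x$grid$n_bins, sum(ok),
              if (any(ok)) max(x$values[ok]) else NA_real_))
  invisible(x)
}

#' @param x A `depth_profile`.
#' @param ... Passed to [graphics::plot()].
#' @rdname depth_profile
#' @export
plot.depth_profile <- function(x, ...) {
  graphics::plot(x$grid$depths, x$values, type = "l",
                 xlab = "depth (mm)", ylab = sprintf("%s (%s)", x$quantity, x$units),
                 ...)
  invisible(x)
}

# Stopping power at the energy-bin centers for every species of a map:
# matrix [n_bins x n_species].
sp_matrix <- function(map, provider) {
  centers <- bin_centers(map$energy_edges)
  S <- vapply(map$species,
              function(s) stopping_power(provider, s, centers),
              numeric(length(centers)))
  matrix(S, nrow = length(centers))
}

#' Dose from fluence
#'
#' D(E_j, Z_i) = Phi(E_j, Z_i) * dE/dx(E_j, Z_i), elementwise at the
#' energy-bin centers; linear in the fluence.
#'
#' @param map A [fluence_map].
#' @param provider An [sp_provider].
#' @return Array `[n_depth, n_bins, n_species]` of dose contributions
#'   (relative units), with the stopping-power matrix attached as attribute
#'   `"sp"`.
#' @export
dose_from_fluence <- function(map, provider) {
  stopifnot(inherits(map, "fluence_map"))
  S <- sp_matrix(map, provider)
  d <- dim(map$phi)
  out <- array(0, d)
  for (i in seq_len(d[3])) {
    phi_i <- matrix(map$phi[, , i, drop = FALSE], nrow = d[1])
    out[, , i] <- sweep(phi_i, 2, S[, i], "*")
  }
  attr(out, "sp") <- S
  out
}

#' Dose-averaged LET at one depth
#'
#' LET_d = sum_ij D(E_j, Z_i) S(E_j, Z_i) / sum_ij D(E_j, Z_i): the
#' dose-weighted mean stopping power over every species and energy bin
#' contributing at the depth. Invariant under uniform rescaling of the
#' fluence and bounded by the min and max stopping power of the contributing
#' cells. Zero total dose yields `NA` (undefined), not 0.
#'
#' @param map A [fluence_map].
#' @param provider An [sp_provider].
#' @param depth_index Depth-bin index.
#' @return LET_d in keV/um, or `NA` if no dose is deposited in the bin.
#' @export
dose_averaged_let <- function(map, provider, depth_index) {
  dose3 <- dose_from_fluence(map, provider)
  .let_at(dose3, attr(dose3, "sp"), depth_index)
}

.let_at <- function(dose3, S, depth_index) {
  D <- dose3[depth_index, , , drop = FALSE][1, , , drop = TRUE]
  D <- matrix(D, nrow = dim(dose3)[2])
  den <- sum(D)
  if (den <= 0) return(NA_real_)
  sum(D * S) / den
}

#' Dose-averaged LET versus depth
#'
#' Applies [dose_averaged_let()] per depth bin; zero-dose bins are `NA`.
#'
#' @param map A [fluence_map].
#' @param provider An [sp_provider].
#' @return A [depth_profile] with quantity `"LET_d"` (keV/um).
#' @export
let_profile <- function(map, provider) {
  dose3 <- dose_from_fluence(map, provider)
  S <- attr(dose3, "sp")
  nd <- dim(dose3)[1]
  num <- numeric(nd); den <- numeric(nd)
  for (i in seq_len(dim(dose3)[3])) {
    Dm <- matrix(dose3[, , i, drop = FALSE][, , 1], nrow = nd)
    num <- num + drop(Dm %*% S[, i])
    den <- den + rowSums(Dm)
  }
  vals <- ifelse(den > 0, num / den, NA_real_)
  depth_profile(map$grid, vals, "LET_d", "keV/um")
}
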