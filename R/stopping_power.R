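#' Stopping-power table for one species in water
#'
#' Holds linear stopping power in unit-density liquid water (keV/um, which is
#' numerically identical to MeV/mm) on a strictly ascending grid of kinetic
#' energy per nucleon. Queries between nodes use log-log linear interpolation;
#' queries outside the grid are an error, never an extrapolation.
#'
#' @param species An [ion_species].
#' @param energy Strictly ascending kinetic energies (MeV/n).
#' @param stopping Positive stopping powers (keV/um), one per energy.
#' @return An object of class `sp_table`.
#' @export
sp_table <- function(species, energy, stopping) {
  stopifnot(inherits(species, "ion_species"))
  energy <- as.numeric(energy); stopping <- as.numeric(stopping)
  if (length(energy) == 0L) stop("empty stopping-power table")
  if (length(energy) != length(stopping))
    stop("energy and stopping must have equal length")
  if (any(!is.finite(energy)) || any(!is.finite(stopping)))
    stop("non-finite value in stopping-power table")
  if (any(diff(energy) <= 0)) stop("energy grid must be strictly ascending")
  if (any(stopping <= 0)) stop("stopping power must be positive")
  structure(list(species = species, energy = energy, stopping = stopping),
            class = "sp_table")
}

#' @export
print.sp_table <- function(x, ...) {
  cat(sprintf("<sp_table> %s: %d nodes, %.4g-%.4g MeV/n, %.4g-%.4g keV/um\n",
              x$species$symbol, length(x$energy),
              min(x$energy), max(x$energy),
              min(x$stopping), max(x$stopping)))
  invisible(x)
}

# log-log linear interpolation with hard range checking
loglog_interp <- function(xgrid, ygrid, x, what = "value") {
  if (any(x < min(xgrid) | x > max(xgrid)))
    stop(sprintf("%s query outside table range [%g, %g]",
                 what, min(xgrid), max(xgrid)))
  exp(stats::approx(log(xgrid), log(ygrid), xout = log(x), ties = "ordered")$y)
}

#' Interpolate stopping power from a table
#'
#' @param table An [sp_table].
#' @param energy Kinetic energy per nucleon (MeV/n), inside the table grid.
#' @return Stopping power (keV/um).
#' @export
sp_interp <- function(table, energy) {
  stopifnot(inherits(table, "sp_table"))
  loglog_interp(table$energy, table$stopping, energy,
                sprintf("stopping power (%s)", table$species$symbol))
}

#' Read a NIST-layout stopping-power table
#'
#' Parses the ASCII layout of the PSTAR/ASTAR/MSTAR databases: an arbitrary
#' header block followed by whitespace-separated numeric columns. The first
#' column is kinetic energy (MeV, or MeV/n via `energy_unit`), and the
#' stopping-power column is either the total (default, 4th column when the
#' file carries collision/nuclear/total columns) or the collision-only
#' (electronic) one. Mass stopping powers (MeV cm^2/g) are converted to
#' linear stopping power in unit-density water (keV/um) at load time.
#'
#' @param source Path or connection to the table, or a character vector of
#'   lines.
#' @param species The [ion_species] the table describes.
#' @param energy_unit `"MeV"` (total kinetic energy, divided by A) or
#'   `"MeV/n"`.
#' @param column `"total"` or `"collision"`; which stopping-power column feeds
#'   the dose/LET formulas.
#' @return An [sp_table].
#' @export
load_nist_table <- function(source, species,
                            energy_unit = c("MeV", "MeV/n"),
                            column = c("total", "collision")) {
  energy_unit <- match.arg(energy_unit)
  column <- match.arg(column)
  lines <- if (is.character(source) && length(source) > 1L) source
           else readLines(source)
  lines <- trimws(lines)
  is_numeric_row <- function(ln) {
    if (!nzchar(ln)) return(FALSE)
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    all(!is.na(suppressWarnings(as.numeric(toks))))
  }
  numeric_mask <- vapply(lines, is_numeric_row, logical(1), USE.NAMES = FALSE)
  first <- which(numeric_mask)[1]
  if (is.na(first)) stop("no numeric rows found in NIST-layout table")
  body_idx <- first:length(lines)
  body_idx <- body_idx[nzchar(lines[body_idx])]
  bad <- body_idx[!numeric_mask[body_idx]]
  if (length(bad))
    stop(sprintf("malformed numeric row at line %d: '%s'", bad[1], lines[bad[1]]))
  rows <- lapply(lines[body_idx],
                 function(ln) as.numeric(strsplit(ln, "[[:space:]]+")[[1]]))
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L)
    stop("inconsistent column count across numeric rows")
  mat <- do.call(rbind, rows)
  energy <- mat[, 1]
  sp_col <- if (column == "collision") 2L else if (ncols >= 4L) 4L else 2L
  mass_sp <- mat[, sp_col]
  if (any(diff(energy) <= 0)) stop("energy column is not strictly ascending")
  if (energy_unit == "MeV") energy <- energy / species$A
  # MeV cm^2/g at rho = 1 g/cm^3 -> MeV/cm -> keV/um (= MeV/mm): factor 0.1
  sp_table(species, energy, mass_sp * 0.1)
}

#' Read / write the package's CSV fixture format
#'
#' Columns: `energy_MeV_per_n`, `stopping_keV_per_um`. Species identity is
#' carried in the header comment line `# species,Z,A`.
#'
#' @param path File path.
#' @param table An [sp_table] (for writing).
#' @return `read_sp_table()` returns an [sp_table]; `write_sp_table()` its
#'   path, invisibly.
#' @export
read_sp_table <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("fixture table must start with a '# symbol,Z,A' header line")
  meta <- strsplit(sub("^#\\s*", "", header), ",")[[1]]
  species <- ion_species(meta[1], as.integer(meta[2]), as.integer(meta[3]))
  dat <- utils::read.csv(path, comment.char = "#")
  sp_table(species, dat$energy_MeV_per_n, dat$stopping_keV_per_um)
}

#' @rdname read_sp_table
#' @export
write_sp_table <- function(table, path) {
  stopifnot(inherits(table, "sp_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s,%d,%d", table$species$symbol,
                     table$species$Z, table$species$A), con)
  writeLines("energy_MeV_per_n,stopping_keV_per_um", con)
  writeLines(sprintf("%.17g,%.17g", table$energy, table$stopping), con)
  invisible(path)
}

#' Effective-charge scaling of the proton stopping power
#'
#' Fallback for species without a bundled table: S(E) = S_p(E) * Z_eff^2 with
#' the Barkas effective charge, evaluated at the same energy per nucleon.
#'
#' @param species Target [ion_species].
#' @param energy Kinetic energy per nucleon (MeV/n).
#' @param proton_table [sp_table] for protons covering `energy`.
#' @return Stopping power (keV/um).
#' @export
effective_charge_stopping <- function(species, energy, proton_table) {
  stopifnot(inherits(proton_table, "sp_table"),
            proton_table$species$Z == 1L)
  sp_interp(proton_table, energy) * effective_charge(species$Z, energy)^2
}

#' Stopping-power provider
#'
#' Bundles the loaded per-species tables with the proton table used for
#' effective-charge fallback and caches range-energy fits. The default
#' provider loads the synthetic fixture tables shipped under
#' `inst/extdata/` (a coarse parameterization approximating published water
#' stopping powers; constructed, not NIST data).
#'
#' @param tables List of [sp_table] objects; must include a proton table.
#' @return An object of class `sp_provider`.
#' @export
sp_provider <- function(tables) {
  stopifnot(length(tables) > 0L,
            all(vapply(tables, inherits, logical(1), "sp_table")))
  keys <- vapply(tables, function(t) species_key(t$species), character(1))
  names(tables) <- keys
  proton <- tables[["Z1_A1"]]
  if (is.null(proton)) stop("provider requires a proton (Z=1, A=1) table")
  structure(list(tables = tables, proton = proton,
                 fits = new.env(parent = emptyenv())),
            class = "sp_provider")
}

#' @export
print.sp_provider <- function(x, ...) {
  cat(sprintf("<sp_provider> %d species tables: %s\n", length(x$tables),
              paste(vapply(x$tables, function(t) t$species$symbol,
                           character(1)), collapse = ", ")))
  invisible(x)
}

#' @rdname sp_provider
#' @export
default_sp_provider <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- system.file("extdata", package = "sobpr")
    paths <- list.files(dir, pattern = "^stopping_power_.*_synthetic\\.csv$",
                        full.names = TRUE)
    cache <<- sp_provider(lapply(paths, read_sp_table))
    cache
  }
})

#' Stopping power for any species through a provider
#'
#' Uses the species' own table when loaded, otherwise Barkas effective-charge
#' scaling of the proton table.
#'
#' @param provider An [sp_provider].
#' @param species An [ion_species].
#' @param energy Kinetic energy per nucleon (MeV/n).
#' @return Stopping power (keV/um).
#' @export
stopping_power <- function(provider, species, energy) {
  stopifnot(inherits(provider, "sp_provider"))
  tab <- provider$tables[[species_key(species)]]
  if (!is.null(tab)) sp_interp(tab, energy)
  else effective_charge_stopping(species, energy, provider$proton)
}

#' CSDA range by integrating a stopping-power curve
#'
#' R(E) = A * integral_0^E dE'/S(E') with S in keV/um (= MeV/mm), giving the
#' continuous-slowing-down range in mm of water. The integral below the lowest
#' grid node (a sub-0.1 mm contribution) is closed with a linear-stopping
#' approximation.
#'
#' @param provider An [sp_provider].
#' @param species An [ion_species].
#' @param energy Energies per nucleon at which ranges are wanted (MeV/n).
#' @param n_steps Resolution of the log-spaced integration grid.
#' @return Ranges (mm), same length as `energy`.
#' @export
csda_range <- function(provider, species, energy, n_steps = 600) {
  e_lo <- 0.025
  e_hi <- max(energy)
  grid <- exp(seq(log(e_lo), log(e_hi), length.out = n_steps))
  grid[length(grid)] <- e_hi  # guard against rounding below the top query
  s <- stopping_power(provider, species, grid)
  r <- species$A * c(0, pracma::cumtrapz(grid, 1 / s))
  # below e_lo assume S ~ const: residual path = A * e_lo / S(e_lo)
  r0 <- species$A * e_lo / s[1]
  loglog_interp(grid, r[-1] + r0, energy, "csda range")
}

#' Bragg-Kleeman range-energy fit
#'
#' Fits R = alpha * (A*E)^p to the CSDA ranges of a species over the
#' therapeutic window (10-500 MeV/n by default). The convention is fixed to
#' total kinetic energy A*E (MeV) inside the power law, with E per nucleon at
#' the interface; alpha in mm/MeV^p.
#'
#' @param provider An [sp_provider].
#' @param species An [ion_species].
#' @param e_window Energy-per-nucleon window (MeV/n) the fit is anchored on.
#' @return An object of class `range_energy_fit` with fields `species`,
#'   `alpha`, `p`.
#' @export
fit_range_energy <- function(provider, species, e_window = c(20, 300)) {
  key <- species_key(species)
  cached <- get0(key, envir = provider$fits, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  e <- exp(seq(log(e_window[1]), log(e_window[2]), length.out = 40))
  r <- csda_range(provider, species, e)
  fit <- stats::lm(log(r) ~ log(species$A * e))
  alpha <- exp(unname(stats::coef(fit)[1]))
  p <- unname(stats::coef(fit)[2])
  if (!(alpha > 0)) stop("range-energy fit produced non-positive alpha")
  if (!(p > 1 && p < 2)) stop(sprintf("range-energy exponent %.3f outside (1, 2)", p))
  out <- structure(list(species = species, alpha = alpha, p = p),
                   class = "range_energy_fit")
  assign(key, out, envir = provider$fits)
  out
}

#' @export
print.range_energy_fit <- function(x, ...) {
  cat(sprintf("<range_energy_fit> %s: R = %.4g * (A*E)^%.4f mm\n",
              x$species$symbol, x$alpha, x$p))
  invisible(x)
}

#' Range from energy and its inverse
#'
#' `range_from_energy()` evaluates R = alpha*(A*E)^p (mm of water);
#' `energy_from_range()` inverts it. Round-trips are exact to floating-point
#' precision.
#'
#' @param fit A `range_energy_fit`.
#' @param energy Kinetic energy per nucleon (MeV/n), > 0.
#' @param range Range (mm), > 0.
#' @return Range in mm, or energy in MeV/n.
#' @export
range_from_energy <- function(fit, energy) {
  stopifnot(inherits(fit, "range_energy_fit"))
  if (any(energy <= 0)) stop("energy must be positive")
  fit$alpha * (fit$species$A * energy)^fit$p
}

#' @rdname range_from_energy
#' @export
energy_from_range <- function(fit, range) {
  stopifnot(inherits(fit, "range_energy_fit"))
  if (any(range <= 0)) stop("range must be positive")
  (range / fit$alpha)^(1 / fit$p) / fit$species$A
}
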