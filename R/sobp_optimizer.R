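#' SOBP plan
#'
#' The weight vector over a beam library's mono-energetic peaks, together
#' with the optimization mode and prescription it was solved for.
#'
#' @param library A [beam_library] (identity is retained as species +
#'   energies).
#' @param weights Non-negative weights, one per peak, at least one positive.
#' @param mode `"physical"` or `"biological"`.
#' @param prescription Target dose level (relative units).
#' @param region Target interval `c(proximal, distal)` in mm.
#' @return An object of class `sobp_plan`.
#' @export
sobp_plan <- function(library, weights, mode = c("physical", "biological"),
                      prescription = 100, region = c(80, 130)) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "beam_library"))
  weights <- as.numeric(weights)
  if (length(weights) != length(library$peaks))
    stop("one weight per library peak required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!any(weights > 0)) stop("at least one weight must be positive")
  phantom <- library$grid$n_bins * library$grid$resolution
  if (region[1] >= region[2] || region[2] > phantom)
    stop("target region must lie inside the phantom")
  structure(list(species = library$species, energies = library$energies,
                 weights = weights, mode = mode,
                 prescription = prescription, region = region),
            class = "sobp_plan")
}

#' @export
print.sobp_plan <- function(x, ...) {
  cat(sprintf("<sobp_plan> %s, %s mode: %d beams, region %g-%g mm, prescription %g\n",
              x$species$symbol, x$mode, length(x$weights),
              x$region[1], x$region[2], x$prescription))
  invisible(x)
}

region_bins <- function(grid, region) {
  which(grid$depths > region[1] & grid$depths < region[2])
}

# columns = per-peak depth-dose restricted to the region bins
dose_matrix <- function(library, bins) {
  A <- vapply(library$peaks, function(p) p$dose[bins],
              numeric(length(bins)))
  matrix(A, nrow = length(bins))
}

#' Minimum-norm non-negative least squares
#'
#' Solves min ||A f - b||^2, f >= 0. Overlapping Bragg-peak columns are
#' nearly collinear, so many weight vectors reach almost the same residual;
#' an active-set solver alone can then return solutions with arbitrarily
#' inflated (all-positive) weights. The tie is broken toward the
#' minimum-norm solution by a small ridge term `ridge * s^2 * ||f||^2`, with
#' `s^2` the mean squared column norm of A, far below the residual scale.
#'
#' @param A Design matrix (region bins x beams).
#' @param b Target vector.
#' @param ridge Relative ridge weight.
#' @return Non-negative weight vector.
#' @export
nnls_weights <- function(A, b, ridge = 1e-4) {
  stopifnot(is.matrix(A), nrow(A) == length(b), ridge >= 0)
  if (ridge > 0) {
    s <- sqrt(mean(colSums(A^2)))
    A <- rbind(A, sqrt(ridge) * s * diag(ncol(A)))
    b <- c(b, rep(0, ncol(A)))
  }
  pracma::lsqnonneg(A, b)$x
}

check_flatness <- function(dose_vals, bins, prescription, window,
                           on_infeasible, mode) {
  pct <- 100 * dose_vals[bins] / prescription
  bad <- bins[pct < window[1] | pct > window[2]]
  if (length(bad)) {
    msg <- sprintf(
      "%s optimization infeasible: achieved [%.2f, %.2f]%% of prescription; %d violating bins (first at bin %d)",
      mode, min(pct), max(pct), length(bad), bad[1])
    if (on_infeasible == "error") stop(msg) else warning(msg)
  }
  invisible(c(min(pct), max(pct)))
}

#' Physically flat SOBP weights
#'
#' Solves min ||A f - p||^2 subject to f >= 0 by non-negative least squares,
#' where A's columns are the library's per-peak depth-dose curves restricted
#' to the target-region bins and p is the flat prescription. The resulting
#' dose must lie within the homogeneity window (95-107% of prescription by
#' default) at every region bin, otherwise the optimization is reported
#' infeasible together with the achieved range.
#'
#' @param library A [beam_library].
#' @param region Target interval `c(proximal, distal)` in mm.
#' @param prescription Target dose level (relative units).
#' @param window Homogeneity window in % of prescription.
#' @param on_infeasible `"error"` (default) or `"warn"`.
#' @param ridge Minimum-norm tie-break weight passed to [nnls_weights()].
#' @return An [sobp_plan] with mode `"physical"`.
#' @export
optimize_physical <- function(library, region = c(80, 130), prescription = 100,
                              window = c(95, 107),
                              on_infeasible = c("error", "warn"),
                              ridge = 1e-4) {
  on_infeasible <- match.arg(on_infeasible)
  bins <- region_bins(library$grid, region)
  if (!length(bins)) stop("target region contains no depth bins")
  A <- dose_matrix(library, bins)
  w <- nnls_weights(A, rep(prescription, length(bins)), ridge)
  plan <- sobp_plan(library, w, "physical", prescription, region)
  dose <- mixed_field(plan, library)$dose
  check_flatness(dose$values, bins, prescription, window, on_infeasible,
                 "physical")
  plan
}

#' Biologically flat SOBP weights
#'
#' Fixed-point iteration on the weights: starting from the physical plan,
#' compute the mixed-field RBE_DSB profile for the current weights, re-solve
#' the non-negative least squares against per-bin targets
#' prescription / RBE(d), and repeat until the maximum relative weight change
#' falls below `tol`. The converged plan's biological dose
#' (physical dose x RBE) is required to lie within the homogeneity window.
#'
#' @param library A [beam_library].
#' @param region,prescription,window,on_infeasible As [optimize_physical()].
#' @param yield_model A [dsb_yield_model].
#' @param provider An [sp_provider].
#' @param tol Relative weight-change convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   residual history.
#' @param start Optional starting plan (defaults to the physical solution).
#' @param ridge Minimum-norm tie-break weight passed to [nnls_weights()].
#' @return An [sobp_plan] with mode `"biological"` and attribute
#'   `"iterations"`.
#' @export
optimize_biological <- function(library, region = c(80, 130),
                                prescription = 100,
                                yield_model = default_yield_model(),
                                provider = default_sp_provider(),
                                tol = 1e-3, max_iter = 50,
                                window = c(95, 107),
                                on_infeasible = c("error", "warn"),
                                start = NULL, ridge = 1e-4) {
  on_infeasible <- match.arg(on_infeasible)
  stopifnot(tol > 0)
  bins <- region_bins(library$grid, region)
  A <- dose_matrix(library, bins)
  if (is.null(start))
    start <- optimize_physical(library, region, prescription,
                               window = c(0, Inf))
  w <- start$weights
  history <- numeric(0)
  for (iter in seq_len(max_iter)) {
    field <- mixed_field(w, library)
    rbe <- rbe_profile(field$fluence, yield_model, provider)
    r <- rbe$total$values[bins]
    if (any(is.na(r)))
      stop("RBE undefined at target-region bins; cannot optimize biologically")
    target <- prescription / r
    w_new <- nnls_weights(A, target, ridge)
    delta <- max(abs(w_new - w)) / max(w_new, 1e-300)
    history <- c(history, delta)
    w <- w_new
    if (delta < tol) break
  }
  if (history[length(history)] >= tol)
    stop(sprintf(
      "biological optimization did not converge in %d iterations (last delta %.3g; history: %s)",
      max_iter, history[length(history)],
      paste(signif(history, 3), collapse = ", ")))
  plan <- sobp_plan(library, w, "biological", prescription, region)
  prof <- sobp_dose_profiles(plan, library, yield_model, provider)
  check_flatness(prof$biological$values, bins, prescription, window,
                 on_infeasible, "biological")
  attr(plan, "iterations") <- length(history)
  plan
}

#' Flatness and width metrics of a depth-dose curve
#'
#' Reports the min/max dose over the region (in % of prescription), the
#' 95%-to-95% width from linear interpolation of the crossings, the
#' SOBP-mean to entrance-dose ratio (entrance = mean of the first
#' `entrance_bins` bins) and the tail ratio (mean dose 2-10 mm past the
#' distal edge over the prescription).
#'
#' @param dose A [depth_profile] of physical or biological dose.
#' @param region Target interval `c(proximal, distal)` in mm.
#' @param prescription Target dose level; must be positive.
#' @param entrance_bins Number of leading bins averaged for the entrance dose.
#' @return An object of class `flatness_report`: `min_pct`, `max_pct`,
#'   `width_mm`, `entrance_ratio`, `tail_ratio`, `degenerate` (TRUE when the
#'   curve never reaches 95% and the width is reported as 0).
#' @export
flatness_metrics <- function(dose, region = c(80, 130), prescription = 100,
                             entrance_bins = 5) {
  stopifnot(inherits(dose, "depth_profile"))
  if (prescription <= 0) stop("prescription must be positive")
  z <- dose$grid$depths
  v <- ifelse(is.na(dose$values), 0, dose$values)
  bins <- region_bins(dose$grid, region)
  pct <- 100 * v / prescription
  thr <- 95
  above <- pct >= thr
  degenerate <- !any(above)
  if (degenerate) {
    width <- 0
  } else {
    first <- which(above)[1]
    last <- which(above)[length(which(above))]
    # linear interpolation of the crossings just outside the >=95% run
    prox <- if (first == 1) z[1] else {
      z[first - 1] + (thr - pct[first - 1]) / (pct[first] - pct[first - 1]) *
        (z[first] - z[first - 1])
    }
    dist <- if (last == length(z)) z[length(z)] else {
      z[last] + (pct[last] - thr) / (pct[last] - pct[last + 1]) *
        (z[last + 1] - z[last])
    }
    width <- dist - prox
  }
  entrance <- mean(v[seq_len(entrance_bins)])
  tail_bins <- which(z > region[2] + 2 & z < region[2] + 10)
  structure(list(
    min_pct = min(pct[bins]), max_pct = max(pct[bins]),
    width_mm = width,
    entrance_ratio = mean(v[bins]) / entrance,
    tail_ratio = mean(v[tail_bins]) / prescription,
    degenerate = degenerate),
    class = "flatness_report")
}

#' @export
print.flatness_report <- function(x, ...) {
  cat(sprintf(
    "<flatness_report> [%.1f, %.1f]%% of prescription, width %.1f mm, SOBP/entrance %.2f, tail %.3f%s\n",
    x$min_pct, x$max_pct, x$width_mm, x$entrance_ratio, x$tail_ratio,
    if (x$degenerate) " (degenerate: never reaches 95%)" else ""))
  invisible(x)
}

#' Physical dose, RBE and biological dose of a plan
#'
#' D_bio(d) = D_phys(d) * RBE(d) bin-wise; depth bins with undefined RBE
#' (zero dose) yield an undefined biological dose.
#'
#' @param plan An [sobp_plan].
#' @param library The [beam_library] the plan was solved on.
#' @param yield_model A [dsb_yield_model].
#' @param provider An [sp_provider].
#' @return List of three [depth_profile]s: `physical`, `rbe`, `biological`,
#'   plus the `fluence` map of the mixed field.
#' @export
sobp_dose_profiles <- function(plan, library,
                               yield_model = default_yield_model(),
                               provider = default_sp_provider()) {
  field <- mixed_field(plan, library)
  rbe <- rbe_profile(field$fluence, yield_model, provider)
  bio <- field$dose$values * rbe$total$values
  list(physical = field$dose,
       rbe = rbe$total,
       biological = depth_profile(library$grid, bio, "bio_dose", "relative"),
       rbe_full = rbe,
       fluence = field$fluence)
}
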