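#' Study configuration
#'
#' Validated bundle of every knob the full comparison study needs. Defaults
#' reproduce the package's reference geometry: 1-mm grid through a 20-cm
#' water phantom, a 5-cm target lying at 8 cm depth (80-130 mm), flat
#' prescription 100.
#'
#' @param species Character vector of primary species symbols (subset of
#'   `names(beam_species())`).
#' @param resolution Depth-bin width (mm).
#' @param phantom_depth Phantom depth (mm).
#' @param target_region `c(proximal, distal)` in mm.
#' @param prescription Target dose level (relative units).
#' @param modes Optimization modes to run: `"physical"`, `"biological"` or
#'   both.
#' @param straggling_fraction,ripple_sigma Transport parameters; `NULL`
#'   (default) uses the per-species defaults
#'   ([default_straggling_fraction()], [default_ripple_sigma()]).
#' @param mask_helium_tail Mask 4He outputs beyond 2 mm past the distal edge
#'   (the region where a Monte Carlo tail estimate would be statistically
#'   unreliable); `FALSE` unmasks.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(species = names(beam_species()),
                         resolution = 1, phantom_depth = 200,
                         target_region = c(80, 130), prescription = 100,
                         modes = c("physical", "biological"),
                         straggling_fraction = NULL, ripple_sigma = NULL,
                         mask_helium_tail = TRUE,
                         log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  modes <- match.arg(modes, c("physical", "biological"), several.ok = TRUE)
  known <- names(beam_species())
  bad <- setdiff(species, known)
  if (length(bad))
    stop(sprintf("unsupported species: %s (supported: %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  stopifnot(resolution > 0, phantom_depth > 0,
            target_region[1] < target_region[2],
            target_region[2] < phantom_depth,
            prescription > 0)
  structure(list(species = species, resolution = resolution,
                 phantom_depth = phantom_depth,
                 target_region = target_region, prescription = prescription,
                 modes = modes, straggling_fraction = straggling_fraction,
                 ripple_sigma = ripple_sigma,
                 mask_helium_tail = mask_helium_tail,
                 log_level = log_level),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> species %s; region %g-%g mm; modes %s\n",
              paste(x$species, collapse = "/"),
              x$target_region[1], x$target_region[2],
              paste(x$modes, collapse = "+")))
  invisible(x)
}

study_log <- function(config, fmt, ...) {
  if (config$log_level == "info")
    message(sprintf("[sobpr] %s", sprintf(fmt, ...)))
}

mask_tail <- function(profile, distal, margin = 2) {
  profile$values[profile$grid$depths > distal + margin] <- NA_real_
  profile
}

#' Run the full beam-comparison study
#'
#' For every configured species: build the ripple-filtered beam library,
#' optimize the physical weights, derive depth-dose / LET_d / RBE_DSB
#' profiles, optionally optimize biologically, and collect flatness reports.
#' A stage failure aborts that species with a logged diagnostic; the other
#' species proceed.
#'
#' @param config A [study_config].
#' @param provider An [sp_provider].
#' @param yield_model A [dsb_yield_model].
#' @return An object of class `study_bundle`: per-species results under
#'   `$results[[symbol]]` (fields `library`, `physical_plan`, `pdd_physical`,
#'   `let`, `rbe`, `biological_plan`, `pdd_biological`, `flatness_physical`,
#'   `flatness_biological`, or `$error`), plus the config.
#' @export
run_beam_study <- function(config = study_config(),
                           provider = default_sp_provider(),
                           yield_model = default_yield_model()) {
  stopifnot(inherits(config, "study_config"))
  grid <- depth_grid(config$resolution,
                     round(config$phantom_depth / config$resolution))
  all_species <- beam_species()
  results <- list()
  for (sym in config$species) {
    res <- tryCatch({
      study_log(config, "building %s library", sym)
      sp_obj <- all_species[[sym]]
      sf <- if (is.null(config$straggling_fraction))
              default_straggling_fraction(sp_obj)
            else config$straggling_fraction
      lib <- build_library(sp_obj,
                           config$target_region[1], config$target_region[2],
                           grid, provider,
                           straggling_fraction = sf,
                           ripple_sigma = config$ripple_sigma)
      out <- list(library = lib)
      plan_p <- optimize_physical(lib, config$target_region,
                                  config$prescription)
      prof_p <- sobp_dose_profiles(plan_p, lib, yield_model, provider)
      out$physical_plan <- plan_p
      out$pdd_physical <- prof_p$physical
      out$let <- let_profile(prof_p$fluence, provider)
      out$rbe <- prof_p$rbe
      out$rbe_full <- prof_p$rbe_full
      out$flatness_physical <- flatness_metrics(prof_p$physical,
                                                config$target_region,
                                                config$prescription)
      study_log(config, "%s physical: [%.1f, %.1f]%%, width %.1f mm", sym,
                out$flatness_physical$min_pct, out$flatness_physical$max_pct,
                out$flatness_physical$width_mm)
      if ("biological" %in% config$modes) {
        plan_b <- optimize_biological(lib, config$target_region,
                                      config$prescription, yield_model,
                                      provider, start = plan_p)
        prof_b <- sobp_dose_profiles(plan_b, lib, yield_model, provider)
        out$biological_plan <- plan_b
        out$pdd_biological <- prof_b$biological
        out$pdd_biological_physical <- prof_b$physical
        out$rbe_biological <- prof_b$rbe
        out$flatness_biological <- flatness_metrics(prof_b$biological,
                                                    config$target_region,
                                                    config$prescription)
        study_log(config, "%s biological: [%.1f, %.1f]%%, %d iterations", sym,
                  out$flatness_biological$min_pct,
                  out$flatness_biological$max_pct,
                  attr(plan_b, "iterations"))
      }
      if (sym == "4He" && config$mask_helium_tail) {
        distal <- config$target_region[2]
        for (f in intersect(c("pdd_physical", "let", "rbe", "pdd_biological",
                              "pdd_biological_physical", "rbe_biological"),
                            names(out)))
          out[[f]] <- mask_tail(out[[f]], distal)
      }
      out
    }, error = function(e) {
      study_log(config, "species %s failed: %s", sym, conditionMessage(e))
      list(error = conditionMessage(e))
    })
    results[[sym]] <- res
  }
  structure(list(config = config, results = results), class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  ok <- names(Filter(function(r) is.null(r$error), x$results))
  failed <- setdiff(names(x$results), ok)
  cat(sprintf("<study_bundle> %d species completed (%s)%s\n", length(ok),
              paste(ok, collapse = ", "),
              if (length(failed)) sprintf("; failed: %s",
                                          paste(failed, collapse = ", "))
              else ""))
  invisible(x)
}

#' Ratio of two depth profiles after SOBP-center normalization
#'
#' Each profile is first normalized to 1 at the bin containing
#' `normalization_depth`; the per-bin ratio a/b is returned, exactly 1 at the
#' normalization bin and `NA` where either input is missing or the
#' denominator is zero.
#'
#' @param a,b [depth_profile]s on the same grid.
#' @param normalization_depth Depth (mm) of the normalization bin; 105 mm
#'   (the SOBP center of the reference geometry) by default.
#' @return An object of class `ratio_curve` (also a [depth_profile] with
#'   quantity `"ratio"`).
#' @export
ratio_curve <- function(a, b, normalization_depth = 105) {
  stopifnot(inherits(a, "depth_profile"), inherits(b, "depth_profile"))
  if (!same_grid(a$grid, b$grid)) stop("profiles are on different depth grids")
  k <- findInterval(normalization_depth, (0:a$grid$n_bins) * a$grid$resolution)
  if (k < 1 || k > a$grid$n_bins) stop("normalization depth outside grid")
  if (is.na(a$values[k]) || a$values[k] <= 0 ||
      is.na(b$values[k]) || b$values[k] <= 0)
    stop("profiles must be positive at the normalization bin")
  av <- a$values / a$values[k]
  bv <- b$values / b$values[k]
  vals <- ifelse(!is.na(bv) & bv > 0, av / bv, NA_real_)
  vals[k] <- 1
  out <- depth_profile(a$grid, vals, "ratio", "dimensionless")
  out$normalization_depth <- normalization_depth
  class(out) <- c("ratio_curve", class(out))
  out
}

profile_df <- function(profile, value_name) {
  df <- data.frame(depth_mm = profile$grid$depths, value = profile$values)
  names(df)[2] <- value_name
  df
}

write_profile_csv <- function(profile, path, value_name) {
  df <- profile_df(profile, value_name)
  df[[2]] <- ifelse(is.na(df[[2]]), NA, signif(df[[2]], 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Export a study bundle to CSV files
#'
#' Writes, per species: `pdd_physical`, `let_profile`, `rbe_profile`,
#' `pdd_biological`, `plan` and `flatness` CSVs; plus ratio curves of the
#' biologically optimized doses for the pairs 7Li/12C, 1H/12C and 4He/12C
#' (when the species are present) and a run manifest recording the config
#' echo and its hash. Profiles are written at 6 significant digits, missing
#' values as `NA`, one row per depth bin.
#'
#' @param bundle A `study_bundle` from [run_beam_study()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_study <- function(bundle, directory) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create output directory")
  files <- character(0)
  wr <- function(name) {
    path <- file.path(directory, name)
    files <<- c(files, path)
    path
  }
  for (sym in names(bundle$results)) {
    res <- bundle$results[[sym]]
    if (!is.null(res$error)) next
    tag <- gsub("[^0-9A-Za-z]", "", sym)
    write_profile_csv(res$pdd_physical, wr(sprintf("pdd_physical_%s.csv", tag)),
                      "dose_rel")
    write_profile_csv(res$let, wr(sprintf("let_profile_%s.csv", tag)),
                      "let_d_keV_per_um")
    write_profile_csv(res$rbe, wr(sprintf("rbe_profile_%s.csv", tag)),
                      "rbe_total")
    plan <- res$physical_plan
    utils::write.csv(
      data.frame(beam_index = seq_along(plan$weights),
                 nominal_energy_MeV_per_n = signif(plan$energies, 8),
                 weight = signif(plan$weights, 8)),
      wr(sprintf("plan_physical_%s.csv", tag)), row.names = FALSE,
      quote = FALSE)
    flat <- res$flatness_physical
    flat_df <- data.frame(
      key = c("min_pct", "max_pct", "width_mm", "entrance_ratio", "tail_ratio"),
      value = signif(c(flat$min_pct, flat$max_pct, flat$width_mm,
                       flat$entrance_ratio, flat$tail_ratio), 6))
    if (!is.null(res$pdd_biological)) {
      write_profile_csv(res$pdd_biological,
                        wr(sprintf("pdd_biological_%s.csv", tag)), "bio_dose_rel")
      write_profile_csv(res$pdd_biological_physical,
                        wr(sprintf("pdd_biological_physical_%s.csv", tag)),
                        "dose_rel")
      write_profile_csv(res$rbe_biological,
                        wr(sprintf("rbe_biological_%s.csv", tag)), "rbe_total")
      utils::write.csv(
        data.frame(beam_index = seq_along(res$biological_plan$weights),
                   nominal_energy_MeV_per_n =
                     signif(res$biological_plan$energies, 8),
                   weight = signif(res$biological_plan$weights, 8)),
        wr(sprintf("plan_biological_%s.csv", tag)), row.names = FALSE,
        quote = FALSE)
      flat_b <- res$flatness_biological
      flat_df <- rbind(flat_df, data.frame(
        key = paste0("bio_", flat_df$key),
        value = signif(c(flat_b$min_pct, flat_b$max_pct, flat_b$width_mm,
                         flat_b$entrance_ratio, flat_b$tail_ratio), 6)))
    }
    utils::write.csv(flat_df, wr(sprintf("flatness_%s.csv", tag)),
                     row.names = FALSE, quote = FALSE)
  }
  pairs <- list(c("7Li", "12C"), c("1H", "12C"), c("4He", "12C"))
  center <- mean(bundle$config$target_region)
  for (pr in pairs) {
    ra <- bundle$results[[pr[1]]]; rb <- bundle$results[[pr[2]]]
    if (is.null(ra$pdd_biological) || is.null(rb$pdd_biological)) next
    rc <- ratio_curve(ra$pdd_biological, rb$pdd_biological, center)
    write_profile_csv(rc, wr(sprintf("ratio_bio_%s_over_%s.csv",
                                     gsub("[^0-9A-Za-z]", "", pr[1]),
                                     gsub("[^0-9A-Za-z]", "", pr[2]))),
                      "ratio")
  }
  cfg_path <- wr("config.csv")
  cfg <- bundle$config
  cfg_df <- data.frame(
    key = c("species", "resolution_mm", "phantom_depth_mm",
            "target_proximal_mm", "target_distal_mm", "prescription",
            "modes", "straggling_fraction", "ripple_sigma_mm",
            "mask_helium_tail"),
    value = c(paste(cfg$species, collapse = "|"), cfg$resolution,
              cfg$phantom_depth, cfg$target_region[1], cfg$target_region[2],
              cfg$prescription, paste(cfg$modes, collapse = "|"),
              if (is.null(cfg$straggling_fraction)) "species-default"
              else cfg$straggling_fraction,
              if (is.null(cfg$ripple_sigma)) "species-default"
              else cfg$ripple_sigma,
              cfg$mask_helium_tail))
  utils::write.csv(cfg_df, cfg_path, row.names = FALSE, quote = FALSE)
  manifest <- file.path(directory, "manifest.txt")
  writeLines(c(
    sprintf("sobpr version: %s",
            as.character(utils::packageVersion("sobpr"))),
    sprintf("config file: config.csv"),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("files: %s", paste(basename(files), collapse = ", "))),
    manifest)
  invisible(c(files, manifest))
}

#' Overlay the depth-dose curves of a study
#'
#' One line per species, entrance- or center-normalized, in the style of the
#' standard SOBP comparison figures.
#'
#' @param bundle A `study_bundle`.
#' @param what `"pdd_physical"` or `"pdd_biological"`.
#' @param normalize `"entrance"` (mean of first 5 bins) or `"none"`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted curves.
#' @export
plot_study_pdd <- function(bundle, what = c("pdd_physical", "pdd_biological"),
                           normalize = c("entrance", "none"), ...) {
  what <- match.arg(what); normalize <- match.arg(normalize)
  keep <- Filter(function(r) !is.null(r[[what]]), bundle$results)
  if (!length(keep)) stop("nothing to plot")
  grid <- keep[[1]][[what]]$grid
  mat <- vapply(keep, function(r) {
    v <- r[[what]]$values
    if (normalize == "entrance") v <- v / mean(v[1:5], na.rm = TRUE)
    v
  }, numeric(grid$n_bins))
  graphics::matplot(grid$depths, mat, type = "l", lty = 1,
                    xlab = "depth (mm)", ylab = sprintf("%s (norm.)", what),
                    ...)
  graphics::legend("topleft", legend = colnames(mat), lty = 1,
                   col = seq_len(ncol(mat)), bty = "n", cex = 0.8)
  invisible(mat)
}
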