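# Shared fixtures: everything is built in code, lazily, and cached across
# test files (libraries and plans are the expensive objects).

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache, inherits = FALSE))
    assign(name, force(expr), envir = .cache)
  get(name, envir = .cache, inherits = FALSE)
}

test_provider <- function() cached("provider", default_sp_provider())
test_yields <- function() cached("yields", default_yield_model())

test_library <- function(sym) {
  cached(paste0("lib_", sym),
         build_library(beam_species()[[sym]], 80, 130,
                       provider = test_provider()))
}

test_physical_plan <- function(sym) {
  cached(paste0("plan_", sym), optimize_physical(test_library(sym)))
}

test_field <- function(sym) {
  cached(paste0("field_", sym),
         mixed_field(test_physical_plan(sym), test_library(sym)))
}

test_bio_plan <- function(sym) {
  cached(paste0("bioplan_", sym),
         optimize_biological(test_library(sym),
                             yield_model = test_yields(),
                             provider = test_provider(),
                             start = test_physical_plan(sym)))
}

# A provider whose species have constant stopping powers: exact hand
# arithmetic for the LET/RBE aggregation oracles.
const_sp_provider <- function(values = c(3, 2, 4, 7)) {
  e <- c(0.025, 1, 1000)
  tabs <- lapply(seq_along(values), function(i) {
    sp_table(ion_species(paste0("X", i), i, 2L * i - 1L),
             e, rep(values[i], 3))
  })
  # a proton table is required by the provider contract
  if (tabs[[1]]$species$Z != 1L)
    tabs <- c(tabs, list(sp_table(ion_species("1H", 1L, 1L), e, rep(1, 3))))
  sp_provider(tabs)
}

# Toy fluence map on a small grid; phi filled from a seeded RNG unless given.
toy_map <- function(n_depth = 5, n_bins = 3, species = NULL, phi = NULL,
                    seed = 42) {
  grid <- depth_grid(resolution = 1, n_bins = n_depth)
  if (is.null(species))
    species <- list(ion_species("X1", 1L, 1L), ion_species("X2", 2L, 3L))
  edges <- exp(seq(log(0.5), log(500), length.out = n_bins + 1))
  if (is.null(phi)) {
    set.seed(seed)
    phi <- array(stats::runif(n_depth * n_bins * length(species)),
                 c(n_depth, n_bins, length(species)))
  }
  fluence_map(grid, species, edges, phi)
}

# Uniform-yield model: every species' yield equals the reference at all
# energies, so every RBE must collapse to exactly 1.
uniform_yield_model <- function(species_list = NULL) {
  if (is.null(species_list))
    species_list <- c(beam_species(), fragment_species())
  energy <- c(0.025, 1, 10, 100, 1000)
  tables <- lapply(species_list, function(s) {
    t <- data.frame(energy = energy,
                    yield = rep(CO60_REFERENCE_YIELD, length(energy)))
    attr(t, "species") <- s
    t
  })
  names(tables) <- vapply(species_list,
                          function(s) sprintf("Z%d_A%d", s$Z, s$A),
                          character(1))
  dsb_yield_model(tables)
}

# Brute-force double-loop dose-averaged LET, independent of let_profile()
brute_force_let <- function(map, provider) {
  centers <- sqrt(map$energy_edges[-1] * map$energy_edges[-length(map$energy_edges)])
  nd <- dim(map$phi)[1]
  out <- rep(NA_real_, nd)
  for (d in seq_len(nd)) {
    num <- 0; den <- 0
    for (i in seq_along(map$species)) {
      for (j in seq_along(centers)) {
        S <- stopping_power(provider, map$species[[i]], centers[j])
        D <- map$phi[d, j, i] * S
        num <- num + D * S
        den <- den + D
      }
    }
    if (den > 0) out[d] <- num / den
  }
  out
}

# Exhaustive two-parameter grid search (coarse pass then a fine pass around
# the coarse optimum), the independent oracle for the NNLS solve.
grid_search_2beam <- function(A, b, upper = 3, fine = 5e-4) {
  obj <- function(f1, f2) colSums((A %*% rbind(f1, f2) - b)^2)
  stage <- function(lo1, hi1, lo2, hi2, by) {
    g <- expand.grid(f1 = seq(lo1, hi1, by = by), f2 = seq(lo2, hi2, by = by))
    g[which.min(obj(g$f1, g$f2)), ]
  }
  c1 <- stage(0, upper, 0, upper, 0.05)
  c2 <- stage(max(0, c1$f1 - 0.06), c1$f1 + 0.06,
              max(0, c1$f2 - 0.06), c1$f2 + 0.06, fine)
  c(c2$f1, c2$f2)
}

# Two hand-built triangular "peaks" wrapped as a minimal beam library, for
# the NNLS grid-search oracle.
triangle_library <- function() {
  grid <- depth_grid(1, 10)
  s <- ion_species("1H", 1L, 1L)
  edges <- c(1, 10, 100)
  mk_peak <- function(dose) {
    structure(list(species = s, E0 = 100, R0 = 10, grid = grid,
                   fluence = fluence_map(grid, list(s), edges,
                                         array(0, c(10, 2, 1))),
                   dose = dose, lambda = Inf, straggling_fraction = 0.01),
              class = "pristine_peak")
  }
  d1 <- c(1, 2, 3, 4, 5, 4, 3, 2, 1, 0)
  d2 <- c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1)
  structure(list(species = s, peaks = list(mk_peak(d1), mk_peak(d2)),
                 energies = c(90, 100), ranges = c(9, 10), grid = grid,
                 energy_edges = edges, target = c(3, 8)),
            class = "beam_library")
}
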