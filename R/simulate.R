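# Synthetic data with the statistical structure of a multi-species qPCR
# efficiency study: 90 primer-pair/amplicon combinations (amplicons
# 74-907 bp, primers 18-25 nt), replicated reactions with efficiencies in
# [1, 2], a smooth ground-truth efficiency surface over the six model
# covariates, and Gaussian residual noise at the study's residual scale
# (variance 0.0092293). Features are computed from the generated sequences
# by the real extractors, never resampled independently, so covariate
# correlations are realistic.

#' Simulation configuration
#'
#' @param n_pairs Number of amplicon / primer-pair combinations (default 90).
#' @param replicates Reactions per pair (default 44, giving ~3960 rows, the
#'   scale of a ~4000-reaction study).
#' @param amplicon_range Amplicon length range in bp (default 74-907).
#' @param primer_range Primer length range in nt (default 18-25).
#' @param gc_shape Beta shape parameter for base-composition draws
#'   (symmetric Beta(gc_shape, gc_shape); default 12, G+C mostly 0.3-0.7).
#' @param noise_sd Residual SD of observed efficiency (default
#'   `sqrt(0.0092293)`, the study-scale residual).
#' @param true_r2 Fraction of row variance carried by the true surface
#'   (default 0.41); sets the signal SD given `noise_sd`.
#' @param intercept Mean of the true efficiency surface (default 1.738).
#' @param cycles Cycles per amplification curve (default 40).
#' @param seed Mandatory integer seed; every stochastic draw flows from it.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_pairs = 90L, replicates = 44L,
                              amplicon_range = c(74L, 907L),
                              primer_range = c(18L, 25L),
                              gc_shape = 12,
                              noise_sd = sqrt(0.0092293),
                              true_r2 = 0.41,
                              intercept = 1.738,
                              cycles = 40L,
                              seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    qe_stop("a seed is mandatory for all stochastic output", "qe_config_error")
  if (n_pairs < 1L || replicates < 1L)
    qe_stop("n_pairs and replicates must be positive", "qe_config_error")
  if (amplicon_range[1] > amplicon_range[2] ||
      primer_range[1] > primer_range[2] ||
      amplicon_range[1] < 2 * primer_range[2])
    qe_stop("infeasible length ranges", "qe_config_error")
  if (noise_sd < 0 || true_r2 < 0 || true_r2 >= 1)
    qe_stop("need noise_sd >= 0 and 0 <= true_r2 < 1", "qe_config_error")
  structure(list(n_pairs = as.integer(n_pairs),
                 replicates = as.integer(replicates),
                 amplicon_range = as.integer(amplicon_range),
                 primer_range = as.integer(primer_range),
                 gc_shape = gc_shape, noise_sd = noise_sd,
                 true_r2 = true_r2, intercept = intercept,
                 cycles = as.integer(cycles), seed = as.integer(seed)),
            class = "sim_config")
}

#' Random DNA sequence with a given expected G+C fraction
#'
#' @param n Length in nucleotides.
#' @param gc Expected G+C fraction.
#' @return DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# smooth ground-truth surface: one Gaussian bump + a linear tilt per
# covariate pair, on within-dataset z-scores, so each term is a smooth
# function a bivariate spline basis can represent
surface_raw <- function(z) {
  bump <- function(u, v, u0, v0, s) exp(-((u - u0)^2 + (v - v0)^2) / (2 * s^2))
  bump(z$lengthSequence, z$gcSequence, -0.5, 0.5, 1.2) -
    0.25 * z$gcSequence +
    bump(z$primersLength, z$gcPrimers, 0.6, -0.4, 1.0) +
    0.3 * z$primersLength -
    bump(z$gcImbalance, z$primerDimers, 0.8, 0.8, 1.1) -
    0.35 * z$gcImbalance
}

sim_species_pool <- data.frame(
  species = c("E.coli", "A.tumefaciens", "S.lycopersicum", "P.hybrida",
              "A.majus", "O.ficus-indica", "H.sapiens"),
  stringsAsFactors = FALSE)

#' Generate a synthetic efficiency dataset
#'
#' Draws random amplicons and primer pairs within the configured ranges,
#' computes their covariates with the package's own extractors, evaluates a
#' documented smooth true-efficiency surface over the six model covariates
#' (scaled so the surface carries `true_r2` of the row variance, centered
#' at `intercept`), and adds Gaussian residual noise truncated to \[1, 2\].
#'
#' @param config A [simulation_config()].
#' @return Tibble in the canonical feature schema plus `true_efficiency`;
#'   `efficiency` holds the noisy observation. One row per replicate
#'   reaction, `id` identifying the pair.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pairs <- lapply(seq_len(config$n_pairs), function(i) {
    len <- sample(config$amplicon_range[1]:config$amplicon_range[2], 1L)
    amp_gc <- stats::rbeta(1, config$gc_shape, config$gc_shape)
    amp <- amplicon(random_dna(len, amp_gc))
    plen <- sample(config$primer_range[1]:config$primer_range[2], 2L,
                   replace = TRUE)
    pgc <- stats::rbeta(2, config$gc_shape, config$gc_shape)
    pair <- primer_pair(random_dna(plen[1], pgc[1]),
                        random_dna(plen[2], pgc[2]))
    meta <- list(
      machine = sample(c("rotorgene2000", "mx3000p"), 1L),
      template = sample(c("GD", "CD", "plasmid", "yGD"), 1L),
      source = sample(c("leaf", "root", "culture", "cytology"), 1L),
      operator = sample(paste0("op", 1:5), 1L),
      species = sample(sim_species_pool$species, 1L),
      var = paste0("line", sample(1:3, 1L)))
    extract_features(amp, pair, metadata = meta, id = sprintf("pair%02d", i))
  })
  pairs <- dplyr::bind_rows(pairs)
  z <- lapply(pairs[GAM_COVARIATES], function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  raw <- surface_raw(z)
  signal_sd <- config$noise_sd * sqrt(config$true_r2 / (1 - config$true_r2))
  raw_sd <- sd(raw)
  signal <- if (raw_sd == 0 || signal_sd == 0) rep(0, length(raw)) else
    (raw - mean(raw)) / raw_sd * signal_sd
  pairs$true_efficiency <- pmin(pmax(config$intercept + signal, 1), 2)
  rows <- pairs[rep(seq_len(nrow(pairs)), each = config$replicates), ]
  rows$replicate <- rep(seq_len(config$replicates), times = nrow(pairs))
  rows$efficiency <- pmin(pmax(
    rows$true_efficiency + rnorm(nrow(rows), 0, config$noise_sd), 1), 2)
  tibble::as_tibble(rows)
}

#' Simulate one amplification curve
#'
#' The exponential phase grows by exactly `true_E` per cycle from an
#' initial amount anchored so the unbounded exponential would reach the
#' plateau at `knee_cycle`; a sharp Hill-type knee bends it into the
#' plateau, giving a sigmoid whose rising limb keeps the exact per-cycle
#' ratio (an exact logistic never does). `true_E = 1` yields the baseline
#' only.
#'
#' @param true_E True per-cycle amplification factor in \[1, 2\].
#' @param F0 Additive baseline fluorescence (default 10).
#' @param amplitude Plateau height above baseline (default 100).
#' @param cycles Number of cycles (default 40, >= 20 required).
#' @param noise Multiplicative Gaussian noise SD (default 0).
#' @param seed Seed used when `noise > 0`.
#' @param knee_cycle Cycle at which the exponential reaches the plateau.
#'   The default (`NULL`) places the take-off (1% of plateau) at cycle 18
#'   for fast reactions, emulating a typical template load, and caps the
#'   knee at `cycles - 6` so slow reactions still reach their plateau
#'   inside the observation window.
#' @return An [amplification_curve()] with `baseline_state = "raw"`.
#' @export
#' @examples
#' curve <- simulate_curve(2, cycles = 40)
#' estimate_efficiency(curve)$E  # ~2.0
simulate_curve <- function(true_E, F0 = 10, amplitude = 100, cycles = 40L,
                           noise = 0, seed = NULL, knee_cycle = NULL) {
  if (!is.finite(true_E) || true_E < 1 || true_E > 2)
    qe_stop("true_E must lie in [1, 2]", "qe_config_error")
  if (cycles < 20L)
    qe_stop("need at least 20 cycles", "qe_config_error")
  cyc <- seq_len(cycles)
  if (true_E == 1) {
    f <- rep(F0, cycles)
  } else {
    if (is.null(knee_cycle))
      knee_cycle <- min(cycles - 6, 18 + log(100) / log(true_E))
    A0 <- amplitude * true_E^(-knee_cycle)
    u <- A0 * true_E^cyc
    h <- 8  # sharp knee: exponential below ~0.5*amplitude, plateau above
    f <- F0 + u / (1 + (u / amplitude)^h)^(1 / h)
  }
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f * (1 + rnorm(cycles, 0, noise))
  }
  amplification_curve(cyc, f)
}

#' Write a set of simulated curves as a long-format CSV
#'
#' @param true_E Vector of true efficiencies, one curve each.
#' @param path Output CSV (`well`, `cycle`, `fluorescence`).
#' @param seed Base seed; curve i uses `seed + i`.
#' @param ... Passed to [simulate_curve()].
#' @return Invisibly, the tibble written.
#' @export
write_sim_curves_csv <- function(true_E, path, seed = 1L, ...) {
  rows <- lapply(seq_along(true_E), function(i) {
    cv <- simulate_curve(true_E[i], seed = seed + i, ...)
    tibble::tibble(well = sprintf("W%03d", i), cycle = cv$cycles,
                   fluorescence = cv$fluorescence)
  })
  out <- dplyr::bind_rows(rows)
  readr::write_csv(out, path)
  invisible(out)
}

#' Read / write a simulation configuration as JSON
#'
#' @param config A [simulation_config()].
#' @param path JSON file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(simulation_config, raw)
}
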