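# Per-reaction amplification efficiency from a raw fluorescence curve.
#
# Pipeline: (optional) baseline correction -> 4-parameter logistic fit
# (baseline left free, so early-cycle signal cannot bias the background
# estimate) -> analytic maximum of the second derivative (cpD2) -> anchor
# cycle n where the fitted sigmoid reaches 20% of its fluorescence at cpD2
# -> efficiency E = F(n)/F(n-1), where F is an exponential model fitted to
# the baseline-subtracted observed fluorescence over the cycles bracketing
# n. On the exponential phase of a well-behaved reaction that ratio is
# exactly the per-cycle amplification factor; E = 1 means no amplification
# and E = 2 perfect duplication.

LN_2_PLUS_SQRT3 <- log(2 + sqrt(3))  # second-derivative max offset (in b units)

#' Construct an amplification curve
#'
#' @param cycles Strictly increasing integer cycle numbers (typically 1:40).
#' @param fluorescence Numeric fluorescence readings, same length.
#' @param baseline_state One of `"raw"`, `"standard"`, `"dynamic_tube"`,
#'   `"adaptive"` — whether (and how) the curve was baseline-corrected.
#' @return Object of class `amplification_curve`.
#' @export
amplification_curve <- function(cycles, fluorescence, baseline_state = "raw") {
  cycles <- as.numeric(cycles)
  fluorescence <- as.numeric(fluorescence)
  if (length(cycles) != length(fluorescence))
    qe_stop("cycles and fluorescence must have equal length", "qe_invalid_input")
  if (any(diff(cycles) <= 0))
    qe_stop("cycles must be strictly increasing", "qe_invalid_input")
  if (any(!is.finite(fluorescence)))
    qe_stop("fluorescence contains non-finite values", "qe_invalid_input")
  state <- match.arg(baseline_state,
                     c("raw", "standard", "dynamic_tube", "adaptive"))
  structure(list(cycles = cycles, fluorescence = fluorescence,
                 baseline_state = state),
            class = "amplification_curve")
}

#' @export
print.amplification_curve <- function(x, ...) {
  cat(sprintf("amplification curve: %d cycles, baseline '%s', F range [%.3g, %.3g]\n",
              length(x$cycles), x$baseline_state,
              min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}

#' Baseline-correct an amplification curve
#'
#' Three conventions used by common thermocycler software:
#' \describe{
#'   \item{standard}{subtract the mean fluorescence of cycles 1-5.}
#'   \item{dynamic_tube}{locate the take-off cycle at the maximum of the
#'     smoothed finite-difference second derivative and subtract the mean
#'     fluorescence of the cycles before it (per-tube threshold).}
#'   \item{adaptive}{subtract the median of the lowest quartile of
#'     fluorescence values (per-sample background).}
#' }
#' Corrected values may be negative. Re-correcting an already corrected
#' curve is an error; a curve with no usable take-off under `dynamic_tube`
#' falls back to `standard` with a warning.
#'
#' @param curve An [amplification_curve()] with `baseline_state = "raw"`.
#' @param method Correction method (above).
#' @return Corrected `amplification_curve`.
#' @export
baseline_correct <- function(curve,
                             method = c("standard", "dynamic_tube", "adaptive")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "amplification_curve"))
  if (curve$baseline_state != "raw")
    qe_stop("curve is already baseline-corrected", "qe_invalid_input")
  f <- curve$fluorescence
  if (length(f) < 10L)
    qe_stop("need at least 10 cycles to baseline-correct", "qe_invalid_input")
  base <- switch(method,
    standard = mean(f[1:5]),
    adaptive = median(f[f <= quantile(f, 0.25)]),
    dynamic_tube = {
      d2 <- diff(diff(f))
      # 3-point moving average stabilizes single-cycle noise
      if (length(d2) >= 3L) d2 <- stats::filter(d2, rep(1 / 3, 3), sides = 2)
      d2 <- as.numeric(d2)
      takeoff <- which.max(d2) + 1L  # d2[i] sits at cycle index i + 1
      if (all(!is.finite(d2)) || diff(range(f)) < .Machine$double.eps^0.5 ||
          takeoff < 3L) {
        qe_warn("no usable take-off; falling back to standard correction",
                "qe_baseline_fallback")
        mean(f[1:5])
      } else mean(f[seq_len(takeoff - 1L)])
    })
  amplification_curve(curve$cycles, f - base, baseline_state = method)
}

logistic4 <- function(cyc, F0, a, chalf, b) F0 + a / (1 + exp(-(cyc - chalf) / b))

#' Fit a 4-parameter logistic sigmoid to an amplification curve
#'
#' Least-squares fit of `F(c) = F0 + a / (1 + exp(-(c - chalf)/b))` with
#' deterministic multi-start initialization. A flat curve (maximum-to-median
#' fluorescence ratio after background removal below `flat_ratio`) raises a
#' no-amplification condition that [estimate_efficiency()] maps to E = 1.
#'
#' @param curve An [amplification_curve()]; the baseline parameter `F0` is
#'   estimated as part of the fit, so both raw and corrected curves work.
#' @param flat_ratio No-amplification threshold on max/median of the
#'   background-subtracted trace (default 1.2).
#' @return List with class `sigmoid_fit`: `F0`, `a`, `chalf`, `b`, `sse`.
#' @export
fit_sigmoid <- function(curve, flat_ratio = 1.2) {
  stopifnot(inherits(curve, "amplification_curve"))
  cyc <- curve$cycles
  f <- curve$fluorescence
  if (length(cyc) < 10L)
    qe_stop("need at least 10 cycles to fit a sigmoid", "qe_invalid_input")
  # signal visibility on a positive scale regardless of prior correction
  shifted <- f - min(f)
  med <- median(shifted)
  if (med <= .Machine$double.eps^0.5) med <- mean(shifted) + .Machine$double.eps
  if (max(shifted) / med < flat_ratio)
    qe_stop("no amplification detected (flat curve)", "qe_no_amplification")
  amp0 <- max(f) - min(f)
  c0 <- cyc[which.max(diff(f))]
  dat <- data.frame(cyc = cyc, f = f)
  best <- NULL
  for (b0 in c(1, 0.5, 2, 4, 8)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ F0 + a / (1 + exp(-(cyc - chalf) / b)),
        data = dat,
        start = list(F0 = min(f), a = amp0, chalf = c0, b = b0),
        lower = c(F0 = -Inf, a = amp0 * 1e-3, chalf = min(cyc) - 10,
                  b = 1e-3),
        upper = c(F0 = Inf, a = amp0 * 100, chalf = max(cyc) + 60, b = 60),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(resid(fit)^2)
      if (is.null(best) || sse < best$sse)
        best <- c(as.list(coef(fit)), list(sse = sse))
    }
  }
  if (is.null(best))
    qe_stop("sigmoid fit failed to converge", "qe_fit_error")
  structure(best, class = "sigmoid_fit")
}

#' Cycle of the second-derivative maximum of a fitted sigmoid
#'
#' For the 4-parameter logistic the maximum of `d2F/dc2` has the closed
#' form `chalf - b * log(2 + sqrt(3))`, returned as a real-valued cycle.
#'
#' @param params A `sigmoid_fit` (or list with `chalf` and `b`).
#' @return cpD2, real-valued cycle.
#' @export
#' @examples
#' second_derivative_max(list(chalf = 25, b = 1))  # 23.683
second_derivative_max <- function(params) {
  b <- params$b
  if (is.null(b) || !is.finite(b) || b <= 0)
    qe_stop("invalid sigmoid fit: slope b must be positive", "qe_fit_error")
  params$chalf - b * LN_2_PLUS_SQRT3
}

#' Estimate amplification efficiency from one curve
#'
#' Implements the second-derivative-maximum efficiency estimator: fit the
#' sigmoid, locate cpD2 and the anchor cycle `n` at which the fitted
#' (baseline-subtracted) fluorescence equals 20% of its value at cpD2
#' (inverted analytically on the rising limb, rounded to the nearest
#' cycle), then report `E = F(n)/F(n-1)`. `F` here is an exponential-phase
#' model `A * E^c + d` fitted to the observed fluorescence over a window
#' of cycles centered on `n` (capped at cpD2): the free additive offset
#' `d` absorbs any residual background, so on the exponential phase the
#' ratio of the exponential component equals the true per-cycle
#' amplification factor, and the window averages out single-cycle noise.
#' A flat curve yields `E = 1` (no amplification).
#'
#' @param curve An [amplification_curve()]; raw curves are corrected with
#'   `baseline` first (the fit also keeps its own free baseline term).
#' @param baseline Correction applied to raw input (see
#'   [baseline_correct()]).
#' @param window Half-width of the exponential-fit window (default 4).
#' @param flat_ratio Passed to [fit_sigmoid()].
#' @return Object of class `efficiency_estimate`: `E`, `n`, `cpD2`,
#'   `F_at_cpD2` (baseline-subtracted fitted fluorescence at cpD2), the
#'   sigmoid parameters and the fit SSE.
#' @export
estimate_efficiency <- function(curve, baseline = "standard", window = 4L,
                                flat_ratio = 1.2) {
  stopifnot(inherits(curve, "amplification_curve"))
  if (curve$baseline_state == "raw" && !is.null(baseline))
    curve <- withCallingHandlers(
      baseline_correct(curve, baseline),
      qpcrEff_warning = function(w) invokeRestart("muffleWarning"))
  fit <- tryCatch(fit_sigmoid(curve, flat_ratio = flat_ratio),
                  qe_no_amplification = function(e) NULL)
  if (is.null(fit))
    return(structure(list(E = 1, n = NA_real_, cpD2 = NA_real_,
                          F_at_cpD2 = NA_real_, params = NULL,
                          sse = NA_real_, no_amplification = TRUE),
                     class = "efficiency_estimate"))
  cpD2 <- second_derivative_max(fit)
  # baseline-subtracted fitted fluorescence at cpD2: a / (3 + sqrt(3))
  F_cpD2 <- fit$a / (1 + exp(LN_2_PLUS_SQRT3))
  target <- 0.2 * F_cpD2
  if (target <= 0)
    qe_stop("20% anchor lies below the fitted baseline", "qe_estimation_error")
  # invert the logistic (rising limb): F0-subtracted F(n_real) = target
  n_real <- fit$chalf - fit$b * log(fit$a / target - 1)
  n <- round(n_real)
  E <- exp_window_ratio(curve, n, cpD2, window)
  structure(list(E = E, n = n, cpD2 = cpD2, F_at_cpD2 = F_cpD2,
                 params = fit, sse = fit$sse, no_amplification = FALSE),
            class = "efficiency_estimate")
}

# exponential-phase ratio around the anchor cycle: fit A * E^c + d over
# the window [n - window, min(n + window, cpD2)], widening downward when
# the cap leaves too few points. Difference ratios (which cancel any
# additive offset) seed a small multi-start; weights reflect fluorescence
# noise that scales with the raw signal (approximated on a shifted scale
# so corrected curves, whose values may touch zero, stay usable).
exp_window_ratio <- function(curve, n, cpD2, window) {
  cyc <- curve$cycles
  f <- curve$fluorescence
  hi <- min(max(cyc), n + window, floor(cpD2))
  lo <- max(min(cyc), min(n - window, hi - 2L * window))
  idx <- which(cyc >= lo & cyc <= hi)
  if (n - 1 < min(cyc) || n > max(cyc) || length(idx) < 4L)
    qe_stop("exponential phase not observed within the cycle range",
            "qe_estimation_error")
  cw <- cyc[idx] - cyc[idx][1L]  # rescale to keep A tame
  fw <- f[idx]
  d1 <- diff(fw)
  rr <- d1[-1L] / d1[-length(d1)]
  rr <- rr[is.finite(rr) & rr > 0]
  E0 <- if (length(rr) > 0L) exp(mean(log(rr))) else 1.5
  E0 <- min(max(E0, 1.01), 2.4)
  w <- 1 / (fw - min(fw) + 0.1 * max(diff(range(fw)), .Machine$double.eps))^2
  dat <- data.frame(cw = cw, fw = fw, w = w)
  best <- NULL
  for (Es in unique(c(E0, 1.2, 1.5, 1.9))) {
    A0 <- max((fw[length(fw)] - fw[1L]) /
                max(Es^cw[length(cw)] - 1, 1e-9), 1e-9)
    efit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        fw ~ A * E^cw + d, data = dat, weights = w,
        start = list(A = A0, E = Es, d = fw[1L] - A0),
        lower = c(A = .Machine$double.eps, E = 1.0001, d = -Inf),
        upper = c(A = Inf, E = 2.5, d = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300))),
      error = function(e) NULL)
    if (!is.null(efit)) {
      sse <- sum(w * resid(efit)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(E = unname(coef(efit)[["E"]]), sse = sse)
    }
  }
  if (is.null(best)) return(E0)
  # a fit stuck at a box bound carries no information; keep the
  # offset-free difference-ratio estimate instead
  if (best$E >= 2.5 - 1e-8 || best$E <= 1.0001 + 1e-8) E0 else best$E
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  if (isTRUE(x$no_amplification)) {
    cat("efficiency estimate: E = 1 (no amplification)\n")
  } else {
    cat(sprintf("efficiency estimate: E = %.4f (n = %d, cpD2 = %.2f)\n",
                x$E, as.integer(x$n), x$cpD2))
  }
  invisible(x)
}

#' Read amplification curves from CSV
#'
#' Accepts long format (columns `well`, `cycle`, `fluorescence`) or wide
#' format (a `cycle` column plus one column per well).
#'
#' @param path CSV path.
#' @return Named list of [amplification_curve()] objects, one per well.
#' @export
read_curves_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("well", "cycle", "fluorescence") %in% names(df))) {
    split_df <- split(df, df$well)
    return(lapply(split_df, function(d) {
      d <- d[order(d$cycle), ]
      amplification_curve(d$cycle, d$fluorescence)
    }))
  }
  if ("cycle" %in% names(df)) {
    wells <- setdiff(names(df), "cycle")
    if (length(wells) == 0L)
      qe_stop("wide curve CSV has no well columns", "qe_schema_error")
    return(setNames(lapply(wells, function(w)
      amplification_curve(df$cycle, df[[w]])), wells))
  }
  qe_stop("curve CSV must be long (well,cycle,fluorescence) or wide (cycle + wells)",
          "qe_schema_error")
}

#' Estimate efficiency for every well in a curve set
#'
#' @param curves Named list of curves, as from [read_curves_csv()].
#' @param ... Passed to [estimate_efficiency()].
#' @return Tibble: `well`, `E`, `n`, `cpD2`, `no_amplification`.
#' @export
estimate_efficiencies <- function(curves, ...) {
  rows <- lapply(names(curves), function(w) {
    est <- tryCatch(estimate_efficiency(curves[[w]], ...),
                    qpcrEff_error = function(e) NULL)
    if (is.null(est))
      return(tibble::tibble(well = w, E = NA_real_, n = NA_real_,
                            cpD2 = NA_real_, no_amplification = NA))
    tibble::tibble(well = w, E = est$E, n = as.numeric(est$n),
                   cpD2 = est$cpD2,
                   no_amplification = isTRUE(est$no_amplification))
  })
  dplyr::bind_rows(rows)
}
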