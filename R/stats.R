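# Univariate rank-test battery and effect-size conversions.
#
# Efficiency data are heavily tied (many identical readings), so the tests
# use asymptotic approximations with explicit tie handling: midrank
# averaging by default, or seeded random assignment of distinct ranks
# within tie groups ("random rank averaging"). Effect sizes chain from the
# rank correlation: d = 2r/sqrt(1-r^2), logOdds = d*pi/sqrt(3), and
# Hedges' g = d*(1 - 3/(4n - 9)) as the small-sample-unbiased d.

rank_with_policy <- function(x, tie_policy = c("midrank", "random"),
                             seed = NULL) {
  tie_policy <- match.arg(tie_policy)
  if (tie_policy == "midrank") return(rank(x, ties.method = "average"))
  if (!is.null(seed)) set.seed(seed)
  rank(x, ties.method = "random")
}

test_result <- function(statistic_type, statistic, df = NA_real_, p, rho = NA_real_,
                        n) {
  # |rho| = 1 (perfect monotone association) maps to an infinite d
  d <- if (!is.finite(rho)) NA_real_ else
    if (abs(rho) >= 1) sign(rho) * Inf else r_to_d(rho)
  structure(list(statistic_type = statistic_type, statistic = statistic,
                 df = df, p = p, rho = rho, d = d,
                 g = if (is.finite(d) && n > 3) d_to_g(d, n) else NA_real_,
                 log_odds = if (!is.na(d)) d * pi / sqrt(3) else NA_real_,
                 n = n),
            class = "qe_test_result")
}

#' @export
print.qe_test_result <- function(x, ...) {
  cat(sprintf("%s = %.4f%s, p = %.4g (n = %d)\n", x$statistic_type,
              x$statistic,
              if (is.finite(x$df)) sprintf(", df = %g", x$df) else "",
              x$p, x$n))
  if (is.finite(x$rho))
    cat(sprintf("  rho = %.3f  d = %.3f  g = %.3f  logOdds = %.3f\n",
                x$rho, x$d, x$g, x$log_odds))
  invisible(x)
}

#' Asymptotic Spearman rank-correlation test
#'
#' Rank correlation with tie handling by midranks (default) or seeded
#' random rank averaging; `Z = rho * sqrt(n - 1)` with a two-sided normal
#' p-value.
#'
#' @param x,y Numeric vectors of equal length, n >= 10.
#' @param tie_policy `"midrank"` or `"random"`.
#' @param seed Seed for the random tie policy.
#' @return A test-result object (statistic, p, rho and the derived effect
#'   sizes d, Hedges' g, log odds).
#' @export
spearman_asymptotic <- function(x, y, tie_policy = "midrank", seed = NULL) {
  if (length(x) != length(y))
    qe_stop("x and y must have equal length", "qe_invalid_input")
  n <- length(x)
  if (n < 10L)
    qe_stop("asymptotic Spearman test needs n >= 10", "qe_invalid_input")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    qe_stop("correlation undefined for a constant vector", "qe_invalid_input")
  if (!is.null(seed)) set.seed(seed)
  rx <- rank_with_policy(x, tie_policy)
  ry <- rank_with_policy(y, tie_policy)
  rho <- cor(rx, ry)
  Z <- rho * sqrt(n - 1)
  test_result("Z", Z, p = z_to_p(Z), rho = rho, n = n)
}

#' Asymptotic Kruskal-Wallis test
#'
#' Standard tie-corrected H statistic on `k` groups with `df = k - 1` and a
#' chi-squared p-value (delegated to [stats::kruskal.test()]).
#'
#' @param values Numeric response.
#' @param groups Group labels (factor or coercible).
#' @return A test-result object (chi-squared statistic, df, p).
#' @export
kruskal_wallis_asymptotic <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    qe_stop("need at least 2 groups", "qe_invalid_input")
  if (any(table(droplevels(groups)) < 2L))
    qe_stop("every group needs at least 2 observations", "qe_invalid_input")
  if (length(unique(values)) == 1L)  # identical distributions, H = 0
    return(test_result("chi-squared", 0, df = nlevels(droplevels(groups)) - 1,
                       p = 1, n = length(values)))
  kt <- stats::kruskal.test(values, groups)
  test_result("chi-squared", unname(kt$statistic), df = unname(kt$parameter),
              p = kt$p.value, n = length(values))
}

#' Asymptotic Wilcoxon-Mann-Whitney rank-sum test
#'
#' U-statistic Z with tie-corrected variance and a two-sided normal
#' p-value; effect sizes derive from `r = Z / sqrt(n)`.
#'
#' @param a,b Numeric samples, each with >= 2 observations.
#' @return A test-result object.
#' @export
wilcoxon_mw_asymptotic <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    qe_stop("both samples need at least 2 observations", "qe_invalid_input")
  n1 <- length(a)
  n2 <- length(b)
  n <- n1 + n2
  r <- rank(c(a, b), ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * (n + 1 - tie_corr)
  Z <- if (v > 0) (U - mu) / sqrt(v) else 0
  rho <- Z / sqrt(n)
  test_result("Z", Z, p = z_to_p(Z), rho = rho, n = n)
}

#' Effect-size conversions
#'
#' Closed-form conversions between the rank correlation `rho`, Cohen's d,
#' the log odds ratio and Hedges' g:
#' `d = 2*rho / sqrt(1 - rho^2)`, `logOdds = d * pi / sqrt(3)`,
#' `g = d * (1 - 3 / (4n - 9))`.
#'
#' @param rho Correlation, `|rho| < 1`.
#' @return Converted effect size.
#' @export
#' @examples
#' r_to_d(0.177)              # 0.360
#' d_to_logodds(-0.169)       # -0.307
r_to_d <- function(rho) {
  if (!is.finite(rho) || abs(rho) >= 1)
    qe_stop("r_to_d requires |rho| < 1", "qe_domain_error")
  2 * rho / sqrt(1 - rho^2)
}

#' @rdname r_to_d
#' @param d Cohen's d.
#' @export
d_to_logodds <- function(d) {
  if (!is.finite(d)) qe_stop("d must be finite", "qe_domain_error")
  d * pi / sqrt(3)
}

#' @rdname r_to_d
#' @param n Total sample size, n > 3.
#' @export
d_to_g <- function(d, n) {
  if (!is.finite(d)) qe_stop("d must be finite", "qe_domain_error")
  if (n <= 3) qe_stop("Hedges' g requires n > 3", "qe_domain_error")
  d * (1 - 3 / (4 * n - 9))
}

#' @rdname r_to_d
#' @param Z Standard-normal test statistic.
#' @export
z_to_p <- function(Z) {
  if (!is.finite(Z)) qe_stop("Z must be finite", "qe_domain_error")
  2 * pnorm(-abs(Z))
}

#' Run the full univariate battery on a feature table
#'
#' Tests every quantitative covariate against efficiency with the
#' asymptotic Spearman test, and every categorical covariate with the
#' asymptotic Kruskal-Wallis test; returns a table of statistic, df, rho,
#' d, log odds and raw p-values (no multiplicity correction by default,
#' with a cutoff of 0.05 in mind; set `adjust = "holm"` to adjust).
#'
#' @param features Feature table with an `efficiency` column.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @param tie_policy,seed Passed to [spearman_asymptotic()].
#' @return Tibble: `variable`, `test`, `statistic`, `df`, `rho`, `d`,
#'   `logOdds`, `p`.
#' @export
univariate_battery <- function(features, adjust = "none",
                               tie_policy = "midrank", seed = NULL) {
  if (!"efficiency" %in% names(features))
    qe_stop("feature table lacks an efficiency column", "qe_schema_error")
  eff <- features$efficiency
  quantitative <- c(primersLength = "primersLength",
                    lengthSequence = "lengthSequence",
                    gcSequence = "gcSequence",
                    aRepeats = "aRepeats", tRepeats = "tRepeats",
                    cRepeats = "cRepeats", gRepeats = "gRepeats",
                    tmPrimers = NA, primersSelfcom = "primersSelfcom",
                    primerDimers = "primerDimers",
                    gcImbalance = "gcImbalance", gcPrimers = "gcPrimers",
                    sequencePalindromes = "sequencePalindromes")
  categorical <- c("species", "template", "var", "source", "operator")
  rows <- list()
  add <- function(variable, res) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      variable = variable, test = res$statistic_type,
      statistic = res$statistic, df = res$df, rho = res$rho, d = res$d,
      logOdds = res$log_odds, p = res$p)
  }
  for (v in names(quantitative)) {
    col <- quantitative[[v]]
    x <- if (v == "tmPrimers") {
      (features$tmForward + features$tmReverse) / 2
    } else features[[col]]
    if (is.null(x)) next
    x <- as.numeric(x)
    res <- tryCatch(
      spearman_asymptotic(x, eff, tie_policy = tie_policy, seed = seed),
      qpcrEff_error = function(e) NULL)
    if (!is.null(res)) add(v, res)
  }
  for (v in categorical) {
    x <- features[[v]]
    if (is.null(x) || all(is.na(x))) next
    res <- tryCatch(kruskal_wallis_asymptotic(eff, x),
                    qpcrEff_error = function(e) NULL)
    if (!is.null(res)) add(v, res)
  }
  out <- dplyr::bind_rows(rows)
  if (adjust != "none") out$p <- stats::p.adjust(out$p, method = adjust)
  out
}
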