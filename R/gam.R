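# Efficiency prediction model: a Gaussian generalized additive model with
# three bivariate smooths,
#
#   efficiency ~ s(lengthSequence, gcSequence)
#              + s(primersLength, gcPrimers)
#              + s(gcImbalance,  primerDimers)
#
# fitted by penalized least squares with smoothing parameters chosen by
# GCV (mgcv backend). The response is modelled directly on the efficiency
# scale [1, 2] (no link transform); predictions are clamped to that
# physical range with a flag, and covariates outside the training ranges
# are flagged as extrapolation. Variables that are univariately
# significant but absent from this formula (species, operator, 3' termini,
# palindromes, repeats, Tm) are deliberately not covariates: they carry no
# additional predictive signal once the three interactions are in the
# model, and remain in the feature table for user-defined refits.

GAM_COVARIATES <- c("lengthSequence", "gcSequence", "primersLength",
                    "gcPrimers", "gcImbalance", "primerDimers")
MODEL_FORMAT_VERSION <- "qpcrEff-gam-1"

#' Fit the efficiency GAM
#'
#' @param training Feature table (tibble/data.frame) with the six model
#'   covariates and a numeric `efficiency` column; at least 100 complete
#'   records.
#' @param k Basis dimension of each bivariate thin-plate smooth
#'   (default 30).
#' @param method Smoothing-parameter selection criterion: `"GCV.Cp"`
#'   (default) or `"REML"`.
#' @return Object of class `efficiency_gam`: the mgcv fit, a
#'   [fit_summary()]-style summary (adjusted R^2, deviance explained, GCV
#'   score, scale estimate, per-smooth edf table, AIC), training covariate
#'   ranges and the training n.
#' @export
fit_gam <- function(training, k = 30, method = c("GCV.Cp", "REML")) {
  method <- match.arg(method)
  missing <- setdiff(c(GAM_COVARIATES, "efficiency"), names(training))
  if (length(missing) > 0L)
    qe_stop(sprintf("training table lacks column(s): %s",
                    paste(missing, collapse = ", ")), "qe_schema_error")
  dat <- as.data.frame(training)[, c(GAM_COVARIATES, "efficiency")]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 100L)
    qe_stop(sprintf("need >= 100 complete training records, got %d",
                    nrow(dat)), "qe_invalid_input")
  if (any(!is.finite(as.matrix(dat))))
    qe_stop("training covariates must be finite", "qe_invalid_input")
  for (v in GAM_COVARIATES)
    if (stats::var(dat[[v]]) == 0)
      qe_stop(sprintf("degenerate design: covariate '%s' is constant", v),
              "qe_degenerate_design")
  # basis cannot exceed the number of distinct covariate points per smooth
  kk <- vapply(list(c("lengthSequence", "gcSequence"),
                    c("primersLength", "gcPrimers"),
                    c("gcImbalance", "primerDimers")),
               function(vars) min(k, nrow(unique(dat[vars])) - 1L), numeric(1))
  form <- stats::as.formula(sprintf(
    "efficiency ~ s(lengthSequence, gcSequence, k = %d) + s(primersLength, gcPrimers, k = %d) + s(gcImbalance, primerDimers, k = %d)",
    kk[1], kk[2], kk[3]))
  fit <- mgcv::gam(form, data = dat, method = method, family = stats::gaussian())
  ranges <- lapply(dat[GAM_COVARIATES], range)
  structure(list(fit = fit,
                 summary = fit_summary(fit),
                 ranges = ranges,
                 k = kk,
                 method = method,
                 n = nrow(dat),
                 version = MODEL_FORMAT_VERSION),
            class = "efficiency_gam")
}

#' Summary statistics of a fitted efficiency GAM
#'
#' @param fit An mgcv `gam` object (or an `efficiency_gam`).
#' @return List: `intercept`, `r_squared_adj`, `deviance_explained`
#'   (fraction), `gcv_score`, `scale_estimate`, `n`, `edf_total`, `aic`
#'   (-2 log-likelihood + 2 edf_total) and `smooths`, a per-term table of
#'   edf, reference df, F and p-value.
#' @export
fit_summary <- function(fit) {
  if (inherits(fit, "efficiency_gam")) fit <- fit$fit
  s <- summary(fit)
  dev_expl <- s$dev.expl
  if (!is.finite(dev_expl)) dev_expl <- 0  # constant response: no deviance
  edf_total <- sum(fit$edf)
  smooths <- tibble::tibble(
    term = rownames(s$s.table),
    edf = s$s.table[, "edf"],
    ref_df = s$s.table[, "Ref.df"],
    F = s$s.table[, "F"],
    p_value = s$s.table[, "p-value"])
  list(intercept = unname(coef(fit)[1L]),
       r_squared_adj = s$r.sq,
       deviance_explained = dev_expl,
       gcv_score = as.numeric(fit$gcv.ubre),
       scale_estimate = s$scale,
       n = stats::nobs(fit),
       edf_total = edf_total,
       aic = -2 * as.numeric(logLik(fit)) + 2 * edf_total,
       smooths = smooths)
}

#' @export
print.efficiency_gam <- function(x, ...) {
  s <- x$summary
  cat("efficiency GAM (three bivariate smooths)\n")
  cat(sprintf("  intercept      %.5f\n", s$intercept))
  cat(sprintf("  R-sq (adj)     %.3f   deviance explained %.1f%%\n",
              s$r_squared_adj, 100 * s$deviance_explained))
  cat(sprintf("  GCV %.3g   scale est. %.3g   n = %d\n",
              s$gcv_score, s$scale_estimate, s$n))
  sm <- s$smooths
  for (i in seq_len(nrow(sm)))
    cat(sprintf("  %-38s edf %6.2f  F %8.3f  p %.3g\n",
                sm$term[i], sm$edf[i], sm$F[i], sm$p_value[i]))
  invisible(x)
}

#' Predict efficiency for new records
#'
#' Evaluates intercept plus the three smooths, clamps predictions into the
#' physical range \[1, 2\] and flags records whose covariates fall outside
#' the training ranges (extrapolation).
#'
#' @param model An `efficiency_gam` (native or loaded via [load_model()]).
#' @param records Feature table containing the six model covariates.
#' @return Tibble: `prediction` (clamped), `raw_prediction`, `clamped`
#'   and `extrapolated` flags; an `id` column is carried through if present.
#' @export
predict_efficiency <- function(model, records) {
  stopifnot(inherits(model, "efficiency_gam"))
  missing <- setdiff(GAM_COVARIATES, names(records))
  if (length(missing) > 0L)
    qe_stop(sprintf("records lack model covariate(s): %s",
                    paste(missing, collapse = ", ")), "qe_schema_error")
  newdata <- as.data.frame(records)[, GAM_COVARIATES, drop = FALSE]
  if (any(!is.finite(as.matrix(newdata))))
    qe_stop("record covariates must be finite", "qe_invalid_input")
  raw <- if (!is.null(model$fit)) {
    as.numeric(predict(model$fit, newdata = newdata))
  } else {
    predict_portable(model$portable, newdata)
  }
  clamped <- pmin(pmax(raw, 1), 2)
  extrap <- rep(FALSE, nrow(newdata))
  for (v in GAM_COVARIATES) {
    r <- model$ranges[[v]]
    extrap <- extrap | newdata[[v]] < r[1] | newdata[[v]] > r[2]
  }
  out <- tibble::tibble(prediction = clamped, raw_prediction = raw,
                        clamped = raw != clamped, extrapolated = extrap)
  if ("id" %in% names(records))
    out <- dplyr::bind_cols(tibble::tibble(id = records$id), out)
  out
}

#' Generalized cross-validation score
#'
#' Computes `n * D / (n - edf_total)^2` with `D` the residual deviance
#' (sum of squared residuals for the Gaussian model) — the criterion whose
#' minimum the smoothing-parameter search reports.
#'
#' @param model An `efficiency_gam` with a native mgcv fit.
#' @param data Optional data frame with covariates and `efficiency`;
#'   defaults to the training data.
#' @return Scalar GCV score.
#' @export
gcv_score <- function(model, data = NULL) {
  stopifnot(inherits(model, "efficiency_gam"))
  if (is.null(model$fit))
    qe_stop("gcv_score needs a native fit (not a loaded portable model)",
            "qe_invalid_input")
  edf_total <- sum(model$fit$edf)
  if (is.null(data)) {
    r <- resid(model$fit)
  } else {
    pred <- as.numeric(predict(model$fit, newdata = as.data.frame(data)))
    r <- data$efficiency - pred
  }
  n <- length(r)
  if (edf_total >= n)
    qe_stop("effective degrees of freedom exceed the sample size",
            "qe_invalid_input")
  n * sum(r^2) / (n - edf_total)^2
}

#' Compare two fitted models by AIC
#'
#' `AIC = -2 log-likelihood + 2 edf_total`; the lower value wins, ties go
#' to the model with fewer effective degrees of freedom. Both models must
#' have been fitted to the same records.
#'
#' @param model_a,model_b `efficiency_gam` objects (or plain mgcv fits).
#' @return List: `preferred` (1 or 2), `delta_aic` (AIC_a - AIC_b),
#'   `aic_a`, `aic_b`.
#' @export
compare_models_aic <- function(model_a, model_b) {
  fa <- if (inherits(model_a, "efficiency_gam")) model_a$fit else model_a
  fb <- if (inherits(model_b, "efficiency_gam")) model_b$fit else model_b
  ya <- fa$y
  yb <- fb$y
  if (length(ya) != length(yb) || !isTRUE(all.equal(ya, yb)))
    qe_stop("models were fitted to different training data; AIC not comparable",
            "qe_incomparable_models")
  aic <- function(f) -2 * as.numeric(logLik(f)) + 2 * sum(f$edf)
  aa <- aic(fa)
  ab <- aic(fb)
  preferred <- if (aa < ab) 1L else if (ab < aa) 2L else
    if (sum(fa$edf) <= sum(fb$edf)) 1L else 2L
  list(preferred = preferred, delta_aic = aa - ab, aic_a = aa, aic_b = ab)
}

# ---- portable JSON serialization ------------------------------------------
# The model file stores everything prediction needs explicitly: the
# coefficient vector, each smooth's basis construction (knots, projection
# matrices, dimensions) and the training covariate ranges, under a version
# tag. Loading rebuilds the smooth objects and predicts through the same
# basis evaluation used at fit time.

# attributes beyond names/dim/class (e.g. the absorbed identifiability
# constraint "qrc"/"nCons" on a fitted smooth) are serialized recursively
ser_attrs <- function(x) {
  at <- attributes(x)
  at <- at[setdiff(names(at), c("names", "dim", "dimnames", "class"))]
  if (length(at) == 0L) return(NULL)
  lapply(at, ser_node)
}

ser_node <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  if (is.matrix(x)) return(list(t = "matrix", dim = dim(x),
                                v = as.vector(x), attrs = ser_attrs(x)))
  if (is.list(x)) {
    return(list(t = "list", class = class(x), names = names(x),
                items = lapply(x, ser_node), attrs = ser_attrs(x)))
  }
  if (is.numeric(x) || is.character(x) || is.logical(x))
    return(list(t = class(x)[1L], names = names(x), v = x,
                attrs = ser_attrs(x)))
  list(t = "skipped")
}

deser_node <- function(node) {
  tt <- node$t
  if (tt == "null" || tt == "skipped") return(NULL)
  out <- if (tt == "matrix") {
    matrix(as.numeric(unlist(node$v)),
           nrow = node$dim[[1]], ncol = node$dim[[2]])
  } else if (tt == "list") {
    items <- lapply(node$items, deser_node)
    names(items) <- as.character(node$names)
    cls <- as.character(unlist(node$class))
    if (!identical(cls, "list")) class(items) <- cls
    items
  } else {
    v <- unlist(node$v)
    v <- switch(tt, integer = as.integer(v), numeric = as.numeric(v),
                logical = as.logical(v), character = as.character(v), v)
    if (!is.null(node$names)) names(v) <- as.character(unlist(node$names))
    v
  }
  if (!is.null(node$attrs))
    for (a in names(node$attrs))
      attr(out, a) <- deser_node(node$attrs[[a]])
  out
}

#' Save / load a fitted efficiency GAM as a portable JSON file
#'
#' The file is self-describing (version tag, coefficients, smooth basis
#' construction, training ranges); a loaded model predicts identically to
#' the model it was saved from.
#'
#' @param model An `efficiency_gam` from [fit_gam()].
#' @param path Output / input file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns an
#'   `efficiency_gam` usable with [predict_efficiency()].
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "efficiency_gam"))
  if (is.null(model$fit))
    qe_stop("cannot re-save a loaded portable model", "qe_invalid_input")
  fit <- model$fit
  payload <- list(
    version = MODEL_FORMAT_VERSION,
    coefficients = ser_node(coef(fit)),
    smooths = lapply(fit$smooth, ser_node),
    ranges = model$ranges,
    scale = model$summary$scale_estimate,
    intercept = model$summary$intercept,
    n = model$n)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) qe_stop(
                        sprintf("cannot parse model file '%s': %s",
                                path, conditionMessage(e)), "qe_io_error"))
  if (is.null(payload$version) || !identical(payload$version,
                                             MODEL_FORMAT_VERSION))
    qe_stop(sprintf("unsupported model file version '%s' (expected '%s')",
                    payload$version %||% "<none>", MODEL_FORMAT_VERSION),
            "qe_version_error")
  if (is.null(payload$coefficients) || is.null(payload$smooths))
    qe_stop("model file is incomplete", "qe_io_error")
  portable <- list(
    coefficients = deser_node(payload$coefficients),
    smooths = lapply(payload$smooths, deser_node))
  ranges <- lapply(payload$ranges, function(r) as.numeric(unlist(r)))
  structure(list(fit = NULL,
                 portable = portable,
                 ranges = ranges,
                 summary = list(intercept = payload$intercept,
                                scale_estimate = payload$scale,
                                n = payload$n),
                 n = payload$n,
                 version = payload$version),
            class = "efficiency_gam")
}

predict_portable <- function(portable, newdata) {
  beta <- portable$coefficients
  eta <- rep(beta[[1L]], nrow(newdata))  # intercept
  for (sm in portable$smooths) {
    X <- mgcv::PredictMat(sm, newdata)
    idx <- sm$first.para:sm$last.para
    eta <- eta + as.numeric(X %*% beta[idx])
  }
  eta
}
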