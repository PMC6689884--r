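# Linear calibration from logG/R to nanologP, fit metrics, k-fold CV,
# and the ligand-weighted-average logP baseline.

#' The published logG/R-to-nanologP calibration
#'
#' The shipped default model carries the published coefficients
#' `nanologP = 0.7334 * logG/R - 2.4306`, fitted on a 41-particle
#' gold-nanoparticle library with experimentally measured octanol-water
#' logP.
#'
#' @return A `vgnp_calibration` model.
#' @export
#' @examples
#' predict_nanologp(0)    # the intercept, -2.4306
default_calibration <- function() {
  read_calibration(system.file("extdata", "default_model.json",
                               package = "vgnp"))
}

new_calibration <- function(slope, intercept, n_fit, metrics = NULL,
                            provenance = "fitted") {
  structure(list(slope = slope, intercept = intercept,
                 n_fit = as.integer(n_fit), metrics = metrics,
                 provenance = provenance),
            class = "vgnp_calibration")
}

#' Fit the linear calibration
#'
#' Ordinary least squares of experimental logP (`elogp`) on `log_g_over_r`
#' over particle records; metrics are computed on the fit set.
#'
#' @param records Data frame with numeric columns `log_g_over_r` and
#'   `elogp`; rows with either value missing are dropped.
#' @return A `vgnp_calibration` with `slope`, `intercept`, `n_fit` and
#'   `metrics` (r_squared, mae, rmse).
#' @export
fit_calibration <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("log_g_over_r", "elogp") %in% names(records)))
  d <- records[is.finite(records$log_g_over_r) & is.finite(records$elogp),
               c("log_g_over_r", "elogp")]
  if (nrow(d) < 2) {
    vgnp_abort(sprintf(
      "need >= 2 records with both logG/R and elogP (got %d)", nrow(d)),
      "vgnp_fit_error")
  }
  if (stats::sd(d$log_g_over_r) == 0) {
    vgnp_abort("zero variance in logG/R; cannot fit a line",
               "vgnp_fit_error")
  }
  fit <- stats::lm(elogp ~ log_g_over_r, data = d)
  model <- new_calibration(unname(stats::coef(fit)[2]),
                           unname(stats::coef(fit)[1]), nrow(d))
  # metrics from the model's own prediction path, so predict-after-fit
  # reproduces them bit-exactly
  model$metrics <- regression_metrics(
    predict_nanologp(d$log_g_over_r, model), d$elogp)
  model
}

#' Predict nanologP from logG/R
#'
#' @param x Numeric vector of logG/R values.
#' @param model A `vgnp_calibration`; the published default if omitted.
#' @return `slope * x + intercept`.
#' @export
predict_nanologp <- function(x, model = default_calibration()) {
  stopifnot(inherits(model, "vgnp_calibration"), is.numeric(x))
  model$slope * x + model$intercept
}

#' Regression accuracy metrics
#'
#' Coefficient of determination `R^2 = 1 - SSres/SStot` (not squared
#' Pearson r), mean absolute error, and root mean square error.
#'
#' @param pred,obs Equal-length numeric vectors (n >= 2).
#' @return List with `r_squared`, `mae`, `rmse`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(0, 1, 2))  # R^2 = -0.5, MAE = RMSE = 1
regression_metrics <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    vgnp_abort("pred and obs must have equal length", "vgnp_domain_error")
  }
  if (length(obs) < 2) {
    vgnp_abort("need at least 2 observations", "vgnp_domain_error")
  }
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0) {
    vgnp_abort("constant observations: R^2 undefined", "vgnp_domain_error")
  }
  res <- obs - pred
  list(r_squared = 1 - sum(res^2) / sstot,
       mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)))
}

#' k-fold cross-validation of the calibration
#'
#' Seeded uniform random partition into k near-equal folds; the line is
#' refit on each training portion and evaluated on the held-out fold;
#' metrics are pooled over all held-out predictions (not averaged per
#' fold), which keeps them comparable with fit-set metrics at small n.
#'
#' @param records As in [fit_calibration()].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return List with `metrics`, `predictions` (data frame of observed,
#'   predicted, fold), `k`, `seed`.
#' @export
kfold_cv <- function(records, k = 5L, seed = 1L) {
  stopifnot(is.data.frame(records))
  d <- records[is.finite(records$log_g_over_r) & is.finite(records$elogp),
               c("log_g_over_r", "elogp")]
  n <- nrow(d)
  if (k < 2) vgnp_abort("k must be >= 2", "vgnp_domain_error")
  if (k > n) {
    vgnp_abort(sprintf("k = %d exceeds usable records n = %d", k, n),
               "vgnp_domain_error")
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    hold <- folds == f
    model <- fit_calibration(d[!hold, , drop = FALSE])
    pred[hold] <- predict_nanologp(d$log_g_over_r[hold], model)
  }
  list(metrics = regression_metrics(pred, d$elogp),
       predictions = data.frame(observed = d$elogp, predicted = pred,
                                fold = folds),
       k = as.integer(k), seed = as.integer(seed))
}

#' Ligand-weighted-average logP baseline
#'
#' The surface-ligand-only baseline: the particle's logP approximated by
#' the ligand logP values averaged with the ligand copy numbers as
#' weights.  Ligand logP values come from the same atom-contribution
#' scheme as the surface potential.
#'
#' @param logp Numeric vector of per-ligand logP values.
#' @param counts Matching vector of copy numbers (sum > 0).
#' @return The weighted average.
#' @export
#' @examples
#' ligand_baseline_logp(c(3, -1), c(30, 10))  # 2
ligand_baseline_logp <- function(logp, counts) {
  stopifnot(is.numeric(logp), is.numeric(counts),
            length(logp) == length(counts))
  if (sum(counts) <= 0) {
    vgnp_abort("total ligand count must be > 0", "vgnp_domain_error")
  }
  sum(logp * counts) / sum(counts)
}

#' Read / write a calibration model as JSON
#'
#' @param path File path.
#' @return `read_calibration` returns a `vgnp_calibration`;
#'   `write_calibration` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration(j$slope, j$intercept, j$n_fit %||% NA_integer_,
                  metrics = j$metrics, provenance = j$provenance %||% "file")
}

#' @rdname read_calibration
#' @param model A `vgnp_calibration`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "vgnp_calibration"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.vgnp_calibration <- function(x, ...) {
  cat(sprintf("<vgnp_calibration> nanologP = %.4f * logG/R %+.4f  (%s, n = %s)\n",
              x$slope, x$intercept, x$provenance,
              ifelse(is.na(x$n_fit), "?", x$n_fit)))
  if (!is.null(x$metrics)) {
    cat(sprintf("  fit metrics: R^2 = %.3f, MAE = %.3f, RMSE = %.3f\n",
                x$metrics$r_squared, x$metrics$mae, x$metrics$rmse))
  }
  invisible(x)
}
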