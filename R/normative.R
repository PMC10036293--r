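#' Fit per-region normative regression models in controls
#'
#' For each (roi, modality) the control values are regressed by ordinary
#' least squares on age, sex, total intracranial volume and scanner type
#' (one additive offset per non-reference scanner category; the reference
#' is the most frequent category among controls, ties broken
#' lexicographically). The residual standard deviation sigma of each fit is
#' the denominator of the w-score; a carrier's w-score is their observed
#' value minus the control-model prediction, divided by sigma, and is
#' interpreted like a Z-score against the control distribution.
#'
#' Models with (numerically) zero residual variance are flagged degenerate
#' and refuse to score. Rows with incomplete covariates or missing values
#' are dropped per region (complete-case; counts logged); a region whose
#' values are all missing is skipped with a log entry.
#'
#' @param measures Long table with columns `participant_id`, `roi`,
#'   `modality`, `value` (controls only).
#' @param covariates One row per control: `participant_id`, `age_years`,
#'   `sex` (`"female"`/`"male"`), `tiv_mm3`, `scanner`.
#' @param sigma_df Degrees-of-freedom convention for sigma:
#'   `"residual"` (default; `RSS / (n - p)`) or `"n-1"` (`RSS / (n - 1)`).
#' @return An object of class `normative_fit`: a list of per-region models
#'   with `print`, `summary`, `coef`, `sigma`, `predict`, `residuals` and
#'   `simulate` methods.
#' @examples
#' spec <- default_genfi_spec()
#' rm <- control_model_params(data.frame(roi = "hippocampus",
#'                                       modality = "volume"))
#' ctl <- generate_controls(spec, rm, seed = 7)
#' fit <- fit_normative(ctl$measures, ctl$participants)
#' summary(fit)
#' @export
fit_normative <- function(measures, covariates,
                          sigma_df = c("residual", "n-1")) {
  sigma_df <- match.arg(sigma_df)
  check_columns(measures, c("participant_id", "roi", "modality", "value"),
                "measures")
  check_columns(covariates, c("participant_id", "age_years", "sex",
                              "tiv_mm3", "scanner"), "covariates")
  if (anyDuplicated(covariates$participant_id))
    stop_wnorm("fit_normative: duplicated participant_id in covariates")

  scan_tab <- table(covariates$scanner)
  scanner_levels <- sort(names(scan_tab))
  reference <- sort(names(scan_tab)[scan_tab == max(scan_tab)])[1]

  keys <- unique(measures[c("roi", "modality")])
  models <- list()
  for (i in seq_len(nrow(keys))) {
    roi <- keys$roi[i]; modality <- keys$modality[i]
    rows <- measures[measures$roi == roi & measures$modality == modality, ]
    cov <- covariates[match(rows$participant_id, covariates$participant_id), ]
    ok <- stats::complete.cases(cov[c("age_years", "sex", "tiv_mm3",
                                      "scanner")]) & is.finite(rows$value)
    if (!all(ok))
      wn_log("%s/%s: dropped %d incomplete row(s)", roi, modality, sum(!ok))
    if (!any(ok)) {
      wn_log("%s/%s: all values missing; model skipped", roi, modality)
      next
    }
    y <- rows$value[ok]; cov <- cov[ok, ]
    X <- normative_design(cov, scanner_levels, reference)
    p <- ncol(X)
    if (length(y) <= p)
      stop_wnorm("fit_normative: %s/%s has %d usable controls for %d parameters",
                 roi, modality, length(y), p)
    qx <- qr(X)
    if (qx$rank < p) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
      stop_wnorm("fit_normative: %s/%s design is rank-deficient; collinear column(s): %s",
                 roi, modality, paste(bad, collapse = ", "))
    }
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    n <- length(y)
    df <- if (sigma_df == "residual") n - p else n - 1
    sigma <- sqrt(rss / df)
    degenerate <- sigma <= 1e-10 * max(1, mean(abs(y)))
    if (degenerate)
      wn_log("%s/%s: zero residual variance; model flagged degenerate",
             roi, modality)
    models[[paste(roi, modality, sep = "|")]] <- list(
      roi = roi, modality = modality,
      coefficients = fit$coefficients, sigma = sigma, n = n, p = p,
      df_residual = n - p, degenerate = degenerate,
      residuals = stats::setNames(fit$residuals, rows$participant_id[ok])
    )
  }
  if (!length(models))
    stop_wnorm("fit_normative: no fittable (roi, modality) found")
  structure(list(models = models, sigma_df = sigma_df,
                 scanner_levels = scanner_levels, reference = reference,
                 call = match.call()),
            class = "normative_fit")
}

# Design matrix: intercept, age, sex (female=0/male=1), TIV, scanner
# dummies relative to the reference category.
normative_design <- function(cov, scanner_levels, reference) {
  unseen <- setdiff(unique(cov$scanner), scanner_levels)
  if (length(unseen))
    stop_wnorm("unseen scanner category: %s (model knows: %s)",
               paste(unseen, collapse = ", "),
               paste(scanner_levels, collapse = ", "))
  bad_sex <- setdiff(unique(cov$sex), c("female", "male"))
  if (length(bad_sex))
    stop_wnorm("sex must be 'female' or 'male'; got: %s",
               paste(bad_sex, collapse = ", "))
  others <- setdiff(scanner_levels, reference)
  X <- cbind(`(Intercept)` = 1,
             age_years = cov$age_years,
             sex_male = as.numeric(cov$sex == "male"),
             tiv_mm3 = cov$tiv_mm3)
  for (s in others)
    X <- cbind(X, as.numeric(cov$scanner == s))
  nm <- c("(Intercept)", "age_years", "sex_male", "tiv_mm3")
  if (length(others)) nm <- c(nm, paste0("scanner", others))
  colnames(X) <- nm
  X
}

#' @export
print.normative_fit <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Normative model set: %d (roi, modality) model(s)\n",
              nrow(s)))
  cat(sprintf("  covariates: age, sex, TIV, scanner (%d categories, ref %s)\n",
              length(x$scanner_levels), x$reference))
  cat(sprintf("  sigma convention: %s; degenerate models: %d\n",
              x$sigma_df, sum(s$degenerate)))
  invisible(x)
}

#' @export
summary.normative_fit <- function(object, ...) {
  out <- do.call(rbind, lapply(object$models, function(m)
    data.frame(roi = m$roi, modality = m$modality, n = m$n,
               df_residual = m$df_residual, sigma = m$sigma,
               degenerate = m$degenerate, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' @export
coef.normative_fit <- function(object, ...) {
  t(vapply(object$models, function(m) m$coefficients,
           numeric(object$models[[1]]$p)))
}

#' Residual standard deviations of a normative fit
#' @param object A `normative_fit`.
#' @param ... Unused.
#' @return Named vector of sigma per `roi|modality`.
#' @importFrom stats sigma
#' @export
sigma.normative_fit <- function(object, ...) {
  vapply(object$models, function(m) m$sigma, numeric(1))
}

#' @export
residuals.normative_fit <- function(object, ...) {
  out <- do.call(rbind, lapply(object$models, function(m)
    data.frame(participant_id = names(m$residuals), roi = m$roi,
               modality = m$modality, residual = unname(m$residuals),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Predict expected regional values for new participants
#'
#' Evaluates each region's control-model linear predictor at the new
#' participants' age, sex, TIV and scanner. A scanner category the control
#' fit never saw raises an error; there is no silent fallback.
#'
#' @param object A `normative_fit`.
#' @param newdata Covariate table (`participant_id`, `age_years`, `sex`,
#'   `tiv_mm3`, `scanner`).
#' @param ... Unused.
#' @return Long data frame `participant_id`, `roi`, `modality`,
#'   `predicted`.
#' @export
predict.normative_fit <- function(object, newdata, ...) {
  check_columns(newdata, c("participant_id", "age_years", "sex", "tiv_mm3",
                           "scanner"), "newdata")
  X <- normative_design(newdata, object$scanner_levels, object$reference)
  out <- do.call(rbind, lapply(object$models, function(m)
    data.frame(participant_id = newdata$participant_id, roi = m$roi,
               modality = m$modality,
               predicted = drop(X %*% m$coefficients),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Simulate regional measures from a fitted normative model
#'
#' Draws `value = prediction + N(0, sigma)` for each (participant, roi,
#' modality); useful for posterior-predictive style checks of the control
#' model.
#'
#' @param object A `normative_fit`.
#' @param nsim Number of simulated replicates.
#' @param seed Integer seed or `NULL`.
#' @param newdata Covariate table (defaults must be supplied; the fit does
#'   not store covariates).
#' @param ... Unused.
#' @return For `nsim = 1` a measure table; otherwise a list of them.
#' @export
simulate.normative_fit <- function(object, nsim = 1, seed = NULL,
                                   newdata, ...) {
  pred <- predict(object, newdata)
  sig <- sigma(object)[paste(pred$roi, pred$modality, sep = "|")]
  sims <- with_seed(seed, lapply(seq_len(nsim), function(k) {
    out <- pred
    out$value <- out$predicted + stats::rnorm(nrow(out), 0, sig)
    out$predicted <- NULL
    out
  }))
  if (nsim == 1) sims[[1]] else sims
}

#' Compute covariate-adjusted w-scores
#'
#' For each measure row, `w = (value - predicted) / sigma` where the
#' prediction and sigma come from that region's control model, together
#' with the implied control percentile `100 * pnorm(w)`. Rows whose region
#' has no (or a degenerate) model, or whose covariates are incomplete, are
#' skipped with a log entry.
#'
#' @param object A `normative_fit`.
#' @param measures Long measure table for the participants to score.
#' @param covariates Covariate table covering those participants.
#' @return Data frame of class `wscore_table`: `participant_id`, `roi`,
#'   `modality`, `value`, `predicted`, `wscore`, `percentile`.
#' @examples
#' spec <- default_genfi_spec()
#' rm <- control_model_params(data.frame(roi = "thalamus",
#'                                       modality = "volume"))
#' ctl <- generate_controls(spec, rm, seed = 1)
#' fit <- fit_normative(ctl$measures, ctl$participants)
#' w <- wscore(fit, ctl$measures, ctl$participants)
#' mean(w$wscore)  # 0 to numerical precision (in-sample controls)
#' @export
wscore <- function(object, measures, covariates) {
  stopifnot(inherits(object, "normative_fit"))
  check_columns(measures, c("participant_id", "roi", "modality", "value"),
                "measures")
  check_columns(covariates, c("participant_id", "age_years", "sex",
                              "tiv_mm3", "scanner"), "covariates")
  cov <- covariates[match(measures$participant_id,
                          covariates$participant_id), ]
  ok_cov <- stats::complete.cases(cov[c("age_years", "sex", "tiv_mm3",
                                        "scanner")])
  if (!all(ok_cov))
    wn_log("wscore: skipped %d row(s) with missing covariates", sum(!ok_cov))
  key <- paste(measures$roi, measures$modality, sep = "|")
  usable <- vapply(object$models, function(m) !m$degenerate, logical(1))
  has_model <- key %in% names(object$models)[usable]
  if (!all(has_model))
    wn_log("wscore: skipped %d row(s) without a usable model (%s)",
           sum(!has_model),
           paste(utils::head(unique(key[!has_model]), 4), collapse = ", "))
  keep <- ok_cov & has_model & is.finite(measures$value)
  if (!any(keep)) {
    out <- data.frame(participant_id = character(), roi = character(),
                      modality = character(), value = numeric(),
                      predicted = numeric(), wscore = numeric(),
                      percentile = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("wscore_table", "data.frame")
    return(out)
  }
  meas <- measures[keep, , drop = FALSE]
  cov <- cov[keep, , drop = FALSE]
  key <- key[keep]

  X <- normative_design(cov, object$scanner_levels, object$reference)
  cf <- t(vapply(object$models[key], function(m) m$coefficients,
                 numeric(ncol(X))))
  predicted <- rowSums(X * cf)
  sig <- vapply(object$models[key], function(m) m$sigma, numeric(1))
  w <- (meas$value - predicted) / sig
  out <- data.frame(participant_id = meas$participant_id, roi = meas$roi,
                    modality = meas$modality, value = meas$value,
                    predicted = predicted, wscore = w,
                    percentile = wscore_percentile(w),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("wscore_table", "data.frame")
  out
}

#' W-score cut point for a control percentile
#'
#' The inverse standard-normal CDF: the w-score below which a fraction `p`
#' of the control distribution lies. `percentile_cutpoint(0.10)` is
#' -1.282, the default abnormality cut; 0.025, 0.05 and 0.25 give -1.960,
#' -1.645 and -0.675.
#'
#' @param p Probability strictly inside (0, 1).
#' @return The w-score cut point.
#' @export
percentile_cutpoint <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop_wnorm("percentile_cutpoint: 'p' must lie strictly in (0, 1)")
  stats::qnorm(p)
}

#' Control percentile implied by a w-score
#'
#' `100 * pnorm(w)`; the inverse of [percentile_cutpoint()] (up to the
#' factor 100). A w-score of 0 sits at the 50th control percentile,
#' -0.675 at the 25th.
#'
#' @param w Finite w-score(s).
#' @return Percentile(s) in (0, 100).
#' @export
wscore_percentile <- function(w) {
  if (any(!is.finite(w)))
    stop_wnorm("wscore_percentile: 'w' must be finite")
  100 * stats::pnorm(w)
}

#' Serialize a normative fit to JSON
#'
#' Coefficients and sigmas are written without rounding (numbers
#' round-trip to within one unit in the last place) so fitting and scoring
#' can run as separate steps without meaningful drift.
#'
#' @param object A `normative_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_normative_json <- function(object, path) {
  stopifnot(inherits(object, "normative_fit"))
  payload <- list(
    format = "wnorm-normative-models",
    version = 1L,
    sigma_df = object$sigma_df,
    scanner_levels = object$scanner_levels,
    reference = object$reference,
    models = lapply(object$models, function(m)
      m[c("roi", "modality", "coefficients", "sigma", "n", "p",
          "df_residual", "degenerate")])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a normative fit back from JSON
#' @param path File written by [write_normative_json()].
#' @return A `normative_fit` (without stored residuals).
#' @export
read_normative_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "wnorm-normative-models"))
    stop_wnorm("read_normative_json: '%s' is not a normative model file",
               path)
  models <- lapply(payload$models, function(m) {
    m$coefficients <- unlist(m$coefficients)
    m$residuals <- NULL
    m
  })
  structure(list(models = models, sigma_df = payload$sigma_df,
                 scanner_levels = payload$scanner_levels,
                 reference = payload$reference, call = NULL),
            class = "normative_fit")
}
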