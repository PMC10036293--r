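# Shared fixtures and independent oracles built in code.

# Small cohort spec for fast end-to-end runs.
small_spec <- function(seed = 11L, n_controls = 80) {
  cohort_spec(
    controls               = group_spec(n_controls, 44.8, 12.2, 0.43),
    c9orf72_presymptomatic = group_spec(40, 45.0, 11.5, 0.42),
    c9orf72_symptomatic    = group_spec(10, 63.5, 7.4, 0.66),
    mapt_presymptomatic    = group_spec(20, 41.1, 10.6, 0.40),
    mapt_symptomatic       = group_spec(5, 59.2, 9.3, 0.60),
    grn_presymptomatic     = group_spec(40, 46.5, 12.2, 0.37),
    grn_symptomatic        = group_spec(8, 63.3, 8.1, 0.47),
    seed = seed
  )
}

# A single-region generative model, optionally overriding parameters.
one_roi_model <- function(roi = "hippocampus", modality = "volume", ...) {
  params <- control_model_params(data.frame(roi = roi, modality = modality,
                                            stringsAsFactors = FALSE))
  override <- list(...)
  for (nm in names(override)) params[[nm]] <- override[[nm]]
  params
}

# Generative-model linear predictor recomputed independently in the test.
oracle_sim_mu <- function(params, participants) {
  off <- unlist(params[paste0("offset_", scanner_types())])
  unname(params$intercept +
           params$beta_age * participants$age_years +
           params$beta_sex * (participants$sex == "male") +
           params$beta_tiv * participants$tiv_mm3 +
           off[match(participants$scanner, scanner_types())])
}

eff_df_test <- function(roi, modality, effect) {
  data.frame(roi = roi, modality = modality, effect = effect,
             stringsAsFactors = FALSE)
}

# All (gene, scale, status) cells with a common change model.
expand_changes <- function(genes, mean_change, sd_change,
                           status = c("normal", "abnormal")) {
  g <- expand.grid(gene = genes, scale = c("cdr_sb", "cbi_r"),
                   status = status, stringsAsFactors = FALSE)
  g$mean_change <- mean_change
  g$sd_change <- sd_change
  g
}

# Brute-force normal-equation OLS oracle on an explicit design matrix.
oracle_ols <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

# Brute-force exact signed-rank p by enumerating all 2^n sign vectors.
oracle_signed_rank_p <- function(deltas) {
  d <- deltas[deltas != 0]
  n <- length(d)
  if (n == 0) return(NA_real_)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- drop(signs %*% r)
  eps <- 1e-9
  p_ge <- mean(Ws >= W - eps)
  p_le <- mean(Ws <= W + eps)
  min(1, 2 * min(p_ge, p_le))
}

# Deterministic six-row covariate fixture with two scanner categories.
six_row_covariates <- function() {
  data.frame(
    participant_id = sprintf("P%02d", 1:6),
    age_years = c(35, 42, 58, 61, 47, 53),
    sex = c("female", "male", "male", "female", "male", "female"),
    tiv_mm3 = c(1.35e6, 1.52e6, 1.41e6, 1.29e6, 1.60e6, 1.44e6),
    scanner = c("A", "A", "A", "B", "B", "B"),
    stringsAsFactors = FALSE
  )
}

# A hand-specified normative fit (intercept-only, sigma known exactly),
# loaded through the package's own JSON model format.
fixed_fit <- function(intercept = 1000, sigma = 50) {
  path <- tempfile(fileext = ".json")
  payload <- list(
    format = "wnorm-normative-models", version = 1L,
    sigma_df = "residual",
    scanner_levels = scanner_types(), reference = scanner_types()[1],
    models = list(`hippocampus|volume` = list(
      roi = "hippocampus", modality = "volume",
      coefficients = stats::setNames(
        c(intercept, rep(0, 7)),
        c("(Intercept)", "age_years", "sex_male", "tiv_mm3",
          paste0("scanner", scanner_types()[-1]))),
      sigma = sigma, n = 100L, p = 8L, df_residual = 92L,
      degenerate = FALSE))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  read_normative_json(path)
}
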