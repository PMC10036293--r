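#' Generative control-model parameters per region
#'
#' The per-(roi, modality) linear model the simulator uses for controls:
#' `value = intercept + beta_age * age + beta_sex * male + beta_tiv * TIV +
#' scanner offset + N(0, sigma)`. Sex is coded female = 0, male = 1.
#' Scanner offsets are small non-zero multiples of the residual SD so the
#' multi-site adjustment is genuinely exercised; the first category
#' (Siemens Trio) is the zero-offset reference.
#'
#' Default magnitudes are plausible for bilateral regional measures:
#' cortical regions around 2.2e4 mm^3 losing ~40 mm^3/year, whole
#' subcortical structures around 6e3 mm^3, tract FA around 0.46 declining
#' slowly with age, tract MD around 7.5e-4 mm^2/s rising with age.
#'
#' @param rois Optional data frame with columns `roi`, `modality` to
#'   restrict the parameter table (default: the full registry grid).
#' @return Data frame of class `roi_model_params` with one row per
#'   (roi, modality): `intercept`, `beta_age`, `beta_sex`, `beta_tiv`,
#'   `sigma` and one `offset_<scanner>` column per scanner category.
#' @export
control_model_params <- function(rois = NULL) {
  reg <- roi_registry()
  grid <- roi_modality_grid(include_subfields = TRUE)
  grid$class <- reg$class[match(grid$roi, reg$roi)]

  base <- function(class, modality) {
    if (modality == "volume") {
      switch(class,
        cortical    = c(22000, -40,   800,  8e-3, 1800),
        subcortical = c(6000,  -12,   200,  3e-3, 500),
        subfield    = c(1200,  -3,    40,   5e-4, 120))
    } else if (modality == "FA") {
      c(0.46, -8e-4, 5e-3, 1e-9, 0.022)
    } else {
      c(7.5e-4, 1.5e-6, 5e-6, 1e-13, 3e-5)
    }
  }
  pars <- t(vapply(seq_len(nrow(grid)),
                   function(i) base(grid$class[i], grid$modality[i]),
                   numeric(5)))
  colnames(pars) <- c("intercept", "beta_age", "beta_sex", "beta_tiv",
                      "sigma")
  out <- cbind(grid[c("roi", "modality")], as.data.frame(pars))
  # whole brain dwarfs the other volumes; give it its own scale
  wb <- out$roi == "whole_brain"
  out[wb, c("intercept", "beta_age", "beta_sex", "beta_tiv", "sigma")] <-
    list(1.1e6, -3000, 2e4, 0.55, 6e4)

  offset_mult <- c(0, 0.40, -0.30, 0.20, -0.25)
  for (k in seq_along(scanner_types()))
    out[[paste0("offset_", scanner_types()[k])]] <- offset_mult[k] * out$sigma

  if (!is.null(rois)) {
    check_columns(rois, c("roi", "modality"), "rois")
    key <- paste(out$roi, out$modality)
    want <- paste(rois$roi, rois$modality)
    missing <- setdiff(want, key)
    if (length(missing))
      stop_wnorm("control_model_params: unknown (roi, modality): %s",
                 paste(missing, collapse = "; "))
    out <- out[key %in% want, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("roi_model_params", "data.frame")
  out
}

# Linear predictor of the generative control model for a covariate table.
sim_predict <- function(params_row, covars) {
  off <- unlist(params_row[paste0("offset_", scanner_types())])
  params_row$intercept +
    params_row$beta_age * covars$age_years +
    params_row$beta_sex * (covars$sex == "male") +
    params_row$beta_tiv * covars$tiv_mm3 +
    off[match(covars$scanner, scanner_types())]
}

# Draw demographics + baseline clinical scores for one group.
sim_participants <- function(grp, spec, group, stage, id_prefix) {
  n <- grp$n
  if (n == 0L) return(NULL)
  df <- data.frame(
    participant_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    group = group,
    stage = stage,
    age_years = stats::rnorm(n, grp$age_mean, grp$age_sd),
    sex = ifelse(stats::runif(n) < grp$prop_male, "male", "female"),
    tiv_mm3 = stats::rnorm(n, spec$tiv_mean, spec$tiv_sd),
    scanner = sample(names(spec$scanner_probs), n, replace = TRUE,
                     prob = spec$scanner_probs),
    visit = "baseline",
    stringsAsFactors = FALSE
  )
  df$age_years <- clamp_logged(df$age_years, 18, 95, "age")
  df$tiv_mm3 <- clamp_logged(df$tiv_mm3, 9e5, 2.1e6, "TIV")
  if (group == "control") {
    df$cdr_global <- 0
    df$cdr_sb <- 0
    df$cbi_r <- pmax(0, round(stats::rnorm(n, 1.5, 2.5)))
  } else if (stage == "presymptomatic") {
    df$cdr_global <- sample(c(0, 0.5), n, replace = TRUE, prob = c(0.6, 0.4))
    base_cbi <- c(C9orf72 = 9.0, MAPT = 6.8, GRN = 5.2)
    sd_cbi <- c(C9orf72 = 9.5, MAPT = 7.8, GRN = 8.5)
    df$cdr_sb <- pmax(0, round(stats::rnorm(n, 0.2, 0.5), 1))
    df$cbi_r <- pmin(180, pmax(0, round(stats::rnorm(n, base_cbi[[group]],
                                                     sd_cbi[[group]]))))
  } else {
    df$cdr_global <- sample(c(1, 2, 3), n, replace = TRUE,
                            prob = c(0.6, 0.3, 0.1))
    df$cdr_sb <- pmax(df$cdr_global, round(stats::rnorm(n, 6, 3), 1))
    df$cbi_r <- pmin(180, pmax(0, round(stats::rnorm(n, 45, 25))))
  }
  df
}

# Draw regional measures for a participant table; `shift` is an optional
# (roi, modality, effect) table applied in residual-SD units.
sim_measures <- function(participants, roi_model, shift = NULL) {
  out <- vector("list", nrow(roi_model))
  for (i in seq_len(nrow(roi_model))) {
    p <- roi_model[i, ]
    mu <- sim_predict(p, participants)
    if (!is.null(shift)) {
      hit <- shift$roi == p$roi & shift$modality == p$modality
      if (any(hit)) mu <- mu + shift$effect[hit][1] * p$sigma
    }
    val <- mu + stats::rnorm(nrow(participants), 0, p$sigma)
    if (p$modality == "volume") val <- clamp_logged(val, 0, Inf, "volume")
    if (p$modality == "FA") val <- clamp_logged(val, 0, 1, "FA")
    if (p$modality == "MD") val <- clamp_logged(val, 1e-6, Inf, "MD")
    out[[i]] <- data.frame(participant_id = participants$participant_id,
                           roi = p$roi, modality = p$modality, value = val,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic control cohort
#'
#' Draws control demographics from the cohort spec and regional measures
#' from the generative control model. Identical `(spec, roi_model, seed)`
#' inputs reproduce bit-identical tables.
#'
#' @param spec A [cohort_spec()].
#' @param roi_model A [control_model_params()] table.
#' @param seed Integer seed (default: the spec's seed).
#' @return List with elements `participants` (one row per participant) and
#'   `measures` (participant x roi x modality long table).
#' @examples
#' spec <- default_genfi_spec()
#' rm1 <- control_model_params(data.frame(roi = "thalamus",
#'                                        modality = "volume"))
#' ctl <- generate_controls(spec, rm1, seed = 42)
#' nrow(ctl$participants)  # 240
#' @export
generate_controls <- function(spec, roi_model = control_model_params(),
                              seed = spec$seed) {
  if (!inherits(spec, "cohort_spec"))
    stop_wnorm("generate_controls: 'spec' must be a cohort_spec")
  with_seed(seed, {
    part <- sim_participants(spec$controls, spec, "control", "control", "CTL")
    meas <- sim_measures(part, roi_model)
    list(participants = part, measures = meas)
  })
}

#' Generate synthetic mutation-carrier cohorts
#'
#' Carrier measures equal the generative control-model prediction plus
#' `effect * sigma_roi` (the configured regional shift in control-residual
#' SD units) plus Gaussian noise, so the expected carrier w-score in a
#' region equals the configured effect by construction.
#'
#' @inheritParams generate_controls
#' @param effects Named list of [roi_effect_map()] objects keyed
#'   `"<gene>.<stage>"` (see [default_effect_maps()]); groups without a map
#'   get no regional shift.
#' @return List with `participants` and `measures` tables covering all six
#'   gene-by-stage groups with non-zero n.
#' @export
generate_carriers <- function(spec, roi_model = control_model_params(),
                              effects = default_effect_maps(),
                              seed = spec$seed) {
  if (!inherits(spec, "cohort_spec"))
    stop_wnorm("generate_carriers: 'spec' must be a cohort_spec")
  registry <- paste(roi_modality_grid()$roi, roi_modality_grid()$modality)
  simulated <- paste(roi_model$roi, roi_model$modality)
  for (m in effects) {
    if (!inherits(m, "roi_effect_map"))
      stop_wnorm("generate_carriers: 'effects' must contain roi_effect_map objects")
    key <- paste(m$effects$roi, m$effects$modality)
    off <- setdiff(key, registry)
    if (length(off))
      stop_wnorm("generate_carriers: effect map %s.%s references unknown (roi, modality): %s",
                 m$gene, m$stage, paste(off, collapse = "; "))
    unsim <- setdiff(key, simulated)
    if (length(unsim))
      wn_log("effect map %s.%s: %d effect(s) on regions not simulated; ignored",
             m$gene, m$stage, length(unsim))
  }
  keys <- vapply(effects, function(m) paste(m$gene, m$stage, sep = "."),
                 character(1))
  cells <- expand.grid(gene = c("C9orf72", "MAPT", "GRN"),
                       stage = c("presymptomatic", "symptomatic"),
                       stringsAsFactors = FALSE)
  with_seed(seed, {
    parts <- list(); meass <- list()
    for (i in seq_len(nrow(cells))) {
      gene <- cells$gene[i]; stage <- cells$stage[i]
      grp_name <- paste0(tolower(gene), "_", stage)
      grp <- spec[[grp_name]]
      if (grp$n == 0L) next
      prefix <- paste0(toupper(substr(gene, 1, 2)),
                       ifelse(stage == "presymptomatic", "P", "S"))
      part <- sim_participants(grp, spec, gene, stage, prefix)
      key <- paste(gene, stage, sep = ".")
      shift <- if (key %in% keys) effects[[which(keys == key)[1]]]$effects
      parts[[key]] <- part
      meass[[key]] <- sim_measures(part, roi_model, shift = shift)
    }
    list(participants = do.call(rbind, c(parts, make.row.names = FALSE)),
         measures = do.call(rbind, c(meass, make.row.names = FALSE)))
  })
}

#' Generate 12-month follow-up clinical scores
#'
#' Each baseline participant is retained with the per-gene follow-up
#' availability probability; retained participants gain a `month12` record
#' whose CDR sum-of-boxes and CBI-R scores equal baseline plus a Gaussian
#' change drawn from the (gene, scale, abnormality status) cell of the
#' progression spec, floored at 0 (CBI-R additionally capped at 180).
#'
#' @param participants Baseline participant table (carriers) with columns
#'   `participant_id`, `group`, `visit`, `cdr_global`, `cdr_sb`, `cbi_r`.
#' @param prog A [progression_spec()].
#' @param abnormality Data frame with columns `participant_id`, `status`
#'   (`"normal"`/`"abnormal"`), derived from baseline measures.
#' @param seed Integer seed.
#' @return Long clinical table (baseline rows for all participants plus
#'   `month12` rows for retained ones) with columns `participant_id`,
#'   `group`, `visit`, `cdr_global`, `cdr_sb`, `cbi_r`.
#' @export
generate_followup <- function(participants, prog, abnormality, seed = 1L) {
  if (!inherits(prog, "progression_spec"))
    stop_wnorm("generate_followup: 'prog' must be a progression_spec")
  check_columns(participants, c("participant_id", "group", "visit",
                                "cdr_global", "cdr_sb", "cbi_r"),
                "participants")
  check_columns(abnormality, c("participant_id", "status"), "abnormality")
  base <- participants[participants$visit == "baseline", , drop = FALSE]
  status <- abnormality$status[match(base$participant_id,
                                     abnormality$participant_id)]
  if (anyNA(status))
    stop_wnorm("generate_followup: missing abnormality label for: %s",
               paste(utils::head(base$participant_id[is.na(status)], 5),
                     collapse = ", "))
  with_seed(seed, {
    avail <- prog$availability[base$group]
    keep <- stats::runif(nrow(base)) < avail
    fu <- base[keep, , drop = FALSE]
    st <- status[keep]
    key_tab <- paste(prog$changes$gene, prog$changes$scale,
                     prog$changes$status)
    draw <- function(scale, baseline, upper) {
      i <- match(paste(fu$group, scale, st), key_tab)
      if (anyNA(i))
        stop_wnorm("generate_followup: progression spec lacks cell(s): %s",
                   paste(unique(paste(fu$group, scale, st)[is.na(i)]),
                         collapse = "; "))
      delta <- stats::rnorm(nrow(fu), prog$changes$mean_change[i],
                            prog$changes$sd_change[i])
      pmin(upper, pmax(0, baseline + delta))
    }
    fu$visit <- "month12"
    fu$cdr_sb <- draw("cdr_sb", fu$cdr_sb, Inf)
    fu$cbi_r <- draw("cbi_r", fu$cbi_r, 180)
    out <- rbind(base, fu)
    rownames(out) <- NULL
    out
  })
}
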