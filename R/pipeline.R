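#' Configure an end-to-end pipeline run
#'
#' Bundles the cohort specification, generative regional model, effect
#' maps, clinical-change model and the analysis parameters (abnormality
#' cut, bootstrap settings, sigma convention) with a master seed from
#' which each stage derives its own stream.
#'
#' @param spec A [cohort_spec()].
#' @param roi_model A [control_model_params()] table.
#' @param effects Named list of [roi_effect_map()]s.
#' @param prog A [progression_spec()].
#' @param cut_percentile Abnormality cut, control percentile in (0, 50).
#' @param B,level Bootstrap replicates and confidence level.
#' @param sigma_df Sigma convention passed to [fit_normative()].
#' @param progression_roi The region whose baseline volume call drives the
#'   simulated clinical change (default `"whole_brain"`).
#' @param seed Master integer seed.
#' @param out_dir Output directory for stage CSVs and the manifest, or
#'   `NULL` to keep everything in memory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(spec = default_genfi_spec(),
                       roi_model = control_model_params(),
                       effects = default_effect_maps(),
                       prog = default_progression_spec(),
                       cut_percentile = 10, B = 1000, level = 0.95,
                       sigma_df = "residual",
                       progression_roi = "whole_brain",
                       seed = 1L, out_dir = NULL) {
  if (!inherits(spec, "cohort_spec")) stop_wnorm("run_config: invalid 'spec'")
  if (cut_percentile <= 0 || cut_percentile >= 50)
    stop_wnorm("run_config: 'cut_percentile' must be in (0, 50)")
  if (B < 1) stop_wnorm("run_config: 'B' must be >= 1")
  if (!progression_roi %in% roi_model$roi)
    stop_wnorm("run_config: progression_roi '%s' not in roi_model",
               progression_roi)
  structure(list(spec = spec, roi_model = roi_model, effects = effects,
                 prog = prog, cut_percentile = cut_percentile, B = B,
                 level = level, sigma_df = sigma_df,
                 progression_roi = progression_roi,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Validate participant / measure / clinical tables
#'
#' Schema, type, range and cross-table referential checks. All violations
#' are collected and returned (never just the first); an empty report
#' means the tables are usable.
#'
#' @param participants Participant table.
#' @param measures Long measure table.
#' @param clinical Optional longitudinal clinical table.
#' @return Data frame with columns `table`, `check`, `detail`; zero rows
#'   when everything passes.
#' @export
validate_inputs <- function(participants, measures, clinical = NULL) {
  v <- list()
  add <- function(table, check, detail)
    v[[length(v) + 1L]] <<- data.frame(table = table, check = check,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  need_p <- c("participant_id", "group", "age_years", "sex", "tiv_mm3",
              "scanner")
  miss <- setdiff(need_p, names(participants))
  if (length(miss))
    add("participants", "schema",
        paste("missing column(s):", paste(miss, collapse = ", ")))
  need_m <- c("participant_id", "roi", "modality", "value")
  miss <- setdiff(need_m, names(measures))
  if (length(miss))
    add("measures", "schema",
        paste("missing column(s):", paste(miss, collapse = ", ")))
  if (length(v)) return(do.call(rbind, v))

  if (anyDuplicated(paste(participants$participant_id,
                          participants$visit %||% "baseline")))
    add("participants", "uniqueness", "duplicated (participant, visit)")
  bad_age <- !is.finite(participants$age_years) |
    participants$age_years < 0 | participants$age_years > 120
  if (any(bad_age))
    add("participants", "range",
        sprintf("%d row(s) with age outside [0, 120]", sum(bad_age)))
  bad_sex <- !participants$sex %in% c("female", "male")
  if (any(bad_sex))
    add("participants", "range",
        sprintf("%d row(s) with sex not in {female, male}", sum(bad_sex)))
  bad_tiv <- !is.finite(participants$tiv_mm3) | participants$tiv_mm3 <= 0
  if (any(bad_tiv))
    add("participants", "range",
        sprintf("%d row(s) with non-positive TIV", sum(bad_tiv)))
  if ("cdr_global" %in% names(participants)) {
    bad <- !is.na(participants$cdr_global) &
      !participants$cdr_global %in% c(0, 0.5, 1, 2, 3)
    if (any(bad))
      add("participants", "range",
          sprintf("%d row(s) with CDR global not in {0, 0.5, 1, 2, 3}",
                  sum(bad)))
  }
  if ("cbi_r" %in% names(participants)) {
    bad <- !is.na(participants$cbi_r) &
      (participants$cbi_r < 0 | participants$cbi_r > 180)
    if (any(bad))
      add("participants", "range",
          sprintf("%d row(s) with CBI-R outside [0, 180]", sum(bad)))
  }

  bad_mod <- !measures$modality %in% c("volume", "FA", "MD")
  if (any(bad_mod))
    add("measures", "range",
        sprintf("%d row(s) with unknown modality", sum(bad_mod)))
  fa <- measures$modality == "FA"
  bad_fa <- fa & (measures$value < 0 | measures$value > 1)
  if (any(bad_fa))
    add("measures", "range",
        sprintf("%d FA row(s) outside [0, 1]", sum(bad_fa)))
  md <- measures$modality == "MD"
  if (any(md & measures$value <= 0))
    add("measures", "range",
        sprintf("%d MD row(s) non-positive", sum(md & measures$value <= 0)))
  vol <- measures$modality == "volume"
  if (any(vol & measures$value < 0))
    add("measures", "range",
        sprintf("%d volume row(s) negative", sum(vol & measures$value < 0)))
  orphan <- setdiff(unique(measures$participant_id),
                    participants$participant_id)
  if (length(orphan))
    add("measures", "referential",
        sprintf("%d measure participant_id(s) not in participants: %s",
                length(orphan),
                paste(utils::head(orphan, 5), collapse = ", ")))
  if (!is.null(clinical)) {
    miss <- setdiff(c("participant_id", "visit"), names(clinical))
    if (length(miss)) {
      add("clinical", "schema",
          paste("missing column(s):", paste(miss, collapse = ", ")))
    } else {
      orphan <- setdiff(unique(clinical$participant_id),
                        participants$participant_id)
      if (length(orphan))
        add("clinical", "referential",
            sprintf("%d clinical participant_id(s) not in participants",
                    length(orphan)))
    }
  }
  if (!length(v))
    return(data.frame(table = character(), check = character(),
                      detail = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

# Fixed CSV dialect: header, UTF-8, "." decimal, NA as empty field.
write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full simulate-fit-score-classify-map-progress pipeline
#'
#' Executes every stage in order on a synthetic cohort: generate controls
#' and carriers, fit the normative models on controls, compute carrier
#' w-scores, classify them at the configured percentile cut, build the
#' group abnormality map, simulate 12-month clinical follow-up driven by
#' the configured region's baseline call, and run the stratified
#' progression analysis per gene and scale. All randomness derives from
#' the config's master seed, so identical configs reproduce identical
#' outputs; when `out_dir` is set, every stage table is written as CSV
#' alongside a JSON manifest with row counts, seeds and warnings.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage outputs (`controls`,
#'   `carriers`, `fit`, `wscores`, `calls`, `group_map`, `clinical`,
#'   `progression`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop_wnorm("run_pipeline: 'config' must be a run_config")
  seeds <- list(controls = derive_seed(config$seed, 1),
                carriers = derive_seed(config$seed, 2),
                map = derive_seed(config$seed, 3),
                followup = derive_seed(config$seed, 4),
                progression = derive_seed(config$seed, 5))
  warnings <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_wnorm("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)))
  }

  controls <- stage("simulate-controls",
                    generate_controls(config$spec, config$roi_model,
                                      seed = seeds$controls))
  carriers <- stage("simulate-carriers",
                    generate_carriers(config$spec, config$roi_model,
                                      config$effects,
                                      seed = seeds$carriers))
  report <- validate_inputs(rbind(controls$participants,
                                  carriers$participants),
                            rbind(controls$measures, carriers$measures))
  if (nrow(report))
    stop_wnorm("pipeline stage 'validate' failed: %d violation(s), first: %s",
               nrow(report), report$detail[1])

  fit <- stage("fit", fit_normative(controls$measures,
                                    controls$participants,
                                    sigma_df = config$sigma_df))
  sfit <- summary(fit)
  if (any(sfit$degenerate)) {
    warnings <- c(warnings,
                  sprintf("degenerate model(s): %s",
                          paste(sfit$roi[sfit$degenerate], collapse = ", ")))
  }
  wscores <- stage("wscore", wscore(fit, carriers$measures,
                                    carriers$participants))
  calls <- stage("classify",
                 classify_wscores(wscores,
                                  cut_percentile = config$cut_percentile))
  groups <- data.frame(
    participant_id = carriers$participants$participant_id,
    group = paste(carriers$participants$group,
                  carriers$participants$stage, sep = "."),
    stringsAsFactors = FALSE)
  gmap <- stage("map", group_abnormality_map(wscores, groups, B = config$B,
                                             level = config$level,
                                             seed = seeds$map))

  abn <- calls[calls$roi == config$progression_roi &
                 calls$modality == "volume",
               c("participant_id", "label")]
  names(abn)[2] <- "status"
  clinical <- stage("followup",
                    generate_followup(carriers$participants, config$prog,
                                      abn, seed = seeds$followup))
  prog_rows <- list()
  n_paired <- c(cdr_sb = 0L, cbi_r = 0L)
  for (scale in c("cdr_sb", "cbi_r")) {
    prs <- stage("pair", pair_visits(clinical, scale))
    n_paired[scale] <- nrow(prs)
    for (gene in c("C9orf72", "GRN", "MAPT")) {
      pg <- stage("progress",
                  progression_by_roi(calls, prs, carriers$participants,
                                     gene, B = config$B,
                                     level = config$level,
                                     seed = derive_seed(seeds$progression,
                                                        match(scale, c("cdr_sb", "cbi_r")) * 10 +
                                                          match(gene, c("C9orf72", "GRN", "MAPT")))))
      pg$scale <- scale
      prog_rows[[paste(scale, gene)]] <- pg
    }
  }
  progression <- do.call(rbind, c(prog_rows, make.row.names = FALSE))
  n_excluded <- sum(progression$flag == "excluded_lt3")
  if (n_excluded)
    warnings <- c(warnings, sprintf("%d stratum/strata excluded (n < 3)",
                                    n_excluded))
  n_caution <- sum(progression$flag == "caution_lt6")
  if (n_caution)
    warnings <- c(warnings, sprintf("%d stratum/strata flagged caution (n < 6)",
                                    n_caution))

  manifest <- list(
    tool = "wnorm",
    version = as.character(utils::packageVersion("wnorm")),
    seed = config$seed, stage_seeds = seeds,
    parameters = list(cut_percentile = config$cut_percentile,
                      B = config$B, level = config$level,
                      sigma_df = config$sigma_df,
                      progression_roi = config$progression_roi),
    rows = list(control_participants = nrow(controls$participants),
                carrier_participants = nrow(carriers$participants),
                control_measures = nrow(controls$measures),
                carrier_measures = nrow(carriers$measures),
                models = length(fit$models),
                wscores = nrow(wscores),
                calls = nrow(calls),
                group_map = nrow(gmap),
                clinical = nrow(clinical),
                paired = as.list(n_paired),
                progression_strata = nrow(progression)),
    warnings = warnings
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_stage_csv(rbind(controls$participants, carriers$participants),
                    p("participants.csv"))
    write_stage_csv(rbind(controls$measures, carriers$measures),
                    p("measures.csv"))
    write_normative_json(fit, p("models.json"))
    write_stage_csv(wscores, p("wscores.csv"))
    write_stage_csv(calls, p("calls.csv"))
    write_stage_csv(gmap, p("groupmap.csv"))
    write_stage_csv(clinical, p("clinical.csv"))
    write_stage_csv(progression, p("progression.csv"))
    cfg_json <- p("config.json")
    jsonlite::write_json(list(seed = config$seed,
                              cut_percentile = config$cut_percentile,
                              B = config$B, level = config$level,
                              sigma_df = config$sigma_df,
                              progression_roi = config$progression_roi,
                              groups = lapply(config$spec[c(
                                "controls", "c9orf72_presymptomatic",
                                "c9orf72_symptomatic", "mapt_presymptomatic",
                                "mapt_symptomatic", "grn_presymptomatic",
                                "grn_symptomatic")], unclass)),
                         cfg_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest$config_hash <- unname(tools::md5sum(cfg_json))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  invisible(list(controls = controls, carriers = carriers, fit = fit,
                 wscores = wscores, calls = calls, group_map = gmap,
                 clinical = clinical, progression = progression,
                 manifest = manifest))
}
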