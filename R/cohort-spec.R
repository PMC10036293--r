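#' Specify one demographic group of a simulated cohort
#'
#' @param n Number of participants (non-negative integer).
#' @param age_mean,age_sd Age moments in years (`age_sd > 0`).
#' @param prop_male Proportion of males in \[0, 1\].
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(n, age_mean, age_sd, prop_male) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop_wnorm("group_spec: 'n' must be a single non-negative integer")
  if (!is.numeric(age_sd) || age_sd <= 0)
    stop_wnorm("group_spec: 'age_sd' must be > 0")
  if (prop_male < 0 || prop_male > 1)
    stop_wnorm("group_spec: 'prop_male' must be in [0, 1]")
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 prop_male = prop_male), class = "group_spec")
}

#' Specify a simulated multi-site cohort
#'
#' Sample sizes and covariate moments for controls and for the six
#' gene-by-stage mutation-carrier groups (C9orf72, GRN, MAPT; each split
#' into presymptomatic and symptomatic), plus head-size and scanner-mix
#' parameters shared across groups.
#'
#' @param controls,c9orf72_presymptomatic,c9orf72_symptomatic,
#'   mapt_presymptomatic,mapt_symptomatic,grn_presymptomatic,grn_symptomatic
#'   [group_spec()] objects.
#' @param tiv_mean,tiv_sd Total intracranial volume moments in mm^3.
#' @param scanner_probs Probabilities of the five scanner categories
#'   (named after [scanner_types()]); must sum to 1.
#' @param seed Default integer seed attached to the spec (can be overridden
#'   at generation time).
#' @return A list of class `cohort_spec`.
#' @seealso [default_genfi_spec()] for defaults matching the study cohort.
#' @export
cohort_spec <- function(controls,
                        c9orf72_presymptomatic, c9orf72_symptomatic,
                        mapt_presymptomatic, mapt_symptomatic,
                        grn_presymptomatic, grn_symptomatic,
                        tiv_mean = 1.40e6, tiv_sd = 1.5e5,
                        scanner_probs = c(SiemensTrio = 0.25,
                                          SiemensSkyra = 0.20,
                                          SiemensPrisma = 0.20,
                                          PhilipsAchieva = 0.20,
                                          GEDiscoveryMR750 = 0.15),
                        seed = 1L) {
  groups <- list(controls = controls,
                 c9orf72_presymptomatic = c9orf72_presymptomatic,
                 c9orf72_symptomatic = c9orf72_symptomatic,
                 mapt_presymptomatic = mapt_presymptomatic,
                 mapt_symptomatic = mapt_symptomatic,
                 grn_presymptomatic = grn_presymptomatic,
                 grn_symptomatic = grn_symptomatic)
  for (nm in names(groups))
    if (!inherits(groups[[nm]], "group_spec"))
      stop_wnorm("cohort_spec: '%s' must be a group_spec object", nm)
  if (!is.numeric(tiv_sd) || tiv_sd <= 0)
    stop_wnorm("cohort_spec: 'tiv_sd' must be > 0")
  if (length(scanner_probs) != 5L || any(scanner_probs < 0) ||
      abs(sum(scanner_probs) - 1) > 1e-8)
    stop_wnorm("cohort_spec: 'scanner_probs' must be 5 non-negative probabilities summing to 1")
  if (is.null(names(scanner_probs))) names(scanner_probs) <- scanner_types()
  structure(c(groups,
              list(tiv_mean = tiv_mean, tiv_sd = tiv_sd,
                   scanner_probs = scanner_probs, seed = as.integer(seed))),
            class = "cohort_spec")
}

#' Default cohort specification matching the genetic FTD study population
#'
#' Group sizes, age moments and sex ratios of the multi-centre cohort the
#' generator emulates: 240 non-carrier controls and C9orf72 / MAPT / GRN
#' mutation carriers split by disease stage (presymptomatic
#' n = 113 / 52 / 130; symptomatic n = 47 / 15 / 30).
#'
#' @param seed Default seed stored on the spec.
#' @return A `cohort_spec`.
#' @examples
#' spec <- default_genfi_spec()
#' spec$controls$n            # 240
#' spec$controls$age_mean     # 44.8
#' @export
default_genfi_spec <- function(seed = 1L) {
  cohort_spec(
    controls               = group_spec(240, 44.8, 12.2, 0.429),
    c9orf72_presymptomatic = group_spec(113, 45.0, 11.5, 0.425),
    c9orf72_symptomatic    = group_spec(47, 63.5, 7.4, 0.660),
    mapt_presymptomatic    = group_spec(52, 41.1, 10.6, 0.404),
    mapt_symptomatic       = group_spec(15, 59.2, 9.3, 0.600),
    grn_presymptomatic     = group_spec(130, 46.5, 12.2, 0.369),
    grn_symptomatic        = group_spec(30, 63.3, 8.1, 0.467),
    seed = seed
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort specification\n")
  grp <- c("controls", "c9orf72_presymptomatic", "c9orf72_symptomatic",
           "mapt_presymptomatic", "mapt_symptomatic",
           "grn_presymptomatic", "grn_symptomatic")
  for (g in grp)
    cat(sprintf("  %-24s n = %3d  age %.1f (%.1f)  male %.1f%%\n", g,
                x[[g]]$n, x[[g]]$age_mean, x[[g]]$age_sd,
                100 * x[[g]]$prop_male))
  cat(sprintf("  TIV %.3g (%.3g) mm^3; scanner mix: %s\n", x$tiv_mean,
              x$tiv_sd,
              paste(sprintf("%s %.2f", names(x$scanner_probs),
                            x$scanner_probs), collapse = ", ")))
  invisible(x)
}

#' Regional effect map for one gene-by-stage carrier group
#'
#' Effect sizes are expressed in control-residual standard deviation units
#' so that the generated mean w-score of the group in a region equals the
#' configured effect by construction. Sign convention: negative for grey
#' matter volume and FA loss, positive for MD increase.
#'
#' @param gene One of `"C9orf72"`, `"GRN"`, `"MAPT"`.
#' @param stage `"presymptomatic"` or `"symptomatic"`.
#' @param effects Data frame with columns `roi`, `modality`, `effect`, or
#'   `NULL` for no regional shift.
#' @return A list of class `roi_effect_map`.
#' @export
roi_effect_map <- function(gene, stage, effects = NULL) {
  gene <- match.arg(gene, c("C9orf72", "GRN", "MAPT"))
  stage <- match.arg(stage, c("presymptomatic", "symptomatic"))
  if (is.null(effects))
    effects <- data.frame(roi = character(), modality = character(),
                          effect = numeric(), stringsAsFactors = FALSE)
  check_columns(effects, c("roi", "modality", "effect"), "effects")
  bad_mod <- setdiff(unique(effects$modality), c("volume", "FA", "MD"))
  if (length(bad_mod))
    stop_wnorm("roi_effect_map: unknown modality: %s",
               paste(bad_mod, collapse = ", "))
  unknown <- setdiff(unique(effects$roi), roi_registry()$roi)
  if (length(unknown))
    stop_wnorm("roi_effect_map: ROI(s) not in registry: %s",
               paste(unknown, collapse = ", "))
  structure(list(gene = gene, stage = stage, effects = effects),
            class = "roi_effect_map")
}

eff_df <- function(roi, modality, effect) {
  data.frame(roi = roi, modality = modality, effect = effect,
             stringsAsFactors = FALSE)
}

#' Default gene-by-stage regional effect maps
#'
#' Qualitative regional patterns the simulator imposes, in control-residual
#' SD units: C9orf72 shows widespread mild presymptomatic involvement with
#' thalamus (especially pulvinar) worst; MAPT shows focal temporal,
#' amygdala and hippocampal involvement; GRN shows temporal pole and
#' presubiculum involvement presymptomatically; symptomatic stages are
#' uniformly more severe. Tract effects are negative for FA, positive for
#' MD.
#'
#' @return Named list of six [roi_effect_map()] objects, keyed
#'   `"<gene>.<stage>"`.
#' @export
default_effect_maps <- function() {
  maps <- list(
    roi_effect_map("C9orf72", "presymptomatic", rbind(
      eff_df(c("thalamus", "pulvinar", "insula", "dlpfc", "medial_parietal",
               "cingulate"), "volume",
             c(-1.1, -1.4, -0.8, -0.8, -0.7, -0.6)),
      eff_df(c("SS", "gCC", "bCC", "pTR", "aCR", "EC"), "FA", rep(-0.8, 6)),
      eff_df(c("SS", "gCC", "bCC", "pTR", "aCR", "EC"), "MD", rep(0.8, 6)))),
    roi_effect_map("C9orf72", "symptomatic", rbind(
      eff_df(c("thalamus", "pulvinar", "insula", "dlpfc", "medial_parietal",
               "cingulate", "orbitofrontal", "whole_brain"), "volume",
             c(-2.0, -2.3, -1.8, -1.8, -1.5, -1.5, -1.5, -1.8)),
      eff_df(c("gCC", "aCR"), "FA", c(-2.1, -2.1)),
      eff_df(c("SS", "gCC", "bCC", "aCR", "sCR", "cingulum", "pTR", "aIC"),
             "MD", rep(2.1, 8)))),
    roi_effect_map("MAPT", "presymptomatic", rbind(
      eff_df(c("dorsolateral_temporal", "amygdala", "hippocampus",
               "thalamus"), "volume", c(-1.0, -1.0, -1.0, -0.7)),
      eff_df("aIC", "FA", -0.8))),
    roi_effect_map("MAPT", "symptomatic", rbind(
      eff_df(c("dorsolateral_temporal", "temporal_pole", "medial_temporal",
               "amygdala", "hippocampus", "insula", "whole_brain"), "volume",
             c(-2.3, -2.3, -2.2, -2.5, -2.5, -2.0, -1.5)),
      eff_df("UF", "FA", -2.0),
      eff_df(c("UF", "SS"), "MD", c(2.0, 2.0)))),
    roi_effect_map("GRN", "presymptomatic", rbind(
      eff_df(c("temporal_pole", "presubiculum"), "volume", c(-0.9, -0.9)),
      eff_df("sCR", "FA", -0.8),
      eff_df(c("UF", "aCR"), "MD", c(0.8, 0.8)))),
    roi_effect_map("GRN", "symptomatic", rbind(
      eff_df(c("dlpfc", "insula", "motor", "presubiculum",
               "mediodorsal_thalamus", "posterior_hypothalamus",
               "whole_brain"), "volume",
             c(-2.3, -2.1, -2.0, -2.2, -2.0, -2.0, -1.8)),
      eff_df(c("gCC", "bCC", "cingulum", "aIC", "aCR"), "FA", rep(-2.0, 5)),
      eff_df(c("UF", "SLF", "cingulum", "SS", "pTR", "aCR", "pCR", "sCR",
               "EC", "aIC", "gCC", "bCC", "sCC"), "MD", rep(2.0, 13))))
  )
  names(maps) <- vapply(maps, function(m) paste(m$gene, m$stage, sep = "."),
                        character(1))
  maps
}

#' Specify the longitudinal clinical-change model
#'
#' For each (gene, clinical scale, baseline abnormality status) cell, the
#' 12-month change in score is drawn from a Gaussian with the configured
#' mean and SD (points), then floored at the scale minimum. Follow-up
#' availability is a per-gene retention probability.
#'
#' @param changes Data frame with columns `gene`, `scale` (`"cdr_sb"` or
#'   `"cbi_r"`), `status` (`"normal"`/`"abnormal"`), `mean_change`,
#'   `sd_change` (points; `sd_change >= 0`).
#' @param availability Named numeric vector of follow-up probabilities per
#'   gene in \[0, 1\] (a single unnamed value is recycled to all genes).
#' @return A list of class `progression_spec`.
#' @export
progression_spec <- function(changes, availability) {
  check_columns(changes, c("gene", "scale", "status", "mean_change",
                           "sd_change"), "changes")
  if (any(changes$sd_change < 0))
    stop_wnorm("progression_spec: 'sd_change' must be >= 0")
  if (any(availability < 0 | availability > 1))
    stop_wnorm("progression_spec: 'availability' must be in [0, 1]")
  genes <- c("C9orf72", "GRN", "MAPT")
  if (length(availability) == 1L && is.null(names(availability)))
    availability <- stats::setNames(rep(availability, 3), genes)
  if (!all(genes %in% names(availability)))
    stop_wnorm("progression_spec: 'availability' must cover genes %s",
               paste(genes, collapse = ", "))
  structure(list(changes = changes, availability = availability),
            class = "progression_spec")
}

#' Default clinical-change model
#'
#' Mean 12-month changes calibrated to the magnitudes the study reports for
#' whole-brain-abnormal presymptomatic carriers (CDR plus NACC FTLD
#' sum-of-boxes increases of about 1 point in C9orf72, 3 in GRN and 2 in
#' MAPT; CBI-R increases of about 8, 11 and 16 points respectively), with
#' small changes in the normal strata. Follow-up availability defaults to
#' the observed per-gene follow-up fractions (56/113, 69/130, 32/52).
#'
#' @return A `progression_spec`.
#' @export
default_progression_spec <- function() {
  g <- c("C9orf72", "GRN", "MAPT")
  changes <- rbind(
    data.frame(gene = g, scale = "cdr_sb", status = "abnormal",
               mean_change = c(1, 3, 2), sd_change = c(1.5, 2.5, 2.0)),
    data.frame(gene = g, scale = "cdr_sb", status = "normal",
               mean_change = c(0.1, 0.3, 0.1), sd_change = c(0.5, 0.6, 0.5)),
    data.frame(gene = g, scale = "cbi_r", status = "abnormal",
               mean_change = c(8, 11, 16), sd_change = c(6, 8, 9)),
    data.frame(gene = g, scale = "cbi_r", status = "normal",
               mean_change = c(0.5, 1.5, 1.0), sd_change = c(3, 4, 3))
  )
  progression_spec(changes,
                   availability = c(C9orf72 = 56 / 113, GRN = 69 / 130,
                                    MAPT = 32 / 52))
}
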