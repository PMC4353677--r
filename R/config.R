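#' Analysis configuration
#'
#' Collects every tunable threshold of the drift-calling and context analyses
#' in one validated list. Defaults are the study's operating values: per-test
#' alpha 0.05, extreme-grade effect threshold 0.05 on the Beta scale (strict
#' inequality), baseline strata cut-offs 0.25/0.75, a 250 kb SNP-proximity
#' window, a 2-fold expression filter, and a base alpha of 0.05 for the
#' array-wide Bonferroni threshold report.
#'
#' @param alpha Per-test significance level for the Spearman, covariate,
#'   ANCOVA and stability screens.
#' @param effect_delta_beta Minimum absolute difference between mean grade-VII
#'   and grade-III intra-pair Delta-Beta (strict `>`).
#' @param strata_high,strata_low Beta cut-offs for the high/intermediate/low
#'   baseline methylation strata (boundaries belong to Intermediate).
#' @param snp_window_bp SNP proximity window in base pairs (inclusive).
#' @param fold_threshold Expression fold-change filter (strict `>`).
#' @param bonferroni_base_alpha Base alpha for the reported array-wide
#'   Bonferroni threshold.
#' @param epsilon_clip Beta clamp used by [beta_to_m()].
#' @param grade_as_factor Treat grade as a categorical factor in the
#'   covariate-adjusted ANOVA (default) or as a numeric trend.
#' @param random_seed Integer seed recorded with the run.
#' @return A list of class `"methdrift_config"`.
#' @export
analysis_config <- function(alpha = 0.05,
                            effect_delta_beta = 0.05,
                            strata_high = 0.75,
                            strata_low = 0.25,
                            snp_window_bp = 250000L,
                            fold_threshold = 2,
                            bonferroni_base_alpha = 0.05,
                            epsilon_clip = 1e-6,
                            grade_as_factor = TRUE,
                            random_seed = 1L) {
  cfg <- list(
    alpha = alpha, effect_delta_beta = effect_delta_beta,
    strata_high = strata_high, strata_low = strata_low,
    snp_window_bp = as.integer(snp_window_bp),
    fold_threshold = fold_threshold,
    bonferroni_base_alpha = bonferroni_base_alpha,
    epsilon_clip = epsilon_clip,
    grade_as_factor = isTRUE(grade_as_factor),
    random_seed = as.integer(random_seed)
  )
  stopifnot(
    cfg$alpha > 0, cfg$effect_delta_beta > 0,
    cfg$strata_low > 0, cfg$strata_low < cfg$strata_high, cfg$strata_high < 1,
    cfg$snp_window_bp > 0, cfg$fold_threshold > 0,
    cfg$bonferroni_base_alpha > 0, cfg$epsilon_clip > 0
  )
  structure(cfg, class = "methdrift_config")
}

#' Synthetic-cohort generator configuration
#'
#' Describes a paired atherosclerotic/normal methylation cohort with planted
#' ground truth. The default grade composition mirrors a 15-donor cohort
#' spanning grades III--VII with nine grade-VII donors. Probe classes:
#'
#' * `null` — no intra-pair difference.
#' * `grade_hyper` / `grade_hypo` — intra-pair difference drifting linearly
#'   with numeric grade on the M scale, scaled so the Beta-scale difference
#'   at grade VII is `+/- drift_amplitude_beta`.
#' * `dm_constant` — constant intra-pair offset (`dm_offset_beta`), i.e.
#'   differentially methylated but grade-independent.
#' * `confound_age` / `confound_sex` / `confound_pmt` — intra-pair difference
#'   proportional to the standardised covariate, with the same M-scale
#'   amplitude as grade drift.
#' * `unstable_N` — grade drift plus a normal-tissue mean that itself shifts
#'   linearly with grade (must be rejected by the stability criterion).
#' * `blacklisted` — carries grade drift but is listed on the probe blacklist
#'   (e.g. SNP-harbouring), so its exclusion is observable.
#'
#' @param n_probes Total number of probes.
#' @param grade_counts Named integer vector, donors per Roman grade.
#' @param class_counts Named integer vector of planted class counts; the
#'   remainder up to `n_probes` is `null`.
#' @param drift_amplitude_beta Target |Delta-Beta| at grade VII for grade
#'   drift probes.
#' @param dm_offset_beta Constant Beta-scale intra-pair offset for
#'   `dm_constant` probes.
#' @param noise_sd_m Standard deviation of the M-scale measurement noise
#'   added independently to every sample value. The default 0.17 corresponds
#'   to about 0.03 on the Beta scale near Beta = 0.5.
#' @param unstable_n_shift_m M-scale shift of the normal-tissue mean of
#'   `unstable_N` probes between grade III and grade VII (about 0.35 on the
#'   Beta scale at mid-range baselines): these probes model loci whose
#'   reference tissue is itself grade-dependent, the confounder the baseline
#'   stability criterion exists to exclude, so the coupling is set well
#'   beyond the stability screen's detection limit.
#' @param compartment_prop Named proportions for gene-compartment assignment
#'   (an `Intergenic` entry yields probes without gene annotation).
#' @param cgi_prop Named proportions for CpG-island relation assignment.
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A list of class `"methdrift_gen_config"`.
#' @export
generator_config <- function(n_probes = 10000L,
                             grade_counts = c(III = 2L, IV = 2L, V = 1L,
                                              VI = 1L, VII = 9L),
                             class_counts = c(grade_hyper = 100L,
                                              grade_hypo = 100L,
                                              dm_constant = 200L,
                                              confound_age = 100L,
                                              confound_sex = 100L,
                                              confound_pmt = 100L,
                                              unstable_N = 100L,
                                              blacklisted = 50L),
                             drift_amplitude_beta = 0.15,
                             dm_offset_beta = 0.10,
                             noise_sd_m = 0.17,
                             unstable_n_shift_m = 2.5,
                             compartment_prop = c(TSS1500 = 0.13, TSS200 = 0.10,
                                                  UTR5 = 0.08, FirstExon = 0.07,
                                                  Body = 0.37, UTR3 = 0.04,
                                                  Intergenic = 0.21),
                             cgi_prop = c(Island = 0.30, Shore = 0.23,
                                          Shelf = 0.10, OpenSea = 0.37),
                             seed = 1L) {
  known <- c("null", "grade_hyper", "grade_hypo", "dm_constant", "confound_age",
             "confound_sex", "confound_pmt", "unstable_N", "blacklisted")
  class_counts <- class_counts[setdiff(names(class_counts), "null")]
  if (length(class_counts) && !all(names(class_counts) %in% known)) {
    abort(sprintf("Unknown probe class(es): %s",
                  paste(setdiff(names(class_counts), known), collapse = ", ")))
  }
  cfg <- list(
    n_probes = as.integer(n_probes),
    grade_counts = grade_counts,
    class_counts = vapply(class_counts, as.integer, integer(1)),
    drift_amplitude_beta = drift_amplitude_beta,
    dm_offset_beta = dm_offset_beta,
    noise_sd_m = noise_sd_m,
    unstable_n_shift_m = unstable_n_shift_m,
    compartment_prop = compartment_prop,
    cgi_prop = cgi_prop,
    seed = as.integer(seed)
  )
  if (sum(cfg$grade_counts) < 2) abort("Cohort needs at least 2 donors.")
  if (!all(names(cfg$grade_counts) %in% names(.grade_levels))) {
    abort("grade_counts names must be Roman grades III-VII.")
  }
  if (any(cfg$class_counts < 0) || sum(cfg$class_counts) > cfg$n_probes) {
    abort("class_counts must be non-negative and sum to at most n_probes.")
  }
  stopifnot(cfg$drift_amplitude_beta > 0, cfg$dm_offset_beta > 0,
            cfg$noise_sd_m >= 0)
  structure(cfg, class = "methdrift_gen_config")
}
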