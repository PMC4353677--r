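#' Intra-pair methylation differences
#'
#' For every donor, the atherosclerotic-minus-normal (A - N) difference per
#' probe, on the M scale (after [beta_to_m()]) or the Beta scale. Testing is
#' done on the M scale; effect sizes are reported on the Beta scale.
#'
#' @param beta Beta matrix tibble (`probe_id` + sample columns).
#' @param cohort Cohort tibble.
#' @param scale `"M"` (default) or `"Beta"`.
#' @param epsilon_clip Beta clamp for the logit.
#' @return Tibble with `probe_id` plus one column per donor, attribute
#'   `"scale"` recording the scale.
#' @export
intra_pair_delta <- function(beta, cohort, scale = c("M", "Beta"),
                             epsilon_clip = 1e-6) {
  scale <- match.arg(scale)
  pairs <- cohort_pairs(cohort)
  mat <- beta_as_matrix(beta)
  missing <- setdiff(c(pairs$sample_A, pairs$sample_N), colnames(mat))
  if (length(missing)) {
    bad <- pairs$donor_id[pairs$sample_A %in% missing |
                            pairs$sample_N %in% missing]
    abort(sprintf("Samples missing from Beta matrix for donor(s): %s",
                  paste(unique(bad), collapse = ", ")))
  }
  if (scale == "M") mat <- beta_to_m(mat, epsilon_clip)
  d <- mat[, pairs$sample_A, drop = FALSE] - mat[, pairs$sample_N, drop = FALSE]
  colnames(d) <- pairs$donor_id
  out <- dplyr::bind_cols(tibble(probe_id = beta$probe_id), as_tibble(d))
  attr(out, "scale") <- scale
  out
}

#' @noRd
.delta_matrix <- function(delta) {
  m <- as.matrix(delta[-1])
  rownames(m) <- delta$probe_id
  m
}

#' Covariate screen of an intra-pair difference
#'
#' Spearman correlation of one probe's intra-pair M differences with donor
#' age, sex (coded M=0, F=1) and post-mortem time. The probe passes when all
#' three p values are at least `alpha`. A constant covariate (e.g. a
#' single-sex cohort) yields an undefined correlation, recorded as p = 1 with
#' a warning.
#'
#' @param delta Numeric vector of per-donor differences.
#' @param cohort Cohort tibble (covariates taken per donor, in donor order of
#'   [cohort_pairs()]).
#' @param alpha Significance level.
#' @return List with `p_age`, `p_sex`, `p_pmt`, `pass`.
#' @export
covariate_screen <- function(delta, cohort, alpha = 0.05) {
  pairs <- cohort_pairs(cohort)
  if (length(delta) != nrow(pairs))
    abort("delta must have one value per donor.")
  covs <- list(p_age = pairs$age, p_sex = pairs$sex_num,
               p_pmt = pairs$postmortem_h)
  if (anyNA(unlist(covs))) abort("Missing covariate value in cohort.")
  out <- lapply(names(covs), function(nm) {
    y <- covs[[nm]]
    if (stats::sd(y) == 0) {
      warn(sprintf("Constant covariate (%s): correlation undefined, p set to 1.",
                   sub("p_", "", nm)))
      return(1)
    }
    rx <- rank(delta); ry <- rank(y)
    rho <- if (stats::sd(rx) == 0) NA_real_ else stats::cor(rx, ry)
    .spearman_p(rho, rx, ry)
  })
  names(out) <- names(covs)
  out$pass <- all(unlist(out) >= alpha)
  out
}

# multi-probe partial-F ANCOVA of delta-M on grade, adjusted for age, sex, pmt
# D: probes x donors; pairs: cohort_pairs() rows aligned with columns of D
.ancova_matrix <- function(D, pairs, grade_as_factor = TRUE) {
  g <- if (grade_as_factor) factor(pairs$grade_num) else pairs$grade_num
  X1 <- stats::model.matrix(~ g + age + sex_num + postmortem_h, data =
                              cbind(data.frame(g = g), pairs))
  X0 <- stats::model.matrix(~ age + sex_num + postmortem_h, data = pairs)
  q1 <- qr(X1); q0 <- qr(X0)
  df1 <- q1$rank - q0$rank
  df2 <- nrow(X1) - q1$rank
  if (df1 < 1) abort("Grade adds no estimable degrees of freedom (rank-deficient design).")
  if (df2 < 1) abort(sprintf(
    "No residual degrees of freedom for the covariate-adjusted ANOVA (n = %d donors, model rank = %d).",
    nrow(X1), q1$rank))
  Y <- t(D)
  rss1 <- colSums(qr.resid(q1, Y)^2)
  rss0 <- colSums(qr.resid(q0, Y)^2)
  tiny <- 1e-20 * pmax(rss0, 1e-12)
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  p[rss1 <= tiny & (rss0 - rss1) <= tiny] <- 1     # flat probe: no effect
  p[rss1 <= tiny & (rss0 - rss1) > tiny] <- 0      # perfect grade fit
  unname(p)
}

#' Covariate-adjusted ANOVA of an intra-pair difference on grade
#'
#' Least-squares fit of `delta ~ grade + age + sex + postmortem_h` with grade
#' categorical (default) or numeric, returning the partial F-test p value for
#' the grade term. This corroborates the rank-correlation screen while
#' adjusting for donor covariates.
#'
#' @param delta Numeric vector of per-donor M differences.
#' @param cohort Cohort tibble.
#' @param grade_as_factor Treat grade as a factor (default) or numeric trend.
#' @return Partial-F p value for grade.
#' @export
ancova_grade <- function(delta, cohort, grade_as_factor = TRUE) {
  pairs <- cohort_pairs(cohort)
  if (length(delta) != nrow(pairs))
    abort("delta must have one value per donor.")
  .ancova_matrix(matrix(delta, 1), pairs, grade_as_factor)
}

#' Extreme-grade effect size
#'
#' Absolute difference between the mean intra-pair Delta-Beta of the grade-VII
#' donors and the grade-III donors; the probe passes when the difference
#' strictly exceeds `threshold`.
#'
#' @param delta_beta Numeric vector of per-donor Beta-scale differences.
#' @param grades Numeric grades per donor.
#' @param threshold Strict lower bound on the effect (default 0.05).
#' @return List with `mean_III`, `mean_VII`, `effect`, `pass`.
#' @export
extreme_grade_effect <- function(delta_beta, grades, threshold = 0.05) {
  if (!any(grades == 3) || !any(grades == 7)) {
    abort("Extreme-grade effect needs at least one grade-III and one grade-VII donor.")
  }
  m3 <- mean(delta_beta[grades == 3])
  m7 <- mean(delta_beta[grades == 7])
  eff <- abs(m7 - m3)
  list(mean_III = m3, mean_VII = m7, effect = eff, pass = eff > threshold)
}

# vectorised Welch two-sample t on rows of two matrices (group by columns)
.welch_rows <- function(X1, X2) {
  n1 <- ncol(X1); n2 <- ncol(X2)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- apply(X1, 1, stats::var); v2 <- apply(X2, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero_se <- se2 == 0
  p[zero_se & m1 == m2] <- 1
  p[zero_se & m1 != m2] <- 0
  p
}

#' Normal-tissue stability between extreme grades
#'
#' Welch two-sample t-test comparing one probe's normal-tissue (N) M values
#' between grade-VII and grade-III donors. A probe passes (is stable) when
#' p >= `alpha`; if either extreme-grade group has fewer than two N samples
#' the criterion is indeterminate and recorded as a pass with a warning.
#'
#' @param m_values Named numeric vector of N-sample M values (names are
#'   sample ids) or a vector aligned with the cohort's N samples.
#' @param cohort Cohort tibble.
#' @param alpha Significance level.
#' @return List with `p` and `pass`.
#' @export
n_sample_stability <- function(m_values, cohort, alpha = 0.05) {
  pairs <- cohort_pairs(cohort)
  if (!is.null(names(m_values))) {
    m_values <- m_values[pairs$sample_N]
  }
  if (length(m_values) != nrow(pairs))
    abort("Need one N-sample M value per donor.")
  g3 <- m_values[pairs$grade_num == 3]
  g7 <- m_values[pairs$grade_num == 7]
  if (length(g3) < 2 || length(g7) < 2) {
    warn("Fewer than 2 N samples in an extreme-grade group: stability criterion indeterminate, recorded as pass.")
    return(list(p = NA_real_, pass = TRUE))
  }
  p <- .welch_rows(matrix(g7, 1), matrix(g3, 1))
  list(p = p, pass = p >= alpha)
}

#' Array-wide Bonferroni significance threshold
#'
#' The per-test p-value threshold controlling the family-wise error rate at
#' `base_alpha` over `n_tested` probes, `base_alpha / n_tested`. For a full
#' 450k-array screen (~485,000 tested probes at base alpha 0.05) this is on
#' the order of 1e-7.
#'
#' @param n_tested Number of probes tested.
#' @param base_alpha Family-wise alpha (default 0.05).
#' @return The corrected per-test threshold.
#' @export
bonferroni_threshold <- function(n_tested, base_alpha = 0.05) {
  if (n_tested < 1) abort("n_tested must be positive.")
  base_alpha / n_tested
}

#' Call grade-CpGs: probes whose intra-pair difference drifts with grade
#'
#' The full per-probe decision rule. After excluding blacklisted probes (e.g.
#' SNP-harbouring) and probes with missing values, each probe must satisfy all
#' three criteria to be a grade-CpG:
#'
#' 1. **Effect size** — the absolute difference between mean grade-VII and
#'    grade-III intra-pair Delta-Beta strictly exceeds
#'    `config$effect_delta_beta`.
#' 2. **Correlation** — significant Spearman correlation (p < alpha) of the
#'    intra-pair Delta-M with numeric grade, no significant correlation with
#'    donor age, sex or post-mortem time, and a significant grade term in the
#'    covariate-adjusted ANOVA.
#' 3. **Baseline stability** — no significant Welch-t difference between the
#'    N-sample M values of grade-VII and grade-III donors.
#'
#' Direction is `hyper` when rho > 0 (progressive hypermethylation), `hypo`
#' otherwise. The array-wide Bonferroni threshold
#' `bonferroni_base_alpha / n_tested` and the number of probes below it are
#' reported alongside.
#'
#' @param beta Beta matrix tibble.
#' @param cohort Cohort tibble.
#' @param annotation Optional probe annotation (carried for summaries).
#' @param blacklist Optional character vector of probe ids to exclude.
#' @param config [analysis_config()].
#' @return An object of class `grade_cpg_calls`; see [tidy()] for the
#'   per-probe table and [glance()] for the one-row summary.
#' @export
call_grade_cpgs <- function(beta, cohort, annotation = NULL, blacklist = NULL,
                            config = analysis_config()) {
  validate_cohort(cohort)
  n_input <- nrow(beta)
  beta <- validate_beta_matrix(beta)
  n_missing <- attr(beta, "n_dropped_missing")
  n_black <- 0L
  if (!is.null(blacklist)) {
    keep <- !(beta$probe_id %in% blacklist)
    n_black <- sum(!keep)
    beta <- beta[keep, ]
  }
  if (nrow(beta) == 0) abort("No probes left to test.")
  pairs <- cohort_pairs(cohort)
  g <- pairs$grade_num

  dM <- .delta_matrix(intra_pair_delta(beta, cohort, "M", config$epsilon_clip))
  dB <- .delta_matrix(intra_pair_delta(beta, cohort, "Beta"))

  sg <- .spearman_matrix(dM, g)

  cov_list <- list(age = pairs$age, sex = pairs$sex_num,
                   pmt = pairs$postmortem_h)
  cov_p <- lapply(names(cov_list), function(nm) {
    y <- cov_list[[nm]]
    if (stats::sd(y) == 0) {
      warn(sprintf("Constant covariate (%s): correlation undefined, p set to 1.", nm))
      return(rep(1, nrow(dM)))
    }
    .spearman_matrix(dM, y)$p
  })
  names(cov_p) <- c("p_age", "p_sex", "p_pmt")

  p_ancova <- .ancova_matrix(dM, pairs, config$grade_as_factor)

  if (!any(g == 3) || !any(g == 7)) {
    abort("Extreme-grade effect criterion inapplicable: cohort lacks a grade-III or grade-VII donor.")
  }
  m3 <- rowMeans(dB[, g == 3, drop = FALSE])
  m7 <- rowMeans(dB[, g == 7, drop = FALSE])
  effect <- abs(m7 - m3)

  # criterion 3 on normal-tissue M values of the extreme grades
  mN <- beta_to_m(beta_as_matrix(beta)[, pairs$sample_N, drop = FALSE],
                  config$epsilon_clip)
  n3 <- sum(g == 3); n7 <- sum(g == 7)
  if (n3 < 2 || n7 < 2) {
    warn("Fewer than 2 N samples in an extreme-grade group: stability criterion indeterminate, recorded as pass.")
    p_stab <- rep(NA_real_, nrow(mN))
    stab_pass <- rep(TRUE, nrow(mN))
  } else {
    p_stab <- .welch_rows(mN[, g == 7, drop = FALSE],
                          mN[, g == 3, drop = FALSE])
    stab_pass <- p_stab >= config$alpha
  }

  cov_pass <- cov_p$p_age >= config$alpha & cov_p$p_sex >= config$alpha &
    cov_p$p_pmt >= config$alpha
  crit_effect <- effect > config$effect_delta_beta
  crit_correlation <- sg$p < config$alpha & cov_pass & p_ancova < config$alpha
  is_called <- crit_effect & crit_correlation & stab_pass

  n_tested <- nrow(beta)
  bonf <- bonferroni_threshold(n_tested, config$bonferroni_base_alpha)

  records <- tibble(
    probe_id = beta$probe_id,
    rho = sg$rho,
    p_grade = sg$p,
    p_age = cov_p$p_age, p_sex = cov_p$p_sex, p_pmt = cov_p$p_pmt,
    covariate_pass = cov_pass,
    p_ancova = p_ancova,
    mean_dbeta_gIII = m3, mean_dbeta_gVII = m7,
    extreme_effect = effect,
    p_n_stability = p_stab,
    crit_effect = crit_effect,
    crit_correlation = crit_correlation,
    crit_stability = stab_pass,
    is_grade_cpg = is_called,
    direction = dplyr::case_when(
      is.na(sg$rho) ~ NA_character_,
      sg$rho > 0 ~ "hyper",
      TRUE ~ "hypo"),
    below_bonferroni = sg$p < bonf
  )

  structure(list(
    records = records,
    annotation = annotation,
    config = config,
    n_input = n_input,
    n_missing_dropped = n_missing,
    n_blacklisted = n_black,
    n_tested = n_tested,
    bonferroni_threshold = bonf,
    n_below_bonferroni = sum(records$below_bonferroni, na.rm = TRUE)
  ), class = "grade_cpg_calls")
}

#' @export
print.grade_cpg_calls <- function(x, ...) {
  s <- summarize_calls(x)
  cat(sprintf("grade-CpG calls: %d / %d tested probes (%d blacklisted, %d missing-dropped)\n",
              s$n_called, x$n_tested, x$n_blacklisted, x$n_missing_dropped))
  cat(sprintf("  %.1f%% hypermethylated with grade; mean extreme |Delta-Beta| %.3f\n",
              s$pct_hyper, s$mean_effect))
  cat(sprintf("  Bonferroni threshold %.3g; %d probe(s) below it\n",
              x$bonferroni_threshold, x$n_below_bonferroni))
  invisible(x)
}

#' @rdname call_grade_cpgs
#' @param x A `grade_cpg_calls` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.grade_cpg_calls <- function(x, ...) x$records

#' Summarise a set of grade-CpG calls
#'
#' Counts of called probes and of the unique gene symbols they map to (each
#' symbol counted once however many probes it carries), the percentage
#' drifting towards hypermethylation, the mean and range of the extreme-grade
#' effect among calls, and the Bonferroni report.
#'
#' @param calls A `grade_cpg_calls` object.
#' @param annotation Probe annotation; defaults to the one stored in `calls`.
#' @return A one-row tibble.
#' @export
summarize_calls <- function(calls, annotation = NULL) {
  if (is.null(annotation)) annotation <- calls$annotation
  rec <- calls$records
  called <- filter(rec, .data$is_grade_cpg)
  n_called <- nrow(called)
  n_genes <- NA_integer_
  if (!is.null(annotation) && n_called > 0) {
    ann <- annotation[match(called$probe_id, annotation$probe_id), ]
    n_genes <- length(unique(toupper(unlist(ann$gene_symbols))))
  } else if (n_called == 0) {
    n_genes <- 0L
  }
  n_hyper <- sum(called$direction == "hyper", na.rm = TRUE)
  tibble(
    n_tested = calls$n_tested,
    n_called = n_called,
    n_genes = n_genes,
    n_hyper = n_hyper,
    n_hypo = n_called - n_hyper,
    pct_hyper = if (n_called > 0) 100 * n_hyper / n_called else 0,
    mean_effect = if (n_called > 0) mean(called$extreme_effect) else 0,
    min_effect = if (n_called > 0) min(called$extreme_effect) else 0,
    max_effect = if (n_called > 0) max(called$extreme_effect) else 0,
    bonferroni_threshold = calls$bonferroni_threshold,
    n_below_bonferroni = calls$n_below_bonferroni
  )
}

#' @rdname summarize_calls
#' @param x A `grade_cpg_calls` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.grade_cpg_calls <- function(x, ...) summarize_calls(x)
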