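#' Simulate a donor-paired methylation cohort with planted ground truth
#'
#' Generates the cohort sheet, probe-by-sample Beta matrix, probe annotation,
#' SNP-probe blacklist and truth table for a paired atherosclerotic/normal
#' design. Per probe j with baseline M value \eqn{\mu_j}, the normal-tissue
#' sample of donor d is \eqn{N = \mu_j + u_j (g_d - 3)/4 + \epsilon} (the
#' grade-coupled term only for `unstable_N` probes) and the atherosclerotic
#' sample is \eqn{A = N + \delta_j(d) + \epsilon'}, with
#' \eqn{\epsilon, \epsilon' \sim Normal(0, noise\_sd\_m)} and the intra-pair
#' shift \eqn{\delta_j(d)} set by the probe class (see [generator_config()]).
#' Grade-drift amplitudes are chosen on the M scale so that the noiseless
#' Beta-scale A-N difference at grade VII equals exactly
#' `+/- drift_amplitude_beta`. Betas are emitted through the inverse logit,
#' so all values lie strictly inside (0, 1).
#'
#' Donor covariates are drawn independently of grade and redrawn until none
#' shows even a marginal rank correlation with grade, so covariate
#' confounding exists only where planted at the probe level.
#'
#' @param config A [generator_config()].
#' @return A list with elements `cohort`, `beta`, `annotation`, `blacklist`,
#'   `truth` and `config`. `truth` maps each probe to its class and signed
#'   planted Beta-scale effect.
#' @export
simulate_cohort_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "methdrift_gen_config"))
  set.seed(config$seed)
  cohort <- .simulate_cohort_sheet(config$grade_counts)
  pairs <- cohort_pairs(cohort)
  n_donor <- nrow(pairs)
  g <- pairs$grade_num
  np <- config$n_probes

  classes <- rep("null", np)
  planted <- rep(names(config$class_counts), config$class_counts)
  if (length(planted)) {
    idx <- sample.int(np, length(planted))
    classes[idx] <- planted
  }
  probe_id <- sprintf("cg%06d", seq_len(np))

  is_planted <- classes != "null"
  beta0 <- numeric(np)
  beta0[!is_planted] <- .baseline_mix(sum(!is_planted))
  # planted-effect probes draw mid-range baselines so +/- amplitude fits (0,1)
  beta0[is_planted] <- runif(sum(is_planted), 0.35, 0.65)
  mu <- beta_to_m(beta0)

  A <- config$drift_amplitude_beta
  sign_j <- numeric(np)
  amp_m <- numeric(np)
  sign_j[classes == "grade_hyper"] <- 1
  sign_j[classes == "grade_hypo"] <- -1
  rand_sign_classes <- c("dm_constant", "confound_age", "confound_sex",
                         "confound_pmt", "unstable_N", "blacklisted")
  rs <- classes %in% rand_sign_classes
  sign_j[rs] <- sample(c(-1, 1), sum(rs), replace = TRUE)
  has_amp <- sign_j != 0
  targ <- beta0 + sign_j * ifelse(classes == "dm_constant",
                                  config$dm_offset_beta, A)
  if (any(has_amp & (targ <= 0 | targ >= 1))) {
    abort("Planted amplitude pushes Beta outside (0, 1); reduce the amplitude.")
  }
  amp_m[has_amp] <- beta_to_m(targ[has_amp]) - mu[has_amp]

  z_age <- as.vector(scale(pairs$age))
  z_sex <- if (stats::sd(pairs$sex_num) > 0) as.vector(scale(pairs$sex_num))
           else rep(0, n_donor)
  z_pmt <- as.vector(scale(pairs$postmortem_h))
  grade_w <- (g - 3) / 4

  # per-probe x per-donor intra-pair shift delta_j(d)
  donor_w <- matrix(0, np, n_donor)
  fill_rows <- function(mask, w) {
    if (any(mask)) donor_w[mask, ] <<- matrix(w, sum(mask), n_donor,
                                              byrow = TRUE)
  }
  fill_rows(classes %in% c("grade_hyper", "grade_hypo", "unstable_N",
                           "blacklisted"), grade_w)
  fill_rows(classes == "dm_constant", rep(1, n_donor))
  fill_rows(classes == "confound_age", z_age / 2)
  fill_rows(classes == "confound_sex", z_sex / 2)
  fill_rows(classes == "confound_pmt", z_pmt / 2)
  delta <- amp_m * donor_w

  # normal-tissue mean: baseline plus grade-coupled instability where planted
  n_shift <- matrix(0, np, n_donor)
  unst <- classes == "unstable_N"
  if (any(unst)) {
    n_shift[unst, ] <- (sign_j[unst] * config$unstable_n_shift_m) *
      matrix(grade_w, sum(unst), n_donor, byrow = TRUE)
  }

  noise <- function() matrix(rnorm(np * n_donor, 0, config$noise_sd_m),
                             np, n_donor)
  mN <- mu + n_shift + noise()
  mA <- mN + delta + noise()

  betaN <- m_to_beta(mN)
  betaA <- m_to_beta(mA)
  colnames(betaN) <- pairs$sample_N
  colnames(betaA) <- pairs$sample_A
  beta <- dplyr::bind_cols(tibble(probe_id = probe_id),
                           as_tibble(betaA), as_tibble(betaN))
  beta <- beta[, c("probe_id", cohort$sample_id)]

  annotation <- .simulate_annotation(probe_id, config)
  blacklist <- probe_id[classes == "blacklisted"]
  effect_beta <- numeric(np)
  effect_beta[has_amp] <- sign_j[has_amp] *
    ifelse(classes[has_amp] == "dm_constant", config$dm_offset_beta, A)
  truth <- tibble(probe_id = probe_id, class = classes, effect = effect_beta)

  list(cohort = cohort, beta = beta, annotation = annotation,
       blacklist = blacklist, truth = truth, config = config)
}

# trimodal array-like baseline Beta distribution
.baseline_mix <- function(n, weights = c(0.35, 0.30, 0.35)) {
  comp <- sample.int(3, n, replace = TRUE, prob = weights)
  out <- numeric(n)
  out[comp == 1] <- rbeta(sum(comp == 1), 5, 45)    # low-methylation mode
  out[comp == 2] <- rbeta(sum(comp == 2), 10, 10)   # intermediate
  out[comp == 3] <- rbeta(sum(comp == 3), 45, 5)    # high-methylation mode
  pmin(pmax(out, 1e-4), 1 - 1e-4)
}

.simulate_cohort_sheet <- function(grade_counts) {
  grades <- rep(names(grade_counts), grade_counts)
  n <- length(grades)
  donor <- sprintf("D%02d", seq_len(n))
  g_num <- grade_to_numeral(grades)
  for (try in 1:1000) {
    age <- round(pmin(pmax(rnorm(n, 70, 9), 45), 95))
    sex <- sample(c("M", "F"), n, replace = TRUE)
    pmt <- round(runif(n, 5, 40), 1)
    if (length(unique(sex)) < 2 && n >= 2) next
    ps <- vapply(list(age, ifelse(sex == "F", 1, 0), pmt), function(y) {
      if (stats::sd(y) == 0) return(1)
      rx <- rank(y); ry <- rank(g_num)
      rho <- stats::cor(rx, ry)
      .spearman_p(rho, rx, ry, exact_max_n = 0L)
    }, numeric(1))
    if (all(ps >= 0.25)) break
    if (try == 1000) abort("Could not draw grade-neutral covariates.")
  }
  tibble(
    sample_id = c(paste0(donor, "_A"), paste0(donor, "_N")),
    donor_id = rep(donor, 2),
    tissue = rep(c("A", "N"), each = n),
    grade = rep(grades, 2),
    age = rep(age, 2),
    sex = rep(sex, 2),
    postmortem_h = rep(pmt, 2)
  ) %>% arrange(.data$donor_id, .data$tissue)
}

.simulate_annotation <- function(probe_id, config) {
  np <- length(probe_id)
  comp <- sample(names(config$compartment_prop), np, replace = TRUE,
                 prob = config$compartment_prop)
  cgi <- sample(names(config$cgi_prop), np, replace = TRUE,
                prob = config$cgi_prop)
  gene <- sprintf("GENE%06d", seq_len(np))
  intergenic <- comp == "Intergenic"
  gene_symbols <- as.list(gene)
  compartments <- as.list(comp)
  gene_symbols[intergenic] <- list(character(0))
  compartments[intergenic] <- list(character(0))
  tibble(
    probe_id = probe_id,
    chrom = paste0("chr", sample(1:22, np, replace = TRUE)),
    pos = sample.int(100000000L, np, replace = TRUE),
    gene_symbols = gene_symbols,
    compartments = compartments,
    cgi_relation = cgi
  )
}

#' Simulate a mouse-style differential-expression table coupled to planted
#' promoter drift
#'
#' Genes carrying a planted grade-drift probe (`grade_hyper`/`grade_hypo`) in
#' a promoter compartment (TSS200/TSS1500) receive
#' `log2FC = coupling_slope * s + Normal(0, noise_sd)` where s is +1 for
#' hypermethylating and -1 for hypomethylating probes; all other genes get
#' pure `Normal(0, noise_sd)` noise. Symbols are emitted in mouse style
#' (first letter capitalised, rest lower case).
#'
#' @param truth Truth table from [simulate_cohort_data()].
#' @param annotation Matching probe annotation.
#' @param coupling_slope Finite slope linking planted direction to log2FC
#'   (negative for the inverse promoter coupling seen in atherosclerosis).
#' @param noise_sd Standard deviation of the expression noise.
#' @param seed Integer seed.
#' @return A DE tibble (`gene`, `log2FC`) over all annotated genes.
#' @export
simulate_expression_data <- function(truth, annotation, coupling_slope = -1,
                                     noise_sd = 0.3, seed = 1L) {
  if (!is.finite(coupling_slope)) abort("coupling_slope must be finite.")
  if (!setequal(truth$probe_id, annotation$probe_id))
    abort("truth and annotation must cover the same probes.")
  set.seed(seed)
  comp <- assign_compartment(annotation)
  ann <- annotation %>%
    mutate(compartment = comp,
           class = truth$class[match(.data$probe_id, truth$probe_id)])
  promoter_drift <- ann %>%
    filter(.data$compartment == "Promoter",
           .data$class %in% c("grade_hyper", "grade_hypo")) %>%
    mutate(gene = toupper(vapply(.data$gene_symbols, `[`, character(1), 1)),
           s = ifelse(.data$class == "grade_hyper", 1, -1)) %>%
    distinct(.data$gene, .keep_all = TRUE)
  genes <- unique(toupper(unlist(ann$gene_symbols)))
  lfc <- rnorm(length(genes), 0, noise_sd)
  hit <- match(promoter_drift$gene, genes)
  lfc[hit] <- lfc[hit] + coupling_slope * promoter_drift$s
  tibble(gene = .mouse_symbol(genes), log2FC = lfc)
}

.mouse_symbol <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' Simulate a WGBS intra-pair difference table for one grade-VII donor
#'
#' For the first grade-VII donor, emits `wgbs_delta` equal to that donor's
#' array A-N Beta difference plus Normal noise, restricted to promoter probes
#' carrying planted grade drift (the loci a promoter-DMR WGBS comparison
#' would recover).
#'
#' @param cohort,beta,truth,annotation Outputs of [simulate_cohort_data()].
#' @param noise_sd WGBS measurement noise standard deviation.
#' @param seed Integer seed.
#' @return Tibble with `probe_id` and `wgbs_delta`.
#' @export
simulate_wgbs_data <- function(cohort, beta, truth, annotation,
                               noise_sd = 0.02, seed = 1L) {
  pairs <- cohort_pairs(cohort)
  vii <- pairs[pairs$grade_num == 7, ]
  if (nrow(vii) == 0) abort("No grade-VII donor in cohort.")
  donor <- vii[order(vii$donor_id), ][1, ]
  set.seed(seed)
  comp <- assign_compartment(annotation)
  keep <- annotation$probe_id[comp == "Promoter"]
  keep <- intersect(keep, truth$probe_id[truth$class %in%
                                           c("grade_hyper", "grade_hypo")])
  keep <- intersect(keep, beta$probe_id)
  if (length(keep) == 0) {
    return(tibble(probe_id = character(0), wgbs_delta = numeric(0)))
  }
  mat <- beta_as_matrix(beta)
  d <- unname(mat[keep, donor$sample_A] - mat[keep, donor$sample_N])
  tibble(probe_id = keep,
         wgbs_delta = d + rnorm(length(keep), 0, noise_sd))
}
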