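# Shared fixtures, built in code. The default simulation and its call set are
# cached per test run because several files exercise the same cohort.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_sim <- function() {
  cached("default_sim", simulate_cohort_data(generator_config(seed = 42)))
}

default_calls <- function() {
  cached("default_calls", {
    sim <- default_sim()
    call_grade_cpgs(sim$beta, sim$cohort, sim$annotation, sim$blacklist)
  })
}

# tiny explicit cohort: one donor per entry of grades, deterministic covariates
make_cohort <- function(grades = c("III", "III", "IV", "V", "VI", "VII", "VII"),
                        ages = NULL, sexes = NULL, pmts = NULL) {
  n <- length(grades)
  donor <- sprintf("D%02d", seq_len(n))
  if (is.null(ages)) ages <- c(61, 74, 68, 80, 55, 71, 66)[seq_len(n)]
  if (is.null(sexes)) sexes <- rep(c("M", "F"), length.out = n)
  if (is.null(pmts)) pmts <- c(12, 30, 8, 22, 17, 26, 10)[seq_len(n)]
  tibble::tibble(
    sample_id = c(paste0(donor, "_A"), paste0(donor, "_N")),
    donor_id = rep(donor, 2),
    tissue = rep(c("A", "N"), each = n),
    grade = rep(grades, 2),
    age = rep(ages, 2),
    sex = rep(sexes, 2),
    postmortem_h = rep(pmts, 2)
  )
}

# beta matrix tibble from a probes x donors list of (A, N) value pairs
make_beta <- function(cohort, beta_A, beta_N, probe_ids = NULL) {
  pairs <- cohort_pairs(cohort)
  if (is.null(dim(beta_A))) beta_A <- matrix(beta_A, nrow = 1)
  if (is.null(dim(beta_N))) beta_N <- matrix(beta_N, nrow = 1)
  if (is.null(probe_ids)) probe_ids <- sprintf("cg%06d", seq_len(nrow(beta_A)))
  colnames(beta_A) <- pairs$sample_A
  colnames(beta_N) <- pairs$sample_N
  out <- dplyr::bind_cols(tibble::tibble(probe_id = probe_ids),
                          tibble::as_tibble(beta_A),
                          tibble::as_tibble(beta_N))
  out[, c("probe_id", cohort$sample_id)]
}

# forge a minimal grade_cpg_calls object for summary/writer tests
forge_calls <- function(records, n_tested = nrow(records),
                        annotation = NULL) {
  defaults <- tibble::tibble(
    probe_id = records$probe_id,
    rho = 0.5, p_grade = 0.01, p_age = 0.5, p_sex = 0.5, p_pmt = 0.5,
    covariate_pass = TRUE, p_ancova = 0.01,
    mean_dbeta_gIII = 0, mean_dbeta_gVII = 0.1, extreme_effect = 0.1,
    p_n_stability = 0.5, crit_effect = TRUE, crit_correlation = TRUE,
    crit_stability = TRUE, is_grade_cpg = TRUE, direction = "hyper",
    below_bonferroni = FALSE)
  for (nm in names(records)) defaults[[nm]] <- records[[nm]]
  structure(list(records = defaults, annotation = annotation,
                 config = analysis_config(), n_input = n_tested,
                 n_missing_dropped = 0L, n_blacklisted = 0L,
                 n_tested = n_tested,
                 bonferroni_threshold = 0.05 / n_tested,
                 n_below_bonferroni = 0L),
            class = "grade_cpg_calls")
}

# independent mid-rank Spearman oracle: explicit mid-ranks + raw Pearson sums
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# independent permutation enumeration for the exact two-sided Spearman p
# (tie-free x): fraction of permutations with |rho| >= |rho_obs|
oracle_spearman_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  obs <- oracle_spearman_rho(x, y)
  all_r <- vapply(perms(x), function(px) oracle_spearman_rho(px, y),
                  numeric(1))
  mean(abs(all_r) >= abs(obs) - 1e-12)
}
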