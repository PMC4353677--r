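test_that("intra-pair deltas compute A - N on the requested scale", {
  co <- make_cohort(c("III", "VII"))
  beta <- make_beta(co, beta_A = c(0.8, 0.6), beta_N = c(0.5, 0.5))
  dM <- intra_pair_delta(beta, co, "M")
  expect_equal(unname(as.matrix(dM[-1]))[1, ], c(2, log2(0.6 / 0.4)))
  dB <- intra_pair_delta(beta, co, "Beta")
  expect_equal(unname(as.matrix(dB[-1]))[1, ], c(0.3, 0.1))
  expect_equal(attr(dB, "scale"), "Beta")

  same <- make_beta(co, beta_A = c(0.4, 0.4), beta_N = c(0.4, 0.4))
  expect_true(all(as.matrix(intra_pair_delta(same, co, "M")[-1]) == 0))

  short <- beta[, 1:4]  # drop one donor's samples
  expect_error(intra_pair_delta(short, co, "M"), "D02")
})

test_that("covariate screen flags covariate-driven deltas and tolerates constants", {
  co <- make_cohort(c("III", "III", "IV", "V", "VI", "VII", "VII"))
  pairs <- cohort_pairs(co)
  flat <- covariate_screen(rep(0.05, 7), co)
  expect_true(flat$pass)

  agey <- covariate_screen(as.vector(scale(pairs$age)), co)
  expect_lt(agey$p_age, 0.05)
  expect_false(agey$pass)

  males <- make_cohort(c("III", "IV", "V", "VI", "VII"),
                       sexes = rep("M", 5))
  expect_warning(res <- covariate_screen(c(0.1, 0.3, 0.2, 0.5, 0.4), males),
                 "Constant covariate")
  expect_equal(res$p_sex, 1)
})

test_that("covariate-adjusted ANOVA separates grade signal from covariate signal", {
  co <- make_cohort(c("III", "III", "IV", "IV", "V", "V", "VI", "VII",
                      "VII", "VII"),
                    ages = c(60, 75, 68, 81, 59, 72, 66, 78, 62, 70),
                    pmts = c(11, 29, 7, 23, 16, 27, 9, 33, 14, 21))
  pairs <- cohort_pairs(co)
  # noiseless linear grade effect -> essentially zero p
  expect_lt(ancova_grade(0.2 * (pairs$grade_num - 3), co), 1e-6)
  # matches anova() partial F on a noisy probe
  set.seed(31)
  d <- 0.1 * (pairs$grade_num - 3) + rnorm(10, 0, 0.1)
  fit1 <- lm(d ~ factor(pairs$grade_num) + age + sex_num + postmortem_h,
             data = pairs)
  fit0 <- lm(d ~ age + sex_num + postmortem_h, data = pairs)
  expect_equal(ancova_grade(d, co), anova(fit0, fit1)[2, "Pr(>F)"],
               tolerance = 1e-10)
  # a design with no residual degrees of freedom is refused with a diagnostic
  tiny <- make_cohort(c("III", "IV", "V", "VI", "VII", "VII", "VII"))
  expect_error(ancova_grade(rep(0.1, 7), tiny), "residual degrees")
})

test_that("ANOVA screen is calibrated under the null and blind to pure age effects", {
  co <- make_cohort(c("III", "III", "IV", "V", "VI", "VII", "VII",
                      "III", "IV", "V", "VI", "VII", "VII", "VII", "VII"),
                    ages = c(61, 74, 68, 80, 55, 71, 66, 59, 77, 63, 70,
                             82, 57, 73, 65),
                    pmts = c(12, 30, 8, 22, 17, 26, 10, 14, 28, 9, 21,
                             19, 31, 6, 24))
  pairs <- cohort_pairs(co)
  set.seed(77)
  D <- matrix(rnorm(1000 * 15), 1000, 15)
  p <- methdrift:::.ancova_matrix(D, pairs)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
  # delta tracking age alone rarely shows a grade effect
  set.seed(78)
  p_age <- replicate(200, {
    ancova_grade(as.vector(scale(pairs$age)) + rnorm(15, 0, 0.05), co)
  })
  expect_gt(median(p_age), 0.05)
})

test_that("extreme-grade effect uses a strict threshold", {
  g <- c(3, 3, 7, 7)
  res <- extreme_grade_effect(c(0.00, 0.02, 0.10, 0.06), g)
  expect_equal(res$effect, 0.07)
  expect_true(res$pass)
  expect_false(extreme_grade_effect(c(0.1, 0.1, 0.1, 0.1), g)$pass)
  # boundary: effect exactly 0.05 fails the strict inequality
  res_b <- extreme_grade_effect(c(0, 0, 0.05, 0.05), g)
  expect_equal(res_b$effect, 0.05)
  expect_false(res_b$pass)
  expect_error(extreme_grade_effect(c(0, 0.1), c(4, 7)), "grade-III")
})

test_that("normal-tissue stability matches the closed-form Welch statistic", {
  co <- make_cohort(c("III", "III", "III", "VII", "VII", "VII"))
  pairs <- cohort_pairs(co)
  mv <- setNames(c(0, 0, 0.01, 3, 3, 3.01), pairs$sample_N)
  res <- n_sample_stability(mv, co)
  expect_lt(res$p, 0.01)
  expect_false(res$pass)
  # closed-form oracle
  x <- c(3, 3, 3.01); y <- c(0, 0, 0.01)
  se2 <- var(x) / 3 + var(y) / 3
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(res$p, 2 * pt(-abs(tt), df), tolerance = 1e-12)

  equal <- setNames(c(0.2, 0.4, 0.3, 0.2, 0.4, 0.3), pairs$sample_N)
  expect_true(n_sample_stability(equal, co)$pass)

  lone <- make_cohort(c("III", "VII", "VII", "VII"))
  lv <- setNames(c(0, 1, 1, 1), cohort_pairs(lone)$sample_N)
  expect_warning(res_l <- n_sample_stability(lv, lone), "indeterminate")
  expect_true(res_l$pass)
  expect_true(is.na(res_l$p))
})

test_that("the full decision rule recovers a single planted probe and honours the blacklist", {
  cfg <- generator_config(n_probes = 100L,
                          grade_counts = c(III = 2L, IV = 2L, V = 1L,
                                           VI = 1L, VII = 9L),
                          class_counts = c(grade_hyper = 1L),
                          noise_sd_m = 0, seed = 12L)
  sim <- simulate_cohort_data(cfg)
  planted <- sim$truth$probe_id[sim$truth$class == "grade_hyper"]
  calls <- call_grade_cpgs(sim$beta, sim$cohort, sim$annotation)
  rec <- tidy(calls)
  expect_identical(rec$probe_id[rec$is_grade_cpg], planted)
  expect_identical(rec$direction[rec$is_grade_cpg], "hyper")

  none <- call_grade_cpgs(sim$beta, sim$cohort, sim$annotation,
                          blacklist = planted)
  expect_equal(sum(tidy(none)$is_grade_cpg), 0)
  expect_equal(none$n_blacklisted, 1L)
  expect_equal(none$n_tested, 99L)
})

test_that("unstable-N probes are rejected by the stability criterion alone", {
  cfg <- generator_config(n_probes = 60L,
                          grade_counts = c(III = 2L, IV = 2L, V = 1L,
                                           VI = 1L, VII = 9L),
                          class_counts = c(unstable_N = 10L),
                          noise_sd_m = 0, seed = 14L)
  sim <- simulate_cohort_data(cfg)
  rec <- tidy(call_grade_cpgs(sim$beta, sim$cohort, sim$annotation))
  unst <- rec[rec$probe_id %in%
                sim$truth$probe_id[sim$truth$class == "unstable_N"], ]
  expect_true(all(unst$p_grade < 0.05))     # the drift signal is there...
  expect_true(all(!unst$crit_stability))    # ...but the baseline moved
  expect_equal(sum(unst$is_grade_cpg), 0)
  expect_equal(sum(rec$is_grade_cpg), 0)
})

test_that("direction partitions the call set and summaries count genes once", {
  rec <- tidy(default_calls())
  called <- rec[rec$is_grade_cpg, ]
  expect_false(any(is.na(called$direction)))
  expect_equal(sum(called$direction == "hyper") +
                 sum(called$direction == "hypo"), nrow(called))
  expect_true(all(called$rho[called$direction == "hyper"] > 0))
  expect_true(all(called$rho[called$direction == "hypo"] <= 0))

  ann <- tibble::tibble(
    probe_id = c("cg1", "cg2", "cg3"), chrom = "chr1", pos = 1:3,
    gene_symbols = list("PDGFA", "PDGFA", "LPL"),
    compartments = list("Body", "TSS200", "Body"),
    cgi_relation = c("Island", "Shore", "OpenSea"))
  two_same <- forge_calls(tibble::tibble(probe_id = c("cg1", "cg2")),
                          annotation = ann)
  expect_equal(summarize_calls(two_same)$n_genes, 1)

  mix <- forge_calls(tibble::tibble(
    probe_id = sprintf("cg%d", 1:10),
    direction = rep(c("hyper", "hypo"), c(8, 2)),
    rho = rep(c(0.6, -0.6), c(8, 2))))
  expect_equal(summarize_calls(mix)$pct_hyper, 80)

  empty <- forge_calls(tibble::tibble(probe_id = "cg1",
                                      is_grade_cpg = FALSE))
  s <- summarize_calls(empty)
  expect_equal(s$n_called, 0)
  expect_equal(s$mean_effect, 0)
})

test_that("Bonferroni reporting matches the array-scale regime", {
  expect_equal(bonferroni_threshold(485512), 0.05 / 485512)
  expect_lt(bonferroni_threshold(485512), 1.1e-7)
  expect_gt(bonferroni_threshold(485512), 1e-7)
  calls <- default_calls()
  expect_equal(calls$bonferroni_threshold, 0.05 / calls$n_tested)
})
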