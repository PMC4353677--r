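test_that("compartment assignment follows the promoter-first precedence", {
  ann <- tibble::tibble(
    probe_id = paste0("cg", 1:5), chrom = "chr1", pos = 1:5,
    gene_symbols = list("G1", c("G1", "G2"), character(0),
                        c("G1", "G2"), "G1"),
    compartments = list("TSS200", c("Body", "TSS1500"), character(0),
                        c("UTR3", "FirstExon"), "Body"),
    cgi_relation = rep("Island", 5))
  expect_equal(assign_compartment(ann),
               c("Promoter", "Promoter", "Intergenic", "FirstExon", "Body"))
})

test_that("background chi-square is zero for matched proportions and matches the oracle", {
  bg <- rep(c("Body", "Promoter", "Island"), c(50, 30, 20))
  sel <- rep(c("Body", "Promoter", "Island"), c(5, 3, 2))
  res <- category_background_test(sel, bg)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  set.seed(41)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    cats <- LETTERS[1:k]
    bg_n <- sample(5:40, k, replace = TRUE)
    sel_n <- vapply(bg_n, function(m) sample.int(m, 1), integer(1))
    bg <- rep(cats, bg_n)
    sel <- rep(cats, sel_n)
    res <- category_background_test(sel, bg)
    expd <- sum(sel_n) * bg_n / sum(bg_n)
    chi2_oracle <- sum((sel_n - expd)^2 / expd)
    expect_equal(res$chi2, chi2_oracle, tolerance = 1e-9)
    expect_equal(res$p, pchisq(chi2_oracle, k - 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("zero-background categories are merged, not dropped", {
  bg <- rep(c("A", "B", "C"), c(40, 30, 5))
  sel <- c(rep("A", 6), rep("B", 3), "D")  # "D" unseen in background
  expect_warning(res <- category_background_test(sel, bg), "other")
  expect_true("other" %in% res$counts$category)
  expect_equal(sum(res$counts$observed), length(sel))
  expect_equal(sum(res$counts$background), length(bg))
  expect_true(all(res$counts$background > 0))
})

test_that("hyper/hypo feature contrast reproduces the 2x2 Pearson oracle", {
  # identical feature rates -> p ~ 1
  ann <- tibble::tibble(
    probe_id = paste0("cg", 1:20), chrom = "chr1", pos = 1:20,
    gene_symbols = replicate(20, "G", simplify = FALSE),
    compartments = replicate(20, "Body", simplify = FALSE),
    cgi_relation = rep(c("Island", "OpenSea"), 10))
  rec <- forge_calls(tibble::tibble(
    probe_id = paste0("cg", 1:20),
    direction = rep(c("hyper", "hypo"), each = 10),
    rho = rep(c(0.5, -0.5), each = 10)))$records
  res <- hyper_hypo_contrast(rec, ann, "Island")
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  # frozen oracle: counts [[24,330],[351,1280]]
  tab <- matrix(c(24, 351, 330, 1280), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2_oracle <- sum((tab - E)^2 / E)
  ann2 <- tibble::tibble(
    probe_id = sprintf("cg%05d", 1:1985), chrom = "chr1", pos = 1:1985,
    gene_symbols = replicate(1985, "G", simplify = FALSE),
    compartments = replicate(1985, "Body", simplify = FALSE),
    cgi_relation = c(rep("Island", 24), rep("OpenSea", 330),
                     rep("Island", 351), rep("OpenSea", 1280)))
  rec2 <- forge_calls(tibble::tibble(
    probe_id = sprintf("cg%05d", 1:1985),
    direction = rep(c("hypo", "hyper"), c(354, 1631)),
    rho = rep(c(-0.5, 0.5), c(354, 1631))))$records
  res2 <- hyper_hypo_contrast(rec2, ann2, "Island")
  expect_equal(unname(res2$table["hypo", "in_feature"]), 24)
  expect_equal(res2$chi2, chi2_oracle, tolerance = 1e-9)
  expect_equal(res2$p, pchisq(chi2_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(res2$pct_hypo, 100 * 24 / 354, tolerance = 1e-9)

  # degenerate single-probe groups with identical labels run and give p = 1
  tiny_ann <- tibble::tibble(
    probe_id = c("cg1", "cg2"), chrom = "chr1", pos = 1:2,
    gene_symbols = list("G", "G"), compartments = list("Body", "Body"),
    cgi_relation = c("Island", "Island"))
  tiny_rec <- forge_calls(tibble::tibble(
    probe_id = c("cg1", "cg2"), direction = c("hyper", "hypo"),
    rho = c(0.5, -0.5)))$records
  res3 <- hyper_hypo_contrast(tiny_rec, tiny_ann, "Island")
  expect_equal(res3$chi2, 0)
  expect_equal(res3$p, 1)

  one_dir <- forge_calls(tibble::tibble(probe_id = c("cg1", "cg2"),
                                        direction = "hyper", rho = 0.5))$records
  expect_error(hyper_hypo_contrast(one_dir, tiny_ann, "Island"), "nonempty")
})

test_that("baseline strata are boundary-exact and exhaustive", {
  x <- c(0.75, 0.76, 0.25, 0.249, 0, 1, 0.5)
  s <- baseline_strata(x)
  expect_equal(as.character(s),
               c("Intermediate", "High", "Intermediate", "Low", "Low",
                 "High", "Intermediate"))
  expect_false(anyNA(s))
  set.seed(19)
  grid <- runif(500)
  st <- baseline_strata(grid)
  expect_equal(sum(table(st)), 500)  # partition: every probe in exactly one
  expect_error(baseline_strata(1.2), "outside")
})

test_that("gene-set overlap p equals binomial-coefficient arithmetic", {
  a <- paste0("G", 1:5)
  res <- gene_overlap(a, a, universe_size = 20)
  expect_equal(res$k, 5)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  res0 <- gene_overlap(paste0("A", 1:4), paste0("B", 1:4), 20)
  expect_equal(res0$k, 0)
  expect_equal(res0$p, 1)

  # case-insensitive matching
  expect_equal(gene_overlap("Pdgfa", "PDGFA", 10)$k, 1)

  # brute-force enumeration oracle on small universes
  set.seed(53)
  for (i in 1:30) {
    N <- sample(6:15, 1)
    nA <- sample(1:(N - 1), 1)
    nB <- sample(1:(N - 1), 1)
    universe <- paste0("g", 1:N)
    A <- sample(universe, nA)
    B <- sample(universe, nB)
    k <- length(intersect(A, B))
    p_oracle <- sum(vapply(k:min(nA, nB), function(j)
      choose(nB, j) * choose(N - nB, nA - j), numeric(1))) / choose(N, nA)
    expect_equal(gene_overlap(A, B, N)$p, p_oracle, tolerance = 1e-9)
  }
  expect_error(gene_overlap(paste0("A", 1:8), paste0("B", 1:8), 10),
               "universe_size")
})

test_that("SNP proximity respects the inclusive window and chromosome", {
  ann <- tibble::tibble(
    probe_id = c("cg1", "cg2", "cg3"), chrom = c("chr1", "chr1", "chr2"),
    pos = c(500000L, 500000L, 700000L),
    gene_symbols = replicate(3, character(0), simplify = FALSE),
    compartments = replicate(3, character(0), simplify = FALSE),
    cgi_relation = rep("OpenSea", 3))
  snp <- tibble::tibble(snp_id = c("rs1", "rs2"),
                        chrom = c("chr1", "chr1"),
                        pos = c(700000L, 760001L))
  hits <- snp_proximity(ann[1, ], snp, 250000L)
  expect_equal(hits$snp_id, "rs1")
  expect_equal(hits$distance, 200000)
  # boundary: exactly window_bp is included
  snp_b <- tibble::tibble(snp_id = "rs3", chrom = "chr1", pos = 750000L)
  expect_equal(nrow(snp_proximity(ann[1, ], snp_b, 250000L)), 1)
  # same position different chromosome excluded
  expect_equal(nrow(snp_proximity(ann[3, ], snp, 250000L)), 0)
  bad <- tibble::tibble(snp_id = "rs4", chrom = NA, pos = 100L)
  expect_error(snp_proximity(ann, bad), "Malformed")
})
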