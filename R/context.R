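#' Collapse multi-valued gene annotation to one compartment per probe
#'
#' A probe annotated to TSS200 or TSS1500 for any of its genes is `Promoter`;
#' otherwise the first match in the precedence
#' `UTR5 > FirstExon > Body > UTR3` across its gene entries wins; probes with
#' no gene entry are `Intergenic`.
#'
#' @param annotation Probe annotation tibble.
#' @return Character vector, one compartment per probe.
#' @export
assign_compartment <- function(annotation) {
  vapply(annotation$compartments, function(v) {
    if (length(v) == 0) return("Intergenic")
    if (any(v %in% c("TSS200", "TSS1500"))) return("Promoter")
    for (lvl in c("UTR5", "FirstExon", "Body", "UTR3")) {
      if (lvl %in% v) return(lvl)
    }
    "Intergenic"
  }, character(1))
}

#' Chi-square test of a probe selection against the array background
#'
#' Pearson goodness-of-fit chi-square of the category counts of a selected
#' probe set against the expected counts derived from the category
#' proportions of the full array background. Categories with zero expected
#' count are merged into `other` (with a warning) so the statistic stays
#' defined.
#'
#' @param selected Character vector of category labels for the selected
#'   probes (e.g. from [assign_compartment()]), or a logical/character subset
#'   paired with `background`.
#' @param background Character vector of category labels for all array
#'   probes.
#' @return A list with `counts` (tibble of category, observed, background),
#'   `chi2`, `df`, `p`.
#' @export
category_background_test <- function(selected, background) {
  cats <- sort(unique(c(selected, background)))
  obs <- table(factor(selected, levels = cats))
  bg <- table(factor(background, levels = cats))
  if (any(bg == 0)) {
    # a zero-background category has expected count 0; pool it with the
    # smallest represented category so the statistic stays defined
    warn("Merging zero-background categories into 'other'.")
    zero <- names(bg)[bg == 0]
    host <- names(which.min(bg[bg > 0]))
    sel2 <- ifelse(selected %in% c(zero, host), "other", selected)
    bgd2 <- ifelse(background %in% c(zero, host), "other", background)
    return(category_background_test(sel2, bgd2))
  }
  if (length(cats) < 2) abort("Need at least 2 categories with nonzero background.")
  props <- as.numeric(bg) / sum(bg)
  expd <- props * sum(obs)
  chi2 <- sum((as.numeric(obs) - expd)^2 / expd)
  df <- length(cats) - 1
  list(
    counts = tibble(category = cats, observed = as.integer(obs),
                    background = as.integer(bg)),
    chi2 = chi2, df = df,
    p = stats::pchisq(chi2, df, lower.tail = FALSE)
  )
}

# 2x2 Pearson chi-square without continuity correction; zero-expected cells
# contribute nothing (a degenerate table gives chi2 = 0, p = 1)
.chisq2x2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ok <- E > 0
  chi2 <- sum((tab[ok] - E[ok])^2 / E[ok])
  list(chi2 = chi2, df = 1,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Contrast a genomic feature between hypo- and hypermethylating grade-CpGs
#'
#' 2x2 Pearson chi-square of feature membership (e.g. CpG-island residence)
#' between the hypomethylating and hypermethylating call sets, with the
#' percentage of feature-positive probes in each set.
#'
#' @param records Tidy per-probe record table (from `tidy()` on a
#'   [call_grade_cpgs()] result); only called probes are used.
#' @param annotation Probe annotation.
#' @param feature Either a CGI-relation value (`"Island"`, `"Shore"`,
#'   `"Shelf"`, `"OpenSea"`) or a compartment value (e.g. `"Promoter"`,
#'   `"Body"`).
#' @return A list with the 2x2 `table`, `pct_hypo`, `pct_hyper`, `chi2`,
#'   `df`, `p`.
#' @export
hyper_hypo_contrast <- function(records, annotation, feature = "Island") {
  called <- filter(records, .data$is_grade_cpg)
  ann <- annotation[match(called$probe_id, annotation$probe_id), ]
  in_feat <- if (feature %in% .cgi_levels) {
    ann$cgi_relation == feature
  } else {
    assign_compartment(ann) == feature
  }
  hypo <- called$direction == "hypo"
  if (!any(hypo) || !any(!hypo)) {
    abort("Both direction groups must be nonempty for the contrast.")
  }
  tab <- rbind(hypo = c(sum(hypo & in_feat), sum(hypo & !in_feat)),
               hyper = c(sum(!hypo & in_feat), sum(!hypo & !in_feat)))
  colnames(tab) <- c("in_feature", "out_feature")
  res <- .chisq2x2(tab)
  c(list(table = tab,
         pct_hypo = 100 * tab["hypo", 1] / sum(tab["hypo", ]),
         pct_hyper = 100 * tab["hyper", 1] / sum(tab["hyper", ])),
    res)
}

#' Baseline methylation strata
#'
#' Classifies mean normal-tissue Beta values into the printed strata rule:
#' High when Beta > 0.75 (strict), Low when Beta < 0.25 (strict),
#' Intermediate for the inclusive band 0.25 <= Beta <= 0.75.
#'
#' @param mean_n_beta Numeric vector of mean N-sample Beta values in \[0,1\].
#' @param config [analysis_config()] supplying the cut-offs.
#' @return Factor with levels High, Intermediate, Low.
#' @export
baseline_strata <- function(mean_n_beta, config = analysis_config()) {
  if (any(mean_n_beta < 0 | mean_n_beta > 1, na.rm = TRUE))
    abort("Beta values outside [0, 1].")
  out <- ifelse(mean_n_beta > config$strata_high, "High",
                ifelse(mean_n_beta < config$strata_low, "Low", "Intermediate"))
  factor(out, levels = c("High", "Intermediate", "Low"))
}

#' Hypergeometric overlap of a called gene set with an external list
#'
#' Upper-tail hypergeometric test for observing at least `k` shared symbols
#' between the grade-CpG-harbouring genes and a user-supplied list, given a
#' stated gene universe. Symbols are upper-cased before matching.
#'
#' @param called_genes Character vector of gene symbols harbouring calls.
#' @param external_list Character vector of external gene symbols.
#' @param universe_size Size of the gene universe both sets are drawn from.
#' @return A list with `overlap` (sorted symbols), `k`, and `p`.
#' @export
gene_overlap <- function(called_genes, external_list, universe_size) {
  a <- unique(toupper(called_genes))
  b <- unique(toupper(external_list))
  if (universe_size < length(union(a, b)))
    abort("universe_size smaller than the union of the two gene sets.")
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(b), universe_size - length(b), length(a),
                     lower.tail = FALSE)
  list(overlap = sort(intersect(a, b)), k = k, p = p)
}

#' Probe-SNP proximity within a window
#'
#' Emits every (probe, SNP) pair on the same chromosome whose 1-based
#' positions differ by at most `window_bp` (inclusive boundary). Positions
#' must share a genome build; no liftover is attempted.
#'
#' @param annotation Probe annotation tibble (uses `probe_id`, `chrom`,
#'   `pos`).
#' @param snp_table Tibble with columns `snp_id`, `chrom`, `pos`.
#' @param window_bp Window size in base pairs (default 250 kb).
#' @return Tibble with `probe_id`, `snp_id`, `distance`, sorted by probe.
#' @export
snp_proximity <- function(annotation, snp_table, window_bp = 250000L) {
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(snp_table)))
    abort("snp_table needs columns snp_id, chrom, pos.")
  if (anyNA(snp_table$chrom) || anyNA(snp_table$pos) ||
      any(snp_table$pos < 1))
    abort("Malformed SNP row: missing chrom/pos or pos < 1.")
  hits <- annotation %>%
    select("probe_id", "chrom", probe_pos = "pos") %>%
    dplyr::inner_join(select(snp_table, "snp_id", "chrom", snp_pos = "pos"),
                      by = "chrom", relationship = "many-to-many") %>%
    mutate(distance = abs(.data$probe_pos - .data$snp_pos)) %>%
    filter(.data$distance <= window_bp) %>%
    select("probe_id", "snp_id", "distance") %>%
    arrange(.data$probe_id, .data$snp_id)
  hits
}
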