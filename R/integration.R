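#' Filter a differential-expression table by fold change
#'
#' Keeps genes whose absolute expression change strictly exceeds
#' `fold_threshold` (i.e. `|log2FC| > log2(fold_threshold)`), annotated with
#' the change direction. Idempotent.
#'
#' @param de DE tibble (`gene`, `log2FC`).
#' @param fold_threshold Linear fold-change cut-off, must exceed 1.
#' @return Filtered DE tibble with an added `de_direction` (`up`/`down`).
#' @export
filter_de <- function(de, fold_threshold = 2) {
  if (fold_threshold <= 1) abort("fold_threshold must exceed 1.")
  de %>%
    filter(abs(.data$log2FC) > log2(fold_threshold)) %>%
    mutate(de_direction = ifelse(.data$log2FC > 0, "up", "down"))
}

#' Map human to mouse gene symbols by case-insensitive identity
#'
#' Orthologs are matched by case-folded symbol equality (PDGFA ~ Pdgfa).
#' Symbols duplicated within a species after case-folding collapse to one
#' entry with a warning; unmatched symbols are reported in the attributes.
#'
#' @param human_symbols,mouse_symbols Character vectors.
#' @return Tibble with columns `human`, `mouse`; attributes
#'   `unmatched_human`, `unmatched_mouse`.
#' @export
map_orthologs <- function(human_symbols, mouse_symbols) {
  dedupe <- function(x, species) {
    key <- toupper(x)
    if (anyDuplicated(key)) {
      warn(sprintf("Duplicate %s symbol(s) after case-folding collapsed: %s",
                   species,
                   paste(unique(key[duplicated(key)]), collapse = ", ")))
    }
    x[!duplicated(key)]
  }
  h <- dedupe(human_symbols, "human")
  m <- dedupe(mouse_symbols, "mouse")
  idx <- match(toupper(h), toupper(m))
  out <- tibble(human = h[!is.na(idx)], mouse = m[idx[!is.na(idx)]])
  attr(out, "unmatched_human") <- h[is.na(idx)]
  attr(out, "unmatched_mouse") <- setdiff(m, out$mouse)
  out
}

#' Correlate methylation drift with heterologous expression, per genomic group
#'
#' For each called probe whose gene maps (via `mapping`) to exactly one
#' fold-change-filtered gene, pairs the probe's grade-correlation rho with
#' the mapped gene's log2 fold change, then reports the Pearson correlation
#' and two-sided p per genomic group (gene compartment or CGI relation).
#' Groups with fewer than 3 pairs are reported with `r = NA`. Probes mapping
#' to two or more filtered genes are excluded with a warning so pairs stay
#' independent.
#'
#' @param records Tidy per-probe table from [call_grade_cpgs()]; only called
#'   probes enter.
#' @param annotation Probe annotation.
#' @param de_filtered Output of [filter_de()] (mouse symbols).
#' @param mapping Ortholog map from [map_orthologs()].
#' @param group_by `"compartment"` (default) or `"cgi_relation"`.
#' @return Tibble with `group`, `n`, `r`, `p`; attribute `"pairs"` holds the
#'   per-probe pairing table.
#' @export
compartment_correlation <- function(records, annotation, de_filtered, mapping,
                                    group_by = c("compartment",
                                                 "cgi_relation")) {
  group_by <- match.arg(group_by)
  called <- filter(records, .data$is_grade_cpg)
  ann <- annotation[match(called$probe_id, annotation$probe_id), ]
  grp <- if (group_by == "compartment") assign_compartment(ann)
         else ann$cgi_relation
  mouse_by_human <- setNames(toupper(mapping$mouse), toupper(mapping$human))
  de_genes <- toupper(de_filtered$gene)
  lfc <- setNames(de_filtered$log2FC, de_genes)

  pair_rows <- purrr::map(seq_len(nrow(called)), function(i) {
    syms <- toupper(ann$gene_symbols[[i]])
    mouse <- unique(stats::na.omit(mouse_by_human[syms]))
    mouse <- mouse[mouse %in% de_genes]
    if (length(mouse) == 0) return(NULL)
    if (length(mouse) > 1) {
      warn(sprintf("Probe %s maps to %d filtered genes; excluded.",
                   called$probe_id[i], length(mouse)))
      return(NULL)
    }
    tibble(probe_id = called$probe_id[i], group = grp[i],
           rho = called$rho[i], log2FC = unname(lfc[mouse]))
  })
  pairs <- bind_rows(pair_rows)
  if (nrow(pairs) == 0) {
    out <- tibble(group = character(0), n = integer(0), r = numeric(0),
                  p = numeric(0))
    attr(out, "pairs") <- pairs
    return(out)
  }
  out <- pairs %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(),
              r = if (dplyr::n() >= 3) stats::cor(.data$rho, .data$log2FC)
                  else NA_real_,
              p = if (dplyr::n() >= 3)
                    stats::cor.test(.data$rho, .data$log2FC)$p.value
                  else NA_real_) %>%
    ungroup()
  if (any(out$n < 3)) warn("Group(s) with n < 3 reported as NA.")
  attr(out, "pairs") <- pairs
  out
}

#' WGBS concordance of grade-VII intra-pair differences
#'
#' Pearson correlation between the mean array intra-pair Delta-Beta over all
#' grade-VII donor pairs and the WGBS intra-pair methylation difference, at
#' the probes shared between the call set and the WGBS table.
#'
#' @param records Tidy per-probe table; only called probes are matched.
#' @param beta Beta matrix tibble.
#' @param cohort Cohort tibble (needs at least one grade-VII pair).
#' @param wgbs_table Tibble with `probe_id`, `wgbs_delta`.
#' @return List with `n`, `r`, `p` and the matched `pairs` tibble.
#' @export
wgbs_concordance <- function(records, beta, cohort, wgbs_table) {
  pairs <- cohort_pairs(cohort)
  if (!any(pairs$grade_num == 7)) abort("No grade-VII pair in cohort.")
  called <- filter(records, .data$is_grade_cpg)
  matched <- intersect(intersect(called$probe_id, wgbs_table$probe_id),
                       beta$probe_id)
  if (length(matched) < 3)
    abort(sprintf("Only %d matched probe(s); need at least 3.",
                  length(matched)))
  dB <- .delta_matrix(intra_pair_delta(beta[beta$probe_id %in% matched, ],
                                       cohort, "Beta"))
  x <- rowMeans(dB[matched, pairs$donor_id[pairs$grade_num == 7],
                   drop = FALSE])
  y <- wgbs_table$wgbs_delta[match(matched, wgbs_table$probe_id)]
  ct <- stats::cor.test(x, y)
  list(n = length(matched), r = unname(ct$estimate), p = ct$p.value,
       pairs = tibble(probe_id = matched, array_delta = unname(x),
                      wgbs_delta = y))
}
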