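#' @noRd
.read_tsv <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types, na = c("", "NA", "."),
                  progress = FALSE, show_col_types = FALSE)
}

#' Validate a cohort sample sheet
#'
#' Checks the donor-paired design: every donor has exactly one atherosclerotic
#' (`A`) and one normal (`N`) sample, grades are Roman III--VII shared within
#' the pair, and covariates are non-negative and shared within the pair.
#'
#' @param cohort Tibble with columns `sample_id`, `donor_id`, `tissue`,
#'   `grade`, `age`, `sex`, `postmortem_h`.
#' @return The cohort tibble, invisibly validated (returned unchanged).
#' @export
validate_cohort <- function(cohort) {
  need <- c("sample_id", "donor_id", "tissue", "grade", "age", "sex",
            "postmortem_h")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) abort(sprintf("Sample sheet lacks column(s): %s",
                                  paste(miss, collapse = ", ")))
  if (anyDuplicated(cohort$sample_id))
    abort("Duplicate sample_id in sample sheet.")
  if (!all(cohort$tissue %in% c("A", "N")))
    abort("tissue must be 'A' or 'N'.")
  grade_to_numeral(cohort$grade)  # errors on anything outside III-VII
  if (!all(cohort$sex %in% c("M", "F"))) abort("sex must be 'M' or 'F'.")
  if (any(cohort$age < 0) || any(cohort$postmortem_h < 0))
    abort("age and postmortem_h must be non-negative.")
  tab <- table(cohort$donor_id, cohort$tissue)
  bad <- rownames(tab)[tab[, "A"] != 1 | tab[, "N"] != 1]
  if (length(bad)) {
    abort(sprintf("Donor(s) without exactly one A and one N sample: %s",
                  paste(bad, collapse = ", ")))
  }
  shared <- cohort %>%
    group_by(.data$donor_id) %>%
    summarise(ok = dplyr::n_distinct(.data$grade) == 1 &
                dplyr::n_distinct(.data$age) == 1 &
                dplyr::n_distinct(.data$sex) == 1 &
                dplyr::n_distinct(.data$postmortem_h) == 1)
  if (!all(shared$ok)) {
    abort(sprintf("Pair members disagree on grade/covariates for donor(s): %s",
                  paste(shared$donor_id[!shared$ok], collapse = ", ")))
  }
  invisible(cohort)
}

#' Read a donor-paired sample sheet
#'
#' @param path TSV with header columns `sample_id`, `donor_id`, `tissue`
#'   (A/N), `grade` (Roman III--VII), `age`, `sex` (M/F), `postmortem_h`.
#' @return A validated cohort tibble, one row per sample.
#' @export
read_cohort <- function(path) {
  x <- .read_tsv(path, readr::cols(
    sample_id = "c", donor_id = "c", tissue = "c", grade = "c",
    age = "d", sex = "c", postmortem_h = "d"))
  validate_cohort(x)
  x
}

#' Write a cohort sample sheet
#' @param cohort Cohort tibble.
#' @param path Output TSV path.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' One row per donor pair
#'
#' Pivots a cohort to its pairing index: donor, A and N sample ids, numeric
#' grade and donor covariates (sex numerically coded M=0, F=1 for the
#' covariate screen).
#'
#' @param cohort Cohort tibble.
#' @return Tibble with columns `donor_id`, `sample_A`, `sample_N`, `grade`,
#'   `grade_num`, `age`, `sex`, `sex_num`, `postmortem_h`.
#' @export
cohort_pairs <- function(cohort) {
  validate_cohort(cohort)
  wide <- cohort %>%
    select("donor_id", "tissue", "sample_id") %>%
    tidyr::pivot_wider(names_from = "tissue", values_from = "sample_id",
                       names_prefix = "sample_")
  covar <- cohort %>%
    distinct(.data$donor_id, .data$grade, .data$age, .data$sex,
             .data$postmortem_h)
  left_join(wide, covar, by = "donor_id") %>%
    mutate(grade_num = grade_to_numeral(.data$grade),
           sex_num = ifelse(.data$sex == "F", 1, 0)) %>%
    select("donor_id", "sample_A", "sample_N", "grade", "grade_num",
           "age", "sex", "sex_num", "postmortem_h")
}

#' Read a probe-by-sample Beta matrix
#'
#' Values are validated into \[0, 1\]; probes containing any missing value are
#' dropped up front (the number dropped is reported via a message and the
#' `"n_dropped_missing"` attribute) so that every downstream test sees a
#' complete matrix.
#'
#' @param path TSV whose first column is `probe_id` and remaining columns are
#'   per-sample Beta values.
#' @return Tibble with `probe_id` plus one numeric column per sample.
#' @export
read_beta_matrix <- function(path) {
  x <- .read_tsv(path)
  names(x)[1] <- "probe_id"
  validate_beta_matrix(x)
}

#' Validate (and missing-filter) a Beta matrix tibble
#' @param x Tibble with `probe_id` plus numeric sample columns.
#' @return The validated tibble, missing-value probes removed.
#' @export
validate_beta_matrix <- function(x) {
  if (anyDuplicated(x$probe_id)) abort("Duplicate probe_id in Beta matrix.")
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) abort("Beta matrix columns must be numeric.")
  if (any(vals < 0 | vals > 1, na.rm = TRUE))
    abort("Beta values outside [0, 1].")
  keep <- stats::complete.cases(vals)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("Dropping %d probe(s) with missing Beta values.", n_drop))
    x <- x[keep, ]
  }
  attr(x, "n_dropped_missing") <- n_drop
  x
}

#' Write a Beta matrix
#' @param beta Beta matrix tibble.
#' @param path Output TSV path.
#' @export
write_beta_matrix <- function(beta, path) {
  readr::write_tsv(beta, path)
  invisible(path)
}

#' Beta matrix tibble to numeric matrix
#' @param beta Beta matrix tibble (`probe_id` + sample columns).
#' @return Numeric matrix, probes as rownames.
#' @export
beta_as_matrix <- function(beta) {
  m <- as.matrix(beta[-1])
  rownames(m) <- beta$probe_id
  m
}

.cgi_levels <- c("Island", "Shore", "Shelf", "OpenSea")
.compartment_levels <- c("TSS1500", "TSS200", "UTR5", "FirstExon", "Body",
                         "UTR3")

#' Read a probe annotation table
#'
#' One row per probe: genomic position, semicolon-separated parallel lists of
#' gene symbols and gene compartments, and the CpG-island relation. The
#' Illumina-style directional labels `N_Shore`/`S_Shore` and
#' `N_Shelf`/`S_Shelf` are collapsed to `Shore`/`Shelf`; the analysis only
#' distinguishes island, shore, shelf and open sea.
#'
#' @param path TSV with columns `probe_id`, `chrom`, `pos`, `gene_symbols`,
#'   `compartments`, `cgi_relation`. Intergenic probes leave the gene columns
#'   missing (`.`).
#' @return Tibble with list-columns `gene_symbols` and `compartments`.
#' @export
read_probe_annotation <- function(path) {
  x <- .read_tsv(path, readr::cols(
    probe_id = "c", chrom = "c", pos = "i", gene_symbols = "c",
    compartments = "c", cgi_relation = "c"))
  validate_probe_annotation(x)
}

.split_field <- function(s) {
  ifelse(is.na(s), list(character(0)), strsplit(s, ";", fixed = TRUE))
}

#' Validate a probe annotation tibble
#' @param x Annotation tibble (character or list gene columns).
#' @return Annotation tibble with list-columns and collapsed CGI labels.
#' @export
validate_probe_annotation <- function(x) {
  if (any(x$pos < 1)) abort("Probe positions must be 1-based (pos >= 1).")
  if (!is.list(x$gene_symbols)) {
    x$gene_symbols <- .split_field(x$gene_symbols)
    x$compartments <- .split_field(x$compartments)
  }
  n_sym <- lengths(x$gene_symbols)
  n_cmp <- lengths(x$compartments)
  if (any(n_sym != n_cmp)) {
    abort(sprintf("Unparallel gene_symbols/compartments for probe(s): %s",
                  paste(head(x$probe_id[n_sym != n_cmp], 3), collapse = ", ")))
  }
  cmp <- unique(unlist(x$compartments))
  cmp_map <- c(TSS1500 = "TSS1500", TSS200 = "TSS200", UTR5 = "UTR5",
               "5'UTR" = "UTR5", FirstExon = "FirstExon",
               "1stExon" = "FirstExon", Body = "Body", UTR3 = "UTR3",
               "3'UTR" = "UTR3")
  if (length(cmp) && !all(cmp %in% names(cmp_map))) {
    abort(sprintf("Unknown gene compartment label(s): %s",
                  paste(setdiff(cmp, names(cmp_map)), collapse = ", ")))
  }
  x$compartments <- lapply(x$compartments, function(v) unname(cmp_map[v]))
  rel_map <- c(Island = "Island", Shore = "Shore", Shelf = "Shelf",
               OpenSea = "OpenSea", N_Shore = "Shore", S_Shore = "Shore",
               N_Shelf = "Shelf", S_Shelf = "Shelf")
  if (!all(x$cgi_relation %in% names(rel_map))) {
    abort(sprintf("Unknown cgi_relation label(s): %s",
                  paste(setdiff(unique(x$cgi_relation), names(rel_map)),
                        collapse = ", ")))
  }
  x$cgi_relation <- unname(rel_map[x$cgi_relation])
  x
}

#' Write a probe annotation table
#' @param annotation Annotation tibble (list-columns allowed).
#' @param path Output TSV path.
#' @export
write_probe_annotation <- function(annotation, path) {
  flat <- annotation %>%
    mutate(
      gene_symbols = vapply(.data$gene_symbols, function(v)
        if (length(v)) paste(v, collapse = ";") else NA_character_,
        character(1)),
      compartments = vapply(.data$compartments, function(v)
        if (length(v)) paste(v, collapse = ";") else NA_character_,
        character(1)))
  readr::write_tsv(flat, path, na = ".")
  invisible(path)
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `gene` and either `log2FC` (default dialect)
#'   or a linear `fold` column.
#' @param fold If `TRUE`, the second column holds linear fold changes and is
#'   converted via `log2FC = log2(fold)`.
#' @return Tibble with columns `gene`, `log2FC` and (if present in the file)
#'   `ranking_score`, rows in input order.
#' @export
read_de_table <- function(path, fold = FALSE) {
  x <- .read_tsv(path)
  if (nrow(x) == 0) {
    return(tibble(gene = character(0), log2FC = numeric(0)))
  }
  names(x)[1] <- "gene"
  if (fold) {
    if (!is.numeric(x[[2]])) abort("Fold-change column must be numeric.")
    if (any(x[[2]] <= 0)) abort("Linear fold changes must be positive.")
    x$log2FC <- log2(x[[2]])
    x[[2]] <- NULL
  } else {
    names(x)[2] <- "log2FC"
    if (!is.numeric(x$log2FC)) abort("log2FC column must be numeric.")
  }
  if (any(!is.finite(x$log2FC))) abort("log2FC must be finite.")
  if (any(!nzchar(x$gene))) abort("Empty gene symbol in DE table.")
  select(x, "gene", "log2FC", dplyr::any_of("ranking_score"))
}

#' Write a differential-expression table
#' @param de DE tibble.
#' @param path Output TSV path.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(de, path)
  invisible(path)
}

#' Read a plain-text ID list (one probe or gene per line)
#' @param path Text file, one identifier per line; blank lines ignored.
#' @return Character vector.
#' @export
read_id_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x[nzchar(x)]
}

#' Write a plain-text ID list
#' @param ids Character vector.
#' @param path Output path.
#' @export
write_id_list <- function(ids, path) {
  readr::write_lines(ids, path)
  invisible(path)
}

#' Write drift-calling outputs: full results TSV and called-probe BED
#'
#' The BED6 file holds one 0-based half-open single-base interval
#' `[pos - 1, pos)` per called probe, `name` the probe id, `score`
#' `round(1000 * |rho|)` clipped to \[0, 1000\], strand `"."`.
#'
#' @param calls A `grade_cpg_calls` object from [call_grade_cpgs()].
#' @param annotation Probe annotation covering every tested probe.
#' @param out_dir Output directory (created if needed).
#' @return Invisible named character vector of the two file paths.
#' @export
write_grade_cpg_outputs <- function(calls, annotation, out_dir) {
  records <- tidy(calls)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  missing_ann <- setdiff(records$probe_id, annotation$probe_id)
  if (length(missing_ann)) {
    abort(sprintf("Probe(s) missing from annotation: %s",
                  paste(head(missing_ann, 3), collapse = ", ")))
  }
  res_path <- file.path(out_dir, "grade_cpg_results.tsv")
  readr::write_tsv(records, res_path)
  called <- records %>%
    filter(.data$is_grade_cpg) %>%
    left_join(select(annotation, "probe_id", "chrom", "pos"), by = "probe_id")
  bed <- tibble(
    chrom = called$chrom,
    start = called$pos - 1L,
    end = called$pos,
    name = called$probe_id,
    score = pmin(pmax(round(1000 * abs(called$rho)), 0), 1000),
    strand = "."
  )
  bed_path <- file.path(out_dir, "grade_cpgs.bed")
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  invisible(c(results = res_path, bed = bed_path))
}
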