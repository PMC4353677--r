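#' Run the drift-calling pipeline from a config file
#'
#' Orchestrates the stages behind one entry point. The config is a flat YAML
#' file mixing [analysis_config()] fields, [generator_config()] fields (for
#' simulation-driven runs) and input file paths (`sample_sheet`,
#' `beta_matrix`, `annotation`, `blacklist`, `de_table`, `wgbs_table`,
#' `snp_table`). Subcommands:
#'
#' * `simulate` — generate a synthetic cohort (sheet, Betas, annotation,
#'   blacklist, truth, expression, WGBS) under `out_dir/sim/`.
#' * `call` — run [call_grade_cpgs()] on the configured inputs and write the
#'   results TSV, BED and summary.
#' * `context` — genomic-distribution, direction-contrast and strata reports
#'   for an existing call run.
#' * `cluster` — Ward bicluster of the called-probe Delta-Beta matrix.
#' * `integrate` — expression and WGBS integration for an existing call run.
#' * `all` — simulate (when no `beta_matrix` path is configured), then call,
#'   context, cluster, integrate, plus a truth-vs-called confusion report.
#'
#' Every run writes `manifest.json` (seed, config checksum, input checksums,
#' stage timings, probe attrition).
#'
#' @param config_file Path to the YAML config.
#' @param subcommand One of `simulate`, `call`, `context`, `cluster`,
#'   `integrate`, `all`.
#' @param out_dir Output directory (created).
#' @param seed Optional integer overriding the config seed.
#' @return Invisible list of stage results (also written to `out_dir`).
#' @export
run_pipeline <- function(config_file,
                         subcommand = c("all", "simulate", "call", "context",
                                        "cluster", "integrate"),
                         out_dir, seed = NULL) {
  subcommand <- match.arg(subcommand)
  if (!file.exists(config_file))
    abort(sprintf("Input file not found: %s", config_file))
  raw <- yaml::read_yaml(config_file)
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  acfg_names <- names(formals(analysis_config))
  acfg <- do.call(analysis_config, raw[intersect(names(raw), acfg_names)])
  manifest <- list(subcommand = subcommand,
                   seed = raw$seed %||% acfg$random_seed,
                   config_md5 = unname(tools::md5sum(config_file)),
                   timings = list(), inputs = list())
  t_stage <- function(nm, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    manifest$timings[[nm]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  results <- list()

  simulate_needed <- subcommand == "simulate" ||
    (subcommand == "all" && is.null(raw$beta_matrix))
  sim <- NULL
  if (simulate_needed) {
    gcfg_names <- names(formals(generator_config))
    gargs <- raw[intersect(names(raw), gcfg_names)]
    if (!is.null(gargs$grade_counts)) gargs$grade_counts <- unlist(gargs$grade_counts)
    if (!is.null(gargs$class_counts)) gargs$class_counts <- unlist(gargs$class_counts)
    gcfg <- do.call(generator_config, gargs)
    sim <- t_stage("simulate", .pipe_simulate(gcfg, raw, out_dir))
    results$simulate <- sim$paths
  }

  if (subcommand %in% c("call", "context", "cluster", "integrate", "all")) {
    inputs <- if (!is.null(sim)) sim$data else .pipe_read_inputs(raw, manifest)
    if (is.null(sim)) {
      for (k in c("sample_sheet", "beta_matrix", "annotation", "blacklist"))
        if (!is.null(raw[[k]]))
          manifest$inputs[[k]] <- unname(tools::md5sum(raw[[k]]))
    }
    calls <- t_stage("call", call_grade_cpgs(
      inputs$beta, inputs$cohort, inputs$annotation, inputs$blacklist, acfg))
    manifest$attrition <- list(
      input = calls$n_input, blacklisted = calls$n_blacklisted,
      missing_dropped = calls$n_missing_dropped, tested = calls$n_tested)
    if (subcommand %in% c("call", "all")) {
      write_grade_cpg_outputs(calls, inputs$annotation, out_dir)
      readr::write_tsv(summarize_calls(calls), file.path(out_dir, "summary.tsv"))
    }
    results$calls <- calls

    if (subcommand %in% c("context", "all")) {
      results$context <- t_stage("context",
                                 .pipe_context(calls, inputs, raw, acfg, out_dir))
    }
    if (subcommand %in% c("cluster", "all")) {
      results$cluster <- t_stage("cluster", .pipe_cluster(calls, inputs, out_dir))
    }
    if (subcommand %in% c("integrate", "all")) {
      results$integrate <- t_stage("integrate",
                                   .pipe_integrate(calls, inputs, raw, acfg, out_dir))
    }
    if (subcommand == "all" && !is.null(inputs$truth)) {
      results$confusion <- .pipe_confusion(calls, inputs, results$cluster,
                                           out_dir)
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pipe_simulate <- function(gcfg, raw, out_dir) {
  sim_dir <- file.path(out_dir, "sim")
  dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort_data(gcfg)
  de <- simulate_expression_data(sim$truth, sim$annotation,
                                 coupling_slope = raw$coupling_slope %||% -1,
                                 noise_sd = raw$expression_noise_sd %||% 0.3,
                                 seed = gcfg$seed + 1L)
  wgbs <- simulate_wgbs_data(sim$cohort, sim$beta, sim$truth, sim$annotation,
                             noise_sd = raw$wgbs_noise_sd %||% 0.02,
                             seed = gcfg$seed + 2L)
  paths <- c(
    sample_sheet = write_cohort(sim$cohort, file.path(sim_dir, "sample_sheet.tsv")),
    beta_matrix = write_beta_matrix(sim$beta, file.path(sim_dir, "beta_matrix.tsv")),
    annotation = write_probe_annotation(sim$annotation,
                                        file.path(sim_dir, "annotation.tsv")),
    blacklist = write_id_list(sim$blacklist, file.path(sim_dir, "blacklist.txt")),
    de_table = write_de_table(de, file.path(sim_dir, "de_table.tsv")),
    wgbs_table = {
      p <- file.path(sim_dir, "wgbs_delta.tsv")
      readr::write_tsv(wgbs, p); p
    },
    truth = {
      p <- file.path(sim_dir, "truth.tsv")
      readr::write_tsv(sim$truth, p); p
    })
  list(paths = paths,
       data = list(cohort = sim$cohort, beta = sim$beta,
                   annotation = sim$annotation, blacklist = sim$blacklist,
                   truth = sim$truth, de = de, wgbs = wgbs))
}

.pipe_read_inputs <- function(raw, manifest) {
  need_file <- function(key) {
    p <- raw[[key]]
    if (is.null(p)) abort(sprintf("Config lacks required input path: %s", key))
    if (!file.exists(p)) abort(sprintf("Input file not found: %s", p))
    p
  }
  inputs <- list(
    cohort = read_cohort(need_file("sample_sheet")),
    beta = read_beta_matrix(need_file("beta_matrix")),
    annotation = read_probe_annotation(need_file("annotation")))
  inputs$blacklist <- if (!is.null(raw$blacklist))
    read_id_list(need_file("blacklist")) else NULL
  if (!is.null(raw$de_table))
    inputs$de <- read_de_table(need_file("de_table"),
                               fold = isTRUE(raw$fold_is_linear))
  if (!is.null(raw$wgbs_table))
    inputs$wgbs <- .read_tsv(need_file("wgbs_table"))
  if (!is.null(raw$truth))
    inputs$truth <- .read_tsv(need_file("truth"))
  inputs
}

.pipe_context <- function(calls, inputs, raw, acfg, out_dir) {
  rec <- calls$records
  ann_tested <- inputs$annotation[
    match(rec$probe_id, inputs$annotation$probe_id), ]
  called_idx <- rec$is_grade_cpg
  comp_all <- assign_compartment(ann_tested)
  out <- list(
    compartment = category_background_test(comp_all[called_idx], comp_all),
    cgi = category_background_test(ann_tested$cgi_relation[called_idx],
                                   ann_tested$cgi_relation))
  if (sum(rec$direction[called_idx] == "hypo", na.rm = TRUE) > 0 &&
      sum(rec$direction[called_idx] == "hyper", na.rm = TRUE) > 0) {
    out$island_contrast <- hyper_hypo_contrast(rec, inputs$annotation, "Island")
  }
  pairs <- cohort_pairs(inputs$cohort)
  mat <- beta_as_matrix(inputs$beta)
  mn <- rowMeans(mat[, pairs$sample_N, drop = FALSE])
  out$strata <- table(baseline_strata(mn[rec$probe_id[called_idx]], acfg))
  if (!is.null(raw$snp_table)) {
    snp <- .read_tsv(raw$snp_table)
    out$snp <- snp_proximity(ann_tested[called_idx, ], snp, acfg$snp_window_bp)
    readr::write_tsv(out$snp, file.path(out_dir, "snp_proximity.tsv"))
  }
  counts <- bind_rows(
    mutate(out$compartment$counts, feature = "compartment"),
    mutate(out$cgi$counts, feature = "cgi_relation"))
  readr::write_tsv(counts, file.path(out_dir, "category_counts.tsv"))
  jsonlite::write_json(
    list(compartment = out$compartment[c("chi2", "df", "p")],
         cgi = out$cgi[c("chi2", "df", "p")],
         strata = as.list(out$strata)),
    file.path(out_dir, "context_tests.json"), auto_unbox = TRUE, pretty = TRUE)
  out
}

.pipe_cluster <- function(calls, inputs, out_dir) {
  called <- calls$records$probe_id[calls$records$is_grade_cpg]
  if (length(called) < 2) {
    warn("Fewer than 2 called probes: clustering skipped.")
    return(NULL)
  }
  dB <- intra_pair_delta(inputs$beta[inputs$beta$probe_id %in% called, ],
                         inputs$cohort, "Beta")
  bc <- ward_bicluster(dB)
  write_bicluster(bc, out_dir)
  bc
}

.pipe_integrate <- function(calls, inputs, raw, acfg, out_dir) {
  out <- list()
  rec <- calls$records
  if (!is.null(inputs$de)) {
    de_f <- filter_de(inputs$de, acfg$fold_threshold)
    called <- filter(rec, .data$is_grade_cpg)
    ann <- inputs$annotation[match(called$probe_id,
                                   inputs$annotation$probe_id), ]
    human <- unique(toupper(unlist(ann$gene_symbols)))
    mapping <- map_orthologs(human, de_f$gene)
    out$correlation <- compartment_correlation(rec, inputs$annotation, de_f,
                                               mapping)
    readr::write_tsv(out$correlation,
                     file.path(out_dir, "expression_correlation.tsv"))
  }
  if (!is.null(inputs$wgbs) && nrow(inputs$wgbs) > 0) {
    n_match <- length(intersect(
      rec$probe_id[rec$is_grade_cpg], inputs$wgbs$probe_id))
    if (n_match >= 3) {
      out$wgbs <- wgbs_concordance(rec, inputs$beta, inputs$cohort,
                                   inputs$wgbs)
      jsonlite::write_json(out$wgbs[c("n", "r", "p")],
                           file.path(out_dir, "wgbs_concordance.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    } else {
      warn("Fewer than 3 WGBS-matched called probes: concordance skipped.")
    }
  }
  out
}

.pipe_confusion <- function(calls, inputs, bc, out_dir) {
  rec <- calls$records
  truth <- inputs$truth
  truth_grade <- truth$probe_id[truth$class %in% c("grade_hyper", "grade_hypo")]
  called <- rec$probe_id[rec$is_grade_cpg]
  tp <- length(intersect(called, truth_grade))
  report <- list(
    n_called = length(called),
    n_planted = length(truth_grade),
    true_positives = tp,
    sensitivity = if (length(truth_grade)) tp / length(truth_grade) else NA,
    precision = if (length(called)) tp / length(called) else NA)
  if (!is.null(bc)) {
    pairs <- cohort_pairs(inputs$cohort)
    truth_split <- ifelse(pairs$grade_num <= 4, "low", "high")
    names(truth_split) <- pairs$donor_id
    keep <- names(bc$col_cut2)
    report$donor_rand_index <- rand_index(bc$col_cut2,
                                          truth_split[keep])
  }
  jsonlite::write_json(report, file.path(out_dir, "confusion.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report
}
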