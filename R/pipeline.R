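#' Analysis configuration
#'
#' Collects the tunable constants of the pipeline: the synonymous-saturation
#' cutoff, omega selection thresholds, cosine/divergence quadrant
#' thresholds, cluster count, estimator and gamma shape.
#'
#' @param ks_cutoff Exclusive Ks upper bound for the saturation filter.
#' @param omega_thresholds `c(purifying_max, positive_min)`.
#' @param cosine_threshold Quadrant cosine threshold, in (0, 1).
#' @param divergence_threshold Quadrant divergence threshold (percent).
#' @param k_clusters Number of expression clusters.
#' @param gamma_shape Gamma shape for the gMYN estimator.
#' @param method Ka/Ks estimator: `"gMYN"`, `"MYN"` or `"NG86"`.
#' @param out_dir Optional output directory for report files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ks_cutoff = 1.1, omega_thresholds = c(0.3, 3),
                       cosine_threshold = 0.5, divergence_threshold = 50,
                       k_clusters = 16, gamma_shape = 1,
                       method = c("gMYN", "MYN", "NG86"), out_dir = NULL) {
  method <- match.arg(method)
  stopifnot(ks_cutoff > 0, all(omega_thresholds > 0),
            cosine_threshold > 0, cosine_threshold < 1,
            divergence_threshold > 0, k_clusters >= 1, gamma_shape > 0)
  structure(list(ks_cutoff = ks_cutoff, omega_thresholds = omega_thresholds,
                 cosine_threshold = cosine_threshold,
                 divergence_threshold = divergence_threshold,
                 k_clusters = k_clusters, gamma_shape = gamma_shape,
                 method = method, out_dir = out_dir),
            class = "run_config")
}

#' Run the full duplicate-gene analysis
#'
#' Composes all stages: (1) Ka/Ks/omega and divergence per pair (skipped
#' when `seqs` is `NULL` and the pair table already carries the columns);
#' (2) saturation filtering, selection classification, replicon-group omega
#' summaries, length bins and rate-divergence correlations; (3) per-pair
#' expression statistics and quadrants; (4) separate clusterings of the
#' in-paralog and out-paralog profiles and bidirectional cluster and gene
#' matching; (5) regressions of expression measures on the structural
#' constraints. Stages 3-5 are skipped with a warning when
#' `expression_table` is `NULL`.
#'
#' @param pairs A `pair_table`.
#' @param seqs Optional named character vector of coding sequences; when
#'   given, `ka`, `ks`, `omega`, `divergence` and `length` are recomputed
#'   from the sequences.
#' @param expression_table Optional `expr_table`.
#' @param config A [run_config()].
#' @return A report list; when `config$out_dir` is set the tables are also
#'   written there as TSV/JSON.
#' @export
run_full_analysis <- function(pairs, seqs = NULL, expression_table = NULL,
                              config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config = config)

  if (!is.null(seqs)) {
    kk <- kaks_table(seqs, pairs, method = config$method,
                     gamma_shape = config$gamma_shape)
    for (col in c("length", "divergence", "ka", "ks", "omega")) {
      pairs[[col]] <- kk[[col]]
    }
    pairs$saturated <- kk$saturated
  }
  needed <- c("ka", "ks", "omega")
  if (!all(needed %in% names(pairs))) {
    stop("pair table lacks ", paste(setdiff(needed, names(pairs)),
                                    collapse = ", "),
         " and no sequences were given [stage kaks]")
  }
  report$kaks <- pairs

  unsat <- filter_unsaturated(pairs, config$ks_cutoff)
  unsat$selection <- classify_selection(unsat$omega,
                                        config$omega_thresholds)
  if (any(unsat$selection == "undefined")) {
    warning(sum(unsat$selection == "undefined"),
            " pair(s) with undefined omega excluded from classification")
  }
  unsat$relation <- replicon_relation(unsat$replicon1, unsat$replicon2)
  report$classified <- unsat
  report$selection_counts <- table(unsat$selection)
  defined <- unsat[unsat$selection != "undefined", , drop = FALSE]
  report$group_summary <- summarize_omega_by_group(defined)
  if ("length" %in% names(pairs) && !anyNA(pairs$length)) {
    report$length_bins <- length_bin_frequencies(pairs)
  }
  if ("divergence" %in% names(pairs)) {
    report$rate_divergence <- lapply(c(ka = "ka", ks = "ks"), function(f) {
      tryCatch(rate_divergence_correlation(pairs, f),
               error = function(e) NULL)
    })
  }

  if (is.null(expression_table)) {
    warning("no expression table: expression stages skipped")
    return(write_report(report, config$out_dir))
  }

  stats <- pair_expression_stats(expression_table, pairs)
  if ("divergence" %in% names(stats) ||
      "quadrant" %in% names(stats)) {
    report$quadrant_counts <- table(stats$quadrant, stats$class)
  }
  report$expression_stats <- stats

  avg <- average_replicates(expression_table)
  z <- zscore_rows(avg)
  genes_in <- intersect(rownames(z),
                        unlist(pairs[pairs$class == "in", c("gene1", "gene2")]))
  genes_out <- intersect(rownames(z),
                         unlist(pairs[pairs$class == "out", c("gene1", "gene2")]))
  if (length(genes_in) >= config$k_clusters &&
      length(genes_out) >= config$k_clusters) {
    cl_in <- kmeans_hac(z[genes_in, , drop = FALSE], config$k_clusters)
    cl_out <- kmeans_hac(z[genes_out, , drop = FALSE], config$k_clusters)
    report$clustering <- list(inparalogs = cl_in, outparalogs = cl_out)
    report$cluster_match <- list(
      in_to_out = match_clusters(cl_in, cl_out),
      out_to_in = match_clusters(cl_out, cl_in))
    report$gene_match <- list(
      in_to_out = gene_best_match(z[genes_in, , drop = FALSE],
                                  z[genes_out, , drop = FALSE]),
      out_to_in = gene_best_match(z[genes_out, , drop = FALSE],
                                  z[genes_in, , drop = FALSE]))
  } else {
    warning("too few profiles per paralog class for k = ",
            config$k_clusters, " clusters: clustering skipped")
  }

  joined <- merge(stats, pairs[, intersect(names(pairs),
                                           c("gene1", "gene2", "ka", "ks",
                                             "omega"))],
                  by = c("gene1", "gene2"))
  report$regressions <- list()
  for (xf in c("ka", "ks")) {
    for (yf in c("transformed_r", "expression_divergence")) {
      report$regressions[[paste(yf, "vs", xf)]] <- tryCatch(
        suppressWarnings(regress_expression_vs_constraint(joined, xf, yf)),
        error = function(e) NULL)
    }
  }
  write_report(report, config$out_dir)
}

write_report <- function(report, out_dir) {
  if (is.null(out_dir)) return(invisible(report))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pair_table(report$kaks, file.path(out_dir, "kaks_table.tsv"))
  cls <- report$classified
  cls$selection <- as.character(cls$selection)
  cls$relation <- as.character(cls$relation)
  write_pair_table(cls, file.path(out_dir, "classification.tsv"))
  write_pair_table(report$group_summary,
                   file.path(out_dir, "group_summary.tsv"))
  if (!is.null(report$length_bins)) {
    write_pair_table(report$length_bins, file.path(out_dir, "length_bins.tsv"))
  }
  if (!is.null(report$expression_stats)) {
    es <- report$expression_stats
    if ("quadrant" %in% names(es)) es$quadrant <- as.character(es$quadrant)
    write_pair_table(es, file.path(out_dir, "expression_stats.tsv"))
  }
  if (!is.null(report$cluster_match)) {
    jsonlite::write_json(
      list(in_to_out = report$cluster_match$in_to_out,
           out_to_in = report$cluster_match$out_to_in),
      file.path(out_dir, "cluster_matches.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    asg <- data.frame(
      gene = c(names(report$clustering$inparalogs$assignments),
               names(report$clustering$outparalogs$assignments)),
      class = c(rep("in", length(report$clustering$inparalogs$assignments)),
                rep("out", length(report$clustering$outparalogs$assignments))),
      cluster = c(report$clustering$inparalogs$assignments,
                  report$clustering$outparalogs$assignments))
    write_pair_table(asg, file.path(out_dir, "cluster_assignments.tsv"))
  }
  if (length(report$regressions %||% list())) {
    jsonlite::write_json(report$regressions,
                         file.path(out_dir, "regressions.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
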