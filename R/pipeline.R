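#' @title End-to-end pipeline driver
#' @description
#' Runs filter -> consensus/matrix -> spatial null -> cluster annotation ->
#' lineage trace -> gene assignment over a sample sheet, writing one
#' subdirectory of TSV/BED reports per stage. Completed stages (marked by
#' a `.done` file) are skipped on rerun unless forced; all randomness
#' derives from the single seed in the run configuration, so two runs with
#' the same seed produce byte-identical reports.
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' Defaults are the analysis constants used throughout: 50 bp minimum HMR
#' length, 6 kb linking distance, clusters of 3+, 10,000 shuffle
#' iterations, 500 kb distance cap, 10-150 kb proportion thresholds and
#' k = 10 methylation groups.
#'
#' @param min_len,link_distance,min_cluster_size,n_iter,cap,thresholds,k,seed
#'   see Description.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_len = 50, link_distance = 6000,
                       min_cluster_size = 3, n_iter = 10000, cap = 500000,
                       thresholds = c(10, 25, 50, 75, 100, 150) * 1000,
                       k = 10, seed = 1) {
  structure(list(min_len = min_len, link_distance = link_distance,
                 min_cluster_size = min_cluster_size, n_iter = n_iter,
                 cap = cap, thresholds = thresholds, k = k, seed = seed),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stage_done <- function(dir) file.exists(file.path(dir, ".done"))
.mark_done <- function(dir) writeLines("ok", file.path(dir, ".done"))

#' Run the full HMR analysis pipeline over a sample sheet
#'
#' @param sheet data frame with columns `cell_type` (unique), `parent`
#'   (parent cell type for lineage tracing, `NA` for roots/unrelated),
#'   `hmr_path` (BED of HMR calls) and optional `meth_path` (bedGraph)
#'   and `expr_path` (expression TSV).
#' @param genes_path gene table TSV (see [read_gene_table()]).
#' @param sizes_path chrom.sizes file.
#' @param tads_path optional TAD BED (enables gene assignment).
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @param force recompute stages whose outputs already exist.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(sheet, genes_path, sizes_path, tads_path = NULL,
                         config = run_config(), out_dir, force = FALSE) {
  need <- c("cell_type", "hmr_path")
  if (!all(need %in% names(sheet)))
    stop("run_pipeline: sheet must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$cell_type))
    stop("run_pipeline: duplicate cell_type in sheet")
  if (is.null(sheet$parent)) sheet$parent <- NA_character_
  paths <- c(sheet$hmr_path, genes_path, sizes_path, tads_path,
             stats::na.omit(sheet$meth_path), stats::na.omit(sheet$expr_path))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("run_pipeline: missing input file(s): ",
         paste(missing, collapse = ", "))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- read_gene_table(genes_path)
  sizes <- read_chrom_sizes(sizes_path)
  tads <- if (!is.null(tads_path)) read_bed(tads_path, label = "tads")
  blacklist <- build_blacklist(genes)
  whitelist <- whitelist_regions(blacklist, sizes)
  cts <- sheet$cell_type
  raw <- lapply(seq_along(cts), function(i)
    hmr_set(as.data.frame(read_bed(sheet$hmr_path[i], label = cts[i])),
            label = cts[i]))
  names(raw) <- cts

  # 1. non-coding filter ----------------------------------------------
  d1 <- file.path(out_dir, "filter")
  filtered <- list()
  if (.stage_done(d1) && !force) {
    message("[filter] outputs present; skipping recompute")
    for (ct in cts)
      filtered[[ct]] <- hmr_set(as.data.frame(
        read_bed(file.path(d1, paste0(ct, ".noncoding.bed")), label = ct)),
        label = ct)
  } else {
    dir.create(d1, showWarnings = FALSE)
    reports <- list()
    for (ct in cts) {
      fr <- filter_noncoding(raw[[ct]], blacklist, min_len = config$min_len)
      filtered[[ct]] <- fr$hmrs
      reports[[ct]] <- fr$report
      write_bed(fr$hmrs, file.path(d1, paste0(ct, ".noncoding.bed")))
      message(sprintf("[filter] %s: %d -> %d HMRs", ct, fr$report$input,
                      fr$report$retained))
    }
    .write_tsv(do.call(rbind, reports), file.path(d1, "filter_report.tsv"))
    .mark_done(d1)
  }

  # 2. consensus + methylation matrix ---------------------------------
  has_meth <- !is.null(sheet$meth_path) && any(!is.na(sheet$meth_path))
  if (has_meth) {
    d2 <- file.path(out_dir, "matrix")
    if (.stage_done(d2) && !force) message("[matrix] skipping")
    else {
      dir.create(d2, showWarnings = FALSE)
      cons <- consensus_union(filtered)
      with_meth <- cts[!is.na(sheet$meth_path)]
      tracks <- lapply(with_meth, function(ct)
        read_bedgraph(sheet$meth_path[sheet$cell_type == ct]))
      names(tracks) <- with_meth
      m <- build_matrix(cons, tracks)
      mat_df <- data.frame(region = rownames(m), as.data.frame(m),
                           check.names = FALSE)
      .write_tsv(mat_df, file.path(d2, "methylation_matrix.tsv"))
      kk <- min(config$k, sum(attr(m, "complete")))
      km <- kmeans_partition(m, k = kk, seed = config$seed)
      .write_tsv(data.frame(region = names(km$labels), group = km$labels),
                 file.path(d2, "kmeans_labels.tsv"))
      lg <- label_groups(km)
      .write_tsv(data.frame(group = names(lg),
                            hypomethylated_in = vapply(lg, paste,
                                                       collapse = ",", "")),
                 file.path(d2, "group_labels.tsv"))
      if (length(tracks) >= 2) {
        hc <- hierarchical_celltypes(m)
        .write_tsv(data.frame(merge_step = seq_len(nrow(hc$merge)),
                              a = hc$merge[, 1], b = hc$merge[, 2],
                              height = hc$height),
                   file.path(d2, "celltype_dendrogram.tsv"))
      }
      .mark_done(d2)
      message(sprintf("[matrix] %d consensus regions x %d cell types, k = %d",
                      nrow(m), ncol(m), kk))
    }
  }

  # 3. spatial null ----------------------------------------------------
  d3 <- file.path(out_dir, "spatial")
  if (.stage_done(d3) && !force) message("[spatial] skipping")
  else {
    dir.create(d3, showWarnings = FALSE)
    rows <- list()
    for (i in seq_along(cts)) {
      ct <- cts[i]
      obs <- nearest_distances(filtered[[ct]], quiet = TRUE)
      nul <- shuffle_null(filtered[[ct]], blacklist, sizes,
                          n_iter = config$n_iter,
                          seed = config$seed + i)
      writeLines(format(nul$means, scientific = FALSE, trim = TRUE),
                 file.path(d3, paste0(ct, ".null_means.tsv")))
      rep1 <- spatial_test(obs, nul, cap = config$cap,
                           method = "ranksum_means")
      rep2 <- spatial_test(obs, nul, cap = config$cap, method = "empirical")
      rows[[ct]] <- data.frame(cell_type = ct,
                               observed_median = rep1$observed_median,
                               expected_median = rep1$expected_median,
                               n_observed = rep1$n_observed,
                               p_ranksum_means = rep1$p_value,
                               p_empirical = rep2$p_value)
      message(sprintf("[spatial] %s: observed median %.0f bp, expected %.0f bp",
                      ct, rep1$observed_median, rep1$expected_median))
    }
    .write_tsv(do.call(rbind, rows), file.path(d3, "spatial_tests.tsv"))
    .mark_done(d3)
  }

  # 4. cluster annotation ----------------------------------------------
  d4 <- file.path(out_dir, "clusters")
  ccfg <- cluster_config(config$link_distance, config$min_cluster_size)
  classes <- list()
  if (.stage_done(d4) && !force) {
    message("[clusters] skipping recompute; reloading classifications")
    for (ct in cts)
      classes[[ct]] <- classify_hmrs(filtered[[ct]], raw[[ct]], blacklist,
                                     whitelist, ccfg)
  } else {
    dir.create(d4, showWarnings = FALSE)
    for (ct in cts) {
      sc <- classify_hmrs(filtered[[ct]], raw[[ct]], blacklist, whitelist, ccfg)
      classes[[ct]] <- sc
      .write_tsv(sc$classes, file.path(d4, paste0(ct, ".classes.tsv")))
      cl <- sc$clusters
      if (nrow(cl)) {
        cl$name <- sprintf("%s_cluster%03d", ct, cl$cluster_id)
        write_bed(interval_set(cl[, c("chrom", "start", "end", "name",
                                      "n_members")], dedup = FALSE),
                  file.path(d4, paste0(ct, ".clusters.bed")))
      } else writeLines(character(), file.path(d4, paste0(ct, ".clusters.bed")))
    }
    sm <- cluster_summary(classes)
    .write_tsv(sm$class_table, file.path(d4, "class_table.tsv"))
    .write_tsv(sm$clustered_fraction, file.path(d4, "clustered_fraction.tsv"))
    .mark_done(d4)
    message("[clusters] classified ", length(cts), " cell type(s)")
  }

  # 5. lineage trace ----------------------------------------------------
  if (any(!is.na(sheet$parent))) {
    d5 <- file.path(out_dir, "trace")
    if (.stage_done(d5) && !force) message("[trace] skipping")
    else {
      dir.create(d5, showWarnings = FALSE)
      parents <- stats::setNames(sheet$parent, sheet$cell_type)
      ord <- lineage_order(filtered, parents)
      .write_tsv(trace_lineage(ord), file.path(d5, "retention.tsv"))
      .mark_done(d5)
      message("[trace] retention report written")
    }
  }

  # 6. gene assignment ---------------------------------------------------
  has_expr <- !is.null(sheet$expr_path) && any(!is.na(sheet$expr_path)) &&
    !is.null(tads)
  if (has_expr) {
    d6 <- file.path(out_dir, "genes")
    if (.stage_done(d6) && !force) message("[genes] skipping")
    else {
      dir.create(d6, showWarnings = FALSE)
      for (ct in cts[!is.na(sheet$expr_path)]) {
        expr <- read_expression(sheet$expr_path[sheet$cell_type == ct])
        sc <- classes[[ct]]
        spans <- sc$clusters[sc$clusters$n_members >= config$min_cluster_size,
                             , drop = FALSE]
        uncl <- sc$classes[sc$classes$class == "unclustered", , drop = FALSE]
        if (!nrow(spans) || !nrow(uncl)) {
          message("[genes] ", ct, ": too few clustered/unclustered regions; skipped")
          next
        }
        ga <- interval_set(spans[, c("chrom", "start", "end")], dedup = FALSE)
        gb <- interval_set(uncl[, c("chrom", "start", "end")], dedup = FALSE)
        curve <- proportion_active_curve(ga, gb, genes, tads, expr,
                                         thresholds = config$thresholds)
        .write_tsv(as.data.frame(curve),
                   file.path(d6, paste0(ct, ".proportion_curve.tsv")))
        ec <- tryCatch(expression_comparison(ga, gb, genes, tads, expr),
                       error = function(e) NULL)
        if (!is.null(ec))
          .write_tsv(data.frame(group = c("clustered", "unclustered"),
                                n_genes = c(length(ec$tpm_a), length(ec$tpm_b)),
                                median_tpm = c(stats::median(ec$tpm_a),
                                               stats::median(ec$tpm_b)),
                                p_value = ec$rank_sum$p_value),
                     file.path(d6, paste0(ct, ".expression_comparison.tsv")))
      }
      .mark_done(d6)
      message("[genes] assignments written")
    }
  }
  invisible(out_dir)
}
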