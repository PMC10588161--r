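#' @title TAD-constrained, expression-filtered nearest-gene assignment
#' @description
#' Regions (HMRs or cluster spans) are paired with gene TSSs; distance is
#' measured from the nearest region edge to the TSS point (0 when the TSS
#' lies inside the region). Pairs whose spanning interval crosses every
#' TAD boundary are removed (the pair must sit fully inside a single TAD),
#' and only expressed genes (TPM > 0) are eligible, so the assignment
#' approximates the regulatory search space of an enhancer.
#' @name genes
NULL

# distance from a region to TSS points on the same chromosome
.tss_distance <- function(start, end, tss) {
  ifelse(tss < start, start - tss, ifelse(tss >= end, tss - end, 0))
}

#' k nearest TSSs to each region
#'
#' Ties are broken by (distance, gene id) for determinism.
#'
#' @param regions an `interval_set` (HMRs or cluster spans).
#' @param genes a `gene_table` with elected TSS points.
#' @param k number of genes to keep per region.
#' @return data frame of class `gene_pairs`: region_id (row index into the
#'   sorted regions), chrom, start, end, gene_id, tss, distance. Regions on
#'   chromosomes without genes get no rows (noted by message).
#' @export
k_nearest_tss <- function(regions, genes, k = 100) {
  s <- interval_set(as.data.frame(regions), dedup = FALSE)
  out <- vector("list", nrow(s))
  no_gene <- 0L
  for (i in seq_len(nrow(s))) {
    g <- genes[genes$chrom == s$chrom[i], , drop = FALSE]
    if (!nrow(g)) { no_gene <- no_gene + 1L; next }
    d <- .tss_distance(s$start[i], s$end[i], g$tss)
    o <- order(d, g$gene_id)[seq_len(min(k, nrow(g)))]
    out[[i]] <- data.frame(region_id = i, chrom = s$chrom[i],
                           start = s$start[i], end = s$end[i],
                           gene_id = g$gene_id[o], tss = g$tss[o],
                           distance = d[o], stringsAsFactors = FALSE)
  }
  if (no_gene) message(no_gene, " region(s) on chromosomes without genes")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(region_id = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      gene_id = character(), tss = numeric(),
                      distance = numeric(), stringsAsFactors = FALSE)
  structure(res, class = c("gene_pairs", "data.frame"))
}

#' Keep region-TSS pairs fully contained in a single TAD
#'
#' The pair's spanning interval `[min(start, tss), max(end, tss + 1))`
#' must lie inside at least one TAD; with nested or overlapping TADs,
#' containment in any single TAD suffices. The id (row index) of the
#' containing TAD is recorded.
#'
#' @param pairs a `gene_pairs` data frame.
#' @param tads an `interval_set` of TADs.
#' @return filtered `gene_pairs` with a `tad_id` column.
#' @export
tad_filter <- function(pairs, tads) {
  if (!nrow(pairs)) { pairs$tad_id <- integer(0); return(pairs) }
  span_s <- pmin(pairs$start, pairs$tss)
  span_e <- pmax(pairs$end, pairs$tss + 1)
  tid <- rep(NA_integer_, nrow(pairs))
  for (cn in intersect(unique(pairs$chrom), unique(tads$chrom))) {
    pi <- which(pairs$chrom == cn)
    ti <- which(tads$chrom == cn)
    tt <- tads[ti, , drop = FALSE]
    o <- order(tt$start)
    tt <- tt[o, , drop = FALSE]; ti <- ti[o]
    cm_end <- cummax(tt$end)
    j <- findInterval(span_s[pi], tt$start)  # TADs starting at or before span
    ok <- j > 0 & cm_end[pmax(j, 1)] >= span_e[pi]
    for (w in which(ok)) {                   # first containing TAD for the id
      jj <- j[w]
      hit <- which(tt$end[seq_len(jj)] >= span_e[pi][w])
      tid[pi[w]] <- ti[hit[1]]
    }
  }
  out <- pairs[!is.na(tid), , drop = FALSE]
  out$tad_id <- tid[!is.na(tid)]
  rownames(out) <- NULL
  out
}

#' Nearest expressed gene within a TAD, per region
#'
#' Among the `k` nearest TSSs surviving the TAD filter and the expression
#' filter (TPM > 0), the minimum-distance pair per region (tie-break by
#' gene id); regions with no surviving candidate get `NA`.
#'
#' @param regions an `interval_set`.
#' @param genes a `gene_table`.
#' @param tads TAD `interval_set`, or `NULL` to skip the TAD constraint.
#' @param expr data frame (gene_id, tpm).
#' @param k candidate pool size.
#' @param n_keep how many nearest surviving genes to keep per region.
#' @return data frame, one row per region (region_id, chrom, start, end,
#'   gene_id, distance, tad_id, tpm), with `NA` gene columns where no
#'   assignment exists; when `n_keep > 1`, up to `n_keep` rows per region
#'   and no `NA` placeholders.
#' @export
nearest_active_gene <- function(regions, genes, tads, expr, k = 100,
                                n_keep = 1) {
  pairs <- k_nearest_tss(regions, genes, k = k)
  pairs <- if (!is.null(tads)) tad_filter(pairs, tads)
           else { pairs$tad_id <- NA_integer_; pairs }
  pairs$tpm <- expr$tpm[match(pairs$gene_id, expr$gene_id)]
  pairs <- pairs[!is.na(pairs$tpm) & pairs$tpm > 0, , drop = FALSE]
  picked <- do.call(rbind, lapply(split(pairs, pairs$region_id), function(d) {
    d[order(d$distance, d$gene_id)[seq_len(min(n_keep, nrow(d)))], ,
      drop = FALSE]
  }))
  if (n_keep > 1) {
    rownames(picked) <- NULL
    return(picked)
  }
  s <- interval_set(as.data.frame(regions), dedup = FALSE)
  out <- data.frame(region_id = seq_len(nrow(s)), chrom = s$chrom,
                    start = s$start, end = s$end,
                    gene_id = NA_character_, distance = NA_real_,
                    tad_id = NA_integer_, tpm = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(picked) && nrow(picked)) {
    m <- match(picked$region_id, out$region_id)
    out$gene_id[m] <- picked$gene_id
    out$distance[m] <- picked$distance
    out$tad_id[m] <- picked$tad_id
    out$tpm[m] <- picked$tpm
  }
  out
}

#' Proportion of regions near an expressed gene, by distance threshold
#'
#' Per group and threshold, the fraction of regions whose nearest active
#' gene (TAD-constrained) lies at or below the threshold, with a
#' two-sample proportion test per threshold. Denominators are the total
#' region counts per group; regions with no assignment never count as
#' near.
#'
#' @param group_a,group_b `interval_set`s of regions (e.g. cluster spans
#'   vs unclustered HMRs).
#' @param genes,tads,expr as in [nearest_active_gene()].
#' @param thresholds distance thresholds in bp.
#' @param k candidate pool size.
#' @return data frame of class `proportion_curve`: threshold, count/denom/
#'   proportion per group, chi-square statistic and p-value.
#' @export
proportion_active_curve <- function(group_a, group_b, genes, tads, expr,
                                    thresholds = c(10, 25, 50, 75, 100, 150) * 1000,
                                    k = 100) {
  stopifnot(nrow(group_a) > 0, nrow(group_b) > 0)
  da <- nearest_active_gene(group_a, genes, tads, expr, k = k)$distance
  db <- nearest_active_gene(group_b, genes, tads, expr, k = k)$distance
  rows <- lapply(thresholds, function(th) {
    xa <- sum(!is.na(da) & da <= th)
    xb <- sum(!is.na(db) & db <= th)
    pt <- two_sample_proportion_test(xa, length(da), xb, length(db))
    data.frame(threshold = th,
               count_a = xa, denom_a = length(da), prop_a = xa / length(da),
               count_b = xb, denom_b = length(db), prop_b = xb / length(db),
               statistic = pt$statistic, p_value = pt$p_value)
  })
  structure(do.call(rbind, rows),
            class = c("proportion_curve", "data.frame"))
}

# up-to-two nearest TAD-valid expressed genes per region, deduplicated
# within the group
.group_gene_tpms <- function(regions, genes, tads, expr, k) {
  picked <- nearest_active_gene(regions, genes, tads, expr, k = max(k, 2),
                                n_keep = 2)
  if (is.null(picked) || !nrow(picked)) return(NULL)
  picked <- picked[!duplicated(picked$gene_id), , drop = FALSE]
  picked
}

#' Compare expression of genes assigned to two region groups
#'
#' Per region, up to two nearest TAD-valid expressed genes are assigned;
#' genes are deduplicated within each group; the two TPM lists are
#' compared by the Wilcoxon rank-sum test.
#'
#' @inheritParams proportion_active_curve
#' @param k candidate pool size for the two-nearest assignment.
#' @return list of class `expression_comparison`: `tpm_a`, `tpm_b`
#'   (named by gene), `rank_sum`.
#' @export
expression_comparison <- function(group_a, group_b, genes, tads, expr, k = 2) {
  ga <- .group_gene_tpms(group_a, genes, tads, expr, k)
  gb <- .group_gene_tpms(group_b, genes, tads, expr, k)
  if (is.null(ga) || is.null(gb))
    stop("expression_comparison: a group has no assigned genes")
  rs <- wilcoxon_rank_sum(ga$tpm, gb$tpm)
  structure(list(tpm_a = stats::setNames(ga$tpm, ga$gene_id),
                 tpm_b = stats::setNames(gb$tpm, gb$gene_id),
                 rank_sum = rs),
            class = "expression_comparison")
}

#' Distance-binned expression comparison
#'
#' Assigned region-gene pairs are binned by distance (half-open bins;
#' 10,000 bp falls in the 10-50 kb bin) and compared per bin; bins with
#' fewer than two genes in either group are flagged untested.
#'
#' @inheritParams expression_comparison
#' @param breaks bin edges in bp (last bin is unbounded above).
#' @return data frame: bin, n_a, n_b, p_value (`NA` when untested),
#'   tested.
#' @export
distance_binned_comparison <- function(group_a, group_b, genes, tads, expr,
                                       k = 2,
                                       breaks = c(0, 10, 50, 100) * 1000) {
  pa <- nearest_active_gene(group_a, genes, tads, expr, k = max(k, 2), n_keep = 2)
  pb <- nearest_active_gene(group_b, genes, tads, expr, k = max(k, 2), n_keep = 2)
  edges <- c(breaks, Inf)
  labs <- paste0("[", format(edges[-length(edges)], scientific = FALSE, trim = TRUE),
                 ",", format(edges[-1], scientific = FALSE, trim = TRUE), ")")
  bin_of <- function(d) findInterval(d, edges)
  rows <- lapply(seq_along(labs), function(b) {
    da <- pa[bin_of(pa$distance) == b, , drop = FALSE]
    db <- pb[bin_of(pb$distance) == b, , drop = FALSE]
    da <- da[!duplicated(da$gene_id), , drop = FALSE]
    db <- db[!duplicated(db$gene_id), , drop = FALSE]
    tested <- nrow(da) >= 2 && nrow(db) >= 2
    data.frame(bin = labs[b], n_a = nrow(da), n_b = nrow(db),
               p_value = if (tested) wilcoxon_rank_sum(da$tpm, db$tpm)$p_value
                         else NA_real_,
               tested = tested, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
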