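#' @title Non-coding HMR filtering
#' @description
#' The exclusion list combines strand-aware promoter windows (-2000/+1000 bp
#' around each TSS) with exons; HMRs touching it by even a single base pair,
#' or shorter than a minimum length, are removed so downstream analyses see
#' only non-coding HMRs harboring putative enhancers.
#' @name preprocess
NULL

#' Build the promoter/exon exclusion blacklist
#'
#' Promoter windows extend 2000 bp upstream and 1000 bp downstream of the
#' TSS, mirrored by strand ([tss-2000, tss+1000) for `+` genes,
#' [tss-1000, tss+2000) for `-` genes), clipped at position 0. Exons are
#' added verbatim and the union is merged.
#'
#' @param genes a `gene_table`; every gene must have strand `+` or `-`.
#' @param upstream,downstream promoter window extents in bp.
#' @return merged `interval_set` of class `blacklist`, with attributes
#'   `n_tss` and `n_exons`.
#' @export
build_blacklist <- function(genes, upstream = 2000, downstream = 1000) {
  if (!all(genes$strand %in% c("+", "-")))
    stop("build_blacklist: unknown strand for gene ",
         genes$gene_id[which(!genes$strand %in% c("+", "-"))[1]])
  plus <- genes$strand == "+"
  win_start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  win_end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  win_start <- pmax(0, win_start)
  prom <- data.frame(chrom = genes$chrom, start = win_start, end = win_end,
                     stringsAsFactors = FALSE)
  ex <- gene_exons(genes)
  all_df <- rbind(prom, as.data.frame(ex)[, c("chrom", "start", "end")])
  bl <- merge_intervals(interval_set(all_df, dedup = FALSE), 0)
  bl$n_members <- NULL
  structure(interval_set(as.data.frame(bl), label = "blacklist", dedup = FALSE),
            n_tss = nrow(genes), n_exons = nrow(ex),
            class = c("blacklist", "interval_set", "data.frame"))
}

#' Filter an HMR set down to non-coding HMRs
#'
#' Removal precedence is fixed: blacklist overlap (>= 1 bp) is checked
#' first, then minimum length, so the report categories are disjoint and
#' sum to the input count. Filtering is idempotent.
#'
#' @param hmrs an `hmr_set`.
#' @param blacklist a `blacklist` from [build_blacklist()].
#' @param min_len minimum retained HMR length in bp (>= 1).
#' @return list with `hmrs` (the retained `hmr_set`) and `report`, a one-row
#'   data frame of counts (input, removed_blacklist, removed_length,
#'   retained).
#' @export
filter_noncoding <- function(hmrs, blacklist, min_len = 50) {
  stopifnot(min_len >= 1)
  n_in <- nrow(hmrs)
  hit <- overlaps_any(hmrs, blacklist)
  short <- !hit & (hmrs$end - hmrs$start < min_len)
  keep <- !hit & !short
  out <- hmr_set(as.data.frame(hmrs)[keep, , drop = FALSE],
                 label = attr(hmrs, "label"), stage = attr(hmrs, "stage"))
  report <- data.frame(
    label = if (is.null(attr(hmrs, "label"))) NA_character_ else attr(hmrs, "label"),
    input = n_in,
    removed_blacklist = sum(hit),
    removed_length = sum(short),
    retained = sum(keep),
    stringsAsFactors = FALSE)
  list(hmrs = out, report = report)
}

#' Cross-cell-type consensus regions
#'
#' Concatenates HMR sets from all cell types and merges overlapping
#' features (gap 0). Each consensus region records which input sets
#' contributed at least 1 bp of overlap.
#'
#' @param sets named list of `hmr_set` objects (names = cell types).
#' @return `interval_set` with columns `n_members` and `contributors`
#'   (comma-separated cell-type names) plus a logical membership matrix in
#'   attribute `membership`.
#' @export
consensus_union <- function(sets) {
  stopifnot(length(sets) >= 1)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  cat_df <- do.call(rbind, lapply(sets, function(s)
    as.data.frame(s)[, c("chrom", "start", "end"), drop = FALSE]))
  cons <- merge_intervals(interval_set(cat_df, dedup = FALSE), 0)
  memb <- vapply(sets, function(s) overlaps_any(cons, s), logical(nrow(cons)))
  if (nrow(cons) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(sets)))
  cons$contributors <- apply(memb, 1, function(r)
    paste(names(sets)[r], collapse = ","))
  attr(cons, "membership") <- memb
  attr(cons, "label") <- "consensus"
  cons
}
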