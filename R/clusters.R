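#' @title Boundary-constrained HMR cluster linking and spatial classification
#' @description
#' Non-coding HMRs are chained into clusters when consecutive end-to-end
#' gaps are at most the linking distance (6 kb by default, inclusive) and
#' all members lie fully inside the same whitelist region (a maximal
#' segment of the genome free of promoter windows and exons), so clusters
#' never cross a TSS or exon. Each HMR then receives exactly one spatial
#' class: cluster member (size >= 3 by default), pair member (size 2),
#' unclustered (no HMR of any kind within the linking distance),
#' TSS/exon-proximal (only blacklist-overlapping HMRs nearby), or residual
#' (a non-coding HMR nearby but across a blacklist boundary).
#' @name clusters
NULL

#' Cluster configuration
#' @param link_distance maximum end-to-end gap for linking, bp (inclusive).
#' @param min_cluster_size members needed to call a cluster (pairs below).
#' @return list of class `cluster_config`.
#' @export
cluster_config <- function(link_distance = 6000, min_cluster_size = 3) {
  stopifnot(link_distance > 0, min_cluster_size >= 2)
  structure(list(link_distance = link_distance,
                 min_cluster_size = min_cluster_size),
            class = "cluster_config")
}

#' Whitelist regions: complement of the blacklist
#' @param blacklist promoter/exon exclusion `interval_set`.
#' @param sizes `chrom_sizes`.
#' @return `interval_set` of regions free of TSS windows and exons.
#' @export
whitelist_regions <- function(blacklist, sizes) {
  w <- complement_intervals(blacklist, sizes)
  attr(w, "label") <- "whitelist"
  w
}

# whitelist region index fully containing each interval (NA if none);
# whitelist regions are disjoint and sorted
.containing_region <- function(set, whitelist) {
  out <- rep(NA_integer_, nrow(set))
  for (cn in intersect(unique(set$chrom), unique(whitelist$chrom))) {
    qi <- which(set$chrom == cn)
    wi <- which(whitelist$chrom == cn)
    j <- findInterval(set$start[qi], whitelist$start[wi])
    ok <- j > 0
    ok[ok] <- whitelist$end[wi][j[ok]] >= set$end[qi][ok]
    out[qi][ok] <- wi[j[ok]]
  }
  out
}

#' Link HMRs into clusters within whitelist regions
#'
#' HMRs fully contained in the same whitelist region are chained whenever
#' the gap to the previous member is `<= link_distance`. Chains of two or
#' more members are returned; singletons are not clusters. An HMR
#' straddling a blacklist edge (possible only in unfiltered sets) belongs
#' to no whitelist region and is excluded from linking.
#'
#' @param hmrs a non-coding-filtered `hmr_set`.
#' @param whitelist from [whitelist_regions()].
#' @param config a `cluster_config`.
#' @return list: `clusters` (data frame chrom, start, end = span, cluster_id,
#'   n_members, whitelist_id) and `members` (data frame chrom, start, end,
#'   cluster_id with `NA` for unassigned HMRs), both aligned to the sorted
#'   HMR order.
#' @export
link_clusters <- function(hmrs, whitelist, config = cluster_config()) {
  s <- interval_set(as.data.frame(hmrs), label = attr(hmrs, "label"),
                    dedup = FALSE)
  reg <- .containing_region(s, whitelist)
  n <- nrow(s)
  members <- data.frame(chrom = s$chrom, start = s$start, end = s$end,
                        cluster_id = rep(NA_integer_, n),
                        stringsAsFactors = FALSE)
  if (!n) return(list(clusters = data.frame(chrom = character(),
                                            start = numeric(), end = numeric(),
                                            cluster_id = integer(),
                                            n_members = integer(),
                                            whitelist_id = integer()),
                      members = members))
  ord <- order(is.na(reg), reg, s$start)   # group by region, keep genomic order
  chain_new <- logical(n)
  prev_end <- -Inf
  grp <- rep(NA_integer_, n)
  g <- 0L
  for (i in ord) {
    if (is.na(reg[i])) next
    if (g == 0L || is.na(reg_prev) || reg[i] != reg_prev ||
        s$start[i] - prev_end > config$link_distance) {
      g <- g + 1L
      prev_end <- s$end[i]
    } else prev_end <- max(prev_end, s$end[i])
    grp[i] <- g
    reg_prev <- reg[i]
  }
  sizes <- table(grp)
  keep_g <- as.integer(names(sizes)[sizes >= 2])
  cl <- lapply(seq_along(keep_g), function(k) {
    idx <- which(grp == keep_g[k])
    data.frame(chrom = s$chrom[idx[1]], start = min(s$start[idx]),
               end = max(s$end[idx]), cluster_id = k,
               n_members = length(idx), whitelist_id = reg[idx[1]],
               stringsAsFactors = FALSE)
  })
  clusters <- if (length(cl)) do.call(rbind, cl)
              else data.frame(chrom = character(), start = numeric(),
                              end = numeric(), cluster_id = integer(),
                              n_members = integer(), whitelist_id = integer())
  for (k in seq_along(keep_g))
    members$cluster_id[grp == keep_g[k] & !is.na(grp)] <- k
  o <- order(clusters$chrom, clusters$start)
  clusters <- clusters[o, , drop = FALSE]
  rownames(clusters) <- NULL
  list(clusters = clusters, members = members)
}

# gap from each row of `query` to the nearest interval of `subject` other
# than the query itself (matched by identical coordinates). Requires the
# subject to be sorted and pairwise non-overlapping (an HMR set invariant),
# so the nearest non-self interval is the predecessor or successor in start
# order; any overlap with a non-self interval yields gap 0.
.gap_excluding_self <- function(query, subject) {
  out <- rep(NA_real_, nrow(query))
  for (cn in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == cn)
    d <- subject[subject$chrom == cn, , drop = FALSE]
    nd <- nrow(d)
    qs <- query$start[qi]; qe <- query$end[qi]
    j <- findInterval(qs, d$start)
    jj <- pmax(j, 1L)
    is_self <- j > 0 & d$start[jj] == qs & d$end[jj] == qe
    prev_idx <- ifelse(is_self, j - 1L, j)
    next_idx <- j + 1L
    gp <- ifelse(prev_idx >= 1,
                 pmax(0, qs - d$end[pmax(prev_idx, 1L)]), Inf)
    gn <- ifelse(next_idx <= nd,
                 pmax(0, d$start[pmin(next_idx, nd)] - qe), Inf)
    g <- pmin(gp, gn)
    out[qi] <- ifelse(is.finite(g), g, NA_real_)
  }
  out
}

#' Spatial classification of non-coding HMRs
#'
#' @param noncoding the filtered non-coding `hmr_set`.
#' @param all_hmrs the unfiltered call set for the same cell type
#'   (superset of `noncoding`; needed for the proximity test against
#'   promoter/exon-overlapping HMRs).
#' @param blacklist promoter/exon exclusion set.
#' @param whitelist from [whitelist_regions()].
#' @param config a `cluster_config`.
#' @return list of class `spatial_class`: `classes` (data frame chrom,
#'   start, end, class, cluster_id), `clusters` (as [link_clusters()]),
#'   `config`.
#' @export
classify_hmrs <- function(noncoding, all_hmrs, blacklist, whitelist,
                          config = cluster_config()) {
  nc <- interval_set(as.data.frame(noncoding), dedup = FALSE)
  al <- interval_set(as.data.frame(all_hmrs), dedup = FALSE)
  key_nc <- paste(nc$chrom, nc$start, nc$end)
  key_al <- paste(al$chrom, al$start, al$end)
  if (!all(key_nc %in% key_al))
    stop("classify_hmrs: noncoding set is not a subset of all_hmrs")
  lk <- link_clusters(nc, whitelist, config)
  cls <- rep(NA_character_, nrow(nc))
  in_cluster <- !is.na(lk$members$cluster_id)
  if (any(in_cluster)) {
    sz <- lk$clusters$n_members[match(lk$members$cluster_id[in_cluster],
                                      lk$clusters$cluster_id)]
    cls[in_cluster] <- ifelse(sz >= config$min_cluster_size,
                              "cluster_member", "pair_member")
  }
  rest <- which(!in_cluster)
  if (length(rest)) {
    gap_all <- .gap_excluding_self(nc[rest, , drop = FALSE], al)
    gap_nc <- .gap_excluding_self(nc[rest, , drop = FALSE], nc)
    far <- is.na(gap_all) | gap_all > config$link_distance
    cls[rest[far]] <- "unclustered"
    near <- rest[!far]
    gn <- gap_nc[!far]
    cls[near] <- ifelse(!is.na(gn) & gn <= config$link_distance,
                        "residual", "tss_exon_proximal")
  }
  structure(list(classes = data.frame(chrom = nc$chrom, start = nc$start,
                                      end = nc$end, class = cls,
                                      cluster_id = lk$members$cluster_id,
                                      stringsAsFactors = FALSE),
                 clusters = lk$clusters,
                 config = config,
                 label = attr(noncoding, "label")),
            class = "spatial_class")
}

#' @export
print.spatial_class <- function(x, ...) {
  cat("Spatial classification",
      if (!is.null(x$label) && !is.na(x$label)) paste0("(", x$label, ")"),
      "\n")
  print(table(class = x$classes$class))
  invisible(x)
}

#' Summaries of spatial classes across cell types
#'
#' @param class_list named list of `spatial_class` objects (one per cell
#'   type).
#' @return list: `class_table` (counts and fractions per class per cell
#'   type; fractions sum to 1), `clustered_fraction` (clustered /
#'   (clustered + unclustered), one row per cell type), `cluster_lengths`
#'   (span length statistics per cell type).
#' @export
cluster_summary <- function(class_list) {
  lv <- c("cluster_member", "pair_member", "unclustered",
          "tss_exon_proximal", "residual")
  rows <- lapply(names(class_list), function(ct) {
    cl <- class_list[[ct]]$classes$class
    cnt <- table(factor(cl, levels = lv))
    data.frame(cell_type = ct, class = lv, count = as.integer(cnt),
               fraction = as.numeric(cnt) / max(length(cl), 1),
               stringsAsFactors = FALSE)
  })
  frac <- lapply(names(class_list), function(ct) {
    cl <- class_list[[ct]]$classes$class
    ncl <- sum(cl == "cluster_member")
    nun <- sum(cl == "unclustered")
    data.frame(cell_type = ct, n_clustered = ncl, n_unclustered = nun,
               clustered_fraction = if (ncl + nun > 0) ncl / (ncl + nun) else 0,
               stringsAsFactors = FALSE)
  })
  lens <- lapply(names(class_list), function(ct) {
    sp <- class_list[[ct]]$clusters
    sp <- sp[sp$n_members >= class_list[[ct]]$config$min_cluster_size, ,
             drop = FALSE]
    data.frame(cell_type = ct, n_clusters = nrow(sp),
               mean_span = if (nrow(sp)) mean(sp$end - sp$start) else NA_real_,
               median_span = if (nrow(sp)) stats::median(sp$end - sp$start) else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(class_table = do.call(rbind, rows),
       clustered_fraction = do.call(rbind, frac),
       cluster_lengths = do.call(rbind, lens))
}
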