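#' @title Consensus-HMR methylation matrix and unsupervised grouping
#' @description
#' Rows are consensus HMR regions, columns are cell types, values are the
#' mean per-CpG methylation fraction within the region (unweighted by
#' coverage by default). Groups of HMRs are found by seeded k-means with a
#' k-means++ best-of-restarts initialization; cell-type relationships by
#' Ward (D2) hierarchical clustering on Euclidean distances.
#' @name meth_matrix
NULL

#' Mean methylation of regions over a CpG track
#'
#' Unweighted mean of per-CpG fractions at positions `p` with
#' `start <= p < end`; `NA` where a region contains no CpG. With
#' `weight_coverage = TRUE` and a `coverage` column present, a
#' coverage-weighted mean is returned instead.
#'
#' @param regions an `interval_set`.
#' @param track a `meth_track`.
#' @param weight_coverage weight CpGs by read coverage (off by default).
#' @return numeric vector, one value (or `NA`) per region row.
#' @export
mean_methylation <- function(regions, track, weight_coverage = FALSE) {
  n <- nrow(regions)
  out <- rep(NA_real_, n)
  if (!n || !nrow(track)) return(out)
  w <- if (weight_coverage && !is.null(track$coverage)) track$coverage
       else rep(1, nrow(track))
  for (cn in intersect(unique(regions$chrom), unique(track$chrom))) {
    ti <- track$chrom == cn
    pos <- track$pos[ti]
    cw <- cumsum(w[ti])
    cwf <- cumsum(w[ti] * track$frac[ti])
    qi <- which(regions$chrom == cn)
    lo <- findInterval(regions$start[qi] - 0.5, pos)
    hi <- findInterval(regions$end[qi] - 0.5, pos)
    ww <- ifelse(lo > 0, cw[pmax(lo, 1)], 0)
    wf <- ifelse(lo > 0, cwf[pmax(lo, 1)], 0)
    tot_w <- ifelse(hi > 0, cw[pmax(hi, 1)], 0) - ww
    tot_f <- ifelse(hi > 0, cwf[pmax(hi, 1)], 0) - wf
    out[qi] <- ifelse(tot_w > 0, tot_f / tot_w, NA_real_)
  }
  out
}

#' Build the consensus-region x cell-type methylation matrix
#'
#' @param consensus an `interval_set` of consensus regions (non-empty).
#' @param tracks named list of `meth_track` objects, one per cell type.
#' @param weight_coverage passed to [mean_methylation()].
#' @return numeric matrix (rows = "chrom:start-end" region ids in consensus
#'   order, columns = cell types) with `NA` for regions lacking CpGs in a
#'   track; attribute `complete` flags rows with no missing cell.
#' @export
build_matrix <- function(consensus, tracks, weight_coverage = FALSE) {
  if (!length(tracks) || is.null(names(tracks)))
    stop("build_matrix: tracks must be a named list")
  if (!nrow(consensus)) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(tracks),
                dimnames = list(NULL, names(tracks)))
    attr(m, "complete") <- logical(0)
    return(m)
  }
  vals <- vapply(tracks, function(tr) {
    if (is.null(tr)) stop("build_matrix: missing track for a declared cell type")
    mean_methylation(consensus, tr, weight_coverage = weight_coverage)
  }, numeric(nrow(consensus)))
  if (nrow(consensus) == 1)
    vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(tracks)))
  rownames(vals) <- sprintf("%s:%s-%s", consensus$chrom,
                            format(consensus$start, scientific = FALSE, trim = TRUE),
                            format(consensus$end, scientific = FALSE, trim = TRUE))
  attr(vals, "complete") <- rowSums(is.na(vals)) == 0
  vals
}

# k-means++ initial centers (Arthur & Vassilvitskii seeding)
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) i <- sample.int(n, 1)
      else i <- sample.int(n, 1, prob = d2)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

#' Seeded k-means partition of the methylation matrix
#'
#' Lloyd iterations from k-means++ starts; `nstart` restarts are run under
#' `set.seed(seed)` and the solution with the lowest total within-group sum
#' of squares is kept. Determinism is guaranteed per seed within this
#' package (not bit-identical to any particular external run).
#'
#' @param matrix numeric matrix from [build_matrix()].
#' @param k number of groups (`1 <= k <=` retained rows).
#' @param seed integer RNG seed.
#' @param drop_missing drop rows with any `NA` before clustering (the rows
#'   kept are reported in the result).
#' @param nstart number of k-means++ restarts.
#' @return list of class `hmr_kmeans`: `k`, `labels` (named by row),
#'   `centers`, `wss` (total within-group SS), `seed`, `rows_used`.
#' @export
kmeans_partition <- function(matrix, k, seed = 86, drop_missing = TRUE,
                             nstart = 10) {
  x <- matrix
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  if (drop_missing) {
    keep <- rowSums(is.na(x)) == 0
    if (any(!keep)) message(sum(!keep), " row(s) with missing cells dropped")
    x <- x[keep, , drop = FALSE]
  } else if (anyNA(x)) stop("kmeans_partition: matrix has missing values")
  if (k < 1) stop("kmeans_partition: k must be >= 1")
  if (k > nrow(x)) stop("kmeans_partition: k exceeds number of rows")
  # canonical row order so the seeded stream (and thus the solution) does
  # not depend on how the caller happened to order the matrix
  ord <- do.call(order, c(as.list(as.data.frame(x)), list(rownames(x))))
  xs <- x[ord, , drop = FALSE]
  ux <- unique(xs)
  if (nrow(ux) <= k) {
    # fewer distinct rows than groups: each distinct row is its own group
    lab_s <- match(apply(xs, 1, paste, collapse = "\r"),
                   apply(ux, 1, paste, collapse = "\r"))
    centers <- ux
    if (nrow(ux) < k)   # pad unused groups; Inf centers label no cell type
      centers <- rbind(ux, matrix(Inf, k - nrow(ux), ncol(ux)))
    rownames(centers) <- NULL
    labels <- stats::setNames(lab_s, rownames(xs))[rownames(x)]
    return(structure(list(k = k, labels = labels, centers = centers,
                          wss = 0, seed = seed, rows_used = rownames(x)),
                     class = "hmr_kmeans"))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- .kmeanspp_init(xs, k)
    fit <- suppressWarnings(
      stats::kmeans(xs, centers = init, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(k = k,
                 labels = stats::setNames(best$cluster, rownames(xs))[rownames(x)],
                 centers = best$centers,
                 wss = best$tot.withinss,
                 seed = seed,
                 rows_used = rownames(x)),
            class = "hmr_kmeans")
}

#' @export
print.hmr_kmeans <- function(x, ...) {
  cat(sprintf("k-means partition: k = %d, %d rows, total WSS = %.4g (seed %d)\n",
              x$k, length(x$labels), x$wss, x$seed))
  print(table(group = x$labels))
  invisible(x)
}

#' Elbow curve of within-group sum of squares over a k range
#'
#' @inheritParams kmeans_partition
#' @param k_range integer vector of k values (default 1..12).
#' @return named numeric vector, WSS per k.
#' @export
elbow_curve <- function(matrix, k_range = 1:12, seed = 86, nstart = 10) {
  vapply(stats::setNames(k_range, k_range), function(k)
    kmeans_partition(matrix, k, seed = seed, nstart = nstart)$wss, 0)
}

#' Label k-means groups by their hypomethylated cell types
#'
#' A cell type belongs to a group's label when the group-center methylation
#' is at or below the threshold (<= 50% by default; the boundary is
#' inclusive).
#'
#' @param result an `hmr_kmeans` object.
#' @param threshold methylation fraction cutoff.
#' @return list, one character vector of cell types per group; empty groups
#'   carry attribute `"note" = "no hypomethylated cell type"`.
#' @export
label_groups <- function(result, threshold = 0.5) {
  out <- lapply(seq_len(result$k), function(g) {
    ct <- colnames(result$centers)[result$centers[g, ] <= threshold]
    if (!length(ct)) attr(ct, "note") <- "no hypomethylated cell type"
    ct
  })
  names(out) <- paste0("group", seq_len(result$k))
  out
}

#' Ward (D2) dendrogram of cell types
#'
#' Agglomerative clustering of the matrix columns by Euclidean distance
#' over rows without missing values, using the Ward.D2 criterion.
#'
#' @param matrix numeric matrix from [build_matrix()] (>= 2 columns).
#' @return an `hclust` object.
#' @export
hierarchical_celltypes <- function(matrix) {
  if (ncol(matrix) < 2) stop("hierarchical_celltypes: need >= 2 columns")
  x <- matrix[rowSums(is.na(matrix)) == 0, , drop = FALSE]
  stats::hclust(stats::dist(t(x), method = "euclidean"), method = "ward.D2")
}
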