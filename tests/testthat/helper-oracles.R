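# Independent oracles used across the suite. All operate per base pair or
# by exhaustive enumeration on small instances, deliberately sharing no
# code with the package internals they check.

# occupancy-vector (per-basepair) representation of an interval set on a
# single chromosome of length L
bp_occupancy <- function(starts, ends, L) {
  occ <- logical(L)
  for (i in seq_along(starts))
    if (ends[i] > starts[i]) occ[(starts[i] + 1):ends[i]] <- TRUE
  occ
}

# intervals of a logical occupancy vector (0-based half-open)
bp_intervals <- function(occ) {
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# merge with max_gap via occupancy: pad each interval by max_gap on the
# right, take covered runs, then trim back
oracle_merge <- function(starts, ends, L, max_gap = 0) {
  if (!length(starts)) return(data.frame(start = numeric(), end = numeric()))
  occ <- bp_occupancy(starts, ends + max_gap, L + max_gap)
  iv <- bp_intervals(occ)
  # trim the padding: each merged run's true end is the max input end within it
  iv$end <- vapply(seq_len(nrow(iv)), function(i)
    max(ends[starts >= iv$start[i] & starts < iv$end[i]]), 0)
  iv$n <- vapply(seq_len(nrow(iv)), function(i)
    sum(starts >= iv$start[i] & starts < iv$end[i]), 0L)
  iv
}

oracle_complement <- function(starts, ends, L) {
  bp_intervals(!bp_occupancy(starts, ends, L))
}

oracle_overlaps_any <- function(qs, qe, ss, se, L) {
  occ <- bp_occupancy(ss, se, L)
  vapply(seq_along(qs), function(i) any(occ[(qs[i] + 1):qe[i]]), TRUE)
}

# random interval set on one chromosome
random_intervals <- function(n, L, max_len = NULL) {
  if (is.null(max_len)) max_len <- max(2, L %/% 5)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(L - l + 1, 1) - 1L, 0L)
  df <- data.frame(chrom = "chrS", start = start, end = start + len)
  df[!duplicated(df), , drop = FALSE]
}

# transitive-closure clustering oracle: undirected relation
# {gap <= d AND both fully inside the same whitelist region}; connected
# components of size >= 2 are clusters
oracle_clusters <- function(hmrs, whitelist, d) {
  n <- nrow(hmrs)
  region_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    w <- which(whitelist$chrom == hmrs$chrom[i] &
                 whitelist$start <= hmrs$start[i] &
                 whitelist$end >= hmrs$end[i])
    if (length(w)) region_of[i] <- w[1]
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || is.na(region_of[i]) || is.na(region_of[j])) next
    if (region_of[i] != region_of[j]) next
    if (hmrs$chrom[i] != hmrs$chrom[j]) next
    gap <- max(0, max(hmrs$start[i], hmrs$start[j]) -
                 min(hmrs$end[i], hmrs$end[j]))
    if (gap <= d) adj[i, j] <- TRUE
  }
  comp <- seq_len(n)   # union-find by repeated relabeling
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp[is.na(region_of)] <- NA_integer_
  comp
}

# exact two-sided rank-sum p by enumeration of all group labelings
oracle_ranksum_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_along(x)])
  combs <- utils::combn(n, length(x))
  ws <- apply(combs, 2, function(idx) sum(ranks[idx]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# closed-form pooled-z chi-square for two proportions (no correction)
oracle_prop_chisq <- function(x1, n1, x2, n2) {
  p_pool <- (x1 + x2) / (n1 + n2)
  z <- (x1 / n1 - x2 / n2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z^2
}

# greedy Ward.D2 agglomeration computed from first principles: at each
# step merge the pair of clusters minimizing the D2 merge cost
# sqrt(2 * (ESS(A u B) - ESS(A) - ESS(B))); returns merge heights sorted
oracle_ward_heights <- function(x) {
  ess <- function(rows) {
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- sqrt(2 * (ess(c(clusters[[i]], clusters[[j]])) -
                       ess(clusters[[i]]) - ess(clusters[[j]])))
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# minimal within-group sum of squares over all 2-partitions (<= 12 rows)
oracle_best_wss_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  wss_of <- function(rows) {
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  for (mask in 1:(2^(n - 1) - 1)) {
    g1 <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    g2 <- setdiff(seq_len(n), g1)
    best <- min(best, wss_of(g1) + wss_of(g2))
  }
  best
}

# tiny deterministic genome fixtures -----------------------------------
toy_genes <- function() {
  gene_table(c("gA", "gB"), c("chr1", "chr1"), c("+", "-"),
             c(10000, 40000), c(20000, 48000),
             exon_starts = list(c(10000, 15000), c(40000, 47000)),
             exon_ends = list(c(10200, 15200), c(40200, 47200)))
}

toy_sizes <- function() chrom_sizes("chr1", 100000)
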