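#' @title Genomic interval containers and arithmetic
#' @description
#' All coordinates in this package are 0-based, half-open (BED convention):
#' an interval covers positions `start, start+1, ..., end-1`. Interval sets
#' are plain data frames with columns `chrom`, `start`, `end` and optional
#' `name`/`strand`, carrying class `interval_set`; HMR sets additionally
#' carry class `hmr_set` and must be pairwise non-overlapping.
#' @name intervals
NULL

.iv_strands <- c("+", "-", "*")

#' Construct an interval set
#'
#' @param chrom character vector of chromosome names, or a data frame with at
#'   least columns `chrom`, `start`, `end` (then other arguments are ignored).
#' @param start,end 0-based half-open coordinates; `0 <= start < end` required.
#' @param name optional labels (recycled).
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"` (unknown).
#' @param label dataset label (cell type or annotation name).
#' @param dedup drop exact duplicate intervals (with a message); duplicates in
#'   MethBase-style tracks would distort region counts.
#'
#' @return A data frame of class `interval_set`, sorted by (chrom, start, end),
#'   with attribute `label`.
#' @export
interval_set <- function(chrom, start = NULL, end = NULL, name = NULL,
                         strand = NULL, label = NA_character_, dedup = TRUE) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  } else {
    df <- data.frame(chrom = as.character(chrom),
                     start = as.numeric(start),
                     end = as.numeric(end),
                     stringsAsFactors = FALSE)
    if (!is.null(name)) df$name <- as.character(name)
    if (!is.null(strand)) df$strand <- as.character(strand)
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (nrow(df)) {
    if (any(is.na(df$chrom) | !nzchar(df$chrom)))
      stop("interval_set: empty chromosome name")
    bad <- which(!(df$start >= 0 & df$start < df$end))
    if (length(bad))
      stop(sprintf("interval_set: invalid coordinates at row %d (start=%s end=%s)",
                   bad[1], df$start[bad[1]], df$end[bad[1]]))
    if (!is.null(df$strand)) {
      df$strand[is.na(df$strand)] <- "*"
      if (!all(df$strand %in% .iv_strands))
        stop("interval_set: strand must be one of '+', '-', '*'")
    }
  }
  o <- order(df$chrom, df$start, df$end)
  if (is.unsorted(o)) df <- df[o, , drop = FALSE]
  if (dedup && nrow(df) > 1) {
    dup <- duplicated(df[, c("chrom", "start", "end")])
    if (any(dup)) {
      message(sum(dup), " duplicate interval(s) removed")
      df <- df[!dup, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(df, label = label, class = c("interval_set", "data.frame"))
}

#' Construct an HMR set (non-overlapping interval set with a stage tag)
#'
#' @inheritParams interval_set
#' @param stage optional developmental-stage tag.
#' @param min_len if not `NULL`, assert every interval length `>= min_len`.
#' @return An `hmr_set` (subclass of `interval_set`) with attribute `stage`.
#' @export
hmr_set <- function(chrom, start = NULL, end = NULL, name = NULL,
                    label = NA_character_, stage = NA_character_,
                    min_len = NULL) {
  s <- interval_set(chrom, start, end, name = name, label = label)
  if (nrow(s) > 1) {
    same <- s$chrom[-1] == s$chrom[-nrow(s)]
    ov <- same & s$start[-1] < cummax_by_chrom(s$chrom, s$end)[-nrow(s)]
    if (any(ov))
      stop("hmr_set: intervals overlap within one set (first at sorted row ",
           which(ov)[1] + 1L, ")")
  }
  if (!is.null(min_len) && nrow(s) && any(s$end - s$start < min_len))
    stop("hmr_set: interval shorter than min_len present")
  structure(s, stage = stage, class = c("hmr_set", class(s)))
}

#' @export
print.interval_set <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("<%s> %s: %d interval(s) on %d chromosome(s)\n",
              class(x)[1], if (is.na(lbl)) "(unlabeled)" else lbl,
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# running max of `val` reset at chromosome changes (input sorted by chrom)
cummax_by_chrom <- function(chrom, val) {
  if (!length(val)) return(val)
  r <- rle(chrom)
  idx <- rep(seq_along(r$lengths), r$lengths)
  unlist(lapply(split(val, idx), cummax), use.names = FALSE)
}

#' Gap distance between two intervals
#'
#' Non-negative distance in bp between interval edges; 0 if the intervals
#' overlap or are bookended (this diverges from `bedtools closest -d`, which
#' reports 1 for bookended features; immaterial at kb-scale thresholds).
#' Vectorized over rows.
#'
#' @param a,b data frames (or one-row lists) with `chrom`, `start`, `end`.
#' @return numeric vector of distances; `NA` where chromosomes differ.
#' @export
gap_distance <- function(a, b) {
  d <- pmax(0, pmax(a$start, b$start) - pmin(a$end, b$end))
  d[a$chrom != b$chrom] <- NA_real_
  d
}

#' Do two intervals overlap (>= 1 bp)?
#'
#' @inheritParams gap_distance
#' @return logical vector.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end)
}

#' Merge intervals within a maximum gap
#'
#' Combines intervals whose gap is `<= max_gap` (so overlapping or bookended
#' intervals always merge), reporting how many input intervals each merged
#' region absorbed, like `bedtools merge -d -c`.
#'
#' @param set an `interval_set` (or coercible data frame).
#' @param max_gap non-negative merge distance in bp.
#' @return `interval_set` with a column `n_members`.
#' @export
merge_intervals <- function(set, max_gap = 0) {
  stopifnot(max_gap >= 0)
  if (!nrow(set))
    return(interval_set(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), n_members = integer()),
                        label = attr(set, "label")))
  s <- interval_set(as.data.frame(set), label = attr(set, "label"), dedup = FALSE)
  cm <- cummax_by_chrom(s$chrom, s$end)
  new_grp <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                 s$start[-1] > cm[-nrow(s)] + max_gap)
  g <- cumsum(new_grp)
  out <- data.frame(
    chrom = s$chrom[new_grp],
    start = s$start[new_grp],
    end = as.numeric(tapply(s$end, g, max)),
    n_members = as.integer(tabulate(g)),
    stringsAsFactors = FALSE)
  interval_set(out, label = attr(set, "label"), dedup = FALSE)
}

#' Chromosome sizes
#'
#' @param chrom chromosome names (or a named numeric vector of lengths).
#' @param length chromosome lengths in bp (> 0).
#' @return named numeric vector of class `chrom_sizes`.
#' @export
chrom_sizes <- function(chrom, length = NULL) {
  if (is.null(length)) {
    stopifnot(!is.null(names(chrom)))
    sz <- as.numeric(chrom)
    names(sz) <- names(chrom)
  } else {
    sz <- as.numeric(length)
    names(sz) <- as.character(chrom)
  }
  if (any(sz <= 0)) stop("chrom_sizes: lengths must be > 0")
  if (anyDuplicated(names(sz))) stop("chrom_sizes: duplicated chromosome")
  structure(sz, class = "chrom_sizes")
}

#' Complement of an interval set over the genome
#'
#' Returns the regions not covered by `set`, per chromosome, like
#' `bedtools complement`.
#'
#' @param set an `interval_set`.
#' @param sizes a `chrom_sizes` vector covering every chromosome in `set`.
#' @return `interval_set` of uncovered regions.
#' @export
complement_intervals <- function(set, sizes) {
  if (nrow(set)) {
    miss <- setdiff(unique(set$chrom), names(sizes))
    if (length(miss)) stop("complement_intervals: chromosome not in sizes: ", miss[1])
    over <- set$end > sizes[set$chrom]
    if (any(over)) stop("complement_intervals: interval exceeds chromosome length on ",
                        set$chrom[which(over)[1]])
  }
  m <- merge_intervals(set, 0)
  res <- lapply(names(sizes), function(cn) {
    d <- m[m$chrom == cn, , drop = FALSE]
    bounds_s <- c(0, d$end)
    bounds_e <- c(d$start, sizes[[cn]])
    keep <- bounds_e > bounds_s
    data.frame(chrom = rep(cn, sum(keep)), start = bounds_s[keep],
               end = bounds_e[keep], stringsAsFactors = FALSE)
  })
  interval_set(do.call(rbind, res), label = attr(set, "label"), dedup = FALSE)
}

#' Which query intervals overlap (>= 1 bp) any subject interval?
#'
#' @param query,subject interval sets.
#' @return logical vector, one per query row.
#' @export
overlaps_any <- function(query, subject) {
  nq <- nrow(query)
  if (!nq) return(logical(0))
  out <- logical(nq)
  if (!nrow(subject)) return(out)
  m <- merge_intervals(subject, 0)
  for (cn in intersect(unique(query$chrom), unique(m$chrom))) {
    qi <- which(query$chrom == cn)
    d <- m[m$chrom == cn, , drop = FALSE]
    # merged subject is disjoint + sorted: only candidate is the last
    # subject start strictly below the query end
    j <- findInterval(query$end[qi] - 0.5, d$start)
    hit <- j > 0
    hit[hit] <- d$end[j[hit]] > query$start[qi][hit]
    out[qi] <- hit
  }
  out
}

#' Gap from each query interval to the nearest covered base of a subject set
#'
#' 0 where the query overlaps the subject; `NA` where the subject has no
#' interval on the query's chromosome.
#'
#' @inheritParams overlaps_any
#' @return numeric vector of gaps.
#' @export
gap_to_nearest <- function(query, subject) {
  nq <- nrow(query)
  out <- rep(NA_real_, nq)
  if (!nq || !nrow(subject)) return(out)
  m <- merge_intervals(subject, 0)
  for (cn in intersect(unique(query$chrom), unique(m$chrom))) {
    qi <- which(query$chrom == cn)
    d <- m[m$chrom == cn, , drop = FALSE]
    j <- findInterval(query$start[qi], d$start)         # last start <= q$start
    left <- ifelse(j > 0, pmax(0, query$start[qi] - d$end[pmax(j, 1)]), Inf)
    ov <- j > 0 & d$end[pmax(j, 1)] > query$start[qi]
    jn <- pmin(j + 1L, nrow(d))
    right <- ifelse(j < nrow(d), pmax(0, d$start[jn] - query$end[qi]), Inf)
    g <- pmin(left, right)
    g[ov] <- 0
    out[qi] <- g
  }
  out
}

#' Distance from each interval to its nearest neighbor within the same set
#'
#' For possibly overlapping intervals sorted by start, the nearest other
#' interval is found through the running maximum of preceding ends (left
#' side) and the next start (right side). `NA` for intervals alone on their
#' chromosome.
#'
#' @param set an `interval_set`.
#' @return numeric vector aligned with the sorted rows of `set`.
#' @export
neighbor_gaps <- function(set) {
  n <- nrow(set)
  if (!n) return(numeric(0))
  s <- interval_set(as.data.frame(set), dedup = FALSE)
  out <- rep(NA_real_, n)
  r <- rle(s$chrom)
  stops <- cumsum(r$lengths)
  starts_i <- c(1L, utils::head(stops, -1) + 1L)
  for (k in seq_along(r$values)) {
    i <- starts_i[k]:stops[k]
    if (length(i) < 2) next
    st <- s$start[i]; en <- s$end[i]
    cm <- cummax(en)
    left <- c(Inf, pmax(0, st[-1] - cm[-length(i)]))
    right <- c(pmax(0, st[-1] - en[-length(i)]), Inf)
    out[i] <- pmin(left, right)
  }
  out
}
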