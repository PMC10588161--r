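#' @title Overlap statistics against external annotation sets
#' @description
#' Overlap is always counted in units of HMRs (or consensus regions),
#' never base pairs: an HMR touching three annotation intervals counts
#' once. Multi-set (Euler) counts follow the merge-then-map recipe: the
#' inputs are concatenated and merged into consensus units, and each unit
#' is flagged per input by >= 1 bp overlap.
#' @name annotation_overlap
NULL

#' Fraction of HMRs containing at least one annotation interval
#'
#' @param hmrs an `hmr_set`.
#' @param annotation an `interval_set`.
#' @return list: `count`, `denominator`, `fraction`.
#' @export
fraction_containing <- function(hmrs, annotation) {
  hit <- overlaps_any(hmrs, annotation)
  list(count = sum(hit), denominator = nrow(hmrs),
       fraction = if (nrow(hmrs)) sum(hit) / nrow(hmrs) else 0)
}

#' Per-state overlap fractions with proportion tests between two groups
#'
#' For each chromatin state of interest, the fraction of each group's
#' HMRs overlapping that state's intervals, with a two-sample proportion
#' test between the two groups (or each group against a named baseline
#' when more than two are given).
#'
#' @param groups named list of `hmr_set` objects (>= 2).
#' @param annotation an `interval_set` with a `name` column holding state
#'   labels (e.g. ChromHMM states).
#' @param states character vector of states to evaluate (default: all in
#'   the annotation).
#' @param baseline group name to test the others against (default: first).
#' @return data frame of class `overlap_table`: state, group, count,
#'   denominator, fraction, statistic, p_value (test columns `NA` for the
#'   baseline rows; degenerate tests flagged by `NA` p).
#' @export
state_overlap_table <- function(groups, annotation, states = NULL,
                                baseline = names(groups)[1]) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  if (is.null(annotation$name)) stop("state_overlap_table: annotation needs names")
  if (is.null(states)) states <- unique(annotation$name)
  .chrom_vocab_check(groups, annotation)
  rows <- list()
  for (st in states) {
    ann <- annotation[annotation$name == st, , drop = FALSE]
    if (!nrow(ann))
      warning("state absent from annotation: ", st)
    fr <- lapply(groups, function(g) fraction_containing(g, ann))
    base <- fr[[baseline]]
    for (gn in names(groups)) {
      f <- fr[[gn]]
      if (gn == baseline || f$denominator == 0 || base$denominator == 0) {
        stat <- NA_real_; p <- NA_real_
      } else {
        pt <- tryCatch(two_sample_proportion_test(f$count, f$denominator,
                                                  base$count, base$denominator),
                       error = function(e) NULL)
        stat <- if (is.null(pt)) NA_real_ else pt$statistic
        p <- if (is.null(pt)) NA_real_ else pt$p_value
      }
      rows[[length(rows) + 1]] <- data.frame(
        state = st, group = gn, count = f$count,
        denominator = f$denominator, fraction = f$fraction,
        statistic = stat, p_value = p, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), baseline = baseline,
            class = c("overlap_table", "data.frame"))
}

.chrom_vocab_check <- function(groups, annotation) {
  gch <- unique(unlist(lapply(groups, function(g) unique(g$chrom))))
  if (!length(intersect(gch, unique(annotation$chrom))))
    warning("no shared chromosome names between HMR groups and annotation; ",
            "check assembly/naming compatibility")
}

#' Euler counts over consensus units
#'
#' Inputs are concatenated and merged (gap 0) into consensus units; each
#' unit is flagged per input by >= 1 bp overlap and counts are tallied per
#' membership combination. Because consensus units can absorb several
#' native regions, per-input native-unit overlap counts are also reported.
#'
#' @param inputs named list of `interval_set` objects (>= 2).
#' @return list of class `euler_counts`: `consensus` (merged regions with
#'   membership flags), `combination_counts` (named integer vector, names
#'   like "A+B"), `native_counts` (per input, regions overlapping the
#'   union of the others).
#' @export
euler_counts <- function(inputs) {
  stopifnot(length(inputs) >= 2, !is.null(names(inputs)))
  cat_df <- do.call(rbind, lapply(inputs, function(s)
    as.data.frame(s)[, c("chrom", "start", "end"), drop = FALSE]))
  cons <- merge_intervals(interval_set(cat_df, dedup = FALSE), 0)
  memb <- vapply(inputs, function(s) overlaps_any(cons, s),
                 logical(nrow(cons)))
  if (nrow(cons) == 1)
    memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(inputs)))
  combo <- apply(memb, 1, function(r) paste(names(inputs)[r], collapse = "+"))
  counts <- table(combo)
  native <- vapply(names(inputs), function(nm) {
    others_df <- do.call(rbind, lapply(inputs[setdiff(names(inputs), nm)],
      function(s) as.data.frame(s)[, c("chrom", "start", "end"), drop = FALSE]))
    sum(overlaps_any(inputs[[nm]], interval_set(others_df, dedup = FALSE)))
  }, 0L)
  structure(list(consensus = cbind(as.data.frame(cons)[
                   , c("chrom", "start", "end")], memb),
                 combination_counts = stats::setNames(as.integer(counts),
                                                      names(counts)),
                 native_counts = native,
                 n_units = nrow(cons)),
            class = "euler_counts")
}

#' @export
print.euler_counts <- function(x, ...) {
  cat("Euler counts over", x$n_units, "consensus unit(s):\n")
  print(x$combination_counts)
  invisible(x)
}
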