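#' @title Developmental lineage tracing of HMR establishment and retention
#' @description
#' Cell types are arranged on a lineage tree (a pseudo-time course, e.g.
#' embryonic stem cell -> multipotent progenitor -> differentiated cell).
#' HMRs first observed at a stage (no overlap with any ancestor stage) form
#' that stage's origin set; retention is the fraction of origin HMRs
#' represented (>= 1 bp overlap) in descendant stages. Overlap is always
#' counted in units of the origin set: one origin HMR overlapping several
#' descendant HMRs counts once.
#' @name lineage
NULL

#' Define a lineage order over HMR sets
#'
#' @param sets named list of `hmr_set` objects, one per stage.
#' @param parents named character vector mapping each stage to its parent
#'   stage (`NA` for the root); must be acyclic with a single root.
#' @return list of class `lineage_order`: `sets`, `parents`, `stages`.
#' @export
lineage_order <- function(sets, parents) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  stages <- names(sets)
  if (!setequal(names(parents), stages))
    stop("lineage_order: parents must name every stage")
  parents <- parents[stages]
  root <- stages[is.na(parents)]
  if (length(root) != 1) stop("lineage_order: exactly one root stage required")
  for (s in stages) {   # acyclicity: walk each stage to the root
    seen <- character()
    cur <- s
    while (!is.na(parents[[cur]])) {
      if (cur %in% seen) stop("lineage_order: cycle at stage ", cur)
      seen <- c(seen, cur)
      cur <- parents[[cur]]
      if (!cur %in% stages) stop("lineage_order: unknown parent ", cur)
    }
  }
  structure(list(sets = sets, parents = parents, stages = stages, root = root),
            class = "lineage_order")
}

.path_to_root <- function(order, stage) {
  path <- character()
  cur <- order$parents[[stage]]
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- order$parents[[cur]]
  }
  path
}

.descendants <- function(order, stage) {
  order$stages[vapply(order$stages, function(s)
    stage %in% .path_to_root(order, s), TRUE)]
}

#' Partition a query set by overlap with a reference set
#'
#' @param query,reference HMR sets.
#' @return list: `overlapping` and `non_overlapping` subsets of `query`
#'   (>= 1 bp rule), plus counts `n_overlapping`, `n_non_overlapping`.
#' @export
overlap_partition <- function(query, reference) {
  hit <- overlaps_any(query, reference)
  q <- as.data.frame(query)
  list(overlapping = q[hit, , drop = FALSE],
       non_overlapping = q[!hit, , drop = FALSE],
       n_overlapping = sum(hit), n_non_overlapping = sum(!hit))
}

#' Trace HMR establishment and retention along a lineage
#'
#' For each stage, the origin set holds the HMRs not overlapping any
#' earlier stage on the path to the root. For each descendant, two
#' retention variants are reported: `direct` (origin HMRs overlapping the
#' descendant) and `path` (origin HMRs overlapping every intermediate
#' stage down to the descendant — the variant used for multi-step
#' pseudo-time comparisons). Percentages use the origin count as
#' denominator, rounded half-up to 2 decimals.
#'
#' @param order a `lineage_order`.
#' @return data frame of class `retention_report` with columns
#'   origin_stage, descendant, n_origin, n_overlap_direct, pct_direct,
#'   n_overlap_path, pct_path, pct_path_string.
#' @export
trace_lineage <- function(order) {
  stopifnot(inherits(order, "lineage_order"))
  if (length(order$stages) < 2) stop("trace_lineage: need >= 2 stages")
  rows <- list()
  for (s in order$stages) {
    anc <- .path_to_root(order, s)
    set_s <- order$sets[[s]]
    if (length(anc)) {
      hit_any <- Reduce(`|`, lapply(anc, function(a)
        overlaps_any(set_s, order$sets[[a]])))
      origin <- as.data.frame(set_s)[!hit_any, , drop = FALSE]
    } else origin <- as.data.frame(set_s)
    n_origin <- nrow(origin)
    for (d in setdiff(.descendants(order, s), s)) {
      chain <- rev(setdiff(.path_to_root(order, d),
                           c(anc, s)))          # stages strictly between s and d
      chain <- c(chain, d)
      direct <- overlaps_any(origin, order$sets[[d]])
      surv <- rep(TRUE, n_origin)
      for (st in chain) surv <- surv & overlaps_any(origin, order$sets[[st]])
      pp <- format_percent(sum(surv), n_origin)
      rows[[length(rows) + 1]] <- data.frame(
        origin_stage = s, descendant = d, n_origin = n_origin,
        n_overlap_direct = sum(direct),
        pct_direct = format_percent(sum(direct), n_origin)$percent,
        n_overlap_path = sum(surv),
        pct_path = pp$percent, pct_path_string = pp$string,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("retention_report", "data.frame"))
}

#' Developmental derivation labels for a target cell type's HMRs
#'
#' Mirrors the annotation used to stratify partitioned-heritability inputs:
#' `stem_derived` overlaps both the stem and the progenitor set;
#' `progenitor_derived` overlaps the progenitor but not the stem;
#' `cell_specific` overlaps no set in the comparison panel; everything
#' else (e.g. overlapping the stem but not the progenitor) is `other` —
#' the three named groups alone are not exhaustive.
#'
#' @param target `hmr_set` of the cell type being labeled.
#' @param stem,progenitor `hmr_set` objects (e.g. embryonic stem cell and
#'   multipotent progenitor).
#' @param panel list of `hmr_set` objects for the full comparison
#'   collection (should include stem and progenitor; must exclude the
#'   target itself).
#' @return data frame chrom, start, end, label (factor with the four
#'   levels), class `derivation_labels`.
#' @export
derive_labels <- function(target, stem, progenitor, panel) {
  ov_stem <- overlaps_any(target, stem)
  ov_prog <- overlaps_any(target, progenitor)
  ov_panel <- Reduce(`|`, lapply(panel, function(s) overlaps_any(target, s)))
  lab <- rep("other", nrow(target))
  lab[ov_stem & ov_prog] <- "stem_derived"
  lab[ov_prog & !ov_stem] <- "progenitor_derived"
  lab[!ov_panel] <- "cell_specific"
  structure(data.frame(chrom = target$chrom, start = target$start,
                       end = target$end,
                       label = factor(lab, levels = c("stem_derived",
                                                      "progenitor_derived",
                                                      "cell_specific", "other")),
                       stringsAsFactors = FALSE),
            class = c("derivation_labels", "data.frame"))
}

#' Cell-specific versus shared HMR counts
#'
#' @param target `hmr_set`.
#' @param others non-empty list of `hmr_set` objects (the other cell types).
#' @return list: `n_specific` (overlap none), `n_shared` (overlap >= 1
#'   other set), `fold` = shared/specific rounded half-up to 2 dp (`NA`
#'   when no specific HMRs exist).
#' @export
shared_vs_specific <- function(target, others) {
  stopifnot(length(others) >= 1)
  ov <- Reduce(`|`, lapply(others, function(s) overlaps_any(target, s)))
  n_spec <- sum(!ov)
  n_shared <- sum(ov)
  list(n_specific = n_spec, n_shared = n_shared,
       fold = if (n_spec > 0) round_half_up(n_shared / n_spec, 2) else NA_real_)
}

#' Flow table from progenitor spatial context to target spatial class
#'
#' Each target HMR is assigned one source category by the hierarchy:
#' overlaps a progenitor HMR classified `cluster_member` -> "clustered";
#' else overlaps an `unclustered` progenitor HMR -> "unclustered"; else
#' overlaps any progenitor HMR -> "shared" (pair/proximal/residual
#' context); else overlaps no set of the comparison panel ->
#' "cell_specific"; else "other". The source is cross-tabulated against
#' the target's own class collapsed to clustered/unclustered/other.
#'
#' @param target_classes `spatial_class` for the target cell type.
#' @param progenitor_classes `spatial_class` for the progenitor.
#' @param panel list of `hmr_set` objects for the specificity comparison
#'   (excluding the target).
#' @return list of class `sankey_table`: `table` (source x target counts),
#'   `flows` (long-format data frame).
#' @export
sankey_flows <- function(target_classes, progenitor_classes, panel) {
  tcl <- target_classes$classes
  pcl <- progenitor_classes$classes
  tgt <- interval_set(tcl[, c("chrom", "start", "end")], dedup = FALSE)
  prog_of <- function(cls) {
    sub <- pcl[pcl$class %in% cls, c("chrom", "start", "end"), drop = FALSE]
    if (!nrow(sub)) return(rep(FALSE, nrow(tgt)))
    overlaps_any(tgt, interval_set(sub, dedup = FALSE))
  }
  ov_clustered <- prog_of("cluster_member")
  ov_unclustered <- prog_of("unclustered")
  ov_any <- prog_of(unique(pcl$class))
  ov_panel <- Reduce(`|`, lapply(panel, function(s) overlaps_any(tgt, s)))
  src <- rep("other", nrow(tgt))
  src[!ov_panel] <- "cell_specific"
  src[ov_any] <- "shared"
  src[ov_unclustered] <- "unclustered_progenitor"
  src[ov_clustered] <- "clustered_progenitor"
  n_other <- sum(src == "other")
  if (n_other) message(n_other,
    " target HMR(s) overlap the panel but not the progenitor: source 'other'")
  dest <- ifelse(tcl$class == "cluster_member", "clustered",
                 ifelse(tcl$class == "unclustered", "unclustered", "other"))
  tab <- table(source = factor(src, levels = c("clustered_progenitor",
                                               "unclustered_progenitor",
                                               "shared", "cell_specific",
                                               "other")),
               target = factor(dest, levels = c("clustered", "unclustered",
                                                "other")))
  structure(list(table = tab,
                 flows = as.data.frame(tab, stringsAsFactors = FALSE)),
            class = "sankey_table")
}

#' @export
print.sankey_table <- function(x, ...) {
  cat("HMR flow table (source context -> target class):\n")
  print(x$table)
  invisible(x)
}

#' Write one sorted BED file per label group
#'
#' The files partition the labeled set: disjoint groups whose union is the
#' input; empty groups still produce an (empty) file.
#'
#' @param labels a `derivation_labels` data frame, or any data frame with
#'   chrom/start/end and a `label` or `class` column.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of file paths, invisibly.
#' @export
export_annotation_beds <- function(labels, out_dir, prefix = "hmr") {
  lab <- if (!is.null(labels$label)) labels$label else labels$class
  if (is.null(lab)) stop("export_annotation_beds: no label/class column")
  lab <- as.character(lab)
  lv <- if (is.factor(labels$label)) levels(labels$label) else unique(lab)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(lv, function(g) {
    sub <- labels[lab == g, c("chrom", "start", "end"), drop = FALSE]
    p <- file.path(out_dir, paste0(prefix, "_", g, ".bed"))
    if (nrow(sub)) {
      sub$name <- g
      write_bed(interval_set(sub, dedup = FALSE), p)
    } else writeLines(character(), p)
    p
  }, "")
  invisible(paths)
}
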