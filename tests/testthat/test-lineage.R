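test_that("overlap partition counts in query units with the 1 bp rule", {
  q <- hmr_set(c("chr1", "chr1"), c(0, 200), c(100, 300))
  r <- hmr_set("chr1", 250, 260)
  p <- overlap_partition(q, r)
  expect_equal(p$n_overlapping, 1)
  expect_equal(p$n_non_overlapping, 1)
  empty <- hmr_set(character(), numeric(), numeric())
  p0 <- overlap_partition(q, empty)
  expect_equal(p0$n_overlapping, 0)
  expect_equal(p0$n_non_overlapping, 2)
  expect_equal(overlap_partition(q, q)$n_overlapping, 2)
  # one query HMR over two reference HMRs still counts once
  multi <- hmr_set(c("chr1", "chr1"), c(10, 60), c(20, 70))
  expect_equal(overlap_partition(hmr_set("chr1", 0, 100), multi)$n_overlapping, 1)
})

test_that("retention arithmetic reproduces printed-ratio formatting", {
  expect_equal(format_percent(11959, 18235)$string, "65.58%")
  expect_equal(format_percent(11310, 18235)$string, "62.02%")
  expect_equal(format_percent(10285, 18235)$string, "56.40%")
  expect_equal(format_percent(27312, 34605)$string, "78.93%")
})

test_that("lineage trace handles nested, disjoint and branched toy sets", {
  a <- hmr_set("chr1", 100, 200, label = "A")
  b <- hmr_set(c("chr1", "chr1"), c(100, 400), c(200, 500), label = "B")
  cset <- hmr_set(c("chr1", "chr1", "chr1"), c(100, 400, 800),
                  c(200, 500, 900), label = "C")
  ord <- lineage_order(list(A = a, B = b, C = cset),
                       c(A = NA, B = "A", C = "B"))
  tr <- trace_lineage(ord)
  # A-origin HMRs are fully nested: 100% everywhere
  arow <- tr[tr$origin_stage == "A" & tr$descendant == "C", ]
  expect_equal(arow$pct_path, 100)
  expect_equal(arow$pct_path_string, "100.00%")
  # B origin excludes the A-overlapping interval
  brow <- tr[tr$origin_stage == "B" & tr$descendant == "C", ]
  expect_equal(brow$n_origin, 1)
  expect_equal(brow$pct_path, 100)
  # disjoint descendant -> 0%
  d <- hmr_set("chr2", 0, 100, label = "D")
  ord2 <- lineage_order(list(A = a, D = d), c(A = NA, D = "A"))
  expect_equal(trace_lineage(ord2)$pct_path, 0)
  expect_equal(trace_lineage(ord2)$pct_path_string, "0.00%")
})

test_that("path-conditioned retention differs from direct overlap", {
  # root HMR present in grandchild but absent in child
  root <- hmr_set("chr1", 0, 100, label = "r")
  child <- hmr_set("chr1", 5000, 5100, label = "c")
  grand <- hmr_set(c("chr1", "chr1"), c(0, 5000), c(100, 5100), label = "g")
  ord <- lineage_order(list(r = root, c = child, g = grand),
                       c(r = NA, c = "r", g = "c"))
  tr <- trace_lineage(ord)
  row <- tr[tr$origin_stage == "r" & tr$descendant == "g", ]
  expect_equal(row$n_overlap_direct, 1)
  expect_equal(row$n_overlap_path, 0)   # lost at the intermediate stage
})

test_that("trace is invariant to within-stage interval order", {
  set.seed(13)
  mk <- function(perm_seed) {
    r <- random_intervals(20, 30000)
    r
  }
  r <- random_intervals(20, 30000)
  m <- as.data.frame(merge_intervals(interval_set(r, dedup = FALSE), 0))
  h1 <- hmr_set(m[, c("chrom", "start", "end")], label = "s1")
  r2 <- random_intervals(25, 30000)
  m2 <- as.data.frame(merge_intervals(interval_set(r2, dedup = FALSE), 0))
  h2a <- hmr_set(m2[, c("chrom", "start", "end")], label = "s2")
  h2b <- hmr_set(m2[sample(nrow(m2)), c("chrom", "start", "end")], label = "s2")
  t1 <- trace_lineage(lineage_order(list(s1 = h1, s2 = h2a),
                                    c(s1 = NA, s2 = "s1")))
  t2 <- trace_lineage(lineage_order(list(s1 = h1, s2 = h2b),
                                    c(s1 = NA, s2 = "s1")))
  expect_equal(t1, t2)
})

test_that("derivation labels follow the overlap hierarchy and partition the set", {
  stem <- hmr_set("chr1", 0, 1000, label = "stem")
  prog <- hmr_set(c("chr1", "chr1"), c(0, 5000), c(1000, 6000), label = "prog")
  other <- hmr_set("chr1", 20000, 21000, label = "other_ct")
  target <- hmr_set(rep("chr1", 4), c(100, 5100, 20100, 50000),
                    c(200, 5200, 20200, 50100), label = "target")
  lab <- derive_labels(target, stem, prog,
                       panel = list(stem, prog, other))
  expect_equal(as.character(lab$label),
               c("stem_derived", "progenitor_derived", "other", "cell_specific"))
  expect_equal(sum(table(lab$label)), nrow(target))
  # overlapping stem but not progenitor, with panel overlap -> other
  t2 <- hmr_set("chr1", 100, 200)
  stem_only <- derive_labels(t2, stem, hmr_set("chr2", 0, 10),
                             panel = list(stem))
  expect_equal(as.character(stem_only$label), "other")
})

test_that("shared vs specific fold matches printed-ratio formatting", {
  expect_equal(round_half_up(15619 / 2616, 2), 5.97)
  t1 <- hmr_set(rep("chr1", 3), c(0, 1000, 2000), c(100, 1100, 2100))
  others <- list(hmr_set("chr1", 0, 50), hmr_set("chr1", 1000, 1050))
  sv <- shared_vs_specific(t1, others)
  expect_equal(sv$n_shared, 2)
  expect_equal(sv$n_specific, 1)
  expect_equal(sv$fold, 2)
  none <- shared_vs_specific(t1, list(hmr_set("chr2", 0, 10)))
  expect_equal(none$n_shared, 0)
  expect_equal(none$fold, 0)   # specific HMRs exist, none shared
  all_shared <- shared_vs_specific(t1, list(t1))
  expect_equal(all_shared$n_specific, 0)
  expect_true(is.na(all_shared$fold))
})

test_that("sankey flows follow the source hierarchy and sum to the target size", {
  w <- whitelist_regions(interval_set(character(), numeric(), numeric()),
                         chrom_sizes("chr1", 200000))
  empty_bl <- interval_set(character(), numeric(), numeric())
  # progenitor: trio cluster at 0-5k, isolated HMR at 100k
  prog <- hmr_set(rep("chr1", 4), c(0, 2000, 4000, 100000),
                  c(1000, 3000, 5000, 100500))
  pc <- classify_hmrs(prog, prog, empty_bl, w)
  # target: trio overlapping the progenitor cluster, one HMR over the
  # isolated progenitor HMR, one cell-specific HMR far away
  tgt <- hmr_set(rep("chr1", 5), c(0, 2000, 4000, 100000, 150000),
                 c(1000, 3000, 5000, 100500, 150500))
  tc <- classify_hmrs(tgt, tgt, empty_bl, w)
  sk <- sankey_flows(tc, pc, panel = list(prog))
  expect_equal(sum(sk$table), nrow(tgt))
  expect_equal(unname(sk$table["clustered_progenitor", "clustered"]), 3)
  expect_equal(unname(sk$table["unclustered_progenitor", "unclustered"]), 1)
  expect_equal(unname(sk$table["cell_specific", "unclustered"]), 1)
})

test_that("annotation BED export partitions the set and round trips", {
  lab <- data.frame(chrom = rep("chr1", 4), start = c(0, 100, 200, 300),
                    end = c(50, 150, 250, 350),
                    label = factor(c("a", "b", "a", "c"),
                                   levels = c("a", "b", "c", "d")))
  out <- tempfile()
  paths <- export_annotation_beds(lab, out, prefix = "t")
  expect_equal(length(paths), 4)
  expect_true(all(file.exists(paths)))
  back_a <- read_bed(paths[["a"]])
  expect_equal(back_a$start, c(0, 200))
  # empty group still produces a file
  expect_equal(length(readLines(paths[["d"]])), 0)
  n_total <- sum(vapply(paths, function(p) length(readLines(p)), 0L))
  expect_equal(n_total, nrow(lab))
})
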