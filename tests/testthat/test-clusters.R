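make_whitelist <- function(blacklist_df, L = 100000) {
  bl <- if (is.null(blacklist_df))
    interval_set(character(), numeric(), numeric())
  else interval_set(blacklist_df, dedup = FALSE)
  whitelist_regions(bl, chrom_sizes("chr1", L))
}

test_that("whitelist is the complement of the blacklist", {
  w0 <- make_whitelist(NULL, 20000)
  expect_equal(as.data.frame(w0)[, c("start", "end")],
               data.frame(start = 0, end = 20000))
  w1 <- make_whitelist(data.frame(chrom = "chr1", start = 5000, end = 5100),
                       20000)
  expect_equal(w1$start, c(0, 5100))
  expect_equal(w1$end, c(5000, 20000))
  # adjacent blacklist regions leave a single gap on each side
  w2 <- make_whitelist(data.frame(chrom = "chr1", start = c(1000, 2000),
                                  end = c(2000, 3000)), 10000)
  expect_equal(nrow(w2), 2)
})

test_that("linking chains HMRs within 6 kb inside one whitelist region", {
  h <- hmr_set(rep("chr1", 3), c(0, 3000, 8000), c(1000, 4000, 9000))
  lk <- link_clusters(h, make_whitelist(NULL))
  expect_equal(nrow(lk$clusters), 1)
  expect_equal(lk$clusters$n_members, 3)
  expect_equal(lk$clusters$start, 0)
  expect_equal(lk$clusters$end, 9000)
  # an exon between members blocks the link
  wex <- make_whitelist(data.frame(chrom = "chr1", start = 5000, end = 5100))
  lk2 <- link_clusters(h, wex)
  expect_equal(nrow(lk2$clusters), 1)
  expect_equal(lk2$clusters$n_members, 2)
  expect_equal(lk2$clusters$end, 4000)
  expect_true(is.na(lk2$members$cluster_id[3]))
})

test_that("the 6 kb linking threshold is inclusive", {
  w <- make_whitelist(NULL)
  at <- hmr_set(c("chr1", "chr1"), c(0, 7000), c(1000, 8000))   # gap 6000
  expect_equal(nrow(link_clusters(at, w)$clusters), 1)
  over <- hmr_set(c("chr1", "chr1"), c(0, 7001), c(1000, 8000)) # gap 6001
  expect_equal(nrow(link_clusters(over, w)$clusters), 0)
})

test_that("classification covers the four-way scheme plus residuals", {
  # whitelist split at an exon [5000,5100); HMRs: a trio cluster far away,
  # an isolated HMR, a cross-boundary near pair, and an HMR near a
  # blacklist-overlapping HMR only
  bl <- data.frame(chrom = "chr1", start = c(5000, 40000), end = c(5100, 43000))
  w <- make_whitelist(bl)
  blset <- interval_set(bl, dedup = FALSE)
  nc <- hmr_set(rep("chr1", 6),
                c(12000, 14000, 16000, 30000, 4000, 5200),
                c(12500, 14500, 16500, 30500, 4500, 5700))
  all_h <- hmr_set(rep("chr1", 7),
                   c(12000, 14000, 16000, 30000, 4000, 5200, 39000),
                   c(12500, 14500, 16500, 30500, 4500, 5700, 41000))
  sc <- classify_hmrs(nc, all_h, blset, w)
  cls <- sc$classes
  key <- paste(cls$start, cls$end)
  expect_equal(cls$class[key == "12000 12500"], "cluster_member")
  expect_equal(cls$class[key == "14000 14500"], "cluster_member")
  expect_equal(cls$class[key == "16000 16500"], "cluster_member")
  expect_equal(cls$class[key == "30000 30500"], "unclustered")
  expect_equal(cls$class[key == "4000 4500"], "residual")
  expect_equal(cls$class[key == "5200 5700"], "residual")
  expect_error(classify_hmrs(hmr_set("chr1", 0, 10), all_h, blset, w),
               "subset")
})

test_that("an HMR whose only neighbor overlaps the blacklist is TSS/exon-proximal", {
  bl <- data.frame(chrom = "chr1", start = 40000, end = 43000)
  w <- make_whitelist(bl)
  blset <- interval_set(bl, dedup = FALSE)
  # non-coding HMR at 3 kb from a promoter-overlapping HMR, nothing else near
  nc <- hmr_set("chr1", 36000, 36500)
  all_h <- hmr_set(c("chr1", "chr1"), c(36000, 39500), c(36500, 41000))
  sc <- classify_hmrs(nc, all_h, blset, w)
  expect_equal(sc$classes$class, "tss_exon_proximal")
  # and a lone HMR >= 7 kb from everything is unclustered
  nc2 <- hmr_set("chr1", 60000, 60500)
  all2 <- hmr_set(c("chr1", "chr1"), c(60000, 70000), c(60500, 70500))
  expect_equal(classify_hmrs(nc2, all2, blset, w)$classes$class, "unclustered")
})

test_that("pair members are distinguished from clusters by size", {
  w <- make_whitelist(NULL)
  pair <- hmr_set(c("chr1", "chr1"), c(0, 2000), c(1000, 3000))
  sc <- classify_hmrs(pair, pair, interval_set(character(), numeric(),
                                               numeric()), w)
  expect_equal(sc$classes$class, c("pair_member", "pair_member"))
})

test_that("linking equals the transitive-closure oracle on random instances", {
  set.seed(17)
  for (rep in 1:60) {
    L <- 50000
    bl_n <- sample(0:3, 1)
    bl <- if (bl_n) {
      r <- random_intervals(bl_n, L, max_len = 3000)
      r$chrom <- "chr1"
      as.data.frame(merge_intervals(interval_set(r, dedup = FALSE), 0))
    } else NULL
    w <- make_whitelist(bl, L)
    r <- random_intervals(sample(2:25, 1), L, max_len = 1500)
    r$chrom <- "chr1"
    m <- merge_intervals(interval_set(r, dedup = FALSE), 0)
    h <- hmr_set(as.data.frame(m)[, c("chrom", "start", "end")])
    d <- sample(c(500, 2000, 6000), 1)
    lk <- link_clusters(h, w, cluster_config(link_distance = d))
    comp <- oracle_clusters(as.data.frame(h), as.data.frame(w), d)
    # same grouping: member cluster ids must be a relabeling of components
    got <- lk$members$cluster_id
    comp_sizes <- table(comp[!is.na(comp)])
    big <- names(comp_sizes)[comp_sizes >= 2]
    for (cid in big) {
      idx <- which(!is.na(comp) & comp == as.integer(cid))
      expect_equal(length(unique(got[idx])), 1)
      expect_false(any(is.na(got[idx])))
    }
    expect_equal(sum(!is.na(got)), sum(comp %in% as.integer(big), na.rm = TRUE))
  }
})

test_that("increasing link distance never shrinks clusters", {
  set.seed(23)
  w <- make_whitelist(NULL, 50000)
  for (rep in 1:20) {
    r <- random_intervals(15, 50000, max_len = 800)
    r$chrom <- "chr1"
    m <- merge_intervals(interval_set(r, dedup = FALSE), 0)
    h <- hmr_set(as.data.frame(m)[, c("chrom", "start", "end")])
    l1 <- link_clusters(h, w, cluster_config(link_distance = 2000))
    l2 <- link_clusters(h, w, cluster_config(link_distance = 8000))
    # every cluster at 2 kb is contained in a single cluster at 8 kb
    for (cid in unique(stats::na.omit(l1$members$cluster_id))) {
      idx <- which(l1$members$cluster_id == cid)
      expect_equal(length(unique(l2$members$cluster_id[idx])), 1)
    }
  }
})

test_that("cluster summary fractions behave like the published ratios", {
  w <- make_whitelist(NULL)
  trio <- hmr_set(rep("chr1", 4), c(0, 2000, 4000, 50000),
                  c(1000, 3000, 5000, 50500))
  sc <- classify_hmrs(trio, trio, interval_set(character(), numeric(),
                                               numeric()), w)
  sm <- cluster_summary(list(toy = sc))
  cf <- sm$clustered_fraction
  expect_equal(cf$n_clustered, 3)
  expect_equal(cf$n_unclustered, 1)
  expect_equal(cf$clustered_fraction, 0.75)
  expect_equal(sum(sm$class_table$count), 4)
  expect_equal(sum(sm$class_table$fraction), 1)
  # every HMR gets exactly one label
  expect_false(any(is.na(sc$classes$class)))
})
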