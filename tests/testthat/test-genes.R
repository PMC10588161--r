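# A small deterministic landscape: one chromosome, genes at known TSSs,
# two TADs tiling [0, 100k) and [100k, 200k).
land_genes <- function(tss = c(500, 2500, 9000, 95000, 150000),
                       strand = rep("+", length(tss))) {
  start <- ifelse(strand == "+", tss, tss - 1000)
  end <- start + 1000
  gene_table(sprintf("g%02d", seq_along(tss)), rep("chr1", length(tss)),
             strand, start, end)
}
land_tads <- function() interval_set(c("chr1", "chr1"), c(0, 100000),
                                     c(100000, 200000), label = "tads")
land_expr <- function(tpm = c(5, 5, 5, 5, 5))
  data.frame(gene_id = sprintf("g%02d", seq_along(tpm)), tpm = tpm)

test_that("k nearest TSSs measure edge-to-point distance with ties by gene id", {
  region <- interval_set("chr1", 1000, 2000)
  kn <- k_nearest_tss(region, land_genes(), k = 2)
  expect_equal(nrow(kn), 2)
  expect_equal(sort(kn$distance), c(500, 500))       # both 500 bp away (tie)
  expect_setequal(kn$gene_id, c("g01", "g02"))
  # TSS inside the region -> distance 0
  kin <- k_nearest_tss(interval_set("chr1", 1000, 2000),
                       land_genes(tss = c(1500, 50000)), k = 1)
  expect_equal(kin$distance, 0)
  # k beyond the gene count returns all genes
  kall <- k_nearest_tss(region, land_genes(), k = 100)
  expect_equal(nrow(kall), 5)
  # chromosome without genes
  expect_message(k0 <- k_nearest_tss(interval_set("chrX", 0, 10),
                                     land_genes(), k = 3), "without genes")
  expect_equal(nrow(k0), 0)
})

test_that("TAD filter keeps pairs fully inside a single TAD", {
  region <- interval_set("chr1", 90000, 91000)
  kn <- k_nearest_tss(region, land_genes(), k = 5)
  tf <- tad_filter(kn, land_tads())
  # pair to TSS 150000 spans the 100k boundary -> removed
  expect_false("g05" %in% tf$gene_id)
  expect_true("g04" %in% tf$gene_id)
  expect_true(all(tf$tad_id == 1))
  # nested/overlapping TADs: containment in any one suffices
  nested <- interval_set(rep("chr1", 3), c(0, 0, 80000),
                         c(100000, 200000, 120000))
  region2 <- interval_set("chr1", 95000, 96000)
  kn2 <- k_nearest_tss(region2, land_genes(tss = c(99000, 110000)), k = 2)
  tf2 <- tad_filter(kn2, nested)
  expect_equal(nrow(tf2), 2)     # 110000 pair fits the [0,200k) TAD
  # enumeration check against direct containment logic
  for (i in seq_len(nrow(kn2))) {
    span_s <- min(kn2$start[i], kn2$tss[i])
    span_e <- max(kn2$end[i], kn2$tss[i] + 1)
    manual <- any(nested$start <= span_s & nested$end >= span_e)
    expect_equal(kn2$gene_id[i] %in% tf2$gene_id, manual)
  }
})

test_that("nearest active gene skips unexpressed and out-of-TAD candidates", {
  region <- interval_set("chr1", 1000, 2000)
  # nearest gene unexpressed, next expressed
  na1 <- nearest_active_gene(region, land_genes(), land_tads(),
                             land_expr(c(0, 5, 5, 5, 5)))
  expect_equal(na1$gene_id, "g02")
  expect_equal(na1$distance, 500)
  # all candidates outside the region's TAD -> no assignment
  far <- interval_set("chr1", 99000, 99500)
  na2 <- nearest_active_gene(far, land_genes(tss = 150000), land_tads(),
                             data.frame(gene_id = "g01", tpm = 9))
  expect_true(is.na(na2$gene_id))
  # single expressed in-TAD gene at a distance is returned
  na3 <- nearest_active_gene(interval_set("chr1", 50000, 51000),
                             land_genes(), land_tads(),
                             land_expr(c(0, 0, 0, 5, 5)))
  expect_equal(na3$gene_id, "g04")
  expect_equal(na3$distance, 95000 - 51000)
})

test_that("filters only remove candidates, never shorten distances", {
  set.seed(19)
  genes <- land_genes(tss = sort(sample.int(190000, 30)))
  expr_all <- data.frame(gene_id = genes$gene_id, tpm = 1)
  for (rep in 1:20) {
    s0 <- sample.int(180000, 1)
    region <- interval_set("chr1", s0, s0 + 500)
    free <- k_nearest_tss(region, genes, k = 1)$distance
    con <- nearest_active_gene(region, genes, land_tads(), expr_all)$distance
    if (!is.na(con)) expect_gte(con, free)
    # no TAD constraint + all expressed == plain nearest TSS
    un <- nearest_active_gene(region, genes, NULL, expr_all)$distance
    expect_equal(un, free)
  }
})

test_that("proportion curve is monotone and saturates for near assignments", {
  ga <- interval_set(rep("chr1", 3), c(400, 2400, 8900), c(600, 2600, 9100))
  gb <- interval_set(rep("chr1", 2), c(40000, 60000), c(41000, 61000))
  curve <- proportion_active_curve(ga, gb, land_genes(), land_tads(),
                                   land_expr())
  expect_true(all(diff(curve$prop_a) >= 0))
  expect_true(all(diff(curve$prop_b) >= 0))
  expect_true(all(curve$prop_a == 1))   # all group-A TSS distances ~0-100 bp
  expect_true(all(curve$count_a <= curve$denom_a))
  # identical groups -> p = 1 at every threshold
  same <- proportion_active_curve(ga, ga, land_genes(), land_tads(),
                                  land_expr())
  expect_true(all(same$p_value == 1))
})

test_that("expression comparison deduplicates genes and detects null identity", {
  ga <- interval_set(rep("chr1", 3), c(400, 450, 2400), c(420, 470, 2600))
  gb <- ga
  ec <- expression_comparison(ga, gb, land_genes(), land_tads(), land_expr())
  expect_equal(ec$rank_sum$p_value, 1)
  # the three regions share neighbors g01/g02: dedup keeps each gene once
  expect_equal(length(ec$tpm_a), length(unique(names(ec$tpm_a))))
  expect_error(expression_comparison(
    interval_set("chrX", 0, 10), gb, land_genes(), land_tads(), land_expr()),
    "no assigned genes")
})

test_that("distance bins are half-open with 10 kb in the second bin", {
  # region at exactly 10,000 bp from its only gene
  g <- land_genes(tss = c(20000))
  expr <- data.frame(gene_id = "g01", tpm = 3)
  ga <- interval_set("chr1", 9000, 10000)
  gb <- interval_set("chr1", 19000, 19500)
  bins <- distance_binned_comparison(ga, gb, g, land_tads(), expr)
  expect_equal(bins$n_a[2], 1)   # 10,000 falls in [10k, 50k)
  expect_equal(bins$n_a[1], 0)
  expect_equal(bins$n_b[1], 1)   # distance 500 in [0, 10k)
  expect_true(all(!bins$tested[bins$n_a < 2 | bins$n_b < 2]))
})

test_that("replicate averaging produces the row mean", {
  df <- data.frame(gene_id = c("a", "b"), tpm_rep1 = c(2, 0),
                   tpm_rep2 = c(4, 10))
  av <- average_replicates(df)
  expect_equal(av$tpm, c(3, 5))
})
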