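#' @title Synthetic developmental lineages of HMR sets with ground truth
#' @description
#' Generates a small genome (chromosomes, genes with exons and strands,
#' tiling TADs, the derived promoter/exon blacklist), a lineage tree of
#' HMR sets (a basal set at the root; per transition, parental HMRs
#' retained with a fixed probability plus newly gained HMRs, a fraction of
#' which is placed in proximity to existing HMRs), bimodal per-CpG
#' methylation tracks, and gene expression with a planted effect for
#' genes whose TAD hosts an HMR cluster. Every HMR carries provenance
#' (stage of establishment, proximal-placement flag) so parameter-recovery
#' tests can compare estimates against the generating truth.
#'
#' Defaults echo the magnitudes reported for human WGBS HMR atlases:
#' a median HMR length near 866 bp, roughly 35% of newly established HMRs
#' placed within 6 kb of an existing HMR, and 90% retention per
#' developmental transition.
#' @name synthetic
NULL

#' Simulation configuration
#'
#' @param seed master seed; all stage-specific randomness derives from it
#'   through named substreams.
#' @param n_chrom,chrom_len genome layout (default 3 chromosomes x 10 Mb).
#' @param cpg_spacing mean bp between CpGs (geometric spacing).
#' @param gene_count genes per genome; `gene_len_range` their body lengths;
#'   `exons_per_gene`/`exon_len` the exon layout.
#' @param tad_size TAD tiling width in bp.
#' @param lineage named character vector of parents (NA for root); default
#'   H1 -> HSPC -> {macrophage, Bcell}.
#' @param basal_count HMRs at the root stage.
#' @param gain_per_transition new HMRs per transition.
#' @param retention_prob probability a parental HMR is retained at a
#'   transition (scalar, or named per child stage).
#' @param p_cluster probability a gained HMR is placed near an existing
#'   one; `prox_window` the maximum gap for such proximal placement.
#' @param hmr_meanlog,hmr_sdlog log-normal HMR length parameters
#'   (median = exp(meanlog) ~ 866 bp); lengths resampled below `min_len`.
#' @param min_len minimum HMR length.
#' @param meth_low,meth_high Beta(shape1, shape2) for CpG methylation
#'   inside / outside HMRs (means 0.1 and 0.9).
#' @param expr_meanlog,expr_sdlog baseline log-normal TPM; `zero_prob`
#'   zero-inflation; `expression_effect` multiplicative boost for genes in
#'   a TAD containing an HMR cluster span.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 3, chrom_len = 1e7,
                       cpg_spacing = 100,
                       gene_count = 300,
                       gene_len_range = c(5000, 50000),
                       exons_per_gene = 4, exon_len = 150,
                       tad_size = 5e5,
                       lineage = c(H1 = NA, HSPC = "H1",
                                   macrophage = "HSPC", Bcell = "HSPC"),
                       basal_count = 600,
                       gain_per_transition = 1000,
                       retention_prob = 0.9,
                       p_cluster = 0.35,
                       prox_window = 6000,
                       hmr_meanlog = log(866), hmr_sdlog = 0.7,
                       min_len = 50,
                       meth_low = c(2, 18), meth_high = c(18, 2),
                       expr_meanlog = log(10), expr_sdlog = 1,
                       zero_prob = 0.3,
                       expression_effect = 2) {
  cfg <- list(seed = seed, n_chrom = n_chrom, chrom_len = chrom_len,
              cpg_spacing = cpg_spacing, gene_count = gene_count,
              gene_len_range = gene_len_range,
              exons_per_gene = exons_per_gene, exon_len = exon_len,
              tad_size = tad_size, lineage = lineage,
              basal_count = basal_count,
              gain_per_transition = gain_per_transition,
              retention_prob = retention_prob, p_cluster = p_cluster,
              prox_window = prox_window, hmr_meanlog = hmr_meanlog,
              hmr_sdlog = hmr_sdlog, min_len = min_len,
              meth_low = meth_low, meth_high = meth_high,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              zero_prob = zero_prob, expression_effect = expression_effect)
  stopifnot(cfg$p_cluster >= 0, cfg$p_cluster <= 1,
            all(cfg$retention_prob >= 0), all(cfg$retention_prob <= 1),
            cfg$zero_prob >= 0, cfg$zero_prob <= 1,
            cfg$min_len >= 1, cfg$chrom_len > 0, cfg$tad_size > 0)
  structure(cfg, class = "sim_config")
}

# named substreams from the master seed: stages can be regenerated
# independently and deterministically
.sub_seed <- function(seed, stream) {
  streams <- c("genome", "lineage", "methylome", "expression")
  i <- match(stream, streams)
  stopifnot(!is.na(i))
  as.integer((as.numeric(seed) * 48271 + i * 2246822519) %% 2147483647) + 1L
}

.rlen <- function(n, cfg) {
  len <- round(stats::rlnorm(n, cfg$hmr_meanlog, cfg$hmr_sdlog))
  while (any(len < cfg$min_len))
    len[len < cfg$min_len] <- round(stats::rlnorm(sum(len < cfg$min_len),
                                                  cfg$hmr_meanlog, cfg$hmr_sdlog))
  len
}

#' Simulate the genome scaffold
#'
#' Genes are placed uniformly with Bernoulli(0.5) strand; exons sit inside
#' gene bodies; TADs tile each chromosome; the blacklist is derived from
#' the genes via [build_blacklist()].
#'
#' @param config a `sim_config`.
#' @return list of class `sim_genome`: `sizes`, `genes`, `tads`,
#'   `blacklist`, `whitelist`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(.sub_seed(config$seed, "genome"))
  sizes <- chrom_sizes(paste0("chr", seq_len(config$n_chrom)),
                       rep(config$chrom_len, config$n_chrom))
  ng <- config$gene_count
  if (ng > 0) {
    glen <- round(stats::runif(ng, config$gene_len_range[1],
                               config$gene_len_range[2]))
    if (any(glen >= config$chrom_len))
      stop("simulate_genome: gene longer than chromosome")
    chrom <- sample(names(sizes), ng, replace = TRUE)
    start <- floor(stats::runif(ng, 0, config$chrom_len - glen))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    ex_s <- vector("list", ng); ex_e <- vector("list", ng)
    for (i in seq_len(ng)) {
      k <- min(config$exons_per_gene,
               max(1, floor(glen[i] / (2 * config$exon_len))))
      off <- sort(sample.int(glen[i] - config$exon_len, k))
      s <- start[i] + off
      e <- s + config$exon_len
      keep <- c(TRUE, s[-1] >= cummax(e)[-k])   # drop overlapping exons
      ex_s[[i]] <- s[keep]; ex_e[[i]] <- e[keep]
    }
    genes <- gene_table(sprintf("g%04d", seq_len(ng)), chrom, strand,
                        start, start + glen, ex_s, ex_e)
  } else {
    genes <- gene_table(character(), character(), character(),
                        numeric(), numeric())
  }
  tad_s <- unlist(lapply(names(sizes), function(cn)
    seq(0, sizes[[cn]] - 1, by = config$tad_size)))
  tad_c <- rep(names(sizes), vapply(names(sizes), function(cn)
    length(seq(0, sizes[[cn]] - 1, by = config$tad_size)), 0L))
  tads <- interval_set(tad_c, tad_s,
                       pmin(tad_s + config$tad_size,
                            rep(as.numeric(sizes), table(factor(tad_c, names(sizes))))),
                       label = "tads", dedup = FALSE)
  blacklist <- if (nrow(genes)) build_blacklist(genes)
               else interval_set(data.frame(chrom = character(),
                                            start = numeric(), end = numeric()),
                                 label = "blacklist")
  structure(list(sizes = sizes, genes = genes, tads = tads,
                 blacklist = blacklist,
                 whitelist = whitelist_regions(blacklist, sizes)),
            class = "sim_genome")
}

# sample a uniform legal start for an interval of length len on a given
# chromosome's whitelist segments, avoiding `placed` (two-column matrix of
# start/end); NULL when no legal start exists
.uniform_start <- function(len, seg, placed, max_tries = 200) {
  counts <- pmax(0, (seg$end - seg$start) - len + 1)
  total <- sum(counts)
  if (total <= 0) return(NULL)
  cum <- cumsum(counts)
  for (t in seq_len(max_tries)) {
    u <- stats::runif(1) * total
    k <- sum(u > cum) + 1L
    s0 <- seg$start[k] + min(floor(u - c(0, cum)[k]), counts[k] - 1)
    e0 <- s0 + len
    if (!nrow(placed) || !any(placed[, 1] < e0 & placed[, 2] > s0))
      return(s0)
  }
  NULL
}

# legal proximal starts: gap to the anchor at most window, fully inside a
# whitelist segment, not overlapping placed intervals
.proximal_start <- function(len, anchor_s, anchor_e, window, seg, placed) {
  cand <- c(seq(anchor_s - window - len, anchor_s - len),
            seq(anchor_e, anchor_e + window))
  cand <- cand[cand >= 0]
  if (!length(cand)) return(NULL)
  j <- findInterval(cand, seg$start)
  ok <- j > 0 & seg$end[pmax(j, 1)] >= cand + len & seg$start[pmax(j, 1)] <= cand
  cand <- cand[ok]
  if (!length(cand)) return(NULL)
  if (nrow(placed)) {
    lo <- anchor_s - window - len
    hi <- anchor_e + window + len
    near <- placed[placed[, 1] < hi & placed[, 2] > lo, , drop = FALSE]
    if (nrow(near)) {
      free <- rep(TRUE, length(cand))
      for (r in seq_len(nrow(near)))
        free <- free & !(near[r, 1] < cand + len & near[r, 2] > cand)
      cand <- cand[free]
    }
  }
  if (!length(cand)) return(NULL)
  cand[sample.int(length(cand), 1)]
}

#' Simulate a developmental lineage of HMR sets
#'
#' The root stage receives `basal_count` HMRs placed uniformly in the
#' whitelist (sequential placement, non-overlapping). At each transition,
#' every parental HMR is retained with `retention_prob` (identical
#' coordinates) and `gain_per_transition` new HMRs are added; each gain is
#' proximal with probability `p_cluster` — placed uniformly among legal
#' starts with gap at most `prox_window` to a randomly chosen existing HMR
#' of that stage — and uniform otherwise. HMRs within a stage never
#' overlap.
#'
#' @param config a `sim_config`.
#' @param genome a `sim_genome` (regenerated from `config` when `NULL`).
#' @return list of class `sim_lineage`: `sets` (named list of `hmr_set`),
#'   `truth` (per-stage data frames with stage_established and proximal
#'   flags), `retention` (per-transition realized retention counts),
#'   `config`.
#' @export
simulate_lineage_hmrs <- function(config = sim_config(), genome = NULL) {
  if (is.null(genome)) genome <- simulate_genome(config)
  set.seed(.sub_seed(config$seed, "lineage"))
  wl <- genome$whitelist
  seg_by <- split(as.data.frame(wl)[, c("start", "end")], wl$chrom)
  stages <- names(config$lineage)
  root <- stages[is.na(config$lineage)]
  rp <- config$retention_prob
  ret_of <- function(st) if (length(rp) == 1) rp else unname(rp[st])
  sets <- list(); truth <- list(); ret_rows <- list()

  place_stage <- function(df0, n_new, stage, established_from, p_prox) {
    # df0: retained HMRs (chrom, start, end, origin_stage, proximal)
    placed_by <- lapply(names(seg_by), function(cn) {
      m <- as.matrix(df0[df0$chrom == cn, c("start", "end"), drop = FALSE])
      if (!nrow(m)) matrix(numeric(0), 0, 2) else m
    })
    names(placed_by) <- names(seg_by)
    lens <- .rlen(n_new, config)
    prox <- stats::runif(n_new) < p_prox
    new_rows <- vector("list", n_new)
    for (i in seq_len(n_new)) {
      s0 <- NULL; cn <- NULL
      if (prox[i]) {
        n_exist <- sum(vapply(placed_by, nrow, 0L))
        for (a in seq_len(min(20, max(n_exist, 0)))) {
          if (!n_exist) break
          w <- vapply(placed_by, nrow, 0L)
          cn_a <- sample(names(placed_by), 1, prob = pmax(w, 1e-9))
          if (!nrow(placed_by[[cn_a]])) next
          r <- placed_by[[cn_a]][sample.int(nrow(placed_by[[cn_a]]), 1), ]
          s0 <- .proximal_start(lens[i], r[1], r[2], config$prox_window,
                                seg_by[[cn_a]], placed_by[[cn_a]])
          if (!is.null(s0)) { cn <- cn_a; break }
        }
      }
      realized_prox <- !is.null(s0)
      if (is.null(s0)) {   # uniform over chromosomes weighted by capacity
        caps <- vapply(names(seg_by), function(cn2)
          sum(pmax(0, (seg_by[[cn2]]$end - seg_by[[cn2]]$start) - lens[i] + 1)), 0)
        cn <- sample(names(seg_by), 1, prob = caps)
        s0 <- .uniform_start(lens[i], seg_by[[cn]], placed_by[[cn]])
        if (is.null(s0))
          stop("simulate_lineage_hmrs: could not place HMR of length ",
               lens[i], " at stage ", stage)
      }
      placed_by[[cn]] <- rbind(placed_by[[cn]], c(s0, s0 + lens[i]))
      new_rows[[i]] <- data.frame(chrom = cn, start = s0, end = s0 + lens[i],
                                  origin_stage = established_from,
                                  proximal = realized_prox,
                                  stringsAsFactors = FALSE)
    }
    rbind(df0, do.call(rbind, new_rows))
  }

  # root
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      origin_stage = character(), proximal = logical(),
                      stringsAsFactors = FALSE)
  df_root <- place_stage(empty, config$basal_count, root, root, p_prox = 0)
  stage_dfs <- list()
  stage_dfs[[root]] <- df_root
  pending <- stages[!is.na(config$lineage)]
  done <- root
  while (length(pending)) {
    ready <- pending[config$lineage[pending] %in% done]
    for (st in ready) {
      par_df <- stage_dfs[[config$lineage[[st]]]]
      keep <- stats::runif(nrow(par_df)) < ret_of(st)
      ret_rows[[length(ret_rows) + 1]] <- data.frame(
        parent = config$lineage[[st]], child = st,
        n_parent = nrow(par_df), n_retained = sum(keep),
        retention_prob = ret_of(st), stringsAsFactors = FALSE)
      stage_dfs[[st]] <- place_stage(par_df[keep, , drop = FALSE],
                                     config$gain_per_transition, st, st,
                                     p_prox = config$p_cluster)
    }
    done <- c(done, ready)
    pending <- setdiff(pending, ready)
  }
  for (st in stages) {
    d <- stage_dfs[[st]]
    o <- order(d$chrom, d$start, d$end)
    d <- d[o, , drop = FALSE]
    rownames(d) <- NULL
    sets[[st]] <- hmr_set(d[, c("chrom", "start", "end")], label = st,
                          stage = st)
    truth[[st]] <- d
  }
  structure(list(sets = sets, truth = truth,
                 retention = do.call(rbind, ret_rows), config = config,
                 genome = genome),
            class = "sim_lineage")
}

#' Simulate a per-CpG methylation track for one stage
#'
#' CpG positions follow geometric spacing; methylation fractions are drawn
#' from a low-mean Beta inside the stage's HMRs and a high-mean Beta
#' outside, reproducing the bimodal methylation landscape HMR callers
#' assume.
#'
#' @param hmrs the stage's `hmr_set`.
#' @param genome a `sim_genome`.
#' @param config a `sim_config`.
#' @param stage_index integer offset so each stage gets its own substream.
#' @return a `meth_track`.
#' @export
simulate_methylome <- function(hmrs, genome, config = sim_config(),
                               stage_index = 1) {
  set.seed(.sub_seed(config$seed + stage_index, "methylome"))
  res <- lapply(names(genome$sizes), function(cn) {
    L <- genome$sizes[[cn]]
    n_exp <- ceiling(L / config$cpg_spacing * 1.2) + 50
    pos <- cumsum(stats::rgeom(n_exp, 1 / config$cpg_spacing) + 1)
    pos <- pos[pos < L]
    inside <- overlaps_any(data.frame(chrom = cn, start = pos, end = pos + 1),
                           hmrs)
    frac <- numeric(length(pos))
    frac[inside] <- stats::rbeta(sum(inside), config$meth_low[1],
                                 config$meth_low[2])
    frac[!inside] <- stats::rbeta(sum(!inside), config$meth_high[1],
                                  config$meth_high[2])
    data.frame(chrom = cn, pos = pos, frac = frac, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  meth_track(df$chrom, df$pos, df$frac)
}

#' Simulate gene expression with a planted cluster effect
#'
#' Baseline TPM is zero-inflated log-normal; genes whose TAD contains an
#' HMR cluster span are multiplied by `expression_effect`.
#'
#' @param genome a `sim_genome`.
#' @param cluster_spans data frame of cluster spans (chrom, start, end)
#'   for the stage (e.g. from [classify_hmrs()]), or `NULL` for none.
#' @param config a `sim_config`.
#' @return data frame (gene_id, tpm) with attribute `boosted` (logical per
#'   gene).
#' @export
simulate_expression <- function(genome, cluster_spans = NULL,
                                config = sim_config()) {
  set.seed(.sub_seed(config$seed, "expression"))
  ng <- nrow(genome$genes)
  tpm <- stats::rlnorm(ng, config$expr_meanlog, config$expr_sdlog)
  tpm[stats::runif(ng) < config$zero_prob] <- 0
  boosted <- rep(FALSE, ng)
  if (!is.null(cluster_spans) && nrow(cluster_spans)) {
    sp <- interval_set(cluster_spans[, c("chrom", "start", "end")],
                       dedup = FALSE)
    tad_has <- overlaps_any(genome$tads, sp)
    hot <- genome$tads[tad_has, , drop = FALSE]
    if (nrow(hot)) {
      tss_df <- data.frame(chrom = genome$genes$chrom,
                           start = genome$genes$tss,
                           end = genome$genes$tss + 1)
      boosted <- overlaps_any(tss_df, hot)
      tpm[boosted] <- tpm[boosted] * config$expression_effect
    }
  }
  structure(data.frame(gene_id = genome$genes$gene_id, tpm = tpm,
                       stringsAsFactors = FALSE),
            boosted = boosted)
}
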