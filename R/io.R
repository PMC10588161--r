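#' @title Readers and writers for BED, bedGraph, chrom.sizes and gene tables
#' @description
#' All files are plain tab-separated text without headers (BED dialects) or
#' with a header line (gene and expression tables). Read/write round trips
#' preserve coordinates and labels exactly.
#' @name io
NULL

.read_tsv_lines <- function(path, min_fields) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad))
    stop(sprintf("%s: line %d has %d field(s), expected >= %d",
                 path, bad[1], nf[bad[1]], min_fields))
  fields
}

#' Read a BED3/BED4/BED6 file
#'
#' @param path file path.
#' @param label dataset label attached to the result (defaults to file stem).
#' @return an `interval_set`; unsorted input is sorted with a message.
#' @export
read_bed <- function(path, label = NULL) {
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  f <- .read_tsv_lines(path, 3L)
  if (!length(f))
    return(interval_set(data.frame(chrom = character(), start = numeric(),
                                   end = numeric()), label = label))
  chrom <- vapply(f, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("%s: line %d: invalid BED coordinates", path, bad[1]))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  nf <- lengths(f)
  if (all(nf >= 4L)) df$name <- vapply(f, `[`, "", 4L)
  if (all(nf >= 6L)) {
    df$strand <- vapply(f, `[`, "", 6L)
    if (!all(df$strand %in% c("+", "-", ".")))
      stop(path, ": invalid strand field")
    df$strand[df$strand == "."] <- "*"
  }
  if (is.unsorted(order(df$chrom, df$start, df$end)))
    message(path, ": input not sorted; sorting")
  interval_set(df, label = label)
}

#' Write an interval set as BED
#'
#' Emits BED3, BED4 (when `name` present) or BED6 (when `strand` present;
#' the score column is taken from `n_members` if available, else 0).
#'
#' @param set an `interval_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(set, path) {
  df <- as.data.frame(set)
  cols <- c("chrom", "start", "end")
  if (!is.null(df$name)) cols <- c(cols, "name")
  if (!is.null(df$strand)) {
    if (is.null(df$name)) df$name <- "."
    df$score <- if (!is.null(df$n_members)) df$n_members else 0L
    s <- df$strand
    s[s == "*"] <- "."
    df$strand <- s
    cols <- c("chrom", "start", "end", "name", "score", "strand")
  }
  lines <- do.call(paste, c(lapply(cols, function(cl) {
    v <- df[[cl]]
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else v
  }), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph methylation track
#'
#' Expects columns chrom, start, end, value with the value being the
#' methylation fraction in `[0, 1]` at the CpG whose interval starts at
#' `start` (CpG position = interval start, 0-based).
#'
#' @param path file path.
#' @return a `meth_track`: data frame (chrom, pos, frac), sorted, positions
#'   strictly increasing per chromosome.
#' @export
read_bedgraph <- function(path) {
  f <- .read_tsv_lines(path, 4L)
  if (!length(f)) return(meth_track(character(), numeric(), numeric()))
  chrom <- vapply(f, `[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  frac <- suppressWarnings(as.numeric(vapply(f, `[`, "", 4L)))
  bad <- which(is.na(pos) | is.na(frac) | frac < 0 | frac > 1)
  if (length(bad))
    stop(sprintf("%s: line %d: invalid bedGraph record", path, bad[1]))
  meth_track(chrom, pos, frac)
}

#' Construct a per-CpG methylation track
#'
#' @param chrom,pos,frac chromosome, 0-based CpG position, methylation
#'   fraction in `[0, 1]`.
#' @param coverage optional read coverage per CpG.
#' @return data frame of class `meth_track`, sorted by (chrom, pos).
#' @export
meth_track <- function(chrom, pos, frac, coverage = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   frac = as.numeric(frac), stringsAsFactors = FALSE)
  if (!is.null(coverage)) df$coverage <- as.numeric(coverage)
  if (nrow(df)) {
    if (any(df$frac < 0 | df$frac > 1))
      stop("meth_track: fraction outside [0, 1]")
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (any(same & diff(df$pos) <= 0))
      stop("meth_track: positions not strictly increasing within chromosome")
  }
  rownames(df) <- NULL
  structure(df, class = c("meth_track", "data.frame"))
}

#' Write a methylation track as bedGraph
#' @param track a `meth_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", track$chrom,
                   format(track$pos, scientific = FALSE, trim = TRUE),
                   format(track$pos + 1, scientific = FALSE, trim = TRUE),
                   format(track$frac, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a chrom.sizes file (chrom <tab> length)
#' @param path file path.
#' @return a `chrom_sizes` vector.
#' @export
read_chrom_sizes <- function(path) {
  f <- .read_tsv_lines(path, 2L)
  chrom_sizes(vapply(f, `[`, "", 1L),
              suppressWarnings(as.numeric(vapply(f, `[`, "", 2L))))
}

#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%s", names(sizes),
                     format(as.numeric(sizes), scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Construct a gene model table
#'
#' One row per gene. The transcription start site is elected by strand:
#' `start` for `+` genes, `end` for `-` genes. Exon coordinates are stored
#' as comma-separated absolute positions and must lie within the gene body.
#'
#' @param gene_id,chrom,strand,start,end vectors; strand must be `+` or `-`.
#' @param exon_starts,exon_ends lists (or comma-strings) of exon coordinates.
#' @param tpm optional expression values.
#' @return data frame of class `gene_table` with derived `tss` column.
#' @export
gene_table <- function(gene_id, chrom, strand, start, end,
                       exon_starts = NULL, exon_ends = NULL, tpm = NULL) {
  .join <- function(x, n) {
    if (is.null(x)) return(rep("", n))
    if (is.list(x))
      vapply(x, function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                                  collapse = ","), "")
    else as.character(x)
  }
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   strand = as.character(strand), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  df$exon_starts <- .join(exon_starts, nrow(df))
  df$exon_ends <- .join(exon_ends, nrow(df))
  if (!is.null(tpm)) df$tpm <- as.numeric(tpm)
  if (nrow(df)) {
    if (!all(df$strand %in% c("+", "-")))
      stop("gene_table: strand must be '+' or '-' (gene ",
           df$gene_id[which(!df$strand %in% c("+", "-"))[1]], ")")
    if (any(df$start < 0 | df$start >= df$end))
      stop("gene_table: invalid gene body coordinates")
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  structure(df, class = c("gene_table", "data.frame"))
}

#' Exons of a gene table as one interval set
#' @param genes a `gene_table`.
#' @return an `interval_set` of exons (may be empty).
#' @export
gene_exons <- function(genes) {
  es <- strsplit(genes$exon_starts, ",", fixed = TRUE)
  ee <- strsplit(genes$exon_ends, ",", fixed = TRUE)
  n <- lengths(es)
  if (!sum(n))
    return(interval_set(data.frame(chrom = character(), start = numeric(),
                                   end = numeric()), label = "exons"))
  df <- data.frame(chrom = rep(genes$chrom, n),
                   start = as.numeric(unlist(es)),
                   end = as.numeric(unlist(ee)),
                   name = rep(genes$gene_id, n),
                   stringsAsFactors = FALSE)
  ok <- df$start >= rep(genes$start, n) & df$end <= rep(genes$end, n)
  if (!all(ok)) stop("gene_exons: exon outside gene body (gene ",
                     df$name[which(!ok)[1]], ")")
  interval_set(df, label = "exons", dedup = FALSE)
}

#' Read a gene table (TSV with header)
#'
#' Columns: gene_id, chrom, strand, start, end, exon_starts, exon_ends and
#' optionally tpm. Exon columns hold comma-separated coordinates ("" for
#' none).
#'
#' @param path file path.
#' @return a `gene_table`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df)))
    stop(path, ": gene table must have columns ", paste(need, collapse = ", "))
  gene_table(df$gene_id, df$chrom, df$strand,
             as.numeric(df$start), as.numeric(df$end),
             exon_starts = if (!is.null(df$exon_starts)) df$exon_starts,
             exon_ends = if (!is.null(df$exon_ends)) df$exon_ends,
             tpm = if (!is.null(df$tpm)) as.numeric(df$tpm))
}

#' @export
write_gene_table <- function(genes, path) {
  df <- as.data.frame(genes)
  df$tss <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table (gene_id <tab> tpm, with header)
#' @param path file path.
#' @return data frame (gene_id, tpm).
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tpm") %in% names(df)))
    stop(path, ": expression table must have columns gene_id, tpm")
  if (any(df$tpm < 0)) stop(path, ": negative TPM")
  df[, c("gene_id", "tpm")]
}

#' Average expression replicates into one TPM column
#' @param df data frame with `gene_id` and two or more `tpm_*` columns.
#' @return data frame (gene_id, tpm) with the row mean of the replicates.
#' @export
average_replicates <- function(df) {
  reps <- grep("^tpm", names(df), value = TRUE)
  if (length(reps) < 1) stop("average_replicates: no tpm columns")
  data.frame(gene_id = df$gene_id,
             tpm = rowMeans(df[, reps, drop = FALSE]),
             stringsAsFactors = FALSE)
}
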