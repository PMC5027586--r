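#' @importFrom data.table data.table fread fwrite setorder as.data.table :=
#' @importFrom stats setNames
NULL

# ---- gene tables -----------------------------------------------------------

#' Build a gene table
#'
#' Genes are kept in a plain data.table with 0-based half-open coordinates,
#' the convention used throughout the package (BED-like). TSS/TTS are derived
#' from the strand.
#'
#' @param gene_id character ids (unique).
#' @param chrom chromosome names.
#' @param start,end 0-based half-open spans.
#' @param strand `"+"` or `"-"`.
#' @return data.table with class `gene_table` attribute columns
#'   `gene_id, chrom, start, end, strand`.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand) {
  if (anyDuplicated(gene_id)) stop("duplicate gene ids")
  if (any(end <= start)) stop("gene end must exceed start")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  g <- data.table(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  start = as.integer(start), end = as.integer(end),
                  strand = as.character(strand))
  setorder(g, chrom, start)
  g[]
}

#' Transcription start sites of a gene table
#' @param genes a gene table (see [gene_table()]).
#' @return integer vector of 0-based TSS positions (rightmost coordinate for
#'   minus-strand genes).
#' @export
gene_tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)

#' Transcription termination sites of a gene table
#' @inheritParams gene_tss
#' @return integer vector of 0-based TTS positions.
#' @export
gene_tts <- function(genes) ifelse(genes$strand == "+", genes$end, genes$start)

# ---- bedGraph --------------------------------------------------------------

#' Write one strand of binned coverage as bedGraph
#'
#' Runs of equal adjacent bin values are merged and zero runs are omitted,
#' the usual sparse bedGraph layout. Coordinates are 0-based half-open.
#'
#' @param bins named list of per-bin count vectors (one per chromosome).
#' @param bin_width bin width in bp.
#' @param path output file.
#' @export
write_bedgraph <- function(bins, bin_width, path) {
  out <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    v <- bins[[i]]
    r <- rle(as.numeric(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    out[[i]] <- data.table(chrom = names(bins)[i],
                           start = starts[keep] * bin_width,
                           end = ends[keep] * bin_width,
                           value = r$values[keep])
  }
  dt <- data.table::rbindlist(out)
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file onto a fixed bin grid
#'
#' Strict parser: every interval must be aligned to the bin grid (start and
#' end multiples of `bin_width`), within the declared chromosome lengths and
#' non-inverted; violations are reported with their line number.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param bin_width grid width in bp.
#' @param chrom_lengths named vector of chromosome lengths in bp
#'   (grid-aligned).
#' @return named list of per-bin numeric vectors.
#' @export
read_bedgraph <- function(path, bin_width, chrom_lengths) {
  if (!file.exists(path)) stop("no such file: ", path)
  bins <- lapply(chrom_lengths, function(len) numeric(len / bin_width))
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(dt) == 0) return(bins)
  if (ncol(dt) < 4) stop("bedGraph ", path, ": fewer than 4 columns")
  setnames_bg <- c("chrom", "start", "end", "value")
  data.table::setnames(dt, seq_len(4), setnames_bg)
  bad <- function(cond, what) {
    if (any(cond)) stop("bedGraph ", path, " line ", which(cond)[1], ": ", what)
  }
  bad(!dt$chrom %in% names(chrom_lengths), "unknown chromosome")
  bad(dt$end <= dt$start, "inverted or empty interval")
  bad(dt$start %% bin_width != 0 | dt$end %% bin_width != 0,
      paste0("interval not aligned to the ", bin_width, "-bp bin grid"))
  bad(dt$end > chrom_lengths[dt$chrom], "interval beyond chromosome end")
  bad(dt$value < 0, "negative coverage value")
  for (cur in unique(dt$chrom)) {
    d <- dt[dt$chrom == cur]
    first <- d$start / bin_width + 1L
    n <- d$end / bin_width - d$start / bin_width
    idx <- sequence(n, from = first)
    bins[[cur]][idx] <- rep(d$value, n)
  }
  bins
}

#' Write a full stranded library as a pair of bedGraph files
#' @param cov a `StrandedCoverage`.
#' @param prefix path prefix; files `<prefix>_plus.bedgraph` and
#'   `<prefix>_minus.bedgraph` are written.
#' @return character vector of the two paths.
#' @export
write_coverage_bedgraphs <- function(cov, prefix) {
  paths <- paste0(prefix, c("_plus.bedgraph", "_minus.bedgraph"))
  write_bedgraph(cov$plus, cov$bin_width, paths[1])
  write_bedgraph(cov$minus, cov$bin_width, paths[2])
  paths
}

#' Read a stranded library from a pair of bedGraph files
#' @param plus_path,minus_path bedGraph files for the two strands.
#' @inheritParams read_bedgraph
#' @param library_id label for the library.
#' @return a `StrandedCoverage`.
#' @export
read_coverage_bedgraphs <- function(plus_path, minus_path, bin_width,
                                    chrom_lengths, library_id = "lib") {
  stranded_coverage(read_bedgraph(plus_path, bin_width, chrom_lengths),
                    read_bedgraph(minus_path, bin_width, chrom_lengths),
                    bin_width, library_id)
}

# ---- BED -------------------------------------------------------------------

#' Read a BED file (3-6 columns, 0-based half-open)
#'
#' @param path BED file.
#' @return data.table with columns `chrom, start, end` and, when present,
#'   `name, score, strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(dt) == 0)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  if (ncol(dt) < 3) stop("BED ", path, ": fewer than 3 columns")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6)), nm[seq_len(min(ncol(dt), 6))])
  if (!is.numeric(dt$start) || !is.numeric(dt$end))
    stop("BED ", path, ": non-numeric coordinates")
  if (any(dt$end <= dt$start))
    stop("BED ", path, " line ", which(dt$end <= dt$start)[1],
         ": inverted or empty interval")
  if ("strand" %in% names(dt) && !all(dt$strand %in% c("+", "-", ".")))
    stop("BED ", path, " line ",
         which(!dt$strand %in% c("+", "-", "."))[1], ": bad strand")
  dt
}

#' Write intervals as BED6
#' @param dt data.table/data.frame with `chrom, start, end` and optionally
#'   `name, score, strand`.
#' @param path output file.
#' @export
write_bed <- function(dt, path) {
  dt <- as.data.table(dt)
  n <- nrow(dt)
  out <- data.table(
    chrom = dt$chrom, start = as.integer(dt$start), end = as.integer(dt$end),
    name = if ("name" %in% names(dt)) dt$name else paste0("feature_", seq_len(max(n, 0))),
    score = if ("score" %in% names(dt)) dt$score else 0L,
    strand = if ("strand" %in% names(dt)) dt$strand else ".")
  setorder(out, chrom, start)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---- GFF3 / BED12 gene annotation -----------------------------------------

#' Write a gene table as GFF3 (1-based closed coordinates)
#' @param genes a gene table.
#' @param path output file.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tnascentr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Only `gene` features are kept; 1-based closed GFF coordinates are
#' converted to the package's 0-based half-open convention on read.
#'
#' @param path GFF3 file.
#' @return a gene table.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  keep <- !grepl("^#", raw) & nzchar(raw)
  if (!any(keep)) stop("GFF3 ", path, ": no feature lines")
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nfield <- lengths(fields)
  if (any(nfield != 9))
    stop("GFF3 ", path, " line ", lineno[which(nfield != 9)[1]],
         ": expected 9 tab-separated fields")
  m <- do.call(rbind, fields)
  is_gene <- m[, 3] == "gene"
  m <- m[is_gene, , drop = FALSE]
  ids <- sub("^.*ID=([^;]+).*$", "\\1", m[, 9])
  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
  if (any(is.na(start1) | is.na(end1)))
    stop("GFF3 ", path, ": non-numeric coordinates")
  gene_table(ids, m[, 1], start1 - 1L, end1, m[, 7])
}

#' Write a gene table as BED12
#' @param genes a gene table.
#' @param path output file.
#' @export
write_bed12_genes <- function(genes, path) {
  out <- data.table(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = 0L, strand = genes$strand,
    thickStart = genes$start, thickEnd = genes$end, itemRgb = "0,0,0",
    blockCount = 1L, blockSizes = paste0(genes$end - genes$start, ","),
    blockStarts = "0,")
  setorder(out, chrom, start)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
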