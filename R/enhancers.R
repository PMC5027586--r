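#' @importFrom IRanges IRanges findOverlaps countOverlaps
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# GRanges from a 0-based half-open table (internally 1-based closed).
as_granges0 <- function(dt) {
  GRanges(dt$chrom, IRanges(start = dt$start + 1L, end = dt$end))
}


# seqlevel-mismatch-quiet overlap helpers (disjoint chromosome sets between
# two tables are legitimate here, e.g. an empty or single-chromosome set)
count_overlaps0 <- function(a, b) suppressWarnings(countOverlaps(a, b))
find_overlaps0 <- function(a, b, ...) suppressWarnings(findOverlaps(a, b, ...))

empty_enhancer_table <- function() {
  data.table(enh_id = character(), kind = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             host_gene = character(), plus_start = integer(),
             plus_end = integer(), minus_start = integer(),
             minus_end = integer())
}

check_sorted <- function(transcripts) {
  if (nrow(transcripts) > 1) {
    o <- order(transcripts$chrom, transcripts$start)
    if (!identical(o, seq_len(nrow(transcripts))))
      stop("transcripts must be sorted by (chrom, start)")
  }
}

#' Call intergenic (bidirectional) eRNA enhancers
#'
#' Candidate transcripts overlap no annotated gene and lie strictly more
#' than `min_tts_distance` (both endpoints) from every gene TTS. Pairs of
#' opposite-strand candidates whose interval gap is at most `max_pair_gap`
#' (overlapping intervals count as gap 0) form one enhancer spanning the
#' union of the pair; each transcript joins at most one enhancer, conflicts
#' resolved by greedy nearest-pairing with ties to the leftmost partner.
#'
#' @param transcripts data.table from [detect_transcripts()], sorted.
#' @param genes a gene table.
#' @param max_pair_gap maximum gap between the opposing transcripts (bp).
#' @param min_tts_distance exclusion distance from every gene TTS (bp,
#'   strict).
#' @return enhancer catalog rows of kind `"intergenic"`.
#' @export
call_intergenic <- function(transcripts, genes, max_pair_gap = 1000,
                            min_tts_distance = 3000) {
  check_sorted(transcripts)
  if (nrow(transcripts) == 0) return(empty_enhancer_table())
  # candidates: no gene overlap, > min_tts_distance from every TTS
  ovl <- if (nrow(genes)) count_overlaps0(as_granges0(transcripts),
                                        as_granges0(genes)) else
    rep(0L, nrow(transcripts))
  tts <- gene_tts(genes)
  far <- vapply(seq_len(nrow(transcripts)), function(i) {
    t_ <- transcripts[i]
    same <- genes$chrom == t_$chrom
    if (!any(same)) return(TRUE)
    d <- pmin(abs(t_$start - tts[same]), abs(t_$end - tts[same]))
    all(d > min_tts_distance)
  }, TRUE)
  cand <- transcripts[ovl == 0 & far]
  if (nrow(cand) == 0) return(empty_enhancer_table())

  plus <- which(cand$strand == "+")
  minus <- which(cand$strand == "-")
  pairs <- list()
  for (i in plus) for (j in minus) {
    if (cand$chrom[i] != cand$chrom[j]) next
    gap <- max(cand$start[i] - cand$end[j], cand$start[j] - cand$end[i], 0)
    if (gap <= max_pair_gap)
      pairs[[length(pairs) + 1L]] <- data.table(
        p = i, m = j, gap = gap, left = min(cand$start[i], cand$start[j]))
  }
  if (!length(pairs)) return(empty_enhancer_table())
  pairs <- data.table::rbindlist(pairs)
  setorder(pairs, gap, left, p, m)
  used <- logical(nrow(cand))
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$p[r]; j <- pairs$m[r]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    out[[length(out) + 1L]] <- data.table(
      kind = "intergenic", chrom = cand$chrom[i],
      start = min(cand$start[i], cand$start[j]),
      end = max(cand$end[i], cand$end[j]),
      strand = ".", host_gene = NA_character_,
      plus_start = cand$start[i], plus_end = cand$end[i],
      minus_start = cand$start[j], minus_end = cand$end[j])
  }
  res <- data.table::rbindlist(out)
  setorder(res, chrom, start)
  res[, enh_id := sprintf("intergenic_%03d", .I)]
  data.table::setcolorder(res, "enh_id")
  res[]
}

#' Call intragenic (antisense) eRNA enhancers
#'
#' A transcript fully inside a gene span, on the strand opposite to that
#' gene, with length inside `length_range` and overlapping at least 1 bp of
#' an H3K4me2 interval becomes one enhancer. A transcript contained in two
#' overlapping genes of opposite strands is ambiguous and rejected with a
#' message.
#'
#' @inheritParams call_intergenic
#' @param h3k4me2 data.table of `chrom, start, end` intervals (sorted).
#' @param length_range inclusive transcript length gate in bp.
#' @return enhancer catalog rows of kind `"intragenic"`.
#' @export
call_intragenic <- function(transcripts, genes, h3k4me2,
                            length_range = c(150, 500)) {
  check_sorted(transcripts)
  if (nrow(transcripts) == 0 || nrow(genes) == 0)
    return(empty_enhancer_table())
  tx_gr <- as_granges0(transcripts)
  within <- find_overlaps0(tx_gr, as_granges0(genes), type = "within")
  k4_hit <- if (nrow(h3k4me2))
    count_overlaps0(tx_gr, as_granges0(h3k4me2)) > 0 else
    rep(FALSE, nrow(transcripts))
  out <- list()
  for (i in unique(queryHits(within))) {
    hosts <- subjectHits(within)[queryHits(within) == i]
    if (length(unique(genes$strand[hosts])) > 1) {
      message("ambiguous intragenic transcript at ", transcripts$chrom[i],
              ":", transcripts$start[i], "-", transcripts$end[i],
              " (inside overlapping genes of opposite strands); rejected")
      next
    }
    opp <- hosts[genes$strand[hosts] != transcripts$strand[i]]
    if (length(opp) == 0) next
    len <- transcripts$end[i] - transcripts$start[i]
    if (len < length_range[1] || len > length_range[2]) next
    if (!k4_hit[i]) next
    out[[length(out) + 1L]] <- data.table(
      kind = "intragenic", chrom = transcripts$chrom[i],
      start = transcripts$start[i], end = transcripts$end[i],
      strand = transcripts$strand[i], host_gene = genes$gene_id[opp[1]],
      plus_start = NA_integer_, plus_end = NA_integer_,
      minus_start = NA_integer_, minus_end = NA_integer_)
  }
  if (!length(out)) return(empty_enhancer_table())
  res <- data.table::rbindlist(out)
  setorder(res, chrom, start)
  res[, enh_id := sprintf("intragenic_%03d", .I)]
  data.table::setcolorder(res, "enh_id")
  res[]
}

#' Quantify eRNA enhancer transcription across libraries
#'
#' Intergenic enhancers are counted on both strands over the span;
#' intragenic enhancers only on the antisense (eRNA) strand, to keep the
#' host gene's transcription out of the count.
#'
#' @param enhancers catalog from [call_intergenic()] / [call_intragenic()]
#'   (rows may mix kinds).
#' @param coverages list of `StrandedCoverage`, one per library.
#' @param conditions condition label per library.
#' @return a [feature_counts()] object (lengths = span widths).
#' @export
quantify_enhancers <- function(enhancers, coverages, conditions) {
  if (length(coverages) != length(conditions))
    stop("conditions must match the number of coverages")
  n <- nrow(enhancers)
  counts <- matrix(0L, nrow = n, ncol = length(coverages),
                   dimnames = list(enhancers$enh_id,
                                   vapply(coverages, `[[`, "", "library_id")))
  for (j in seq_along(coverages)) {
    cov <- coverages[[j]]
    for (i in seq_len(n)) {
      e <- enhancers[i]
      counts[i, j] <- if (e$kind == "intergenic")
        as.integer(round(
          interval_tags(cov, e$chrom, e$start, e$end, "+") +
          interval_tags(cov, e$chrom, e$start, e$end, "-")))
      else
        as.integer(round(interval_tags(cov, e$chrom, e$start, e$end, e$strand)))
    }
  }
  feature_counts(counts, vapply(coverages, `[[`, 0, "total_tags"),
                 pmax(enhancers$end - enhancers$start, 1L), conditions,
                 feature_ids = enhancers$enh_id)
}

#' Overlap of enhancer regulation classes between timepoints
#'
#' Set arithmetic by enhancer id over the same catalog: for each class,
#' how many enhancers share the class at both timepoints and which are
#' unique to each.
#'
#' @param classes_a,classes_b data.tables with `enh_id` and `class` computed
#'   on the same catalog at two timepoints.
#' @return data.table with per-class counts and shared fractions
#'   (`frac_shared_of_a`, `frac_shared_of_b`; NA when a side is empty).
#' @export
enhancer_timepoint_overlap <- function(classes_a, classes_b) {
  if (!setequal(classes_a$enh_id, classes_b$enh_id))
    stop("timepoint class tables cover different enhancer catalogs")
  classes <- union(unique(classes_a$class), unique(classes_b$class))
  out <- lapply(classes, function(cl) {
    a <- classes_a$enh_id[classes_a$class == cl]
    b <- classes_b$enh_id[classes_b$class == cl]
    s <- length(intersect(a, b))
    data.table(class = cl, n_a = length(a), n_b = length(b), n_shared = s,
               frac_shared_of_a = if (length(a)) s / length(a) else NA_real_,
               frac_shared_of_b = if (length(b)) s / length(b) else NA_real_)
  })
  data.table::rbindlist(out)
}

#' Post-hoc validation of an enhancer catalog against its definitions
#'
#' Independent brute-force checker (plain loops): intergenic spans must
#' overlap no gene and keep > `min_tts_distance` from every TTS; intragenic
#' members must sit inside their host, antisense, length-gated and on an
#' H3K4me2 interval.
#'
#' @param enhancers an enhancer catalog.
#' @param genes a gene table.
#' @param h3k4me2 H3K4me2 intervals.
#' @param min_tts_distance,length_range the gates used for calling.
#' @return TRUE invisibly; errors on the first violation.
#' @export
validate_enhancers <- function(enhancers, genes, h3k4me2,
                               min_tts_distance = 3000,
                               length_range = c(150, 500)) {
  tts <- gene_tts(genes)
  for (i in seq_len(nrow(enhancers))) {
    e <- enhancers[i]
    if (e$kind == "intergenic") {
      for (j in seq_len(nrow(genes))) {
        if (genes$chrom[j] != e$chrom) next
        if (e$start < genes$end[j] && genes$start[j] < e$end)
          stop(e$enh_id, " overlaps gene ", genes$gene_id[j])
        if (min(abs(e$start - tts[j]), abs(e$end - tts[j])) <= min_tts_distance)
          stop(e$enh_id, " within ", min_tts_distance, " bp of a TTS")
      }
    } else {
      g <- genes[genes$gene_id == e$host_gene]
      if (nrow(g) != 1 || e$start < g$start || e$end > g$end)
        stop(e$enh_id, " not inside its host gene")
      if (e$strand == g$strand) stop(e$enh_id, " not antisense to host")
      len <- e$end - e$start
      if (len < length_range[1] || len > length_range[2])
        stop(e$enh_id, " length outside gate")
      hit <- FALSE
      for (j in seq_len(nrow(h3k4me2)))
        if (h3k4me2$chrom[j] == e$chrom && h3k4me2$start[j] < e$end &&
            e$start < h3k4me2$end[j]) hit <- TRUE
      if (!hit) stop(e$enh_id, " lacks H3K4me2 overlap")
    }
  }
  invisible(TRUE)
}
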