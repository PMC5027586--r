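#' Parameters for de novo nascent-transcript detection
#'
#' The detection rule follows the GRO-seq convention: a transcript opens
#' where read density rises `init_fold`-fold (default 3) over the previous
#' `init_window` (default 200 bp) region, and an internal density step of
#' `body_fold` (default 3) over the running body density splits the unit
#' into a new transcript. Closure semantics, unstated by that rule, are
#' explicit here: a window continues an open transcript only when its
#' density reaches both `closure_frac` of the running body density and
#' `min_density` (the latter capped at the running body density itself, so
#' genuinely weak transcripts are not torn apart); a low-density run longer
#' than `max_gap` bp closes the transcript at the last qualifying window.
#' Calls shorter than `min_length` or with body density below `min_density`
#' are discarded. Boundaries are refined to bin resolution by trimming
#' leading/trailing bins that fail the same continuation rule.
#'
#' @param init_window initiation window in bp (positive multiple of the
#'   coverage bin width).
#' @param init_fold fold increase over the previous window that opens a
#'   transcript (inclusive, > 1).
#' @param body_fold fold increase over the running body density that splits
#'   a transcript (inclusive, > 1).
#' @param min_density density floor in tags/kb: gates initiation, window
#'   continuation (capped at the running body density) and the final call's
#'   body density.
#' @param min_length minimum transcript length in bp.
#' @param max_gap maximum low-density run in bp before closure.
#' @param closure_frac fraction of the running body density below which a
#'   window counts as a gap.
#' @return a validated `detection_params` list.
#' @export
detection_params <- function(init_window = 200, init_fold = 3, body_fold = 3,
                             min_density = 50, min_length = 150,
                             max_gap = 1000, closure_frac = 0.1) {
  if (init_fold <= 1 || body_fold <= 1) stop("fold thresholds must exceed 1")
  if (init_window <= 0) stop("init_window must be positive")
  if (closure_frac <= 0 || closure_frac >= 1) stop("closure_frac must be in (0, 1)")
  if (min_density < 0 || min_length < 0 || max_gap < 0)
    stop("min_density, min_length and max_gap must be non-negative")
  structure(list(init_window = init_window, init_fold = init_fold,
                 body_fold = body_fold, min_density = min_density,
                 min_length = min_length, max_gap = max_gap,
                 closure_frac = closure_frac),
            class = "detection_params")
}

# Scan one strand's bin vector (already oriented 5' -> 3') and return
# transcripts as (start_bin, end_bin) pairs in scan orientation plus stats.
scan_strand <- function(bins, bin_width, p) {
  k <- p$init_window / bin_width
  if (k != round(k))
    stop("init_window must be a multiple of the coverage bin width")
  k <- as.integer(k)
  n_tiles <- length(bins) %/% k
  if (n_tiles == 0) return(list())
  tile_tags <- vapply(seq_len(n_tiles), function(i)
    sum(bins[((i - 1L) * k + 1L):(i * k)]), 0)
  tile_dens <- tile_tags / p$init_window * 1000

  out <- list()
  open <- FALSE
  start_tile <- last_good <- 0L
  cum_tags <- cum_bp <- 0
  gap_bp <- gap_tags <- 0

  open_at <- function(i) {
    open <<- TRUE; start_tile <<- i; last_good <<- i
    cum_tags <<- tile_tags[i]; cum_bp <<- p$init_window
    gap_bp <<- 0; gap_tags <<- 0
  }
  emit <- function() {
    first_bin <- (start_tile - 1L) * k + 1L
    last_bin <- last_good * k
    body <- cum_tags / cum_bp * 1000
    # bin-level boundary refinement, same continuation rule as the scan
    thr <- max(p$closure_frac * body, min(p$min_density, body))
    lo <- first_bin; hi <- last_bin
    while (lo <= hi && bins[lo] / bin_width * 1000 < thr) lo <- lo + 1L
    while (hi >= lo && bins[hi] / bin_width * 1000 < thr) hi <- hi - 1L
    if (hi >= lo) {
      n_tags <- sum(bins[lo:hi])
      len <- (hi - lo + 1L) * bin_width
      dens <- n_tags / len * 1000
      if (len >= p$min_length && dens >= p$min_density)
        out[[length(out) + 1L]] <<- list(start_bin = lo, end_bin = hi,
                                         n_tags = n_tags, body_density = dens)
    }
    open <<- FALSE
  }

  for (i in seq_len(n_tiles)) {
    d <- tile_dens[i]
    if (!open) {
      prev <- if (i > 1L) tile_dens[i - 1L] else 0
      if (d > 0 && d >= p$init_fold * prev && d >= p$min_density) open_at(i)
    } else {
      body <- cum_tags / cum_bp * 1000
      if (d >= p$body_fold * body) {
        emit()
        open_at(i)
      } else if (d < max(p$closure_frac * body, min(p$min_density, body))) {
        gap_bp <- gap_bp + p$init_window
        gap_tags <- gap_tags + tile_tags[i]
        if (gap_bp > p$max_gap) emit()
      } else {
        # resume: absorb any pending gap tiles into the body
        cum_tags <- cum_tags + gap_tags + tile_tags[i]
        cum_bp <- cum_bp + gap_bp + p$init_window
        gap_bp <- 0; gap_tags <- 0
        last_good <- i
      }
    }
  }
  if (open) emit()
  out
}

#' De novo nascent-transcript detection from stranded coverage
#'
#' Scans each strand 5' to 3' (minus-strand bins are reversed before the
#' scan) applying the initiation / bodyFold / closure rules of
#' [detection_params()].
#'
#' @param cov a `StrandedCoverage`.
#' @param params a [detection_params()].
#' @return data.table of transcripts with columns
#'   `chrom, start, end, strand, n_tags, body_density` (0-based half-open,
#'   density in tags/kb), sorted by chromosome then start.
#' @export
detect_transcripts <- function(cov, params = detection_params()) {
  stopifnot(is_stranded_coverage(cov), inherits(params, "detection_params"))
  w <- cov$bin_width
  rows <- list()
  for (chrom in names(cov$plus)) {
    nb <- length(cov$plus[[chrom]])
    for (strand in c("+", "-")) {
      bins <- if (strand == "+") cov$plus[[chrom]] else rev(cov$minus[[chrom]])
      for (tr in scan_strand(bins, w, params)) {
        if (strand == "+") {
          start <- (tr$start_bin - 1L) * w; end <- tr$end_bin * w
        } else {
          # reverse mapping: scan bin j is original bin nb - j + 1
          start <- (nb - tr$end_bin) * w; end <- (nb - tr$start_bin + 1L) * w
        }
        rows[[length(rows) + 1L]] <- data.table(
          chrom = chrom, start = start, end = end, strand = strand,
          n_tags = tr$n_tags, body_density = tr$body_density)
      }
    }
  }
  if (!length(rows))
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), n_tags = numeric(),
                      body_density = numeric()))
  res <- data.table::rbindlist(rows)
  setorder(res, chrom, start, end, strand)
  res[]
}

#' Write detected transcripts as BED6
#'
#' Score is the body density in tags/kb times 1000, integer-truncated.
#'
#' @param transcripts output of [detect_transcripts()].
#' @param path output file.
#' @export
write_transcripts_bed <- function(transcripts, path) {
  dt <- data.table(chrom = transcripts$chrom, start = transcripts$start,
                   end = transcripts$end,
                   name = sprintf("tx_%05d", seq_len(nrow(transcripts))),
                   score = as.integer(trunc(transcripts$body_density * 1000)),
                   strand = transcripts$strand)
  write_bed(dt, path)
}

#' Promoter-proximal pausing index of a gene
#'
#' PPI is the ratio of sense-strand promoter-window density to gene-body
#' density. The promoter window defaults to `[TSS - 50, TSS + 250)` and the
#' body to `[TSS + body_offset, TTS)`, mirrored for minus-strand genes.
#'
#' @param gene one-row gene table (or list with `gene_id, chrom, start,
#'   end, strand`).
#' @param cov a `StrandedCoverage`.
#' @param promoter_window bp offsets of the promoter window relative to the
#'   TSS in transcription direction.
#' @param body_offset bp downstream of the TSS where the body starts.
#' @return list with `gene_id`, `promoter_density`, `body_density`, `ppi`
#'   (NA when undefined) and `defined` (FALSE when body density is 0).
#' @export
pausing_index <- function(gene, cov, promoter_window = c(-50, 250),
                          body_offset = 250) {
  len <- gene$end - gene$start
  if (len <= body_offset + cov$bin_width)
    stop("gene ", gene$gene_id, " is shorter than the PPI windows")
  if (gene$strand == "+") {
    tss <- gene$start
    prom <- c(tss + promoter_window[1], tss + promoter_window[2])
    body <- c(tss + body_offset, gene$end)
  } else {
    tss <- gene$end
    prom <- c(tss - promoter_window[2], tss - promoter_window[1])
    body <- c(gene$start, tss - body_offset)
  }
  prom[1] <- max(prom[1], 0)
  pd <- interval_density(cov, gene$chrom, prom[1], prom[2], gene$strand)
  bd <- interval_density(cov, gene$chrom, body[1], body[2], gene$strand)
  list(gene_id = gene$gene_id, promoter_density = pd, body_density = bd,
       ppi = if (bd > 0) pd / bd else NA_real_, defined = bd > 0)
}

#' Compare PPI distributions between gene groups
#'
#' Kruskal-Wallis test across all groups followed by Dunn's post-test for
#' every pair, with multiplicity correction; undefined PPIs (zero body
#' density) are excluded before testing.
#'
#' @param groups named list of numeric PPI vectors (NAs dropped).
#' @param p_adjust_method correction for the Dunn pairwise p-values
#'   (default Bonferroni, Dunn's classical choice).
#' @return list with `kw_statistic`, `kw_p`, `dunn` (data.table of pairwise
#'   z and adjusted p) and `summary` (n, median, 10th/90th percentile per
#'   group).
#' @export
compare_ppi_groups <- function(groups, p_adjust_method = "bonferroni") {
  if (length(groups) < 2) stop("need at least two groups")
  groups <- lapply(groups, function(x) x[is.finite(x)])
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 defined PPIs: ",
         paste(names(groups)[sizes < 2], collapse = ", "))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), sizes), levels = names(groups))
  kw <- stats::kruskal.test(values, labels)

  # Dunn's test with tie correction
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, labels, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  dunn <- data.table(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = vapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      se <- sqrt((N * (N + 1) / 12 - tie_term) *
                   (1 / sizes[[a]] + 1 / sizes[[b]]))
      (mean_rank[[a]] - mean_rank[[b]]) / se
    }, 0))
  dunn[, p := 2 * stats::pnorm(-abs(z))]
  dunn[, p_adj := stats::p.adjust(p, method = p_adjust_method)]

  summary <- data.table(
    group = names(groups), n = as.integer(sizes),
    median = vapply(groups, stats::median, 0),
    q10 = vapply(groups, stats::quantile, 0, probs = 0.1, names = FALSE),
    q90 = vapply(groups, stats::quantile, 0, probs = 0.9, names = FALSE))
  list(kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
       dunn = dunn[], summary = summary)
}
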