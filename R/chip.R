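#' Fold-enrichment ChIP-seq peak calling against a matched control
#'
#' Both signals are scaled to 10^7 mapped tags. Sliding windows (width
#' `window`, step one bin) where scaled treatment is at least `fold` times
#' the scaled control plus a pseudocount are marked; overlapping or
#' adjacent marked windows merge into peaks; the summit is the centre of
#' the maximum-signal bin; peaks whose normalized tag count falls below
#' `min_norm_tags` are dropped. All gates are inclusive. ChIP coverage is
#' unstranded: the plus-strand bins are read.
#'
#' @param treatment,control `StrandedCoverage` objects on the same grid.
#' @param window window width in bp (multiple of the bin width).
#' @param fold enrichment gate (> 1; a configuration with `fold <= 1` marks
#'   the whole genome and is refused).
#' @param min_norm_tags minimum normalized (per 10^7) tag count per peak.
#' @param pseudocount added to the scaled control per window.
#' @return data.table `chrom, start, end, summit, norm_tags, fold_over_control`
#'   sorted by coordinate.
#' @export
call_peaks <- function(treatment, control, window = 200, fold = 4,
                       min_norm_tags = 10, pseudocount = 0.5) {
  stopifnot(is_stranded_coverage(treatment), is_stranded_coverage(control))
  if (fold <= 1)
    stop("fold must exceed 1: a fold <= 1 gate saturates (marks everything)")
  if (!identical(sort(names(treatment$plus)), sort(names(control$plus))) ||
      treatment$bin_width != control$bin_width)
    stop("treatment and control are not on the same grid")
  w <- treatment$bin_width
  k <- window / w
  if (k != round(k)) stop("window must be a multiple of the bin width")
  k <- as.integer(k)
  t_total <- sum(vapply(treatment$plus, sum, 0))
  c_total <- sum(vapply(control$plus, sum, 0))
  if (t_total <= 0 || c_total <= 0) stop("empty treatment or control coverage")
  t_scale <- 1e7 / t_total
  c_scale <- 1e7 / c_total

  out <- list()
  for (chrom in names(treatment$plus)) {
    tv <- treatment$plus[[chrom]] * t_scale
    cv <- control$plus[[chrom]] * c_scale
    if (length(cv) != length(tv))
      stop("treatment and control are not on the same grid (", chrom, ")")
    n <- length(tv)
    if (n < k) next
    tw <- cumsum_window(tv, k)
    cw <- cumsum_window(cv, k)
    marked <- tw >= fold * (cw + pseudocount)
    if (!any(marked)) next
    # bins covered by any marked window
    covered <- logical(n)
    for (pos in which(marked)) covered[pos:(pos + k - 1L)] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values)) {
      b0 <- starts[ri]; b1 <- ends[ri]
      seg <- tv[b0:b1]
      smax <- b0 + which.max(seg) - 1L
      norm_tags <- sum(seg)
      if (norm_tags < min_norm_tags) next
      ctl <- sum(cv[b0:b1])
      out[[length(out) + 1L]] <- data.table(
        chrom = chrom, start = (b0 - 1L) * w, end = b1 * w,
        summit = as.integer((smax - 1L) * w + w %/% 2),
        norm_tags = norm_tags,
        fold_over_control = norm_tags / (ctl + pseudocount))
    }
  }
  if (!length(out))
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), norm_tags = numeric(),
                      fold_over_control = numeric()))
  res <- data.table::rbindlist(out)
  setorder(res, chrom, start)
  res[]
}

# sliding-window sums of width k, step 1 (length n - k + 1)
cumsum_window <- function(v, k) {
  cs <- cumsum(c(0, v))
  cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]
}

#' Replicate consensus of two peak sets
#'
#' Keeps every rep1 peak that overlaps (>= 1 bp) a rep2 peak, with the span
#' merged across the overlapping partners and the normalized tag count
#' averaged between the replicates.
#'
#' @param peaks_rep1,peaks_rep2 peak tables from [call_peaks()].
#' @return consensus peak table.
#' @export
replicate_consensus <- function(peaks_rep1, peaks_rep2) {
  if (nrow(peaks_rep1) == 0 || nrow(peaks_rep2) == 0)
    return(peaks_rep1[0])
  hits <- find_overlaps0(as_granges0(peaks_rep1), as_granges0(peaks_rep2))
  if (!length(hits)) return(peaks_rep1[0])
  out <- list()
  for (i in unique(queryHits(hits))) {
    js <- subjectHits(hits)[queryHits(hits) == i]
    out[[length(out) + 1L]] <- data.table(
      chrom = peaks_rep1$chrom[i],
      start = min(peaks_rep1$start[i], peaks_rep2$start[js]),
      end = max(peaks_rep1$end[i], peaks_rep2$end[js]),
      summit = peaks_rep1$summit[i],
      norm_tags = (peaks_rep1$norm_tags[i] + mean(peaks_rep2$norm_tags[js])) / 2,
      fold_over_control = peaks_rep1$fold_over_control[i])
  }
  res <- data.table::rbindlist(out)
  setorder(res, chrom, start)
  res[]
}

#' Genomic categorization of peaks: promoter, intragenic, intergenic
#'
#' Mutually exclusive with promoter precedence: a peak is `promoter` when
#' its summit lies within `promoter_window` bp of a TSS, otherwise
#' `intragenic` when the summit falls inside a gene span, otherwise
#' `intergenic`.
#'
#' @param peaks peak table with a `summit` column.
#' @param genes a gene table.
#' @param promoter_window half-width of the promoter window (bp).
#' @return list with `category` (per peak) and `counts` (named vector).
#' @export
categorize_genomic <- function(peaks, genes, promoter_window = 1000) {
  tss <- gene_tss(genes)
  category <- vapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$summit[i]
    same <- genes$chrom == peaks$chrom[i]
    if (any(same & abs(s - tss) <= promoter_window)) return("promoter")
    if (any(same & s >= genes$start & s < genes$end)) return("intragenic")
    "intergenic"
  }, "")
  counts <- vapply(c("promoter", "intragenic", "intergenic"),
                   function(x) sum(category == x), 0L)
  list(category = category, counts = counts)
}

#' Three-timepoint overlap categories (Venn groups)
#'
#' The three peak sets are flattened into a universe of merged intervals;
#' each universe region is assigned a category by which timepoints it
#' overlaps (>= 1 bp): 1 = all three; 2 = first+second only; 3 =
#' second+third only; 4 = first only; 5 = first+third only; 6 = second
#' only; 7 = third only. For an androgen time course, pass the 0.5 h, 2 h
#' and 4 h sets in order, so that group 4 is "0.5 h only" and group 7 is
#' "4 h only".
#'
#' @param set1,set2,set3 peak/interval tables (`chrom, start, end`).
#' @return list with `regions` (universe table with `category`) and
#'   `counts` (named vector over categories 1..7).
#' @export
timepoint_venn <- function(set1, set2, set3) {
  sets <- list(set1, set2, set3)
  all_iv <- data.table::rbindlist(lapply(sets, function(s)
    data.table(chrom = s$chrom, start = s$start, end = s$end)))
  if (nrow(all_iv) == 0)
    return(list(regions = data.table(chrom = character(), start = integer(),
                                     end = integer(), category = integer()),
                counts = setNames(rep(0L, 7), as.character(1:7))))
  gr <- GenomicRanges::reduce(as_granges0(all_iv))
  uni <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  member <- vapply(sets, function(s) {
    if (nrow(s) == 0) rep(FALSE, nrow(uni))
    else count_overlaps0(gr, as_granges0(s)) > 0
  }, logical(nrow(uni)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  code <- function(a, b, c) {
    if (a && b && c) 1L else if (a && b) 2L else if (b && c) 3L
    else if (a && c) 5L else if (a) 4L else if (b) 6L else 7L
  }
  uni$category <- vapply(seq_len(nrow(uni)), function(i)
    code(member[i, 1], member[i, 2], member[i, 3]), 0L)
  counts <- vapply(1:7, function(x) sum(uni$category == x), 0L)
  names(counts) <- as.character(1:7)
  list(regions = uni[], counts = counts)
}

#' Associate peaks with the nearest gene TSS within a search window
#'
#' Each peak maps to the closest TSS within `window` bp of its summit
#' (inclusive); ties go to the smaller absolute distance, then the
#' lexicographically smaller gene id. When a differential table is given,
#' the fraction of associated peaks per regulation class and the per-gene
#' peak counts are reported.
#'
#' @param peaks peak table with a `summit` column.
#' @param genes a gene table.
#' @param window search half-width in bp.
#' @param diff_table optional differential table with `feature_id` and
#'   `class` (one row per gene).
#' @param transcribed_only drop genes classed `untranscribed` before
#'   association.
#' @return list with `associations` (per-peak table: `gene_id`, `distance`,
#'   `class`), `class_fractions` and `peaks_per_gene`.
#' @export
associate_to_genes <- function(peaks, genes, window = 50000,
                               diff_table = NULL, transcribed_only = FALSE) {
  if (!is.null(diff_table) && transcribed_only) {
    keep <- diff_table$feature_id[diff_table$class != "untranscribed"]
    genes <- genes[genes$gene_id %in% keep]
  }
  tss <- gene_tss(genes)
  assoc <- lapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$summit[i]
    same <- which(genes$chrom == peaks$chrom[i])
    d <- abs(s - tss[same])
    ok <- d <= window
    if (!any(ok))
      return(data.table(peak = i, gene_id = NA_character_,
                        distance = NA_integer_))
    cand <- data.table(gene_id = genes$gene_id[same[ok]], d = d[ok])
    setorder(cand, d, gene_id)
    data.table(peak = i, gene_id = cand$gene_id[1],
               distance = as.integer(cand$d[1]))
  })
  assoc <- data.table::rbindlist(assoc)
  if (!is.null(diff_table)) {
    cls <- diff_table$class[match(assoc$gene_id, diff_table$feature_id)]
    assoc$class <- cls
    done <- assoc[!is.na(assoc$gene_id)]
    class_fractions <- if (nrow(done))
      vapply(c("up", "non", "down"),
             function(x) mean(done$class == x, na.rm = TRUE), 0) else
      setNames(rep(NA_real_, 3), c("up", "non", "down"))
  } else class_fractions <- NULL
  ppg <- assoc[!is.na(assoc$gene_id), .N, by = "gene_id"]
  data.table::setnames(ppg, "N", "n_peaks")
  list(associations = assoc[], class_fractions = class_fractions,
       peaks_per_gene = ppg[])
}

#' Pairwise co-occurrence matrix of interval sets
#'
#' Entry (A, B) is the maximal overlap percentage: 100 times the fraction
#' of sites in the smaller set that overlap (>= 1 bp) any site of the
#' other set (for equal sizes, the larger of the two directional
#' fractions). Exactly symmetric; diagonal 100 for nonempty sets; rows for
#' empty sets are NA.
#'
#' @param sets named list of interval tables (`chrom, start, end`).
#' @return numeric percentage matrix with the sets' names as dimnames.
#' @export
cooccurrence <- function(sets) {
  n <- length(sets)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  grs <- lapply(sets, function(s) if (nrow(s)) as_granges0(s) else NULL)
  m <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j < i) next
    if (is.null(grs[[i]]) || is.null(grs[[j]])) next
    if (i == j) { m[i, j] <- 100; next }
    fa <- mean(count_overlaps0(grs[[i]], grs[[j]]) > 0)
    fb <- mean(count_overlaps0(grs[[j]], grs[[i]]) > 0)
    na <- nrow(sets[[i]]); nb <- nrow(sets[[j]])
    val <- 100 * if (na < nb) fa else if (nb < na) fb else max(fa, fb)
    m[i, j] <- m[j, i] <- val
  }
  m
}

#' Hierarchically cluster a co-occurrence matrix
#'
#' Agglomerative clustering with Euclidean distance on rows and average
#' linkage; the leaf ordering is deterministic for a given input.
#'
#' @param m square numeric matrix with dimnames.
#' @return list with `order` (leaf labels), `hclust` and `newick` (the
#'   dendrogram as a Newick string).
#' @export
cluster_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
  phy <- ape::as.phylo(hc)
  list(order = rownames(m)[hc$order], hclust = hc,
       newick = ape::write.tree(phy))
}

#' Fold-change distributions of genes associated with enhancer groups
#'
#' Associates each enhancer (by span midpoint) with the closest transcribed
#' gene TSS within the window and summarizes the associated genes' log2
#' fold changes per group, with a Kruskal-Wallis/Dunn comparison across
#' groups having at least two associated genes.
#'
#' @param groups named list of interval tables (`chrom, start, end`), e.g.
#'   up/down/non-regulated enhancers or factor-co-occupied enhancers.
#' @param genes a gene table.
#' @param diff_table differential table with `feature_id`, `class`, `log2fc`.
#' @param window association half-width in bp.
#' @return list with `summary` (group, n, median, q10, q90), `values`
#'   (named list of per-group log2fc vectors; empty groups flagged) and
#'   `test` (output of [compare_ppi_groups()], or NULL if < 2 usable
#'   groups).
#' @export
enhancer_gene_change <- function(groups, genes, diff_table, window = 50000) {
  transcribed <- diff_table[diff_table$class != "untranscribed"]
  genes_t <- genes[genes$gene_id %in% transcribed$feature_id]
  values <- lapply(groups, function(g) {
    if (nrow(g) == 0) return(numeric(0))
    mid <- (g$start + g$end) %/% 2
    fake_peaks <- data.table(chrom = g$chrom, summit = mid)
    assoc <- associate_to_genes(fake_peaks, genes_t, window)$associations
    ids <- assoc$gene_id[!is.na(assoc$gene_id)]
    transcribed$log2fc[match(ids, transcribed$feature_id)]
  })
  summary <- data.table(
    group = names(groups), n = lengths(values),
    median = vapply(values, function(v) if (length(v)) stats::median(v) else NA_real_, 0),
    q10 = vapply(values, function(v) if (length(v))
      stats::quantile(v, 0.1, names = FALSE) else NA_real_, 0),
    q90 = vapply(values, function(v) if (length(v))
      stats::quantile(v, 0.9, names = FALSE) else NA_real_, 0))
  usable <- values[lengths(values) >= 2]
  test <- if (length(usable) >= 2) compare_ppi_groups(usable) else NULL
  list(summary = summary[], values = values, test = test)
}

#' Write a peak table as BED6+ (extra columns: norm_tags, fold)
#' @param peaks a peak table.
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- data.table(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                    name = sprintf("peak_%05d", seq_len(nrow(peaks))),
                    score = as.integer(round(pmin(peaks$norm_tags, 1000))),
                    strand = ".", norm_tags = peaks$norm_tags,
                    fold = peaks$fold_over_control)
  setorder(out, chrom, start)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
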