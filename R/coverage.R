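#' Stranded binned coverage
#'
#' Container for strand-specific tag counts on a fixed-width bin grid, the
#' unit of signal consumed by transcript detection, quantification and peak
#' calling. Bin `i` of a chromosome covers the 0-based half-open interval
#' `[(i-1)*bin_width, i*bin_width)`.
#'
#' @param plus,minus named lists (one element per chromosome) of non-negative
#'   numeric vectors of per-bin tag counts. Both strands must share the same
#'   chromosome names and bin-vector lengths.
#' @param bin_width bin width in bp (positive integer).
#' @param library_id label for the library.
#' @return an object of class `StrandedCoverage`: a list with elements
#'   `plus`, `minus`, `bin_width`, `total_tags` (sum over both strands) and
#'   `library_id`.
#' @export
stranded_coverage <- function(plus, minus, bin_width, library_id = "lib") {
  if (!is.list(plus) || !is.list(minus))
    stop("plus and minus must be named lists of per-bin count vectors")
  if (is.null(names(plus)) || !identical(sort(names(plus)), sort(names(minus))))
    stop("plus and minus must cover the same chromosomes")
  minus <- minus[names(plus)]
  for (chrom in names(plus)) {
    p <- plus[[chrom]]; m <- minus[[chrom]]
    if (length(p) != length(m))
      stop("bin grids differ between strands on chromosome ", chrom)
    if (any(p < 0) || any(m < 0))
      stop("negative tag counts on chromosome ", chrom)
  }
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width <= 0) stop("bin_width must be a positive integer")
  total <- sum(vapply(plus, sum, 0)) + sum(vapply(minus, sum, 0))
  structure(
    list(plus = plus, minus = minus, bin_width = bin_width,
         total_tags = total, library_id = library_id),
    class = "StrandedCoverage")
}

#' @export
print.StrandedCoverage <- function(x, ...) {
  cat("StrandedCoverage:", x$library_id, "\n")
  cat("  chromosomes:", paste(names(x$plus), collapse = ", "), "\n")
  cat("  bin width:", x$bin_width, "bp; total tags:",
      format(x$total_tags, big.mark = ","), "\n")
  invisible(x)
}

is_stranded_coverage <- function(x) inherits(x, "StrandedCoverage")

#' Chromosome lengths of a coverage object (in bp, grid-aligned)
#' @param cov a `StrandedCoverage`.
#' @return named integer vector of chromosome lengths.
#' @export
coverage_chrom_lengths <- function(cov) {
  vapply(cov$plus, function(v) length(v) * cov$bin_width, 0)
}

#' Combine GRO-seq libraries to maximise read depth
#'
#' Bin-wise sum of several libraries on identical grids; used to pool all
#' conditions before de novo transcript detection so weakly transcribed
#' units are detectable.
#'
#' @param coverages list of `StrandedCoverage` objects with identical
#'   chromosome sets and bin grids.
#' @param library_id label for the combined library.
#' @return a `StrandedCoverage` whose bins are the element-wise sums and
#'   whose `total_tags` is the sum of the inputs' totals.
#' @export
combine_libraries <- function(coverages, library_id = "combined") {
  if (!length(coverages)) stop("no coverages supplied")
  stopifnot(all(vapply(coverages, is_stranded_coverage, TRUE)))
  ref <- coverages[[1]]
  for (cov in coverages[-1]) {
    if (!identical(sort(names(cov$plus)), sort(names(ref$plus))))
      stop("chromosome sets differ between libraries")
    if (cov$bin_width != ref$bin_width)
      stop("bin widths differ between libraries")
    for (chrom in names(ref$plus))
      if (length(cov$plus[[chrom]]) != length(ref$plus[[chrom]]))
        stop("bin grids differ on chromosome ", chrom)
  }
  plus <- lapply(names(ref$plus), function(chrom)
    Reduce(`+`, lapply(coverages, function(cov) cov$plus[[chrom]])))
  minus <- lapply(names(ref$plus), function(chrom)
    Reduce(`+`, lapply(coverages, function(cov) cov$minus[[chrom]])))
  names(plus) <- names(minus) <- names(ref$plus)
  stranded_coverage(plus, minus, ref$bin_width, library_id)
}

#' Sum of tags overlapping a 0-based half-open interval on one strand
#'
#' Partial bins are pro-rated by the fraction of the bin covered by the
#' interval; the caller decides whether to round.
#'
#' @param cov a `StrandedCoverage`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return numeric tag sum (possibly fractional at the boundaries).
#' @export
interval_tags <- function(cov, chrom, start, end, strand) {
  bins <- if (strand == "+") cov$plus[[chrom]] else cov$minus[[chrom]]
  if (is.null(bins)) stop("unknown chromosome: ", chrom)
  w <- cov$bin_width
  n <- length(bins)
  if (start < 0 || end > n * w || end <= start)
    stop("interval [", start, ",", end, ") outside coverage of ", chrom)
  first <- floor(start / w) + 1L
  last <- ceiling(end / w)
  idx <- first:last
  # overlap fraction of each touched bin
  bstart <- (idx - 1L) * w
  bend <- idx * w
  frac <- (pmin(bend, end) - pmax(bstart, start)) / w
  sum(bins[idx] * frac)
}

#' Mean tag density of an interval in tags per kb
#' @inheritParams interval_tags
#' @return tags/kb over the interval.
#' @export
interval_density <- function(cov, chrom, start, end, strand) {
  interval_tags(cov, chrom, start, end, strand) / (end - start) * 1000
}
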