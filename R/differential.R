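#' @importFrom stats dnbinom pbinom var
NULL

#' Assemble a feature-by-library count container
#'
#' @param counts matrix of non-negative integer counts, features in rows,
#'   libraries in columns.
#' @param library_sizes total mapped tags per library (length = ncol).
#' @param feature_lengths feature lengths in bp (length = nrow).
#' @param conditions condition label per library.
#' @param feature_ids optional ids (default rownames or `feature_1...`).
#' @return a `FeatureCounts` object.
#' @export
feature_counts <- function(counts, library_sizes, feature_lengths, conditions,
                           feature_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must match the number of libraries")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (length(feature_lengths) != nrow(counts))
    stop("feature_lengths must match the number of features")
  if (any(feature_lengths <= 0)) stop("feature lengths must be positive")
  if (length(conditions) != ncol(counts))
    stop("conditions must match the number of libraries")
  if (is.null(feature_ids))
    feature_ids <- rownames(counts) %||% sprintf("feature_%d", seq_len(nrow(counts)))
  structure(list(counts = counts, library_sizes = as.numeric(library_sizes),
                 feature_lengths = as.numeric(feature_lengths),
                 conditions = as.character(conditions),
                 feature_ids = as.character(feature_ids)),
            class = "FeatureCounts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count coverage tags over features, strand-aware
#'
#' Sums bin tags overlapping each region on the requested strand relative
#' to the region's own strand; partial bins are pro-rated by overlap
#' fraction and the total rounded to the nearest integer.
#'
#' @param regions data.table with `chrom, start, end, strand` (strand may be
#'   `"."` only in `"both"` mode).
#' @param cov a `StrandedCoverage`.
#' @param mode `"sense"`, `"antisense"` or `"both"`.
#' @return integer vector of counts, one per region.
#' @export
count_features <- function(regions, cov, mode = c("sense", "antisense", "both")) {
  mode <- match.arg(mode)
  n <- nrow(regions)
  out <- numeric(n)
  for (i in seq_len(n)) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(cov$plus))
      stop("region ", i, " on unknown chromosome ", chrom)
    s <- regions$strand[i]
    val <- switch(mode,
      both = interval_tags(cov, chrom, regions$start[i], regions$end[i], "+") +
             interval_tags(cov, chrom, regions$start[i], regions$end[i], "-"),
      sense = interval_tags(cov, chrom, regions$start[i], regions$end[i], s),
      antisense = interval_tags(cov, chrom, regions$start[i], regions$end[i],
                                if (s == "+") "-" else "+"))
    out[i] <- val
  }
  as.integer(round(out))
}

#' Reads per kilobase per million mapped reads
#' @param count tag count(s).
#' @param length_bp feature length(s) in bp (> 0).
#' @param library_size total mapped tags (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) stop("feature length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  count / (length_bp / 1000 * library_size / 1e6)
}

#' Trimmed mean of M-values normalization factors
#'
#' Robinson-Oshlack TMM: against a reference library (the one whose 75th
#' count percentile, scaled by library size, is closest to the mean), the
#' weighted mean of log2 count ratios is taken after trimming the most
#' extreme 30% of log-ratios and 5% of average intensities on each side;
#' factors are rescaled to have geometric mean 1. Multiply library sizes by
#' these factors to correct composition bias (e.g. deep induction inflating
#' a treated library's total).
#'
#' @param counts matrix of non-negative counts, features x libraries.
#' @param library_sizes total tags per library.
#' @param logratio_trim,sum_trim two-sided trim fractions.
#' @return numeric vector of normalization factors, one per library.
#' @export
tmm_factors <- function(counts, library_sizes, logratio_trim = 0.3,
                        sum_trim = 0.05) {
  counts <- as.matrix(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j], 0.75) / library_sizes[j], 0)
  ref <- which.min(abs(f75 - mean(f75)))
  r <- counts[, ref]; Nr <- library_sizes[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    y <- counts[, j]; N <- library_sizes[j]
    keep <- y > 0 & r > 0
    if (!any(keep)) return(1)
    yk <- y[keep]; rk <- r[keep]
    M <- log2((yk / N) / (rk / Nr))
    A <- 0.5 * log2((yk / N) * (rk / Nr))
    w <- (N - yk) / (N * yk) + (Nr - rk) / (Nr * rk)
    mq <- stats::quantile(M, c(logratio_trim, 1 - logratio_trim))
    aq <- stats::quantile(A, c(sum_trim, 1 - sum_trim))
    use <- M >= mq[1] & M <= mq[2] & A >= aq[1] & A <= aq[2]
    if (!any(use)) return(1)
    2^(sum(w[use] * M[use]) / sum(w[use]))
  }, 0)
  f / exp(mean(log(f)))
}

# Library-size-normalized pseudocounts: scale every library to the
# geometric mean library size, then round.
normalize_pseudocounts <- function(counts, library_sizes) {
  ref <- exp(mean(log(library_sizes)))
  round(sweep(counts, 2, ref / library_sizes, `*`))
}

# Method-of-moments common dispersion across features, estimated within
# conditions on normalized counts; <= 0 collapses to Poisson (returns 0).
estimate_common_dispersion <- function(pseudo, conditions) {
  ests <- c()
  for (cond in unique(conditions)) {
    cols <- which(conditions == cond)
    if (length(cols) < 2) next
    m <- rowMeans(pseudo[, cols, drop = FALSE])
    v <- apply(pseudo[, cols, drop = FALSE], 1, var)
    ok <- m > 0
    ests <- c(ests, (v[ok] - m[ok]) / m[ok]^2)
  }
  if (!length(ests)) return(0)
  max(mean(ests), 0)
}

# Two-sided conditional exact p-value for one feature: pooled sums yA, yB
# from nA and nB libraries, common per-library mean under the null, NB
# dispersion phi (0 = Poisson / conditional binomial).
exact_test_p <- function(yA, yB, nA, nB, phi) {
  s <- yA + yB
  if (s == 0) return(1)
  if (phi <= 0) {
    q <- nA / (nA + nB)
    p_low <- pbinom(yA, s, q)
    p_high <- 1 - pbinom(yA - 1, s, q)
  } else {
    mu <- s / (nA + nB)
    a <- 0:s
    logp <- dnbinom(a, size = nA / phi, mu = nA * mu, log = TRUE) +
      dnbinom(s - a, size = nB / phi, mu = nB * mu, log = TRUE)
    w <- exp(logp - max(logp))
    w <- w / sum(w)
    p_low <- sum(w[a <= yA])
    p_high <- sum(w[a >= yA])
  }
  min(1, 2 * min(p_low, p_high))
}

#' Negative-binomial exact test between two conditions
#'
#' Per feature: counts are converted to library-size-normalized
#' pseudocounts, a common dispersion is estimated across features by the
#' method of moments (falling back to a Poisson/conditional-binomial test
#' when the estimate is not positive), and a conditional exact test on the
#' pooled per-condition sums yields a two-sided p-value by doubling the
#' smaller tail (capped at 1). Features with all-zero counts get p = 1.
#'
#' @param counts a [feature_counts()] object.
#' @param condition_a,condition_b condition labels (a is the baseline).
#' @param dispersion optional fixed dispersion overriding the estimate.
#' @return list with `pvalue` (per feature), `dispersion` (value used) and
#'   `all_zero` (logical flag per feature).
#' @export
nb_exact_test <- function(counts, condition_a, condition_b, dispersion = NULL) {
  stopifnot(inherits(counts, "FeatureCounts"))
  for (cond in c(condition_a, condition_b))
    if (!cond %in% counts$conditions) stop("condition not present: ", cond)
  cols <- counts$conditions %in% c(condition_a, condition_b)
  sub <- counts$counts[, cols, drop = FALSE]
  libs <- counts$library_sizes[cols]
  conds <- counts$conditions[cols]
  pseudo <- normalize_pseudocounts(sub, libs)
  phi <- dispersion %||% estimate_common_dispersion(pseudo, conds)
  ca <- conds == condition_a
  yA <- rowSums(pseudo[, ca, drop = FALSE])
  yB <- rowSums(pseudo[, !ca, drop = FALSE])
  nA <- sum(ca); nB <- sum(!ca)
  p <- vapply(seq_along(yA), function(i) exact_test_p(yA[i], yB[i], nA, nB, phi), 0)
  list(pvalue = p, dispersion = phi, all_zero = yA + yB == 0)
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return FDR values in the input order, monotone in sorted-p order and
#'   bounded by 1.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- rev(cummin(rev(pmin(q, 1))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Differential-call thresholds
#'
#' @param min_rpkm transcribed/untranscribed RPKM gate (genes; `NA` skips
#'   the gate, as for enhancers).
#' @param max_fdr FDR gate (inclusive).
#' @param min_abs_log2fc absolute log2 fold-change gate (inclusive).
#' @return a `thresholds` list.
#' @export
thresholds <- function(min_rpkm = 0.5, max_fdr = 0.01, min_abs_log2fc = 0.585) {
  if ((!is.na(min_rpkm) && min_rpkm < 0) || max_fdr <= 0 || min_abs_log2fc <= 0)
    stop("thresholds must be positive")
  structure(list(min_rpkm = min_rpkm, max_fdr = max_fdr,
                 min_abs_log2fc = min_abs_log2fc), class = "thresholds")
}

#' Gene gates: RPKM >= 0.5, FDR <= 0.01, |log2FC| >= log2(1.5)
#'
#' The fold-change gate is the exact log2(1.5) = 0.58496 rather than its
#' conventional rounding 0.585, so that a fold change of exactly 1.5 passes
#' the inclusive gate.
#' @return a [thresholds()] object.
#' @export
gene_thresholds <- function() thresholds(0.5, 0.01, log2(1.5))

#' Enhancer gates: FDR <= 0.05, |log2FC| >= 1 (no RPKM gate)
#' @return a [thresholds()] object.
#' @export
enhancer_thresholds <- function() thresholds(NA, 0.05, 1)

#' Attach regulation classes to differential records
#'
#' A feature is `untranscribed` when its maximal RPKM over all libraries is
#' below `min_rpkm` (skipped when the gate is `NA`); otherwise `up` when
#' `fdr <= max_fdr` and `log2fc >= min_abs_log2fc`, `down` when
#' `fdr <= max_fdr` and `log2fc <= -min_abs_log2fc`, else `non`. All gates
#' are inclusive.
#'
#' @param records data.table with `log2fc`, `fdr` and `rpkm_max` columns.
#' @param gates a [thresholds()] object.
#' @return the records with a `class` column added.
#' @export
classify_features <- function(records, gates) {
  records <- as.data.table(records)
  cls <- rep("non", nrow(records))
  sig <- records$fdr <= gates$max_fdr
  cls[sig & records$log2fc >= gates$min_abs_log2fc] <- "up"
  cls[sig & records$log2fc <= -gates$min_abs_log2fc] <- "down"
  if (!is.na(gates$min_rpkm))
    cls[records$rpkm_max < gates$min_rpkm] <- "untranscribed"
  records$class <- cls
  records[]
}

#' Run the full differential-transcription analysis
#'
#' One record per feature per treated condition against the control: exact
#' NB test, BH correction within each contrast, log2 fold change from
#' library-size-normalized mean pseudocounts with a 0.5 pseudocount added
#' to both means, per-condition RPKM and regulation class.
#'
#' @param counts a [feature_counts()] object.
#' @param gates a [thresholds()] object.
#' @param control_condition condition used as baseline.
#' @param treatment_conditions conditions to test (default: all others).
#' @param dispersion optional fixed NB dispersion.
#' @param norm_method `"total"` (per-million total tags, the default) or
#'   `"tmm"` ([tmm_factors()] applied to the library sizes used for testing
#'   and fold changes; RPKM always uses the raw totals).
#' @return data.table with columns `feature_id, condition, rpkm_control,
#'   rpkm_treatment, rpkm_max, log2fc, pvalue, fdr, class`.
#' @export
run_differential <- function(counts, gates, control_condition,
                             treatment_conditions = NULL, dispersion = NULL,
                             norm_method = c("total", "tmm")) {
  stopifnot(inherits(counts, "FeatureCounts"))
  norm_method <- match.arg(norm_method)
  if (!control_condition %in% counts$conditions)
    stop("control condition not present: ", control_condition)
  treatment_conditions <- treatment_conditions %||%
    setdiff(unique(counts$conditions), control_condition)
  rpkm_all <- sweep(sweep(counts$counts, 2, counts$library_sizes / 1e6, `/`),
                    1, counts$feature_lengths / 1000, `/`)
  rpkm_max <- apply(rpkm_all, 1, max)
  if (norm_method == "tmm") {
    counts$library_sizes <- counts$library_sizes *
      tmm_factors(counts$counts, counts$library_sizes)
  }
  pseudo_all <- normalize_pseudocounts(counts$counts, counts$library_sizes)
  out <- list()
  for (cond in treatment_conditions) {
    if (!cond %in% counts$conditions) stop("condition not present: ", cond)
    test <- nb_exact_test(counts, control_condition, cond, dispersion)
    mean_ctrl <- rowMeans(pseudo_all[, counts$conditions == control_condition,
                                     drop = FALSE])
    mean_trt <- rowMeans(pseudo_all[, counts$conditions == cond, drop = FALSE])
    rec <- data.table(
      feature_id = counts$feature_ids, condition = cond,
      rpkm_control = rowMeans(rpkm_all[, counts$conditions == control_condition,
                                       drop = FALSE]),
      rpkm_treatment = rowMeans(rpkm_all[, counts$conditions == cond,
                                         drop = FALSE]),
      rpkm_max = rpkm_max,
      log2fc = log2((mean_trt + 0.5) / (mean_ctrl + 0.5)),
      pvalue = test$pvalue,
      fdr = benjamini_hochberg(test$pvalue))
    out[[cond]] <- classify_features(rec, gates)
  }
  data.table::rbindlist(out)
}
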