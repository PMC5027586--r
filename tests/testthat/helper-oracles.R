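# Independent brute-force oracles. These re-derive expected results from the
# documented rules with plain loops (no package internals, no IRanges), so
# every dual-route check compares two separately coded paths.

# --- coverage builders ------------------------------------------------------

make_cov <- function(plus, minus = NULL, bin_width = 50, chrom = "chrT",
                     library_id = "test") {
  if (is.null(minus)) minus <- rep(0, length(plus))
  stranded_coverage(setNames(list(plus), chrom), setNames(list(minus), chrom),
                    bin_width, library_id)
}

# --- transcript-scan oracle -------------------------------------------------

# Re-implements the documented scan on a raw bin vector (plus-strand
# orientation): tile initiation/bodyFold/closure rules, gap absorption,
# bin-level trim, length and density floors.
oracle_scan_bins <- function(bins, bin_width, p) {
  k <- p$init_window %/% bin_width
  nt <- length(bins) %/% k
  if (nt == 0) return(list())
  tiles <- vapply(seq_len(nt), function(i)
    sum(bins[((i - 1) * k + 1):(i * k)]), 0)
  dens <- tiles / p$init_window * 1000
  res <- list()
  st <- NULL
  finish <- function(st) {
    body <- st$tags / st$bp * 1000
    thr <- max(p$closure_frac * body, min(p$min_density, body))
    lo <- (st$start - 1) * k + 1
    hi <- st$lastgood * k
    while (lo <= hi && bins[lo] / bin_width * 1000 < thr) lo <- lo + 1
    while (hi >= lo && bins[hi] / bin_width * 1000 < thr) hi <- hi - 1
    if (hi < lo) return(NULL)
    tags <- sum(bins[lo:hi])
    len <- (hi - lo + 1) * bin_width
    if (len < p$min_length || tags / len * 1000 < p$min_density) return(NULL)
    list(start = (lo - 1) * bin_width, end = hi * bin_width,
         n_tags = tags, body_density = tags / len * 1000)
  }
  fresh <- function(i) list(start = i, lastgood = i, tags = tiles[i],
                            bp = p$init_window, gap_bp = 0, gap_tags = 0)
  for (i in seq_len(nt)) {
    d <- dens[i]
    if (is.null(st)) {
      prev <- if (i > 1) dens[i - 1] else 0
      if (d > 0 && d >= p$init_fold * prev && d >= p$min_density)
        st <- fresh(i)
    } else {
      body <- st$tags / st$bp * 1000
      if (d >= p$body_fold * body) {
        r <- finish(st)
        if (!is.null(r)) res[[length(res) + 1]] <- r
        st <- fresh(i)
      } else if (d < max(p$closure_frac * body, min(p$min_density, body))) {
        st$gap_bp <- st$gap_bp + p$init_window
        st$gap_tags <- st$gap_tags + tiles[i]
        if (st$gap_bp > p$max_gap) {
          r <- finish(st)
          if (!is.null(r)) res[[length(res) + 1]] <- r
          st <- NULL
        }
      } else {
        st$tags <- st$tags + st$gap_tags + tiles[i]
        st$bp <- st$bp + st$gap_bp + p$init_window
        st$gap_bp <- 0; st$gap_tags <- 0
        st$lastgood <- i
      }
    }
  }
  if (!is.null(st)) {
    r <- finish(st)
    if (!is.null(r)) res[[length(res) + 1]] <- r
  }
  res
}

oracle_scan_table <- function(bins, bin_width, p) {
  res <- oracle_scan_bins(bins, bin_width, p)
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      n_tags = numeric(), body_density = numeric()))
  do.call(rbind, lapply(res, as.data.frame))
}

# --- BH step-up oracle ------------------------------------------------------

# fdr_i = min over j with p_(j) >= p_i of m * p_(j) / rank(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  fdr_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * sorted[i:m] / (i:m))), 0)
  out <- numeric(m)
  out[o] <- fdr_sorted
  out
}

# --- conditional binomial (Poisson-limit) exact-test oracle -----------------

oracle_binom_exact <- function(yA, yB, nA, nB) {
  s <- yA + yB
  if (s == 0) return(1)
  q <- nA / (nA + nB)
  probs <- vapply(0:s, function(a) stats::dbinom(a, s, q), 0)
  p_low <- sum(probs[seq_len(yA + 1)])
  p_high <- sum(probs[(yA + 1):(s + 1)])
  min(1, 2 * min(p_low, p_high))
}

# --- interval oracles -------------------------------------------------------

# 0-based half-open overlap of >= 1 bp
iv_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

oracle_overlap_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(b)))
      if (a$chrom[i] == b$chrom[j] &&
          iv_overlap(a$start[i], a$end[i], b$start[j], b$end[j])) hit <- TRUE
    hit
  }, TRUE)
}

oracle_cooccurrence <- function(sets) {
  n <- length(sets)
  m <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (nrow(sets[[i]]) == 0 || nrow(sets[[j]]) == 0) next
    if (i == j) { m[i, j] <- 100; next }
    fa <- mean(oracle_overlap_any(sets[[i]], sets[[j]]))
    fb <- mean(oracle_overlap_any(sets[[j]], sets[[i]]))
    na <- nrow(sets[[i]]); nb <- nrow(sets[[j]])
    m[i, j] <- 100 * if (na < nb) fa else if (nb < na) fb else max(fa, fb)
  }
  m
}

# per-bp membership scan for 3-set Venn categories on one chromosome
oracle_venn_counts <- function(set1, set2, set3, L) {
  sets <- list(set1, set2, set3)
  covered <- matrix(FALSE, nrow = L, ncol = 3)
  for (k in 1:3) {
    s <- sets[[k]]
    for (j in seq_len(nrow(s)))
      if (s$end[j] > s$start[j])
        covered[(s$start[j] + 1):s$end[j], k] <- TRUE
  }
  union_cov <- rowSums(covered) > 0
  r <- rle(union_cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  counts <- setNames(rep(0L, 7), as.character(1:7))
  for (ri in which(r$values)) {
    mem <- colSums(covered[starts[ri]:ends[ri], , drop = FALSE]) > 0
    cat_n <- if (all(mem)) 1 else if (mem[1] && mem[2]) 2 else
      if (mem[2] && mem[3]) 3 else if (mem[1] && mem[3]) 5 else
      if (mem[1]) 4 else if (mem[2]) 6 else 7
    counts[cat_n] <- counts[cat_n] + 1L
  }
  counts
}

# Kruskal-Wallis H by direct rank arithmetic (no ties in the inputs used)
oracle_kw_h <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 0
  for (g in seq_along(groups)) {
    rbar <- mean(r[idx == g])
    h <- h + lengths(groups)[g] * (rbar - (N + 1) / 2)^2
  }
  unname(12 / (N * (N + 1)) * h)
}

# random interval set on one chromosome
random_set <- function(n, L = 10000, max_w = 400, chrom = "chrT") {
  s <- sort(sample.int(L - max_w, n))
  data.table::data.table(chrom = chrom, start = s,
                         end = s + sample.int(max_w, n, replace = TRUE))
}
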