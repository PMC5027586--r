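#' @importFrom stats rnbinom rpois runif
NULL

# Run code with a temporarily-seeded RNG, restoring global state afterwards,
# so no package function leaks randomness into the caller's session.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed for a (seed, key...) combination, < 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(..., sep = "/")
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

GRO_CONDITIONS <- c("vehicle", "t0.5", "t2")
CHIP_CONDITIONS <- c("vehicle", "t0.5", "t2", "t4")

#' Configuration for the synthetic genome generator
#'
#' Defaults describe a miniature two-chromosome genome dense enough to carry
#' ~300 transcribed genes plus 60 intergenic and 60 intragenic eRNA
#' enhancers, with two replicates per condition (vehicle, 0.5 h and 2 h of
#' androgen), negative-binomial count noise and condition-dependent fold
#' changes. See the methods vignette for the reasoning behind each default.
#'
#' @param n_chromosomes,chrom_length genome shape (bp).
#' @param n_genes number of genes across the genome.
#' @param gene_length_range uniform range of gene lengths (bp, min >= 1000).
#' @param gene_density_range uniform range of basal sense-strand gene-body
#'   densities, tags/bp per library.
#' @param n_intergenic_enhancers,n_intragenic_enhancers enhancer counts.
#' @param enhancer_density_range uniform range of eRNA densities, tags/bp
#'   per library per strand.
#' @param frac_genes_up,frac_genes_down fractions of genes (and, via the
#'   same draw, enhancers) regulated up/down by androgen.
#' @param gene_log2fc_range,enhancer_log2fc_range uniform ranges for
#'   regulated-feature |log2 fold change|.
#' @param pausing_fraction fraction of genes with a promoter-proximal pause.
#' @param pausing_ratio_range uniform range of promoter/body density ratios
#'   for pausing genes.
#' @param background_density GRO-seq background, tags/bp per strand per
#'   library.
#' @param chip_background_density ChIP/input background, tags/bp per library.
#' @param chip_enrichment fold enrichment of ChIP signal over background at
#'   occupied sites.
#' @param chip_site_width width of a planted binding site (bp).
#' @param nb_dispersion negative-binomial dispersion shared by all GRO-seq
#'   bins (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param chip_nb_dispersion dispersion for ChIP/input tag draws; default 0
#'   (Poisson), the standard null model for ChIP-seq tag counts.
#' @param n_replicates biological replicates per condition.
#' @param bin_width coverage bin width (bp).
#' @param intergenic_gap_range uniform range of gaps between adjacent genes
#'   (bp).
#' @param enhancer_gene_coupling probability that an enhancer inherits the
#'   regulation class of its nearest gene (within 50 kb) instead of an
#'   independent draw; models the observed enhancer-gene co-regulation.
#' @param frac_active_early fraction of regulated features whose fold change
#'   is already present at 0.5 h (the rest respond only at 2 h).
#' @param seed integer seed; all randomness derives from it.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 5e6,
                       n_genes = 300,
                       gene_length_range = c(2000, 20000),
                       gene_density_range = c(0.05, 1.0),
                       n_intergenic_enhancers = 60,
                       n_intragenic_enhancers = 60,
                       enhancer_density_range = c(0.05, 0.3),
                       frac_genes_up = 0.15,
                       frac_genes_down = 0.10,
                       gene_log2fc_range = c(0.8, 2.5),
                       enhancer_log2fc_range = c(1.5, 3.0),
                       pausing_fraction = 0.2,
                       pausing_ratio_range = c(2, 15),
                       background_density = 0.002,
                       chip_background_density = 0.15,
                       chip_enrichment = 8,
                       chip_site_width = 400,
                       nb_dispersion = 0.1,
                       chip_nb_dispersion = 0,
                       n_replicates = 2,
                       bin_width = 50,
                       intergenic_gap_range = c(12000, 20000),
                       enhancer_gene_coupling = 0.8,
                       frac_active_early = 0.5,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_chromosomes", "n_genes", "n_intergenic_enhancers",
              "n_intragenic_enhancers", "n_replicates")
  for (f in counts)
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop(f, " must be a non-negative integer")
  props <- c("frac_genes_up", "frac_genes_down", "pausing_fraction",
             "enhancer_gene_coupling", "frac_active_early")
  for (f in props)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$frac_genes_up + cfg$frac_genes_down > 1)
    stop("frac_genes_up + frac_genes_down must not exceed 1")
  if (cfg$gene_length_range[1] < 1000)
    stop("gene_length_range minimum must be >= 1000 bp")
  if (cfg$bin_width <= 0) stop("bin_width must be positive")
  if (cfg$chrom_length %% cfg$bin_width != 0)
    stop("chrom_length must be a multiple of bin_width")
  if (cfg$nb_dispersion < 0 || cfg$chip_nb_dispersion < 0)
    stop("dispersions must be >= 0")
  if (cfg$background_density < 0 || cfg$chip_background_density < 0)
    stop("background densities must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# Safety margin keeping intergenic enhancer spans clear of gene spans and of
# the >3 kb TTS exclusion: 3 kb + maximal half-span of a divergent pair.
INTERGENIC_ENHANCER_MARGIN <- 4500

#' Generate the ground-truth feature set for a synthetic genome
#'
#' Places non-overlapping genes with randomized strands, lengths, basal
#' expression, regulation classes and pausing ratios; divergent transcript
#' pairs at intergenic enhancer loci (kept clear of gene spans and > 3 kb
#' from every TTS); short antisense transcripts inside host genes
#' (intragenic enhancers) each overlapping a planted H3K4me2 interval; and
#' condition-labelled transcription-factor binding sites. Deterministic for
#' a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `TruthSet`: list with `config`, `chrom_lengths`, `genes`,
#'   `intergenic_enhancers`, `intragenic_enhancers`, `h3k4me2`, `tf_sites`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "truth"), generate_truth_impl(config))
}

generate_truth_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chromosomes), chroms)

  ## ---- genes ----
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1)))
  glist <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    pos <- round(runif(1, cfg$intergenic_gap_range[1], cfg$intergenic_gap_range[2]))
    for (k in seq_len(per_chrom[ci])) {
      len <- round(runif(1, cfg$gene_length_range[1], cfg$gene_length_range[2]))
      gap <- round(runif(1, cfg$intergenic_gap_range[1], cfg$intergenic_gap_range[2]))
      if (pos + len + cfg$intergenic_gap_range[1] > cfg$chrom_length)
        stop("placement failure: chromosome ", chroms[ci], " too short for ",
             per_chrom[ci], " genes with the configured gene_length_range ",
             "and intergenic_gap_range spacing rule")
      gid <- gid + 1L
      glist[[gid]] <- data.table(
        gene_id = sprintf("gene_%03d", gid), chrom = chroms[ci],
        start = pos, end = pos + len,
        strand = sample(c("+", "-"), 1))
      pos <- pos + len + gap
    }
  }
  genes <- if (gid > 0) data.table::rbindlist(glist) else
    data.table(gene_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character())
  n <- nrow(genes)
  if (n > 0) {
    cls <- sample(c("up", "down", "non"), n, replace = TRUE,
                  prob = c(cfg$frac_genes_up, cfg$frac_genes_down,
                           1 - cfg$frac_genes_up - cfg$frac_genes_down))
    mag <- runif(n, cfg$gene_log2fc_range[1], cfg$gene_log2fc_range[2])
    fc2 <- ifelse(cls == "up", mag, ifelse(cls == "down", -mag, 0))
    early <- runif(n) < cfg$frac_active_early
    genes[, `:=`(
      base_density = runif(n, cfg$gene_density_range[1], cfg$gene_density_range[2]),
      log2fc_t0.5 = ifelse(early, fc2, 0),
      log2fc_t2 = fc2,
      pausing_ratio = ifelse(runif(n) < cfg$pausing_fraction,
                             runif(n, cfg$pausing_ratio_range[1],
                                   cfg$pausing_ratio_range[2]), 1))]
  } else {
    genes[, `:=`(base_density = numeric(), log2fc_t0.5 = numeric(),
                 log2fc_t2 = numeric(), pausing_ratio = numeric())]
  }

  ## ---- regulation class draw shared by enhancers ----
  draw_class <- function(m) sample(c("up", "down", "non"), m, replace = TRUE,
                                   prob = c(cfg$frac_genes_up, cfg$frac_genes_down,
                                            1 - cfg$frac_genes_up - cfg$frac_genes_down))
  couple_class <- function(chs, centers) {
    # nearest gene TSS within 50 kb inherits its class with configured prob
    vapply(seq_along(chs), function(i) {
      ch <- chs[i]
      g <- genes[genes$chrom == ch]
      if (nrow(g) == 0) return(draw_class(1))
      d <- abs(gene_tss(g) - centers[i])
      j <- which.min(d)
      if (d[j] <= 50000 && runif(1) < cfg$enhancer_gene_coupling) {
        fc <- g$log2fc_t2[j]
        if (fc > 0) "up" else if (fc < 0) "down" else "non"
      } else draw_class(1)
    }, "")
  }
  enhancer_fc <- function(cls, m) {
    mag <- runif(m, cfg$enhancer_log2fc_range[1], cfg$enhancer_log2fc_range[2])
    ifelse(cls == "up", mag, ifelse(cls == "down", -mag, 0))
  }

  ## ---- intergenic enhancers: divergent pairs in gene-free gaps ----
  gaps <- list()
  for (ci in chroms) {
    g <- genes[genes$chrom == ci]
    edges <- c(0L, as.vector(rbind(g$start, g$end)), chrom_lengths[[ci]])
    starts <- edges[seq(1, length(edges) - 1, by = 2)]
    ends <- edges[seq(2, length(edges), by = 2)]
    ok <- (ends - starts) > 2 * INTERGENIC_ENHANCER_MARGIN
    if (any(ok))
      gaps[[ci]] <- data.table(chrom = ci, lo = starts[ok] + INTERGENIC_ENHANCER_MARGIN,
                               hi = ends[ok] - INTERGENIC_ENHANCER_MARGIN)
  }
  gaps <- data.table::rbindlist(gaps)
  if (cfg$n_intergenic_enhancers > nrow(gaps))
    stop("placement failure: only ", nrow(gaps), " intergenic gaps can host an ",
         "enhancer > 3 kb from every gene TTS; reduce n_intergenic_enhancers ",
         "or increase intergenic_gap_range")
  if (cfg$n_intergenic_enhancers > 0) {
    pick <- gaps[sample(nrow(gaps), cfg$n_intergenic_enhancers)]
    m <- nrow(pick)
    center <- round(runif(m, pick$lo, pick$hi))
    inner_gap <- round(runif(m, 100, 600))
    len_p <- round(runif(m, 300, 1000))
    len_m <- round(runif(m, 300, 1000))
    cls <- couple_class(pick$chrom, center)
    fc2 <- enhancer_fc(cls, m)
    early <- runif(m) < cfg$frac_active_early
    inter <- data.table(
      enh_id = sprintf("ige_%03d", seq_len(m)), chrom = pick$chrom,
      center = center,
      minus_start = center - inner_gap %/% 2 - len_m,
      minus_end = center - inner_gap %/% 2,
      plus_start = center + (inner_gap - inner_gap %/% 2),
      plus_end = center + (inner_gap - inner_gap %/% 2) + len_p,
      density = runif(m, cfg$enhancer_density_range[1], cfg$enhancer_density_range[2]),
      log2fc_t0.5 = ifelse(early, fc2, 0), log2fc_t2 = fc2)
  } else {
    inter <- data.table(enh_id = character(), chrom = character(),
                        center = integer(), minus_start = integer(),
                        minus_end = integer(), plus_start = integer(),
                        plus_end = integer(), density = numeric(),
                        log2fc_t0.5 = numeric(), log2fc_t2 = numeric())
  }

  ## ---- intragenic enhancers: short antisense transcripts in host genes ----
  hosts <- genes[genes$end - genes$start >= 4000]
  if (cfg$n_intragenic_enhancers > nrow(hosts))
    stop("placement failure: only ", nrow(hosts), " genes are long enough ",
         "(>= 4 kb) to host an intragenic enhancer fully inside their span")
  if (cfg$n_intragenic_enhancers > 0) {
    host <- hosts[sample(nrow(hosts), cfg$n_intragenic_enhancers)]
    m <- nrow(host)
    len <- round(runif(m, 200, 400))
    start <- round(runif(m, host$start + 1000, host$end - 1000 - len))
    cls <- couple_class(host$chrom, start + len %/% 2)
    fc2 <- enhancer_fc(cls, m)
    early <- runif(m) < cfg$frac_active_early
    intra <- data.table(
      enh_id = sprintf("iae_%03d", seq_len(m)), host_gene = host$gene_id,
      chrom = host$chrom, start = start, end = start + len,
      strand = ifelse(host$strand == "+", "-", "+"),
      density = runif(m, cfg$enhancer_density_range[1], cfg$enhancer_density_range[2]),
      log2fc_t0.5 = ifelse(early, fc2, 0), log2fc_t2 = fc2)
  } else {
    intra <- data.table(enh_id = character(), host_gene = character(),
                        chrom = character(), start = integer(), end = integer(),
                        strand = character(), density = numeric(),
                        log2fc_t0.5 = numeric(), log2fc_t2 = numeric())
  }

  ## ---- H3K4me2 intervals: around every intragenic enhancer, plus decoys ----
  k4 <- data.table(chrom = intra$chrom,
                   start = pmax(intra$start - 500L, 0L),
                   end = intra$end + 500L)
  n_decoy <- cfg$n_intragenic_enhancers
  if (n_decoy > 0 && nrow(genes) > 0) {
    dg <- genes[sample(nrow(genes), n_decoy, replace = TRUE)]
    dstart <- round(runif(n_decoy, dg$start, pmax(dg$start, dg$end - 1000)))
    k4 <- rbind(k4, data.table(chrom = dg$chrom, start = dstart,
                               end = dstart + 1000L))
  }
  setorder(k4, chrom, start)

  ## ---- TF binding sites ----
  w <- cfg$chip_site_width
  enh_centers <- rbind(
    data.table(chrom = inter$chrom, center = inter$center,
               cls = ifelse(inter$log2fc_t2 > 0, "up",
                            ifelse(inter$log2fc_t2 < 0, "down", "non"))),
    data.table(chrom = intra$chrom, center = (intra$start + intra$end) %/% 2,
               cls = ifelse(intra$log2fc_t2 > 0, "up",
                            ifelse(intra$log2fc_t2 < 0, "down", "non"))))
  site_at <- function(chrom, center, conditions) data.table(
    chrom = chrom, start = as.integer(center - w %/% 2),
    end = as.integer(center + w %/% 2), conditions = conditions)
  ar_profile <- function(m) {
    lab <- sample(c("t0.5,t2,t4", "t2,t4", "t0.5", "t4", "t0.5,t2"), m,
                  replace = TRUE, prob = c(0.6, 0.15, 0.1, 0.1, 0.05))
    lab
  }
  sites <- list()
  up <- enh_centers[enh_centers$cls == "up"]
  down <- enh_centers[enh_centers$cls == "down"]
  if (nrow(up) > 0)
    sites$AR_enh <- cbind(factor = "AR", site_at(up$chrom, up$center, ar_profile(nrow(up))))
  # excess distal ARBs away from enhancers (most ARBs are non-functional)
  n_extra <- 2 * nrow(enh_centers)
  if (n_extra > 0 && nrow(gaps) > 0) {
    gpick <- gaps[sample(nrow(gaps), n_extra, replace = TRUE)]
    extra_center <- round(runif(n_extra, gpick$lo, gpick$hi))
    sites$AR_extra <- cbind(factor = "AR",
                            site_at(gpick$chrom, extra_center, ar_profile(n_extra)))
  }
  if (nrow(enh_centers) > 0) {
    keep <- runif(nrow(enh_centers)) < 0.8
    fox <- enh_centers[keep]
    if (nrow(fox) > 0)
      sites$FOXA1 <- cbind(factor = "FOXA1",
                           site_at(fox$chrom, fox$center, "vehicle,t0.5,t2,t4"))
  }
  for (fac in c("PIAS1", "ERG", "HDAC3")) {
    rows <- list()
    if (nrow(up) > 0) {
      keep <- runif(nrow(up)) < 0.8
      if (any(keep))
        rows$up <- site_at(up$chrom[keep], up$center[keep], "t0.5,t2,t4")
    }
    if (fac %in% c("PIAS1", "HDAC3") && nrow(down) > 0) {
      keep <- runif(nrow(down)) < 0.6
      if (any(keep))  # bound before androgen, lost upon treatment
        rows$down <- site_at(down$chrom[keep], down$center[keep], "vehicle")
    }
    if (length(rows))
      sites[[fac]] <- cbind(factor = fac, data.table::rbindlist(rows))
  }
  tf_sites <- if (length(sites)) data.table::rbindlist(sites) else
    data.table(factor = character(), chrom = character(), start = integer(),
               end = integer(), conditions = character())
  setorder(tf_sites, factor, chrom, start)

  truth <- list(config = cfg, chrom_lengths = chrom_lengths, genes = genes,
                intergenic_enhancers = inter, intragenic_enhancers = intra,
                h3k4me2 = k4, tf_sites = tf_sites)
  class(truth) <- "TruthSet"
  truth
}

#' Brute-force validation of a TruthSet against its own invariants
#'
#' Independent checker used by tests and by [generate_truth()] consumers:
#' plain loops, no interval library. Errors on the first violated rule.
#'
#' @param truth a `TruthSet`.
#' @return `TRUE` invisibly.
#' @export
validate_truth <- function(truth) {
  genes <- truth$genes
  tts <- gene_tts(genes)
  for (i in seq_len(nrow(truth$intergenic_enhancers))) {
    e <- truth$intergenic_enhancers[i]
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != e$chrom) next
      for (p in c(e$minus_start, e$minus_end, e$plus_start, e$plus_end)) {
        if (abs(p - tts[j]) <= 3000)
          stop("truth invariant violated: ", e$enh_id, " within 3 kb of ",
               genes$gene_id[j], " TTS")
        if (p > genes$start[j] && p < genes$end[j])
          stop("truth invariant violated: ", e$enh_id, " inside gene span ",
               genes$gene_id[j])
      }
    }
    if (!(e$minus_end <= e$plus_start))
      stop("truth invariant violated: ", e$enh_id, " transcripts not divergent")
  }
  for (i in seq_len(nrow(truth$intragenic_enhancers))) {
    e <- truth$intragenic_enhancers[i]
    g <- genes[genes$gene_id == e$host_gene]
    if (nrow(g) != 1 || e$start < g$start || e$end > g$end)
      stop("truth invariant violated: ", e$enh_id, " not inside its host gene")
    len <- e$end - e$start
    if (len < 150 || len > 500)
      stop("truth invariant violated: ", e$enh_id, " length ", len,
           " outside [150, 500]")
    if (e$strand == g$strand)
      stop("truth invariant violated: ", e$enh_id, " not antisense to host")
    hit <- FALSE
    for (j in seq_len(nrow(truth$h3k4me2))) {
      k <- truth$h3k4me2[j]
      if (k$chrom == e$chrom && k$start < e$end && e$start < k$end) hit <- TRUE
    }
    if (!hit)
      stop("truth invariant violated: ", e$enh_id, " has no H3K4me2 overlap")
  }
  invisible(TRUE)
}

# ---- emission --------------------------------------------------------------

# Add `density` (tags/bp) over [start, end) to a per-bin mean vector,
# pro-rating partial bins.
add_emission <- function(mu, start, end, density, bin_width) {
  n <- length(mu)
  start <- max(0, start); end <- min(end, n * bin_width)
  if (end <= start) return(mu)
  first <- floor(start / bin_width) + 1
  last <- ceiling(end / bin_width)
  idx <- first:last
  bstart <- (idx - 1) * bin_width
  bend <- idx * bin_width
  ovl <- pmin(bend, end) - pmax(bstart, start)
  mu[idx] <- mu[idx] + density * ovl
  mu
}

gro_fc <- function(feature_row, condition) {
  switch(condition,
         vehicle = 0,
         `t0.5` = feature_row$log2fc_t0.5,
         t2 = feature_row$log2fc_t2,
         stop("unknown condition label: ", condition))
}

draw_counts <- function(mu, dispersion) {
  if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  else rpois(length(mu), mu)
}

#' Simulate a stranded GRO-seq library
#'
#' Emits sense-strand gene-body signal scaled by the condition's fold
#' change, promoter-proximal pausing peaks over `[TSS, TSS + 250)`,
#' divergent eRNA pairs at intergenic enhancers, antisense eRNAs at
#' intragenic enhancers and a flat background, then draws per-bin tags from
#' a negative-binomial with the configured dispersion.
#'
#' @param truth a `TruthSet`.
#' @param condition one of `"vehicle"`, `"t0.5"`, `"t2"`.
#' @param replicate replicate index (1-based).
#' @param config the [sim_config()] used to build `truth` (defaults to
#'   `truth$config`).
#' @return a `StrandedCoverage`.
#' @export
simulate_groseq <- function(truth, condition, replicate, config = truth$config) {
  if (!condition %in% GRO_CONDITIONS)
    stop("unknown condition label: ", condition,
         " (expected one of ", paste(GRO_CONDITIONS, collapse = ", "), ")")
  w <- config$bin_width
  mu <- list()
  for (chrom in names(truth$chrom_lengths)) {
    nb <- truth$chrom_lengths[[chrom]] / w
    mu[[chrom]] <- list(`+` = rep(config$background_density * w, nb),
                        `-` = rep(config$background_density * w, nb))
  }
  for (i in seq_len(nrow(truth$genes))) {
    g <- truth$genes[i]
    d <- g$base_density * 2^gro_fc(g, condition)
    mu[[g$chrom]][[g$strand]] <-
      add_emission(mu[[g$chrom]][[g$strand]], g$start, g$end, d, w)
    if (g$pausing_ratio > 1) {
      tss <- if (g$strand == "+") g$start else g$end
      pw <- if (g$strand == "+") c(tss, tss + 250) else c(tss - 250, tss)
      mu[[g$chrom]][[g$strand]] <-
        add_emission(mu[[g$chrom]][[g$strand]], pw[1], pw[2],
                     d * (g$pausing_ratio - 1), w)
    }
  }
  for (i in seq_len(nrow(truth$intergenic_enhancers))) {
    e <- truth$intergenic_enhancers[i]
    d <- e$density * 2^gro_fc(e, condition)
    mu[[e$chrom]][["+"]] <-
      add_emission(mu[[e$chrom]][["+"]], e$plus_start, e$plus_end, d, w)
    mu[[e$chrom]][["-"]] <-
      add_emission(mu[[e$chrom]][["-"]], e$minus_start, e$minus_end, d, w)
  }
  for (i in seq_len(nrow(truth$intragenic_enhancers))) {
    e <- truth$intragenic_enhancers[i]
    d <- e$density * 2^gro_fc(e, condition)
    mu[[e$chrom]][[e$strand]] <-
      add_emission(mu[[e$chrom]][[e$strand]], e$start, e$end, d, w)
  }
  lib_id <- paste0("gro_", condition, "_rep", replicate)
  with_seed(derive_seed(config$seed, "groseq", condition, replicate), {
    plus <- lapply(mu, function(x) draw_counts(x[["+"]], config$nb_dispersion))
    minus <- lapply(mu, function(x) draw_counts(x[["-"]], config$nb_dispersion))
    stranded_coverage(plus, minus, w, lib_id)
  })
}

chip_mu <- function(truth, factor, condition, config) {
  w <- config$bin_width
  mu <- lapply(truth$chrom_lengths, function(len)
    rep(config$chip_background_density * w, len / w))
  if (!is.null(factor)) {
    fac <- factor  # avoid data.table scoping onto the `factor` column
    sites <- truth$tf_sites[truth$tf_sites$factor == fac]
    if (nrow(sites) == 0 && !fac %in% truth$tf_sites$factor)
      stop("unknown factor: ", factor)
    for (i in seq_len(nrow(sites))) {
      s <- sites[i]
      active <- condition %in% strsplit(s$conditions, ",", fixed = TRUE)[[1]]
      if (!active) next
      mu[[s$chrom]] <- add_emission(
        mu[[s$chrom]], s$start, s$end,
        (config$chip_enrichment - 1) * config$chip_background_density, w)
    }
  }
  mu
}

#' Simulate ChIP-seq coverage for one factor, condition and replicate
#'
#' Unstranded: the returned `StrandedCoverage` carries the same draw on both
#' strands; downstream peak calling reads the plus strand. Sites are
#' enriched `chip_enrichment`-fold over background in the conditions listed
#' in the truth table; everywhere else the signal is flat background.
#'
#' @inheritParams simulate_groseq
#' @param factor factor name present in `truth$tf_sites`.
#' @param condition one of `"vehicle"`, `"t0.5"`, `"t2"`, `"t4"`.
#' @return a `StrandedCoverage`.
#' @export
simulate_chip_coverage <- function(truth, factor, condition, replicate,
                                   config = truth$config) {
  if (!condition %in% CHIP_CONDITIONS)
    stop("unknown condition label: ", condition)
  if (!factor %in% truth$tf_sites$factor)
    stop("unknown factor: ", factor)
  mu <- chip_mu(truth, factor, condition, config)
  with_seed(derive_seed(config$seed, "chip", factor, condition, replicate), {
    tags <- lapply(mu, draw_counts, dispersion = config$chip_nb_dispersion)
    stranded_coverage(tags, tags, config$bin_width,
                      paste0("chip_", factor, "_", condition, "_rep", replicate))
  })
}

#' Simulate a matched ChIP input (control) library: background only
#' @inheritParams simulate_chip_coverage
#' @return a `StrandedCoverage`.
#' @export
simulate_chip_control <- function(truth, replicate, config = truth$config) {
  mu <- chip_mu(truth, NULL, "vehicle", config)
  with_seed(derive_seed(config$seed, "chip", "input", "na", replicate), {
    tags <- lapply(mu, draw_counts, dispersion = config$chip_nb_dispersion)
    stranded_coverage(tags, tags, config$bin_width,
                      paste0("chip_input_rep", replicate))
  })
}

# ---- fixtures --------------------------------------------------------------

#' Write a TruthSet and a set of coverages to disk as plain-text fixtures
#'
#' Emits bedGraph pairs per library, the gene annotation as GFF3 and BED12,
#' truth tables as TSV and a manifest listing every file with its role and
#' md5 checksum.
#'
#' @param truth a `TruthSet`.
#' @param coverages named list of `StrandedCoverage` objects (names become
#'   file prefixes).
#' @param out_dir output directory (created if absent).
#' @return data.table manifest with columns `file, role, md5`.
#' @export
write_fixtures <- function(truth, coverages, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  entries <- list()
  add <- function(path, role) {
    entries[[length(entries) + 1]] <<- data.table(
      file = basename(path), role = role,
      md5 = unname(tools::md5sum(path)))
  }
  for (nm in names(coverages)) {
    paths <- write_coverage_bedgraphs(coverages[[nm]], file.path(out_dir, nm))
    add(paths[1], paste0("coverage_plus:", nm))
    add(paths[2], paste0("coverage_minus:", nm))
  }
  gsub_cols <- c("gene_id", "chrom", "start", "end", "strand")
  gff <- file.path(out_dir, "genes.gff3")
  write_gff3_genes(truth$genes[, gsub_cols, with = FALSE], gff); add(gff, "genes_gff3")
  b12 <- file.path(out_dir, "genes.bed12")
  write_bed12_genes(truth$genes, b12); add(b12, "genes_bed12")
  tables <- list(genes = truth$genes,
                 intergenic_enhancers = truth$intergenic_enhancers,
                 intragenic_enhancers = truth$intragenic_enhancers,
                 h3k4me2 = truth$h3k4me2, tf_sites = truth$tf_sites)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0("truth_", nm, ".tsv"))
    fwrite(tables[[nm]], p, sep = "\t")
    add(p, paste0("truth:", nm))
  }
  cl <- file.path(out_dir, "chrom_lengths.tsv")
  fwrite(data.table(chrom = names(truth$chrom_lengths),
                    length = as.integer(truth$chrom_lengths)), cl, sep = "\t")
  add(cl, "chrom_lengths")
  manifest <- data.table::rbindlist(entries)
  fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t")
  manifest
}
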