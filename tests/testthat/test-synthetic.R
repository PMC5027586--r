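# minimal hand-built TruthSet so emission tests control every parameter
blank_truth <- function(cfg, genes = NULL, inter = NULL, intra = NULL,
                        tf = NULL, chrom_length = 4e5) {
  empty_genes <- data.table::data.table(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), base_density = numeric(),
    log2fc_t0.5 = numeric(), log2fc_t2 = numeric(), pausing_ratio = numeric())
  empty_iv <- data.table::data.table(chrom = character(), start = integer(),
                                     end = integer())
  empty_tf <- data.table::data.table(factor = character(), chrom = character(),
                                     start = integer(), end = integer(),
                                     conditions = character())
  structure(list(config = cfg,
                 chrom_lengths = c(chrT = chrom_length),
                 genes = if (is.null(genes)) empty_genes else genes,
                 intergenic_enhancers = if (is.null(inter))
                   data.table::data.table() else inter,
                 intragenic_enhancers = if (is.null(intra))
                   data.table::data.table() else intra,
                 h3k4me2 = empty_iv,
                 tf_sites = if (is.null(tf)) empty_tf else tf),
            class = "TruthSet")
}
# zero-row enhancer tables with the right columns
no_inter <- data.table::data.table(
  enh_id = character(), chrom = character(), center = integer(),
  minus_start = integer(), minus_end = integer(), plus_start = integer(),
  plus_end = integer(), density = numeric(), log2fc_t0.5 = numeric(),
  log2fc_t2 = numeric())
no_intra <- data.table::data.table(
  enh_id = character(), host_gene = character(), chrom = character(),
  start = integer(), end = integer(), strand = character(),
  density = numeric(), log2fc_t0.5 = numeric(), log2fc_t2 = numeric())

test_that("generate_truth honours counts, determinism and invariants", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e6, n_genes = 10,
                    n_intergenic_enhancers = 0, n_intragenic_enhancers = 0,
                    seed = 1)
  truth <- generate_truth(cfg)
  expect_equal(nrow(truth$genes), 10)
  expect_equal(nrow(truth$intergenic_enhancers), 0)
  expect_identical(truth, generate_truth(cfg))

  cfg2 <- sim_config(n_chromosomes = 1, chrom_length = 1e6, n_genes = 20,
                     n_intergenic_enhancers = 3, n_intragenic_enhancers = 5,
                     seed = 2)
  t2 <- generate_truth(cfg2)
  # brute-force containment / length / H3K4me2 oracle on intragenic truths
  for (i in seq_len(nrow(t2$intragenic_enhancers))) {
    e <- t2$intragenic_enhancers[i]
    g <- t2$genes[t2$genes$gene_id == e$host_gene]
    expect_true(e$start >= g$start && e$end <= g$end)
    expect_true(e$end - e$start >= 150 && e$end - e$start <= 500)
    k4_hit <- FALSE
    for (j in seq_len(nrow(t2$h3k4me2)))
      if (t2$h3k4me2$chrom[j] == e$chrom &&
          iv_overlap(e$start, e$end, t2$h3k4me2$start[j], t2$h3k4me2$end[j]))
        k4_hit <- TRUE
    expect_true(k4_hit)
  }
  expect_silent(validate_truth(t2))
})

test_that("infeasible placement fails loudly naming the rule", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 2e5, n_genes = 50,
                    n_intergenic_enhancers = 0, n_intragenic_enhancers = 0)
  expect_error(generate_truth(cfg), "placement failure")
  cfg2 <- sim_config(n_chromosomes = 1, chrom_length = 1e6, n_genes = 30,
                     n_intergenic_enhancers = 50, n_intragenic_enhancers = 0)
  expect_error(generate_truth(cfg2), "placement failure")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(frac_genes_up = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(gene_length_range = c(500, 2000)), ">= 1000")
  expect_error(sim_config(n_genes = -1), "non-negative")
  expect_error(sim_config(frac_genes_up = 0.7, frac_genes_down = 0.6),
               "exceed 1")
})

test_that("GRO-seq emission has the right support and conserves totals", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 4e5,
                    background_density = 0, nb_dispersion = 0, seed = 5)
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chrT", start = 100000L, end = 110000L,
    strand = "+", base_density = 0.5, log2fc_t0.5 = 0, log2fc_t2 = 0,
    pausing_ratio = 1)
  truth <- blank_truth(cfg, genes = genes, inter = no_inter, intra = no_intra)
  cov <- simulate_groseq(truth, "vehicle", 1, cfg)
  w <- cfg$bin_width
  inside <- (100000 / w + 1):(110000 / w)
  expect_true(all(cov$plus$chrT[-inside] == 0))
  expect_true(sum(cov$plus$chrT[inside]) > 0)
  expect_true(all(cov$minus$chrT == 0))
  # conservation: recorded total equals the sum over both strands
  expect_equal(cov$total_tags, sum(cov$plus$chrT) + sum(cov$minus$chrT))
  # determinism and error on unknown condition
  expect_identical(cov, simulate_groseq(truth, "vehicle", 1, cfg))
  expect_error(simulate_groseq(truth, "t7", 1, cfg), "unknown condition")
})

test_that("condition fold changes are recovered in expectation", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e5,
                    background_density = 0, seed = 6)
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chrT", start = 20000L, end = 40000L,
    strand = "+", base_density = 0.5, log2fc_t0.5 = 0, log2fc_t2 = 1.0,
    pausing_ratio = 1)
  truth <- blank_truth(cfg, genes = genes, inter = no_inter, intra = no_intra,
                       chrom_length = 1e5)
  body <- function(cond, r) interval_tags(simulate_groseq(truth, cond, r, cfg),
                                          "chrT", 20000, 40000, "+")
  ratio <- mean(vapply(1:50, body, 0, cond = "t2")) /
    mean(vapply(1:50, body, 0, cond = "vehicle"))
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("pausing genes carry the configured promoter/body density ratio", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e5,
                    background_density = 0, seed = 7)
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chrT", start = 20000L, end = 40000L,
    strand = "+", base_density = 0.5, log2fc_t0.5 = 0, log2fc_t2 = 0,
    pausing_ratio = 10)
  truth <- blank_truth(cfg, genes = genes, inter = no_inter, intra = no_intra,
                       chrom_length = 1e5)
  prom <- body <- numeric(50)
  for (r in 1:50) {
    cov <- simulate_groseq(truth, "vehicle", r, cfg)
    prom[r] <- interval_density(cov, "chrT", 20000, 20250, "+")
    body[r] <- interval_density(cov, "chrT", 20250, 40000, "+")
  }
  expect_gt(mean(prom) / mean(body), 8)
  expect_lt(mean(prom) / mean(body), 12)
})

test_that("ChIP simulation: null factor matches control, sites are enriched", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 2e5, seed = 8)
  tf <- data.table::data.table(
    factor = c("X", "Y"), chrom = "chrT",
    start = c(50000L, 100000L), end = c(50400L, 100400L),
    conditions = c("t4", "vehicle"))
  truth <- blank_truth(cfg, tf = tf, chrom_length = 2e5)
  truth$genes <- data.table::data.table(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), base_density = numeric(),
    log2fc_t0.5 = numeric(), log2fc_t2 = numeric(), pausing_ratio = numeric())
  # X has no site active in vehicle -> genome-wide mean ratio near 1
  covX <- simulate_chip_coverage(truth, "X", "vehicle", 1, cfg)
  ctl <- simulate_chip_control(truth, 1, cfg)
  ratio <- mean(covX$plus$chrT) / mean(ctl$plus$chrT)
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)
  # Y active in vehicle: site enrichment near the configured 8-fold
  site_ratio <- mean(vapply(1:50, function(r)
    interval_tags(simulate_chip_coverage(truth, "Y", "vehicle", r, cfg),
                  "chrT", 100000, 100400, "+"), 0)) /
    mean(vapply(1:50, function(r)
      interval_tags(simulate_chip_control(truth, r, cfg),
                    "chrT", 100000, 100400, "+"), 0))
  expect_gt(site_ratio, 6); expect_lt(site_ratio, 10)
  expect_identical(covX, simulate_chip_coverage(truth, "X", "vehicle", 1, cfg))
  expect_error(simulate_chip_coverage(truth, "Z", "t2", 1, cfg),
               "unknown factor")
})

test_that("write_fixtures emits a complete, round-trippable manifest", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 6e5, n_genes = 8,
                    n_intergenic_enhancers = 2, n_intragenic_enhancers = 2,
                    seed = 4)
  truth <- generate_truth(cfg)
  cov <- simulate_groseq(truth, "vehicle", 1, cfg)
  manifest <- write_fixtures(truth, list(gro_vehicle_rep1 = cov), dir)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  # gene TSV row count equals n_genes
  gt <- data.table::fread(file.path(dir, "truth_genes.tsv"))
  expect_equal(nrow(gt), 8)
  # coverage round trip is bin-identical
  back <- read_coverage_bedgraphs(
    file.path(dir, "gro_vehicle_rep1_plus.bedgraph"),
    file.path(dir, "gro_vehicle_rep1_minus.bedgraph"),
    cfg$bin_width, truth$chrom_lengths)
  expect_equal(back$plus$chr1, as.numeric(cov$plus$chr1))
  expect_equal(back$minus$chr1, as.numeric(cov$minus$chr1))
  # BED12 and GFF3 agree after convention conversion
  gff <- read_gff3_genes(file.path(dir, "genes.gff3"))
  bed <- read_bed(file.path(dir, "genes.bed12"))
  expect_equal(gff$start, sort(bed$start))
  expect_equal(gff$end, sort(bed$end))
  # byte-identical fixtures on regeneration with the same seed
  dir2 <- withr::local_tempdir()
  manifest2 <- write_fixtures(generate_truth(cfg),
                              list(gro_vehicle_rep1 =
                                     simulate_groseq(truth, "vehicle", 1, cfg)),
                              dir2)
  expect_equal(manifest$md5, manifest2$md5)
})
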