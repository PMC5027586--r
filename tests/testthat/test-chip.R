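flat_cov <- function(value, n = 200, bw = 50)
  make_cov(rep(value, n), rep(value, n), bin_width = bw)

test_that("peak calling: null input, inclusive gates, sanity refusal", {
  # flat equal treatment and control -> no peaks
  expect_equal(nrow(call_peaks(flat_cov(5), flat_cov(5))), 0)
  expect_error(call_peaks(flat_cov(5), flat_cov(5), fold = 1), "saturates")
  expect_error(call_peaks(flat_cov(5), flat_cov(5, bw = 25)), "grid")

  # single enriched window over empty control: treatment 40 scaled tags vs
  # control 0 (+0.5): fold 80 >= 4 and norm_tags 40 >= 10 -> one peak.
  # Totals are made exactly 1e7 so the scale factor is 1 on both sides.
  trt <- rep(0, 200); trt[101:104] <- 10  # one 200-bp window with 40 tags
  trt[1:50] <- (1e7 - 40) / 50
  ctl <- rep(0, 200); ctl[1:50] <- 1e7 / 50
  got <- call_peaks(make_cov(trt, trt), make_cov(ctl, ctl))
  expect_equal(nrow(got), 1)
  # every sliding window touching the signal is marked over an empty
  # control, so the merged peak contains (and slightly pads) the signal
  expect_lte(got$start, 5000L)
  expect_gte(got$end, 5200L)
  expect_equal(got$norm_tags, 40)
  expect_equal(got$summit, 5025L)

  # exactly 4-fold and exactly min_norm_tags: retained (inclusive gates)
  # treatment 80, control 19.5 (+0.5 pseudocount) -> fold exactly 4.0
  trt2 <- rep(0, 200); trt2[101:104] <- 20
  trt2[1:50] <- (1e7 - 80) / 50
  ctl2 <- rep(0, 200); ctl2[101:104] <- 4.875  # 19.5 in the window
  ctl2[1:50] <- (1e7 - 19.5) / 50
  at_gate <- call_peaks(make_cov(trt2, trt2), make_cov(ctl2, ctl2),
                        fold = 4, min_norm_tags = 80)
  expect_equal(nrow(at_gate), 1)
  # a hair above the fold gate on the control side -> dropped
  ctl3 <- ctl2; ctl3[101] <- ctl3[101] + 0.5
  expect_equal(nrow(call_peaks(make_cov(trt2, trt2), make_cov(ctl3, ctl3),
                               fold = 4, min_norm_tags = 80)), 0)
  # norm_tags one unit under the floor -> dropped
  expect_equal(nrow(call_peaks(make_cov(trt2, trt2), make_cov(ctl2, ctl2),
                               fold = 4, min_norm_tags = 81)), 0)
})

test_that("replicate consensus matches a brute-force overlap oracle", {
  mk_peaks <- function(dt) {
    dt$summit <- (dt$start + dt$end) %/% 2L
    dt$norm_tags <- 100
    dt$fold_over_control <- 8
    data.table::setorder(dt, chrom, start)
    dt
  }
  set.seed(13)
  for (i in 1:20) {
    p1 <- mk_peaks(random_set(5))
    p2 <- mk_peaks(random_set(4))
    got <- replicate_consensus(p1, p2)
    want <- oracle_overlap_any(p1, p2)
    expect_equal(nrow(got), sum(want))
  }
  p <- mk_peaks(random_set(5))
  expect_equal(replicate_consensus(p, p)[, c("chrom", "start", "end")],
               p[, c("chrom", "start", "end")])
  far <- mk_peaks(data.table::data.table(chrom = "chrT",
                                         start = 20000L, end = 20200L))
  expect_equal(nrow(replicate_consensus(p, far)), 0)
})

test_that("genomic categorization: examples and random oracle", {
  genes <- gene_table(c("g1", "g2"), c("chrT", "chrT"), c(10000, 40000),
                      c(20000, 45000), c("+", "-"))
  pk <- function(s) data.table::data.table(chrom = "chrT", start = s - 100L,
                                           end = s + 100L, summit = as.integer(s))
  expect_equal(categorize_genomic(pk(10200), genes)$category, "promoter")
  expect_equal(categorize_genomic(pk(15000), genes)$category, "intragenic")
  expect_equal(categorize_genomic(pk(30000), genes)$category, "intergenic")
  # minus-strand TSS is the right end
  expect_equal(categorize_genomic(pk(45200), genes)$category, "promoter")
  set.seed(14)
  summits <- sample.int(50000, 1000)
  got <- categorize_genomic(pk(summits), genes, promoter_window = 1000)$category
  tss <- c(10000, 45000)
  want <- vapply(summits, function(s) {
    if (any(abs(s - tss) <= 1000)) "promoter"
    else if ((s >= 10000 && s < 20000) || (s >= 40000 && s < 45000)) "intragenic"
    else "intergenic"
  }, "")
  expect_equal(got, want)
})

test_that("three-set Venn categories equal the brute-force scan", {
  # anchored categories on a constructed layout
  s1 <- data.table::data.table(chrom = "chrT", start = c(100L, 1000L),
                               end = c(300L, 1200L))
  s2 <- data.table::data.table(chrom = "chrT", start = c(150L, 2000L),
                               end = c(350L, 2200L))
  s3 <- data.table::data.table(chrom = "chrT", start = c(120L, 3000L),
                               end = c(310L, 3200L))
  got <- timepoint_venn(s1, s2, s3)
  expect_equal(unname(got$counts[c("1", "4", "6", "7")]), c(1L, 1L, 1L, 1L))
  # category sizes sum to the merged universe size
  expect_equal(sum(got$counts), nrow(got$regions))
  set.seed(15)
  for (i in 1:15) {
    a <- random_set(6); b <- random_set(5); c_ <- random_set(7)
    got <- timepoint_venn(a, b, c_)
    expect_equal(got$counts, oracle_venn_counts(a, b, c_, 10000))
    expect_equal(sum(got$counts), nrow(got$regions))
  }
})

test_that("peak-to-TSS association: boundaries, nearest rule, fractions", {
  genes <- gene_table(c("gA", "gB", "gC"), rep("chrT", 3),
                      c(100000, 149999, 210000),
                      c(120000, 170000, 230000), c("+", "+", "+"))
  pk <- function(s) data.table::data.table(chrom = "chrT", summit = as.integer(s))
  # TSS 49,999 bp away: associated; 50,001 bp: not
  a1 <- associate_to_genes(pk(100000 - 49999), genes)$associations
  expect_equal(a1$gene_id, "gA")
  a2 <- associate_to_genes(pk(100000 - 50001), genes)$associations
  expect_true(is.na(a2$gene_id))
  # two TSSs at +10 kb and -40 kb: the +10 kb gene wins
  a3 <- associate_to_genes(pk(140000), genes)$associations
  expect_equal(a3$gene_id, "gB")
  expect_equal(a3$distance, 9999L)
  # tie at equal distance -> lexicographically smaller gene id
  genes_tie <- gene_table(c("gB", "gA"), c("chrT", "chrT"), c(0, 20000),
                          c(5000, 30000), c("+", "+"))  # TSS 0 and 20000
  a4 <- associate_to_genes(pk(10000), genes_tie)$associations
  expect_equal(a4$gene_id, "gA")
  # hand-computed association fractions on a toy table of 8 peaks, 4 genes
  genes4 <- gene_table(c("g1", "g2", "g3", "g4"), rep("chrT", 4),
                       c(10000, 100000, 200000, 300000),
                       c(20000, 110000, 210000, 310000), rep("+", 4))
  diff4 <- data.table::data.table(feature_id = c("g1", "g2", "g3", "g4"),
                                  class = c("up", "down", "non", "up"))
  peaks8 <- pk(c(9000, 12000, 99000, 101000, 199000, 202000, 299000, 600000))
  got <- associate_to_genes(peaks8, genes4, 50000, diff4)
  # peaks 1-2 -> g1 (up), 3-4 -> g2 (down), 5-6 -> g3 (non), 7 -> g4 (up),
  # 8 unassociated; fractions over the 7 associated peaks
  expect_equal(unname(got$class_fractions),
               c(3 / 7, 2 / 7, 2 / 7))
  expect_equal(got$peaks_per_gene$n_peaks[got$peaks_per_gene$gene_id == "g1"], 2L)
  # invariance to peak order
  got_rev <- associate_to_genes(peaks8[8:1], genes4, 50000, diff4)
  expect_equal(got_rev$class_fractions, got$class_fractions)
})

test_that("co-occurrence matrix: rules, symmetry, brute-force oracle", {
  # |A| = 4, |B| = 10, 3 of A overlapping -> 75
  a <- data.table::data.table(chrom = "chrT",
                              start = c(100L, 500L, 900L, 5000L),
                              end = c(200L, 600L, 1000L, 5100L))
  b <- data.table::data.table(chrom = "chrT",
                              start = c(100L, 520L, 950L, seq(2000L, 2600L, 100L)),
                              end = c(150L, 560L, 980L, seq(2050L, 2650L, 100L)))
  m <- cooccurrence(list(A = a, B = b))
  expect_equal(m["A", "B"], 75)
  expect_equal(m["A", "A"], 100)
  expect_equal(m, t(m))
  # empty set rows are NA, flagged not crashed
  m2 <- cooccurrence(list(A = a, E = a[0]))
  expect_true(is.na(m2["A", "E"]))
  expect_equal(m2["A", "A"], 100)
  set.seed(16)
  for (i in 1:10) {
    sets <- list(s1 = random_set(sample(3:20, 1)),
                 s2 = random_set(sample(3:20, 1)),
                 s3 = random_set(sample(3:20, 1)),
                 s4 = random_set(sample(3:20, 1)),
                 s5 = random_set(sample(3:20, 1)))
    m <- cooccurrence(sets)
    expect_equal(m, oracle_cooccurrence(sets))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 100))
    expect_true(all(m >= 0 & m <= 100))
  }
})

test_that("matrix clustering: adjacency, blocks, label equivariance", {
  m <- rbind(c(100, 95, 10), c(95, 100, 12), c(10, 12, 100))
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  cl <- cluster_matrix(m)
  # the two near-identical rows are adjacent leaves
  ab <- match(c("a", "b"), cl$order)
  expect_equal(abs(diff(ab)), 1)
  expect_match(cl$newick, "^\\(")
  # block-diagonal matrix: blocks form separate subtrees (first merge pairs
  # stay within blocks, cutting into 2 clusters recovers the blocks)
  blk <- matrix(5, 6, 6)
  blk[1:3, 1:3] <- 90; blk[4:6, 4:6] <- 90; diag(blk) <- 100
  dimnames(blk) <- list(letters[1:6], letters[1:6])
  cl2 <- cluster_matrix(blk)
  groups <- stats::cutree(cl2$hclust, k = 2)
  expect_equal(length(unique(groups[1:3])), 1)
  expect_equal(length(unique(groups[4:6])), 1)
  expect_false(groups[1] == groups[4])
  # label permutation yields a consistently permuted ordering
  perm <- c(3, 1, 2)
  mp <- m[perm, perm]
  clp <- cluster_matrix(mp)
  expect_equal(sort(clp$order), sort(cl$order))
  adj <- function(ord) abs(diff(match(c("a", "b"), ord)))
  expect_equal(adj(clp$order), 1)
  expect_error(cluster_matrix(matrix(1, 2, 3)), "square")
})

test_that("enhancer-group gene fold changes: trivial cases and gates", {
  genes <- gene_table(c("g1", "g2", "g3"), rep("chrT", 3),
                      c(10000, 100000, 200000),
                      c(20000, 110000, 210000), rep("+", 3))
  diff0 <- data.table::data.table(feature_id = c("g1", "g2", "g3"),
                                  class = c("non", "non", "untranscribed"),
                                  log2fc = c(0, 0, 5))
  groups <- list(up = data.table::data.table(chrom = "chrT", start = 9000L,
                                             end = 9400L),
                 non = data.table::data.table(chrom = "chrT", start = 99000L,
                                              end = 99400L),
                 empty = data.table::data.table(chrom = "chrT",
                                                start = integer(),
                                                end = integer()))
  got <- enhancer_gene_change(groups, genes, diff0)
  # all genes at log2fc 0 -> every nonempty group median 0
  expect_equal(got$summary$median[1:2], c(0, 0))
  expect_equal(got$summary$n[3], 0L)  # empty group flagged, not an error
  # untranscribed neighbours never appear even when closest
  g3_enh <- list(x = data.table::data.table(chrom = "chrT", start = 199000L,
                                            end = 199400L),
                 y = groups$up)
  got3 <- enhancer_gene_change(g3_enh, genes, diff0)
  expect_equal(got3$summary$n[1], 0L)
})
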