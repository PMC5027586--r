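#' Assemble and validate a full pipeline configuration
#'
#' All stage parameters live in one auditable object; every module block is
#' validated by its own constructor before any computation starts.
#'
#' @param sim a [sim_config()].
#' @param detection a [detection_params()].
#' @param gene_gates,enhancer_gates [thresholds()] objects.
#' @param chip_window,chip_fold,chip_min_norm_tags peak-calling gates.
#' @param association_window TSS association half-width (bp).
#' @param promoter_window promoter half-width for genomic categories (bp).
#' @param norm_method differential normalization: `"total"` or `"tmm"`.
#' @param out_dir output directory.
#' @param seed overrides `sim$seed` when non-NULL.
#' @param write_fixture_files also write the simulated coverages/truth as
#'   fixture files under `out_dir/fixtures`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(sim = sim_config(), detection = detection_params(),
                       gene_gates = gene_thresholds(),
                       enhancer_gates = enhancer_thresholds(),
                       chip_window = 200, chip_fold = 4,
                       chip_min_norm_tags = 10,
                       association_window = 50000, promoter_window = 1000,
                       norm_method = c("total", "tmm"),
                       out_dir = tempfile("nascentr_run_"), seed = NULL,
                       write_fixture_files = FALSE) {
  norm_method <- match.arg(norm_method)
  stopifnot(inherits(sim, "sim_config"), inherits(detection, "detection_params"),
            inherits(gene_gates, "thresholds"),
            inherits(enhancer_gates, "thresholds"))
  if (chip_fold <= 1) stop("chip_fold must exceed 1")
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, detection = detection, gene_gates = gene_gates,
                 enhancer_gates = enhancer_gates, chip_window = chip_window,
                 chip_fold = chip_fold, chip_min_norm_tags = chip_min_norm_tags,
                 association_window = association_window,
                 promoter_window = promoter_window,
                 norm_method = norm_method, out_dir = out_dir,
                 write_fixture_files = write_fixture_files),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Recognised top-level blocks: `sim`, `detection`, `gene_gates`,
#' `enhancer_gates` plus the scalar fields of [run_config()]; each block is
#' passed to its constructor so invalid values fail before computation.
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  args <- list()
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, as.list(raw$sim))
  if (!is.null(raw$detection))
    args$detection <- do.call(detection_params, as.list(raw$detection))
  if (!is.null(raw$gene_gates))
    args$gene_gates <- do.call(thresholds, as.list(raw$gene_gates))
  if (!is.null(raw$enhancer_gates))
    args$enhancer_gates <- do.call(thresholds, as.list(raw$enhancer_gates))
  for (f in c("chip_window", "chip_fold", "chip_min_norm_tags",
              "association_window", "promoter_window", "norm_method",
              "out_dir", "seed", "write_fixture_files"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(run_config, args)
}

gro_library_set <- function(truth, cfg) {
  libs <- list()
  conditions <- character(0)
  for (cond in GRO_CONDITIONS) for (r in seq_len(cfg$n_replicates)) {
    id <- paste0("gro_", cond, "_rep", r)
    libs[[id]] <- simulate_groseq(truth, cond, r, cfg)
    conditions <- c(conditions, cond)
  }
  list(libs = libs, conditions = conditions)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulate -> detect -> quantify -> classify -> integrate, writing every
#' result table under `config$out_dir` and returning them together with a
#' checksummed manifest. Reruns with an identical configuration reproduce
#' byte-identical manifests.
#'
#' @param config a [run_config()].
#' @return invisible list with all stage outputs (`truth`, `transcripts`,
#'   `gene_diff`, `ppi`, `enhancers`, `enhancer_diff`, `peak_sets`,
#'   `genomic_categories`, `venn`, `association`, `cooccurrence`,
#'   `clustering`, `enhancer_gene_fc`, `evaluation`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config$sim
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("stage setup failed: cannot create ", out_dir)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      marker <- file.path(out_dir, "failed")
      writeLines(paste0("failed stage: ", name, "\n", conditionMessage(e)), marker)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  truth <- stage("simulate", {
    t <- generate_truth(cfg)
    validate_truth(t)
    t
  })
  gro <- stage("simulate", gro_library_set(truth, cfg))
  if (isTRUE(config$write_fixture_files))
    stage("fixtures", write_fixtures(truth, gro$libs,
                                     file.path(out_dir, "fixtures")))

  combined <- stage("detect", combine_libraries(gro$libs))
  transcripts <- stage("detect", detect_transcripts(combined, config$detection))

  gene_diff <- stage("differential_genes", {
    counts <- vapply(gro$libs, function(cov)
      count_features(truth$genes, cov, "sense"), integer(nrow(truth$genes)))
    fc <- feature_counts(counts, vapply(gro$libs, `[[`, 0, "total_tags"),
                         truth$genes$end - truth$genes$start, gro$conditions,
                         feature_ids = truth$genes$gene_id)
    run_differential(fc, config$gene_gates, "vehicle",
                     norm_method = config$norm_method)
  })

  ppi <- stage("pausing", {
    rows <- lapply(seq_len(nrow(truth$genes)), function(i) {
      r <- pausing_index(truth$genes[i], combined)
      data.table(gene_id = r$gene_id, promoter_density = r$promoter_density,
                 body_density = r$body_density, ppi = r$ppi,
                 defined = r$defined)
    })
    data.table::rbindlist(rows)
  })

  enhancers <- stage("enhancers", {
    inter <- call_intergenic(transcripts, truth$genes)
    intra <- call_intragenic(transcripts, truth$genes, truth$h3k4me2)
    rbind(inter, intra)
  })
  enhancer_diff <- stage("differential_enhancers", {
    if (nrow(enhancers) == 0) NULL else {
      ec <- quantify_enhancers(enhancers, gro$libs, gro$conditions)
      run_differential(ec, config$enhancer_gates, "vehicle",
                       norm_method = config$norm_method)
    }
  })
  timepoint_classes <- stage("differential_enhancers", {
    if (is.null(enhancer_diff)) NULL else enhancer_timepoint_overlap(
      enhancer_diff[enhancer_diff$condition == "t0.5",
                    c("feature_id", "class")][, .(enh_id = feature_id, class)],
      enhancer_diff[enhancer_diff$condition == "t2",
                    c("feature_id", "class")][, .(enh_id = feature_id, class)])
  })

  chip <- stage("chip", {
    controls <- lapply(seq_len(cfg$n_replicates), function(r)
      simulate_chip_control(truth, r, cfg))
    plan <- list(AR = c("t0.5", "t2", "t4"), FOXA1 = c("vehicle", "t2"),
                 PIAS1 = c("vehicle", "t2"), ERG = c("vehicle", "t2"),
                 HDAC3 = c("vehicle", "t2"))
    plan <- plan[names(plan) %in% unique(truth$tf_sites$factor)]
    peak_sets <- list()
    for (fac in names(plan)) for (cond in plan[[fac]]) {
      reps <- lapply(seq_len(cfg$n_replicates), function(r)
        call_peaks(simulate_chip_coverage(truth, fac, cond, r, cfg),
                   controls[[r]], config$chip_window, config$chip_fold,
                   config$chip_min_norm_tags))
      consensus <- if (length(reps) > 1)
        replicate_consensus(reps[[1]], reps[[2]]) else reps[[1]]
      peak_sets[[paste0(fac, "_", cond)]] <- consensus
    }
    peak_sets
  })

  ar_sets <- chip[grep("^AR_", names(chip))]
  genomic_categories <- stage("categorize", lapply(ar_sets, function(p)
    categorize_genomic(p, truth$genes, config$promoter_window)$counts))
  venn <- stage("venn", if (all(c("AR_t0.5", "AR_t2", "AR_t4") %in% names(chip)))
    timepoint_venn(chip$AR_t0.5, chip$AR_t2, chip$AR_t4) else NULL)

  gene_diff_t2 <- gene_diff[gene_diff$condition == "t2"]
  association <- stage("associate", if ("AR_t2" %in% names(chip))
    associate_to_genes(chip$AR_t2, truth$genes, config$association_window,
                       gene_diff_t2) else NULL)

  enh_class_sets <- stage("cooccurrence", {
    if (is.null(enhancer_diff)) list() else {
      d2 <- enhancer_diff[enhancer_diff$condition == "t2"]
      lapply(setNames(c("up", "down", "non"),
                      paste0("enhancers_", c("up", "down", "non"))),
             function(cl) {
               ids <- d2$feature_id[d2$class == cl]
               enhancers[enhancers$enh_id %in% ids,
                         c("chrom", "start", "end")]
             })
    }
  })
  cooc_sets <- c(enh_class_sets,
                 lapply(chip, function(p) p[, c("chrom", "start", "end")]))
  cooc_sets <- cooc_sets[vapply(cooc_sets, nrow, 0L) > 0]
  cooc <- stage("cooccurrence",
                if (length(cooc_sets) >= 2) cooccurrence(cooc_sets) else NULL)
  clustering <- stage("cooccurrence",
                      if (!is.null(cooc) && nrow(cooc) >= 2 && !anyNA(cooc))
                        cluster_matrix(cooc) else NULL)

  enhancer_gene_fc <- stage("enhancer_gene_change", {
    if (!length(enh_class_sets)) NULL else {
      groups <- enh_class_sets
      if ("AR_t2" %in% names(chip) && nrow(enhancers)) {
        hit <- count_overlaps0(as_granges0(enhancers), as_granges0(chip$AR_t2)) > 0
        groups$enhancers_with_AR <- enhancers[hit, c("chrom", "start", "end")]
      }
      enhancer_gene_change(groups, truth$genes, gene_diff_t2,
                           config$association_window)
    }
  })

  evaluation <- stage("evaluate", evaluate_run(
    truth, transcripts, enhancers, gene_diff, enhancer_diff, chip,
    config$detection$init_window))

  manifest <- stage("write", {
    paths <- c()
    wr <- function(name, writer) {
      p <- file.path(out_dir, name); writer(p); paths <<- c(paths, p)
    }
    wr("transcripts.bed", function(p) write_transcripts_bed(transcripts, p))
    wr("gene_differential.tsv", function(p) fwrite(gene_diff, p, sep = "\t"))
    wr("pausing_index.tsv", function(p) fwrite(ppi, p, sep = "\t"))
    wr("enhancers.tsv", function(p) fwrite(enhancers, p, sep = "\t"))
    if (!is.null(enhancer_diff))
      wr("enhancer_differential.tsv",
         function(p) fwrite(enhancer_diff, p, sep = "\t"))
    for (nm in names(chip)) {
      local({
        nm2 <- nm
        wr(paste0("peaks_", nm2, ".bed"),
           function(p) write_peaks_bed(chip[[nm2]], p))
      })
    }
    if (!is.null(venn))
      wr("venn_categories.tsv", function(p)
        fwrite(data.table(category = names(venn$counts),
                          n = as.integer(venn$counts)), p, sep = "\t"))
    if (!is.null(cooc))
      wr("cooccurrence.tsv", function(p)
        fwrite(data.table(set = rownames(cooc), as.data.table(cooc)), p,
               sep = "\t"))
    if (!is.null(clustering))
      wr("cooccurrence_dendrogram.nwk",
         function(p) writeLines(clustering$newick, p))
    wr("evaluation.tsv", function(p) fwrite(evaluation, p, sep = "\t"))
    mf <- data.table(file = basename(paths), md5 = unname(tools::md5sum(paths)))
    fwrite(mf, file.path(out_dir, "manifest.tsv"), sep = "\t")
    mf
  })

  invisible(list(truth = truth, transcripts = transcripts,
                 gene_diff = gene_diff, ppi = ppi, enhancers = enhancers,
                 enhancer_diff = enhancer_diff,
                 timepoint_classes = timepoint_classes, peak_sets = chip,
                 genomic_categories = genomic_categories, venn = venn,
                 association = association, cooccurrence = cooc,
                 clustering = clustering, enhancer_gene_fc = enhancer_gene_fc,
                 evaluation = evaluation, manifest = manifest))
}

#' Compare pipeline calls against the planted ground truth
#'
#' Reports recovery and false-call rates: a gene counts as recovered when
#' same-strand transcripts cover it with both boundary errors (of their
#' union hull) within one initiation window; enhancers by >= 1 bp overlap
#' of a call of the right kind; ChIP sites by consensus-peak overlap in the
#' conditions where the site is active.
#'
#' @param truth a `TruthSet`.
#' @param transcripts detected transcripts.
#' @param enhancers called enhancer catalog.
#' @param gene_diff,enhancer_diff differential tables (may be NULL).
#' @param peak_sets named list of consensus peak tables (may be empty).
#' @param init_window boundary tolerance in bp for gene recovery.
#' @return data.table of `metric, value, n`.
#' @export
evaluate_run <- function(truth, transcripts, enhancers, gene_diff = NULL,
                         enhancer_diff = NULL, peak_sets = list(),
                         init_window = 200) {
  rows <- list()
  add <- function(metric, value, n) rows[[length(rows) + 1L]] <<-
    data.table(metric = metric, value = value, n = as.integer(n))

  genes <- truth$genes
  if (nrow(genes)) {
    rec <- vapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i]
      tx <- transcripts[transcripts$chrom == g$chrom &
                          transcripts$strand == g$strand &
                          transcripts$start < g$end & transcripts$end > g$start]
      if (nrow(tx) == 0) return(FALSE)
      abs(min(tx$start) - g$start) <= init_window &&
        abs(max(tx$end) - g$end) <= init_window
    }, TRUE)
    add("gene_unit_recovery", mean(rec), nrow(genes))
  }

  inter_t <- truth$intergenic_enhancers
  if (nrow(inter_t)) {
    called <- enhancers[enhancers$kind == "intergenic"]
    rec <- vapply(seq_len(nrow(inter_t)), function(i) {
      e <- inter_t[i]
      any(called$chrom == e$chrom & called$start < e$plus_end &
            called$end > e$minus_start)
    }, TRUE)
    add("intergenic_enhancer_recovery", mean(rec), nrow(inter_t))
  }
  intra_t <- truth$intragenic_enhancers
  if (nrow(intra_t)) {
    called <- enhancers[enhancers$kind == "intragenic"]
    rec <- vapply(seq_len(nrow(intra_t)), function(i) {
      e <- intra_t[i]
      any(called$chrom == e$chrom & called$strand == e$strand &
            called$start < e$end & called$end > e$start)
    }, TRUE)
    add("intragenic_enhancer_recovery", mean(rec), nrow(intra_t))
  }
  if (nrow(enhancers)) {
    truth_spans <- rbind(
      data.table(chrom = inter_t$chrom, start = inter_t$minus_start,
                 end = inter_t$plus_end),
      data.table(chrom = intra_t$chrom, start = intra_t$start,
                 end = intra_t$end))
    false <- vapply(seq_len(nrow(enhancers)), function(i) {
      e <- enhancers[i]
      !any(truth_spans$chrom == e$chrom & truth_spans$start < e$end &
             e$start < truth_spans$end)
    }, TRUE)
    add("enhancer_false_call_rate", mean(false), nrow(enhancers))
  }

  if (!is.null(gene_diff)) {
    d2 <- gene_diff[gene_diff$condition == "t2"]
    planted_up <- genes$gene_id[genes$log2fc_t2 > 0]
    planted_down <- genes$gene_id[genes$log2fc_t2 < 0]
    if (length(planted_up))
      add("gene_up_recovery",
          mean(d2$class[match(planted_up, d2$feature_id)] == "up"),
          length(planted_up))
    if (length(planted_down))
      add("gene_down_recovery",
          mean(d2$class[match(planted_down, d2$feature_id)] == "down"),
          length(planted_down))
    null_ids <- genes$gene_id[genes$log2fc_t2 == 0]
    if (length(null_ids))
      add("gene_null_false_call",
          mean(d2$class[match(null_ids, d2$feature_id)] %in% c("up", "down")),
          length(null_ids))
  }
  if (!is.null(enhancer_diff)) {
    d2 <- enhancer_diff[enhancer_diff$condition == "t2"]
    truth_fc <- rbind(
      data.table(chrom = inter_t$chrom, start = inter_t$minus_start,
                 end = inter_t$plus_end, fc = inter_t$log2fc_t2),
      data.table(chrom = intra_t$chrom, start = intra_t$start,
                 end = intra_t$end, fc = intra_t$log2fc_t2))
    reg <- truth_fc[truth_fc$fc != 0]
    if (nrow(reg) && nrow(enhancers)) {
      hit <- vapply(seq_len(nrow(reg)), function(i) {
        e <- reg[i]
        j <- which(enhancers$chrom == e$chrom & enhancers$start < e$end &
                     e$start < enhancers$end)
        if (!length(j)) return(NA)
        cls <- d2$class[match(enhancers$enh_id[j], d2$feature_id)]
        if (e$fc > 0) "up" %in% cls else "down" %in% cls
      }, TRUE)
      add("enhancer_regulation_recovery", mean(hit, na.rm = TRUE),
          sum(!is.na(hit)))
    }
  }

  for (nm in names(peak_sets)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    fac <- parts[1]; cond <- paste(parts[-1], collapse = "_")
    sites <- truth$tf_sites[truth$tf_sites$factor == fac]
    if (nrow(sites) == 0) next
    active <- vapply(sites$conditions, function(cs)
      cond %in% strsplit(cs, ",", fixed = TRUE)[[1]], TRUE)
    sites <- sites[active]
    pk <- peak_sets[[nm]]
    if (nrow(sites)) {
      rec <- vapply(seq_len(nrow(sites)), function(i) {
        s <- sites[i]
        any(pk$chrom == s$chrom & pk$start < s$end & s$start < pk$end)
      }, TRUE)
      add(paste0("peak_recovery_", nm), mean(rec), nrow(sites))
    }
  }
  data.table::rbindlist(rows)
}
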