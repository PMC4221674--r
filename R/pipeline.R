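#' Default end-to-end run configuration
#'
#' Assembles the configuration consumed by [run_all()]: simulation
#' parameters (a [simulation_config()]), analysis parameters and stage
#' toggles. Stage seeds are derived from the single master seed through
#' named substreams, so one number reproduces the whole run.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed.
#' @param alpha Omnibus FDR threshold.
#' @param n_perm Monte Carlo permutations (used only above the exhaustive
#'   cap).
#' @param window_bp Peak-to-gene assignment window.
#' @param mark Histone mark label for the simulated ChIP arm.
#' @param sim Optional [simulation_config()] override.
#' @param stages Named logical vector toggling `simulate`, `diff_mirna`,
#'   `smallrna`, `chipseq`, `plasticity`, `network`.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(outdir, seed = 1L, alpha = 0.05,
                               n_perm = 2000L, window_bp = 2000L,
                               mark = "H3K4me1", sim = NULL,
                               stages = c(simulate = TRUE,
                                          diff_mirna = TRUE,
                                          smallrna = TRUE,
                                          chipseq = TRUE,
                                          plasticity = TRUE,
                                          network = TRUE)) {
  if (is.null(sim)) {
    sim <- simulation_config(seed = seed, n_features = 80L, n_onoff = 1L,
                             n_genes = 60L, n_peaks = 30L,
                             n_smallrna_reads = 1500L, n_mirnas = 15L)
  }
  cfg <- list(outdir = outdir, seed = as.integer(seed), alpha = alpha,
              n_perm = as.integer(n_perm), window_bp = as.integer(window_bp),
              mark = mark, sim = sim, stages = stages)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads scalar fields (`outdir`, `seed`, `alpha`, `n_perm`, `window_bp`,
#' `mark`), a `stages` map and a `sim` map of [simulation_config()]
#' arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(simulation_config, y$sim) else NULL
  args <- y[setdiff(names(y), c("sim", "stages"))]
  cfg <- do.call(default_run_config, c(args, list(sim = sim)))
  if (!is.null(y$stages)) {
    st <- cfg$stages
    st[names(y$stages)] <- unlist(y$stages)
    cfg$stages <- st
  }
  cfg
}

#' Run the full synthetic-to-network pipeline
#'
#' Executes the enabled stages in dependency order - simulation,
#' miRNA/gene differential analysis, degradation-fragment calling, ChIP
#' peak merging + FPKM + background correction, chip differential
#' analysis, plasticity classification and network construction - writing
#' each stage's tables under `outdir` and finally a `manifest.json`
#' recording parameters, seeds and the MD5 checksum of every output.
#' Re-running the same configuration reproduces identical checksums.
#'
#' @param config A `run_config` (from [default_run_config()] or
#'   [read_run_config()]) or a path to a YAML file.
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  skipped <- names(config$stages)[!config$stages]
  st <- function(name) isTRUE(config$stages[[name]])
  emit <- function(obj, file, writer = utils::write.table) {
    fp <- file.path(config$outdir, file)
    if (identical(writer, utils::write.table)) {
      utils::write.table(obj, fp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      writer(obj, fp)
    }
    paths <<- c(paths, fp)
    fp
  }
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- NULL
  if (st("simulate")) {
    sim <- run_stage("simulate", {
      cfg <- config$sim
      design <- simulate_design(cfg$n_replicates)
      annotation <- simulate_annotation(cfg)
      mirna <- simulate_counts(cfg, "mirna")
      gene_cfg <- cfg; gene_cfg$n_features <- cfg$n_genes
      genes <- simulate_counts(gene_cfg, "gene")
      rownames(genes$counts) <- genes$truth$feature <- annotation$gene_id
      chip <- simulate_peaks(cfg, design, annotation)
      srna <- simulate_smallrna_reads(cfg, design, annotation)
      inter <- simulate_interactions(cfg, annotation)
      emit(design, "design.tsv")
      emit(NULL, "annotation.gff3", function(o, fp)
        write_annotation(annotation, fp))
      write_counts_tsv(mirna$counts,
                       file.path(config$outdir, "mirna_counts.tsv"))
      write_counts_tsv(genes$counts,
                       file.path(config$outdir, "gene_counts.tsv"))
      paths <<- c(paths, file.path(config$outdir,
                                   c("mirna_counts.tsv", "gene_counts.tsv")))
      emit(inter$targets, "mirna_targets.tsv")
      emit(inter$interactions, "gene_interactions.tsv")
      emit(mirna$truth, "truth_mirna.tsv")
      emit(chip$truth, "truth_peaks.tsv")
      emit(srna$truth, "truth_smallrna.tsv")
      list(design = design, annotation = annotation, mirna = mirna,
           genes = genes, chip = chip, srna = srna, inter = inter)
    })
  }
  need_sim <- function(stage) {
    if (is.null(sim)) {
      stop(sprintf("stage '%s' needs the simulate stage outputs", stage),
           call. = FALSE)
    }
  }

  diff_mirna <- diff_genes <- NULL
  if (st("diff_mirna")) {
    diff_mirna <- run_stage("diff_mirna", {
      need_sim("diff_mirna")
      dm <- differential_analysis(sim$mirna$counts, sim$design,
                                  alpha = config$alpha,
                                  n_perm = config$n_perm,
                                  seed = stage_seed(config$seed, "diff_mirna"))
      dg <- differential_analysis(sim$genes$counts, sim$design,
                                  alpha = config$alpha,
                                  n_perm = config$n_perm,
                                  seed = stage_seed(config$seed, "diff_genes"))
      emit(dm, "diff_mirna.tsv")
      emit(dg, "diff_genes.tsv")
      diff_genes <- dg
      dm
    })
  }

  if (st("smallrna")) {
    run_stage("smallrna", {
      need_sim("smallrna")
      calls <- call_degradation_genes(sim$srna$reads, sim$annotation,
                                      sim$design)
      hist_all <- do.call(rbind, lapply(sim$design$sample_id, function(s) {
        h <- length_histogram(sim$srna$reads[[s]])
        cbind(sample_id = s, h, stringsAsFactors = FALSE)
      }))
      emit(calls, "degradation_calls.tsv")
      emit(hist_all, "smallrna_length_histograms.tsv")
    })
  }

  chipres <- diff_chip <- peak_genes <- NULL
  if (st("chipseq")) {
    chipres <- run_stage("chipseq", {
      need_sim("chipseq")
      merged <- merge_peaks(sim$chip$peaks)
      cf <- count_and_fpkm(merged, sim$chip$reads, sim$chip$library_sizes)
      bc <- background_correct(cf$fpkm, sim$chip$reads, merged,
                               sim$chip$genome, sim$chip$library_sizes)
      pg <- assign_genes(merged, sim$annotation, config$window_bp)
      emit(merged, "merged_peaks.tsv")
      write_counts_tsv(bc$corrected,
                       file.path(config$outdir, "peak_signal.tsv"))
      paths <<- c(paths, file.path(config$outdir, "peak_signal.tsv"))
      emit(pg, "peak_genes.tsv")
      dc <- differential_analysis(bc$corrected, sim$design,
                                  alpha = config$alpha, normalize = FALSE,
                                  n_perm = config$n_perm,
                                  seed = stage_seed(config$seed, "diff_chip"))
      emit(dc, "diff_chip.tsv")
      diff_chip <- dc
      peak_genes <- pg
      list(merged = merged, corrected = bc$corrected, peak_genes = pg)
    })
  }

  memb_mirna <- memb_chip <- NULL
  if (st("plasticity")) {
    run_stage("plasticity", {
      if (is.null(diff_mirna) || is.null(diff_chip)) {
        stop("plasticity needs diff_mirna and chipseq outputs", call. = FALSE)
      }
      memb_mirna <- classify_contrasts(diff_mirna)
      memb_chip <- classify_contrasts(diff_chip)
      venn <- venn_overlap(memb_mirna)
      markers <- accelerated_aging_markers(memb_chip, peak_genes)
      emit(memb_mirna, "membership_mirna.tsv")
      emit(memb_chip, "membership_chip.tsv")
      emit(venn, "venn_mirna.tsv")
      emit(markers$markers, "aging_markers.tsv")
    })
  }

  if (st("network")) {
    run_stage("network", {
      if (is.null(memb_mirna) || is.null(diff_genes) || is.null(diff_chip)) {
        stop("network needs plasticity, diff_mirna and chipseq outputs",
             call. = FALSE)
      }
      plastic_mirnas <- memb_mirna$feature[
        memb_mirna$sig_young_mated_vs_virgin]
      ## simulated target tables index miRNAs by the same ids as the counts
      plastic_genes <- diff_genes$feature[
        diff_genes$sig_young_mated_vs_virgin]
      net <- build_network(plastic_mirnas, sim$inter$targets,
                           plastic_genes, sim$inter$interactions)
      diff_peaks <- diff_chip$feature[
        rowSums(as.matrix(diff_chip[, paste0("sig_", contrast_names())])) > 0]
      net <- overlay_histone_marks(
        net,
        stats::setNames(list(peak_genes), config$mark),
        stats::setNames(list(diff_peaks), config$mark)
      )
      fn <- export_network(net, file.path(config$outdir, "network"),
                           format = "tsv")
      paths <<- c(paths, fn)
      fn2 <- export_network(net, file.path(config$outdir, "network.sif"),
                            format = "sif")
      paths <<- c(paths, fn2)
    })
  }

  manifest <- list(
    parameters = list(seed = config$seed, alpha = config$alpha,
                      n_perm = config$n_perm, window_bp = config$window_bp,
                      mark = config$mark,
                      sim = unclass(config$sim)),
    stages_run = names(config$stages)[config$stages],
    stages_skipped = skipped,
    outputs = lapply(stats::setNames(paths, basename(paths)), function(fp) {
      list(path = basename(fp), md5 = unname(tools::md5sum(fp)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
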