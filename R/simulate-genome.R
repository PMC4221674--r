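#' Simulate a toy gene annotation
#'
#' Places `n_genes` non-overlapping genes on the configured chromosomes.
#' Genes are laid on disjoint slots (slot width = max gene length + 5 kb)
#' so that gene spans, and their 2 kb flanking windows, rarely collide and
#' planted per-gene truths stay unambiguous. Coordinates are 0-based,
#' half-open, matching BED conventions.
#'
#' @param config A [simulation_config()].
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, "annotation", {
    slot <- max(config$gene_length) + 5000
    per_chrom <- floor(config$chrom_length / slot)
    total_slots <- per_chrom * config$n_chromosomes
    if (total_slots < config$n_genes) {
      stop("genome too small for the requested number of genes")
    }
    slots <- sort(sample.int(total_slots, config$n_genes))
    chrom_i <- (slots - 1L) %/% per_chrom + 1L
    offset <- ((slots - 1L) %% per_chrom) * slot
    len <- round(stats::runif(config$n_genes, config$gene_length[1],
                              config$gene_length[2]))
    start <- offset + round(stats::runif(config$n_genes, 0,
                                         slot - len - 4000)) + 2000
    data.frame(gene_id = sprintf("g%04d", seq_len(config$n_genes)),
               chrom = paste0("chr", chrom_i),
               start = as.integer(start), end = as.integer(start + len),
               stringsAsFactors = FALSE)
  })
}

#' Toy genome table for a configuration
#' @param config A [simulation_config()].
#' @return data.frame with columns `chrom` and `length`.
#' @export
simulate_genome <- function(config) {
  data.frame(chrom = paste0("chr", seq_len(config$n_chromosomes)),
             length = rep(config$chrom_length, config$n_chromosomes),
             stringsAsFactors = FALSE)
}

## The planted peak classes and their per-condition log2 fold changes
## (in units of peak_effect_lfc), in conditions() order:
## marker          0 d d d  (up after mating, persists, co-occurs in aged virgins)
## transient       0 d 0 0  (up after mating, reverses with age in mated flies)
## persistent_only 0 d 0 d  (persists but never arises in aging virgins)
## aging_only      0 0 d 0  (virgin-aging change without a mating response)
peak_class_patterns <- function() {
  rbind(marker          = c(0, 1, 1, 1),
        transient       = c(0, 1, 0, 0),
        persistent_only = c(0, 1, 0, 1),
        aging_only      = c(0, 0, 1, 0),
        null            = c(0, 0, 0, 0))
}

#' Simulate per-sample ChIP peak calls and reads
#'
#' Builds master peaks on the toy genome, each anchored on a distinct gene,
#' then realizes them per sample with boundary jitter and negative-binomial
#' read counts. Planted classes (see Details) are present in every sample;
#' null master peaks recur in a configurable fraction of samples and half
#' of the null peaks are drawn narrow enough to fail the >146 bp merged-
#' width filter. Reads are scattered inside the realized peaks; background
#' reads (with a per-sample depth multiplier) populate non-peak space.
#'
#' @details Planted classes follow the accelerated-aging marker logic:
#' `marker` peaks rise after mating in young flies, persist in aged mated
#' flies and also rise with age in virgins; `transient` peaks reverse with
#' age; `persistent_only` peaks persist without a virgin-aging echo;
#' `aging_only` peaks change only in aging virgins. Remaining peaks are
#' null.
#'
#' @param config A [simulation_config()].
#' @param design Design table; defaults to
#'   `simulate_design(config$n_replicates)`.
#' @param annotation Gene table from [simulate_annotation()]; simulated
#'   from `config` when missing.
#' @param class_counts Named integer vector giving how many master peaks of
#'   each planted class to generate, e.g. `c(marker = 4, transient = 4,
#'   persistent_only = 4, aging_only = 4)`; the rest of `n_peaks` are null.
#' @return A list with `peaks` (per-sample list of data.frames `chrom`,
#'   `start`, `end`, `count`), `reads` (per-sample read-interval
#'   data.frames), `library_sizes` (total reads per sample), `truth`
#'   (per master peak: interval, class, anchor `gene_id`, flags
#'   `is_differential` and `is_marker`), `annotation`, `genome`, `design`.
#' @export
simulate_peaks <- function(config, design = NULL, annotation = NULL,
                           class_counts = c(marker = 4L, transient = 4L,
                                            persistent_only = 4L,
                                            aging_only = 4L)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(design)) design <- simulate_design(config$n_replicates)
  design <- validate_design(design)
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  patterns <- peak_class_patterns()
  stopifnot(all(names(class_counts) %in% rownames(patterns)))
  n_planted <- sum(class_counts)
  if (n_planted > config$n_peaks) stop("more planted classes than peaks")
  if (config$n_peaks > nrow(annotation)) {
    stop("need at least as many genes as peaks (one anchor gene per peak)")
  }

  with_stage_seed(config$seed, "peaks", {
    n_pk <- config$n_peaks
    cls <- c(rep(names(class_counts), class_counts),
             rep("null", n_pk - n_planted))
    anchor <- sample.int(nrow(annotation), n_pk)
    ## planted peaks must be able to survive the >146 bp width filter;
    ## null widths span the whole configured range, which straddles 146 bp,
    ## so the filter is exercised
    width <- round(stats::runif(n_pk, config$peak_width[1], config$peak_width[2]))
    width[cls != "null"] <- pmax(width[cls != "null"], 180L)
    start <- pmax(annotation$start[anchor] - 50L, 0L)
    master <- data.frame(
      peak_id = sprintf("mp%03d", seq_len(n_pk)),
      chrom = annotation$chrom[anchor],
      start = start, end = start + width,
      class = cls, gene_id = annotation$gene_id[anchor],
      stringsAsFactors = FALSE
    )

    n_s <- nrow(design)
    cond_idx <- as.integer(design$condition)
    lfc <- patterns[master$class, , drop = FALSE] * config$peak_effect_lfc
    base_mu <- config$peak_mean_reads *
      2^stats::rnorm(n_pk, 0, config$baseline_log2_sd / 2)

    present <- matrix(TRUE, n_pk, n_s)
    is_null <- master$class == "null"
    for (i in which(is_null)) {
      k <- stats::rbinom(1L, n_s, config$peak_recurrence)
      keep <- sample.int(n_s, k)
      present[i, ] <- seq_len(n_s) %in% keep
    }

    genome <- simulate_genome(config)
    peaks <- vector("list", n_s)
    reads <- vector("list", n_s)
    names(peaks) <- names(reads) <- design$sample_id
    bg_mult <- stats::runif(n_s, 1 - config$background_variation,
                            1 + config$background_variation)
    for (s in seq_len(n_s)) {
      idx <- which(present[, s])
      j1 <- round(stats::runif(length(idx), -config$peak_jitter_bp,
                               config$peak_jitter_bp))
      j2 <- round(stats::runif(length(idx), -config$peak_jitter_bp,
                               config$peak_jitter_bp))
      ps <- pmax(master$start[idx] + j1, 0)
      pe <- pmax(master$end[idx] + j2, ps + 20)
      mu_s <- base_mu[idx] * 2^lfc[idx, cond_idx[s]]
      cnt <- draw_counts(mu_s, config)
      peaks[[s]] <- data.frame(chrom = master$chrom[idx], start = ps,
                               end = pe, count = cnt,
                               stringsAsFactors = FALSE)
      ## scatter reads inside each realized peak
      rs <- rep.int(seq_along(idx), cnt)
      pos <- ps[rs] + floor(stats::runif(length(rs)) *
                              pmax(pe[rs] - ps[rs] - config$read_length, 1))
      peak_reads <- data.frame(chrom = master$chrom[idx][rs], start = pos,
                               end = pos + config$read_length,
                               stringsAsFactors = FALSE)
      n_bg <- if (config$noise == "exact") {
        round(config$background_reads * bg_mult[s])
      } else {
        stats::rpois(1L, config$background_reads * bg_mult[s])
      }
      if (n_bg > 0) {
        ci <- sample.int(nrow(genome), n_bg, replace = TRUE)
        bp <- floor(stats::runif(n_bg) * (genome$length[ci] - config$read_length))
        bg_reads <- data.frame(chrom = genome$chrom[ci], start = bp,
                               end = bp + config$read_length,
                               stringsAsFactors = FALSE)
        reads[[s]] <- rbind(peak_reads, bg_reads)
      } else {
        reads[[s]] <- peak_reads
      }
    }

    master$is_differential <- master$class != "null"
    master$is_marker <- master$class == "marker"
    list(peaks = peaks, reads = reads,
         library_sizes = vapply(reads, nrow, integer(1)),
         truth = master, annotation = annotation, genome = genome,
         design = design)
  })
}

#' Simulate length-tagged small-RNA reads per sample
#'
#' Read lengths are drawn from a mixture with modes at 22 nt (miRNA-like)
#' and 30 nt (rasiRNA-like) in every sample; the miRNA/rasiRNA components
#' are truncated at >= 19 nt so the 15-18 nt degradation window stays
#' unambiguous. In young mated samples only, an additional 15-18 nt
#' component (weight `degradation_weight`) is placed inside the planted
#' degradation-source genes; all other reads are scattered across random
#' genes.
#'
#' @param config A [simulation_config()].
#' @param design Design table (defaults from config).
#' @param annotation Gene table ([simulate_annotation()]); must be
#'   non-empty.
#' @return A list with `reads` (per-sample data.frames `chrom`, `start`,
#'   `end`, `length`), `truth` (data.frame `gene_id`,
#'   `is_degradation_source`), `annotation`, `design`.
#' @export
simulate_smallrna_reads <- function(config, design = NULL,
                                    annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(design)) design <- simulate_design(config$n_replicates)
  design <- validate_design(design)
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  if (nrow(annotation) == 0L) stop("annotation must be non-empty")
  if (config$n_degradation_genes > nrow(annotation)) {
    stop("more degradation-source genes than genes in the annotation")
  }

  with_stage_seed(config$seed, "smallrna", {
    src <- sort(sample.int(nrow(annotation), config$n_degradation_genes))
    is_src <- seq_len(nrow(annotation)) %in% src
    n_r <- config$n_smallrna_reads
    reads <- vector("list", nrow(design))
    names(reads) <- design$sample_id
    for (s in seq_len(nrow(design))) {
      young_mated <- design$condition[s] == "young_mated"
      w_deg <- if (young_mated) config$degradation_weight else 0
      w <- c(mirna = 0.6, rasirna = 0.4) * (1 - w_deg)
      comp <- sample(c("mirna", "rasirna", "deg"), n_r, replace = TRUE,
                     prob = c(w, deg = w_deg))
      len <- integer(n_r)
      len[comp == "mirna"] <- pmax(19L, round(stats::rnorm(sum(comp == "mirna"), 22, 1.2)))
      len[comp == "rasirna"] <- pmax(19L, round(stats::rnorm(sum(comp == "rasirna"), 30, 1.5)))
      len[comp == "deg"] <- sample(15:18, sum(comp == "deg"), replace = TRUE)
      ## place degradation fragments inside source genes, everything else
      ## inside random non-source genes (lengths >= 19 nt would not break
      ## exclusivity either way, but this keeps the planted truth crisp)
      gi <- integer(n_r)
      gi[comp == "deg"] <- resample(src, sum(comp == "deg"), replace = TRUE)
      non_deg <- comp != "deg"
      gi[non_deg] <- resample(which(!is_src), sum(non_deg), replace = TRUE)
      span <- annotation$end[gi] - annotation$start[gi]
      start <- annotation$start[gi] +
        floor(stats::runif(n_r) * pmax(span - len, 1))
      reads[[s]] <- data.frame(chrom = annotation$chrom[gi], start = start,
                               end = start + len, length = len,
                               stringsAsFactors = FALSE)
    }
    truth <- data.frame(gene_id = annotation$gene_id,
                        is_degradation_source = is_src,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, annotation = annotation,
         design = design)
  })
}

#' Simulate miRNA-target and gene-gene interaction tables
#'
#' Emits a miRNA-to-target table (a TargetScan/MinoTar-like input) and a
#' symmetric gene-gene interaction table (a DroID-like input). Partner
#' genes are planted with exactly one versus two or more links into the
#' target set, so the more-than-one-target network filter is exercised
#' with known truth.
#'
#' @param config A [simulation_config()].
#' @param annotation Gene table providing the gene universe.
#' @param targets_per_mirna Predicted targets per miRNA.
#' @return A list with `targets` (data.frame `mirna`, `target`),
#'   `interactions` (data.frame `gene_a`, `gene_b`) and `truth`
#'   (data.frame `partner`, `n_target_links`).
#' @export
simulate_interactions <- function(config, annotation = NULL,
                                  targets_per_mirna = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  genes <- annotation$gene_id
  if (length(genes) < 10L) stop("gene universe too small")

  with_stage_seed(config$seed, "interactions", {
    mirnas <- sprintf("mir_%04d", seq_len(config$n_mirnas))
    n_target_pool <- min(length(genes) %/% 2L,
                         config$n_mirnas * targets_per_mirna)
    target_pool <- sample(genes, n_target_pool)
    targets <- do.call(rbind, lapply(mirnas, function(m) {
      data.frame(mirna = m,
                 target = sample(target_pool, targets_per_mirna),
                 stringsAsFactors = FALSE)
    }))
    partners <- setdiff(genes, target_pool)
    n_partner <- min(length(partners), 20L)
    partners <- sample(partners, n_partner)
    ## first half of partners get >= 2 target links, second half exactly 1
    n_multi <- ceiling(n_partner / 2)
    links <- lapply(seq_len(n_partner), function(i) {
      k <- if (i <= n_multi) sample(2:3, 1L) else 1L
      data.frame(gene_a = partners[i],
                 gene_b = sample(target_pool, min(k, length(target_pool))),
                 stringsAsFactors = FALSE)
    })
    interactions <- do.call(rbind, links)
    truth <- data.frame(
      partner = partners,
      n_target_links = vapply(partners, function(p) {
        sum(interactions$gene_a == p)
      }, integer(1)),
      stringsAsFactors = FALSE
    )
    list(targets = targets, interactions = interactions, truth = truth,
         mirnas = mirnas)
  })
}
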