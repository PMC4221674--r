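#' Configuration for the synthetic-data generator
#'
#' One object holds every tunable of the generator: the factorial layout,
#' the count noise model, the planted-effect model and the toy genome. All
#' random draws downstream flow from `seed` through named per-stage
#' substreams, so a fixed config reproduces byte-identical outputs.
#'
#' The count noise is negative binomial, parameterized by a per-feature
#' baseline mean (log-normal around `baseline_mean`) and a common
#' `dispersion` (variance `mu + mu^2 * dispersion`); `noise = "exact"`
#' replaces draws by their rounded expectations for zero-noise runs.
#'
#' @param seed Master seed (integer).
#' @param n_features Features per simulated count table.
#' @param n_replicates Replicates per condition (>= 2; default 2).
#' @param baseline_mean Median baseline expected count.
#' @param baseline_log2_sd Spread (log2 SD) of per-feature baselines.
#' @param dispersion Negative-binomial dispersion; 0 gives Poisson noise.
#' @param noise `"nb"` for stochastic counts, `"exact"` for noise-free
#'   rounded expectations.
#' @param effect_fraction Fraction of features planted with an effect.
#' @param effect_lfc Log2 fold change applied in the planted condition set.
#' @param n_onoff Number of planted on/off features expressed only in
#'   mated conditions (a mir-309-cluster-like pattern).
#' @param n_chromosomes,chrom_length Toy genome shape (0-based, half-open
#'   coordinates throughout).
#' @param n_genes,gene_length Gene count and min/max gene span (bp); genes
#'   are placed on non-overlapping slots so planted truths stay disjoint.
#' @param n_peaks,peak_width Master ChIP peak count and width range (bp);
#'   the range straddles the 146 bp mono-nucleosome span so the merge-width
#'   filter is exercised.
#' @param peak_jitter_bp Per-sample jitter of shared peak boundaries.
#' @param peak_recurrence Fraction of samples (beyond the planted classes)
#'   in which a null master peak recurs.
#' @param peak_mean_reads Expected read count of a baseline peak.
#' @param peak_effect_lfc Log2 fold change of planted differential peaks.
#' @param background_reads Background reads per sample scattered outside
#'   peaks (0 for zero-noise runs).
#' @param background_variation Half-width of the per-sample uniform
#'   multiplier on `background_reads` (creates sample-specific background
#'   levels for the correction stage to remove).
#' @param read_length ChIP read length (bp).
#' @param n_smallrna_reads Small-RNA reads per sample.
#' @param degradation_weight Mixture weight of the 15-18 nt degradation
#'   component in young mated samples.
#' @param n_degradation_genes Genes planted as degradation-fragment sources.
#' @param n_mirnas miRNAs in the interaction simulation.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_features = 500L,
                              n_replicates = 2L,
                              baseline_mean = 500,
                              baseline_log2_sd = 1,
                              dispersion = 0.04,
                              noise = c("nb", "exact"),
                              effect_fraction = 0.05,
                              effect_lfc = 2,
                              n_onoff = 0L,
                              n_chromosomes = 2L,
                              chrom_length = 1e6,
                              n_genes = 120L,
                              gene_length = c(1000, 5000),
                              n_peaks = 40L,
                              peak_width = c(100, 400),
                              peak_jitter_bp = 20L,
                              peak_recurrence = 0.5,
                              peak_mean_reads = 200,
                              peak_effect_lfc = 2,
                              background_reads = 2000L,
                              background_variation = 0.5,
                              read_length = 50L,
                              n_smallrna_reads = 3000L,
                              degradation_weight = 0.15,
                              n_degradation_genes = 10L,
                              n_mirnas = 30L) {
  noise <- match.arg(noise)
  cfg <- list(seed = as.integer(seed), n_features = as.integer(n_features),
              n_replicates = as.integer(n_replicates),
              baseline_mean = baseline_mean,
              baseline_log2_sd = baseline_log2_sd,
              dispersion = dispersion, noise = noise,
              effect_fraction = effect_fraction, effect_lfc = effect_lfc,
              n_onoff = as.integer(n_onoff),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length,
              n_genes = as.integer(n_genes), gene_length = gene_length,
              n_peaks = as.integer(n_peaks), peak_width = peak_width,
              peak_jitter_bp = as.integer(peak_jitter_bp),
              peak_recurrence = peak_recurrence,
              peak_mean_reads = peak_mean_reads,
              peak_effect_lfc = peak_effect_lfc,
              background_reads = as.integer(background_reads),
              background_variation = background_variation,
              read_length = as.integer(read_length),
              n_smallrna_reads = as.integer(n_smallrna_reads),
              degradation_weight = degradation_weight,
              n_degradation_genes = as.integer(n_degradation_genes),
              n_mirnas = as.integer(n_mirnas))
  stopifnot(cfg$n_replicates >= 2L, cfg$baseline_mean > 0,
            cfg$dispersion >= 0, cfg$effect_fraction >= 0,
            cfg$effect_fraction <= 1, cfg$n_chromosomes >= 1L,
            cfg$chrom_length > 0, all(cfg$gene_length > 0),
            all(cfg$peak_width > 0), cfg$peak_recurrence >= 0,
            cfg$peak_recurrence <= 1, cfg$read_length > 0,
            cfg$degradation_weight >= 0, cfg$degradation_weight < 1)
  if (cfg$effect_fraction > 0 && cfg$effect_lfc < 0) {
    stop("'effect_lfc' must be >= 0; direction is chosen per feature")
  }
  class(cfg) <- "sim_config"
  cfg
}

## Derive a reproducible per-stage seed from the master seed and a stage
## name, so each simulate_* operation has its own named substream.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 97) %% 2147483629)
}

## Evaluate `code` under the given stage substream, restoring the caller's
## RNG state afterwards.
with_stage_seed <- function(seed, stage, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  code
}

## sample() that never falls into the 1:x scalar trap and tolerates
## empty input with size 0.
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

## Draw counts with expectation mu under the configured noise model.
draw_counts <- function(mu, cfg) {
  mu <- pmax(mu, 0)
  if (cfg$noise == "exact") return(round(mu))
  if (cfg$dispersion <= 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
}

#' Simulate a feature-by-sample count table with planted effects
#'
#' Generates a nonnegative integer matrix over the 4 x `n_replicates`
#' design. Planted features carry a log2 fold change in a target condition
#' set (by default a random non-empty proper subset of the four
#' conditions, signed at random); optional on/off features are expressed
#' only in the two mated conditions, mimicking the mir-309-cluster
#' pattern. Null features are exchangeable across conditions.
#'
#' @param config A [simulation_config()].
#' @param kind Feature kind used for ids: `"mirna"` or `"gene"`.
#' @param effects Optional `n_features x 4` matrix of per-condition log2
#'   fold changes (columns in [conditions()] order) overriding the default
#'   planting; `-Inf` silences a condition entirely.
#' @return A list with `counts` (matrix, features x samples), `design`,
#'   `effects` (the planted lfc matrix) and `truth`: one row per feature
#'   with `is_planted` and, per contrast, `plastic_<contrast>` flags
#'   (TRUE iff the planted effect differs between the contrasted
#'   conditions).
#' @export
simulate_counts <- function(config, kind = c("mirna", "gene"),
                            effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  kind <- match.arg(kind)
  n <- config$n_features
  if (n < 1L) stop("need at least one feature")
  design <- simulate_design(config$n_replicates)

  with_stage_seed(config$seed, paste0("counts_", kind), {
    if (is.null(effects)) {
      effects <- matrix(0, n, 4L, dimnames = list(NULL, conditions()))
      n_planted <- floor(config$effect_fraction * n)
      if (n_planted > 0L) {
        planted <- sample.int(n, n_planted)
        for (i in planted) {
          set_size <- sample(1:3, 1L)
          set <- sample(conditions(), set_size)
          effects[i, set] <- sample(c(-1, 1), 1L) * config$effect_lfc
        }
      }
      if (config$n_onoff > 0L) {
        nulls <- which(rowSums(effects != 0) == 0)
        if (length(nulls) < config$n_onoff) {
          stop("not enough null features to plant on/off features")
        }
        onoff <- nulls[seq_len(config$n_onoff)]
        effects[onoff, c("young_virgin", "aged_virgin")] <- -Inf
      }
    } else {
      effects <- as.matrix(effects)
      if (!identical(dim(effects), c(n, 4L))) {
        stop("'effects' must be an n_features x 4 matrix")
      }
      colnames(effects) <- conditions()
    }

    base_mu <- config$baseline_mean *
      2^stats::rnorm(n, 0, config$baseline_log2_sd)
    mu <- base_mu * 2^effects[, as.character(design$condition)]
    counts <- matrix(draw_counts(as.numeric(mu), config), n,
                     nrow(design))
    dimnames(counts) <- list(
      sprintf("%s_%04d", if (kind == "mirna") "mir" else "gene", seq_len(n)),
      design$sample_id
    )

    ct <- contrast_table()
    truth <- data.frame(feature = rownames(counts),
                        is_planted = rowSums(effects != 0) > 0,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ct))) {
      truth[[paste0("plastic_", ct$contrast[i])]] <-
        effects[, ct$high[i]] != effects[, ct$low[i]]
    }
    list(counts = counts, design = design, effects = effects, truth = truth)
  })
}
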