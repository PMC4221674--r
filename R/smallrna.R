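#' Read-length histogram of a small-RNA sample
#'
#' @param reads A data.frame of read intervals with a `length` column (nt);
#'   if absent, lengths are derived as `end - start`.
#' @return A data.frame `length`, `count`, zero-filled over the observed
#'   length range; counts sum to the number of reads. Empty input gives an
#'   empty histogram.
#' @export
length_histogram <- function(reads) {
  len <- read_lengths(reads)
  if (length(len) == 0L) {
    return(data.frame(length = integer(0), count = integer(0)))
  }
  if (any(len < 1L)) stop("read lengths must be >= 1")
  rng <- seq(min(len), max(len))
  cnt <- tabulate(len - min(len) + 1L, nbins = length(rng))
  data.frame(length = rng, count = cnt)
}

read_lengths <- function(reads) {
  if (is.null(reads) || nrow(reads) == 0L) return(integer(0))
  if ("length" %in% names(reads)) as.integer(reads$length)
  else as.integer(reads$end - reads$start)
}

#' Call genes shedding 15-18 nt degradation fragments only in young mated flies
#'
#' A gene is called when degradation-window fragments overlap its span (by
#' at least 1 bp, strand-ignored) with at least `min_reads` reads in young
#' mated samples, and zero such fragments overlap it in every other
#' sample. By default presence is required in *every* young mated
#' replicate (the strictest, replicate-robust reading of "exclusively in
#' young flies after mating"); `require_all = FALSE` relaxes this to at
#' least one replicate.
#'
#' @param reads Named list of per-sample read data.frames (`chrom`,
#'   `start`, `end`, optional `length`), names matching
#'   `design$sample_id`.
#' @param annotation Gene table (`gene_id`, `chrom`, `start`, `end`;
#'   0-based half-open). Duplicated gene ids are an error.
#' @param design Design table; must include young mated samples.
#' @param len_range Inclusive degradation-fragment length window in nt
#'   (default 15-18).
#' @param min_reads Minimum fragments per young mated replicate
#'   (default 1).
#' @param require_all Require fragments in all young mated replicates
#'   (default TRUE) rather than in at least one.
#' @return A data.frame of calls: `gene_id`, one fragment-count column per
#'   sample, and `exclusive = TRUE`. Attribute `counts` carries the full
#'   gene-by-sample fragment-count matrix.
#' @export
call_degradation_genes <- function(reads, annotation, design,
                                   len_range = c(15L, 18L), min_reads = 1L,
                                   require_all = TRUE) {
  design <- validate_design(design)
  if (anyDuplicated(annotation$gene_id)) {
    stop("duplicated gene ids in annotation")
  }
  if (!all(design$sample_id %in% names(reads))) {
    stop("every design sample needs a read set")
  }
  ym <- design$sample_id[design$condition == "young_mated"]
  if (length(ym) == 0L) stop("design includes no young_mated samples")
  other <- setdiff(design$sample_id, ym)

  genes <- df_to_granges(annotation)
  counts <- vapply(design$sample_id, function(s) {
    r <- reads[[s]]
    len <- read_lengths(r)
    keep <- len >= len_range[1] & len <= len_range[2]
    if (!any(keep)) return(integer(length(genes)))
    GenomicRanges::countOverlaps(genes,
                                 df_to_granges(r[keep, , drop = FALSE]))
  }, integer(length(genes)))
  rownames(counts) <- annotation$gene_id

  in_ym <- counts[, ym, drop = FALSE] >= min_reads
  present <- if (require_all) rowSums(in_ym) == length(ym)
             else rowSums(in_ym) > 0L
  absent_elsewhere <- rowSums(counts[, other, drop = FALSE]) == 0L
  called <- present & absent_elsewhere

  out <- data.frame(gene_id = annotation$gene_id[called],
                    stringsAsFactors = FALSE)
  for (s in design$sample_id) out[[s]] <- counts[called, s]
  out$exclusive <- rep(TRUE, sum(called))
  attr(out, "counts") <- counts
  out
}
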