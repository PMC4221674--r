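## Interval data.frames are 0-based half-open throughout the package
## (BED convention); GRanges conversion shifts to 1-based closed.
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge peak calls across samples
#'
#' Peaks from all samples are clustered by single-linkage overlap (at
#' least `min_overlap_bp` shared base pairs; overlapping peaks within one
#' sample are merged first and count as that sample's single
#' contribution). Each cluster's merged interval is the union of its
#' members. Clusters are kept only when supported by at least
#' `min_support` distinct samples ("present in more than one sample") and
#' when the merged width exceeds 146 bp, the mono-nucleosome span
#' (`min_width_bp = 147` means width >= 147).
#'
#' Merging is order-independent: permuting the sample list yields the
#' identical merged set.
#'
#' @param peaks Named list of per-sample peak data.frames (`chrom`,
#'   `start`, `end`, 0-based half-open).
#' @param min_overlap_bp Minimum intersection for two peaks to be "the
#'   same" (default 1 bp, the least-assumption choice).
#' @param min_support Minimum number of distinct contributing samples
#'   (default 2).
#' @param min_width_bp Minimum merged width in bp (default 147, i.e.
#'   strictly wider than 146 bp).
#' @return A data.frame `peak_id`, `chrom`, `start`, `end`, `width`,
#'   `support`, ordered by genomic position.
#' @export
merge_peaks <- function(peaks, min_overlap_bp = 1L, min_support = 2L,
                        min_width_bp = 147L) {
  stopifnot(is.list(peaks), length(peaks) > 0L)
  if (is.null(names(peaks))) names(peaks) <- paste0("sample_", seq_along(peaks))
  per_sample <- lapply(names(peaks), function(s) {
    df <- peaks[[s]]
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    if (any(df$end <= df$start)) stop("invalid peak interval in sample ", s)
    gr <- GenomicRanges::reduce(df_to_granges(df))
    gr$sample <- s
    gr
  })
  pooled <- do.call(c, per_sample[!vapply(per_sample, is.null, logical(1))])
  if (is.null(pooled) || length(pooled) == 0L) {
    return(empty_merged_peaks())
  }
  hits <- GenomicRanges::findOverlaps(pooled, pooled,
                                      minoverlap = min_overlap_bp)
  g <- igraph::graph_from_edgelist(
    cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits)),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  keep <- logical(max(comp))
  res <- lapply(seq_len(max(comp)), function(ci) {
    members <- pooled[comp == ci]
    support <- length(unique(members$sample))
    start <- min(GenomicRanges::start(members)) - 1L
    end <- max(GenomicRanges::end(members))
    data.frame(chrom = as.character(GenomicRanges::seqnames(members))[1],
               start = start, end = end, width = end - start,
               support = support, stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, res)
  merged <- merged[merged$support >= min_support &
                     merged$width >= min_width_bp, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty_merged_peaks())
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  merged <- cbind(peak_id = sprintf("peak_%04d", seq_len(nrow(merged))),
                  merged, stringsAsFactors = FALSE)
  rownames(merged) <- NULL
  merged
}

empty_merged_peaks <- function() {
  data.frame(peak_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), width = integer(0),
             support = integer(0), stringsAsFactors = FALSE)
}

#' Per-sample read counts and FPKM over merged peaks
#'
#' `FPKM(peak, sample) = count / ((width / 1000) * (library_size / 1e6))`.
#' Library sizes are the total mapped reads per sample, supplied by the
#' caller.
#'
#' @param merged Merged peak table from [merge_peaks()].
#' @param reads Either a named list of per-sample read data.frames (counts
#'   are reads overlapping the peak by >= 1 bp) or a precomputed
#'   peak-by-sample count matrix.
#' @param library_sizes Named vector of per-sample library sizes (> 0).
#' @return List with `counts` and `fpkm` (peak-by-sample matrices, rows
#'   named by `peak_id`).
#' @export
count_and_fpkm <- function(merged, reads, library_sizes) {
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (is.matrix(reads)) {
    counts <- reads
    if (nrow(counts) != nrow(merged)) stop("count matrix does not match peaks")
  } else {
    stopifnot(is.list(reads))
    gr <- df_to_granges(merged)
    counts <- vapply(names(reads), function(s) {
      GenomicRanges::countOverlaps(gr, df_to_granges(reads[[s]]))
    }, integer(nrow(merged)))
  }
  rownames(counts) <- merged$peak_id
  if (is.null(names(library_sizes))) names(library_sizes) <- colnames(counts)
  library_sizes <- library_sizes[colnames(counts)]
  fpkm <- sweep(counts / (merged$width / 1000), 2L,
                as.numeric(library_sizes) / 1e6, "/")
  list(counts = counts, fpkm = fpkm)
}

#' Background-correct FPKM using non-peak intervals
#'
#' Tiles the genome outside the merged peaks with fixed `bin_bp` bins,
#' computes each sample's FPKM in those bins, and subtracts the per-sample
#' median background FPKM from the peak FPKM matrix, flooring at zero
#' (negative signal is not meaningful). The corrected matrix is then
#' quantile-normalized across samples unless `normalize = FALSE`.
#'
#' @param fpkm Peak-by-sample FPKM matrix from [count_and_fpkm()].
#' @param reads Named list of per-sample read data.frames.
#' @param merged Merged peak table.
#' @param genome data.frame `chrom`, `length`.
#' @param library_sizes Named per-sample library sizes.
#' @param bin_bp Background bin width (default 1000 bp).
#' @param normalize Quantile-normalize after correction (default TRUE).
#' @return List with `corrected` (matrix), `background` (data.frame
#'   `sample_id`, `median_fpkm`) and `bin_bp`.
#' @export
background_correct <- function(fpkm, reads, merged, genome, library_sizes,
                               bin_bp = 1000L, normalize = TRUE) {
  bins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0L, genome$length[i] - bin_bp, by = bin_bp)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = starts + bin_bp, stringsAsFactors = FALSE)
  }))
  bins_gr <- df_to_granges(bins)
  if (nrow(merged) > 0L) {
    hit <- GenomicRanges::countOverlaps(bins_gr, df_to_granges(merged)) > 0L
    bins_gr <- bins_gr[!hit]
  }
  if (length(bins_gr) == 0L) stop("no non-peak space left for background bins")
  if (is.null(names(library_sizes))) names(library_sizes) <- colnames(fpkm)
  med <- vapply(colnames(fpkm), function(s) {
    cnt <- GenomicRanges::countOverlaps(bins_gr, df_to_granges(reads[[s]]))
    stats::median(cnt / (bin_bp / 1000) / (library_sizes[[s]] / 1e6))
  }, numeric(1))
  corrected <- pmax(sweep(fpkm, 2L, med), 0)
  if (normalize && ncol(corrected) >= 2L && nrow(corrected) >= 1L) {
    corrected <- quantile_normalize(corrected)
  }
  list(corrected = corrected,
       background = data.frame(sample_id = colnames(fpkm),
                               median_fpkm = unname(med),
                               stringsAsFactors = FALSE),
       bin_bp = bin_bp)
}

#' Assign candidate genes to merged peaks
#'
#' A gene is assigned to a peak when the window
#' `[gene_start - window_bp, gene_end + window_bp)` intersects the peak
#' interval (strand-ignored). A peak may receive several genes and a gene
#' several peaks.
#'
#' @param merged Merged peak table.
#' @param annotation Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param window_bp Flank added on both sides of each gene (default
#'   2000 bp).
#' @return data.frame `peak_id`, `gene_id`, one row per assignment.
#' @export
assign_genes <- function(merged, annotation, window_bp = 2000L) {
  if (nrow(merged) == 0L || nrow(annotation) == 0L) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  win <- annotation
  win$start <- pmax(win$start - window_bp, 0L)
  win$end <- win$end + window_bp
  hits <- GenomicRanges::findOverlaps(df_to_granges(merged),
                                      df_to_granges(win))
  data.frame(peak_id = merged$peak_id[S4Vectors::queryHits(hits)],
             gene_id = annotation$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}
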