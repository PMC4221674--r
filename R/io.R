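#' Write / read a feature-by-sample count table as TSV
#'
#' The first column (`feature`) carries row names; remaining columns are
#' samples in design order.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output file.
#' @return `write_counts_tsv` invisibly returns `path`;
#'   `read_counts_tsv` returns the matrix.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write / read intervals as BED
#'
#' Intervals are 0-based half-open. `name` and `score` columns are
#' optional on write (filled with `.`/`0`); the score column is used for
#' read counts (peaks) or read lengths (small-RNA reads), selected by the
#' `score_is` dialect flag on read.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, and one of `count`/`length`/`score`.
#' @param path File path.
#' @param score_is On read, interpret the BED score column as `"score"`,
#'   `"count"` or `"length"`; `"auto"` leaves it named `score`.
#' @return `write_bed` invisibly returns `path`; `read_bed` a data.frame.
#' @export
write_bed <- function(df, path) {
  score <- if ("count" %in% names(df)) df$count
           else if ("length" %in% names(df)) df$length
           else if ("score" %in% names(df)) df$score
           else 0L
  name <- if ("name" %in% names(df)) df$name
          else sprintf("iv_%06d", seq_len(nrow(df)))
  out <- data.frame(df$chrom, df$start, df$end, name, score, ".",
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path, score_is = c("auto", "score", "count", "length")) {
  score_is <- match.arg(score_is)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  if (ncol(df) >= 5L) {
    names(df)[5] <- if (score_is == "auto") "score" else score_is
  }
  df[seq_len(min(ncol(df), 5L))]
}

#' Write / read a gene annotation
#'
#' Writes minimal GFF3 (type `gene`, `ID=` attribute) alongside BED.
#' `read_annotation` accepts BED (via [read_bed()]) or GFF3; GFF3 parsing
#' goes through rtracklayer when available.
#'
#' @param annotation data.frame `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param path File path; format chosen by extension (`.bed` vs
#'   `.gff3`/`.gff`).
#' @return `write_annotation` invisibly returns `path`;
#'   `read_annotation` the annotation data.frame.
#' @export
write_annotation <- function(annotation, path) {
  if (grepl("\\.bed$", path)) {
    df <- annotation[, c("chrom", "start", "end")]
    df$name <- annotation$gene_id
    return(write_bed(df, path))
  }
  lines <- c("##gff-version 3",
             sprintf("%s\tplastinet\tgene\t%d\t%d\t.\t.\t.\tID=%s",
                     annotation$chrom, annotation$start + 1L,
                     annotation$end, annotation$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  if (grepl("\\.bed$", path)) {
    df <- read_bed(path)
    return(data.frame(gene_id = df$name, chrom = df$chrom,
                      start = df$start, end = df$end,
                      stringsAsFactors = FALSE))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(gene_id = gr$ID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
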