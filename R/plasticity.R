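#' Per-feature contrast membership
#'
#' Reshapes a differential-analysis table into one membership record per
#' feature: for each of the four pairwise contrasts, a significance flag
#' (omnibus `q < alpha` and |difference| > pooled SD, as computed by
#' [differential_analysis()]) and a direction, `"up"`/`"down"` under the
#' mated-minus-virgin / aged-minus-young sign convention. Direction is
#' defined only for significant contrasts.
#'
#' @param diff A [differential_analysis()] result.
#' @return data.frame with `feature` and, per contrast, `sig_*` (logical)
#'   and `dir_*` (`"up"`, `"down"` or `NA`).
#' @export
classify_contrasts <- function(diff) {
  cns <- contrast_names()
  need <- c(paste0("diff_", cns), paste0("sig_", cns))
  if (!all(need %in% names(diff))) {
    stop("'diff' must contain all four contrasts (diff_*/sig_* columns)")
  }
  out <- data.frame(feature = diff$feature, stringsAsFactors = FALSE)
  for (cn in cns) {
    sig <- diff[[paste0("sig_", cn)]]
    d <- diff[[paste0("diff_", cn)]]
    out[[paste0("sig_", cn)]] <- sig
    out[[paste0("dir_", cn)]] <- ifelse(sig, ifelse(d > 0, "up", "down"), NA)
  }
  out
}

#' Venn region counts over contrast memberships
#'
#' Counts, for every non-empty subset of the chosen contrasts, the
#' features significant in exactly that subset (and in none of the other
#' chosen contrasts). Region counts sum to the size of the union.
#'
#' @param membership A [classify_contrasts()] table.
#' @param contrasts Contrast names to intersect (>= 2; default all four).
#' @return data.frame `region` (contrast names joined by `&`) and `count`,
#'   covering all `2^k - 1` regions.
#' @export
venn_overlap <- function(membership, contrasts = contrast_names()) {
  if (length(contrasts) < 2L) stop("need at least two contrasts")
  sig <- vapply(contrasts, function(cn) membership[[paste0("sig_", cn)]],
                logical(nrow(membership)))
  sig <- matrix(sig, nrow = nrow(membership),
                dimnames = list(NULL, contrasts))
  k <- length(contrasts)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  region <- apply(subsets, 1L, function(in_set) {
    paste(contrasts[as.logical(in_set)], collapse = "&")
  })
  count <- apply(subsets, 1L, function(in_set) {
    in_set <- as.logical(in_set)
    sum(apply(sig, 1L, function(r) all(r[in_set]) && !any(r[!in_set])))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE)
}

#' Features whose post-mating change persists in aged mated flies
#'
#' Persistence is read as the absence of a significant reversal: a feature
#' significant after mating in young flies (`young_mated_vs_virgin`) is
#' persistent unless its mated aged-vs-young contrast is significant in
#' the direction that undoes the post-mating change. The alternative
#' definition `"still_significant"` instead requires the aged
#' mated-vs-virgin contrast to remain significant in the same direction.
#'
#' @param membership A [classify_contrasts()] table.
#' @param definition `"non_reversal"` (default) or `"still_significant"`.
#' @return Character vector of persistent feature ids.
#' @export
persistent_marks <- function(membership,
                             definition = c("non_reversal",
                                            "still_significant")) {
  definition <- match.arg(definition)
  if (nrow(membership) == 0L) return(character(0))
  young <- membership$sig_young_mated_vs_virgin
  dir_young <- membership$dir_young_mated_vs_virgin
  keep <- if (definition == "non_reversal") {
    reversal <- membership$sig_mated_aged_vs_young &
      membership$dir_mated_aged_vs_young != dir_young
    young & !ifelse(is.na(reversal), FALSE, reversal)
  } else {
    young & membership$sig_aged_mated_vs_virgin &
      membership$dir_aged_mated_vs_virgin == dir_young
  }
  membership$feature[which(keep)]
}

#' Mating-induced accelerated-aging markers
#'
#' Markers are post-mating changes in young flies that persist in mated
#' flies ([persistent_marks()]) and also arise, in the same direction,
#' with age in virgin flies (`virgin_aged_vs_young` significant with
#' matching sign). Candidate genes are attached through the peak-to-gene
#' map when one is supplied.
#'
#' @param membership A [classify_contrasts()] table (histone features).
#' @param peak_genes Optional data.frame `peak_id`, `gene_id` from
#'   [assign_genes()]; when missing, markers are returned without genes
#'   (with a warning).
#' @param definition Persistence definition, see [persistent_marks()].
#' @return List with `markers` (data.frame `feature`, `direction`,
#'   `genes` as a semicolon-joined string), `n_persistent`,
#'   `marker_fraction` (markers / persistent, NA when no persistent
#'   features) and `genes` (unique associated gene ids).
#' @export
accelerated_aging_markers <- function(membership, peak_genes = NULL,
                                      definition = "non_reversal") {
  persistent <- persistent_marks(membership, definition)
  rows <- membership[membership$feature %in% persistent, , drop = FALSE]
  co <- rows$sig_virgin_aged_vs_young &
    rows$dir_virgin_aged_vs_young == rows$dir_young_mated_vs_virgin
  marker_rows <- rows[which(co), , drop = FALSE]
  if (is.null(peak_genes)) {
    if (nrow(marker_rows) > 0L) {
      warning("no peak-to-gene map supplied; markers reported without genes")
    }
    gene_str <- rep(NA_character_, nrow(marker_rows))
    all_genes <- character(0)
  } else {
    gene_str <- vapply(marker_rows$feature, function(f) {
      g <- sort(unique(peak_genes$gene_id[peak_genes$peak_id == f]))
      if (length(g) == 0L) NA_character_ else paste(g, collapse = ";")
    }, character(1))
    all_genes <- sort(unique(
      peak_genes$gene_id[peak_genes$peak_id %in% marker_rows$feature]
    ))
  }
  markers <- data.frame(feature = marker_rows$feature,
                        direction = marker_rows$dir_young_mated_vs_virgin,
                        genes = unname(gene_str),
                        stringsAsFactors = FALSE)
  list(markers = markers,
       n_persistent = length(persistent),
       marker_fraction = if (length(persistent) == 0L) NA_real_
                         else nrow(markers) / length(persistent),
       genes = all_genes)
}
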