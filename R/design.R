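#' Experimental conditions of the mating-by-age factorial design
#'
#' The design crosses two ages (young, 3-5 days; aged, 4 weeks) with two
#' mating states (virgin, mated), giving four conditions. All differential
#' analyses, contrast definitions and simulations in this package are keyed
#' on these four levels, in this order.
#'
#' @return Character vector of the four condition names.
#' @export
conditions <- function() {
  c("young_virgin", "young_mated", "aged_virgin", "aged_mated")
}

#' The four pairwise contrasts of the factorial design
#'
#' Differences are always signed mated minus virgin (within an age) and
#' aged minus young (within a mating state), so a positive difference means
#' higher abundance after mating, or at older age.
#'
#' @return A data.frame with columns `contrast`, `high` and `low`; the
#'   contrast difference is `mean(high) - mean(low)`.
#' @export
contrast_table <- function() {
  data.frame(
    contrast = c("young_mated_vs_virgin", "aged_mated_vs_virgin",
                 "virgin_aged_vs_young", "mated_aged_vs_young"),
    high = c("young_mated", "aged_mated", "aged_virgin", "aged_mated"),
    low  = c("young_virgin", "aged_virgin", "young_virgin", "young_mated"),
    stringsAsFactors = FALSE
  )
}

#' Names of the four pairwise contrasts
#' @return Character vector of length four.
#' @export
contrast_names <- function() contrast_table()$contrast

#' Build the sample design table
#'
#' Lays out `4 * n_replicates` samples: each of the four conditions gets
#' `n_replicates` replicate samples with stable, unique sample ids.
#'
#' @param n_replicates Replicates per condition; at least 2 (a single
#'   replicate leaves the permutation ANOVA undefined). Default 2, matching
#'   a two-independent-samples-per-condition layout.
#' @return A data.frame with columns `sample_id`, `condition` (factor with
#'   the levels of [conditions()]) and `replicate`.
#' @examples
#' simulate_design(2)
#' @export
simulate_design <- function(n_replicates = 2L) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      is.na(n_replicates) || n_replicates != round(n_replicates)) {
    stop("'n_replicates' must be a single integer")
  }
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L) {
    stop("'n_replicates' must be >= 2: with a single replicate per ",
         "condition the permutation ANOVA is undefined")
  }
  cond <- rep(conditions(), each = n_replicates)
  rep_idx <- rep(seq_len(n_replicates), times = 4L)
  data.frame(
    sample_id = paste0(cond, "_r", rep_idx),
    condition = factor(cond, levels = conditions()),
    replicate = rep_idx,
    stringsAsFactors = FALSE
  )
}

## Internal: check a design data.frame, optionally against a value vector or
## matrix whose columns must line up with design rows.
validate_design <- function(design, values = NULL) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "condition") %in% names(design))) {
    stop("'design' must be a data.frame with columns 'sample_id' and 'condition'")
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicated sample ids in design")
  }
  cond <- factor(design$condition, levels = conditions())
  if (anyNA(cond)) stop("design conditions must be among: ",
                        paste(conditions(), collapse = ", "))
  tab <- table(cond)
  if (sum(tab > 0L) < 2L) stop("degenerate design: need >= 2 conditions with samples")
  if (any(tab[tab > 0L] < 2L)) {
    stop("degenerate design: every occupied condition needs >= 2 samples")
  }
  if (!is.null(values)) {
    nv <- if (is.matrix(values)) ncol(values) else length(values)
    if (nv != nrow(design)) stop("values do not match the number of design samples")
    nm <- if (is.matrix(values)) colnames(values) else names(values)
    if (!is.null(nm) && !identical(nm, design$sample_id)) {
      stop("column/sample names do not match design sample ids (same order required)")
    }
  }
  design$condition <- cond
  design
}
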