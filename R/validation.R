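#' Two-sided pooled-variance Student's t-test p-value
#'
#' The classical two-sample Student's t-test (equal-variance pooling),
#' used on normalized qPCR expression values (virgin vs mated replicates).
#' When both groups have zero variance and equal means the p-value is 1;
#' with zero variance but different means it tends to 0.
#'
#' @param group_a,group_b Numeric replicate vectors (>= 2 values each).
#' @return A p-value in [0, 1].
#' @export
ttest_expression <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need at least two replicate values per group")
  }
  na <- length(group_a); nb <- length(group_b)
  sp2 <- (sum((group_a - mean(group_a))^2) +
            sum((group_b - mean(group_b))^2)) / (na + nb - 2)
  d <- mean(group_a) - mean(group_b)
  if (sp2 == 0) return(if (d == 0) 1 else 0)
  t <- d / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(t), df = na + nb - 2)
}

#' Gapdh-style mean normalization of expression values
#'
#' Each target measurement is divided by its sample's reference (Gapdh)
#' measurement and the ratios are scaled by their cross-sample mean, so
#' the normalized values average 1. The normalizer is deliberately
#' pluggable: any function mapping (target, reference) to normalized
#' values can replace it upstream of [ttest_expression()].
#'
#' @param target,reference Numeric vectors of equal length;
#'   `reference > 0`.
#' @return Normalized expression values.
#' @export
mean_normalize <- function(target, reference) {
  stopifnot(length(target) == length(reference))
  if (any(reference <= 0)) stop("reference expression must be positive")
  r <- target / reference
  r / mean(r)
}

#' Significance-discordance call for miRNA overexpression
#'
#' Overexpressing a miRNA is called to affect a target gene (`"+"`) when
#' the virgin-vs-mated expression difference is significant (p < alpha)
#' in exactly one of the two crosses - control but not overexpression, or
#' vice versa - and `"-"` otherwise. The rule is symmetric in its two
#' arguments.
#'
#' @param p_control,p_overexp P-values in (0, 1] from the control and the
#'   overexpression cross (vectorized).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of `"+"` / `"-"` marks.
#' @export
call_overexpression_effect <- function(p_control, p_overexp, alpha = 0.05) {
  p <- c(p_control, p_overexp)
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  ifelse(xor(p_control < alpha, p_overexp < alpha), "+", "-")
}

#' Fraction of target genes affected by miRNA overexpression
#'
#' @param calls Character vector (or data.frame with an `effect` column)
#'   of `"+"`/`"-"` marks from [call_overexpression_effect()].
#' @return List with `n_affected`, `n_total`, `fraction` and `percent`.
#' @export
effect_summary <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$effect
  if (length(calls) == 0L) stop("no effect calls to summarize")
  if (!all(calls %in% c("+", "-"))) stop("calls must be '+' or '-'")
  n <- length(calls)
  k <- sum(calls == "+")
  list(n_affected = k, n_total = n, fraction = k / n,
       percent = 100 * k / n)
}

#' Dunnett many-to-one comparisons by Monte Carlo
#'
#' Compares each treatment line against a shared control with familywise
#' adjustment over the correlated t statistics (shared control mean and
#' pooled error). The null distribution of the maximum absolute Dunnett
#' statistic is integrated by seeded Monte Carlo (`n_mc` draws), so for a
#' single comparison the adjusted p-value reduces to the plain two-sided
#' pooled t-test p-value within Monte Carlo error.
#'
#' @param control Numeric vector of control replicate measurements
#'   (e.g. egg counts of replicate groups of five females).
#' @param treatments Named list of numeric replicate vectors, one per
#'   line.
#' @param n_mc Monte Carlo draws for the null max-|t| surface
#'   (default 1e5).
#' @param seed Integer seed for the Monte Carlo integration.
#' @return data.frame with one row per line: `line`, `n`, `mean`,
#'   `diff` (line - control), `percent_change` (relative to the control
#'   mean, in percent), `t`, `p_adjusted` (in (0, 1]).
#' @export
dunnett_test <- function(control, treatments, n_mc = 1e5L, seed = 1L) {
  stopifnot(is.list(treatments), length(treatments) >= 1L)
  if (is.null(names(treatments))) {
    names(treatments) <- paste0("line_", seq_along(treatments))
  }
  if (length(control) < 2L || any(vapply(treatments, length, 0L) < 2L)) {
    stop("need at least two replicates per group")
  }
  k <- length(treatments)
  n0 <- length(control)
  ni <- vapply(treatments, length, integer(1))
  df <- n0 + sum(ni) - (k + 1L)
  sp2 <- (sum((control - mean(control))^2) +
            sum(vapply(treatments, function(v) sum((v - mean(v))^2),
                       numeric(1)))) / df
  if (sp2 == 0) stop("zero pooled variance: Dunnett statistics undefined")
  diff <- vapply(treatments, mean, numeric(1)) - mean(control)
  tstat <- diff / sqrt(sp2 * (1 / ni + 1 / n0))

  set.seed(as.integer(seed))
  z0 <- stats::rnorm(n_mc, 0, sqrt(1 / n0))
  s <- sqrt(stats::rchisq(n_mc, df) / df)
  tmax <- rep(0, n_mc)
  for (i in seq_len(k)) {
    zi <- stats::rnorm(n_mc, 0, sqrt(1 / ni[i]))
    tmax <- pmax(tmax, abs(zi - z0) / (s * sqrt(1 / ni[i] + 1 / n0)))
  }
  p_adj <- vapply(abs(tstat), function(ti) {
    (1 + sum(tmax >= ti)) / (n_mc + 1)
  }, numeric(1))
  data.frame(line = names(treatments), n = ni,
             mean = vapply(treatments, mean, numeric(1)),
             diff = diff,
             percent_change = 100 * diff / mean(control),
             t = tstat, p_adjusted = p_adj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bundled qPCR p-values from a published miRNA overexpression screen
#'
#' Virgin-vs-mated expression t-test p-values for 20 Drosophila miRNA
#' target genes, measured in a control cross and in the matching
#' miRNA-overexpression cross, together with the published effect mark.
#' Used as the worked example for [call_overexpression_effect()] and
#' [effect_summary()].
#'
#' @return data.frame `mirna`, `target_gene`, `p_control`,
#'   `p_overexpression`, `reported_effect`.
#' @export
mirna_overexpression_qpcr <- function() {
  path <- system.file("extdata", "mirna_overexpression_qpcr.tsv",
                      package = "plastinet", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
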