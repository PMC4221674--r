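#' Quantile normalization across samples
#'
#' Forces every sample column to share one empirical distribution: each
#' value is replaced by the mean, across samples, of the values at its
#' rank. Ties within a column receive the mean of the normalized values at
#' their tied ranks. Delegates to [limma::normalizeQuantiles()] with
#' `ties = TRUE`, which implements exactly this rank-and-average rule.
#'
#' @param mat Numeric matrix, features in rows, samples in columns. No
#'   missing values are allowed (no imputation is performed).
#' @return Matrix of the same dimension and dimnames; all columns share a
#'   single sorted value vector. The operation is idempotent.
#' @examples
#' quantile_normalize(cbind(a = c(2, 4, 6), b = c(1, 3, 5)))
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("'mat' must be numeric")
  if (nrow(mat) < 1L || ncol(mat) < 2L) {
    stop("need at least 1 feature and 2 samples")
  }
  if (anyNA(mat)) stop("missing values are not allowed in quantile normalization")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' False-discovery-rate adjustment valid under arbitrary dependence among
#' tests: `q_(i) = min_{j >= i} min(1, p_(j) * m * c(m) / j)` with
#' `c(m) = sum_{k=1..m} 1/k`. Thin wrapper over
#' `stats::p.adjust(method = "BY")`.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BY")
}

## Number of distinct assignments of samples to labelled groups of the
## given sizes: n! / prod(n_g!).
n_distinct_assignments <- function(sizes) {
  round(exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1))))
}

## Enumerate every distinct assignment of positions 1..n to labelled groups.
## Returns an integer matrix (assignments x n) of group labels; the row
## order is deterministic and includes every labelling exactly once.
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  k <- length(sizes)
  res <- vector("list", n_distinct_assignments(sizes))
  cnt <- 0L
  rec <- function(avail, g, cur) {
    if (g == k) {
      cur[avail] <- g
      cnt <<- cnt + 1L
      res[[cnt]] <<- cur
      return(invisible(NULL))
    }
    cmb <- utils::combn(avail, sizes[g])
    for (j in seq_len(ncol(cmb))) {
      nxt <- cur
      nxt[cmb[, j]] <- g
      rec(setdiff(avail, cmb[, j]), g + 1L, nxt)
    }
  }
  rec(seq_len(n), 1L, integer(n))
  do.call(rbind, res)
}

## F statistics for many label assignments x many features at once.
## A: assignments x n matrix of labels 1..k; Y: n x m matrix of values.
## Returns an assignments x m matrix of F values; features with zero total
## sum of squares get F = 0 in every row.
f_stat_batch <- function(A, Y, sizes) {
  n <- ncol(A)
  k <- length(sizes)
  tot <- colSums(Y)
  sst <- colSums(Y^2) - tot^2 / n
  ssb <- 0
  for (g in seq_len(k)) {
    Sg <- (A == g) %*% Y
    ssb <- ssb + Sg^2 / sizes[g]
  }
  ssb <- sweep(ssb, 2L, tot^2 / n)
  ssb <- pmax(ssb, 0)
  ssw <- pmax(sweep(-ssb, 2L, sst, "+"), 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  ## degenerate features: no variation at all => F defined as 0
  zero <- sst <= 0
  if (any(zero)) f[, zero] <- 0
  f[is.nan(f)] <- 0
  f
}

## Count, per feature, the fraction of rows of F that reach the observed
## statistic. Ties count as >= (inclusive), with a small relative tolerance
## so that exact mathematical ties (label relabelings) survive floating-
## point summation-order noise.
perm_p_from_f <- function(f_perm, f_obs) {
  thr <- ifelse(is.finite(f_obs),
                f_obs - 1e-8 * (1 + abs(f_obs)),
                .Machine$double.xmax)
  cmp <- sweep(f_perm, 2L, thr, ">=")
  colMeans(cmp)
}

#' Permutation one-way ANOVA for a single feature
#'
#' Tests the model `Y = mu + C + eps`, with `C` the condition effect, by
#' permuting condition labels. The p-value is the fraction of evaluated
#' label assignments (always including the identity) whose F statistic is
#' at least the observed one; ties in F count as reaching it. When the
#' number of distinct label assignments is at most `exhaustive_cap` the
#' full set is enumerated and the p-value is exact; otherwise `n_perm`
#' random permutations are drawn (seeded) and the identity is included.
#'
#' Note that with `g` equal-size groups, the `g!` relabelings of any
#' grouping have identical F, so the minimum attainable exact p-value is
#' `g! / N` (e.g. 24/2520 = 1/105 for four conditions with two replicates).
#'
#' @param values Numeric vector of per-sample abundances (one feature).
#' @param design Design data.frame as from [simulate_design()].
#' @param n_perm Number of Monte Carlo permutations when the assignment
#'   space exceeds `exhaustive_cap`.
#' @param seed Integer seed for the Monte Carlo draw; ignored in
#'   exhaustive mode.
#' @param exhaustive_cap Enumerate exhaustively when the number of distinct
#'   assignments is at most this (default 10000; the 4x2 design has 2520
#'   and is always exact).
#' @return A list of class `perm_anova` with elements `f_obs`, `p_perm`,
#'   `n_evaluated`, `method` (`"exhaustive"` or `"monte_carlo"`),
#'   `means` (per-condition means) and `pooled_sd`.
#' @export
permutation_anova <- function(values, design, n_perm = 10000L, seed = NULL,
                              exhaustive_cap = 10000L) {
  design <- validate_design(design, values)
  if (anyNA(values)) stop("missing values are not allowed")
  labels <- as.integer(droplevels(design$condition))
  sizes <- as.integer(table(labels))
  n <- length(values)
  Y <- matrix(as.numeric(values), ncol = 1L)
  f_obs <- as.numeric(f_stat_batch(matrix(labels, nrow = 1L), Y, sizes))

  N <- n_distinct_assignments(sizes)
  if (N <= exhaustive_cap) {
    A <- enumerate_assignments(sizes)
    method <- "exhaustive"
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    A <- rbind(labels,
               t(vapply(seq_len(n_perm), function(i) labels[sample.int(n)],
                        integer(n))))
    method <- "monte_carlo"
  }
  p <- perm_p_from_f(f_stat_batch(A, Y, sizes), f_obs)

  means <- tapply(as.numeric(values), design$condition, mean)
  structure(
    list(f_obs = f_obs, p_perm = as.numeric(p), n_evaluated = nrow(A),
         method = method, means = means,
         pooled_sd = pooled_sd(values, design)),
    class = "perm_anova"
  )
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("Permutation one-way ANOVA (%s, %d assignments)\n",
              x$method, x$n_evaluated))
  cat(sprintf("  F = %.4g, p = %.4g\n", x$f_obs, x$p_perm))
  invisible(x)
}

#' Pooled standard deviation across conditions
#'
#' Square root of the within-condition mean-square error (the residual
#' variance pooled over all conditions). Used as the minimum-effect-size
#' gate for post hoc pairwise comparisons.
#'
#' @inheritParams permutation_anova
#' @return A non-negative number.
#' @export
pooled_sd <- function(values, design) {
  design <- validate_design(design, values)
  values <- as.numeric(values)
  grp <- split(values, droplevels(design$condition))
  ss <- sum(vapply(grp, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- length(values) - length(grp)
  sqrt(ss / df)
}

#' Differential analysis across the four conditions
#'
#' The shared engine applied to miRNA counts and to background-corrected
#' ChIP peak signals: optional quantile normalization, optional `log2(x+1)`
#' transform, a permutation one-way ANOVA per feature, Benjamini-Yekutieli
#' FDR adjustment over all features, and the four pairwise contrasts. A
#' contrast is called significant when the omnibus `q < alpha` AND the
#' absolute mean difference exceeds one pooled standard deviation.
#'
#' In exhaustive mode (the 4x2 design) every feature is tested against the
#' complete set of distinct label assignments; in Monte Carlo mode one
#' seeded set of permutations is shared across features.
#'
#' @param mat Feature-by-sample numeric matrix; columns must match
#'   `design$sample_id` in order.
#' @param design Design data.frame ([simulate_design()]).
#' @param alpha Omnibus FDR threshold for calling contrasts (default 0.05).
#' @param normalize Quantile-normalize columns first (default TRUE).
#' @param transform `"none"` (default) or `"log2"` for `log2(x + 1)`
#'   applied after normalization.
#' @param n_perm,seed,exhaustive_cap See [permutation_anova()].
#' @return A data.frame with one row per feature and fixed column order:
#'   `feature`, `p`, `q`, the four per-condition means, `pooled_sd`, then
#'   for each contrast `diff_*` (signed difference, mated-virgin /
#'   aged-young), `big_*` (|difference| > pooled SD) and `sig_*`
#'   (q < alpha and big). Attributes `method` and `n_evaluated` record the
#'   permutation scheme.
#' @export
differential_analysis <- function(mat, design, alpha = 0.05,
                                  normalize = TRUE,
                                  transform = c("none", "log2"),
                                  n_perm = 10000L, seed = 1L,
                                  exhaustive_cap = 10000L) {
  transform <- match.arg(transform)
  mat <- as.matrix(mat)
  design <- validate_design(design, mat)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("'alpha' must be a single value in [0, 1]")
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0("feature_", seq_len(nrow(mat)))
  }
  X <- mat
  if (normalize) X <- quantile_normalize(X)
  if (transform == "log2") X <- log2(X + 1)

  labels <- as.integer(design$condition)
  sizes <- as.integer(table(labels))
  n <- ncol(X)
  N <- n_distinct_assignments(sizes)
  if (N <= exhaustive_cap) {
    A <- enumerate_assignments(sizes)
    method <- "exhaustive"
  } else {
    set.seed(as.integer(seed))
    A <- rbind(labels,
               t(vapply(seq_len(n_perm), function(i) labels[sample.int(n)],
                        integer(n))))
    method <- "monte_carlo"
  }

  Yall <- t(X)                              # n x m
  m <- ncol(Yall)
  f_obs <- as.numeric(f_stat_batch(matrix(labels, nrow = 1L), Yall, sizes))
  p <- numeric(m)
  chunk <- max(1L, floor(2e6 / nrow(A)))
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    idx <- s:e
    p[idx] <- perm_p_from_f(f_stat_batch(A, Yall[, idx, drop = FALSE], sizes),
                            f_obs[idx])
  }
  q <- fdr_adjust(p)

  cond_means <- vapply(conditions(), function(cn) {
    rowMeans(X[, design$condition == cn, drop = FALSE])
  }, numeric(nrow(X)))
  grp_ss <- vapply(conditions(), function(cn) {
    sub <- X[, design$condition == cn, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }, numeric(nrow(X)))
  psd <- sqrt(rowSums(grp_ss) / (n - length(sizes)))

  out <- data.frame(feature = rownames(X), p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (cn in conditions()) out[[paste0("mean_", cn)]] <- cond_means[, cn]
  out$pooled_sd <- psd
  ct <- contrast_table()
  for (i in seq_len(nrow(ct))) {
    d <- cond_means[, ct$high[i]] - cond_means[, ct$low[i]]
    big <- abs(d) > psd
    out[[paste0("diff_", ct$contrast[i])]] <- d
    out[[paste0("big_", ct$contrast[i])]] <- big
    out[[paste0("sig_", ct$contrast[i])]] <- (q < alpha) & big
  }
  attr(out, "method") <- method
  attr(out, "n_evaluated") <- nrow(A)
  attr(out, "alpha") <- alpha
  out
}
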