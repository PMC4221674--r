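# Independent oracles and small constructors shared across tests.

# All permutations of a vector, as a matrix of index rows (independent of
# the package's distinct-assignment enumeration).
all_permutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v)) {
    out <- rbind(out, cbind(v[i], all_permutations(v[-i])))
  }
  out
}

# Classical one-way F computed from first principles for fixed groups.
oracle_f <- function(y, g) {
  m <- tapply(y, g, mean)
  n_g <- tabulate(g)
  ssb <- sum(n_g * (m - mean(y))^2)
  ssw <- sum((y - m[g])^2)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (length(n_g) - 1)) / (ssw / (length(y) - length(n_g)))
}

# Exact permutation p for the 4x2 design by brute force over all 8!
# permutations of the value vector (each distinct label assignment appears
# 2!^4 = 16 times, so this equals the distinct-assignment p exactly).
oracle_perm_p <- function(y) {
  g <- rep(1:4, each = 2L)
  f_obs <- oracle_f(y, g)
  P <- perm_idx_8()
  f_perm <- apply(P, 1L, function(ix) oracle_f(y[ix], g))
  thr <- if (is.finite(f_obs)) f_obs - 1e-8 * (1 + abs(f_obs)) else Inf
  if (is.finite(f_obs)) mean(f_perm >= thr) else mean(is.infinite(f_perm))
}

# Cache the 8! index matrix; building it once keeps the oracle fast.
perm_idx_8 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- all_permutations(1:8)
    cache
  }
})

# Hand Benjamini-Yekutieli: step-up on p * m * c(m) / rank.
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  raw <- p[o] * m * cm / seq_len(m)
  q <- rev(cummin(rev(pmin(raw, 1))))
  out <- numeric(m)
  out[o] <- q
  out
}

# Minimal membership table for the plasticity module.
make_membership <- function(feature, sig, dir) {
  cns <- contrast_names()
  out <- data.frame(feature = feature, stringsAsFactors = FALSE)
  for (cn in cns) {
    out[[paste0("sig_", cn)]] <- sig[, cn]
    out[[paste0("dir_", cn)]] <- ifelse(sig[, cn], dir[, cn], NA)
  }
  out
}

# Toy peak sets used by the merge tests: a named list of data.frames.
toy_peak_samples <- function() {
  s <- function(...) data.frame(..., stringsAsFactors = FALSE)
  list(
    s1 = s(chrom = c("chr1", "chr1", "chr2"),
           start = c(1000L, 5000L, 100L),
           end   = c(1200L, 5100L, 400L)),
    s2 = s(chrom = c("chr1", "chr1"),
           start = c(1000L, 5000L),
           end   = c(1200L, 5100L)),
    s3 = s(chrom = "chr2", start = 150L, end = 420L)
  )
}
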