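test_that("quantile normalization matches the hand rank-and-average oracle", {
  out <- quantile_normalize(cbind(a = c(2, 4, 6), b = c(1, 3, 5)))
  expect_equal(unname(out), cbind(c(1.5, 3.5, 5.5), c(1.5, 3.5, 5.5)))

  ## identical columns are left untouched
  m <- cbind(x = c(3, 1, 7), y = c(3, 1, 7))
  expect_equal(quantile_normalize(m), m)

  ## a constant column receives the mean of the rank-means everywhere:
  ## sorted row means are (3, 4, 5), so the tied column becomes 4
  out2 <- quantile_normalize(cbind(a = c(5, 5, 5), b = c(1, 3, 5)))
  expect_equal(unname(out2[, 1]), rep(4, 3))
  expect_equal(unname(out2[, 2]), c(3, 4, 5))
})

test_that("quantile normalization equalizes sorted columns and is idempotent", {
  set.seed(11)
  m <- matrix(rexp(60, 1 / 50), 10, 6)
  qn <- quantile_normalize(m)
  ref <- sort(qn[, 1])
  for (j in 2:ncol(qn)) expect_equal(sort(qn[, j]), ref)
  expect_equal(quantile_normalize(qn), qn)
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("exhaustive permutation ANOVA equals the brute-force enumeration", {
  d <- simulate_design(2)
  set.seed(21)
  for (i in 1:4) {
    y <- rnorm(8, sd = sample(c(0.5, 2), 1))
    res <- permutation_anova(y, d)
    expect_equal(res$method, "exhaustive")
    expect_equal(res$n_evaluated, 2520L)
    expect_equal(res$p_perm, oracle_perm_p(y), tolerance = 1e-12)
  }
})

test_that("degenerate inputs: flat features give p = 1, bad designs error", {
  d <- simulate_design(2)
  res <- permutation_anova(rep(4, 8), d)
  expect_equal(res$p_perm, 1)
  expect_equal(res$f_obs, 0)
  bad <- data.frame(sample_id = paste0("s", 1:4),
                    condition = c("young_virgin", "young_virgin",
                                  "young_virgin", "young_mated"))
  expect_error(permutation_anova(rnorm(4), bad), "degenerate")
})

test_that("a strongly shifted condition attains the tie-limited minimum p", {
  d <- simulate_design(2)
  set.seed(5)
  y <- rnorm(8)
  y[d$condition == "aged_virgin"] <- y[d$condition == "aged_virgin"] + 1e4
  res <- permutation_anova(y, d)
  ## ties at the top: at least the 4! relabelings of the observed grouping
  expect_gte(res$p_perm, 24 / 2520)
  expect_equal(res$p_perm, oracle_perm_p(y), tolerance = 1e-12)
})

test_that("Monte Carlo p converges to the exhaustive p", {
  d <- simulate_design(2)
  set.seed(33)
  y <- rnorm(8)
  exact <- permutation_anova(y, d)$p_perm
  mc <- permutation_anova(y, d, n_perm = 4000, seed = 1, exhaustive_cap = 10)
  expect_equal(mc$method, "monte_carlo")
  expect_equal(mc$p_perm, exact, tolerance = 0.03)
  ## identical seed, identical answer
  mc2 <- permutation_anova(y, d, n_perm = 4000, seed = 1, exhaustive_cap = 10)
  expect_identical(mc$p_perm, mc2$p_perm)
})

test_that("BY adjustment matches hand evaluation and dominates BH", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3))
  set.seed(2)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_equal(q, oracle_by(p))
  expect_true(all(q >= p.adjust(p, "BH")))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("pooled SD is the root mean-square within-condition error", {
  d <- simulate_design(2)
  expect_equal(pooled_sd(rep(c(0, 2), 4), d), sqrt(2))
  expect_equal(pooled_sd(rep(5, 8), d), 0)
  set.seed(8)
  y <- rnorm(8)
  expect_equal(pooled_sd(3.5 * y, d), 3.5 * pooled_sd(y, d))
  ## agreement with the classical anova MSE
  fit <- stats::aov(y ~ d$condition)
  expect_equal(pooled_sd(y, d)^2, summary(fit)[[1]]["Residuals", "Mean Sq"],
               ignore_attr = TRUE)
})

test_that("differential analysis recovers a planted on/off feature", {
  n <- 20
  cfg <- simulation_config(seed = 13, n_features = n, n_replicates = 4,
                           effect_fraction = 0)
  eff <- matrix(0, n, 4)
  eff[1, c(1, 3)] <- -Inf                    # silent in virgins
  sim <- simulate_counts(cfg, "mirna", effects = eff)
  da <- differential_analysis(sim$counts, sim$design, alpha = 0.05,
                              n_perm = 20000, seed = 3)
  expect_true(da$sig_young_mated_vs_virgin[1])
  expect_true(da$sig_aged_mated_vs_virgin[1])
  expect_false(da$sig_virgin_aged_vs_young[1])
  expect_gt(da$diff_young_mated_vs_virgin[1], 0)
})

test_that("differential analysis: invariants, boundaries and input checks", {
  cfg <- simulation_config(seed = 17, n_features = 30)
  sim <- simulate_counts(cfg, "mirna")
  da <- differential_analysis(sim$counts, sim$design, seed = 1)
  expect_true(all(da$q >= da$p - 1e-12))
  ## contrast differences reproduce the mean differences exactly
  expect_equal(da$diff_young_mated_vs_virgin,
               da$mean_young_mated - da$mean_young_virgin)
  expect_equal(da$diff_mated_aged_vs_young,
               da$mean_aged_mated - da$mean_young_mated)
  expect_identical(da$big_young_mated_vs_virgin,
                   abs(da$diff_young_mated_vs_virgin) > da$pooled_sd)
  ## alpha = 0 calls nothing
  da0 <- differential_analysis(sim$counts, sim$design, alpha = 0, seed = 1)
  expect_false(any(as.matrix(
    da0[, paste0("sig_", contrast_names())])))
  ## column/design mismatch is an error
  expect_error(
    differential_analysis(sim$counts[, 8:1], sim$design, seed = 1),
    "match"
  )
})

test_that("null permutation p-values are conservative at the 5% level", {
  cfg <- simulation_config(seed = 19, n_features = 400, effect_fraction = 0)
  sim <- simulate_counts(cfg, "mirna")
  da <- differential_analysis(sim$counts, sim$design, seed = 1)
  expect_lt(mean(da$p < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
  expect_gt(min(da$p), 24 / 2520 - 1e-12)   # tie-class floor
})
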