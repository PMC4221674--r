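## Build a small DiffResult-like table directly from chosen means and flags.
toy_diff <- function(features, means, sig) {
  ct <- contrast_table()
  out <- data.frame(feature = features, p = 0.01, q = 0.01,
                    stringsAsFactors = FALSE)
  for (cn in conditions()) out[[paste0("mean_", cn)]] <- means[, cn]
  out$pooled_sd <- 0.1
  for (i in seq_len(nrow(ct))) {
    d <- means[, ct$high[i]] - means[, ct$low[i]]
    out[[paste0("diff_", ct$contrast[i])]] <- d
    out[[paste0("big_", ct$contrast[i])]] <- abs(d) > out$pooled_sd
    out[[paste0("sig_", ct$contrast[i])]] <- sig[, ct$contrast[i]]
  }
  out
}

test_that("contrast classification passes flags and directions through", {
  means <- rbind(c(0, 5, 0, 0),   # up after mating in young flies only
                 c(0, 0, 0, 0))   # null
  colnames(means) <- conditions()
  sig <- matrix(FALSE, 2, 4, dimnames = list(NULL, contrast_names()))
  sig[1, "young_mated_vs_virgin"] <- TRUE
  memb <- classify_contrasts(toy_diff(c("f1", "f2"), means, sig))
  expect_true(memb$sig_young_mated_vs_virgin[1])
  expect_equal(memb$dir_young_mated_vs_virgin[1], "up")
  expect_true(is.na(memb$dir_virgin_aged_vs_young[1]))
  expect_false(any(as.logical(memb[2, paste0("sig_", contrast_names())])))
})

test_that("venn regions match brute-force set algebra", {
  set.seed(41)
  n <- 60
  sig <- matrix(runif(n * 4) < 0.3, n, 4,
                dimnames = list(NULL, contrast_names()))
  dir <- matrix("up", n, 4, dimnames = list(NULL, contrast_names()))
  memb <- make_membership(paste0("f", 1:n), sig, dir)
  venn <- venn_overlap(memb)
  expect_equal(nrow(venn), 15L)
  ## brute force: each feature lands in exactly one region
  key <- apply(sig, 1, function(r) paste(contrast_names()[r], collapse = "&"))
  brute <- table(key[key != ""])
  for (i in seq_len(nrow(venn))) {
    expected <- if (venn$region[i] %in% names(brute))
      as.integer(brute[[venn$region[i]]]) else 0L
    expect_equal(venn$count[i], expected)
  }
  expect_equal(sum(venn$count), sum(rowSums(sig) > 0))
})

test_that("venn handles disjoint and identical membership sets", {
  n <- 10
  sig <- matrix(FALSE, n, 4, dimnames = list(NULL, contrast_names()))
  sig[1:3, 1] <- TRUE; sig[4:5, 2] <- TRUE
  dir <- matrix("up", n, 4, dimnames = list(NULL, contrast_names()))
  memb <- make_membership(paste0("f", 1:n), sig, dir)
  v <- venn_overlap(memb, contrast_names()[1:2])
  expect_equal(v$count[v$region == contrast_names()[1]], 3L)
  expect_equal(v$count[v$region == contrast_names()[2]], 2L)
  expect_equal(v$count[v$region ==
                         paste(contrast_names()[1:2], collapse = "&")], 0L)

  sig2 <- sig; sig2[1:3, 2] <- TRUE; sig2[4:5, ] <- FALSE
  memb2 <- make_membership(paste0("f", 1:n), sig2, dir)
  v2 <- venn_overlap(memb2, contrast_names()[1:2])
  expect_equal(v2$count[v2$region ==
                          paste(contrast_names()[1:2], collapse = "&")], 3L)
  expect_equal(sum(v2$count), 3L)
})

## Memberships for the persistence / marker rules, one feature per case.
marker_cases <- function() {
  cns <- contrast_names()
  sig <- rbind(
    marker      = c(TRUE,  FALSE, TRUE,  FALSE),  # persists, echoed in virgins
    reversal    = c(TRUE,  FALSE, FALSE, TRUE),   # undone in aged mated flies
    persist_only= c(TRUE,  FALSE, FALSE, FALSE),  # persists, no virgin echo
    mismatch    = c(TRUE,  FALSE, TRUE,  FALSE),  # echo with opposite sign
    maintained  = c(TRUE,  FALSE, FALSE, TRUE),   # aged change, same sign
    null        = c(FALSE, FALSE, FALSE, FALSE)
  )
  colnames(sig) <- c("young_mated_vs_virgin", "aged_mated_vs_virgin",
                     "virgin_aged_vs_young", "mated_aged_vs_young")
  sig <- sig[, cns]
  dir <- matrix("up", nrow(sig), 4, dimnames = list(rownames(sig), cns))
  dir["reversal", "mated_aged_vs_young"] <- "down"
  dir["mismatch", "virgin_aged_vs_young"] <- "down"
  make_membership(rownames(sig), sig, dir)
}

test_that("persistence is the absence of a significant reversal", {
  memb <- marker_cases()
  pers <- persistent_marks(memb)
  expect_setequal(pers, c("marker", "persist_only", "mismatch", "maintained"))
  ## same-direction aged change does not break persistence
  expect_true("maintained" %in% pers)
  expect_false("reversal" %in% pers)
  expect_length(persistent_marks(memb[0, , drop = FALSE]), 0L)
})

test_that("the alternative persistence definition uses the aged contrast", {
  memb <- marker_cases()
  ## only features still significant (same direction) in aged V-vs-M count
  sig_aged <- memb
  sig_aged$sig_aged_mated_vs_virgin[sig_aged$feature == "marker"] <- TRUE
  sig_aged$dir_aged_mated_vs_virgin[sig_aged$feature == "marker"] <- "up"
  expect_equal(persistent_marks(sig_aged, "still_significant"), "marker")
  expect_length(persistent_marks(memb, "still_significant"), 0L)
})

test_that("accelerated-aging markers require a same-direction virgin echo", {
  memb <- marker_cases()
  pg <- data.frame(peak_id = c("marker", "marker", "mismatch"),
                   gene_id = c("gene1", "gene2", "gene3"))
  res <- accelerated_aging_markers(memb, pg)
  expect_equal(res$markers$feature, "marker")
  expect_equal(res$markers$direction, "up")
  expect_equal(res$markers$genes, "gene1;gene2")
  expect_setequal(res$genes, c("gene1", "gene2"))
  expect_equal(res$n_persistent, 4L)
  expect_equal(res$marker_fraction, 1 / 4)
  ## markers are a subset of persistent marks which are a subset of the
  ## mating-responsive set
  young <- memb$feature[memb$sig_young_mated_vs_virgin]
  expect_true(all(res$markers$feature %in% persistent_marks(memb)))
  expect_true(all(persistent_marks(memb) %in% young))
})

test_that("markers without a gene map warn; empty persistence gives NA fraction", {
  memb <- marker_cases()
  expect_warning(res <- accelerated_aging_markers(memb), "gene")
  expect_true(is.na(res$markers$genes))
  none <- memb[memb$feature == "null", , drop = FALSE]
  res0 <- accelerated_aging_markers(none, data.frame(peak_id = character(0),
                                                     gene_id = character(0)))
  expect_equal(nrow(res0$markers), 0L)
  expect_true(is.na(res0$marker_fraction))
})
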