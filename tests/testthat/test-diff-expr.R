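counts_fixture <- function() {
  set.seed(21)
  v <- matrix(rnbinom(120, mu = 200, size = 50), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6)))
  v[1, ] <- c(1L, 0L, 2L, 1L, 0L, 1L)  # below the 10-read filter
  meta <- tibble::tibble(sample_id = colnames(v),
                         strain = rep(c("WT", "dF"), each = 3),
                         replicate = rep(1:3, 2), condition = "batch")
  expression_matrix(v, "counts", meta)
}

test_that("filter_and_normalize removes low-count genes and scales to CPM", {
  x <- counts_fixture()
  fn <- filter_and_normalize(x, min_reads = 10L)
  expect_false("g01" %in% fn$kept)
  expect_equal(nrow(fn$cpm$values), 19L)
  expect_true(all(abs(colSums(fn$cpm$values) - 1e6) < 1e-6))
  # filtering happens before CPM: columns sum to 1e6 after the filter
  zero <- x
  zero$values[, 1] <- 0L
  expect_error(filter_and_normalize(zero), "zero total counts")
  expect_error(filter_and_normalize(fn$cpm), "expects counts")
})

test_that("run_contrast matches the Welch t-test on log2(CPM + pseudocount)", {
  x <- counts_fixture()
  fn <- filter_and_normalize(x)
  ct <- run_contrast(fn$cpm, paste0("s", 1:3), paste0("s", 4:6))
  v <- fn$cpm$values
  for (g in c("g02", "g07", "g15")) {
    la <- log2(v[g, 1:3] + 0.5)
    lb <- log2(v[g, 4:6] + 0.5)
    tt <- t.test(lb, la, var.equal = FALSE)
    expect_equal(unname(ct$p[ct$gene == g]), tt$p.value, tolerance = 1e-12)
    expect_equal(ct$lfc[ct$gene == g],
                 log2((mean(v[g, 4:6]) + 0.5) / (mean(v[g, 1:3]) + 0.5)),
                 tolerance = 1e-12)
  }
  expect_equal(unname(ct$padj), bh_oracle(unname(ct$p)), tolerance = 1e-12)
  expect_error(run_contrast(fn$cpm, "s1", paste0("s", 4:6)), ">= 2 replicates")
  expect_error(run_contrast(fn$cpm, paste0("s", 1:3), c("s4", "nope")),
               "unknown sample")
})

test_that("BH adjustment reproduces the canonical worked example", {
  # p = (0.01, 0.02, 0.03) all adjust to 0.03
  ct <- as_contrast(tibble::tibble(gene = c("a", "b", "c"),
                                   lfc = c(2, 2, 2), p = c(0.01, 0.02, 0.03)))
  expect_equal(ct$padj, c(0.03, 0.03, 0.03))
  expect_equal(ct$padj, bh_oracle(c(0.01, 0.02, 0.03)))
})

test_that("call_degs applies both thresholds with >= on the fold change", {
  cfg <- pipeline_config()
  tab <- tibble::tibble(
    gene = c("up_hit", "down_hit", "weak_fold", "weak_p", "boundary_fold"),
    lfc = c(2.0, -1.5, 0.8, 3.0, 1.0),
    p = c(1e-6, 1e-6, 1e-6, 0.5, 1e-6),
    padj = c(1e-5, 1e-5, 1e-5, 0.6, 1e-5))
  dg <- call_degs(as_contrast(tab), cfg)
  expect_equal(dg$up, c("up_hit", "boundary_fold"))  # |lfc| >= 1 inclusive
  expect_equal(dg$down, "down_hit")
  expect_equal(dg$table$direction[dg$table$gene == "weak_fold"], "none")
  expect_equal(dg$table$direction[dg$table$gene == "weak_p"], "none")
  # padj exactly at alpha is not significant (strict <)
  at_alpha <- as_contrast(tibble::tibble(gene = "x", lfc = 2, p = 0.05, padj = 0.05))
  expect_equal(call_degs(at_alpha, cfg)$table$direction, "none")
})

test_that("as_contrast recomputes missing padj by BH", {
  df <- tibble::tibble(gene = letters[1:4], lfc = 1:4,
                       p = c(0.04, 0.01, 0.3, 0.02))
  ct <- as_contrast(df)
  expect_equal(ct$padj, bh_oracle(df$p))
  expect_error(as_contrast(tibble::tibble(gene = "a", lfc = 1)))
})
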