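mk_contrast <- function(genes, lfc, p = NULL) {
  p <- p %||% ifelse(abs(lfc) >= 1, 1e-8, 0.9)
  as_contrast(tibble::tibble(gene = genes, lfc = lfc, p = p))
}

test_that("additivity_table computes delta and flags against the tolerance", {
  genes <- c("add1", "add2", "nonadd", "quiet", "boundary")
  d <- mk_contrast(genes, c(3.0, -2.0, 4.0, 0.2, 2.0))
  s1 <- mk_contrast(genes, c(1.5, -1.0, 0.5, 0.1, 0.5))
  s2 <- mk_contrast(genes, c(1.4, -1.1, 0.5, 0.0, 0.5))
  tab <- additivity_table(d, s1, s2)
  expect_equal(tab$delta, c(3.0 - 2.9, -2.0 + 2.1, 4.0 - 1.0, 0.1, 1.0),
               tolerance = 1e-12)
  expect_equal(tab$additive, c(TRUE, TRUE, FALSE, TRUE, TRUE))  # |delta| <= 1 inclusive
  # scatter: double DEG or summed singles reaching the fold cutoff
  expect_equal(tab$in_scatter, c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("additivity_table restricts to the shared gene universe", {
  d <- mk_contrast(c("a", "b", "c"), c(2, 2, 2))
  s1 <- mk_contrast(c("a", "b"), c(1, 1))
  s2 <- mk_contrast(c("a", "b", "d"), c(1, 1, 1))
  expect_message(tab <- additivity_table(d, s1, s2), "restricted to 2 shared")
  expect_equal(tab$gene, c("a", "b"))
})

test_that("attribute_degs assigns and exactly partitions double-mutant DEGs", {
  genes <- c("only1", "only2", "both", "neither", "wrong_sign", "mid1")
  d <- mk_contrast(genes, c(2, 2, 2, 2, 2, 2))
  # single 1: only1 strong DEG, both strong, wrong_sign negative, mid1 at 0.5
  s1 <- mk_contrast(genes, c(2.0, 0.3, 1.8, 0.2, -2.0, 0.5))
  # single 2: only2 strong DEG, both strong
  s2 <- mk_contrast(genes, c(0.4, 2.2, 1.5, 0.3, 0.2, 0.4))
  att <- attribute_degs(call_degs(d), s1, s2)
  rec <- setNames(att$records$attribution, att$records$gene)
  expect_equal(rec[["only1"]], "TF1")
  expect_equal(rec[["only2"]], "TF2")
  expect_equal(rec[["both"]], "overlapping")
  expect_equal(rec[["neither"]], "unassigned")
  expect_equal(rec[["wrong_sign"]], "unassigned")
  expect_equal(rec[["mid1"]], "unassigned")  # single 1 above cutoff? no: 0.5 < 1
  # counts partition the DEG set exactly
  expect_equal(sum(att$counts$n), nrow(att$records))
  expect_setequal(att$counts$attribution,
                  c("TF1", "TF2", "overlapping", "unassigned"))
})

test_that("attribution Z-test matches the Yates chi-square from prop.test", {
  res <- attribution_significance(30, 100, 50, 100)
  pt <- prop.test(c(30, 50), c(100, 100), correct = TRUE)
  expect_equal(res$z^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(res$p, pt$p.value, tolerance = 1e-10)
  # more small instances against the chi-square oracle
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    if ((k1 + k2) %in% c(0, n1 + n2)) next
    res <- attribution_significance(k1, n1, k2, n2)
    pt <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2), correct = TRUE))
    expect_equal(res$z^2, unname(pt$statistic), tolerance = 1e-10)
  }
  # degenerate pooled proportions
  expect_equal(attribution_significance(0, 10, 0, 12)$p, 1)
  expect_equal(attribution_significance(10, 10, 12, 12)$p, 1)
  expect_error(attribution_significance(5, 4, 1, 10))
})
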