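test_that("classify_targets distinguishes direct, novel and indirect", {
  degs <- tibble::tibble(gene = c("bound_reg", "novel_reg", "silent_b", "other"),
                         direction = c("up", "down", "up", "down"))
  regspec <- c("BOUND_REG", "novel_reg")           # case differs on purpose
  binding <- list(arcA = c("bound_reg", "SILENT_B"), fnr = character(0))
  cls <- classify_targets(degs, regspec, binding, deleted_tfs = c("arcA"))
  got <- setNames(cls$class, cls$gene)
  expect_equal(got[["bound_reg"]], "direct")
  expect_equal(got[["novel_reg"]], "putative_novel_direct")
  expect_equal(got[["silent_b"]], "indirect")
  expect_equal(got[["other"]], "indirect")
  expect_equal(cls$silent_binding, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(classify_targets(degs, regspec, binding, deleted_tfs = "gadE"),
               "no binding evidence")
})

test_that("regulation_specific_set contrasts the chemostat pair", {
  trn <- generate_trn(seed = 2L)
  des <- strain_design(trn$truth$tfs[1:3])
  pan <- simulate_strain_panel(trn$truth, des, seed = 2L)
  rs <- regulation_specific_set(pan$counts)
  expect_true(all(c("gene", "lfc", "padj", "direction") %in% names(rs)))
  expect_true(all(rs$direction %in% c("up", "down")))
  expect_gt(length(attr(rs, "universe")), 0)
  # recovered set matches the planted regulation-specific genes well
  truth_rs <- intersect(pan$truth$regspec_genes, attr(rs, "universe"))
  jacc <- length(intersect(rs$gene, truth_rs)) / length(union(rs$gene, truth_rs))
  expect_gt(jacc, 0.7)
  # directions follow the planted anaerobic-vs-aerobic fold change
  sgn <- sign(pan$truth$regspec_lfc[rs$gene])
  expect_gt(mean((rs$direction == "up") == (sgn > 0)), 0.95)
  # fails without both chemostat conditions
  batch_only <- select_samples(pan$counts,
                               samples_of(pan$counts, condition = "batch"))
  expect_error(regulation_specific_set(batch_only), ">= 2 replicates")
})

test_that("pathway_enrichment matches the hypergeometric oracle", {
  universe <- sprintf("g%03d", 1:60)
  sets <- gene_sets(list(big = universe[1:20], small = universe[21:26],
                         outside = c("x1", "x2", "x3")))
  query <- universe[c(1:12, 21:23, 40:44)]
  enr <- pathway_enrichment(query, sets, universe)
  for (i in seq_len(nrow(enr))) {
    K <- enr$set_size[i]; k <- enr$overlap[i]
    expect_equal(enr$p[i], hyper_upper_oracle(k, K, 60, length(query)),
                 tolerance = 1e-12)
  }
  expect_equal(enr$padj, bh_oracle(enr$p), tolerance = 1e-12)
  # sets with no members in the universe are not tested
  expect_false("outside" %in% enr$set_id)
  # the >= 9-gene rule: overlap 12 passes, overlap 3 cannot be significant
  expect_true(enr$significant[enr$set_id == "big"])
  expect_false(enr$significant[enr$set_id == "small"])
  # empty / disjoint query yields an empty result
  expect_equal(nrow(pathway_enrichment(character(0), sets, universe)), 0)
  expect_error(pathway_enrichment(query, sets, character(0)), "empty universe")
})

test_that("the 9-gene rule vetoes significant but small overlaps", {
  universe <- sprintf("g%03d", 1:200)
  sets <- gene_sets(list(tight = universe[1:8]))
  query <- universe[1:8]  # overlap 8/8: p is tiny but below the size floor
  enr <- pathway_enrichment(query, sets, universe)
  expect_lt(enr$padj[1], 0.05)
  expect_false(enr$significant[1])
})

test_that("kpe_genes returns the query members of enriched sets", {
  universe <- sprintf("g%03d", 1:60)
  sets <- gene_sets(list(big = universe[1:20]))
  query <- universe[c(1:12, 40:42)]
  enr <- pathway_enrichment(query, sets, universe)
  expect_setequal(kpe_genes(enr, query, sets), universe[1:12])
  none <- enr; none$significant <- FALSE
  expect_equal(kpe_genes(none, query, sets), character(0))
})
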