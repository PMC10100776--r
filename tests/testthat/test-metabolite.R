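small_met <- function() {
  v <- matrix(c(4, 8, NA, 6, 10, 12,
                1, 2, 1.5, 8, 9, 10), nrow = 2, byrow = TRUE,
              dimnames = list(c("metA", "metB"),
                              c("w1", "w2", "w3", "d1", "d2", "d3")))
  meta <- tibble::tibble(sample_id = colnames(v),
                         strain = rep(c("WT", "dF"), each = 3),
                         replicate = rep(1:3, 2))
  metabolite_matrix(v, meta, setNames(rep(1, 6), colnames(v)))
}

test_that("preprocess imputes half-minimum, normalizes and tests vs WT", {
  cfg <- pipeline_config(glog_a = 1)
  prep <- preprocess_metabolites(small_met(), config = cfg)
  # the NA in metA was replaced by min/2 = 2 before the glog
  g <- prep$processed
  expect_equal(g["metA", "w3"], regdissect:::glog(2, 1))
  expect_equal(prep$glog_a, 1)
  # equal-variance t-test against an explicit t.test oracle
  tt <- t.test(g["metB", 4:6], g["metB", 1:3], var.equal = TRUE)
  row <- prep$tests[prep$tests$metabolite == "metB", ]
  expect_equal(unname(row$p), tt$p.value, tolerance = 1e-12)
  expect_equal(unname(row$lfc), mean(g["metB", 4:6]) - mean(g["metB", 1:3]),
               tolerance = 1e-12)
  expect_equal(unname(prep$tests$padj), bh_oracle(unname(prep$tests$p)),
               tolerance = 1e-12)
  # strain means on the glog scale
  expect_equal(prep$strain_means["metA", "WT"], mean(g["metA", 1:3]))
})

test_that("preprocess drops all-missing metabolites and validates replicates", {
  met <- small_met()
  met$values["metA", ] <- NA
  expect_warning(prep <- preprocess_metabolites(met), "entirely missing")
  expect_false("metA" %in% rownames(prep$processed))
  met2 <- small_met()
  met2$sample_meta$strain[3] <- "dX"
  expect_error(suppressWarnings(preprocess_metabolites(met2)), "< 2 replicates")
})

test_that("biomass division happens before the glog transform", {
  met <- small_met()
  met$biomass[] <- 2
  prep <- preprocess_metabolites(met, config = pipeline_config(glog_a = 1))
  expect_equal(prep$processed["metB", "d1"], regdissect:::glog(8 / 2, 1))
})

test_that("joint_pathway_filter scores impact by betweenness with fallback", {
  nodes <- tibble::tibble(
    pathway = c(rep("chain", 3), rep("star", 4)),
    node = c("m1", "gMid", "gEnd", "hub", "m2", "gL1", "gL2"),
    type = c("metabolite", "gene", "gene", "gene", "metabolite", "gene", "gene"))
  edges <- tibble::tibble(
    pathway = c("chain", "chain", "star", "star", "star"),
    from = c("m1", "gMid", "hub", "hub", "hub"),
    to = c("gMid", "gEnd", "m2", "gL1", "gL2"))
  ps <- pathway_set(nodes, edges)
  # chain m1-gMid-gEnd: only gMid has nonzero betweenness (=1 normalized)
  res <- joint_pathway_filter("m1", "gMid", ps)
  imp <- setNames(res$impact$impact, res$impact$pathway)
  expect_equal(imp[["chain"]], 1)  # gMid carries all betweenness; m1 adds 0
  expect_equal(nrow(res$pairs[res$pairs$pathway == "chain", ]), 1L)
  # star leaves have zero betweenness -> degree fallback: (1+1)/(3+1+1+1)
  res2 <- joint_pathway_filter("m2", "gL1", ps)
  imp2 <- setNames(res2$impact$impact, res2$impact$pathway)
  expect_equal(imp2[["star"]], 2 / 6, tolerance = 1e-12)
  expect_true("m2" %in% res2$retained_metabolites)
  # impact at or below the threshold excludes the pair
  res3 <- joint_pathway_filter("m2", "gL1", ps,
                               config = pipeline_config(impact_threshold = 0.5))
  expect_false("m2" %in% res3$retained_metabolites)
  expect_error(joint_pathway_filter("m", "g",
                                    structure(list(), class = "pathway_set")),
               "empty pathway set")
})

test_that("metabolite-TF correlations match cor.test and its closed form", {
  set.seed(41)
  M <- matrix(rnorm(2 * 6), 2, 6, dimnames = list(c("m1", "m2"), LETTERS[1:6]))
  P <- matrix(rnorm(2 * 6), 2, 6, dimnames = list(c("t1", "t2"), LETTERS[1:6]))
  cors <- correlate_metabolite_tf(M, P)
  expect_equal(nrow(cors), 4L)
  for (i in seq_len(nrow(cors))) {
    ct <- cor.test(M[cors$metabolite[i], ], P[cors$itf[i], ])
    expect_equal(cors$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(cors$p[i], ct$p.value, tolerance = 1e-12)
    expect_equal(cors$p[i], pearson_p_oracle(cors$r[i], 6), tolerance = 1e-12)
  }
  expect_error(correlate_metabolite_tf(M[, 1:3], P), "fewer than 4")
  Mz <- M; Mz["m1", ] <- 5
  expect_warning(cz <- correlate_metabolite_tf(Mz, P), "zero variance")
  expect_false("m1" %in% cz$metabolite)
})

test_that("tier assignment is a deterministic function of (r, p, flags)", {
  ps <- pathway_set(
    tibble::tibble(pathway = "p1", node = c("m1", "gI"),
                   type = c("metabolite", "gene")),
    tibble::tibble(pathway = "p1", from = "m1", to = "gI"))
  net <- as_regulatory_network(tibble::tibble(
    tf = c("t1", "t2"), target = c("gI", "gX"), effect = "activation"))
  base <- tibble::tibble(metabolite = "m1", itf = "t1", n = 7L)
  tier_of <- function(r, p, itf = "t1", lit = NULL) {
    cors <- tibble::tibble(metabolite = "m1", itf = itf, r = r, p = p, n = 7L)
    tier_interactions(cors, ps, indirect_genes = "gI", network = net,
                      literature_pairs = lit)$tier
  }
  expect_equal(tier_of(0.95, 0.001), "high_confidence")
  # same correlation without the subsystem link falls back to screen tier
  expect_equal(tier_of(0.95, 0.001, itf = "t2"), "screen")
  # literature tier needs the listed pair and its own thresholds
  lit <- tibble::tibble(metabolite = "m1", itf = "t1")
  expect_equal(tier_of(0.85, 0.02, lit = lit), "literature_supported")
  expect_equal(tier_of(0.85, 0.02), "screen")         # unlisted pair
  expect_equal(tier_of(-0.8, 0.01), "screen")          # sign-agnostic screen
  expect_equal(tier_of(0.5, 0.001), "rejected")
  expect_equal(tier_of(0.95, 0.2), "rejected")
  # precedence: HC conditions beat the literature tier
  expect_equal(tier_of(0.95, 0.001, lit = lit), "high_confidence")
  # boundary: thresholds are strict inequalities
  expect_equal(tier_of(0.75, 0.001), "rejected")
  # determinism
  expect_identical(tier_of(0.95, 0.001), tier_of(0.95, 0.001))
})
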