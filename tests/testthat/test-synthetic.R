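test_that("generate_trn plants an identifiable network deterministically", {
  out <- generate_trn(n_genes = 120, n_tfs = 5, seed = 7L)
  expect_s3_class(out$network, "regnet")
  expect_equal(dim(out$truth$A), c(120L, 5L))
  # exclusive targets: regulated by exactly one TF
  for (tf in out$truth$tfs) {
    excl <- out$truth$exclusive[[tf]]
    expect_length(excl, 5L)
    expect_true(all(rowSums(out$truth$A[excl, , drop = FALSE] != 0) == 1))
    expect_true(all(out$truth$A[excl, tf] != 0))
  }
  rep <- check_nca_identifiability(out$truth$A)
  expect_true(rep$pass_structure)
  # |A| magnitudes within the declared range
  mag <- abs(out$truth$A[out$truth$A != 0])
  expect_true(all(mag >= out$truth$params$magnitude_range[1] &
                    mag <= out$truth$params$magnitude_range[2]))
  again <- generate_trn(n_genes = 120, n_tfs = 5, seed = 7L)
  expect_identical(out$truth$A, again$truth$A)
  expect_error(generate_trn(n_genes = 10, n_tfs = 8), "infeasible")
  expect_error(generate_trn(min_unique_targets = 1L), "must be >= 2")
})

test_that("strain_design growth rates are additive across the doubles", {
  des <- strain_design(c("TF01", "TF02", "TF03"))
  mu <- setNames(des$strains$mu, des$strains$strain)
  # single-mutant growth deficits sum exactly to the double-mutant deficits
  expect_equal((mu["WT"] - mu["FA"]),
               (mu["WT"] - mu["dF"]) + (mu["WT"] - mu["dA"]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal((mu["WT"] - mu["FI"]),
               (mu["WT"] - mu["dF"]) + (mu["WT"] - mu["dI"]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal((mu["WT"] - mu["AI"]),
               (mu["WT"] - mu["dA"]) + (mu["WT"] - mu["dI"]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(nrow(des$strains), 7L)
  expect_error(strain_design(c("a", "b")), "three distinct")
})

trn <- generate_trn(seed = 3L)
des <- strain_design(trn$truth$tfs[1:3])
pan <- simulate_strain_panel(trn$truth, des, seed = 3L)

test_that("simulate_strain_panel emits a consistent labelled panel", {
  expect_s3_class(pan$counts, "expr_mat")
  expect_equal(pan$counts$unit, "counts")
  expect_equal(ncol(pan$counts$values), 9L * des$replicates)  # 7 strains + 2 chemostat
  expect_true(all(pan$counts$values >= 0))
  expect_true(all(pan$counts$values == round(pan$counts$values)))
  # TPM columns each sum to 1e6
  expect_true(all(abs(colSums(pan$tpm$values) - 1e6) < 1e-6))
  truth <- pan$truth
  # expected fold changes recomputable from the noiseless TPM
  relfc <- log2(truth$tpm_noiseless[, "dF"] / truth$tpm_noiseless[, "WT"])
  expect_equal(unname(truth$expected_lfc[, "dF"]), unname(relfc), tolerance = 1e-12)
  # labels: direct iff deleted-TF target among expected DEGs
  lab <- truth$labels[["FA"]]
  del <- c(des$focal_tfs[1], des$focal_tfs[2])
  is_target <- rowSums(truth$A[, del, drop = FALSE] != 0) > 0
  expect_true(all(lab$label[lab$expected_deg & is_target] == "direct"))
  expect_true(all(lab$label[lab$expected_deg & !is_target] == "indirect"))
  expect_true(all(lab$label[!lab$expected_deg] == "none"))
  # binding evidence: regulon minus withheld novel targets plus silent extras
  for (tf in des$focal_tfs) {
    reg <- regulon(trn$network, tf)
    expect_true(all(setdiff(reg, truth$novel[[tf]]) %in% truth$binding[[tf]]))
    expect_false(any(truth$novel[[tf]] %in% truth$binding[[tf]]))
    expect_true(all(truth$silent[[tf]] %in% truth$binding[[tf]]))
    expect_false(any(truth$silent[[tf]] %in% reg))
  }
  # focal activities: zero exactly in the strains deleting them
  for (i in seq_len(nrow(des$strains))) {
    st <- des$strains$strain[i]
    for (tf in des$focal_tfs) {
      if (tf %in% des$strains$deleted[[i]]) {
        expect_equal(truth$P[tf, st], 0)
      } else {
        expect_gt(truth$P[tf, st], 0)
      }
    }
  }
  # chemostat pair differs only through the focal program
  itfs <- setdiff(truth$tfs, des$focal_tfs)
  expect_true(all(truth$P[itfs, "chemAn"] == truth$P[itfs, "chemAe"]))
})

test_that("panel generation is deterministic in the seed", {
  pan2 <- simulate_strain_panel(generate_trn(seed = 3L)$truth, des, seed = 3L)
  expect_identical(pan$counts$values, pan2$counts$values)
  pan3 <- simulate_strain_panel(generate_trn(seed = 3L)$truth, des, seed = 4L)
  expect_false(identical(pan$counts$values, pan3$counts$values))
})

test_that("planted non-additive interactions are recorded and localized", {
  pan_na <- simulate_strain_panel(generate_trn(seed = 5L)$truth,
                                  strain_design(generate_trn(seed = 5L)$truth$tfs[1:3]),
                                  nonadditive_fraction = 0.1, seed = 5L)
  na_tab <- pan_na$truth$nonadditive
  expect_gt(nrow(na_tab), 0)
  expect_true(all(na_tab$strain %in% c("FA", "FI", "AI")))
  expect_true(all(abs(na_tab$interaction_log2) >= 2))
})

test_that("simulate_metabolites plants correlated couplings with pathways", {
  mets <- simulate_metabolites(pan$truth, des, seed = 9L)
  expect_s3_class(mets$metabolites, "met_mat")
  expect_s3_class(mets$pathways, "pathway_set")
  expect_equal(nrow(mets$couplings), 6L)
  # each coupled metabolite shares a pathway with its driver gene
  for (i in seq_len(nrow(mets$couplings))) {
    pid <- paste0("path_", mets$couplings$metabolite[i])
    nd <- mets$pathways[[pid]]$nodes
    expect_true(mets$couplings$metabolite[i] %in% nd$node)
    expect_true(mets$couplings$driver[i] %in% nd$node)
  }
  # no metabolite is entirely missing
  expect_true(all(rowSums(!is.na(mets$metabolites$values)) > 0))
  mets2 <- simulate_metabolites(pan$truth, des, seed = 9L)
  expect_identical(mets$metabolites$values, mets2$metabolites$values)
  expect_error(simulate_metabolites(trn$truth, des), "not completed")
})

test_that("module assignment is one colour per gene with grey background", {
  mod <- simulate_module_assignment(pan$truth)
  expect_equal(nrow(mod), length(pan$truth$genes))
  expect_false(anyDuplicated(mod$gene) > 0)
  unreg <- pan$truth$genes[rowSums(pan$truth$A != 0) == 0]
  bg <- setdiff(unreg, pan$truth$growth_genes)
  expect_true(all(mod$module[mod$gene %in% bg] == "grey"))
  expect_true(all(mod$module[mod$gene %in% pan$truth$growth_genes] != "grey"))
})
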