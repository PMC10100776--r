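test_that("enrich_itfs reproduces Fisher's exact test and the 5-gene rule", {
  # 2x2 table [[4,1],[2,13]]: universe 20, indirect set 5, regulon 6, overlap 4
  universe <- sprintf("g%02d", 1:20)
  indirect <- universe[1:5]
  reg_big <- universe[c(1:4, 6, 7)]          # 4 of the indirect set
  reg_small <- universe[10:13]               # only 4 members -> skipped
  net <- as_regulatory_network(tibble::tibble(
    tf = c(rep("itfA", 6), rep("tiny", 4), rep("focal", 5)),
    target = c(reg_big, reg_small, universe[5:9]),
    effect = "activation"))
  enr <- enrich_itfs(indirect, net, universe, focal_tfs = "focal")
  expect_equal(enr$tf, "itfA")               # tiny skipped, focal suppressed
  ft <- fisher.test(matrix(c(4, 1, 2, 13), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(enr$p, ft$p.value, tolerance = 1e-10)
  expect_equal(enr$p, hyper_upper_oracle(4, 6, 20, 5), tolerance = 1e-12)
})

test_that("the 70 percent rule gives increased / decreased / dual calls", {
  mk_net <- function(effects) as_regulatory_network(tibble::tibble(
    tf = "tfX", target = sprintf("t%02d", seq_along(effects)), effect = effects))
  degs <- function(dirs) tibble::tibble(gene = sprintf("t%02d", seq_along(dirs)),
                                        direction = dirs)
  # repressor with 8/10 targets down -> increased (f+ = 0.8)
  r <- infer_activity_direction("tfX", degs(rep(c("down", "up"), c(8, 2))),
                                mk_net(rep("repression", 10)))
  expect_equal(r$direction, "increased")
  expect_equal(r$f_plus, 0.8)
  # repressor with 8/10 targets up -> decreased
  r2 <- infer_activity_direction("tfX", degs(rep(c("up", "down"), c(8, 2))),
                                 mk_net(rep("repression", 10)))
  expect_equal(r2$direction, "decreased")
  # 6/10 consistent -> dual
  r3 <- infer_activity_direction("tfX", degs(rep(c("up", "down"), c(6, 4))),
                                 mk_net(rep("activation", 10)))
  expect_equal(r3$direction, "dual")
  # boundary: exactly 70% consistent counts as increased
  r4 <- infer_activity_direction("tfX", degs(rep(c("up", "down"), c(7, 3))),
                                 mk_net(rep("activation", 10)))
  expect_equal(r4$direction, "increased")
  # dual-effect edges never enter the tally
  net_dual <- as_regulatory_network(tibble::tibble(
    tf = "tfX", target = c("t01", "t02", "t03"),
    effect = c("dual", "activation", "activation")))
  r5 <- infer_activity_direction("tfX", degs(c("down", "up", "up")), net_dual)
  expect_equal(r5$n_targets, 2L)
  expect_equal(r5$direction, "increased")
  # zero usable targets -> warning + excluded
  expect_warning(
    r6 <- infer_activity_direction("tfX", degs(character(0)),
                                   mk_net("activation")),
    "no usable DEG targets")
  expect_equal(r6$direction, "excluded")
})

test_that("identifiability report implements the standard NCA criteria", {
  # two TFs with identical regulons fail the reduced-rank condition
  A_dup <- matrix(0, 6, 2, dimnames = list(letters[1:6], c("t1", "t2")))
  A_dup[1:4, ] <- 1
  rep_dup <- check_nca_identifiability(A_dup)
  expect_false(rep_dup$pass_structure)
  expect_false(any(rep_dup$per_tf$reduced_rank_ok))
  # generate_trn output passes, agreeing with a Gaussian-elimination oracle
  trn <- generate_trn(n_genes = 80, n_tfs = 4, seed = 11L)
  rep_trn <- check_nca_identifiability(trn$truth$A, n_conditions = 6)
  expect_true(rep_trn$pass)
  expect_equal(rank_oracle(trn$truth$A), 4L)
  # conditions < TFs fails criterion (iii)
  rep_cond <- check_nca_identifiability(trn$truth$A, n_conditions = 2)
  expect_true(rep_cond$pass_structure)
  expect_false(rep_cond$conditions_ok)
  expect_false(rep_cond$pass)
  expect_error(check_nca_identifiability(matrix(0, 3, 2)), "empty connectivity")
})

test_that("fit_nca recovers a noiseless planted factorization", {
  sys <- make_planted_nca(60, 4, 6, seed = 5L)
  fit <- fit_nca(sys$X, sign(sys$A), quiet = TRUE)
  # relative reconstruction error < 1e-8
  rel <- sqrt(sum((sys$X - fit$A %*% fit$P)^2) / sum(sys$X^2))
  expect_lt(rel, 1e-8)
  # per-TF |r| = 1 up to numerical error
  for (l in 1:4) {
    expect_gt(abs(cor(fit$P[l, ], sys$P[l, ])), 1 - 1e-8)
  }
  # objective non-increasing; zero pattern preserved; normalization convention
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_true(all(fit$A[sign(sys$A) == 0] == 0))
  expect_equal(unname(sqrt(colSums(fit$A^2))), rep(1, 4), tolerance = 1e-8)
  expect_error(fit_nca(sys$X * NA, sign(sys$A)), "non-finite")
})

test_that("fit_nca is invariant to permuting gene order", {
  sys <- make_planted_nca(50, 3, 5, seed = 6L, noise_sd = 0.05)
  fit1 <- fit_nca(sys$X, sign(sys$A), quiet = TRUE)
  set.seed(1); perm <- sample(nrow(sys$X))
  fit2 <- fit_nca(sys$X[perm, ], sign(sys$A)[perm, ], quiet = TRUE)
  expect_equal(fit1$P, fit2$P, tolerance = 1e-3)
})

test_that("tidy and glance summarize an nca_fit", {
  sys <- make_planted_nca(40, 3, 4, seed = 7L)
  fit <- fit_nca(sys$X, sign(sys$A), quiet = TRUE)
  td <- tidy(fit)
  expect_equal(nrow(td), 12L)
  expect_named(td, c("tf", "condition", "activity"))
  gl <- glance(fit)
  expect_equal(gl$n_tfs, 3L)
  expect_gt(gl$r_squared, 1 - 1e-10)
})

test_that("build_connectivity encodes signs and drops dual edges", {
  net <- as_regulatory_network(tibble::tibble(
    tf = c("t1", "t1", "t2"), target = c("gA", "gB", "gA"),
    effect = c("activation", "repression", "dual")))
  A <- build_connectivity(net, c("gA", "gB"), c("t1", "t2"))
  expect_equal(A["gA", "t1"], 1)
  expect_equal(A["gB", "t1"], -1)
  expect_equal(A["gA", "t2"], 0)
})

test_that("bootstrap_nca is deterministic with degenerate noiseless widths", {
  sys <- make_planted_nca(40, 3, 5, seed = 8L)
  b1 <- bootstrap_nca(sys$X, sign(sys$A), n_boot = 100, seed = 4L)
  b2 <- bootstrap_nca(sys$X, sign(sys$A), n_boot = 100, seed = 4L)
  expect_identical(b1, b2)
  # noiseless data: CI width < 1e-6 and the estimate inside the CI
  expect_lt(max(b1$upper - b1$lower), 1e-6)
  expect_true(all(b1$lower <= b1$estimate + 1e-9 &
                    b1$estimate - 1e-9 <= b1$upper))
  expect_error(bootstrap_nca(sys$X, sign(sys$A), n_boot = 50), ">= 100")
  # regulon of size 1 -> excluded with a warning
  A1 <- sign(sys$A)
  A1[, 3] <- 0; A1[1, ] <- 0; A1[1, 3] <- 1
  expect_warning(b3 <- bootstrap_nca(sys$X, A1, n_boot = 100, seed = 1L),
                 "size 1 excluded")
  expect_false("T03" %in% b3$tf)
})

test_that("reproduce_activities compares NCA deltas with qualitative calls", {
  acts <- tibble::tibble(tf = rep(c("t1", "t2"), each = 3),
                         condition = rep(c("WT", "m1", "m2"), 2),
                         activity = c(1, 2, 0.5, 1, 0.2, 1.5))
  qual <- tibble::tibble(tf = c("t1", "t1", "t2", "t2"),
                         strain = c("m1", "m2", "m1", "m2"),
                         direction = c("increased", "increased",
                                       "decreased", "dual"))
  out <- reproduce_activities(acts, qual)
  expect_equal(nrow(out), 3L)  # dual call dropped
  expect_equal(out$reproduced[out$tf == "t1" & out$strain == "m1"], TRUE)
  expect_equal(out$reproduced[out$tf == "t1" & out$strain == "m2"], FALSE)
  expect_equal(out$reproduced[out$tf == "t2" & out$strain == "m1"], TRUE)
})
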