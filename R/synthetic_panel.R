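#' Simulate the expression panel of the strain design
#'
#' Ground-truth forward model on the log10 scale:
#' `log10 expr = baseline + A %*% P[, condition] + beta * mu * 1{growth gene}
#'  + interaction + eps`, with `eps ~ Normal(0, noise_sd)`. Focal-TF deletion
#' zeroes the TF's activity in that strain; every non-focal TF (an iTF) is
#' driven allosterically through a designated exclusive direct target of a
#' focal TF, so iTF activities co-vary with focal direct-target expression
#' across strains. TPM is obtained by exponentiation and per-sample
#' normalization to 1e6; counts are negative-binomial with mean proportional
#' to TPM x library size and a common dispersion. Planted non-additive genes
#' add an interaction term only in the corresponding double mutant.
#'
#' The emitted truth tables are consistent with the data by construction:
#' expected log2 fold changes are computed from the noiseless TPM, and genes
#' are labelled `direct` (target of a deleted focal TF, hence part of the
#' regulation-specific anaerobiosis program) or `indirect` (growth-rate or
#' iTF mediated) wherever the expected |log2 FC| reaches the DEG cutoff.
#'
#' @param truth partial `synthetic_truth` from [generate_trn()].
#' @param design a [strain_design()]; its focal TFs must exist in `truth`.
#' @param noise_sd log10 residual standard deviation.
#' @param dispersion negative-binomial overdispersion (0 gives Poisson).
#' @param lib_size mean library size (reads per sample).
#' @param growth_gene_count number of growth-rate-responsive genes (drawn
#'   from genes not in any regulon).
#' @param growth_coef_range beta range (log10 units per unit growth-rate
#'   deviation from the wild type); growth genes respond positively, like
#'   the translation machinery.
#' @param growth_saturation growth-rate deficit (h^-1) at which the growth
#'   response saturates; the chemostat conditions sit beyond it, the double
#'   mutants within the linear range.
#' @param core_gene_count highly expressed stable genes anchoring library
#'   mass (keeps per-sample normalization shifts small).
#' @param focal_activity wild-type (anaerobic) activity of each focal TF.
#' @param itf_amplitude maximum |activity difference from WT| for iTFs.
#' @param itf_jitter sd of per-strain jitter decorrelating iTF activities.
#' @param nonadditive_fraction fraction of each double mutant's focal-target
#'   genes given a planted interaction term (default 0 = exact additivity).
#' @param nonadditive_size log2-unit range of planted interaction magnitudes.
#' @param novel_fraction fraction of each focal regulon withheld from the
#'   binding-evidence set (emulating uncharacterized novel direct targets).
#' @param n_silent bound-but-unregulated genes added per focal TF's
#'   binding-evidence set.
#' @param deg_lfc log2 cutoff used for the truth labels.
#' @param seed integer seed; identical seeds give byte-identical tables.
#' @return A list with `counts` and `tpm` (both `expr_mat`) and the completed
#'   `truth` (activities `P`, expected log2 fold changes, per-mutant labels,
#'   regulation-specific gene set, binding evidence, growth program, iTF
#'   drivers, non-additive plantings).
#' @export
simulate_strain_panel <- function(truth, design,
                                  noise_sd = 0.05,
                                  dispersion = 0.01,
                                  lib_size = 5e6,
                                  growth_gene_count = 40,
                                  growth_coef_range = c(6.5, 7.5),
                                  growth_saturation = 0.25,
                                  core_gene_count = 30,
                                  focal_activity = 1.0,
                                  itf_amplitude = 0.75,
                                  itf_jitter = 0.03,
                                  nonadditive_fraction = 0,
                                  nonadditive_size = c(2, 3),
                                  novel_fraction = 0.15,
                                  n_silent = 5,
                                  deg_lfc = 1.0,
                                  seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(design, "strain_design"))
  A <- truth$A
  genes <- truth$genes
  tfs <- truth$tfs
  focal <- design$focal_tfs
  missing_tf <- setdiff(c(focal, unlist(design$strains$deleted)), tfs)
  if (length(missing_tf) > 0) {
    stop("design references TF(s) absent from truth: ",
         paste(unique(missing_tf), collapse = ", "))
  }
  itfs <- setdiff(tfs, focal)
  strains <- design$strains
  conditions <- c(strains$strain, "chemAn", "chemAe")
  n_cond <- length(conditions)

  set.seed(seed)

  ## --- growth-rate program and stable core (unregulated genes) -------------
  unregulated <- genes[rowSums(A != 0) == 0]
  if (length(unregulated) < growth_gene_count + core_gene_count) {
    stop("not enough unregulated genes for the growth program and core; ",
         "reduce growth_gene_count / core_gene_count")
  }
  growth_genes <- sample(unregulated, growth_gene_count)
  # positively growth-correlated (translation-machinery-like): slower growth
  # removes library mass, which is bounded, instead of adding unbounded mass
  beta <- stats::setNames(
    stats::runif(growth_gene_count, growth_coef_range[1], growth_coef_range[2]),
    growth_genes)
  # highly expressed stable genes (ribosomal-protein-like) anchoring the
  # library mass, so per-sample normalization shifts stay small
  core_genes <- sample(setdiff(unregulated, growth_genes), core_gene_count)

  ## --- activity matrix P (TFs x conditions) --------------------------------
  P <- matrix(0, length(tfs), n_cond, dimnames = list(tfs, conditions))
  for (tf in focal) {
    on <- vapply(seq_len(nrow(strains)), function(i) !(tf %in% strains$deleted[[i]]),
                 logical(1))
    P[tf, strains$strain] <- ifelse(on, focal_activity, 0)
    P[tf, "chemAn"] <- focal_activity  # anaerobiosis program on
    P[tf, "chemAe"] <- 0               # off under aerobic respiration
  }
  # iTF activities ride on a focal exclusive direct target (the allosteric
  # driver); standardized deviation from WT, scaled to itf_amplitude.
  drivers <- tibble(itf = character(), focal = character(), driver = character(),
                    sign = integer())
  used_drivers <- character(0)
  for (j in seq_along(itfs)) {
    foc <- focal[(j - 1L) %% length(focal) + 1L]
    candidates <- setdiff(truth$exclusive[[foc]], used_drivers)
    if (length(candidates) == 0) candidates <- truth$exclusive[[foc]]
    drv <- sample(candidates, 1L)
    used_drivers <- c(used_drivers, drv)
    sgn <- sample(c(-1L, 1L), 1L)
    d <- A[drv, foc] * P[foc, strains$strain]     # driver log10 expression part
    z <- d - d[strains$strain == "WT"]
    zmax <- max(abs(z))
    if (zmax > 0) z <- z / zmax  # flat driver (e.g. null panel): no iTF signal
    act <- sgn * itf_amplitude * z + stats::rnorm(length(z), 0, itf_jitter)
    act <- act - act[strains$strain == "WT"]      # WT anchored at zero
    P[itfs[j], strains$strain] <- act
    P[itfs[j], c("chemAn", "chemAe")] <- 0        # pair differs only via focal program
    drivers <- add_row(drivers, itf = itfs[j], focal = foc, driver = drv, sign = sgn)
  }

  ## --- planted non-additive interactions -----------------------------------
  nonadditive <- tibble(strain = character(), gene = character(),
                        interaction_log2 = numeric())
  doubles <- strains$strain[lengths(strains$deleted) == 2L]
  inter <- matrix(0, length(genes), n_cond, dimnames = list(genes, conditions))
  if (nonadditive_fraction > 0) {
    for (st in doubles) {
      del <- strains$deleted[[which(strains$strain == st)]]
      cand <- genes[rowSums(A[, del, drop = FALSE] != 0) > 0]
      n_pick <- max(1L, ceiling(nonadditive_fraction * length(cand)))
      picked <- sample(cand, n_pick)
      mag <- stats::runif(n_pick, nonadditive_size[1], nonadditive_size[2]) *
        sample(c(-1, 1), n_pick, replace = TRUE)
      inter[picked, st] <- mag * log10(2)  # store on the log10 scale
      nonadditive <- bind_rows(nonadditive,
                               tibble(strain = st, gene = picked, interaction_log2 = mag))
    }
  }

  ## --- noiseless log10 expression and expected fold changes ----------------
  baseline <- stats::setNames(stats::rnorm(length(genes), 2.0, 0.3), genes)
  baseline[core_genes] <- stats::rnorm(core_gene_count, 3.6, 0.15)
  mu_cond <- c(strains$mu, design$mu_chemostat, design$mu_chemostat)
  L0 <- matrix(baseline, length(genes), n_cond, dimnames = list(genes, conditions))
  L0 <- L0 + A %*% P
  # growth response centered at the WT rate (so WT stays at baseline) and
  # saturating `growth_saturation` below it (chemostat regime); the double
  # mutants stay within the linear, hence exactly additive, range
  dmu <- pmax(mu_cond - design$mu_wt, -growth_saturation)
  L0[growth_genes, ] <- L0[growth_genes, ] + outer(beta, dmu)
  L0 <- L0 + inter
  T0 <- apply(10^L0, 2, function(v) v / sum(v) * 1e6)
  dimnames(T0) <- dimnames(L0)
  mutants <- setdiff(strains$strain, "WT")
  expected_lfc <- log2(T0[, mutants, drop = FALSE] / T0[, "WT"])
  regspec_lfc <- log2(T0[, "chemAn"] / T0[, "chemAe"])
  regspec_genes <- genes[abs(regspec_lfc) >= deg_lfc]

  labels <- lapply(mutants, function(st) {
    del <- strains$deleted[[which(strains$strain == st)]]
    focal_target <- rowSums(A[, del, drop = FALSE] != 0) > 0
    lfc <- expected_lfc[, st]
    tibble(gene = genes, expected_lfc = unname(lfc),
           expected_deg = abs(lfc) >= deg_lfc,
           label = ifelse(!abs(lfc) >= deg_lfc, "none",
                          ifelse(focal_target, "direct", "indirect")))
  })
  names(labels) <- mutants

  ## --- binding evidence: regulon minus novel plus silent extras ------------
  binding <- list(); novel <- list(); silent <- list()
  non_targets <- setdiff(genes, rownames(A)[rowSums(A[, focal, drop = FALSE] != 0) > 0])
  protected <- drivers$driver  # allosteric drivers always carry binding evidence
  for (tf in focal) {
    reg <- regulon(truth$network, tf)
    cand <- setdiff(reg, protected)
    n_nov <- floor(novel_fraction * length(reg))
    nov <- if (n_nov > 0) sample(cand, min(n_nov, length(cand))) else character(0)
    sil <- sample(setdiff(non_targets, c(growth_genes, core_genes)), n_silent)
    binding[[tf]] <- c(setdiff(reg, nov), sil)
    novel[[tf]] <- nov
    silent[[tf]] <- sil
  }

  ## --- replicate-level noise, TPM and counts -------------------------------
  reps <- design$replicates
  cond_of_sample <- rep(conditions, each = reps)
  sample_ids <- paste(cond_of_sample, rep(seq_len(reps), times = n_cond), sep = "_")
  strain_of <- ifelse(cond_of_sample %in% strains$strain, cond_of_sample, "WT")
  condition_tag <- dplyr::case_when(
    cond_of_sample == "chemAn" ~ "chemostat_anaerobic",
    cond_of_sample == "chemAe" ~ "chemostat_aerobic",
    TRUE ~ "batch"
  )
  meta <- tibble(sample_id = sample_ids, strain = strain_of,
                 replicate = rep(seq_len(reps), times = n_cond),
                 condition = condition_tag)

  eps <- matrix(stats::rnorm(length(genes) * length(sample_ids), 0, noise_sd),
                length(genes), length(sample_ids))
  Lrep <- L0[, cond_of_sample, drop = FALSE] + eps
  tpm <- apply(10^Lrep, 2, function(v) v / sum(v) * 1e6)
  dimnames(tpm) <- list(genes, sample_ids)
  libs <- lib_size * stats::runif(length(sample_ids), 0.8, 1.2)
  mu_counts <- sweep(tpm / 1e6, 2, libs, `*`)
  counts <- if (dispersion > 0) {
    matrix(stats::rnbinom(length(mu_counts), mu = mu_counts, size = 1 / dispersion),
           nrow(mu_counts), ncol(mu_counts))
  } else {
    matrix(stats::rpois(length(mu_counts), lambda = mu_counts),
           nrow(mu_counts), ncol(mu_counts))
  }
  dimnames(counts) <- dimnames(tpm)

  truth$P <- P
  truth$baseline <- baseline
  truth$log10_noiseless <- L0
  truth$tpm_noiseless <- T0
  truth$expected_lfc <- expected_lfc
  truth$regspec_lfc <- regspec_lfc
  truth$regspec_genes <- regspec_genes
  truth$labels <- labels
  truth$growth_genes <- growth_genes
  truth$core_genes <- core_genes
  truth$beta <- beta
  truth$mu <- stats::setNames(mu_cond, conditions)
  truth$drivers <- drivers
  truth$binding <- binding
  truth$novel <- novel
  truth$silent <- silent
  truth$nonadditive <- nonadditive
  truth$design <- design
  truth$panel_params <- list(noise_sd = noise_sd, dispersion = dispersion,
                             lib_size = lib_size, focal_activity = focal_activity,
                             itf_amplitude = itf_amplitude, itf_jitter = itf_jitter,
                             nonadditive_fraction = nonadditive_fraction,
                             novel_fraction = novel_fraction, n_silent = n_silent,
                             deg_lfc = deg_lfc, seed = as.integer(seed))

  list(counts = expression_matrix(counts, "counts", meta),
       tpm = expression_matrix(tpm, "TPM", meta),
       truth = truth)
}

#' Truth-derived coexpression module assignment
#'
#' Emulates the downstream product of a compendium coexpression analysis:
#' genes driven by the same TF share a module colour, the growth program is
#' merged into the module of one focal TF (its targets and growth-responsive
#' genes co-respond across the panel), and unregulated genes are grey
#' (uncorrelated).
#'
#' @param truth completed `synthetic_truth`.
#' @param merge_growth_with focal TF whose colour the growth program shares
#'   (default the first focal TF).
#' @return Tibble with columns `gene`, `module`.
#' @export
simulate_module_assignment <- function(truth, merge_growth_with = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), !is.null(truth$design))
  focal <- truth$design$focal_tfs
  merge_growth_with <- merge_growth_with %||% focal[1]
  palette <- c("blue", "turquoise", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "salmon", "tan")
  cols <- stats::setNames(rep(palette, length.out = length(truth$tfs)), truth$tfs)
  A <- truth$A
  driver_tf <- apply(abs(A), 1, function(r) if (all(r == 0)) NA_character_ else
    colnames(A)[which.max(r)])
  module <- ifelse(is.na(driver_tf), "grey", cols[driver_tf])
  module[truth$genes %in% truth$growth_genes] <- cols[[merge_growth_with]]
  tibble(gene = truth$genes, module = unname(module))
}
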