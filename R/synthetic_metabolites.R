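#' Simulate metabolite panels with planted allosteric couplings
#'
#' Each coupled metabolite's per-strain mean is a monotone (log-linear)
#' function of the expression of its iTF's allosteric driver gene -- the same
#' focal direct target that drives the iTF's activity in the panel -- so the
#' across-strain correlation of noise-free metabolite means with the planted
#' iTF activity is |r| >= 0.95 by construction. Replicate noise, per-sample
#' biomass factors and a configurable missing-at-random fraction are added.
#' Pathway graphs place each coupled metabolite in a subsystem together with
#' its driver gene and regulon genes of its iTF (so the distance criterion is
#' satisfiable), while decoy metabolites sit in unrelated subsystems.
#'
#' @param truth completed `synthetic_truth` (after [simulate_strain_panel()]).
#' @param design the [strain_design()].
#' @param n_metabolites total metabolites (>= `n_coupled`).
#' @param n_coupled planted metabolite-iTF couplings.
#' @param noise_cv replicate coefficient of variation.
#' @param missing_fraction overall fraction of missing cells; missingness is
#'   left-censored (only a metabolite's lowest-intensity cells drop out), as
#'   in LC-MS data.
#' @param fold_range across-strain fold-change range of coupled metabolites.
#' @param seed integer seed.
#' @return List with `metabolites` (a `met_mat`), `pathways` (a
#'   `pathway_set`) and `couplings` (tibble: metabolite, itf, sign, driver).
#' @export
simulate_metabolites <- function(truth, design,
                                 n_metabolites = 20,
                                 n_coupled = 6,
                                 noise_cv = 0.08,
                                 missing_fraction = 0.05,
                                 fold_range = c(3, 6),
                                 seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(truth$P)) stop("truth is not completed; run simulate_strain_panel() first")
  if (n_coupled > n_metabolites) stop("n_coupled must be <= n_metabolites")
  itfs <- truth$drivers$itf
  if (length(itfs) == 0) stop("truth has no iTFs to couple to")
  dual <- dual_effect_tfs(truth$network)
  set.seed(seed)

  strains <- design$strains$strain
  reps <- design$replicates
  met_ids <- sprintf("met%02d", seq_len(n_metabolites))
  coupled_idx <- seq_len(n_coupled)
  coupled_itfs <- rep(itfs, length.out = n_coupled)
  if (any(coupled_itfs %in% dual)) {
    stop("coupling requested for dual-effect iTF(s): ",
         paste(intersect(coupled_itfs, dual), collapse = ", "))
  }

  log_means <- matrix(0, n_metabolites, length(strains),
                      dimnames = list(met_ids, strains))
  couplings <- tibble(metabolite = character(), itf = character(),
                      sign = integer(), driver = character(), fold = numeric())
  for (k in coupled_idx) {
    itf <- coupled_itfs[k]
    drv_row <- truth$drivers[truth$drivers$itf == itf, ]
    drv <- drv_row$driver[1]
    z <- log10(truth$tpm_noiseless[drv, strains])
    z <- z - z["WT"]
    fold <- stats::runif(1, fold_range[1], fold_range[2])
    sgn <- sample(c(-1L, 1L), 1L)
    k_m <- sgn * log10(fold) / diff(range(z))
    m0 <- 10^stats::rnorm(1, 0, 0.3)  # around 1 umol / g DCW
    log_means[k, ] <- log10(m0) + k_m * z
    # correlation sign between metabolite and the iTF's activity row
    r_sign <- as.integer(sgn * drv_row$sign[1])
    couplings <- add_row(couplings, metabolite = met_ids[k], itf = itf,
                         sign = r_sign, driver = drv, fold = fold)
  }
  for (k in setdiff(seq_len(n_metabolites), coupled_idx)) {
    m0 <- 10^stats::rnorm(1, 0, 0.3)
    log_means[k, ] <- log10(m0) + stats::rnorm(length(strains), 0, 0.05)
  }

  sample_ids <- paste(rep(strains, each = reps), "m", rep(seq_len(reps), length(strains)),
                      sep = "_")
  meta <- tibble(sample_id = sample_ids,
                 strain = rep(strains, each = reps),
                 replicate = rep(seq_len(reps), length(strains)))
  sdlog <- log10(1 + noise_cv)
  conc <- 10^(log_means[, meta$strain, drop = FALSE] +
                matrix(stats::rnorm(n_metabolites * length(sample_ids), 0, sdlog),
                       n_metabolites, length(sample_ids)))
  colnames(conc) <- sample_ids
  biomass <- stats::setNames(stats::rnorm(length(sample_ids), 1, 0.02), sample_ids)
  raw <- sweep(conc, 2, biomass, `*`)
  if (missing_fraction > 0) {
    # left-censored missingness: only a metabolite's lowest-intensity cells
    # (bottom quartile) can drop out, thinned to the requested fraction
    low <- raw <= apply(raw, 1, stats::quantile, probs = 0.25)
    mask <- low & matrix(stats::runif(length(raw)) < 4 * missing_fraction,
                         nrow(raw), ncol(raw))
    # never blank out a metabolite entirely
    full_rows <- rowSums(!mask) == 0
    mask[full_rows, 1] <- FALSE
    raw[mask] <- NA_real_
  }

  ## --- pathway graphs ------------------------------------------------------
  nodes <- list(); edges <- list()
  A <- truth$A
  for (k in coupled_idx) {
    itf <- coupled_itfs[k]
    met <- met_ids[k]
    drv <- couplings$driver[couplings$metabolite == met]
    excl <- truth$exclusive[[itf]]
    tgt <- excl[order(-abs(A[excl, itf]))][1:2]  # strongest exclusive targets
    pid <- paste0("path_", met)
    nodes[[pid]] <- tibble(pathway = pid,
                           node = c(met, drv, tgt),
                           type = c("metabolite", "gene", "gene", "gene"))
    edges[[pid]] <- tibble(pathway = pid,
                           from = c(drv, met, tgt[1]),
                           to = c(met, tgt[1], tgt[2]))
  }
  decoy_ids <- met_ids[setdiff(seq_len(n_metabolites), coupled_idx)]
  spare <- setdiff(truth$genes[rowSums(A != 0) == 0],
                   c(truth$growth_genes, unlist(truth$silent)))
  for (k in seq_len(min(4, length(decoy_ids)))) {
    met <- decoy_ids[k]
    gs <- spare[(2 * k - 1):(2 * k)]
    pid <- paste0("path_", met)
    nodes[[pid]] <- tibble(pathway = pid, node = c(met, gs),
                           type = c("metabolite", "gene", "gene"))
    edges[[pid]] <- tibble(pathway = pid, from = c(met, gs[1]), to = c(gs[1], gs[2]))
  }
  pathways <- pathway_set(bind_rows(nodes), bind_rows(edges))

  list(metabolites = metabolite_matrix(raw, meta, biomass),
       pathways = pathways,
       couplings = couplings)
}
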