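#' Generate a synthetic signed regulatory network with planted connectivity
#'
#' Builds a TF -> target edge set whose connectivity matrix satisfies the
#' network-component-analysis identifiability conditions by construction:
#' every TF receives at least `min_unique_targets` targets regulated by no
#' other TF. Edge signs are drawn with probability `activator_fraction` of
#' activation; connectivity magnitudes |A| are uniform on `magnitude_range`
#' (log10 expression units per unit TF activity).
#'
#' @param n_genes number of genes (must be >= `n_tfs * min_unique_targets`).
#' @param n_tfs number of transcription factors.
#' @param regulon_size_range integer range of regulon sizes.
#' @param min_unique_targets exclusive targets per TF (>= 2).
#' @param activator_fraction probability an edge is an activation.
#' @param magnitude_range range of connectivity magnitudes |A| in log10
#'   units per unit activity.
#' @param seed integer seed; identical seeds give identical networks.
#' @param tf_names,gene_names optional identifier vectors.
#' @return A list with `network` (a `regnet` edge tibble) and `truth`
#'   (a partial `synthetic_truth`: connectivity matrix `A`, exclusive target
#'   lists, identifiers, parameters).
#' @export
generate_trn <- function(n_genes = 400, n_tfs = 8,
                         regulon_size_range = c(15, 30),
                         min_unique_targets = 5,
                         activator_fraction = 0.6,
                         magnitude_range = c(0.7, 1.0),
                         seed = 1L,
                         tf_names = NULL, gene_names = NULL) {
  n_genes <- as.integer(n_genes)
  n_tfs <- as.integer(n_tfs)
  min_unique_targets <- as.integer(min_unique_targets)
  if (min_unique_targets < 2L) stop("min_unique_targets must be >= 2")
  if (n_genes < n_tfs * min_unique_targets) {
    stop("infeasible sizes: need n_genes >= n_tfs * min_unique_targets")
  }
  rng <- as.integer(round(regulon_size_range))
  if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < min_unique_targets) {
    stop("regulon_size_range must be an increasing pair >= min_unique_targets")
  }
  pool_size <- n_genes - n_tfs * min_unique_targets
  if (rng[2] - min_unique_targets > pool_size) {
    stop("infeasible sizes: shared target pool smaller than maximum regulon")
  }
  genes <- gene_names %||% sprintf("g%04d", seq_len(n_genes))
  tfs <- tf_names %||% sprintf("TF%02d", seq_len(n_tfs))
  stopifnot(length(genes) == n_genes, length(tfs) == n_tfs,
            !anyDuplicated(genes), !anyDuplicated(tfs))

  set.seed(seed)
  perm <- sample(genes)
  exclusive <- split(perm[seq_len(n_tfs * min_unique_targets)],
                     rep(seq_len(n_tfs), each = min_unique_targets))
  names(exclusive) <- tfs
  pool <- setdiff(genes, unlist(exclusive))
  sizes <- sample(seq(rng[1], rng[2]), n_tfs, replace = TRUE)

  A <- matrix(0, n_genes, n_tfs, dimnames = list(genes, tfs))
  edges <- vector("list", n_tfs)
  for (l in seq_len(n_tfs)) {
    extra <- if (sizes[l] > min_unique_targets) {
      sample(pool, sizes[l] - min_unique_targets)
    } else character(0)
    targets <- c(exclusive[[l]], extra)
    sgn <- ifelse(stats::runif(length(targets)) < activator_fraction, 1, -1)
    mag <- stats::runif(length(targets), magnitude_range[1], magnitude_range[2])
    A[targets, l] <- sgn * mag
    edges[[l]] <- tibble(
      tf = tfs[l], target = targets,
      effect = ifelse(sgn > 0, "activation", "repression")
    )
  }
  network <- as_regulatory_network(bind_rows(edges))
  report <- check_nca_identifiability(A)
  if (!report$pass_structure) {
    stop("generated connectivity failed the identifiability check; ",
         "increase min_unique_targets")  # unreachable by construction
  }
  truth <- structure(
    list(A = A, network = network, genes = genes, tfs = tfs,
         exclusive = exclusive,
         params = list(n_genes = n_genes, n_tfs = n_tfs,
                       regulon_size_range = rng,
                       min_unique_targets = min_unique_targets,
                       activator_fraction = activator_fraction,
                       magnitude_range = magnitude_range,
                       seed = as.integer(seed))),
    class = "synthetic_truth"
  )
  list(network = network, truth = truth)
}

#' Strain panel design
#'
#' The study layout: wild type, three single-deletion mutants, the three
#' pairwise double mutants, and a growth-rate-matched chemostat condition
#' pair (anaerobic vs aerobic at equal dilution rate). Deleting a TF sets its
#' activity to zero in that strain; the chemostat pair shares its growth
#' rate exactly and differs only through the anaerobiosis program.
#'
#' @param focal_tfs character vector of exactly three focal TF ids.
#' @param replicates biological replicates per strain/condition.
#' @param mu_wt wild-type batch growth rate (h^-1).
#' @param mu_reduction fractional growth-rate reductions for
#'   (single1, single2, single3, double12, double13, double23); the
#'   double-mutant defaults are the study's reported 40/30/37%, and the
#'   single-mutant defaults solve the additive system (each double equals
#'   the sum of its singles), so growth responses carry no epistasis.
#' @param mu_chemostat shared dilution rate of the chemostat pair (h^-1).
#' @return A list of class `strain_design`.
#' @export
strain_design <- function(focal_tfs,
                          replicates = 3L,
                          mu_wt = 0.6,
                          mu_reduction = c(0.165, 0.235, 0.135, 0.40, 0.30, 0.37),
                          mu_chemostat = 0.21) {
  if (length(focal_tfs) != 3L || anyDuplicated(focal_tfs)) {
    stop("strain_design(): focal_tfs must be three distinct TF ids")
  }
  stopifnot(length(mu_reduction) == 6L, all(mu_reduction >= 0), all(mu_reduction < 1),
            replicates >= 2L, mu_wt > 0, mu_chemostat > 0)
  strains <- tibble(
    strain = c("WT", "dF", "dA", "dI", "FA", "FI", "AI"),
    deleted = list(character(0), focal_tfs[1], focal_tfs[2], focal_tfs[3],
                   focal_tfs[c(1, 2)], focal_tfs[c(1, 3)], focal_tfs[c(2, 3)]),
    mu = mu_wt * c(1, 1 - mu_reduction)
  )
  structure(
    list(strains = strains, focal_tfs = focal_tfs,
         replicates = as.integer(replicates),
         mu_wt = mu_wt, mu_chemostat = mu_chemostat),
    class = "strain_design"
  )
}

#' @export
print.strain_design <- function(x, ...) {
  cat(sprintf("<strain_design> %d strains x %d replicates + chemostat pair (D = %.2f h^-1)\n",
              nrow(x$strains), x$replicates, x$mu_chemostat))
  cat("focal TFs:", paste(x$focal_tfs, collapse = ", "), "\n")
  invisible(x)
}
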