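#' Preprocess a metabolite table and test mutants against the wild type
#'
#' Missing values are imputed as half of the metabolite's minimum observed
#' value; concentrations are divided by per-sample biomass; the generalized
#' log `glog(x) = log2((x + sqrt(x^2 + a^2)) / 2)` stabilizes variance; each
#' mutant strain is compared to the wild type per metabolite with a
#' two-sided equal-variance t test, BH-adjusted over all (metabolite,
#' strain) tests; significant iff FDR < `met_fdr`.
#'
#' @param met a `met_mat`.
#' @param wt wild-type strain name.
#' @param config a [pipeline_config()]; `glog_a = NULL` uses the default
#'   `a` = (minimum positive normalized value) / 10.
#' @return List with `processed` (g-logged metabolites x samples matrix),
#'   `strain_means` (metabolites x strains, on the g-log scale),
#'   `tests` (tibble: metabolite, strain, lfc, p, padj, significant) and
#'   `glog_a` (the constant used).
#' @export
preprocess_metabolites <- function(met, wt = "WT", config = pipeline_config()) {
  stopifnot(inherits(met, "met_mat"))
  v <- met$values
  meta <- met$sample_meta
  if (!wt %in% meta$strain) stop("preprocess_metabolites(): no samples for strain ", wt)
  all_na <- rowSums(!is.na(v)) == 0
  if (any(all_na)) {
    warn(sprintf("metabolite(s) entirely missing dropped: %s",
                 paste(rownames(v)[all_na], collapse = ", ")))
    v <- v[!all_na, , drop = FALSE]
  }
  small <- table(meta$strain) < 2L
  if (any(small)) {
    stop("strain(s) with < 2 replicates: ",
         paste(names(small)[small], collapse = ", "))
  }
  for (i in seq_len(nrow(v))) {
    m <- min(v[i, ], na.rm = TRUE)
    v[i, is.na(v[i, ])] <- m / 2
  }
  v <- sweep(v, 2, met$biomass[colnames(v)], `/`)
  a <- config$glog_a %||% (min(v[v > 0]) / 10)
  g <- glog(v, a)
  strains <- unique(meta$strain)
  strain_means <- vapply(strains, function(s) {
    rowMeans(g[, meta$sample_id[meta$strain == s], drop = FALSE])
  }, numeric(nrow(g)))
  # vapply drops to a plain vector when a single metabolite remains
  strain_means <- matrix(strain_means, nrow = nrow(g),
                         dimnames = list(rownames(g), strains))
  wt_cols <- meta$sample_id[meta$strain == wt]
  tests <- purrr::map(setdiff(strains, wt), function(s) {
    cols <- meta$sample_id[meta$strain == s]
    tt <- student_rows(g[, wt_cols, drop = FALSE], g[, cols, drop = FALSE])
    tibble(metabolite = rownames(g), strain = s,
           lfc = tt$mean_b - tt$mean_a, p = tt$p)
  }) |> bind_rows()
  tests$padj <- stats::p.adjust(tests$p, method = "BH")
  tests$significant <- tests$padj < config$met_fdr
  list(processed = g, strain_means = strain_means, tests = tests, glog_a = a)
}

#' Joint metabolite-gene pathway-impact filter
#'
#' Per pathway, the impact of the hit nodes (significant metabolites and
#' direct KPE genes present in the pathway) is the sum of their relative
#' betweenness centralities divided by the sum over all nodes; when the hit
#' nodes' betweenness is all zero (e.g. leaves of a star), degree centrality
#' is used instead. A (metabolite, gene) pair is retained iff both are hits
#' in a common pathway whose impact exceeds `impact_threshold`.
#'
#' @param sig_metabolites significant metabolite ids.
#' @param direct_kpe_genes direct-target genes in enriched pathways.
#' @param pathways a `pathway_set`.
#' @param config a [pipeline_config()].
#' @return List with `impact` (per-pathway tibble), `pairs` (metabolite,
#'   gene, pathway, impact) and `retained_metabolites`.
#' @export
joint_pathway_filter <- function(sig_metabolites, direct_kpe_genes, pathways,
                                 config = pipeline_config()) {
  stopifnot(inherits(pathways, "pathway_set"))
  if (length(pathways) == 0) stop("joint_pathway_filter(): empty pathway set")
  hits <- c(id_key(sig_metabolites), id_key(direct_kpe_genes))
  impact_rows <- list(); pair_rows <- list()
  for (pid in names(pathways)) {
    nd <- pathways[[pid]]$nodes
    g <- pathway_igraph(pathways[[pid]])
    btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
    hit <- id_key(nd$node) %in% hits
    cent <- btw[nd$node]
    if (any(hit) && sum(cent[hit]) == 0) {
      cent <- igraph::degree(g)[nd$node]
    }
    impact <- if (!any(hit) || sum(cent) == 0) 0 else sum(cent[hit]) / sum(cent)
    impact_rows[[pid]] <- tibble(pathway = pid, n_nodes = nrow(nd),
                                 n_hits = sum(hit), impact = impact)
    if (impact > config$impact_threshold) {
      mets <- nd$node[hit & nd$type == "metabolite"]
      genes <- nd$node[hit & nd$type == "gene"]
      genes <- genes[id_key(genes) %in% id_key(direct_kpe_genes)]
      mets <- mets[id_key(mets) %in% id_key(sig_metabolites)]
      if (length(mets) > 0 && length(genes) > 0) {
        pair_rows[[pid]] <- tidyr::expand_grid(metabolite = mets, gene = genes) |>
          mutate(pathway = pid, impact = impact)
      }
    }
  }
  pairs <- bind_rows(pair_rows)
  if (nrow(pairs) == 0) {
    pairs <- tibble(metabolite = character(), gene = character(),
                    pathway = character(), impact = numeric())
  }
  list(impact = bind_rows(impact_rows), pairs = pairs,
       retained_metabolites = unique(pairs$metabolite))
}

#' Pearson correlation of metabolite levels with TF activities across strains
#'
#' For every (metabolite, TF) pair, the Pearson correlation of the
#' across-strain mean vectors, with a two-sided p-value from
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom. Dual-effect
#' TFs must already be absent from `activities` (they are considered
#' neither for NCA nor for correlation analysis). Zero-variance vectors are
#' skipped with a warning.
#'
#' @param met_means metabolites x strains matrix (e.g. `strain_means` from
#'   [preprocess_metabolites()]).
#' @param activities TFs x strains activity matrix.
#' @param strains optional explicit strain subset; default the shared
#'   strains (must be >= 4).
#' @return Tibble with `metabolite`, `itf`, `r`, `p`, `n`.
#' @export
correlate_metabolite_tf <- function(met_means, activities, strains = NULL) {
  shared <- intersect(colnames(met_means), colnames(activities))
  if (!is.null(strains)) shared <- intersect(strains, shared)
  if (length(shared) < 4L) {
    stop("correlate_metabolite_tf(): fewer than 4 shared strains")
  }
  M <- met_means[, shared, drop = FALSE]
  P <- activities[, shared, drop = FALSE]
  rows <- list()
  for (m in rownames(M)) {
    if (stats::sd(M[m, ]) == 0) {
      warn(sprintf("metabolite %s has zero variance across strains; skipped", m))
      next
    }
    for (tf in rownames(P)) {
      if (stats::sd(P[tf, ]) == 0) {
        warn(sprintf("TF %s has zero activity variance across strains; skipped", tf))
        next
      }
      ct <- stats::cor.test(M[m, ], P[tf, ], method = "pearson")
      rows[[length(rows) + 1L]] <- tibble(
        metabolite = m, itf = tf,
        r = unname(ct$estimate), p = ct$p.value, n = length(shared))
    }
  }
  if (length(rows) == 0) {
    return(tibble(metabolite = character(), itf = character(),
                  r = numeric(), p = numeric(), n = integer()))
  }
  bind_rows(rows)
}

#' Tier metabolite-iTF interactions
#'
#' The distance criterion `subsystem_ok` holds when some pathway contains
#' both the metabolite and at least one gene that is an indirect DEG target
#' AND lies in the iTF's regulon. Tiers, by precedence:
#' `high_confidence` (|r| > `hc_r`, p < `hc_p`, subsystem_ok) >
#' `literature_supported` (listed pair, |r| > `lit_r`, p < `lit_p`) >
#' `screen` (|r| > `screen_r`, p < `screen_p`) > `rejected`. The assignment
#' is a pure function of (r, p, flags).
#'
#' @param correlations result of [correlate_metabolite_tf()].
#' @param pathways a `pathway_set`.
#' @param indirect_genes indirect DEG targets (any mutant).
#' @param network a `regnet` (for iTF regulons).
#' @param literature_pairs optional tibble with `metabolite`, `itf` of
#'   literature-reported interactions.
#' @param config a [pipeline_config()].
#' @return The correlation tibble with `subsystem_ok`, `literature`, `tier`.
#' @export
tier_interactions <- function(correlations, pathways, indirect_genes, network,
                              literature_pairs = NULL,
                              config = pipeline_config()) {
  stopifnot(inherits(pathways, "pathway_set"))
  path_mets <- lapply(pathways, function(p) id_key(p$nodes$node[p$nodes$type == "metabolite"]))
  path_genes <- lapply(pathways, function(p) id_key(p$nodes$node[p$nodes$type == "gene"]))
  ind <- id_key(indirect_genes)
  lit_key <- if (is.null(literature_pairs) || nrow(literature_pairs) == 0) {
    character(0)
  } else {
    paste(id_key(literature_pairs$metabolite), id_key(literature_pairs$itf))
  }
  out <- correlations
  out$subsystem_ok <- purrr::map2_lgl(out$metabolite, out$itf, function(m, tf) {
    reg <- id_key(regulon(network, tf, exclude_dual = TRUE))
    any(vapply(names(path_mets), function(pid) {
      id_key(m) %in% path_mets[[pid]] &&
        any(path_genes[[pid]] %in% intersect(ind, reg))
    }, logical(1)))
  })
  out$literature <- paste(id_key(out$metabolite), id_key(out$itf)) %in% lit_key
  out$tier <- case_when(
    abs(out$r) > config$hc_r & out$p < config$hc_p & out$subsystem_ok ~
      "high_confidence",
    out$literature & abs(out$r) > config$lit_r & out$p < config$lit_p ~
      "literature_supported",
    abs(out$r) > config$screen_r & out$p < config$screen_p ~ "screen",
    TRUE ~ "rejected"
  )
  out
}
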