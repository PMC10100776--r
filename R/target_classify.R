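#' Regulation-specific gene set from the chemostat condition pair
#'
#' Contrasts anaerobic vs aerobic chemostat cultivations of the wild type at
#' equal dilution rate; its DEGs change for reasons other than growth rate
#' and are annotated regulation-specific. Directions refer to anaerobic
#' relative to aerobic.
#'
#' @param counts an `expr_mat` in counts containing both chemostat conditions
#'   (>= 2 replicates each).
#' @param config a [pipeline_config()].
#' @return Tibble with `gene`, `lfc`, `padj`, `direction` for the
#'   regulation-specific DEGs, plus attribute `universe` (genes tested).
#' @export
regulation_specific_set <- function(counts, config = pipeline_config()) {
  stopifnot(inherits(counts, "expr_mat"))
  an <- samples_of(counts, condition = "chemostat_anaerobic")
  ae <- samples_of(counts, condition = "chemostat_aerobic")
  if (length(an) < 2L || length(ae) < 2L) {
    stop("regulation_specific_set(): both chemostat conditions need >= 2 replicates")
  }
  fn <- filter_and_normalize(counts, samples = c(ae, an), min_reads = config$min_reads)
  contrast <- run_contrast(fn$cpm, group_a = ae, group_b = an,
                           pseudocount = config$pseudocount)
  degs <- call_degs(contrast, config)$table
  out <- degs[degs$direction != "none", c("gene", "lfc", "padj", "direction")]
  attr(out, "universe") <- fn$kept
  out
}

#' Classify mutant DEGs into direct / putative-novel-direct / indirect
#'
#' A mutant DEG in the regulation-specific set with binding evidence for a
#' deleted focal TF is a `direct` target; regulation-specific without binding
#' evidence is `putative_novel_direct` (an uncharacterized candidate direct
#' target); a DEG outside the regulation-specific set is a growth-rate or
#' iTF-mediated `indirect` target, flagged `silent_binding` when it carries a
#' binding site that is not regulated under this condition. Identifiers are
#' matched case-insensitively.
#'
#' @param deg_table tibble with `gene` and `direction` (mutant DEGs).
#' @param regspec_genes character vector (or the tibble from
#'   [regulation_specific_set()]).
#' @param binding_evidence named list of binding-evidence gene sets per
#'   focal TF.
#' @param deleted_tfs focal TFs deleted in this mutant.
#' @param config a [pipeline_config()].
#' @return Tibble with `gene`, `direction`, `class`, `silent_binding`.
#' @export
classify_targets <- function(deg_table, regspec_genes, binding_evidence,
                             deleted_tfs, config = pipeline_config()) {
  if (is.data.frame(regspec_genes)) regspec_genes <- regspec_genes$gene
  unknown <- setdiff(deleted_tfs, names(binding_evidence))
  if (length(unknown) > 0) {
    stop("no binding evidence for deleted TF(s): ", paste(unknown, collapse = ", "))
  }
  bound <- unique(unlist(binding_evidence[deleted_tfs], use.names = FALSE))
  in_reg <- deg_table$gene %in_ci% regspec_genes
  in_bind <- deg_table$gene %in_ci% bound
  tibble(
    gene = deg_table$gene,
    direction = deg_table$direction,
    class = case_when(
      in_reg & in_bind ~ "direct",
      in_reg ~ "putative_novel_direct",
      TRUE ~ "indirect"
    ),
    silent_binding = !in_reg & in_bind
  )
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test for the overlap of a query gene set with
#' each pathway, conditioned on the testable universe; BH adjustment over
#' tested pathways. A pathway is significant only when `padj < deg_alpha`
#' AND the overlap reaches `pathway_min_genes` (the >= 9-gene rule).
#'
#' @param query character vector of genes (must lie within the universe).
#' @param gene_sets a `gene_sets` collection.
#' @param universe character vector of testable genes.
#' @param config a [pipeline_config()].
#' @return Tibble with `set_id`, `description`, `set_size`, `overlap`,
#'   `expected`, `p`, `padj`, `significant`.
#' @export
pathway_enrichment <- function(query, gene_sets, universe,
                               config = pipeline_config()) {
  if (length(universe) == 0) stop("pathway_enrichment(): empty universe")
  universe <- unique(universe)
  query <- intersect_ci(unique(query), universe)
  if (length(query) == 0) {
    return(tibble(set_id = character(), description = character(),
                  set_size = integer(), overlap = integer(), expected = numeric(),
                  p = numeric(), padj = numeric(), significant = logical()))
  }
  N <- length(universe)
  n <- length(query)
  desc <- attr(gene_sets, "descriptions") %||%
    stats::setNames(rep("", length(gene_sets)), names(gene_sets))
  rows <- purrr::imap(unclass(gene_sets), function(members, id) {
    inU <- intersect_ci(members, universe)
    K <- length(inU)
    if (K == 0) return(NULL)
    k <- sum(query %in_ci% inU)
    tibble(set_id = id, description = desc[[id]] %||% "",
           set_size = K, overlap = k, expected = n * K / N,
           p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) return(out)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$padj < config$deg_alpha &
    out$overlap >= config$pathway_min_genes
  arrange(out, .data$p)
}

#' Genes of a query belonging to significantly enriched pathways (KPE genes)
#'
#' @param enrichment result of [pathway_enrichment()].
#' @param query the query gene vector used for the enrichment.
#' @param gene_sets the `gene_sets` collection.
#' @return Character vector of KPE genes.
#' @export
kpe_genes <- function(enrichment, query, gene_sets) {
  sig <- enrichment$set_id[enrichment$significant]
  if (length(sig) == 0) return(character(0))
  members <- unique(unlist(unclass(gene_sets)[sig], use.names = FALSE))
  intersect_ci(unique(query), members)
}
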