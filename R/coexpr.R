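#' Map gene lists onto precomputed coexpression module assignments
#'
#' Module construction itself (e.g. WGCNA) is consumed, not computed: the
#' assignment maps each gene to exactly one module color, with a special
#' color (conventionally `grey`) for uncorrelated genes. For each input
#' list, per-color memberships and counts are tallied; colors with fewer
#' than `module_min_genes` members in that list are flagged as suppressed
#' (the 5-gene rule) -- kept in the raw output, excluded from downstream
#' summaries. Genes absent from the assignment are reported as uncovered.
#'
#' @param gene_lists named list of gene id vectors (e.g. direct_up,
#'   direct_down, indirect_up, indirect_down).
#' @param assignment tibble with `gene`, `module`.
#' @param config a [pipeline_config()].
#' @return List with `memberships` (list, module, gene), `counts` (list,
#'   module, n, suppressed) and `uncovered` (named list of unmapped genes).
#' @export
map_genes_to_modules <- function(gene_lists, assignment,
                                 config = pipeline_config()) {
  stopifnot(is.list(gene_lists), !is.null(names(gene_lists)),
            all(c("gene", "module") %in% names(assignment)))
  if (anyDuplicated(id_key(assignment$gene))) {
    stop("map_genes_to_modules(): gene(s) assigned to more than one module")
  }
  memberships <- purrr::imap(gene_lists, function(genes, nm) {
    genes <- unique(genes)
    idx <- match(id_key(genes), id_key(assignment$gene))
    tibble(list = nm, module = assignment$module[idx], gene = genes)
  }) |> bind_rows()
  uncovered <- memberships |>
    filter(is.na(.data$module)) |>
    (\(d) split(d$gene, d$list))()
  covered <- memberships[!is.na(memberships$module), ]
  counts <- covered |>
    count(.data$list, .data$module, name = "n") |>
    mutate(suppressed = .data$n < config$module_min_genes)
  list(memberships = covered, counts = counts, uncovered = uncovered)
}

#' Direct-indirect coordination within coexpression modules
#'
#' For every module color retained (not suppressed) by both a direct list
#' and an indirect list of the same direction, each side's module members
#' are functionally profiled with [pathway_enrichment()]; the output pairs
#' the enriched functions of the two sides per (module, direction).
#'
#' @param mapping result of [map_genes_to_modules()] whose list names
#'   follow the `direct_up` / `indirect_down` convention.
#' @param gene_sets a `gene_sets` collection for the enrichment.
#' @param universe testable gene universe.
#' @param config a [pipeline_config()].
#' @return Tibble with `module`, `direction`, `n_direct`, `n_indirect`,
#'   `direct_function`, `indirect_function` (NA when nothing is enriched).
#' @export
coordination_summary <- function(mapping, gene_sets, universe,
                                 config = pipeline_config()) {
  counts <- mapping$counts
  kept <- counts[!counts$suppressed, ]
  parts <- strsplit(kept$list, "_", fixed = TRUE)
  kept$side <- vapply(parts, `[`, "", 1L)
  kept$direction <- vapply(parts, function(p) paste(p[-1], collapse = "_"), "")
  pairs <- inner_join(
    kept[kept$side == "direct", c("module", "direction", "n")],
    kept[kept$side == "indirect", c("module", "direction", "n")],
    by = c("module", "direction"), suffix = c("_direct", "_indirect")
  )
  if (nrow(pairs) == 0) {
    return(tibble(module = character(), direction = character(),
                  n_direct = integer(), n_indirect = integer(),
                  direct_function = character(), indirect_function = character()))
  }
  members <- mapping$memberships
  enriched_of <- function(list_name, module) {
    genes <- members$gene[members$list == list_name & members$module == module]
    enr <- pathway_enrichment(genes, gene_sets, universe, config)
    sig <- enr$set_id[enr$significant]
    if (length(sig) == 0) NA_character_ else paste(sig, collapse = ";")
  }
  pairs |>
    mutate(
      direct_function = purrr::map2_chr(
        paste0("direct_", .data$direction), .data$module, enriched_of),
      indirect_function = purrr::map2_chr(
        paste0("indirect_", .data$direction), .data$module, enriched_of)
    ) |>
    select("module", "direction", n_direct = "n_direct",
           n_indirect = "n_indirect", "direct_function", "indirect_function")
}
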