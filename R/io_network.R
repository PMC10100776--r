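#' Read / write a signed regulatory network
#'
#' TSV with columns `tf`, `target`, `effect` (activation / repression / dual,
#' matched case-insensitively). At most one edge is kept per (tf, target)
#' pair: exact duplicates are dropped, and a pair listed with conflicting
#' effects is collapsed to a single `dual` edge with a warning. Dual edges are
#' retained but excluded downstream from activity-direction tallies, NCA
#' connectivity, and metabolite correlation.
#'
#' @param path TSV file path (`#` comment lines skipped).
#' @return A tibble of class `regnet` with columns `tf`, `target`, `effect`.
#' @export
read_regulatory_network <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("tf", "target", "effect")
  if (!all(need %in% names(df))) {
    stop("network table must have columns tf, target, effect")
  }
  as_regulatory_network(df[need])
}

#' @rdname read_regulatory_network
#' @param edges data frame with columns `tf`, `target`, `effect`.
#' @export
as_regulatory_network <- function(edges) {
  edges <- as_tibble(edges)
  eff <- tolower(trimws(edges$effect))
  bad <- setdiff(unique(eff), c("activation", "repression", "dual"))
  if (length(bad) > 0) {
    stop("unknown effect token(s): ", paste(bad, collapse = ", "),
         " (expected activation / repression / dual)")
  }
  edges$effect <- eff
  edges <- distinct(edges, .data$tf, .data$target, .data$effect)
  n_eff <- edges |>
    count(.data$tf, .data$target, name = "n_effects") |>
    filter(.data$n_effects > 1L)
  if (nrow(n_eff) > 0) {
    warn(sprintf(
      "%d (tf, target) pair(s) listed with conflicting effects; collapsed to dual",
      nrow(n_eff)))
    edges <- edges |>
      group_by(.data$tf, .data$target) |>
      summarise(effect = if (n() > 1L) "dual" else .data$effect[1], .groups = "drop")
  }
  structure(edges, class = c("regnet", class(tibble())))
}

#' @rdname read_regulatory_network
#' @param network a `regnet`.
#' @export
write_regulatory_network <- function(network, path) {
  readr::write_tsv(as_tibble(network)[c("tf", "target", "effect")], path)
  invisible(path)
}

#' Regulon of a transcription factor
#'
#' @param network a `regnet` edge table.
#' @param tf TF identifier (matched case-insensitively).
#' @param exclude_dual drop dual-effect edges (default keeps them; NCA and
#'   correlation stages drop them).
#' @return Character vector of target gene ids.
#' @export
regulon <- function(network, tf, exclude_dual = FALSE) {
  e <- network[id_key(network$tf) == id_key(tf), ]
  if (exclude_dual) e <- e[e$effect != "dual", ]
  unique(e$target)
}

#' TFs whose only annotated mode is unambiguous (no dual edges)
#' @param network a `regnet`.
#' @return Character vector of TF ids having at least one dual edge.
#' @export
dual_effect_tfs <- function(network) {
  unique(network$tf[network$effect == "dual"])
}
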