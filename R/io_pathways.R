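#' Pathway graphs (genes + metabolites)
#'
#' A pathway set is a named list of undirected graphs whose nodes are typed
#' `gene` or `metabolite`. Graphs may be disconnected. Stored on disk as two
#' TSVs: a node table (`pathway`, `node`, `type`) and an edge table
#' (`pathway`, `from`, `to`); every edge must reference declared nodes.
#'
#' @param nodes tibble with columns `pathway`, `node`, `type`.
#' @param edges tibble with columns `pathway`, `from`, `to`.
#' @return A named list of class `pathway_set`; each element has `id`,
#'   `nodes` (tibble) and `edges` (tibble).
#' @export
pathway_set <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("pathway", "node", "type") %in% names(nodes)),
            all(c("pathway", "from", "to") %in% names(edges)))
  bad_type <- setdiff(unique(nodes$type), c("gene", "metabolite"))
  if (length(bad_type) > 0) {
    stop("unknown node type(s): ", paste(bad_type, collapse = ", "))
  }
  ids <- unique(nodes$pathway)
  out <- lapply(ids, function(pid) {
    nd <- nodes[nodes$pathway == pid, c("node", "type")]
    if (anyDuplicated(nd$node)) stop("duplicate node in pathway ", pid)
    ed <- edges[edges$pathway == pid, c("from", "to")]
    undeclared <- setdiff(c(ed$from, ed$to), nd$node)
    if (length(undeclared) > 0) {
      stop("pathway ", pid, ": edge references undeclared node(s): ",
           paste(undeclared, collapse = ", "))
    }
    list(id = pid, nodes = nd, edges = ed)
  })
  structure(stats::setNames(out, ids), class = "pathway_set")
}

#' @rdname pathway_set
#' @param nodes_path,edges_path TSV file paths.
#' @export
read_pathway_graphs <- function(nodes_path, edges_path) {
  nodes <- readr::read_tsv(nodes_path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  edges <- readr::read_tsv(edges_path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  pathway_set(nodes, edges)
}

#' @rdname pathway_set
#' @param x a `pathway_set` to write.
#' @export
write_pathway_graphs <- function(x, nodes_path, edges_path) {
  stopifnot(inherits(x, "pathway_set"))
  nodes <- bind_rows(lapply(x, function(p) mutate(p$nodes, pathway = p$id, .before = 1)))
  edges <- bind_rows(lapply(x, function(p) {
    if (nrow(p$edges) == 0) return(NULL)
    mutate(p$edges, pathway = p$id, .before = 1)
  }))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(pathway = character(), from = character(), to = character())
  }
  readr::write_tsv(nodes, nodes_path)
  readr::write_tsv(edges, edges_path)
  invisible(c(nodes_path, edges_path))
}

# igraph view of one pathway (undirected, node type kept as vertex attribute)
pathway_igraph <- function(p) {
  g <- igraph::graph_from_data_frame(
    d = p$edges, directed = FALSE,
    vertices = data.frame(name = p$nodes$node, type = p$nodes$type,
                          stringsAsFactors = FALSE)
  )
  g
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("<pathway_set> %d pathways\n", length(x)))
  invisible(x)
}
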