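#' Filter low-count genes and compute counts per million
#'
#' Genes with fewer than `min_reads` total reads across the samples entering
#' the contrast are removed before testing; CPM is counts x 1e6 / column sum
#' (computed after the filter, so every CPM column sums to 1e6).
#'
#' @param counts an `expr_mat` in counts unit.
#' @param samples optional sample ids restricting the contrast; default all.
#' @param min_reads minimum total reads across the selected samples.
#' @return List with `cpm` (an `expr_mat` in CPM) and `kept` (gene ids).
#' @export
filter_and_normalize <- function(counts, samples = NULL, min_reads = 10L) {
  stopifnot(inherits(counts, "expr_mat"))
  if (counts$unit != "counts") stop("filter_and_normalize() expects counts")
  x <- if (is.null(samples)) counts else select_samples(counts, samples)
  zero <- colSums(x$values) == 0
  if (any(zero)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(x$values)[zero], collapse = ", "))
  }
  kept <- rownames(x$values)[rowSums(x$values) >= min_reads]
  v <- x$values[kept, , drop = FALSE]
  cpm <- sweep(v, 2, colSums(v), `/`) * 1e6
  list(cpm = expression_matrix(cpm, "CPM", x$sample_meta), kept = kept)
}

#' Differential-expression contrast between two sample groups
#'
#' Log2 fold change is `log2((mean_b + c) / (mean_a + c))` on CPM with
#' pseudocount `c`; p-values come from a two-sided unequal-variance (Welch) t
#' statistic on `log2(CPM + c)`, BH-adjusted over all tested genes. This
#' simplified test stands in for a full count model; externally computed
#' (lfc, p) tables can be supplied downstream via [as_contrast()].
#'
#' @param expr an `expr_mat` in CPM (or TPM) unit.
#' @param group_a,group_b sample ids of the reference and test group
#'   (>= 2 replicates each).
#' @param pseudocount CPM pseudocount.
#' @return Tibble of class `contrast_result` with columns `gene`, `mean_a`,
#'   `mean_b`, `lfc`, `p`, `padj`.
#' @export
run_contrast <- function(expr, group_a, group_b, pseudocount = 0.5) {
  stopifnot(inherits(expr, "expr_mat"))
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("run_contrast(): each group needs >= 2 replicates")
  }
  miss <- setdiff(c(group_a, group_b), colnames(expr$values))
  if (length(miss) > 0) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  a <- expr$values[, group_a, drop = FALSE]
  b <- expr$values[, group_b, drop = FALSE]
  tt <- welch_rows(log2(a + pseudocount), log2(b + pseudocount))
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  res <- tibble(
    gene = rownames(expr$values),
    mean_a = unname(mean_a),
    mean_b = unname(mean_b),
    lfc = log2((mean_b + pseudocount) / (mean_a + pseudocount)),
    p = tt$p,
    padj = stats::p.adjust(tt$p, method = "BH")
  )
  attr(res, "groups") <- list(a = group_a, b = group_b)
  class(res) <- c("contrast_result", class(res))
  res
}

#' Wrap an externally computed differential-expression table
#'
#' @param df data frame with at least `gene`, `lfc`, `p` (and optionally
#'   `padj`; recomputed by BH when absent).
#' @return A `contrast_result` tibble.
#' @export
as_contrast <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("gene", "lfc", "p") %in% names(df)))
  if (!"padj" %in% names(df)) df$padj <- stats::p.adjust(df$p, method = "BH")
  class(df) <- c("contrast_result", class(df))
  df
}

#' Call differentially expressed genes
#'
#' `up = {padj < deg_alpha and lfc >= deg_lfc_threshold}`, `down` symmetric.
#'
#' @param contrast a `contrast_result`.
#' @param config a [pipeline_config()].
#' @return List with `up`, `down` (gene id vectors) and `table` (the
#'   contrast annotated with `deg` and `direction`).
#' @export
call_degs <- function(contrast, config = pipeline_config()) {
  stopifnot(inherits(contrast, "contrast_result"))
  tab <- mutate(as_tibble(contrast),
                deg = .data$padj < config$deg_alpha &
                  abs(.data$lfc) >= config$deg_lfc_threshold,
                direction = case_when(
                  .data$deg & .data$lfc > 0 ~ "up",
                  .data$deg & .data$lfc < 0 ~ "down",
                  TRUE ~ "none"
                ))
  list(up = tab$gene[tab$direction == "up"],
       down = tab$gene[tab$direction == "down"],
       table = tab)
}
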