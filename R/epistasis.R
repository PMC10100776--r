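#' Double-mutant additivity table
#'
#' Per-gene deviation from additivity of a double deletion:
#' `delta = lfc_double - (lfc_single1 + lfc_single2)` in log2 units.
#' A gene enters the additivity scatter (`in_scatter`) when it is a DEG in
#' the double mutant OR the summed single-mutant fold change reaches the DEG
#' fold cutoff; it is flagged `additive` when |delta| is within
#' `config$additivity_tol` (default 1 log2 unit).
#'
#' @param double_contrast,single1_contrast,single2_contrast
#'   `contrast_result`s over a shared gene universe (restricted to the
#'   intersection with a message when they disagree).
#' @param config a [pipeline_config()].
#' @return Tibble with `gene`, `lfc_double`, `lfc_single1`, `lfc_single2`,
#'   `delta`, `in_scatter`, `additive`.
#' @export
additivity_table <- function(double_contrast, single1_contrast, single2_contrast,
                             config = pipeline_config()) {
  gd <- double_contrast$gene
  g1 <- single1_contrast$gene
  g2 <- single2_contrast$gene
  shared <- intersect(intersect(gd, g1), g2)
  dropped <- length(unique(c(gd, g1, g2))) - length(shared)
  if (dropped > 0) {
    inform(sprintf("gene universes disagree; restricted to %d shared genes (%d dropped)",
                   length(shared), dropped))
  }
  dd <- call_degs(double_contrast, config)$table
  dd <- dd[match(shared, dd$gene), ]
  l1 <- single1_contrast$lfc[match(shared, g1)]
  l2 <- single2_contrast$lfc[match(shared, g2)]
  delta <- dd$lfc - (l1 + l2)
  tibble(
    gene = shared,
    lfc_double = dd$lfc,
    lfc_single1 = l1,
    lfc_single2 = l2,
    delta = delta,
    in_scatter = dd$deg | abs(l1 + l2) >= config$deg_lfc_threshold,
    additive = abs(delta) <= config$additivity_tol
  )
}

#' Attribute double-mutant DEGs to single-regulator effects
#'
#' Each double-mutant DEG with direction `d` is classified: `overlapping`
#' when both singles reach the fold cutoff with sign matching `d`; `TF1`
#' when single 1 is a DEG with matching sign while single 2 stays below the
#' fold cutoff (symmetric for `TF2`); `unassigned` otherwise. The classes
#' partition the double-mutant DEG set exactly.
#'
#' @param double_degs result of [call_degs()] on the double-mutant contrast.
#' @param single1_contrast,single2_contrast single-mutant `contrast_result`s.
#' @param config a [pipeline_config()].
#' @return List with `records` (gene, direction, attribution) and `counts`
#'   (attribution class tallies).
#' @export
attribute_degs <- function(double_degs, single1_contrast, single2_contrast,
                           config = pipeline_config()) {
  tab <- double_degs$table
  degs <- tab[tab$direction != "none", c("gene", "direction")]
  thr <- config$deg_lfc_threshold
  s1 <- call_degs(single1_contrast, config)$table
  s2 <- call_degs(single2_contrast, config)$table
  l1 <- s1$lfc[match(degs$gene, s1$gene)]
  d1 <- s1$deg[match(degs$gene, s1$gene)]
  l2 <- s2$lfc[match(degs$gene, s2$gene)]
  d2 <- s2$deg[match(degs$gene, s2$gene)]
  sgn <- ifelse(degs$direction == "up", 1, -1)
  match1 <- !is.na(l1) & abs(l1) >= thr & sign(l1) == sgn
  match2 <- !is.na(l2) & abs(l2) >= thr & sign(l2) == sgn
  deg1 <- match1 & !is.na(d1) & d1
  deg2 <- match2 & !is.na(d2) & d2
  below1 <- !is.na(l1) & abs(l1) < thr
  below2 <- !is.na(l2) & abs(l2) < thr
  attribution <- case_when(
    match1 & match2 ~ "overlapping",
    deg1 & below2 ~ "TF1",
    deg2 & below1 ~ "TF2",
    TRUE ~ "unassigned"
  )
  records <- tibble(gene = degs$gene, direction = degs$direction,
                    attribution = attribution)
  counts <- records |>
    count(.data$attribution, name = "n") |>
    tidyr::complete(attribution = c("TF1", "TF2", "overlapping", "unassigned"),
                    fill = list(n = 0L))
  list(records = records, counts = counts)
}

#' Two-proportion Z-test with Yates' continuity correction
#'
#' `p_hat = (k1 + k2) / (n1 + n2)`; the numerator is
#' `max(0, |k1/n1 - k2/n2| - (1/n1 + 1/n2) / 2)` and
#' `Z = numerator / sqrt(p_hat (1 - p_hat) (1/n1 + 1/n2))`, with a two-sided
#' p-value from the standard normal. A degenerate pooled proportion (0 or 1)
#' returns Z = 0, p = 1.
#'
#' @param k1,n1,k2,n2 successes and sizes of the two groups.
#' @param alpha significance level for the `significant` flag.
#' @return Tibble with `z`, `p`, `significant`.
#' @export
attribution_significance <- function(k1, n1, k2, n2, alpha = 0.01) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p_hat <- (k1 + k2) / (n1 + n2)
  if (p_hat <= 0 || p_hat >= 1) {
    return(tibble(z = 0, p = 1, significant = FALSE))
  }
  num <- max(0, abs(k1 / n1 - k2 / n2) - 0.5 * (1 / n1 + 1 / n2))
  z <- num / sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  p <- 2 * stats::pnorm(-abs(z))
  tibble(z = z, p = p, significant = p < alpha)
}
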