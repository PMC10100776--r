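#' Additivity scatter of a double deletion
#'
#' Summed single-mutant log2 fold changes against the double-mutant fold
#' change, with the identity line and the additivity band (+/- the
#' tolerance); non-additive genes are highlighted.
#'
#' @param additivity result of [additivity_table()].
#' @param config a [pipeline_config()] (band half-width).
#' @return A ggplot object.
#' @export
plot_additivity <- function(additivity, config = pipeline_config()) {
  df <- filter(additivity, .data$in_scatter)
  tol <- config$additivity_tol
  ggplot(df, aes(x = .data$lfc_single1 + .data$lfc_single2,
                 y = .data$lfc_double, colour = .data$additive)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_abline(slope = 1, intercept = c(-tol, tol), linetype = 3,
                colour = "grey50") +
    geom_point(alpha = 0.6, size = 1) +
    scale_colour_manual(values = c(`TRUE` = "grey30", `FALSE` = "firebrick"),
                        name = "additive") +
    labs(x = "sum of single-mutant log2 fold changes",
         y = "double-mutant log2 fold change") +
    theme_minimal()
}

#' @describeIn fit_nca activity profiles across conditions, one line per TF.
#' @param object an `nca_fit`.
#' @export
autoplot.nca_fit <- function(object, ...) {
  df <- tidy(object)
  df$condition <- factor(df$condition, levels = unique(df$condition))
  ggplot(df, aes(x = .data$condition, y = .data$activity,
                 group = .data$tf, colour = .data$tf)) +
    geom_line() +
    geom_point(size = 1.5) +
    labs(x = NULL, y = "estimated TF activity", colour = "TF") +
    theme_minimal()
}

#' Metabolite-iTF interaction map
#'
#' Tile map of the screened correlations; fill encodes the Pearson r and
#' the border marks the assigned tier.
#'
#' @param interactions result of [tier_interactions()].
#' @param drop_rejected hide rejected pairs.
#' @return A ggplot object.
#' @export
plot_interactions <- function(interactions, drop_rejected = TRUE) {
  df <- interactions
  if (drop_rejected) df <- filter(df, .data$tier != "rejected")
  ggplot(df, aes(x = .data$itf, y = .data$metabolite, fill = .data$r)) +
    geom_tile(aes(colour = .data$tier), linewidth = 0.8) +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         limits = c(-1, 1), name = "Pearson r") +
    scale_colour_manual(values = c(high_confidence = "black",
                                   literature_supported = "darkgreen",
                                   screen = "grey60", rejected = "white"),
                        name = "tier") +
    labs(x = "interacting TF", y = "metabolite") +
    theme_minimal()
}
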