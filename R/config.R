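#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one validated record.
#' Defaults mirror the published procedure: DEGs at BH-adjusted p < 0.05 and
#' |log2 fold change| >= 1 after removing genes with fewer than 10 reads;
#' pathway enrichment significant only with at least 9 genes; interacting-TF
#' (iTF) enrichment requires a regulon of at least 5 genes in the universe;
#' the 70% directionality rule for qualitative TF activity; the tiered
#' metabolite-TF Pearson screen (screen |r| > 0.75 / p < 0.05, high-confidence
#' |r| > 0.9 / p < 0.01, literature-supported |r| > 0.8 / p < 0.05); the joint
#' pathway impact cutoff > 0.1; coexpression modules kept at >= 5 genes;
#' metabolite significance at FDR < 0.05; and the two-proportion Z-test at
#' alpha 0.01.
#'
#' @param deg_lfc_threshold absolute log2 fold-change cutoff for DEG calling.
#' @param deg_alpha BH-adjusted p-value cutoff for DEG calling.
#' @param min_reads minimum total reads across a contrast's samples.
#' @param pathway_min_genes minimum overlap for a pathway to be significant.
#' @param itf_min_regulon minimum regulon size (within the universe) tested.
#' @param activity_consistency consistent-target fraction for a qualitative
#'   activity call (the 70% rule).
#' @param screen_r,screen_p screening-tier correlation thresholds.
#' @param hc_r,hc_p high-confidence-tier correlation thresholds.
#' @param lit_r,lit_p literature-supported-tier correlation thresholds.
#' @param impact_threshold joint pathway impact cutoff.
#' @param module_min_genes minimum genes for a coexpression module to be kept.
#' @param met_fdr metabolite t-test FDR cutoff.
#' @param zt_alpha significance level for the two-proportion Z-test.
#' @param glog_a positive constant of the generalized log transform; `NULL`
#'   defaults to one tenth of the smallest positive value in the table.
#' @param additivity_tol absolute log2 tolerance for calling a double-mutant
#'   gene additive.
#' @param pseudocount CPM pseudocount used for finite log fold changes.
#' @param seed integer master seed; all stochastic stages derive from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(deg_lfc_threshold = 1.0,
                            deg_alpha = 0.05,
                            min_reads = 10L,
                            pathway_min_genes = 9L,
                            itf_min_regulon = 5L,
                            activity_consistency = 0.70,
                            screen_r = 0.75, screen_p = 0.05,
                            hc_r = 0.90, hc_p = 0.01,
                            lit_r = 0.80, lit_p = 0.05,
                            impact_threshold = 0.1,
                            module_min_genes = 5L,
                            met_fdr = 0.05,
                            zt_alpha = 0.01,
                            glog_a = NULL,
                            additivity_tol = 1.0,
                            pseudocount = 0.5,
                            seed = 1L) {
  cfg <- list(
    deg_lfc_threshold = as.numeric(deg_lfc_threshold),
    deg_alpha = as.numeric(deg_alpha),
    min_reads = as.integer(min_reads),
    pathway_min_genes = as.integer(pathway_min_genes),
    itf_min_regulon = as.integer(itf_min_regulon),
    activity_consistency = as.numeric(activity_consistency),
    screen_r = as.numeric(screen_r), screen_p = as.numeric(screen_p),
    hc_r = as.numeric(hc_r), hc_p = as.numeric(hc_p),
    lit_r = as.numeric(lit_r), lit_p = as.numeric(lit_p),
    impact_threshold = as.numeric(impact_threshold),
    module_min_genes = as.integer(module_min_genes),
    met_fdr = as.numeric(met_fdr),
    zt_alpha = as.numeric(zt_alpha),
    glog_a = if (is.null(glog_a)) NULL else as.numeric(glog_a),
    additivity_tol = as.numeric(additivity_tol),
    pseudocount = as.numeric(pseudocount),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1L && x > 0 && x < 1
  stopifnot(
    cfg$deg_lfc_threshold > 0,
    in01(cfg$deg_alpha),
    cfg$min_reads >= 0L,
    cfg$pathway_min_genes >= 1L,
    cfg$itf_min_regulon >= 1L,
    cfg$activity_consistency > 0.5, cfg$activity_consistency <= 1,
    in01(cfg$screen_p), in01(cfg$hc_p), in01(cfg$lit_p), in01(cfg$met_fdr),
    in01(cfg$zt_alpha),
    cfg$screen_r > 0, cfg$screen_r < 1,
    cfg$hc_r > 0, cfg$hc_r < 1,
    cfg$lit_r > 0, cfg$lit_r < 1,
    cfg$impact_threshold >= 0, cfg$impact_threshold < 1,
    cfg$module_min_genes >= 1L,
    is.null(cfg$glog_a) || cfg$glog_a > 0,
    cfg$additivity_tol > 0,
    cfg$pseudocount > 0,
    is.integer(cfg$seed), !is.na(cfg$seed)
  )
  invisible(cfg)
}

#' Write / read a pipeline configuration as a plain `key: value` file
#'
#' @param config a `pipeline_config` object.
#' @param path file path.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  keys <- names(config)
  vals <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.null(v)) "NULL" else format(v, digits = 15)
  }, character(1))
  writeLines(paste0(keys, ": ", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), character(1))
  args <- stats::setNames(as.list(vals), keys)
  defaults <- formals(pipeline_config)
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0) {
    stop("read_config(): unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  args <- lapply(args, function(v) if (identical(v, "NULL")) NULL else as.numeric(v))
  do.call(pipeline_config, args)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-22s %s\n", k, if (is.null(x[[k]])) "NULL" else format(x[[k]])))
  }
  invisible(x)
}
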