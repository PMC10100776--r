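#' Truth-derived functional gene sets for the synthetic panel
#'
#' Emits a pathway-style collection matched to the planted ground truth: the
#' union of the focal regulons (the anaerobiosis program), the growth-rate
#' program, one set per iTF regulon, and unrelated decoy sets drawn from
#' unregulated genes.
#'
#' @param truth completed `synthetic_truth`.
#' @param n_decoys number of decoy sets.
#' @param decoy_size genes per decoy set.
#' @param seed integer seed.
#' @return A `gene_sets` collection.
#' @export
simulate_gene_sets <- function(truth, n_decoys = 3L, decoy_size = 12L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), !is.null(truth$design))
  focal <- truth$design$focal_tfs
  itfs <- setdiff(truth$tfs, focal)
  sets <- list(
    anaerobic_program = unique(unlist(lapply(focal, regulon, network = truth$network),
                                      use.names = FALSE)),
    growth_program = truth$growth_genes
  )
  desc <- c(anaerobic_program = "focal-regulated anaerobiosis response",
            growth_program = "growth-rate-responsive genes")
  for (tf in itfs) {
    id <- paste0("regulon_", tf)
    sets[[id]] <- regulon(truth$network, tf)
    desc[[id]] <- paste("regulon of", tf)
  }
  spare <- setdiff(truth$genes[rowSums(truth$A != 0) == 0], truth$growth_genes)
  set.seed(seed)
  for (k in seq_len(n_decoys)) {
    id <- sprintf("decoy_%02d", k)
    sets[[id]] <- sample(spare, min(decoy_size, length(spare)))
    desc[[id]] <- "unrelated decoy set"
  }
  gene_sets(sets, desc)
}

#' Generate the complete synthetic input bundle
#'
#' One call produces every input the pipeline needs, all derived from
#' `config$seed`: regulatory network, strain design (first three TFs are the
#' focal regulators), expression panel, metabolite panel with pathway
#' graphs, functional gene sets, and a coexpression module assignment.
#'
#' @param config a [pipeline_config()].
#' @return Named list with `counts`, `tpm`, `network`, `binding`,
#'   `gene_sets`, `metabolites`, `pathways`, `modules`, `strain_tfs`,
#'   `design`, `truth`, `couplings`, `literature`.
#' @export
simulate_inputs <- function(config = pipeline_config()) {
  trn <- generate_trn(seed = derive_seed(config$seed, 11L))
  design <- strain_design(trn$truth$tfs[1:3])
  panel <- simulate_strain_panel(trn$truth, design,
                                 seed = derive_seed(config$seed, 12L))
  mets <- simulate_metabolites(panel$truth, design,
                               seed = derive_seed(config$seed, 13L))
  sets <- simulate_gene_sets(panel$truth, seed = derive_seed(config$seed, 14L))
  modules <- simulate_module_assignment(panel$truth)
  list(counts = panel$counts, tpm = panel$tpm, network = trn$network,
       binding = panel$truth$binding, gene_sets = sets,
       metabolites = mets$metabolites, pathways = mets$pathways,
       modules = modules,
       strain_tfs = design$strains[, c("strain", "deleted")],
       design = design, truth = panel$truth, couplings = mets$couplings,
       literature = NULL)
}

# F1 of the "direct" call against planted labels for one mutant
direct_f1 <- function(predicted_direct, truth_direct, universe) {
  pred <- intersect_ci(unique(predicted_direct), universe)
  tru <- intersect_ci(unique(truth_direct), universe)
  tp <- sum(pred %in_ci% tru)
  fp <- length(pred) - tp
  fn <- length(tru) - tp
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (synthetic mode) -> differential expression ->
#' epistasis -> regulation-specific set -> target classification -> pathway
#' enrichment -> iTF enrichment / qualitative activity / NCA / bootstrap ->
#' metabolite screen -> coexpression mapping. Every stage logs to stderr
#' with timing, a failure halts with a stage-named error, and all stage
#' outputs plus a reproducibility manifest are written under `out_dir`.
#' Stage outputs are pure functions of (inputs, config, seed): rerunning
#' with the same seed writes byte-identical files.
#'
#' In real mode pass `inputs` with at least `counts` (an `expr_mat` whose
#' sample metadata marks the chemostat condition pair), `network`,
#' `binding` (named list per focal TF), `gene_sets` and `strain_tfs`
#' (tibble `strain`, `deleted` list-column); `metabolites` + `pathways` and
#' `modules` enable the optional metabolite and coexpression stages.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @param inputs `NULL` for synthetic mode, else the real-data input list.
#' @param n_boot bootstrap replicates for the NCA confidence intervals.
#' @return (Invisibly) a list with every stage's result tables plus
#'   `report` (synthetic mode) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         inputs = NULL, n_boot = 100L) {
  t_all <- proc.time()[["elapsed"]]
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  synthetic <- is.null(inputs)
  if (synthetic) {
    inputs <- run_stage("simulate", function() simulate_inputs(config))
  } else {
    required <- c("counts", "network", "binding", "gene_sets", "strain_tfs")
    missing_f <- required[!vapply(required, function(f) !is.null(inputs[[f]]),
                                  logical(1))]
    if (length(missing_f) > 0) {
      stop("real-mode inputs missing field(s): ",
           paste(missing_f, collapse = ", "))
    }
  }
  counts <- inputs$counts
  network <- inputs$network
  meta <- counts$sample_meta
  strain_tfs <- inputs$strain_tfs
  batch <- meta[meta$condition == "batch", ]
  mutants <- setdiff(unique(batch$strain), "WT")
  wt_samples <- batch$sample_id[batch$strain == "WT"]
  deleted_of <- function(st) strain_tfs$deleted[[match(st, strain_tfs$strain)]]

  ## --- differential expression ---------------------------------------------
  de <- run_stage("de", function() {
    stats::setNames(lapply(mutants, function(st) {
      ms <- batch$sample_id[batch$strain == st]
      fn <- filter_and_normalize(counts, c(wt_samples, ms), config$min_reads)
      contrast <- run_contrast(fn$cpm, wt_samples, ms, config$pseudocount)
      c(list(contrast = contrast, kept = fn$kept), call_degs(contrast, config))
    }), mutants)
  })

  ## --- epistasis of the double deletions -----------------------------------
  epistasis <- run_stage("epistasis", function() {
    doubles <- mutants[vapply(mutants, function(st) length(deleted_of(st)) == 2L,
                              logical(1))]
    out <- lapply(doubles, function(st) {
      del <- deleted_of(st)
      single_of <- function(tf) {
        hit <- mutants[vapply(mutants, function(s) identical(deleted_of(s), tf),
                              logical(1))]
        if (length(hit) != 1L) stop("no single-deletion strain for TF ", tf)
        hit
      }
      s1 <- single_of(del[1]); s2 <- single_of(del[2])
      add <- additivity_table(de[[st]]$contrast, de[[s1]]$contrast,
                              de[[s2]]$contrast, config)
      att <- attribute_degs(de[[st]], de[[s1]]$contrast, de[[s2]]$contrast, config)
      n_deg <- nrow(att$records)
      cnt <- stats::setNames(att$counts$n, att$counts$attribution)
      sig <- if (n_deg > 0) {
        attribution_significance(cnt[["TF1"]], n_deg, cnt[["TF2"]], n_deg,
                                 alpha = config$zt_alpha)
      } else tibble(z = NA_real_, p = NA_real_, significant = NA)
      list(strain = st, singles = c(s1, s2), additivity = add,
           attribution = att, significance = sig)
    })
    stats::setNames(out, doubles)
  })

  ## --- regulation-specific set and classification --------------------------
  regspec <- run_stage("regulation_specific_set",
                       function() regulation_specific_set(counts, config))
  classify <- run_stage("classify", function() {
    stats::setNames(lapply(mutants, function(st) {
      tab <- de[[st]]$table
      classify_targets(tab[tab$direction != "none", c("gene", "direction")],
                       regspec, inputs$binding, deleted_of(st), config)
    }), mutants)
  })

  ## --- pathway enrichment and KPE genes ------------------------------------
  enrich <- run_stage("enrich", function() {
    stats::setNames(lapply(mutants, function(st) {
      cls <- classify[[st]]
      universe <- de[[st]]$kept
      direct <- cls$gene[cls$class %in% c("direct", "putative_novel_direct")]
      indirect <- cls$gene[cls$class == "indirect"]
      e_dir <- pathway_enrichment(direct, inputs$gene_sets, universe, config)
      e_ind <- pathway_enrichment(indirect, inputs$gene_sets, universe, config)
      list(direct = e_dir, indirect = e_ind,
           direct_kpe = kpe_genes(e_dir, direct, inputs$gene_sets),
           indirect_kpe = kpe_genes(e_ind, indirect, inputs$gene_sets))
    }), mutants)
  })
  direct_kpe_union <- unique(unlist(lapply(enrich, `[[`, "direct_kpe"),
                                    use.names = FALSE))
  indirect_union <- unique(unlist(lapply(classify, function(cl)
    cl$gene[cl$class == "indirect"]), use.names = FALSE))

  ## --- iTF enrichment, qualitative activity, NCA + bootstrap ---------------
  activity <- run_stage("activity", function() {
    all_focal <- unique(unlist(strain_tfs$deleted, use.names = FALSE))
    itf_enr <- stats::setNames(lapply(mutants, function(st) {
      cls <- classify[[st]]
      enrich_itfs(cls$gene[cls$class == "indirect"], network, de[[st]]$kept,
                  focal_tfs = all_focal, config = config)
    }), mutants)
    selected <- unique(unlist(lapply(itf_enr, function(e) e$tf[e$significant]),
                              use.names = FALSE))
    selected <- setdiff(selected, dual_effect_tfs(network))
    qualitative <- bind_rows(lapply(mutants, function(st) {
      mutate(infer_activity_directions(selected, de[[st]]$table, network, config),
             strain = st)
    }))
    nca <- NULL; boot <- NULL
    if (length(selected) > 0) {
      fn_all <- filter_and_normalize(counts, batch$sample_id, config$min_reads)
      cpm <- fn_all$cpm$values
      strains_b <- unique(batch$strain)
      Xs <- vapply(strains_b, function(s) {
        rowMeans(log10(cpm[, batch$sample_id[batch$strain == s], drop = FALSE] +
                         config$pseudocount))
      }, numeric(nrow(cpm)))
      dimnames(Xs) <- list(rownames(cpm), strains_b)
      # the A*P model has no intercept: work on per-gene deviations
      Xs <- Xs - rowMeans(Xs)
      nd <- network[network$effect != "dual", ]
      regulators_of <- split(id_key(nd$tf), id_key(nd$target))
      repeat {
        rows <- unique(unlist(lapply(selected, function(tf)
          intersect_ci(regulon(network, tf, exclude_dual = TRUE), rownames(Xs))),
          use.names = FALSE))
        # only genes whose complete annotated regulator set is modeled
        rows <- rows[vapply(rows, function(g)
          all(regulators_of[[id_key(g)]] %in% id_key(selected)), logical(1))]
        A_str <- build_connectivity(network, rows, selected)
        empty <- colnames(A_str)[colSums(A_str != 0) == 0]
        if (length(empty) > 0) {
          warn(sprintf("TF(s) dropped from NCA (no usable targets): %s",
                       paste(empty, collapse = ", ")))
          selected <- setdiff(selected, empty)
          next
        }
        rep_id <- check_nca_identifiability(A_str, n_conditions = ncol(Xs))
        if (rep_id$pass || length(selected) == 0) break
        bad <- rep_id$per_tf$tf[!rep_id$per_tf$reduced_rank_ok]
        if (length(bad) == 0) bad <- utils::tail(selected, 1)
        warn(sprintf("TF(s) dropped from NCA (identifiability): %s",
                     paste(bad, collapse = ", ")))
        selected <- setdiff(selected, bad)
      }
      if (length(selected) > 0) {
        nca <- fit_nca(Xs[rows, , drop = FALSE], A_str, quiet = TRUE)
        boot <- bootstrap_nca(Xs[rows, , drop = FALSE], A_str, n_boot = n_boot,
                              seed = derive_seed(config$seed, 21L))
      }
    }
    reproduced <- if (!is.null(nca)) {
      acts <- tidy(nca)
      reproduce_activities(acts, qualitative, wt = "WT")
    } else tibble()
    list(itf_enrichment = itf_enr, selected = selected,
         qualitative = qualitative, nca = nca, bootstrap = boot,
         reproduced = reproduced)
  })

  ## --- metabolite-TF screen -------------------------------------------------
  metscreen <- if (!is.null(inputs$metabolites) && !is.null(inputs$pathways) &&
                   !is.null(activity$nca)) {
    run_stage("metscreen", function() {
      prep <- preprocess_metabolites(inputs$metabolites, "WT", config)
      sig <- unique(prep$tests$metabolite[prep$tests$significant])
      jf <- joint_pathway_filter(sig, direct_kpe_union, inputs$pathways, config)
      retained <- jf$retained_metabolites
      interactions <- if (length(retained) > 0) {
        cors <- correlate_metabolite_tf(
          prep$strain_means[retained, , drop = FALSE], activity$nca$P)
        tier_interactions(cors, inputs$pathways, indirect_union, network,
                          inputs$literature, config)
      } else {
        tibble(metabolite = character(), itf = character(), r = numeric(),
               p = numeric(), n = integer(), subsystem_ok = logical(),
               literature = logical(), tier = character())
      }
      list(preprocess = prep, filter = jf, interactions = interactions)
    })
  } else NULL

  ## --- coexpression module mapping ------------------------------------------
  coexpr <- if (!is.null(inputs$modules)) {
    run_stage("coexpr", function() {
      pick <- function(side, dir) {
        unique(unlist(lapply(classify, function(cl) {
          keep <- if (side == "direct") {
            cl$class %in% c("direct", "putative_novel_direct")
          } else cl$class == "indirect"
          cl$gene[keep & cl$direction == dir]
        }), use.names = FALSE))
      }
      lists <- list(direct_up = pick("direct", "up"),
                    direct_down = pick("direct", "down"),
                    indirect_up = pick("indirect", "up"),
                    indirect_down = pick("indirect", "down"))
      universe <- unique(unlist(lapply(de, `[[`, "kept"), use.names = FALSE))
      mapping <- map_genes_to_modules(lists, inputs$modules, config)
      list(mapping = mapping,
           coordination = coordination_summary(mapping, inputs$gene_sets,
                                               universe, config))
    })
  } else NULL

  ## --- recovery report (synthetic mode) -------------------------------------
  report <- if (synthetic) {
    run_stage("report", function() {
      truth <- inputs$truth
      rows <- list()
      all_pred_direct <- character(0); all_true_direct <- character(0)
      pooled_universe <- character(0)
      for (st in mutants) {
        cls <- classify[[st]]
        lab <- truth$labels[[st]]
        universe <- de[[st]]$kept
        pred <- cls$gene[cls$class %in% c("direct", "putative_novel_direct")]
        tru <- lab$gene[lab$label == "direct"]
        rows[[length(rows) + 1L]] <- tibble(
          metric = "direct_f1", context = st,
          value = direct_f1(pred, tru, universe))
        rows[[length(rows) + 1L]] <- tibble(
          metric = "n_deg", context = st, value = nrow(cls))
        all_pred_direct <- c(all_pred_direct, paste(st, id_key(pred)))
        all_true_direct <- c(all_true_direct,
                             paste(st, id_key(intersect_ci(tru, universe))))
        pooled_universe <- c(pooled_universe, paste(st, id_key(universe)))
      }
      rows[[length(rows) + 1L]] <- tibble(
        metric = "direct_f1", context = "pooled",
        value = direct_f1(all_pred_direct, all_true_direct, pooled_universe))
      if (!is.null(activity$nca)) {
        for (tf in rownames(activity$nca$P)) {
          if (tf %in% rownames(truth$P)) {
            strains_b <- colnames(activity$nca$P)
            rows[[length(rows) + 1L]] <- tibble(
              metric = "nca_abs_cor", context = tf,
              value = abs(stats::cor(activity$nca$P[tf, strains_b],
                                     truth$P[tf, strains_b])))
          }
        }
      }
      for (st in names(epistasis)) {
        add <- epistasis[[st]]$additivity
        rows[[length(rows) + 1L]] <- tibble(
          metric = "additive_fraction", context = st,
          value = mean(add$additive[add$in_scatter]))
      }
      if (!is.null(metscreen)) {
        ints <- metscreen$interactions
        cpl <- inputs$couplings
        key <- paste(id_key(ints$metabolite), id_key(ints$itf))
        hc <- key[ints$tier == "high_confidence"]
        planted <- paste(id_key(cpl$metabolite), id_key(cpl$itf))
        rows[[length(rows) + 1L]] <- tibble(
          metric = "met_screen_sensitivity", context = "planted",
          value = mean(planted %in% hc))
        rows[[length(rows) + 1L]] <- tibble(
          metric = "met_decoy_hc_pairs", context = "decoys",
          value = sum(!hc %in% planted))
      }
      bind_rows(rows)
    })
  } else NULL

  result <- list(config = config, inputs = inputs, de = de,
                 epistasis = epistasis, regspec = regspec,
                 classify = classify, enrich = enrich, activity = activity,
                 metscreen = metscreen, coexpr = coexpr, report = report)
  if (!is.null(out_dir)) {
    result$manifest <- run_stage("write",
                                 function() write_pipeline_outputs(result, out_dir))
  }
  message(sprintf("[total] %.1fs", proc.time()[["elapsed"]] - t_all))
  invisible(result)
}

# Serialize every stage table under out_dir and return the manifest.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(df, rel) {
    full <- file.path(out_dir, rel)
    dir.create(dirname(full), recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(as_tibble(df), full)
    paths <<- c(paths, rel)
  }
  for (st in names(result$de)) {
    put(result$de[[st]]$table, file.path("de", paste0(st, ".tsv")))
  }
  for (st in names(result$epistasis)) {
    ep <- result$epistasis[[st]]
    put(ep$additivity, file.path("epistasis", paste0(st, "_additivity.tsv")))
    put(ep$attribution$records, file.path("epistasis", paste0(st, "_attribution.tsv")))
  }
  put(result$regspec, "regspec.tsv")
  for (st in names(result$classify)) {
    put(result$classify[[st]], file.path("classify", paste0(st, ".tsv")))
  }
  for (st in names(result$enrich)) {
    put(result$enrich[[st]]$direct, file.path("enrich", paste0(st, "_direct.tsv")))
    put(result$enrich[[st]]$indirect, file.path("enrich", paste0(st, "_indirect.tsv")))
  }
  act <- result$activity
  put(bind_rows(act$itf_enrichment, .id = "strain"), "activity/itf_enrichment.tsv")
  put(act$qualitative, "activity/qualitative.tsv")
  if (!is.null(act$nca)) {
    put(tidy(act$nca), "activity/nca_activities.tsv")
    put(act$bootstrap, "activity/nca_bootstrap.tsv")
    put(act$reproduced, "activity/reproduced.tsv")
  }
  if (!is.null(result$metscreen)) {
    put(result$metscreen$preprocess$tests, "metscreen/tests.tsv")
    put(result$metscreen$filter$impact, "metscreen/pathway_impact.tsv")
    put(result$metscreen$interactions, "metscreen/interactions.tsv")
  }
  if (!is.null(result$coexpr)) {
    put(result$coexpr$mapping$counts, "coexpr/module_counts.tsv")
    put(result$coexpr$coordination, "coexpr/coordination.tsv")
  }
  if (!is.null(result$report)) put(result$report, "report.tsv")
  cfg <- result$config
  cfg_list <- lapply(unclass(cfg), function(v) v %||% "default")
  paths <- sort(paths)
  digests <- unname(tools::md5sum(file.path(out_dir, paths)))
  manifest <- list(
    config = cfg_list,
    seed = cfg$seed,
    outputs = stats::setNames(as.list(digests), paths),
    versions = list(
      package = as.character(utils::packageVersion("regdissect")),
      r = paste(R.version$major, R.version$minor, sep = "."))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
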