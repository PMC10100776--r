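#' Enrichment of interacting TFs (iTFs) on indirect targets
#'
#' One-sided Fisher's exact test (upper hypergeometric tail) on the 2x2
#' table (in indirect set / not) x (in regulon / not), for every TF whose
#' regulon has at least `itf_min_regulon` genes in the universe (the 5-gene
#' rule), BH-adjusted across tested TFs. Deleted focal TFs are excluded from
#' the results: their binding sites among indirect targets are assumed to be
#' overlapping or silent under this condition.
#'
#' @param indirect_genes character vector (subset of `universe`).
#' @param network a `regnet` edge table.
#' @param universe testable gene universe.
#' @param focal_tfs TFs deleted in this strain (suppressed from results).
#' @param config a [pipeline_config()].
#' @return Tibble with `tf`, `regulon_size`, `overlap`, `p`, `padj`,
#'   `significant`.
#' @export
enrich_itfs <- function(indirect_genes, network, universe, focal_tfs = character(0),
                        config = pipeline_config()) {
  universe <- unique(universe)
  indirect_genes <- intersect_ci(unique(indirect_genes), universe)
  N <- length(universe)
  n <- length(indirect_genes)
  tfs <- unique(network$tf)
  rows <- purrr::map(tfs, function(tf) {
    reg <- intersect_ci(regulon(network, tf), universe)
    K <- length(reg)
    if (K < config$itf_min_regulon) return(NULL)
    k <- sum(indirect_genes %in_ci% reg)
    tibble(tf = tf, regulon_size = K, overlap = k,
           p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(tibble(tf = character(), regulon_size = integer(), overlap = integer(),
                  p = numeric(), padj = numeric(), significant = logical()))
  }
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$padj < config$deg_alpha
  out <- out[!id_key(out$tf) %in% id_key(focal_tfs), ]
  arrange(out, .data$p)
}

#' Qualitative TF activity direction (the 70% rule)
#'
#' An observed DEG target is consistent with increased TF activity when
#' (activation edge and target up) or (repression edge and target down) --
#' e.g. a repressor whose targets drop implies the repressor became more
#' active. With consistent fraction `f+`: `f+ >= 0.70` gives `increased`,
#' `f+ <= 0.30` gives `decreased`, anything between is `dual` (excluded from
#' NCA and correlation analysis). Dual-effect edges never enter the tally.
#'
#' @param tf TF identifier.
#' @param deg_table tibble with `gene`, `direction` in `{up, down}`.
#' @param network a `regnet`.
#' @param config a [pipeline_config()].
#' @return Tibble with `tf`, `n_targets`, `f_plus`, `direction`.
#' @export
infer_activity_direction <- function(tf, deg_table, network,
                                     config = pipeline_config()) {
  edges <- network[id_key(network$tf) == id_key(tf) & network$effect != "dual", ]
  degs <- deg_table[deg_table$direction %in% c("up", "down"), ]
  hit <- edges[id_key(edges$target) %in% id_key(degs$gene), ]
  if (nrow(hit) == 0) {
    warn(sprintf("TF %s has no usable DEG targets; excluded", tf))
    return(tibble(tf = tf, n_targets = 0L, f_plus = NA_real_, direction = "excluded"))
  }
  dirs <- degs$direction[match(id_key(hit$target), id_key(degs$gene))]
  consistent <- (hit$effect == "activation" & dirs == "up") |
    (hit$effect == "repression" & dirs == "down")
  f_plus <- mean(consistent)
  cc <- config$activity_consistency
  direction <- if (f_plus >= cc) "increased" else if (f_plus <= 1 - cc) "decreased" else "dual"
  tibble(tf = tf, n_targets = nrow(hit), f_plus = f_plus, direction = direction)
}

#' @rdname infer_activity_direction
#' @param tfs TF identifiers to tally.
#' @export
infer_activity_directions <- function(tfs, deg_table, network,
                                      config = pipeline_config()) {
  bind_rows(lapply(tfs, infer_activity_direction,
                   deg_table = deg_table, network = network, config = config))
}

#' Check NCA identifiability of a connectivity structure
#'
#' The standard criteria: (i) the connectivity pattern has full column rank
#' generically (random magnitudes on the zero pattern); (ii) for each TF l,
#' the pattern with column l removed and rows restricted to genes NOT
#' regulated by l has rank L - 1; (iii) the number of conditions is at least
#' the number of TFs.
#'
#' @param A_structure genes x TFs matrix; nonzero entries define the pattern.
#' @param n_conditions optional condition count for criterion (iii).
#' @return List with `pass`, `pass_structure`, `full_column_rank`,
#'   `conditions_ok`, and `per_tf` (tibble naming failing TFs).
#' @export
check_nca_identifiability <- function(A_structure, n_conditions = NULL) {
  pattern <- A_structure != 0
  if (!any(pattern)) stop("empty connectivity structure")
  L <- ncol(pattern)
  M <- withr::with_seed(20231103L, {
    m <- matrix(0, nrow(pattern), L)
    m[pattern] <- stats::runif(sum(pattern), 0.5, 1.5)
    m
  })
  full_rank <- qr(M)$rank == L
  per_tf <- tibble(
    tf = colnames(pattern) %||% paste0("col", seq_len(L)),
    reduced_rank_ok = vapply(seq_len(L), function(l) {
      if (L == 1L) return(TRUE)
      sub <- M[!pattern[, l], -l, drop = FALSE]
      qr(sub)$rank == L - 1L
    }, logical(1))
  )
  conditions_ok <- if (is.null(n_conditions)) NA else n_conditions >= L
  pass_structure <- full_rank && all(per_tf$reduced_rank_ok)
  list(pass = pass_structure && !isFALSE(conditions_ok),
       pass_structure = pass_structure,
       full_column_rank = full_rank,
       conditions_ok = conditions_ok,
       per_tf = per_tf)
}

#' Fit network component analysis by alternating least squares
#'
#' Minimizes `||X - A P||_F^2` over connectivity `A` (zero pattern fixed to
#' the annotated structure) and TF activities `P`. `A` is initialized on the
#' pattern with edge signs and magnitude 1; each iteration solves `P` by
#' least squares given `A`, then each gene's row of `A` restricted to its
#' TFs, until the relative objective decrease falls below `tol` or
#' `max_iter` iterations. Afterwards each TF is put on a fixed convention:
#' its connectivity column is scaled to unit 2-norm with sign chosen so the
#' majority of entries agree with the annotated edge signs, and its activity
#' row is rescaled inversely.
#'
#' @param X genes x conditions matrix of log10 expression (finite).
#' @param A_structure genes x TFs signed structure (e.g. from
#'   [build_connectivity()]); row names must match `X`.
#' @param tol relative objective-change tolerance.
#' @param max_iter iteration cap.
#' @param ridge ridge fallback for rank-deficient subproblems.
#' @param init optional list(A, P) warm start.
#' @param check_identifiability run [check_nca_identifiability()] first.
#' @param quiet suppress subproblem warnings.
#' @return Object of class `nca_fit`: `A`, `P`, `objective` (per-iteration,
#'   non-increasing), `converged`, `iterations`, `total_ss`.
#' @export
fit_nca <- function(X, A_structure, tol = 1e-6, max_iter = 500L, ridge = 1e-8,
                    init = NULL, check_identifiability = FALSE, quiet = FALSE) {
  stopifnot(is.matrix(X), is.matrix(A_structure), nrow(X) == nrow(A_structure))
  if (any(!is.finite(X))) stop("fit_nca(): non-finite values in X")
  pattern <- A_structure != 0
  if (any(colSums(pattern) == 0)) stop("fit_nca(): TF column(s) with no targets")
  if (check_identifiability) {
    rep <- check_nca_identifiability(A_structure, n_conditions = ncol(X))
    if (!rep$pass) stop("connectivity structure failed the identifiability check")
  }
  L <- ncol(pattern)
  A <- init$A %||% (sign(A_structure) * 1.0)
  A[!pattern] <- 0
  key <- apply(pattern, 1L, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(nrow(X)), key)
  groups <- groups[names(groups) != ""]  # genes with no TF contribute nothing
  P <- init$P
  obj <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- solve_ls(A, X, ridge, quiet = quiet)
    for (idx in groups) {
      tfsel <- which(pattern[idx[1L], ])
      Pt <- P[tfsel, , drop = FALSE]
      coefs <- solve_ls(t(Pt), t(X[idx, , drop = FALSE]), ridge, quiet = quiet)
      A[idx, tfsel] <- t(coefs)
    }
    R <- X - A %*% P
    o <- sum(R * R)
    obj <- c(obj, o)
    if (is.finite(prev) && (prev - o) <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- o
  }
  for (l in seq_len(L)) {
    nrm <- sqrt(sum(A[, l]^2))
    if (nrm == 0) next
    agree <- sum(sign(A[pattern[, l], l]) == sign(A_structure[pattern[, l], l]))
    s <- if (2 * agree < sum(pattern[, l])) -1 else 1
    A[, l] <- A[, l] / nrm * s
    P[l, ] <- P[l, ] * nrm * s
  }
  dimnames(A) <- dimnames(A_structure)
  dimnames(P) <- list(colnames(A_structure), colnames(X))
  structure(
    list(A = A, P = P, objective = obj, converged = converged,
         iterations = length(obj), total_ss = sum(X * X),
         structure = pattern),
    class = "nca_fit"
  )
}

#' @export
print.nca_fit <- function(x, ...) {
  cat(sprintf("<nca_fit> %d genes, %d TFs, %d conditions; %d iterations (%s)\n",
              nrow(x$A), ncol(x$A), ncol(x$P), x$iterations,
              if (x$converged) "converged" else "iteration cap"))
  cat(sprintf("  residual SS %.4g (R^2 = %.4f)\n", tail(x$objective, 1),
              1 - tail(x$objective, 1) / x$total_ss))
  invisible(x)
}

#' @describeIn fit_nca tidy activities: one row per (tf, condition).
#' @param x an `nca_fit`.
#' @param ... unused.
#' @export
tidy.nca_fit <- function(x, ...) {
  as_tibble(x$P, rownames = "tf") |>
    pivot_longer(-"tf", names_to = "condition", values_to = "activity")
}

#' @describeIn fit_nca one-row fit summary.
#' @export
glance.nca_fit <- function(x, ...) {
  tibble(n_genes = nrow(x$A), n_tfs = ncol(x$A), n_conditions = ncol(x$P),
         iterations = x$iterations, converged = x$converged,
         objective = tail(x$objective, 1),
         r_squared = 1 - tail(x$objective, 1) / x$total_ss)
}

#' Signed connectivity structure from an edge table
#'
#' Dual-effect edges are excluded (dual regulators are considered neither
#' for NCA nor for correlation analysis).
#'
#' @param network a `regnet`.
#' @param genes gene universe (rows).
#' @param tfs TF set (columns).
#' @return genes x TFs matrix with +1 activation / -1 repression.
#' @export
build_connectivity <- function(network, genes, tfs) {
  A <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  e <- network[network$effect != "dual" &
                 id_key(network$tf) %in% id_key(tfs) &
                 id_key(network$target) %in% id_key(genes), ]
  gi <- match(id_key(e$target), id_key(genes))
  ti <- match(id_key(e$tf), id_key(tfs))
  A[cbind(gi, ti)] <- ifelse(e$effect == "activation", 1, -1)
  A
}

#' Bootstrap confidence intervals for NCA activities
#'
#' Resamples each TF's target genes with replacement within its regulon,
#' refits the factorization (warm-started from the full-data fit), aligns
#' each replicate to the full-data fit per TF by least-squares sign/scale,
#' and reports percentile intervals. TFs with a single target are excluded
#' with a warning.
#'
#' @param X genes x conditions log10 expression matrix.
#' @param A_structure signed structure matching `X` rows.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed (fixed seed gives identical intervals).
#' @param conf confidence level.
#' @param tol,max_iter,ridge passed to [fit_nca()].
#' @return Tibble with `tf`, `condition`, `estimate`, `lower`, `upper`.
#' @export
bootstrap_nca <- function(X, A_structure, n_boot = 200L, seed = 1L, conf = 0.95,
                          tol = 1e-6, max_iter = 200L, ridge = 1e-8) {
  if (n_boot < 100L) stop("bootstrap_nca(): n_boot must be >= 100")
  fit0 <- fit_nca(X, A_structure, tol = tol, max_iter = 500L, ridge = ridge,
                  quiet = TRUE)
  pattern <- A_structure != 0
  L <- ncol(pattern)
  regs <- lapply(seq_len(L), function(l) which(pattern[, l]))
  small <- lengths(regs) < 2L
  if (any(small)) {
    warn(sprintf("TF(s) with regulon of size 1 excluded from bootstrap: %s",
                 paste(colnames(A_structure)[small], collapse = ", ")))
  }
  keep_tf <- which(!small)
  S <- ncol(X)
  draws <- array(NA_real_, c(L, S, n_boot))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    rows <- unlist(lapply(keep_tf, function(l) {
      sample(regs[[l]], length(regs[[l]]), replace = TRUE)
    }))
    Xb <- X[rows, , drop = FALSE]
    Ab <- A_structure[rows, , drop = FALSE]
    keep_cols <- colSums(Ab != 0) > 0
    fb <- fit_nca(Xb, Ab[, keep_cols, drop = FALSE], tol = tol,
                  max_iter = max_iter, ridge = ridge,
                  init = list(A = fit0$A[rows, keep_cols, drop = FALSE],
                              P = fit0$P[keep_cols, , drop = FALSE]),
                  quiet = TRUE)
    Pb <- matrix(NA_real_, L, S)
    Pb[keep_cols, ] <- fb$P
    for (l in which(keep_cols)) {
      lam <- sum(Pb[l, ] * fit0$P[l, ]) / sum(Pb[l, ]^2)
      Pb[l, ] <- lam * Pb[l, ]
    }
    draws[, , b] <- Pb
  }
  alpha <- (1 - conf) / 2
  out <- purrr::map(keep_tf, function(l) {
    tibble(
      tf = colnames(A_structure)[l],
      condition = colnames(X) %||% paste0("c", seq_len(S)),
      estimate = fit0$P[l, ],
      lower = apply(draws[l, , , drop = FALSE], 2, stats::quantile,
                    probs = alpha, na.rm = TRUE),
      upper = apply(draws[l, , , drop = FALSE], 2, stats::quantile,
                    probs = 1 - alpha, na.rm = TRUE)
    )
  })
  bind_rows(out)
}

#' Compare qualitative activity directions with NCA activity changes
#'
#' A TF's NCA activity change in a mutant reproduces the qualitative (70%
#' rule) call when the sign of `P[tf, mutant] - P[tf, WT]` matches the
#' inferred direction.
#'
#' @param activities tibble `tf`, `condition`, `activity` (e.g.
#'   `tidy(nca_fit)` averaged per strain).
#' @param qualitative tibble `tf`, `strain`, `direction` of 70%-rule calls.
#' @param wt reference condition name.
#' @return Tibble with `tf`, `strain`, `nca_delta`, `direction`,
#'   `reproduced`.
#' @export
reproduce_activities <- function(activities, qualitative, wt = "WT") {
  ref <- activities[activities$condition == wt, c("tf", "activity")]
  names(ref)[2] <- "wt_activity"
  qual <- qualitative[qualitative$direction %in% c("increased", "decreased"), ]
  act <- activities[activities$condition != wt, ]
  names(act)[names(act) == "condition"] <- "strain"
  out <- inner_join(act, qual, by = c("tf", "strain")) |>
    inner_join(ref, by = "tf") |>
    mutate(nca_delta = .data$activity - .data$wt_activity,
           reproduced = (.data$nca_delta > 0) == (.data$direction == "increased"))
  select(out, "tf", "strain", "nca_delta", "direction", "reproduced")
}
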