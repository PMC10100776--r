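# Internal helpers shared across modules.

# Identifiers are case-preserved everywhere but matched case-insensitively
# across tables (mixed-case b-numbers / gene names are common in public
# regulon exports). Every cross-table membership test goes through id_key().
id_key <- function(x) tolower(trimws(as.character(x)))

`%in_ci%` <- function(x, table) id_key(x) %in% id_key(table)

intersect_ci <- function(x, table) x[id_key(x) %in% id_key(table)]

setdiff_ci <- function(x, table) x[!id_key(x) %in% id_key(table)]

# Vectorized Welch (unequal-variance) t-test over matrix rows.
# a, b: numeric matrices (rows = features, columns = replicates).
# Degenerate rows (zero pooled standard error) get p = 1 when the group
# means coincide and p = 0 otherwise.
welch_rows <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), nrow(a) == nrow(b))
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("welch_rows(): need >= 2 replicates per group")
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  if (any(zero)) {
    p[zero] <- ifelse(abs(ma[zero] - mb[zero]) < .Machine$double.eps^0.5, 1, 0)
    tstat[zero] <- ifelse(abs(ma[zero] - mb[zero]) < .Machine$double.eps^0.5, 0, Inf)
    df[zero] <- NA_real_
  }
  tibble(mean_a = ma, mean_b = mb, t = tstat, df = df, p = p)
}

# Equal-variance two-sample t over rows (metabolomics uses the classical
# Student test per the study design).
student_rows <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), nrow(a) == nrow(b))
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("student_rows(): need >= 2 replicates per group")
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (mb - ma) / se
  df <- na + nb - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se == 0
  if (any(zero)) {
    p[zero] <- ifelse(abs(ma[zero] - mb[zero]) < .Machine$double.eps^0.5, 1, 0)
  }
  tibble(mean_a = ma, mean_b = mb, t = tstat, df = df, p = p)
}

# Least-squares solve argmin_Z ||B - M Z||_F with a tiny ridge fallback for
# rank-deficient subproblems.
solve_ls <- function(M, B, ridge = 1e-8, quiet = FALSE) {
  qr_M <- qr(M)
  if (qr_M$rank < ncol(M)) {
    if (!quiet) warn("rank-deficient least-squares subproblem; using ridge fallback")
    MtM <- crossprod(M) + diag(ridge, ncol(M))
    return(solve(MtM, crossprod(M, B)))
  }
  Z <- qr.coef(qr_M, B)
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = if (is.null(dim(B))) 1L else ncol(B))
  Z
}

# Derive a stage seed from a master seed, staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

glog <- function(x, a) log2((x + sqrt(x^2 + a^2)) / 2)
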