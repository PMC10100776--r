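#' Expression matrix container
#'
#' A light container for a genes x samples abundance matrix together with
#' per-sample metadata (strain, replicate, condition). Counts are integer
#' valued; TPM/CPM are non-negative reals.
#'
#' @param values numeric matrix, rows = genes, columns = samples; dimnames set.
#' @param unit one of `"counts"`, `"TPM"`, `"CPM"`, `"log10TPM"`.
#' @param sample_meta tibble with columns `sample_id`, `strain`, `replicate`,
#'   `condition` covering every column of `values`.
#' @return An object of class `expr_mat`.
#' @export
expression_matrix <- function(values, unit, sample_meta) {
  unit <- match.arg(unit, c("counts", "TPM", "CPM", "log10TPM"))
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression_matrix(): values must have gene and sample dimnames")
  }
  sample_meta <- as_tibble(sample_meta)
  obj <- structure(
    list(values = values, unit = unit, sample_meta = sample_meta),
    class = "expr_mat"
  )
  validate_expr_mat(obj)
}

validate_expr_mat <- function(x) {
  v <- x$values
  dup_g <- rownames(v)[duplicated(rownames(v))]
  if (length(dup_g) > 0) {
    stop("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "))
  }
  dup_s <- colnames(v)[duplicated(colnames(v))]
  if (length(dup_s) > 0) {
    stop("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  }
  if (!is.numeric(v)) stop("expression values must be numeric")
  if (any(!is.finite(v))) stop("expression values must be finite")
  if (x$unit != "log10TPM" && any(v < 0)) stop("abundances must be non-negative")
  if (x$unit == "counts" && any(v != round(v))) stop("counts must be integers")
  meta <- x$sample_meta
  need <- c("sample_id", "strain", "replicate", "condition")
  miss_cols <- setdiff(need, names(meta))
  if (length(miss_cols) > 0) {
    stop("sample metadata missing column(s): ", paste(miss_cols, collapse = ", "))
  }
  uncovered <- setdiff(colnames(v), meta$sample_id)
  if (length(uncovered) > 0) {
    stop("sample(s) without metadata: ", paste(uncovered, collapse = ", "))
  }
  bad_cond <- setdiff(unique(meta$condition),
                      c("batch", "chemostat_anaerobic", "chemostat_aerobic"))
  if (length(bad_cond) > 0) {
    stop("unknown condition tag(s): ", paste(bad_cond, collapse = ", "))
  }
  if (anyNA(meta[need])) stop("sample metadata contains missing values")
  x$sample_meta <- meta[match(colnames(v), meta$sample_id), ]
  x
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat("strains:", paste(unique(x$sample_meta$strain), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @describeIn expression_matrix long-format tibble (gene, sample, value plus
#'   sample metadata).
#' @param x an `expr_mat`.
#' @param ... unused.
#' @export
as_tibble.expr_mat <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene") |>
    pivot_longer(-"gene", names_to = "sample_id", values_to = "value")
  left_join(long, x$sample_meta, by = "sample_id")
}

#' Subset an expression matrix by samples
#'
#' @param x an `expr_mat`.
#' @param samples character vector of sample ids to keep (file order kept).
#' @return An `expr_mat` with the selected columns.
#' @export
select_samples <- function(x, samples) {
  stopifnot(inherits(x, "expr_mat"))
  missing <- setdiff(samples, colnames(x$values))
  if (length(missing) > 0) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  }
  expression_matrix(x$values[, samples, drop = FALSE], x$unit,
                    x$sample_meta[x$sample_meta$sample_id %in% samples, ])
}

#' Samples belonging to given strains / conditions
#'
#' @param x an `expr_mat`.
#' @param strain,condition optional filters.
#' @return Character vector of sample ids.
#' @export
samples_of <- function(x, strain = NULL, condition = NULL) {
  meta <- x$sample_meta
  if (!is.null(strain)) meta <- meta[meta$strain %in% strain, ]
  if (!is.null(condition)) meta <- meta[meta$condition %in% condition, ]
  meta$sample_id
}

#' Read / write an expression table
#'
#' Plain TSV with `#`-prefixed header block: a `#unit:` line and one
#' `#meta<TAB>sample<TAB>strain<TAB>replicate<TAB>condition` line per sample,
#' followed by a header row (`gene_id` then sample ids) and one row per gene.
#' Row and column order are preserved; the reader/writer pair is a lossless
#' round trip.
#'
#' @param path file path.
#' @param unit optional unit override; defaults to the embedded `#unit:` line.
#' @return An `expr_mat`.
#' @export
read_expression_table <- function(path, unit = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) < 2L) stop("expression table has no data rows: ", path)
  unit_line <- grep("^#unit:", hdr, value = TRUE)
  if (is.null(unit)) {
    if (length(unit_line) == 0) stop("no #unit: line and no unit supplied: ", path)
    unit <- trimws(sub("^#unit:", "", unit_line[1]))
  }
  meta_lines <- grep("^#meta\t", hdr, value = TRUE)
  if (length(meta_lines) == 0) stop("no #meta lines in expression table: ", path)
  meta_fields <- strsplit(sub("^#meta\t", "", meta_lines), "\t", fixed = TRUE)
  bad <- which(lengths(meta_fields) != 4L)
  if (length(bad) > 0) stop("malformed #meta line(s): ", paste(bad, collapse = ", "))
  meta <- tibble(
    sample_id = vapply(meta_fields, `[[`, character(1), 1L),
    strain = vapply(meta_fields, `[[`, character(1), 2L),
    replicate = as.integer(vapply(meta_fields, `[[`, character(1), 3L)),
    condition = vapply(meta_fields, `[[`, character(1), 4L)
  )
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  if (any(lengths(rows) != length(header))) {
    stop("ragged row(s) in expression table: ", path)
  }
  gene_ids <- vapply(rows, `[[`, character(1), 1L)
  num <- vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    v
  }, numeric(length(sample_ids)))
  vals <- if (is.matrix(num)) t(num) else matrix(num, ncol = length(sample_ids))
  if (anyNA(vals)) {
    bad_rows <- gene_ids[apply(vals, 1, anyNA)]
    stop("non-numeric cell(s) in row(s): ", paste(utils::head(bad_rows, 5), collapse = ", "))
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  expression_matrix(vals, unit, meta)
}

#' @rdname read_expression_table
#' @param x an `expr_mat` to write.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_mat"))
  meta <- x$sample_meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#unit: ", x$unit), con)
  writeLines(sprintf("#meta\t%s\t%s\t%d\t%s",
                     meta$sample_id, meta$strain, meta$replicate, meta$condition), con)
  writeLines(paste(c("gene_id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1, function(v) paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                                               collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(path)
}
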