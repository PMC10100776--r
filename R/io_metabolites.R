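#' Metabolite concentration matrix
#'
#' Metabolites x samples concentrations (micromoles per gram DCW or height
#' ratio per gram DCW), missing values allowed, with per-sample strain /
#' replicate metadata and biomass scaling factors (g DCW).
#'
#' @param values numeric matrix (metabolites x samples), `NA` allowed.
#' @param sample_meta tibble with `sample_id`, `strain`, `replicate`.
#' @param biomass named numeric vector of per-sample g DCW factors.
#' @return An object of class `met_mat`.
#' @export
metabolite_matrix <- function(values, sample_meta, biomass) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate metabolite identifier(s)")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifier(s)")
  if (any(values < 0, na.rm = TRUE)) stop("concentrations must be >= 0 where present")
  sample_meta <- as_tibble(sample_meta)
  need <- c("sample_id", "strain", "replicate")
  if (!all(need %in% names(sample_meta))) {
    stop("metabolite sample metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (length(setdiff(colnames(values), sample_meta$sample_id)) > 0) {
    stop("metabolite sample(s) without metadata")
  }
  if (anyNA(sample_meta[need])) stop("metabolite sample metadata incomplete")
  biomass <- biomass[colnames(values)]
  if (anyNA(biomass) || any(biomass <= 0)) {
    stop("biomass factors must be positive and cover every sample")
  }
  structure(
    list(values = values,
         sample_meta = sample_meta[match(colnames(values), sample_meta$sample_id), ],
         biomass = biomass),
    class = "met_mat"
  )
}

#' @export
print.met_mat <- function(x, ...) {
  cat(sprintf("<met_mat> %d metabolites x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read / write a metabolite table
#'
#' Plain TSV with one `#meta<TAB>sample<TAB>strain<TAB>replicate<TAB>biomass`
#' line per sample, a header row (`metabolite_id` then sample ids), and one
#' row per metabolite. Missing values are encoded as empty cells or `NA`.
#'
#' @param path file path.
#' @return A `met_mat`.
#' @export
read_metabolite_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  meta_lines <- grep("^#meta\t", hdr, value = TRUE)
  if (length(meta_lines) == 0) stop("no #meta lines in metabolite table: ", path)
  mf <- strsplit(sub("^#meta\t", "", meta_lines), "\t", fixed = TRUE)
  if (any(lengths(mf) != 4L)) stop("malformed #meta line in metabolite table")
  meta <- tibble(
    sample_id = vapply(mf, `[[`, character(1), 1L),
    strain = vapply(mf, `[[`, character(1), 2L),
    replicate = as.integer(vapply(mf, `[[`, character(1), 3L))
  )
  biomass <- stats::setNames(as.numeric(vapply(mf, `[[`, character(1), 4L)),
                             meta$sample_id)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  ids <- header[-1]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  met_ids <- vapply(rows, `[[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) {
    cells <- r[-1]
    length(cells) <- length(ids)  # trailing empty cells
    cells[cells %in% c("", "NA")] <- NA_character_
    suppressWarnings(as.numeric(cells))
  }, numeric(length(ids))))
  dimnames(vals) <- list(met_ids, ids)
  metabolite_matrix(vals, meta, biomass)
}

#' @rdname read_metabolite_table
#' @param x a `met_mat` to write.
#' @export
write_metabolite_table <- function(x, path) {
  stopifnot(inherits(x, "met_mat"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- x$sample_meta
  writeLines(sprintf("#meta\t%s\t%s\t%d\t%s", m$sample_id, m$strain, m$replicate,
                     format(x$biomass[m$sample_id], digits = 15, trim = TRUE,
                            scientific = FALSE)), con)
  writeLines(paste(c("metabolite_id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1, function(v) {
    s <- ifelse(is.na(v), "NA",
                format(v, digits = 15, trim = TRUE, scientific = FALSE))
    paste(s, collapse = "\t")
  })
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(path)
}
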