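#' Read / write gene-set collections (GMT dialect)
#'
#' One set per line: `set_id<TAB>description<TAB>member1<TAB>member2...`.
#' Empty lines are skipped; duplicated members within a set are removed with
#' a message; a line with fewer than three fields is an error naming the line.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of class `gene_sets`, with a
#'   `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(line_no[short], collapse = ", "))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate set id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  n_dup <- sum(vapply(members, function(m) sum(duplicated(m)), integer(1)))
  if (n_dup > 0) {
    inform(sprintf("removed %d duplicated member(s) across sets", n_dup))
    members <- lapply(members, unique)
  }
  if (any(lengths(members) == 0)) stop("gene set(s) with no members")
  gene_sets(stats::setNames(members, ids), stats::setNames(desc, ids))
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector of descriptions.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "gene_sets")
}

#' @rdname read_gene_sets
#' @param x a `gene_sets` collection to write.
#' @export
write_gene_sets <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  desc <- attr(x, "descriptions")
  lines <- vapply(names(x), function(id) {
    paste(c(id, desc[[id]], x[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets, %d member entries\n",
              length(x), sum(lengths(x))))
  invisible(x)
}
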