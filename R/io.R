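# Shared readers and writers: TSV matrices (feature ids in the first column,
# sample ids in the header, empty cells = missing), two-column design files,
# GMT gene-set collections. Numeric output uses fixed 10-significant-digit
# formatting so repeated writes are byte-identical.

#' Read a feature x sample matrix from TSV
#'
#' First column holds feature ids, header holds sample ids; empty cells are
#' missing values. Duplicate feature ids, ragged rows and non-numeric cells
#' are rejected.
#'
#' @param path TSV file path.
#' @return numeric matrix with dimnames; NA marks missing cells.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  ncol_exp <- length(hdr)
  body <- fields[-1]
  bad <- which(lengths(body) != ncol_exp)
  if (length(bad)) stop("ragged row(s) at line ", paste(bad + 1, collapse = ", "),
                        " in ", path)
  ids <- vapply(body, `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  cells <- vapply(body, function(r) r[-1], character(ncol_exp - 1L))
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = 1) else t(cells)
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad_cell <- which(is.na(vals) & cells != "" & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad_cell))
    stop("non-numeric cell at row ", bad_cell[1, 1] + 1, ", column ",
         bad_cell[1, 2] + 1, ": '", cells[bad_cell[1, , drop = FALSE]], "'")
  dimnames(vals) <- list(ids, hdr[-1])
  vals
}

#' Write a feature x sample matrix as TSV
#'
#' Inverse of [read_matrix_tsv()]: missing values become empty cells, numbers
#' are written at fixed precision.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_header header of the feature-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_header = "feature") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  hdr <- paste(c(id_header, colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], format_num(mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a two-column sample design TSV
#'
#' @param path TSV with header `sample<TAB>group`.
#' @return named factor of group labels, names = sample ids.
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("design file needs columns sample, group")
  stats::setNames(factor(d[[2]]), d[[1]])
}

#' Write a sample design TSV
#' @param groups named factor/vector (names = sample ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(groups, path) {
  writeLines(c("sample\tgroup",
               paste(names(groups), as.character(groups), sep = "\t")), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member symbols.
#' Members are deduplicated within each set.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop("GMT line ", bad[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicate set name(s): ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, character(1), 2L), nm)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(names(sets), names(sets))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

# generic data.frame writer with fixed numeric formatting
write_table_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- format_num(out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(is.na(out[[j]]), "", ifelse(out[[j]], "TRUE", "FALSE"))
    out[[j]][is.na(out[[j]])] <- ""
  }
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(unname(out), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
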