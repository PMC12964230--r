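#' Read a gene-expression matrix from TSV
#'
#' Expression matrices are stored as UTF-8 tab-separated text: header row
#' `gene_id<TAB>sample1<TAB>...`, one gene per line, `.` decimal separator,
#' no quoting.  Values are expected on a nonnegative log scale (the input
#' convention for NMF factorization).
#'
#' @param path Path to a TSV file.
#' @param impute_row_mean If `TRUE`, missing values are replaced by the row
#'   mean; by default missing values are an error.
#' @return A numeric genes-by-samples matrix with gene IDs as row names and
#'   sample IDs as column names.
#' @export
read_expression_tsv <- function(path, impute_row_mean = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene_id column plus >= 1 sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene IDs in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyDuplicated(colnames(m))) stop("duplicate sample IDs in ", path)
  if (anyNA(m)) {
    if (!impute_row_mean) {
      stop("missing values in ", path,
           " (set impute_row_mean = TRUE to impute)")
    }
    for (i in which(rowSums(is.na(m)) > 0L)) {
      row <- m[i, ]
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      m[i, ] <- row
    }
  }
  m
}

#' Write a gene-expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; `write` then `read` round-trips the
#' matrix, and re-writing the result reproduces the file byte-wise.
#'
#' @param matrix Numeric genes-by-samples matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  stopifnot_matrix(matrix)
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name<TAB>description<TAB>member...`.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene IDs; the `description`
#'   attribute on each element carries the second field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    structure(parts[-(1:2)], description = parts[2L])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (optionally carrying a
#'   `description` attribute; defaults to the set name).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (length(sets) == 0L || is.null(names(sets))) {
    stop("`sets` must be a non-empty named list")
  }
  lines <- vapply(names(sets), function(nm) {
    members <- sets[[nm]]
    desc <- attr(members, "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(members)), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample/cell annotation table from TSV
#'
#' @param path Path to a TSV with a header row.
#' @return A `data.frame` with character columns kept as-is.
#' @export
read_annotation_tsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             quote = "", stringsAsFactors = FALSE)
}

#' Write a table as TSV
#'
#' @param table A `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# JSON sidecar with provenance/parameters next to a data file
write_sidecar <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
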