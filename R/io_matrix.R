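#' Distance/identity matrix text formats
#'
#' Square symmetric matrices (gene-content distances, identity percentages) are
#' written as labelled TSV or relaxed square PHYLIP, entries printed to six
#' decimals. Undefined entries (e.g. identities with no bidirectional pairs)
#' are written as `NA` in TSV; PHYLIP has no missing-value convention, so
#' writing a matrix with `NA` entries in PHYLIP mode is an error.
#'
#' @param m numeric square matrix with identical row/column labels.
#' @param path output (input) file.
#' @return Writers return `path` invisibly; readers return the matrix.
#' @name matrix_io
NULL

check_square_labelled <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop_input("expected a numeric square matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop_input("matrix must carry identical row and column labels")
  invisible(m)
}

#' @rdname matrix_io
#' @export
write_matrix_tsv <- function(m, path) {
  check_square_labelled(m)
  out <- cbind(label = rownames(m), format(round(m, 6), nsmall = 6, trim = TRUE,
                                           scientific = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  check_square_labelled(m)
}

#' @rdname matrix_io
#' @export
write_matrix_phylip <- function(m, path) {
  check_square_labelled(m)
  lab <- rownames(m)
  if (any(grepl("\\s", lab)))
    stop_input("PHYLIP labels may not contain whitespace: %s",
               paste(lab[grepl("\\s", lab)], collapse = ", "))
  if (any(nchar(lab) > 250L))
    stop_input("PHYLIP labels longer than 250 characters")
  if (anyNA(m))
    stop_input("PHYLIP square format cannot represent NA entries")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(lab[i], sprintf("%.6f", m[i, ])), collapse = " "), con)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_matrix_phylip <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE)
  if (length(tok) < 1L) stop_input("empty PHYLIP file: %s", path)
  n <- suppressWarnings(as.integer(tok[1L]))
  if (is.na(n) || n < 1L)
    stop_input("PHYLIP file must start with the taxon count: %s", path)
  if (length(tok) != 1L + n * (n + 1L))
    stop_input("PHYLIP file has %d tokens; expected %d for %d taxa",
               length(tok) - 1L, n * (n + 1L), n)
  body <- matrix(tok[-1L], nrow = n, byrow = TRUE)
  m <- apply(body[, -1L, drop = FALSE], 2L, as.numeric)
  m <- matrix(as.numeric(m), nrow = n)
  dimnames(m) <- list(body[, 1L], body[, 1L])
  check_square_labelled(m)
}
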