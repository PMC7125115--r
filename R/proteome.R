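#' Construct a proteome
#'
#' A proteome is the ordered set of annotated protein-coding gene products of
#' one genome assembly. Sequences are stored uppercase; residues outside the
#' 20-letter alphabet (ambiguity codes such as B, Z, J, U, O or `*`) are mapped
#' to `X` with a warning.
#'
#' @param genome_id single string identifying the genome.
#' @param sequences named character vector or [Biostrings::AAStringSet] of
#'   amino-acid sequences; names are gene ids, unique within the genome.
#' @return An object of class `"proteome"`: a list with elements `genome_id`
#'   and `seq` (a named `AAStringSet`).
#' @examples
#' p <- proteome("G1", c(gA = "MKV", gB = "MAACWY"))
#' gene_count(p)
#' total_residues(p)
#' @export
proteome <- function(genome_id, sequences) {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop_input("genome_id must be a single non-empty string")
  seqs <- if (is(sequences, "AAStringSet")) as.character(sequences) else sequences
  if (length(seqs) == 0L)
    stop_input("proteome '%s' has no records", genome_id)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop_input("all records need non-empty gene ids (genome '%s')", genome_id)
  if (anyDuplicated(ids))
    stop_input("duplicate gene id(s) in genome '%s': %s", genome_id,
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop_input("empty sequence for gene(s) %s in genome '%s'",
               paste(ids[!nzchar(seqs)], collapse = ", "), genome_id)
  seqs <- toupper(seqs)
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), seqs)
  if (any(bad)) {
    warning(sprintf("%d sequence(s) in genome '%s' contain non-standard residues; mapped to X",
                    sum(bad), genome_id), call. = FALSE)
    seqs[bad] <- vapply(seqs[bad], function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      ch[!ch %in% c(AA20, "X")] <- "X"
      paste(ch, collapse = "")
    }, character(1L))
  }
  structure(list(genome_id = genome_id, seq = AAStringSet(seqs)),
            class = "proteome")
}

#' @rdname proteome
#' @param x a `proteome`.
#' @export
gene_count <- function(x) length(x$seq)

#' @rdname proteome
#' @export
total_residues <- function(x) sum(width(x$seq))

#' @rdname proteome
#' @export
gene_ids <- function(x) names(x$seq)

#' @rdname proteome
#' @export
gene_lengths <- function(x) setNames(width(x$seq), names(x$seq))

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome> %s: %d genes, %d residues\n",
              x$genome_id, gene_count(x), total_residues(x)))
  invisible(x)
}

#' Read a proteome from an amino-acid multi-FASTA file
#'
#' Record ids of the form `"<genome>|<gene>..."` are parsed leniently: text
#' before the first `|` is taken as a genome hint and the remainder as the gene
#' id; plain ids are used as-is. Only the first whitespace-delimited token of
#' each header is used.
#'
#' @param path FASTA file (optionally gzipped).
#' @param genome_id genome identifier; if `NULL`, the genome hint from the
#'   record ids (or the file name) is used.
#' @return A [proteome].
#' @export
read_proteome_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0L)
    stop_input("empty FASTA file: %s", path)
  if (!startsWith(trimws(first[nonblank[1L]]), ">"))
    stop_input("malformed FASTA (%s): line %d does not start a '>' record",
               path, nonblank[1L])
  seqs <- readAAStringSet(path)
  if (length(seqs) == 0L) stop_input("no FASTA records in %s", path)
  ids <- sub("\\s.*$", "", names(seqs))
  hint <- NULL
  if (all(grepl("|", ids, fixed = TRUE))) {
    parts <- strsplit(ids, "|", fixed = TRUE)
    nf <- lengths(parts)
    hints <- vapply(parts, `[`, character(1L), 1L)
    if (length(unique(hints)) == 1L) {
      hint <- hints[1L]
      # simulator dialect "<genome>|<gene>|<family>": middle field is the gene
      # id; plain "<genome>|<gene...>": everything after the first "|"
      ids <- if (all(nf == 3L)) vapply(parts, `[`, character(1L), 2L)
             else sub("^[^|]*\\|", "", ids)
    }
  }
  gid <- genome_id %||% hint %||% sub("\\.(fa|faa|fasta)(\\.gz)?$", "", basename(path))
  names(seqs) <- ids
  proteome(gid, seqs)
}

#' Write a proteome to an amino-acid multi-FASTA file
#'
#' @param x a [proteome].
#' @param path output file.
#' @param family_map optional named character vector gene id -> family id; when
#'   supplied, record ids take the simulator dialect
#'   `"<genome>|<gene>|<family>"`, otherwise `"<genome>|<gene>"`.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(x, path, family_map = NULL) {
  stopifnot(inherits(x, "proteome"))
  ids <- paste(x$genome_id, gene_ids(x), sep = "|")
  if (!is.null(family_map))
    ids <- paste(ids, unname(family_map[gene_ids(x)]), sep = "|")
  out <- x$seq
  names(out) <- ids
  writeXStringSet(out, filepath = path)
  invisible(path)
}
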