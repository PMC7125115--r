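#' Alignment scoring parameters
#'
#' Local (Smith--Waterman) protein alignment under a substitution matrix with
#' affine gaps; a gap of length L costs `gap_open + L * gap_extend`. Defaults
#' are the BLAST protein defaults (BLOSUM62, 11/1).
#'
#' @param matrix substitution matrix: the name of a matrix shipped with
#'   Biostrings (e.g. `"BLOSUM62"`, `"BLOSUM50"`) or a numeric matrix.
#' @param gap_open gap opening cost (positive).
#' @param gap_extend per-residue gap extension cost (positive).
#' @return An object of class `"scoring_params"`.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (gap_open < 0 || gap_extend <= 0)
    stop_input("scoring_params: gap penalties must be positive")
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_params")
}

#' Pair-calling filters
#'
#' A hit qualifies when its alignment identity and coverage pass the floors.
#' The optional k-mer prescreen skips gene pairs sharing fewer than
#' `min_shared_kmers` distinct k-mers before any alignment is computed; it is a
#' speed device for high-identity comparisons and must be off when exact
#' equivalence with exhaustive all-vs-all alignment is required.
#'
#' @param min_identity minimum percent identity of a qualifying hit.
#' @param min_coverage minimum aligned span as a fraction of the shorter
#'   protein.
#' @param prescreen logical; enable the k-mer prescreen.
#' @param min_shared_kmers minimum number of distinct shared k-mers.
#' @param kmer_size k-mer length in residues.
#' @return An object of class `"pair_filters"`.
#' @export
pair_filters <- function(min_identity = 30, min_coverage = 0.5,
                         prescreen = FALSE, min_shared_kmers = 3L,
                         kmer_size = 5L) {
  if (min_identity < 0 || min_identity > 100)
    stop_input("pair_filters: min_identity must be in [0, 100]")
  if (min_coverage < 0 || min_coverage > 1)
    stop_input("pair_filters: min_coverage must be in [0, 1]")
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 prescreen = isTRUE(prescreen),
                 min_shared_kmers = as.integer(min_shared_kmers),
                 kmer_size = as.integer(kmer_size)),
            class = "pair_filters")
}

#' Align two protein sequences locally
#'
#' Highest-scoring local alignment under the configured substitution matrix
#' and affine gap penalties. Identity is BLAST-style: matches divided by
#' alignment columns, internal gap columns included in the denominator.
#' Coverage is the aligned span on the shorter sequence divided by the length
#' of the shorter sequence.
#'
#' @param a,b amino-acid strings (or length-1 `AAStringSet`s).
#' @param scoring a [scoring_params] object.
#' @return A list of class `"alignment_result"` with `score`, `identity`
#'   (percent), `coverage`, `columns` and `matches`, or `NULL` when no
#'   positive-scoring local alignment exists.
#' @export
align_pair <- function(a, b, scoring = scoring_params()) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != 1L || length(b) != 1L || !nzchar(a) || !nzchar(b))
    stop_input("align_pair: both sequences must be single non-empty strings")
  res <- align_batch(AAStringSet(c(q = a)), AAString(b), scoring)
  if (res$score[1L] <= 0) return(NULL)
  structure(list(score = res$score[1L], identity = res$identity[1L],
                 coverage = res$coverage[1L], columns = res$columns[1L],
                 matches = res$matches[1L]),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> score %.1f, identity %.1f%% (%d/%d columns), coverage %.2f\n",
              x$score, x$identity, x$matches, x$columns, x$coverage))
  invisible(x)
}

# vectorized local alignment of a set of queries against one subject
align_batch <- function(queries, subject, scoring) {
  aln <- pairwiseAlignment(queries, subject = subject, type = "local",
                           substitutionMatrix = scoring$matrix,
                           gapOpening = scoring$gap_open,
                           gapExtension = scoring$gap_extend)
  span_q <- end(pattern(aln)) - start(pattern(aln)) + 1L
  span_s <- end(subject(aln)) - start(subject(aln)) + 1L
  len_q <- nchar(queries)
  len_s <- nchar(subject)
  shorter_is_q <- len_q <= len_s
  coverage <- ifelse(shorter_is_q, span_q / len_q, span_s / len_s)
  list(score = score(aln), identity = pid(aln, type = "PID1"),
       coverage = coverage, columns = nchar(aln), matches = nmatch(aln))
}
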