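#' Gene-content distance between two genomes
#'
#' The distance is the part of unshared annotated genes:
#' \deqn{d(G_1,G_2) = 1 - \frac{|G_1 \cap G_2|}{\min(|G_1|,|G_2|)},}
#' where \eqn{|G_1 \cap G_2|} is the number of bidirectional gene pairs
#' between the two genomes and \eqn{|G_i|} the number of annotated
#' (protein-coding) genes in genome i. Because bidirectional pairing is a
#' partial matching, the value lies in \[0, 1\].
#'
#' @param cmp a [compare_proteomes()] result.
#' @return A single proportion in \[0, 1\].
#' @examples
#' # arithmetic check with published CDS counts of two draft genomes
#' cmp <- structure(list(n_genes_a = 2309, n_genes_b = 2263,
#'                       n_bidirectional = 1800),
#'                  class = "pairwise_comparison")
#' gene_content_distance(cmp)  # 1 - 1800/2263 = 0.2045957
#' @export
gene_content_distance <- function(cmp) {
  stopifnot(inherits(cmp, "pairwise_comparison"))
  if (cmp$n_genes_a < 1L || cmp$n_genes_b < 1L)
    stop_input("gene_content_distance: both genomes must have at least one gene")
  1 - cmp$n_bidirectional / min(cmp$n_genes_a, cmp$n_genes_b)
}

comparison_index <- function(comparisons) {
  keys <- vapply(comparisons, function(cmp) pair_key(cmp$genome_a, cmp$genome_b),
                 character(1L))
  if (anyDuplicated(keys)) {
    d <- comparisons[[which(duplicated(keys))[1L]]]
    stop_input("duplicate comparison for pair %s / %s", d$genome_a, d$genome_b)
  }
  setNames(comparisons, keys)
}

fill_pair_matrix <- function(comparisons, labels, diag_value, entry_fun) {
  idx <- comparison_index(comparisons)
  if (is.null(labels))
    labels <- sort(unique(unlist(lapply(comparisons, function(cmp)
      c(cmp$genome_a, cmp$genome_b)))))
  n <- length(labels)
  m <- matrix(diag_value, n, n, dimnames = list(labels, labels))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    cmp <- idx[[pair_key(labels[i], labels[j])]]
    if (is.null(cmp))
      stop_input("missing comparison for pair %s / %s", labels[i], labels[j])
    m[i, j] <- m[j, i] <- entry_fun(cmp)
  }
  m
}

#' Assemble the gene-content distance matrix
#'
#' @param comparisons list of [compare_proteomes()] results covering every
#'   unordered genome pair exactly once.
#' @param labels genome ids fixing the matrix order; defaults to the sorted
#'   ids present in `comparisons`.
#' @return Symmetric numeric matrix of Eq.-style gene-content distances with a
#'   zero diagonal.
#' @export
build_distance_matrix <- function(comparisons, labels = NULL) {
  m <- fill_pair_matrix(comparisons, labels, 0, gene_content_distance)
  validate_distance_matrix(m)
  m
}

#' Assemble the mean bidirectional-pair identity matrix
#'
#' Off-diagonal entries are the mean percent identity of the bidirectional
#' gene pairs of each genome pair; pairs with no bidirectional genes are `NA`
#' (undefined), never 0. The diagonal is 100.
#'
#' @inheritParams build_distance_matrix
#' @return Symmetric percent matrix with diagonal 100.
#' @export
identity_matrix <- function(comparisons, labels = NULL) {
  fill_pair_matrix(comparisons, labels, 100, function(cmp) cmp$mean_identity)
}

#' Validate a distance matrix
#'
#' Checks squareness, labels, zero diagonal, symmetry (to 1e-12 relative) and
#' entries within \[0, 1\] for proportion-scale matrices.
#'
#' @param m matrix to validate.
#' @param proportions logical; enforce entries in \[0, 1\].
#' @return `m`, invisibly.
#' @export
validate_distance_matrix <- function(m, proportions = TRUE) {
  check_square_labelled(m)
  if (anyNA(m)) stop_input("distance matrix contains NA entries")
  if (any(abs(diag(m)) > 1e-12)) stop_input("distance matrix diagonal must be zero")
  if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m))))
    stop_input("distance matrix must be symmetric")
  if (proportions && (min(m) < -1e-12 || max(m) > 1 + 1e-12))
    stop_input("gene-content distances must lie in [0, 1]")
  invisible(m)
}
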