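#' Classification parameters
#'
#' The within-species identity threshold sits between the two observed
#' regimes for closely related species pairs (within-species mean identities
#' well above 99 percent, between-species below 89); it is a report parameter,
#' never hard-coded into any computation. The core eligibility threshold is
#' the strict lower bound on the group core-genome percentage for a
#' core-genome phylogeny to be considered meaningful.
#'
#' @param within_identity_threshold percent; genome pairs with mean
#'   bidirectional-pair identity at or above this are linked when clustering.
#' @param core_eligibility_threshold percent; see [core_phylogeny_eligible()].
#' @return An object of class `"classification_params"`.
#' @export
classification_params <- function(within_identity_threshold = 95,
                                  core_eligibility_threshold = 70) {
  if (!(within_identity_threshold > 0 && within_identity_threshold <= 100))
    stop_input("within_identity_threshold must be in (0, 100]")
  if (!(core_eligibility_threshold > 0 && core_eligibility_threshold <= 100))
    stop_input("core_eligibility_threshold must be in (0, 100]")
  structure(list(within_identity_threshold = within_identity_threshold,
                 core_eligibility_threshold = core_eligibility_threshold),
            class = "classification_params")
}

#' Delimit species from the identity matrix
#'
#' Single-linkage clustering: genomes are the nodes of a graph with an edge
#' wherever the mean bidirectional-pair identity is defined and at least the
#' within-species threshold; species clusters are the connected components.
#' Undefined (`NA`) entries never link. Raising the threshold can only refine
#' the partition.
#'
#' @param identities symmetric percent matrix from [identity_matrix()].
#' @param params a [classification_params].
#' @return An object of class `"species_assignment"`: list with `clusters`
#'   (list of genome-id vectors, ordered by first member), `membership`
#'   (named integer vector), `within_identity` (mean identity inside each
#'   cluster, `NA` for singletons), `between_identity` (cluster x cluster mean
#'   identity matrix) and `params`.
#' @export
delimit_species <- function(identities, params = classification_params()) {
  check_square_labelled(identities)
  stopifnot(inherits(params, "classification_params"))
  labels <- rownames(identities)
  off <- identities[upper.tri(identities)]
  if (length(labels) > 1L && all(is.na(off)))
    warning("delimit_species: no defined identity entries; every genome is its own cluster",
            call. = FALSE)
  adj <- !is.na(identities) & identities >= params$within_identity_threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  comp <- setNames(match(comp, unique(comp)), labels)  # number by first member
  clusters <- split(labels, unname(comp))
  names(clusters) <- sprintf("cluster%d", as.integer(names(clusters)))

  within <- vapply(clusters, function(mem) {
    if (length(mem) < 2L) return(NA_real_)
    sub <- identities[mem, mem]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }, numeric(1L))
  k <- length(clusters)
  between <- matrix(NA_real_, k, k, dimnames = list(names(clusters), names(clusters)))
  if (k > 1L) for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    sub <- identities[clusters[[i]], clusters[[j]], drop = FALSE]
    between[i, j] <- between[j, i] <-
      if (all(is.na(sub))) NA_real_ else mean(sub, na.rm = TRUE)
  }
  structure(list(clusters = clusters, membership = comp,
                 within_identity = within, between_identity = between,
                 params = params),
            class = "species_assignment")
}

#' @export
print.species_assignment <- function(x, ...) {
  cat(sprintf("<species assignment> %d cluster(s) at >= %.1f%% identity\n",
              length(x$clusters), x$params$within_identity_threshold))
  for (nm in names(x$clusters)) {
    w <- x$within_identity[[nm]]
    cat(sprintf("  %s (%d): %s%s\n", nm, length(x$clusters[[nm]]),
                paste(x$clusters[[nm]], collapse = ", "),
                if (is.na(w)) "" else sprintf("  [within %.2f%%]", w)))
  }
  invisible(x)
}

#' Is a set of leaves monophyletic on an unrooted tree?
#'
#' `TRUE` when some edge of the unrooted tree bipartitions the leaf set into
#' the cluster versus the rest. Singletons and the full leaf set are trivially
#' monophyletic (pendant edges and the empty complement).
#'
#' @param tree an ape `"phylo"`.
#' @param cluster character vector of leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
check_monophyly <- function(tree, cluster) {
  stopifnot(inherits(tree, "phylo"))
  cluster <- unique(cluster)
  unknown <- setdiff(cluster, tree$tip.label)
  if (length(unknown) > 0L)
    stop_input("check_monophyly: unknown leaf label(s): %s",
               paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  k <- length(cluster)
  if (k == 0L) stop_input("check_monophyly: empty cluster")
  if (k %in% c(1L, n - 1L, n)) return(TRUE)
  want <- sort(match(cluster, tree$tip.label))
  splits <- ape::prop.part(tree)
  for (s in splits) {
    if (identical(sort(s), want)) return(TRUE)
    if (length(s) == n - k && identical(sort(setdiff(seq_len(n), s)), want))
      return(TRUE)
  }
  FALSE
}
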