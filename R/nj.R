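#' Neighbour-joining tree from a distance matrix
#'
#' Classic agglomerative neighbour joining: at each step the pair minimising
#' the rate-corrected criterion
#' \eqn{Q_{ij} = (n-2) d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}} is joined,
#' branch lengths come from the standard two-point formulas, and the matrix is
#' reduced by \eqn{d_{uk} = (d_{ik} + d_{jk} - d_{ij})/2} until three nodes
#' remain, which are connected through an unrooted trifurcation. On additive
#' matrices the input distances are recovered exactly as path lengths.
#'
#' Determinism: ties in Q are broken by the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its smallest leaf). Negative
#' branch lengths are clamped to 0 without transferring length to the sibling
#' edge; each clamping is reported via a message.
#'
#' @param d symmetric numeric distance matrix with >= 2 identical row/column
#'   labels (any non-negative scale; the gene-content matrix need not satisfy
#'   the triangle inequality and is accepted as-is).
#' @return An unrooted ape `"phylo"` tree with branch lengths in the units of
#'   `d`.
#' @export
neighbour_joining <- function(d) {
  check_square_labelled(d)
  validate_distance_matrix(d, proportions = FALSE)
  n <- nrow(d)
  if (n < 2L) stop_input("neighbour_joining: need at least 2 taxa")
  labels <- rownames(d)
  fmt <- function(x) sprintf("%.12g", x)
  clamp <- function(x, what) {
    if (x < 0) {
      message(sprintf("neighbour_joining: negative %s branch length %.3g clamped to 0", what, x))
      0
    } else x
  }
  if (n == 2L) {
    h <- d[1L, 2L] / 2
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);", labels[1L], fmt(h),
                                         labels[2L], fmt(h))))
  }
  nwk <- labels          # growing newick fragment per active cluster
  rep_lab <- labels      # smallest leaf label per cluster, for tie-breaking
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-9 * max(1, abs(qmin))
    cand <- which(Q - qmin <= tol, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij)
      paste(sort(c(rep_lab[ij[1L]], rep_lab[ij[2L]])), collapse = "\r"))
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- clamp(li, "internal"); lj <- clamp(lj, "internal")
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk), c(dk, 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], new_rep)
    D <- D2
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  la <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  lb <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  lc <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  la <- clamp(la, "terminal"); lb <- clamp(lb, "terminal"); lc <- clamp(lc, "terminal")
  ape::read.tree(text = sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1L], fmt(la),
                                nwk[2L], fmt(lb), nwk[3L], fmt(lc)))
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path; all
#' leaf-to-leaf path lengths are preserved. Used as a display convention for
#' otherwise unrooted trees. If every branch length is zero the root is placed
#' deterministically on the first tip's edge with a warning.
#'
#' @param tree an ape `"phylo"` with branch lengths and >= 2 leaves.
#' @return A rooted `"phylo"`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop_input("midpoint_root: tree has no branch lengths")
  if (ape::Ntip(tree) == 2L) {
    h <- sum(tree$edge.length) / 2
    tree$edge.length <- rep(h, length(tree$edge.length))
    return(tree)
  }
  if (all(tree$edge.length == 0)) {
    warning("midpoint_root: all branch lengths are zero; rooting at the first tip's edge",
            call. = FALSE)
    return(ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Serialize a tree to Newick with fixed precision
#'
#' Branch lengths are printed with a fixed number of decimals (default 6).
#' Labels containing Newick metacharacters (whitespace, `():,;'[]`) are quoted
#' per the Newick convention, with embedded single quotes doubled.
#'
#' @param tree an ape `"phylo"`.
#' @param decimals decimal places for branch lengths.
#' @return A single Newick string terminated by `;`.
#' @export
to_newick <- function(tree, decimals = 6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  quote_label <- function(x) {
    if (grepl("[](),:;'[[:space:]\\[]", x))
      paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
    else x
  }
  fmt <- function(len) {
    if (is.null(len) || is.na(len)) "" else sprintf(":%.*f", decimals, len)
  }
  node_str <- function(node) {
    if (node <= ntip) return(quote_label(tree$tip.label[node]))
    e <- kids[[as.character(node)]]
    parts <- vapply(e, function(k)
      paste0(node_str(tree$edge[k, 2L]), fmt(tree$edge.length[k])), character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(node_str(ntip + 1L), ";")
}

#' Parse a Newick string
#'
#' Accepts quoted labels; reports the position of unbalanced parentheses.
#'
#' @param text a Newick string.
#' @return An ape `"phylo"`.
#' @export
from_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # protect quoted labels before structural checks and parsing
  quoted <- regmatches(text, gregexpr("'([^']|'')*'", text))[[1L]]
  masked <- text
  placeholders <- character(0)
  if (length(quoted) > 0L) {
    placeholders <- sprintf("TAXGENQUOTED%03dX", seq_along(quoted))
    for (k in seq_along(quoted))
      masked <- sub(quoted[k], placeholders[k], masked, fixed = TRUE)
  }
  depth <- cumsum(vapply(strsplit(masked, "", fixed = TRUE)[[1L]],
                         function(ch) (ch == "(") - (ch == ")"), numeric(1L)))
  if (any(depth < 0))
    stop_input("from_newick: unbalanced ')' at position %d", which(depth < 0)[1L])
  if (length(depth) && depth[length(depth)] != 0)
    stop_input("from_newick: %d unclosed '(' at end of input", depth[length(depth)])
  tree <- ape::read.tree(text = masked)
  if (is.null(tree)) stop_input("from_newick: could not parse tree")
  if (length(placeholders) > 0L) {
    restore <- function(lab) {
      k <- match(lab, placeholders)
      ifelse(is.na(k), lab,
             gsub("''", "'", substr(quoted[k], 2L, nchar(quoted[k]) - 1L), fixed = TRUE))
    }
    tree$tip.label <- vapply(tree$tip.label, restore, character(1L), USE.NAMES = FALSE)
    if (!is.null(tree$node.label))
      tree$node.label <- vapply(tree$node.label, restore, character(1L), USE.NAMES = FALSE)
  }
  tree
}
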