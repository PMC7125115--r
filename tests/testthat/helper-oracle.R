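# Independent exhaustive Smith-Waterman oracle (Gotoh affine gaps), used to
# check the package's alignment and reciprocal-best-hit calls. Fill is
# vectorized over anti-diagonals; traceback is scalar. A gap of length L costs
# open + L * ext, matching the package's scoring convention.

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

oracle_sw <- function(a, b, submat, open, ext) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  ai <- match(A, rownames(submat)); bj <- match(B, colnames(submat))
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F_ <- matrix(-Inf, n + 1L, m + 1L)
  for (d in 2:(n + m)) {
    i <- max(1L, d - m):min(n, d - 1L)
    j <- d - i
    cells <- cbind(i + 1L, j + 1L)
    Ev <- pmax(H[cbind(i + 1L, j)] - open - ext, E[cbind(i + 1L, j)] - ext)
    Fv <- pmax(H[cbind(i, j + 1L)] - open - ext, F_[cbind(i, j + 1L)] - ext)
    Dv <- H[cbind(i, j)] + submat[cbind(ai[i], bj[j])]
    E[cells] <- Ev
    F_[cells] <- Fv
    H[cells] <- pmax(0, Dv, Ev, Fv)
  }
  best <- which.max(H)
  score <- H[best]
  if (score <= 0)
    return(list(score = 0, identity = NA_real_, coverage = NA_real_,
                columns = 0L, matches = 0L))
  i <- (best - 1L) %% (n + 1L)        # row index - 1 == i
  j <- (best - 1L) %/% (n + 1L)       # col index - 1 == j
  # traceback
  state <- "M"
  cols <- 0L; matches <- 0L
  i_end <- i; j_end <- j
  repeat {
    if (state == "M") {
      v <- H[i + 1L, j + 1L]
      if (v <= 0) break
      diagv <- H[i, j] + submat[ai[i], bj[j]]
      if (isTRUE(all.equal(v, diagv))) {
        cols <- cols + 1L
        if (A[i] == B[j]) matches <- matches + 1L
        i <- i - 1L; j <- j - 1L
      } else if (isTRUE(all.equal(v, E[i + 1L, j + 1L]))) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      cols <- cols + 1L  # gap column consuming b_j
      from_e <- E[i + 1L, j] - ext
      stay <- isTRUE(all.equal(E[i + 1L, j + 1L], from_e))
      j <- j - 1L
      if (!stay) state <- "M"
    } else {
      cols <- cols + 1L  # gap column consuming a_i
      from_f <- F_[i, j + 1L] - ext
      stay <- isTRUE(all.equal(F_[i + 1L, j + 1L], from_f))
      i <- i - 1L
      if (!stay) state <- "M"
    }
  }
  span_a <- i_end - i
  span_b <- j_end - j
  coverage <- if (n <= m) span_a / n else span_b / m
  list(score = score, identity = 100 * matches / cols, coverage = coverage,
       columns = cols, matches = matches)
}

# Score-only variant with rolling anti-diagonal vectors (no traceback);
# same recurrences as oracle_sw, used where only best-hit ranking is needed.
oracle_sw_score <- function(a, b, submat, open, ext) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  Sm <- submat[match(A, rownames(submat)), match(B, colnames(submat)), drop = FALSE]
  # vectors over i = 0..n (R index i+1), holding the previous two diagonals
  Hm1 <- Hm2 <- rep(0, n + 1L)
  Em1 <- Fm1 <- rep(-Inf, n + 1L)
  oe <- open + ext
  best <- 0
  for (d in 2:(n + m)) {
    i <- max(1L, d - m):min(n, d - 1L)
    ii <- i + 1L
    Ecur <- pmax(Hm1[ii] - oe, Em1[ii] - ext)
    Fcur <- pmax(Hm1[ii - 1L] - oe, Fm1[ii - 1L] - ext)
    Dv <- Hm2[ii - 1L] + Sm[(d - i - 1L) * n + i]
    Hcur <- pmax(0, Dv, Ecur, Fcur)
    best <- max(best, max(Hcur))
    Hm2 <- Hm1
    Hm1 <- rep(0, n + 1L); Em1 <- Fm1 <- rep(-Inf, n + 1L)
    Hm1[ii] <- Hcur; Em1[ii] <- Ecur; Fm1[ii] <- Fcur
    # boundary cells H(i,0)=H(0,j)=0 are the default fill
  }
  best
}

# Batched score-only oracle: all (equal-length) queries against one target in
# a single anti-diagonal sweep, states held in (n+1) x Q matrices. Returns the
# vector of local alignment scores.
oracle_sw_score_many <- function(queries, target, submat, open, ext) {
  stopifnot(length(unique(nchar(queries))) == 1L)
  Q <- length(queries)
  B <- strsplit(target, "", fixed = TRUE)[[1L]]
  m <- length(B); bj <- match(B, colnames(submat))
  qs <- strsplit(queries, "", fixed = TRUE)
  n <- length(qs[[1L]])
  # S[i, j, q] as 3D array of substitution scores
  S3 <- vapply(qs, function(A) submat[match(A, rownames(submat)), bj, drop = FALSE],
               matrix(0, n, m))
  oe <- open + ext
  zero <- matrix(0, n + 1L, Q)
  minf <- matrix(-Inf, n + 1L, Q)
  Hm1 <- Hm2 <- zero
  Em1 <- Fm1 <- minf
  Best <- zero
  qoff <- (seq_len(Q) - 1L) * (n * m)
  for (d in 2:(n + m)) {
    i <- max(1L, d - m):min(n, d - 1L)
    ii <- i + 1L
    Scur <- S3[outer((d - i - 1L) * n + i, qoff, "+")]
    Ecur <- pmax(Hm1[ii, , drop = FALSE] - oe, Em1[ii, , drop = FALSE] - ext)
    Fcur <- pmax(Hm1[ii - 1L, , drop = FALSE] - oe, Fm1[ii - 1L, , drop = FALSE] - ext)
    Hcur <- pmax(Hm2[ii - 1L, , drop = FALSE] + Scur, Ecur, Fcur, 0)
    Best[ii, ] <- pmax(Best[ii, , drop = FALSE], Hcur)
    Hm2 <- Hm1
    Hm1 <- zero; Em1 <- minf; Fm1 <- minf
    Hm1[ii, ] <- Hcur; Em1[ii, ] <- Ecur; Fm1[ii, ] <- Fcur
  }
  apply(Best, 2L, max)
}

# Naive all-vs-all reciprocal-best-hit comparison mirroring the package's
# contract: qualifying hits need positive score and must pass the identity and
# coverage floors; best hits break ties by score, then identity, then
# lexicographically smaller target gene id.
oracle_compare <- function(pa, pb, submat, open, ext,
                           min_identity = 30, min_coverage = 0.5) {
  sa <- as.character(pa$seq); sb <- as.character(pb$seq)
  ids_a <- names(sa); ids_b <- names(sb)
  res <- vector("list", length(sa) * length(sb))
  k <- 0L
  for (i in seq_along(sa)) for (j in seq_along(sb)) {
    k <- k + 1L
    o <- oracle_sw(sa[[i]], sb[[j]], submat, open, ext)
    res[[k]] <- data.frame(q = i, t = j, score = o$score,
                           identity = ifelse(is.na(o$identity), 0, o$identity),
                           coverage = ifelse(is.na(o$coverage), 0, o$coverage))
  }
  hits <- do.call(rbind, res)
  hits <- hits[hits$score > 0 & hits$identity >= min_identity &
                 hits$coverage >= min_coverage, ]
  best <- function(h, tid) {
    if (nrow(h) == 0L) return(integer(0))
    ord <- order(h$q, -h$score, -h$identity, tid[h$t], method = "radix")
    h <- h[ord, ]; h <- h[!duplicated(h$q), ]
    setNames(h$t, h$q)
  }
  ab <- best(hits, ids_b)
  ba <- best(data.frame(q = hits$t, t = hits$q, score = hits$score,
                        identity = hits$identity, coverage = hits$coverage),
             ids_a)
  a_idx <- as.integer(names(ab))
  recip <- unname(ba[as.character(ab)])
  bidir_a <- a_idx[!is.na(recip) & recip == a_idx]
  bidir_b <- unname(ab[as.character(bidir_a)])
  key <- paste(hits$q, hits$t)
  idn <- function(qi, ti) hits$identity[match(paste(qi, ti), key)]
  uni_a <- setdiff(a_idx, bidir_a)
  uni_b <- setdiff(as.integer(names(ba)), bidir_b)
  rbind(
    if (length(bidir_a)) data.frame(gene_a = ids_a[bidir_a], gene_b = ids_b[bidir_b],
                                    direction = "bidirectional",
                                    identity = idn(bidir_a, bidir_b)),
    if (length(uni_a)) data.frame(gene_a = ids_a[uni_a],
                                  gene_b = ids_b[unname(ab[as.character(uni_a)])],
                                  direction = "unidirectional_ab",
                                  identity = idn(uni_a, unname(ab[as.character(uni_a)]))),
    if (length(uni_b)) data.frame(gene_a = ids_a[unname(ba[as.character(uni_b)])],
                                  gene_b = ids_b[uni_b],
                                  direction = "unidirectional_ba",
                                  identity = idn(unname(ba[as.character(uni_b)]), uni_b)))
}

# Fast all-vs-all RBH oracle for equal-length genes with the floors at zero:
# hits qualify on positive score alone; ties broken by score, then oracle
# identity, then target gene id; identities of called pairs from the full
# traceback oracle.
oracle_compare_fast <- function(pa, pb, submat, open, ext) {
  sa <- as.character(pa$seq); sb <- as.character(pb$seq)
  ids_a <- names(sa); ids_b <- names(sb)
  S <- vapply(sb, function(tg) oracle_sw_score_many(sa, tg, submat, open, ext),
              numeric(length(sa)))
  idn_cache <- new.env()
  idn <- function(i, j) {
    k <- paste(i, j)
    if (is.null(idn_cache[[k]]))
      idn_cache[[k]] <- oracle_sw(sa[[i]], sb[[j]], submat, open, ext)$identity
    idn_cache[[k]]
  }
  pick <- function(scores, other_ids, row_i, transposed) {
    mx <- max(scores)
    if (mx <= 0) return(NA_integer_)
    cand <- which(scores >= mx - 1e-9)
    if (length(cand) > 1L) {
      ident <- vapply(cand, function(j)
        if (transposed) idn(j, row_i) else idn(row_i, j), numeric(1L))
      cand <- cand[order(-ident, other_ids[cand])]
    }
    cand[1L]
  }
  ab <- vapply(seq_along(sa), function(i) pick(S[i, ], ids_b, i, FALSE), 1L)
  ba <- vapply(seq_along(sb), function(j) pick(S[, j], ids_a, j, TRUE), 1L)
  rows <- list()
  for (i in seq_along(sa)) {
    if (is.na(ab[i])) next
    j <- ab[i]
    dir <- if (!is.na(ba[j]) && ba[j] == i) "bidirectional" else "unidirectional_ab"
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ids_a[i], gene_b = ids_b[j], direction = dir,
      identity = idn(i, j))
  }
  for (j in seq_along(sb)) {
    if (is.na(ba[j])) next
    i <- ba[j]
    if (!is.na(ab[i]) && ab[i] == j) next  # bidirectional, already recorded
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ids_a[i], gene_b = ids_b[j], direction = "unidirectional_ba",
      identity = idn(i, j))
  }
  do.call(rbind, rows)
}

# canonical sortable form of a pair table for set comparisons
pair_table_key <- function(df) {
  df <- df[order(df$gene_a, df$gene_b), c("gene_a", "gene_b", "direction")]
  rownames(df) <- NULL
  df
}
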