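# ---- k-mer prescreen -------------------------------------------------------

# distinct k-mers of one sequence
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# Candidate gene pairs between two proteomes sharing >= min_shared distinct
# k-mers. Returns a 2-column integer matrix (query index, target index).
kmer_candidates <- function(qseqs, tseqs, k, min_shared) {
  kq <- lapply(qseqs, seq_kmers, k = k)
  kt <- lapply(tseqs, seq_kmers, k = k)
  dq <- data.frame(kmer = unlist(kq, use.names = FALSE),
                   g = rep.int(seq_along(kq), lengths(kq)))
  dt <- data.frame(kmer = unlist(kt, use.names = FALSE),
                   g = rep.int(seq_along(kt), lengths(kt)))
  shared <- intersect(dq$kmer, dt$kmer)
  if (length(shared) == 0L) return(matrix(integer(0), ncol = 2L))
  dq <- dq[dq$kmer %in% shared, ]
  dt <- dt[dt$kmer %in% shared, ]
  lq <- split(dq$g, dq$kmer)
  lt <- split(dt$g, dt$kmer)
  lt <- lt[names(lq)]
  pairs_i <- rep(unlist(lq, use.names = FALSE),
                 rep.int(lengths(lt), lengths(lq)))
  pairs_j <- unlist(mapply(function(a, b) rep(b, times = length(a)),
                           lq, lt, SIMPLIFY = FALSE), use.names = FALSE)
  code <- (pairs_i - 1) * length(tseqs) + pairs_j
  cnt <- table(code)
  keep <- as.integer(names(cnt)[cnt >= min_shared])
  cbind(q = (keep - 1L) %/% length(tseqs) + 1L,
        t = (keep - 1L) %% length(tseqs) + 1L)
}

# ---- hit tables ------------------------------------------------------------

# Align all candidate (query, target) index pairs; returns a data.frame of
# qualifying hits (score > 0 and passing identity/coverage floors).
hit_table <- function(query, target, scoring, filters) {
  qs <- query$seq
  ts <- target$seq
  if (filters$prescreen) {
    cand <- kmer_candidates(as.character(qs), as.character(ts),
                            filters$kmer_size, filters$min_shared_kmers)
  } else {
    cand <- cbind(q = rep(seq_along(qs), times = length(ts)),
                  t = rep(seq_along(ts), each = length(qs)))
  }
  if (nrow(cand) == 0L)
    return(data.frame(q = integer(0), t = integer(0), score = numeric(0),
                      identity = numeric(0), coverage = numeric(0)))
  out <- vector("list", length(ts))
  for (j in unique(cand[, "t"])) {
    qi <- cand[cand[, "t"] == j, "q"]
    res <- align_batch(qs[qi], ts[[j]], scoring)
    out[[j]] <- data.frame(q = qi, t = j, score = res$score,
                           identity = res$identity, coverage = res$coverage)
  }
  hits <- do.call(rbind, out)
  hits[hits$score > 0 & hits$identity >= filters$min_identity &
         hits$coverage >= filters$min_coverage, , drop = FALSE]
}

# Best qualifying hit per query row of a hit table. Ties broken by higher
# score, then higher identity, then lexicographically smaller target gene id.
best_of <- function(hits, target_ids) {
  if (nrow(hits) == 0L) return(integer(0))
  ord <- order(hits$q, -hits$score, -hits$identity, target_ids[hits$t],
               method = "radix")
  h <- hits[ord, ]
  h <- h[!duplicated(h$q), ]
  setNames(h$t, h$q)
}

#' Best hits from one proteome into another
#'
#' For every query gene with at least one qualifying hit (passing the identity
#' and coverage floors), the single highest-scoring target gene. Ties are
#' broken by higher score, then higher identity, then lexicographically
#' smaller target gene id.
#'
#' @param query,target [proteome] objects.
#' @param scoring a [scoring_params].
#' @param filters a [pair_filters].
#' @return Named character vector: query gene id -> target gene id. Queries
#'   with no qualifying hit are absent.
#' @export
best_hits <- function(query, target, scoring = scoring_params(),
                      filters = pair_filters()) {
  stopifnot(inherits(query, "proteome"), inherits(target, "proteome"))
  hits <- hit_table(query, target, scoring, filters)
  bh <- best_of(hits, gene_ids(target))
  setNames(gene_ids(target)[bh], gene_ids(query)[as.integer(names(bh))])
}

#' Compare two proteomes: best hits, bidirectional pairs, identities
#'
#' All-vs-all local protein comparison between two genomes. A gene pair is
#' bidirectional (a reciprocal best hit) when each gene is the other's best
#' qualifying hit; remaining best hits are unidirectional. The comparison is
#' symmetric: swapping the inputs yields the same bidirectional set.
#'
#' Two inputs carrying the same genome id are refused unless they are the
#' identical proteome, in which case the self-comparison is performed.
#'
#' @inheritParams best_hits
#' @param g1,g2 [proteome] objects.
#' @return An object of class `"pairwise_comparison"`: a list with
#'   `genome_a`, `genome_b`, `n_genes_a`, `n_genes_b`, `pairs` (data frame:
#'   gene_a, gene_b, genome_a, genome_b, direction, score, identity,
#'   coverage), `n_bidirectional` and `mean_identity` (over bidirectional
#'   pairs; `NA` if none).
#' @export
compare_proteomes <- function(g1, g2, scoring = scoring_params(),
                              filters = pair_filters()) {
  stopifnot(inherits(g1, "proteome"), inherits(g2, "proteome"))
  if (identical(g1$genome_id, g2$genome_id) &&
      !identical(as.character(g1$seq), as.character(g2$seq)))
    stop_input("genome id '%s' collides between two different proteomes; relabel one",
               g1$genome_id)
  ids_a <- gene_ids(g1)
  ids_b <- gene_ids(g2)
  hits_ab <- hit_table(g1, g2, scoring, filters)
  # alignment is symmetric in the two sequences, so reuse a->b for b->a
  hits_ba <- data.frame(q = hits_ab$t, t = hits_ab$q, score = hits_ab$score,
                        identity = hits_ab$identity, coverage = hits_ab$coverage)
  ba <- best_of(hits_ba, ids_a)
  ab <- best_of(hits_ab, ids_b)
  a_idx <- as.integer(names(ab))
  b_idx <- as.integer(names(ba))
  recip <- unname(ba[as.character(ab)])  # best hit of (best hit of a)
  bidir_a <- a_idx[!is.na(recip) & recip == a_idx]
  bidir_b <- unname(ab[as.character(bidir_a)])

  aln_of <- function(qi, ti) {
    m <- match(paste(qi, ti), paste(hits_ab$q, hits_ab$t))
    hits_ab[m, c("score", "identity", "coverage")]
  }
  rows <- list()
  if (length(bidir_a) > 0L) {
    al <- aln_of(bidir_a, bidir_b)
    rows$bi <- data.frame(gene_a = ids_a[bidir_a], gene_b = ids_b[bidir_b],
                          direction = "bidirectional", al)
  }
  uni_a <- setdiff(a_idx, bidir_a)
  if (length(uni_a) > 0L) {
    tb <- unname(ab[as.character(uni_a)])
    al <- aln_of(uni_a, tb)
    rows$ab <- data.frame(gene_a = ids_a[uni_a], gene_b = ids_b[tb],
                          direction = "unidirectional_ab", al)
  }
  uni_b <- setdiff(b_idx, bidir_b)
  if (length(uni_b) > 0L) {
    ta <- unname(ba[as.character(uni_b)])
    al <- aln_of(ta, uni_b)
    rows$ba <- data.frame(gene_a = ids_a[ta], gene_b = ids_b[uni_b],
                          direction = "unidirectional_ba", al)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               direction = character(0), score = numeric(0),
               identity = numeric(0), coverage = numeric(0))
  rownames(pairs) <- NULL
  pairs <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                      genome_a = rep(g1$genome_id, nrow(pairs)),
                      genome_b = rep(g2$genome_id, nrow(pairs)),
                      direction = pairs$direction, score = pairs$score,
                      identity = pairs$identity, coverage = pairs$coverage)
  bi <- pairs$direction == "bidirectional"
  structure(list(genome_a = g1$genome_id, genome_b = g2$genome_id,
                 n_genes_a = gene_count(g1), n_genes_b = gene_count(g2),
                 pairs = pairs, n_bidirectional = sum(bi),
                 mean_identity = if (any(bi)) mean(pairs$identity[bi]) else NA_real_),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("<pairwise_comparison> %s (%d genes) vs %s (%d genes)\n",
              x$genome_a, x$n_genes_a, x$genome_b, x$n_genes_b))
  cat(sprintf("  %d bidirectional pair(s), mean identity %s\n",
              x$n_bidirectional,
              if (is.na(x$mean_identity)) "undefined"
              else sprintf("%.2f%%", x$mean_identity)))
  invisible(x)
}

#' Write gene-pair and summary tables for a comparison
#'
#' @param cmp a [compare_proteomes()] result.
#' @param pair_path output TSV for the per-pair table; `NULL` to skip.
#' @param summary_path output TSV for the one-line summary; `NULL` to skip.
#' @return `cmp`, invisibly.
#' @export
write_pair_table <- function(cmp, pair_path = NULL, summary_path = NULL) {
  stopifnot(inherits(cmp, "pairwise_comparison"))
  if (!is.null(pair_path))
    write.table(cmp$pairs, pair_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path))
    write.table(data.frame(genome_a = cmp$genome_a, genome_b = cmp$genome_b,
                           n_genes_a = cmp$n_genes_a, n_genes_b = cmp$n_genes_b,
                           n_bidirectional = cmp$n_bidirectional,
                           mean_identity = cmp$mean_identity),
                summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cmp)
}
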