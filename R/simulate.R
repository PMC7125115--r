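#' Simulation parameters for the pangenome generator
#'
#' Defines the planted study conditions: groups of strains that share all core
#' gene families within a group, carry strain-private accessory genes, and
#' diverge to planted pairwise protein identities (star divergence from a group
#' ancestor, groups diverged from a common root). A configurable fraction of
#' core families is universal, i.e. shared across groups at the between-group
#' identity; the rest are group-private, so between-group gene sharing is
#' roughly `shared_core_fraction * core_length_fraction`.
#'
#' Defaults emulate the within/between regime observed for closely related
#' lactic-acid-bacterium species pairs: within-species identity above 99%,
#' between-species identity in the mid-80s, within-group core length fraction
#' near 0.78 and between-group gene sharing near 0.14.
#'
#' @param n_groups number of groups (planted species), 1--26.
#' @param genomes_per_group genomes (strains) per group.
#' @param core_genes core gene families per group.
#' @param accessory_genes_per_genome strain-private accessory genes per genome.
#' @param mean_gene_length mean protein length in residues (shifted geometric,
#'   minimum 50).
#' @param within_identity planted pairwise protein identity within a group, in
#'   percent (0, 100].
#' @param between_identity planted identity between groups for universal
#'   families, percent; must not exceed `within_identity`.
#' @param core_length_fraction planted share of each genome's residues that
#'   belongs to core families, in (0, 1].
#' @param shared_core_fraction fraction of core families shared across all
#'   groups, in \[0, 1\].
#' @param seed integer seed driving all randomness.
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(n_groups = 2, genomes_per_group = 4, core_genes = 250,
                       accessory_genes_per_genome = 70, mean_gene_length = 300,
                       within_identity = 99.5, between_identity = 85,
                       core_length_fraction = 0.78, shared_core_fraction = 0.18,
                       seed = 1L) {
  p <- list(n_groups = as.integer(n_groups),
            genomes_per_group = as.integer(genomes_per_group),
            core_genes = as.integer(core_genes),
            accessory_genes_per_genome = as.integer(accessory_genes_per_genome),
            mean_gene_length = as.numeric(mean_gene_length),
            within_identity = as.numeric(within_identity),
            between_identity = as.numeric(between_identity),
            core_length_fraction = as.numeric(core_length_fraction),
            shared_core_fraction = as.numeric(shared_core_fraction),
            seed = as.integer(seed))
  for (f in c("n_groups", "genomes_per_group", "core_genes"))
    if (is.na(p[[f]]) || p[[f]] < 1L)
      stop_input("sim_params: %s must be a count >= 1", f)
  if (p$n_groups > 26L) stop_input("sim_params: n_groups must be <= 26")
  if (is.na(p$accessory_genes_per_genome) || p$accessory_genes_per_genome < 0L)
    stop_input("sim_params: accessory_genes_per_genome must be >= 0")
  if (p$mean_gene_length < 50)
    stop_input("sim_params: mean_gene_length must be >= 50 residues")
  if (!(p$within_identity > 0 && p$within_identity <= 100))
    stop_input("sim_params: within_identity must be in (0, 100]")
  if (!(p$between_identity > 0 && p$between_identity <= p$within_identity))
    stop_input("sim_params: need 0 < between_identity <= within_identity")
  # f(s) = s^2 + (1-s)^2/19 has minimum 0.05, so pairwise identity below 5%
  # is unreachable under the uniform-substitution star model
  if (p$within_identity <= 5 || p$between_identity <= 5.5)
    stop_input("sim_params: planted identities must exceed ~5%% (uniform-substitution floor)")
  if (!(p$core_length_fraction > 0 && p$core_length_fraction <= 1))
    stop_input("sim_params: core_length_fraction must be in (0, 1]")
  if (p$shared_core_fraction < 0 || p$shared_core_fraction > 1)
    stop_input("sim_params: shared_core_fraction must be in [0, 1]")
  if (p$core_length_fraction < 1 && p$accessory_genes_per_genome > 0) {
    implied <- p$core_genes * p$mean_gene_length *
      (1 / p$core_length_fraction - 1) / p$accessory_genes_per_genome
    if (implied < 50)
      stop_input(paste0("sim_params: core_length_fraction %.2f with %d accessory genes ",
                        "implies mean accessory length %.0f < 50 residues; ",
                        "reduce accessory_genes_per_genome"),
                 p$core_length_fraction, p$accessory_genes_per_genome, implied)
  }
  if (p$core_length_fraction < 1 && p$accessory_genes_per_genome == 0L)
    stop_input("sim_params: core_length_fraction < 1 requires accessory genes")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("<sim_params> %d group(s) x %d genomes; %d core families ",
                     "(%.0f%% shared across groups), %d accessory/genome\n",
                     "  identity within %.2f%% / between %.2f%%; ",
                     "core length fraction %.2f; mean gene length %.0f; seed %d\n"),
              x$n_groups, x$genomes_per_group, x$core_genes,
              100 * x$shared_core_fraction, x$accessory_genes_per_genome,
              x$within_identity, x$between_identity, x$core_length_fraction,
              x$mean_gene_length, x$seed))
  invisible(x)
}

# Probability that the two ends of a path of edges with per-site retention
# probabilities `retentions` carry the same residue, under substitution to a
# uniformly chosen different residue (symmetric doubly stochastic kernel).
path_match_prob <- function(retentions) {
  q <- 1
  for (s in retentions) q <- q * s + (1 - q) * (1 - s) / 19
  q
}

# Per-site retention s such that two sequences independently diverged from a
# common ancestor match at a fraction w of sites: s^2 + (1-s)^2/19 = w.
solve_within_retention <- function(w) {
  if (w >= 1) return(1)
  (1 + sqrt(380 * w - 19)) / 20
}

# Retention r for the group-ancestor edges so that leaves of different groups
# (path leaf-anc-root-anc-leaf with retentions s_w, r, r, s_w) match at b.
solve_between_retention <- function(b, s_w) {
  f <- function(r) path_match_prob(c(s_w, r, r, s_w)) - b
  if (f(1) <= 0) return(1)
  uniroot(f, c(1e-9, 1), tol = 1e-12)$root
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

shifted_geom_lengths <- function(n, mean_length) {
  if (n == 0L) return(integer(0))
  if (mean_length <= 50) return(rep(50L, n))
  50L + rgeom(n, prob = 1 / (mean_length - 49))
}

#' Mutate an amino-acid sequence to a target identity
#'
#' Each position is retained with probability `target_identity / 100`;
#' substituted positions always change, to a residue drawn uniformly from the
#' other 19. Length is preserved. Uses the global RNG; seed with [set.seed()]
#' for reproducibility.
#'
#' @param seq single amino-acid string over the 20-letter alphabet.
#' @param target_identity expected percent of unchanged positions, (0, 100].
#' @return Mutated sequence of the same length.
#' @export
mutate_sequence <- function(seq, target_identity) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop_input("mutate_sequence: seq must be a single non-empty string")
  if (!(target_identity > 0 && target_identity <= 100))
    stop_input("mutate_sequence: target_identity must be in (0, 100]")
  if (target_identity == 100) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(ch, AA20)
  if (anyNA(idx))
    stop_input("mutate_sequence: sequence contains letters outside the 20-letter alphabet")
  hit <- runif(length(ch)) >= target_identity / 100
  n_mut <- sum(hit)
  if (n_mut > 0L) {
    # offset 1..19 guarantees the residue changes
    idx[hit] <- (idx[hit] - 1L + sample.int(19L, n_mut, replace = TRUE)) %% 20L + 1L
    ch <- AA20[idx]
  }
  paste(ch, collapse = "")
}

#' Simulate a pangenome with planted ground truth
#'
#' Emits one [proteome] per genome together with the truth needed to score
#' every downstream stage: the planted tree, the gene-to-family ortholog map,
#' the planted core length fraction and the planted pairwise identities.
#' Genomes are labelled `A1, A2, ... , B1, ...` (letter = group). All
#' randomness flows from `params$seed`; a fixed seed gives bit-identical
#' output.
#'
#' @param params a [sim_params] object.
#' @return A list with elements `proteomes` (list of [proteome]) and `truth`,
#'   itself a list: `true_tree` (ape `"phylo"`), `ortholog_map` (named vector,
#'   gene id -> family id), `planted_core_fraction`, `planted_identity`
#'   (genomes x genomes percent matrix), `group_of` (named vector genome ->
#'   group label), and `params`.
#' @export
simulate_pangenome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  w <- p$within_identity / 100
  b <- p$between_identity / 100
  s_w <- solve_within_retention(w)
  r <- if (p$n_groups > 1L) solve_between_retention(b, s_w) else 1

  n_univ <- if (p$n_groups > 1L) round(p$shared_core_fraction * p$core_genes) else 0L
  n_priv <- p$core_genes - n_univ
  groups <- LETTERS[seq_len(p$n_groups)]
  genomes <- unlist(lapply(groups, function(g) paste0(g, seq_len(p$genomes_per_group))))
  group_of <- setNames(rep(groups, each = p$genomes_per_group), genomes)

  # universal core families: one root each, group ancestors diverged to r
  univ_len <- shifted_geom_lengths(n_univ, p$mean_gene_length)
  univ_root <- vapply(univ_len, random_protein, character(1L))
  univ_anc <- lapply(groups, function(g)
    vapply(univ_root, mutate_sequence, character(1L), target_identity = 100 * r))
  names(univ_anc) <- groups
  univ_fam <- if (n_univ > 0L) sprintf("fam.u%04d", seq_len(n_univ)) else character(0)

  # group-private core families: fresh ancestor per group
  priv_anc <- priv_len <- priv_fam <- list()
  for (g in groups) {
    priv_len[[g]] <- shifted_geom_lengths(n_priv, p$mean_gene_length)
    priv_anc[[g]] <- vapply(priv_len[[g]], random_protein, character(1L))
    priv_fam[[g]] <- if (n_priv > 0L) sprintf("fam.%s.c%04d", g, seq_len(n_priv)) else character(0)
  }

  proteomes <- vector("list", length(genomes))
  names(proteomes) <- genomes
  ortholog_map <- character(0)

  for (gm in genomes) {
    g <- group_of[[gm]]
    anc <- c(univ_anc[[g]], priv_anc[[g]])
    fam <- c(univ_fam, priv_fam[[g]])
    core_seq <- vapply(anc, mutate_sequence, character(1L),
                       target_identity = 100 * s_w)
    core_total <- sum(nchar(core_seq))
    n_acc <- p$accessory_genes_per_genome
    if (p$core_length_fraction >= 1) n_acc <- 0L
    acc_seq <- character(0)
    if (n_acc > 0L) {
      m_acc <- core_total * (1 / p$core_length_fraction - 1) / n_acc
      acc_seq <- vapply(shifted_geom_lengths(n_acc, m_acc), random_protein,
                        character(1L))
    }
    seqs <- c(core_seq, acc_seq)
    ids <- sprintf("%s.g%04d", gm, seq_along(seqs))
    fam_all <- c(fam, if (n_acc > 0L) sprintf("fam.%s.a%04d", gm, seq_len(n_acc)))
    names(seqs) <- ids
    proteomes[[gm]] <- proteome(gm, seqs)
    ortholog_map <- c(ortholog_map, setNames(fam_all, ids))
  }

  planted_identity <- matrix(p$between_identity, length(genomes), length(genomes),
                             dimnames = list(genomes, genomes))
  for (g in groups) {
    idx <- which(group_of == g)
    planted_identity[idx, idx] <- p$within_identity
  }
  diag(planted_identity) <- 100

  lw <- 1 - s_w
  lg <- 1 - r
  tip <- function(g) paste(sprintf("%s:%.8f", names(group_of)[group_of == g], lw),
                           collapse = ",")
  nwk <- if (p$n_groups == 1L) sprintf("(%s);", tip(groups[1L]))
         else sprintf("(%s);", paste(sprintf("(%s):%.8f", vapply(groups, tip, character(1L)), lg),
                                     collapse = ","))
  true_tree <- ape::read.tree(text = nwk)

  truth <- list(true_tree = true_tree, ortholog_map = ortholog_map,
                planted_core_fraction = p$core_length_fraction,
                planted_identity = planted_identity, group_of = group_of,
                params = p)
  list(proteomes = proteomes, truth = truth)
}

#' Write a simulated pangenome to disk
#'
#' One amino-acid multi-FASTA per genome (record ids
#' `"<genome>|<gene>|<family>"`), a truth table
#' `truth.tsv` (gene_id, genome_id, family_id, length) and the planted tree in
#' `true_tree.nwk`.
#'
#' @param sim result of [simulate_pangenome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pangenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in sim$proteomes)
    write_proteome_fasta(p, file.path(dir, paste0(p$genome_id, ".faa")),
                         family_map = sim$truth$ortholog_map)
  rows <- do.call(rbind, lapply(sim$proteomes, function(p)
    data.frame(gene_id = gene_ids(p), genome_id = p$genome_id,
               family_id = unname(sim$truth$ortholog_map[gene_ids(p)]),
               length = unname(gene_lengths(p)))))
  write.table(rows, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(to_newick(sim$truth$true_tree), file.path(dir, "true_tree.nwk"))
  invisible(dir)
}
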