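# shared fixture builders: everything is generated in code at test time

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_prot <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")

# proteome of `n` unrelated random genes
rand_proteome <- function(genome_id, n, len = 80) {
  seqs <- setNames(vapply(rep(len, n), rand_prot, character(1L)),
                   sprintf("%s.g%03d", genome_id, seq_len(n)))
  proteome(genome_id, seqs)
}

# small simulated pangenome used across tests
small_sim <- function(seed = 3, n_groups = 2, genomes_per_group = 2,
                      core_genes = 30, accessory = 8, len = 100,
                      within = 99, between = 85, core_fraction = 0.78) {
  simulate_pangenome(sim_params(
    n_groups = n_groups, genomes_per_group = genomes_per_group,
    core_genes = core_genes, accessory_genes_per_genome = accessory,
    mean_gene_length = len, within_identity = within,
    between_identity = between, core_length_fraction = core_fraction,
    seed = seed))
}

# fraction of identical positions between two equal-length sequences
site_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}

# mock pairwise_comparison carrying only the fields the distance needs
mock_cmp <- function(genome_a, genome_b, n_a, n_b, n_bid, mean_identity = NA_real_) {
  structure(list(genome_a = genome_a, genome_b = genome_b,
                 n_genes_a = n_a, n_genes_b = n_b,
                 n_bidirectional = n_bid, mean_identity = mean_identity,
                 pairs = NULL),
            class = "pairwise_comparison")
}
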