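test_that("sim_params rejects out-of-bound settings and names the bound", {
  expect_error(sim_params(n_groups = 0), "n_groups")
  expect_error(sim_params(within_identity = 0), "within_identity")
  expect_error(sim_params(within_identity = 101), "within_identity")
  expect_error(sim_params(between_identity = 99.9, within_identity = 99),
               "between_identity <= within_identity")
  expect_error(sim_params(core_length_fraction = 0), "core_length_fraction")
  expect_error(sim_params(shared_core_fraction = 1.2), "shared_core_fraction")
  expect_error(sim_params(mean_gene_length = 20), "mean_gene_length")
  # a tiny core cannot feed this many accessory genes at the length floor
  expect_error(sim_params(core_genes = 10, mean_gene_length = 60,
                          core_length_fraction = 0.9,
                          accessory_genes_per_genome = 50),
               "accessory")
})

test_that("mutate_sequence keeps length, hits the target rate, always changes residues", {
  expect_error(mutate_sequence("", 50), "non-empty")
  expect_error(mutate_sequence("MKV", 0), "target_identity")
  set.seed(1)
  s <- rand_prot(60)
  expect_identical(mutate_sequence(s, 100), s)

  set.seed(2)
  long <- rand_prot(10000)
  mut <- mutate_sequence(long, 73)
  expect_equal(nchar(mut), 10000)
  expect_lt(abs(site_identity(long, mut) - 73), 1)

  # substituted positions never keep the original residue
  ca <- strsplit(long, "")[[1L]]
  cb <- strsplit(mut, "")[[1L]]
  expect_true(all(cb[ca != cb] != ca[ca != cb]))

  # single-site sequence flips with probability ~ 1/2 at target 50
  set.seed(3)
  flips <- mean(replicate(400, mutate_sequence("K", 50) != "K"))
  expect_gt(flips, 0.38)
  expect_lt(flips, 0.62)
})

test_that("a fixed seed reproduces the pangenome bit for bit", {
  p <- sim_params(n_groups = 2, genomes_per_group = 2, core_genes = 15,
                  accessory_genes_per_genome = 5, mean_gene_length = 60,
                  seed = 11)
  s1 <- simulate_pangenome(p)
  s2 <- simulate_pangenome(p)
  expect_identical(lapply(s1$proteomes, function(x) as.character(x$seq)),
                   lapply(s2$proteomes, function(x) as.character(x$seq)))
  expect_identical(s1$truth$ortholog_map, s2$truth$ortholog_map)
  s3 <- simulate_pangenome(sim_params(n_groups = 2, genomes_per_group = 2,
                                      core_genes = 15,
                                      accessory_genes_per_genome = 5,
                                      mean_gene_length = 60, seed = 12))
  expect_false(identical(as.character(s1$proteomes[[1]]$seq),
                         as.character(s3$proteomes[[1]]$seq)))
})

test_that("zero divergence with a full core yields identical proteomes", {
  sim <- simulate_pangenome(sim_params(
    n_groups = 1, genomes_per_group = 3, core_genes = 20,
    accessory_genes_per_genome = 0, mean_gene_length = 70,
    within_identity = 100, between_identity = 100,
    core_length_fraction = 1, seed = 5))
  seqs <- lapply(sim$proteomes, function(p) unname(as.character(p$seq)))
  expect_identical(seqs[[1]], seqs[[2]])
  expect_identical(seqs[[1]], seqs[[3]])
  # full core: every family present in every genome
  fam_presence <- table(sim$truth$ortholog_map,
                        sub("\\..*$", "", names(sim$truth$ortholog_map)))
  expect_true(all(rowSums(fam_presence > 0) == 3))
})

test_that("planted pairwise identities are realized by the emitted orthologs", {
  # exhaustive pairwise check of ortholog columns (simulator emits no indels,
  # so per-site comparison is the exact alignment)
  sim <- simulate_pangenome(sim_params(
    n_groups = 2, genomes_per_group = 3, core_genes = 80,
    accessory_genes_per_genome = 0, mean_gene_length = 150,
    within_identity = 99.5, between_identity = 85,
    core_length_fraction = 1, shared_core_fraction = 1, seed = 7))
  fam <- sim$truth$ortholog_map
  genomes <- names(sim$proteomes)
  grp <- sim$truth$group_of
  mean_pair_identity <- function(g1, g2) {
    p1 <- sim$proteomes[[g1]]; p2 <- sim$proteomes[[g2]]
    f1 <- fam[gene_ids(p1)]
    f2 <- fam[gene_ids(p2)]
    shared <- intersect(f1, f2)
    ids1 <- names(f1)[match(shared, f1)]
    ids2 <- names(f2)[match(shared, f2)]
    mean(vapply(seq_along(shared), function(k)
      site_identity(as.character(p1$seq[[ids1[k]]]),
                    as.character(p2$seq[[ids2[k]]])), numeric(1L)))
  }
  within <- between <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    v <- mean_pair_identity(genomes[i], genomes[j])
    if (grp[genomes[i]] == grp[genomes[j]]) within <- c(within, v)
    else between <- c(between, v)
  }
  expect_lt(abs(mean(within) - 99.5), 0.5)
  expect_lt(abs(mean(between) - 85), 1)
})

test_that("realized core residue fraction matches the planted value", {
  sim <- simulate_pangenome(sim_params(
    n_groups = 1, genomes_per_group = 4, core_genes = 200,
    accessory_genes_per_genome = 67, mean_gene_length = 200,
    within_identity = 99.5, core_length_fraction = 0.75, seed = 13))
  fam <- sim$truth$ortholog_map
  core_fams <- names(which(table(fam) == 4))  # families in all 4 genomes
  total <- sum(vapply(sim$proteomes, total_residues, numeric(1)))
  core <- sum(unlist(lapply(sim$proteomes, function(p) {
    l <- gene_lengths(p)
    sum(l[fam[names(l)] %in% core_fams])
  })))
  expect_lt(abs(100 * core / total - 75), 2)
})

test_that("gene ids are globally unique and families never share ids", {
  sim <- small_sim(seed = 9)
  map <- sim$truth$ortholog_map
  all_ids <- unlist(lapply(sim$proteomes, gene_ids), use.names = FALSE)
  expect_false(anyDuplicated(all_ids) > 0)
  expect_setequal(names(map), all_ids)
  # accessory families are singletons; core families have one member per genome
  per_genome <- split(map, sub("\\..*$", "", names(map)))
  for (m in per_genome) expect_false(anyDuplicated(m) > 0)
})

test_that("write_pangenome emits FASTA, truth table and tree that round-trip", {
  sim <- small_sim(seed = 21, n_groups = 1, genomes_per_group = 2,
                   core_genes = 10, accessory = 3, len = 60)
  dir <- withr::local_tempdir()
  write_pangenome(sim, dir)
  expect_true(file.exists(file.path(dir, "A1.faa")))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_setequal(truth$gene_id, names(sim$truth$ortholog_map))
  back <- read_proteome_fasta(file.path(dir, "A1.faa"))
  expect_identical(back$genome_id, "A1")
  expect_identical(as.character(back$seq), as.character(sim$proteomes$A1$seq))
  tr <- from_newick(readLines(file.path(dir, "true_tree.nwk")))
  expect_setequal(tr$tip.label, names(sim$proteomes))
})
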