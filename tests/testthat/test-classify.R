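idm <- function(v, labels) {
  n <- length(labels)
  m <- matrix(100, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

test_that("uniformly high identity yields one cluster, a high bar all singletons", {
  m <- idm(rep(100, 6), LETTERS[1:4])
  one <- delimit_species(m, classification_params(95))
  expect_length(one$clusters, 1L)
  expect_setequal(one$clusters[[1]], LETTERS[1:4])

  m2 <- idm(c(94, 80, 75, 82, 77, 90), LETTERS[1:4])
  all_single <- delimit_species(m2, classification_params(99))
  expect_length(all_single$clusters, 4L)
  expect_true(all(lengths(all_single$clusters) == 1L))
})

test_that("a bimodal identity regime recovers the two planted clusters", {
  labels <- c("A1", "A2", "A3", "B1", "B2", "B3")
  m <- matrix(86, 6, 6, dimnames = list(labels, labels))
  m[1:3, 1:3] <- 99.6
  m[4:6, 4:6] <- 99.5
  diag(m) <- 100
  res <- delimit_species(m, classification_params(95))
  expect_length(res$clusters, 2L)
  expect_setequal(res$clusters[[1]], c("A1", "A2", "A3"))
  expect_setequal(res$clusters[[2]], c("B1", "B2", "B3"))
  expect_equal(unname(res$within_identity), c(99.6, 99.5))
  expect_equal(res$between_identity["cluster1", "cluster2"], 86)
})

test_that("undefined identities never link and all-NA warns into singletons", {
  labels <- c("A", "B", "C")
  m <- matrix(NA_real_, 3, 3, dimnames = list(labels, labels))
  diag(m) <- 100
  expect_warning(res <- delimit_species(m), "own cluster")
  expect_length(res$clusters, 3L)
})

test_that("raising the threshold only refines the partition", {
  set.seed(60)
  labels <- paste0("g", 1:8)
  for (rep_i in 1:10) {
    vals <- sample(c(80, 90, 96, 99.5), 28, replace = TRUE)
    m <- idm(vals, labels)
    low <- delimit_species(m, classification_params(90))$membership
    high <- delimit_species(m, classification_params(97))$membership
    # every high-threshold cluster sits inside one low-threshold cluster
    expect_true(all(tapply(low, high, function(x) length(unique(x))) == 1))
  }
})

test_that("monophyly detection works on unrooted bipartitions", {
  tr <- from_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  expect_true(check_monophyly(tr, c("A", "B")))
  expect_true(check_monophyly(tr, c("D", "E")))
  expect_true(check_monophyly(tr, c("C", "D", "E")))
  expect_false(check_monophyly(tr, c("A", "C")))
  expect_false(check_monophyly(tr, c("B", "D", "E")))
  expect_true(check_monophyly(tr, "A"))
  expect_true(check_monophyly(tr, c("A", "B", "C", "D", "E")))
  # complement of a clade is monophyletic on an unrooted tree
  expect_true(check_monophyly(tr, c("C", "D", "E", "B")))
  expect_error(check_monophyly(tr, c("A", "Z")), "unknown")
})

test_that("full_report validates ids and prints the evidence sections", {
  m <- idm(c(99, 85, 85, 85, 85, 99), c("A1", "A2", "B1", "B2"))
  asg <- delimit_species(m)
  d <- matrix(0.2, 4, 4, dimnames = dimnames(m))
  diag(d) <- 0
  tr <- from_newick("((A1:1,A2:1):1,(B1:1,B2:1):1);")
  rep <- full_report(asg, list(), tr, d, m)
  expect_true(all(rep$monophyletic))
  out <- capture.output(print(rep))
  expect_true(any(grepl("2 cluster", out)))
  expect_true(any(grepl("not applicable", out)))

  bad_tree <- from_newick("((A1:1,A2:1):1,(B1:1,XX:1):1);")
  expect_error(full_report(asg, list(), bad_tree, d, m), "XX")
})

test_that("a single genome reports one singleton cluster", {
  m <- matrix(100, 1, 1, dimnames = list("solo", "solo"))
  asg <- delimit_species(m)
  expect_length(asg$clusters, 1L)
  rep <- full_report(asg, list(), NULL, NULL, NULL)
  out <- capture.output(print(rep))
  expect_true(any(grepl("not applicable", out)))
})

test_that("delimited clusters are monophyletic on the NJ tree across seeds", {
  # between-identity sits well below the threshold minus 5 points, so the
  # planted species should come back monophyletic for every seed
  for (seed in 1:10) {
    sim <- small_sim(seed = seed, n_groups = 2, genomes_per_group = 2,
                     core_genes = 10, accessory = 3, len = 60,
                     within = 99, between = 85)
    ps <- sim$proteomes
    cmps <- list()
    for (i in 1:3) for (j in (i + 1):4)
      cmps[[length(cmps) + 1]] <- compare_proteomes(ps[[i]], ps[[j]])
    tr <- neighbour_joining(build_distance_matrix(cmps))
    asg <- delimit_species(identity_matrix(cmps), classification_params(95))
    expect_length(asg$clusters, 2L)
    for (cl in asg$clusters)
      expect_true(check_monophyly(tr, cl))
  }
})

test_that("machine-readable reports regenerate byte-identically", {
  sim <- small_sim(seed = 61, n_groups = 2, genomes_per_group = 2,
                   core_genes = 12, accessory = 4, len = 70)
  rep <- run_taxgen(sim$proteomes)
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  write_report(rep, d1)
  write_report(rep, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  js <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_length(js$clusters, 2L)
  expect_true(js$clusters[[1]]$monophyletic)
})
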