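#' Assemble the full classification report
#'
#' Aggregates the evidence lines of a taxogenomic analysis into one document:
#' species clusters with identity summaries and monophyly flags against the
#' supplied tree, core-genome percentages with eligibility flags, the
#' gene-content distance matrix alongside the identity matrix (so the
#' dendrogram's basis is auditable), and every non-default parameter and
#' filter used.
#'
#' @param assignment a [delimit_species()] result.
#' @param core_reports list of [core_report()] results (possibly empty), e.g.
#'   one per cluster plus a combined group.
#' @param tree unrooted ape `"phylo"` from [neighbour_joining()], or `NULL`.
#' @param distances gene-content distance matrix.
#' @param identities identity matrix.
#' @param params a [classification_params].
#' @param scoring,filters the [scoring_params] and [pair_filters] used
#'   upstream, recorded for auditability.
#' @return An object of class `"taxgen_report"`.
#' @export
full_report <- function(assignment, core_reports = list(), tree = NULL,
                        distances = NULL, identities = NULL,
                        params = classification_params(),
                        scoring = scoring_params(), filters = pair_filters()) {
  stopifnot(inherits(assignment, "species_assignment"))
  genomes <- unlist(assignment$clusters, use.names = FALSE)
  offenders <- character(0)
  if (!is.null(distances))
    offenders <- c(offenders, setdiff(genomes, rownames(distances)),
                   setdiff(rownames(distances), genomes))
  if (!is.null(identities))
    offenders <- c(offenders, setdiff(genomes, rownames(identities)))
  if (!is.null(tree))
    offenders <- c(offenders, setdiff(genomes, tree$tip.label),
                   setdiff(tree$tip.label, genomes))
  for (cr in core_reports)
    offenders <- c(offenders, setdiff(cr$genome_ids, genomes))
  if (length(offenders) > 0L)
    stop_input("full_report: genome id mismatch across inputs: %s",
               paste(unique(offenders), collapse = ", "))

  mono <- if (is.null(tree)) NULL else
    vapply(assignment$clusters, function(mem) check_monophyly(tree, mem),
           logical(1L))
  core <- lapply(core_reports, function(cr) {
    list(group = cr$group_label, genomes = cr$genome_ids,
         total_core_percent = cr$total_core_percent,
         mean_percent = cr$mean_percent, sd_percent = cr$sd_percent,
         core_family_count = cr$core_family_count,
         eligible_for_core_phylogeny =
           core_phylogeny_eligible(cr, params$core_eligibility_threshold))
  })
  structure(list(assignment = assignment, monophyletic = mono, core = core,
                 distances = distances, identities = identities, tree = tree,
                 params = params, scoring = scoring, filters = filters),
            class = "taxgen_report")
}

#' @export
print.taxgen_report <- function(x, ...) {
  cat("== taxogenomic classification report ==\n\n")
  print(x$assignment)
  if (!is.null(x$monophyletic)) {
    cat("\nMonophyly on the gene-content NJ tree:\n")
    for (nm in names(x$monophyletic))
      cat(sprintf("  %s: %s\n", nm, if (x$monophyletic[[nm]]) "monophyletic" else "NOT monophyletic"))
  }
  if (length(x$core) > 0L) {
    cat(sprintf("\nCore genome (residue-length based; eligibility threshold > %.0f%%):\n",
                x$params$core_eligibility_threshold))
    for (cr in x$core)
      cat(sprintf("  %-12s total %5.1f%%  average %.1f +/- %.1f%%  [%s]\n",
                  cr$group, cr$total_core_percent, cr$mean_percent,
                  cr$sd_percent,
                  if (cr$eligible_for_core_phylogeny) "eligible" else "not eligible"))
  } else {
    cat("\nCore genome: not applicable (no group of >= 2 genomes)\n")
  }
  if (!is.null(x$distances)) {
    cat("\nGene-content distance matrix (part of unshared genes):\n")
    print(round(x$distances, 4))
  }
  if (!is.null(x$identities)) {
    cat("\nMean bidirectional-pair identity matrix (%):\n")
    print(round(x$identities, 2))
  }
  cat(sprintf("\nFilters: identity >= %.0f%%, coverage >= %.0f%% of the shorter protein%s\n",
              x$filters$min_identity, 100 * x$filters$min_coverage,
              if (x$filters$prescreen)
                sprintf("; k-mer prescreen on (>= %d shared %d-mers)",
                        x$filters$min_shared_kmers, x$filters$kmer_size)
              else ""))
  cat(sprintf("Scoring: %s, gap open %g, gap extend %g\n",
              if (is.character(x$scoring$matrix)) x$scoring$matrix else "custom matrix",
              x$scoring$gap_open, x$scoring$gap_extend))
  invisible(x)
}

#' Write a report to disk
#'
#' Writes the machine-readable report (`report.json`), the human-readable
#' text (`report.txt`), the matrices (TSV) and the Newick tree. Output
#' contains no timestamps: regeneration from the same inputs is byte
#' identical.
#'
#' @param report a [full_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "taxgen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- report
  machine <- list(
    clusters = lapply(seq_along(x$assignment$clusters), function(i) list(
      name = names(x$assignment$clusters)[i],
      genomes = x$assignment$clusters[[i]],
      within_identity = x$assignment$within_identity[[i]],
      monophyletic = if (is.null(x$monophyletic)) NULL else x$monophyletic[[i]])),
    between_cluster_identity = x$assignment$between_identity,
    core = x$core,
    parameters = c(unclass(x$params), unclass(x$filters),
                   list(gap_open = x$scoring$gap_open,
                        gap_extend = x$scoring$gap_extend,
                        substitution_matrix =
                          if (is.character(x$scoring$matrix)) x$scoring$matrix
                          else "custom")))
  jsonlite::write_json(machine, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  txt <- utils::capture.output(print(x))
  writeLines(txt, file.path(dir, "report.txt"))
  if (!is.null(x$distances)) {
    write_matrix_tsv(x$distances, file.path(dir, "gene_content_distance.tsv"))
    write_matrix_phylip(x$distances, file.path(dir, "gene_content_distance.phy"))
  }
  if (!is.null(x$identities))
    write_matrix_tsv(x$identities, file.path(dir, "identity.tsv"))
  if (!is.null(x$tree)) {
    writeLines(to_newick(x$tree), file.path(dir, "nj_unrooted.nwk"))
    writeLines(to_newick(midpoint_root(x$tree)), file.path(dir, "nj_midpoint.nwk"))
  }
  invisible(dir)
}

#' Run the whole classification pipeline
#'
#' Compares every pair of proteomes, assembles the gene-content distance and
#' identity matrices, builds the neighbour-joining tree, delimits species by
#' the identity threshold, computes a core-genome report per multi-genome
#' cluster plus one for the combined set, and returns the [full_report()].
#'
#' @param proteomes list of [proteome] objects (>= 2), unique genome ids.
#' @param scoring a [scoring_params].
#' @param filters a [pair_filters]. For large high-identity genome sets,
#'   enabling the k-mer prescreen cuts runtime by orders of magnitude.
#' @param params a [classification_params].
#' @return A `"taxgen_report"` whose `tree`, `distances`, `identities` and
#'   `comparisons` elements expose the intermediate results.
#' @export
run_taxgen <- function(proteomes, scoring = scoring_params(),
                       filters = pair_filters(prescreen = TRUE),
                       params = classification_params()) {
  stopifnot(length(proteomes) >= 2L,
            all(vapply(proteomes, inherits, logical(1L), "proteome")))
  ids <- unname(vapply(proteomes, function(p) p$genome_id, character(1L)))
  if (anyDuplicated(ids))
    stop_input("duplicate genome id(s): %s", paste(ids[duplicated(ids)], collapse = ", "))
  names(proteomes) <- ids
  n <- length(ids)
  comparisons <- list()
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    comparisons[[length(comparisons) + 1L]] <-
      compare_proteomes(proteomes[[i]], proteomes[[j]], scoring, filters)
  distances <- build_distance_matrix(comparisons, labels = ids)
  identities <- identity_matrix(comparisons, labels = ids)
  tree <- neighbour_joining(distances)
  assignment <- delimit_species(identities, params)

  idx <- comparison_index(comparisons)
  group_core <- function(members, label) {
    sub <- list()
    for (a in seq_along(members)) for (b in seq_along(members))
      if (a < b) sub[[length(sub) + 1L]] <- idx[[pair_key(members[a], members[b])]]
    fams <- build_families(proteomes[members], sub)
    core_report(proteomes[members], fams, group_label = label)
  }
  core_reports <- list()
  for (nm in names(assignment$clusters)) {
    mem <- assignment$clusters[[nm]]
    if (length(mem) >= 2L)
      core_reports[[nm]] <- group_core(mem, nm)
  }
  if (length(assignment$clusters) > 1L && n >= 2L)
    core_reports[["combined"]] <- group_core(ids, "combined")

  rep <- full_report(assignment, core_reports, tree, distances, identities,
                     params, scoring, filters)
  rep$comparisons <- comparisons
  rep
}
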