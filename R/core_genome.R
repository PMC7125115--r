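#' Build ortholog families within a group of genomes
#'
#' Reference-star construction: the genome with the fewest genes (ties broken
#' by lexicographically smaller genome id) seeds one family per gene; for
#' every other genome the family contains that gene's bidirectional partner
#' with the reference, if one exists. Non-reference genes that end up in no
#' family remain singleton families. If inconsistent pair tables claim one
#' gene for two families, the higher-identity claim wins and the conflict is
#' reported via a message.
#'
#' @param proteomes list of [proteome] objects forming the group.
#' @param comparisons list of [compare_proteomes()] results covering at least
#'   every (reference, other) pair of the group.
#' @return A data frame of class `"ortholog_families"` with columns
#'   `family_id`, `genome_id`, `gene_id`, `length`; attributes `reference`
#'   (genome id) and `genomes`.
#' @export
build_families <- function(proteomes, comparisons) {
  stopifnot(length(proteomes) >= 1L,
            all(vapply(proteomes, inherits, logical(1L), "proteome")))
  ids <- unname(vapply(proteomes, function(p) p$genome_id, character(1L)))
  names(proteomes) <- ids
  counts <- vapply(proteomes, gene_count, integer(1L))
  ref <- ids[order(counts, ids)][1L]
  idx <- comparison_index(comparisons)

  lens <- lapply(proteomes, gene_lengths)
  ref_genes <- gene_ids(proteomes[[ref]])
  fam_ids <- sprintf("fam%05d", seq_along(ref_genes))
  rows <- list(data.frame(family_id = fam_ids, genome_id = ref,
                          gene_id = ref_genes,
                          length = unname(lens[[ref]][ref_genes])))

  for (g in setdiff(ids, ref)) {
    cmp <- idx[[pair_key(ref, g)]]
    if (is.null(cmp))
      stop_input("build_families: missing comparison for pair %s / %s", ref, g)
    bi <- cmp$pairs[cmp$pairs$direction == "bidirectional", , drop = FALSE]
    if (cmp$genome_a == ref) {
      ref_side <- bi$gene_a; g_side <- bi$gene_b
    } else {
      ref_side <- bi$gene_b; g_side <- bi$gene_a
    }
    if (anyDuplicated(g_side)) {
      message(sprintf("build_families: gene(s) in %s claimed by multiple families; keeping highest identity", g))
      ord <- order(-bi$identity)
      keep <- ord[!duplicated(g_side[ord])]
      keep <- keep[!duplicated(ref_side[keep])]
      ref_side <- ref_side[keep]; g_side <- g_side[keep]
    }
    matched <- data.frame(family_id = fam_ids[match(ref_side, ref_genes)],
                          genome_id = rep(g, length(g_side)), gene_id = g_side,
                          length = unname(lens[[g]][g_side]))
    left <- setdiff(gene_ids(proteomes[[g]]), g_side)
    single <- if (length(left)) data.frame(
      family_id = sprintf("fam.s.%s.%05d", g, seq_along(left)),
      genome_id = rep(g, length(left)), gene_id = left,
      length = unname(lens[[g]][left]))
    rows[[g]] <- rbind(matched, single)
  }
  fams <- do.call(rbind, rows)
  rownames(fams) <- NULL
  structure(fams, class = c("ortholog_families", "data.frame"),
            reference = ref, genomes = unname(ids))
}

#' Core-genome report for a group of genomes
#'
#' Core families are those present in every genome of the group. The total
#' core percentage is the summed residue length of all core-family members
#' divided by the summed residue length of the whole group, times 100; the
#' per-strain percentage is the analogous per-genome share. The mean and SD
#' (population formula, divisor n) are taken over the per-strain percentages.
#' The core is measured on protein-coding genes by residue length; a
#' gene-count core fraction is reported alongside for transparency.
#'
#' @param proteomes list of [proteome] objects forming the group (size >= 2).
#' @param families [build_families()] result for this group.
#' @param group_label label naming the group in reports.
#' @return An object of class `"core_genome_report"`.
#' @export
core_report <- function(proteomes, families, group_label = "group") {
  if (length(proteomes) < 2L)
    stop_input("core_report: a group needs at least 2 genomes")
  ids <- vapply(proteomes, function(p) p$genome_id, character(1L))
  names(proteomes) <- ids
  presence <- tapply(families$genome_id, families$family_id,
                     function(g) length(unique(g)))
  core_fams <- names(presence)[presence == length(ids)]
  is_core <- families$family_id %in% core_fams

  totals <- vapply(proteomes, total_residues, numeric(1L))
  core_res <- tapply(families$length[is_core], families$genome_id[is_core], sum)
  core_by_genome <- setNames(rep(0, length(ids)), ids)
  core_by_genome[names(core_res)] <- core_res
  per_strain <- 100 * core_by_genome[ids] / totals[ids]

  gcounts <- vapply(proteomes, gene_count, numeric(1L))
  core_gene_share <- 100 * length(core_fams) * length(ids) / sum(gcounts)

  n <- length(ids)
  m <- mean(per_strain)
  structure(list(group_label = group_label, genome_ids = unname(ids),
                 reference = attr(families, "reference"),
                 core_family_count = length(core_fams),
                 family_count = length(unique(families$family_id)),
                 total_core_percent = 100 * sum(core_by_genome) / sum(totals),
                 per_strain_percent = per_strain,
                 mean_percent = m,
                 sd_percent = sqrt(sum((per_strain - m)^2) / n),
                 core_gene_percent = core_gene_share),
            class = "core_genome_report")
}

#' @export
print.core_genome_report <- function(x, ...) {
  cat(sprintf("<core genome> group %s (%d genomes, reference %s)\n",
              x$group_label, length(x$genome_ids), x$reference))
  cat(sprintf("  core families: %d of %d; total %.1f%% of residues; average %.1f +/- %.1f%% per strain\n",
              x$core_family_count, x$family_count, x$total_core_percent,
              x$mean_percent, x$sd_percent))
  cat(sprintf("  (gene-count core share: %.1f%%)\n", x$core_gene_percent))
  invisible(x)
}

#' Is a group eligible for core-genome phylogeny?
#'
#' A group qualifies only when its total core-genome percentage is strictly
#' above the threshold (default 70 percent).
#'
#' @param report a [core_report()] result.
#' @param threshold percent threshold.
#' @return `TRUE` or `FALSE`.
#' @export
core_phylogeny_eligible <- function(report, threshold = 70) {
  stopifnot(inherits(report, "core_genome_report"))
  report$total_core_percent > threshold
}

#' Write the families and core report tables
#'
#' @param families [build_families()] result.
#' @param report [core_report()] result for the same group.
#' @param families_path,report_path output TSVs (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_core_tables <- function(families, report, families_path = NULL,
                              report_path = NULL) {
  if (!is.null(families_path)) {
    presence <- tapply(families$genome_id, families$family_id,
                       function(g) length(unique(g)))
    core_fams <- names(presence)[presence == length(attr(families, "genomes"))]
    out <- cbind(as.data.frame(families),
                 is_core = families$family_id %in% core_fams)
    write.table(out, families_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report_path))
    write.table(data.frame(group = report$group_label,
                           total_percent = round(report$total_core_percent, 1),
                           mean_percent = round(report$mean_percent, 1),
                           sd_percent = round(report$sd_percent, 1),
                           core_families = report$core_family_count),
                report_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
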