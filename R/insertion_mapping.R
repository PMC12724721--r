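# Anchoring HEGs to flanking core genes and consolidating the anchors into
# named insertion loci H1..Hn, ordered along the consensus core scaffold.
# Locus equivalence is by flank-pair containment on the consensus order, so
# a genome that happens to have lost one core gene does not split a locus.

#' Extract the DNA of a gene (forward-strand orientation of the CDS)
#' @param genome a `phage_genome`.
#' @param gene_id gene identifier.
#' @return DNA string; reverse-complemented for minus-strand genes.
#' @export
gene_dna <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop(sprintf("gene '%s' not in genome '%s'", gene_id,
                             genome$genome_id), call. = FALSE)
  s <- substring(genome$sequence, genome$genes$start[i] + 1L,
                 genome$genes$end[i])
  if (genome$genes$strand[i] == "-") s <- .revcomp(s)
  s
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Anchor an HNHE gene to its nearest flanking core genes
#'
#' Walks the genome's gene order left and right from the HEG until a member
#' of a core cluster is found on each side, recording the core cluster ids
#' and the number of intervening non-core genes. At a genome end the anchor
#' is `"terminus"`.
#'
#' @param genome a `phage_genome`.
#' @param hnhe_gene gene id of the HEG (must belong to `genome`).
#' @param core_set core cluster ids.
#' @param partition an `ortholog_partition`.
#' @return A `flanking_anchor`: list with `gene_id`, `upstream_core`,
#'   `downstream_core`, `intervening_upstream`, `intervening_downstream`.
#' @export
anchor_heg <- function(genome, hnhe_gene, core_set, partition) {
  if (!length(core_set)) stop("core_set is empty", call. = FALSE)
  gn <- genome$genes
  i <- match(hnhe_gene, gn$gene_id)
  if (is.na(i))
    stop(sprintf("gene '%s' not in genome '%s'", hnhe_gene,
                 genome$genome_id), call. = FALSE)
  cl <- partition$membership[gn$gene_id]
  is_core <- !is.na(cl) & cl %in% core_set
  if (is_core[i])
    stop(sprintf("gene '%s' belongs to core cluster '%s'; core and mobile are exclusive",
                 hnhe_gene, cl[i]), call. = FALSE)
  up <- "terminus"; iu <- 0L
  if (i > 1) for (j in (i - 1):1) {
    if (is_core[j]) { up <- unname(cl[j]); break }
    iu <- iu + 1L
  }
  down <- "terminus"; idn <- 0L
  if (i < nrow(gn)) for (j in (i + 1):nrow(gn)) {
    if (is_core[j]) { down <- unname(cl[j]); break }
    idn <- idn + 1L
  }
  if (up == "terminus" && down == "terminus")
    stop(sprintf("genome '%s' has no core gene on either side of '%s'",
                 genome$genome_id, hnhe_gene), call. = FALSE)
  structure(list(gene_id = hnhe_gene, upstream_core = up,
                 downstream_core = down, intervening_upstream = iu,
                 intervening_downstream = idn),
            class = "flanking_anchor")
}

#' Anchor every classified HEG of a cohort
#'
#' @param genomes list of `phage_genome`.
#' @param assignments data.frame from [classify_cohort()].
#' @param core_set core cluster ids.
#' @param partition an `ortholog_partition`.
#' @return data.frame with one row per HEG (families and `TRUNCATED`;
#'   `UNCLASSIFIED` candidates are skipped): columns `gene_id`, `genome_id`,
#'   `family`, `upstream_core`, `downstream_core`, `intervening_upstream`,
#'   `intervening_downstream`.
#' @export
cohort_anchors <- function(genomes, assignments, core_set, partition) {
  by_id <- setNames(genomes, vapply(genomes, `[[`, "", "genome_id"))
  keep <- assignments$family != "UNCLASSIFIED"
  rows <- lapply(which(keep), function(r) {
    a <- anchor_heg(by_id[[assignments$genome_id[r]]],
                    assignments$gene_id[r], core_set, partition)
    data.frame(gene_id = a$gene_id, genome_id = assignments$genome_id[r],
               family = assignments$family[r],
               upstream_core = a$upstream_core,
               downstream_core = a$downstream_core,
               intervening_upstream = a$intervening_upstream,
               intervening_downstream = a$intervening_downstream,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), genome_id = character(),
                      family = character(), upstream_core = character(),
                      downstream_core = character(),
                      intervening_upstream = integer(),
                      intervening_downstream = integer(),
                      stringsAsFactors = FALSE)
  out
}

# scaffold-rank interval of a flank pair; terminus maps to rank 0 upstream /
# n_core + 1 downstream
.anchor_interval <- function(up, down, ord) {
  n <- length(ord)
  lo <- if (up == "terminus") 0L else match(up, ord)
  hi <- if (down == "terminus") n + 1L else match(down, ord)
  if (is.na(lo) || is.na(hi))
    stop(sprintf("anchor references unknown cluster ('%s','%s')", up, down),
         call. = FALSE)
  sort(c(lo, hi))
}

#' Consolidate HEG anchors into named insertion loci
#'
#' Anchors of intact (family-classified) HEGs are grouped by flank pair; two
#' flank pairs are merged when one's interval on the consensus core order
#' contains the other's (nested anchors arise when a genome is missing a
#' core gene locally). Loci are numbered H1, H2, ... by consensus-order
#' position of the upstream flank. Truncated HEGs are assigned to an
#' existing locus by the same containment rule and tallied, but never create
#' a locus of their own.
#'
#' @param anchors data.frame from [cohort_anchors()].
#' @param scaffold a `core_scaffold`.
#' @param assignments data.frame from [classify_cohort()] (family tallies).
#' @return list with `loci` (a data.frame: `locus_id`, `upstream_core`,
#'   `downstream_core`, `module`, per-family counts, `n_truncated`,
#'   `members` comma-separated) and `unplaced_truncated` (gene ids of
#'   truncated HEGs matching no intact locus).
#' @export
consolidate_loci <- function(anchors, scaffold, assignments) {
  ord <- scaffold$ordered_core
  fam_levels <- c("IHMU", "PACI", "GVE2")
  intact <- anchors[anchors$family %in% fam_levels, , drop = FALSE]
  trunc <- anchors[anchors$family == "TRUNCATED", , drop = FALSE]
  if (!nrow(intact))
    stop("no intact HEG anchors to consolidate", call. = FALSE)

  iv <- t(vapply(seq_len(nrow(intact)), function(r)
    .anchor_interval(intact$upstream_core[r], intact$downstream_core[r], ord),
    integer(2)))
  key <- paste(iv[, 1], iv[, 2])
  seeds <- unique(data.frame(lo = iv[, 1], hi = iv[, 2]))
  ns <- nrow(seeds)
  # containment graph over seed intervals -> merged locus groups
  contain <- which(outer(seeds$lo, seeds$lo, `<=`) &
                   outer(seeds$hi, seeds$hi, `>=`), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = contain[, 1], to = contain[, 2]),
    directed = FALSE, vertices = seq_len(ns))
  comp <- igraph::components(g)$membership

  seed_of <- match(key, paste(seeds$lo, seeds$hi))
  group_of_gene <- comp[seed_of]

  groups <- sort(unique(comp))
  info <- lapply(groups, function(gr) {
    idx <- which(comp == gr)
    # innermost interval represents the locus
    inner <- idx[order(-seeds$lo[idx], seeds$hi[idx])][1]
    list(lo = seeds$lo[inner], hi = seeds$hi[inner],
         genes = intact$gene_id[group_of_gene == gr])
  })
  ord_groups <- order(vapply(info, `[[`, 0L, "lo"),
                      vapply(info, `[[`, 0L, "hi"))
  info <- info[ord_groups]

  # place truncated HEGs by containment against the merged group spans
  unplaced <- character()
  if (nrow(trunc)) {
    tiv <- t(vapply(seq_len(nrow(trunc)), function(r)
      .anchor_interval(trunc$upstream_core[r], trunc$downstream_core[r], ord),
      integer(2)))
    spans <- t(vapply(seq_along(info), function(k) {
      idx <- which(comp == groups[ord_groups[k]])
      c(min(seeds$lo[idx]), max(seeds$hi[idx]))
    }, integer(2)))
    for (r in seq_len(nrow(trunc))) {
      hit <- which((spans[, 1] <= tiv[r, 1] & spans[, 2] >= tiv[r, 2]) |
                   (tiv[r, 1] <= spans[, 1] & tiv[r, 2] >= spans[, 2]))
      if (length(hit)) {
        k <- hit[which.min(spans[hit, 2] - spans[hit, 1])]
        info[[k]]$genes <- c(info[[k]]$genes, trunc$gene_id[r])
      } else {
        unplaced <- c(unplaced, trunc$gene_id[r])
      }
    }
  }

  fam_of <- setNames(assignments$family, assignments$gene_id)
  loci <- do.call(rbind, lapply(seq_along(info), function(k) {
    x <- info[[k]]
    up <- if (x$lo == 0) "terminus" else ord[x$lo]
    down <- if (x$hi > length(ord)) "terminus" else ord[x$hi]
    mod_anchor <- if (up != "terminus") up else down
    fams <- fam_of[x$genes]
    data.frame(locus_id = sprintf("H%d", k), upstream_core = up,
               downstream_core = down,
               module = unname(scaffold$module_of[mod_anchor]),
               n_IHMU = sum(fams == "IHMU"), n_PACI = sum(fams == "PACI"),
               n_GVE2 = sum(fams == "GVE2"),
               n_truncated = sum(fams == "TRUNCATED"),
               members = paste(sort(x$genes), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  list(loci = loci, unplaced_truncated = unplaced)
}

#' Compare a core flanking gene to its counterpart in a reference genome
#'
#' Best local DNA alignment of the query gene against the reference
#' sequence; identity over aligned columns, coverage as aligned fraction of
#' the query. Reported, never filtered.
#'
#' @param core_gene_dna query DNA string.
#' @param reference_dna reference DNA string (gene or genome).
#' @return list with `pct_identity`, `coverage`, `score`.
#' @export
compare_flank_to_reference <- function(core_gene_dna, reference_dna) {
  if (!nzchar(core_gene_dna) || !nzchar(reference_dna))
    stop("empty sequence", call. = FALSE)
  r <- align_pair(core_gene_dna, reference_dna, type = "local",
                  alphabet = "dna")
  list(pct_identity = r$pct_identity, coverage = r$cov_a, score = r$score)
}

#' Write consolidated loci as TSV
#' @param loci result of [consolidate_loci()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  write.table(loci$loci, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
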