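# HNH endonuclease detection and family classification. Queries are scored
# by pairwise local alignment against packaged reference proteins of the
# three families seen in lactococcal Skunavirus phages (I-HmuI-like,
# PacI-like, GVE2-like); profile-profile searching is deliberately not used
# so the pipeline stays self-contained and deterministic. The His-Asn-His/Asn
# active-site motif is located by spacing-constrained scanning scored against
# the I-HmuI catalytic region.

#' Load packaged HNHE reference proteins
#'
#' The package ships one reference protein per family together with its
#' catalytic-residue annotation (for the I-HmuI-like reference: D74, H75,
#' N96, 1-based). The packaged sequences are synthetic homologs constructed
#' to carry the family-defining catalytic architecture (see
#' `inst/extdata/hnhe_references_synthetic.fasta`); users with curated
#' reference proteins can substitute their own FASTA + catalytic TSV.
#'
#' @param fasta path to a reference FASTA (headers are family names).
#' @param catalytic path to a TSV with columns `family`, `position`
#'   (1-based), `residue`.
#' @return named list (by family) of lists with `family`, `protein_seq`,
#'   `catalytic_positions` (data.frame `position`, `residue`).
#' @export
load_hnhe_references <- function(fasta = NULL, catalytic = NULL) {
  if (is.null(fasta))
    fasta <- system.file("extdata", "hnhe_references_synthetic.fasta",
                         package = "hegatlas", mustWork = TRUE)
  if (is.null(catalytic))
    catalytic <- system.file("extdata",
                             "hnhe_reference_catalytic_synthetic.tsv",
                             package = "hegatlas", mustWork = TRUE)
  seqs <- read_protein_fasta(fasta)
  cat_df <- read.delim(catalytic, sep = "\t", stringsAsFactors = FALSE)
  refs <- lapply(names(seqs), function(fam) {
    cp <- cat_df[cat_df$family == fam, c("position", "residue")]
    rownames(cp) <- NULL
    list(family = fam, protein_seq = unname(seqs[[fam]]),
         catalytic_positions = cp)
  })
  names(refs) <- names(seqs)
  for (fam in names(refs)) {
    cp <- refs[[fam]]$catalytic_positions
    got <- substring(refs[[fam]]$protein_seq, cp$position, cp$position)
    if (!all(got == cp$residue))
      stop(sprintf("reference '%s': catalytic annotation disagrees with sequence",
                   fam), call. = FALSE)
  }
  refs
}

# the I-HmuI catalytic region used to score candidate motif windows:
# from 10 residues upstream of the first annotated catalytic residue to 30
# residues downstream of the last
.catalytic_region <- function(ref) {
  pos <- ref$catalytic_positions$position
  from <- max(1, min(pos) - 10)
  to <- min(nchar(ref$protein_seq), max(pos) + 30)
  substring(ref$protein_seq, from, to)
}

#' Scan a protein for the HNH active-site motif
#'
#' Enumerates residue triples H ... N ... (H|N) whose two inter-residue
#' spacings both fall in `spacing` (defaults bracket the 21-residue H75->N96
#' spacing of I-HmuI), scores each candidate window by global alignment to
#' the I-HmuI catalytic region, and returns the best. Absence of any
#' spacing-compatible triple returns `NULL` (absence is a value, not an
#' error).
#'
#' @param protein_seq amino-acid string.
#' @param spacing length-2 integer vector, allowed residue spacing between
#'   consecutive motif residues.
#' @param reference the I-HmuI-like reference (defaults to the packaged one).
#' @return `NULL`, or a `motif_hit`: list with `motif_span` (0-based
#'   half-open on the protein), `matched_pattern` (e.g. `"H-x21-N-x22-H"`),
#'   `score`, and `catalytic_map` (named list, reference position ->
#'   query position or `"absent"`, from a global alignment to the full
#'   reference).
#' @export
scan_hnh_motif <- function(protein_seq, spacing = c(10L, 35L),
                           reference = NULL) {
  if (!nzchar(protein_seq)) stop("empty protein sequence", call. = FALSE)
  if (is.null(reference)) reference <- load_hnhe_references()[["IHMU"]]
  chars <- strsplit(toupper(protein_seq), "", fixed = TRUE)[[1]]
  hs <- which(chars == "H")
  ns <- which(chars == "N")
  hn <- sort(c(hs, ns))
  if (!length(hs) || !length(ns)) return(NULL)

  triples <- NULL
  for (h in hs) {
    n_ok <- ns[ns - h >= spacing[1] & ns - h <= spacing[2]]
    for (n in n_ok) {
      t_ok <- hn[hn - n >= spacing[1] & hn - n <= spacing[2]]
      if (length(t_ok))
        triples <- rbind(triples, cbind(h, n, t_ok))
    }
  }
  if (is.null(triples)) return(NULL)

  region <- .catalytic_region(reference)
  L <- nchar(protein_seq)
  scores <- vapply(seq_len(nrow(triples)), function(i) {
    h <- triples[i, 1]; t <- triples[i, 3]
    win <- substring(protein_seq, max(1, h - 10), min(L, t + 10))
    align_pair(win, region, type = "global")$score
  }, 0)
  # deterministic: best score, ties to the earliest (h, n, t)
  ord <- order(-scores, triples[, 1], triples[, 2], triples[, 3])
  best <- triples[ord[1], ]

  aln <- align_pair(protein_seq, reference$protein_seq, type = "global")
  cat_pos <- reference$catalytic_positions$position
  catalytic_map <- lapply(cat_pos, function(p) {
    col <- which(!is.na(aln$b_idx) & aln$b_idx == p)
    if (length(col) && !is.na(aln$a_idx[col])) aln$a_idx[col] else "absent"
  })
  names(catalytic_map) <- as.character(cat_pos)

  structure(list(
    motif_span = c(best[1] - 1L, best[3]),
    residue_positions = unname(best),
    matched_pattern = sprintf("H-x%d-N-x%d-%s", best[2] - best[1] - 1L,
                              best[3] - best[2] - 1L, chars[best[3]]),
    score = scores[ord[1]],
    catalytic_map = catalytic_map), class = "motif_hit")
}

#' Classify one protein against the HNHE reference families
#'
#' The query is locally aligned to each reference; the best-scoring reference
#' proposes the family. A call requires the active-site motif to be present
#' and the alignment to cover at least `min_coverage_intact` of the
#' reference; similarity without those (fragments, motif-less remnants) is
#' called `TRUNCATED`. Queries whose best alignment score stays below
#' `floor_score` are `UNCLASSIFIED` (not HNHEs as far as the references can
#' tell).
#'
#' @param protein_seq amino-acid string.
#' @param references from [load_hnhe_references()]; must contain all three
#'   families.
#' @param gene_id identifier carried into the result.
#' @param min_coverage_intact minimum reference coverage for an intact call.
#' @param floor_score minimum local alignment score for any call; together
#'   with `floor_identity` this is the calibrated stand-in for a
#'   profile-search significance cutoff (unrelated proteins of these lengths
#'   stay below ~90 score and ~40% local identity).
#' @param floor_identity minimum percent identity of the best local
#'   alignment for any call.
#' @param spacing motif spacing bounds, see [scan_hnh_motif()].
#' @return An `hnhe_assignment`: list with `gene_id`, `family` (one of the
#'   reference families, `"TRUNCATED"`, `"UNCLASSIFIED"`), `best_reference`,
#'   `reference_coverage`, `pct_identity`, `score`, `motif`.
#' @export
classify_hnhe <- function(protein_seq, references, gene_id = NA_character_,
                          min_coverage_intact = 0.6, floor_score = 120,
                          floor_identity = 40, spacing = c(10L, 35L)) {
  if (!length(references)) stop("empty reference set", call. = FALSE)
  need <- c("IHMU", "PACI", "GVE2")
  if (!all(need %in% names(references)))
    stop("references must contain families: ", paste(need, collapse = ", "),
         call. = FALSE)
  hits <- lapply(references, function(ref)
    align_pair(protein_seq, ref$protein_seq, type = "local", id_a = gene_id))
  scores <- vapply(hits, `[[`, 0, "score")
  fams <- sort(names(references))
  best_fam <- fams[which.max(scores[fams])]
  best <- hits[[best_fam]]

  if (best$score < floor_score || best$pct_identity < floor_identity) {
    return(structure(list(gene_id = gene_id, family = "UNCLASSIFIED",
                          best_reference = NA_character_,
                          reference_coverage = 0, pct_identity = 0,
                          score = best$score, motif = NULL),
                     class = "hnhe_assignment"))
  }
  motif <- scan_hnh_motif(protein_seq, spacing = spacing,
                          reference = references[["IHMU"]])
  family <- if (best$cov_b >= min_coverage_intact && !is.null(motif))
    best_fam else "TRUNCATED"
  structure(list(gene_id = gene_id, family = family,
                 best_reference = best_fam,
                 reference_coverage = best$cov_b,
                 pct_identity = best$pct_identity,
                 score = best$score, motif = motif),
            class = "hnhe_assignment")
}

#' Detect and classify HNHE genes across a cohort
#'
#' Candidate genes are those annotated as HNH endonucleases (product matches
#' `"HNH"`) plus any gene carrying a spacing-compatible active-site motif, so
#' recall does not depend on annotation. Each candidate is classified with
#' [classify_hnhe()]; candidates the references cannot support come back
#' `UNCLASSIFIED` and are retained in the table for transparency.
#'
#' @param genomes list of `phage_genome`.
#' @param references from [load_hnhe_references()].
#' @param ... passed to [classify_hnhe()].
#' @return data.frame with one row per candidate: `gene_id`, `genome_id`,
#'   `family`, `best_reference`, `reference_coverage`, `pct_identity`,
#'   `score`, `motif_start`, `motif_end` (0-based half-open, NA when no
#'   motif).
#' @export
classify_cohort <- function(genomes, references = load_hnhe_references(),
                            ...) {
  proteins <- cohort_proteins(genomes)
  g_of <- gene_genome_map(genomes)
  products <- unlist(unname(lapply(genomes, function(g)
    setNames(g$genes$product, g$genes$gene_id))))
  annotated <- setNames(grepl("HNH", products, ignore.case = TRUE),
                        names(products))

  rows <- lapply(names(proteins), function(id) {
    is_cand <- annotated[[id]]
    motif <- NULL
    if (!is_cand) {
      motif <- scan_hnh_motif(proteins[[id]],
                              reference = references[["IHMU"]])
      is_cand <- !is.null(motif)
    }
    if (!is_cand) return(NULL)
    a <- classify_hnhe(proteins[[id]], references, gene_id = id, ...)
    data.frame(gene_id = id, genome_id = unname(g_of[id]),
               family = a$family, best_reference = a$best_reference,
               reference_coverage = a$reference_coverage,
               pct_identity = a$pct_identity, score = a$score,
               motif_start = if (is.null(a$motif)) NA_integer_ else
                 a$motif$motif_span[1],
               motif_end = if (is.null(a$motif)) NA_integer_ else
                 a$motif$motif_span[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), genome_id = character(),
                      family = character(), best_reference = character(),
                      reference_coverage = numeric(),
                      pct_identity = numeric(), score = numeric(),
                      motif_start = integer(), motif_end = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
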