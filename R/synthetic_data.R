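# Synthetic phage cohorts with full ground truth. The generator emulates a
# dairy-phage cohort: ~25-30 kb genomes with a conserved single-copy core in
# three functional modules (morphogenesis / replication / regulation), HNHE
# genes of three families planted at a small set of inter-core loci with
# lineage-correlated divergence and occasional 5'-truncation, lineage-shared
# and private accessory genes, and per-lineage starter-culture metadata.
# Every emitted gene is recorded in a truth table, so pipeline recovery can
# be scored exactly.

#' Configuration for a synthetic phage cohort
#'
#' @param n_genomes number of genomes.
#' @param n_lineages number of lineages; starter labels SM1..SMk are assigned
#'   one-to-one by lineage and genomes are distributed round-robin.
#' @param n_core number of single-copy core gene families (>= 5).
#' @param core_protein_length_range min/max core protein length (aa).
#' @param n_loci number of HEG insertion loci (<= n_core - 1).
#' @param locus_positions inter-core gap index per locus (gap g lies after
#'   core rank g); default: evenly spaced gaps.
#' @param family_of_locus HNHE family per locus; default GVE2 at the first
#'   locus (the terminase/portal gap when it is gap 1), PacI at the second,
#'   I-HmuI-like elsewhere.
#' @param heg_presence_prob probability a genome carries each locus's HEG.
#' @param truncation_prob probability a carried HEG is truncated (random
#'   5'-retention of 20-55% of residues).
#' @param mutation_rate per-residue substitution probability, applied once
#'   from ancestor to lineage and again from lineage to genome.
#' @param family_divergence per-residue divergence of each locus's HEG
#'   ancestor from the packaged family reference.
#' @param accessory_gene_rate expected number of private (genome-specific)
#'   accessory genes per genome (Poisson).
#' @param n_lineage_accessory lineage-specific accessory families per
#'   lineage.
#' @param lineage_accessory_retention probability a genome retains each of
#'   its lineage's accessory families.
#' @param core_deletion_prob per-genome, per-core-gene loss probability
#'   (never applied to the anchor, rank 1).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genomes = 20L, n_lineages = 3L, n_core = 25L,
                             core_protein_length_range = c(150L, 450L),
                             n_loci = 4L, locus_positions = NULL,
                             family_of_locus = NULL,
                             heg_presence_prob = 0.8,
                             truncation_prob = 0.15,
                             mutation_rate = 0.08,
                             family_divergence = 0.10,
                             accessory_gene_rate = 2,
                             n_lineage_accessory = 6L,
                             lineage_accessory_retention = 0.9,
                             core_deletion_prob = 0,
                             seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n_genomes >= 1, n_lineages >= 1, n_core >= 5,
            length(core_protein_length_range) == 2,
            core_protein_length_range[1] <= core_protein_length_range[2])
  probs <- c(heg_presence_prob, truncation_prob, mutation_rate,
             family_divergence, lineage_accessory_retention,
             core_deletion_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities and rates must lie in [0, 1]", call. = FALSE)
  if (n_loci > n_core - 1)
    stop(sprintf("n_loci (%d) exceeds the %d inter-core gaps", n_loci,
                 n_core - 1), call. = FALSE)
  if (is.null(locus_positions) && n_loci > 0)
    locus_positions <- unique(round(seq(1, n_core - 1,
                                        length.out = n_loci)))
  if (n_loci > 0) {
    locus_positions <- as.integer(locus_positions)
    if (length(locus_positions) != n_loci ||
        anyDuplicated(locus_positions) ||
        any(locus_positions < 1 | locus_positions > n_core - 1))
      stop("locus_positions must be n_loci distinct gaps in 1..n_core-1",
           call. = FALSE)
    if (is.null(family_of_locus)) {
      family_of_locus <- rep("IHMU", n_loci)
      family_of_locus[1] <- "GVE2"
      if (n_loci >= 2) family_of_locus[2] <- "PACI"
    }
    if (length(family_of_locus) != n_loci ||
        !all(family_of_locus %in% c("IHMU", "PACI", "GVE2")))
      stop("family_of_locus must give IHMU/PACI/GVE2 per locus",
           call. = FALSE)
  } else {
    locus_positions <- integer()
    family_of_locus <- character()
  }
  structure(list(n_genomes = as.integer(n_genomes),
                 n_lineages = as.integer(n_lineages),
                 n_core = as.integer(n_core),
                 core_protein_length_range = as.integer(core_protein_length_range),
                 n_loci = as.integer(n_loci),
                 locus_positions = locus_positions,
                 family_of_locus = family_of_locus,
                 heg_presence_prob = heg_presence_prob,
                 truncation_prob = truncation_prob,
                 mutation_rate = mutation_rate,
                 family_divergence = family_divergence,
                 accessory_gene_rate = accessory_gene_rate,
                 n_lineage_accessory = as.integer(n_lineage_accessory),
                 lineage_accessory_retention = lineage_accessory_retention,
                 core_deletion_prob = core_deletion_prob,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Random point substitutions on a protein
#'
#' Each residue is independently substituted with probability `rate`; the
#' replacement is drawn uniformly from the other 19 amino acids. Uses the
#' current RNG state.
#'
#' @param seq amino-acid string.
#' @param rate per-residue substitution probability in `[0, 1]`.
#' @return mutated amino-acid string.
#' @export
mutate_protein <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(seq)
  aa20 <- .AA_LETTERS[1:20]
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(aa20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

.random_protein <- function(len) {
  paste(sample(.AA_LETTERS[1:20], len, replace = TRUE), collapse = "")
}

.restore_positions <- function(seq, template, positions) {
  positions <- positions[positions <= nchar(seq)]
  for (p in positions)
    substring(seq, p, p) <- substring(template, p, p)
  seq
}

# codon table for back-translation (uniform synonymous choice)
.codons_by_aa <- function() {
  if (is.null(.hegatlas_env$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .hegatlas_env$codons <- split(names(gc), unname(gc))
  }
  .hegatlas_env$codons
}

.back_translate <- function(protein) {
  cod <- .codons_by_aa()
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  picks <- vapply(chars, function(a) {
    opts <- cod[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste(c(picks, sample(cod[["*"]], 1L)), collapse = "")
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# module truth along the core: three contiguous spans when n_core >= 8
.module_spans <- function(n_core) {
  if (n_core < 8)
    return(list(module_of_rank = rep("unassigned", n_core),
                markers = data.frame(rank = 1L,
                                     product = "terminase large subunit",
                                     module = "morphogenesis",
                                     stringsAsFactors = FALSE)))
  m1 <- round(0.40 * n_core)
  m2 <- round(0.72 * n_core)
  module_of_rank <- rep("regulation", n_core)
  module_of_rank[1:m1] <- "morphogenesis"
  module_of_rank[(m1 + 1):m2] <- "replication"
  markers <- data.frame(
    rank = c(1L, 2L, m1, m1 + 1L, m2, m2 + 1L, n_core),
    product = c("terminase large subunit", "portal protein",
                "major capsid protein", "DNA polymerase",
                "single-stranded DNA annealing protein",
                "transcriptional regulator", "holin"),
    module = c("morphogenesis", "morphogenesis", "morphogenesis",
               "replication", "replication", "regulation", "regulation"),
    stringsAsFactors = FALSE)
  list(module_of_rank = module_of_rank, markers = markers)
}

#' Marker map for functional-module assignment from standard annotations
#'
#' Resolves the usual module marker products (terminase large subunit and
#' major capsid protein for morphogenesis; DNA polymerase and ssDNA
#' annealing protein for replication; transcriptional regulator and holin
#' for regulation) to core cluster ids. Markers whose product is absent from
#' the cohort are skipped; modules with no resolvable marker are dropped.
#'
#' @param partition an `ortholog_partition`.
#' @param genomes list of `phage_genome`.
#' @param core_set core cluster ids (markers outside it are skipped).
#' @return named list module -> cluster ids, usable with
#'   [assign_functional_modules()].
#' @export
default_marker_map <- function(partition, genomes, core_set) {
  spec <- list(
    morphogenesis = c("terminase large subunit", "portal protein",
                      "major capsid protein"),
    replication = c("DNA polymerase", "single-stranded DNA annealing protein"),
    regulation = c("transcriptional regulator", "holin"))
  out <- lapply(spec, function(prods) {
    hits <- character()
    for (p in prods) {
      cl <- tryCatch(find_cluster_by_product(partition, genomes,
                                             paste0("^", p, "$")),
                     error = function(e) NULL)
      if (!is.null(cl) && cl %in% core_set) hits <- c(hits, cl)
    }
    unique(hits)
  })
  out[lengths(out) > 0]
}

#' Simulate a phage cohort with known ground truth
#'
#' See [synthetic_config()] for the generative model. Core and accessory
#' ancestors are random proteins; each locus's HEG ancestor is the packaged
#' family reference mutated by `family_divergence` with the active-site
#' residues restored (purifying selection on the catalytic motif). Lineage
#' ancestors add one round of mutation, genomes a second. Proteins are
#' back-translated with uniform synonymous codons and laid out with random
#' short intergenic spacers; the final core gene sits on the minus strand to
#' exercise strand handling.
#'
#' @param config a `synthetic_config`.
#' @return list with `genomes` (named list of `phage_genome`, metadata set)
#'   and `truth` (list of data.frames: `genomes`, `genes`, `loci`,
#'   `modules`, plus the `config`).
#' @export
simulate_phage_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  refs <- load_hnhe_references()
  .with_seed(config$seed, .simulate_cohort_impl(config, refs))
}

.simulate_cohort_impl <- function(cfg, refs) {
  n <- cfg$n_genomes
  nc <- cfg$n_core
  mod <- .module_spans(nc)

  # protected positions per family: annotated catalytic residues plus the
  # scanned motif triple of the reference itself
  protected <- lapply(refs, function(ref) {
    hit <- scan_hnh_motif(ref$protein_seq, reference = refs[["IHMU"]])
    sort(unique(c(ref$catalytic_positions$position,
                  if (!is.null(hit)) hit$residue_positions)))
  })

  core_len <- sample(cfg$core_protein_length_range[1]:
                       cfg$core_protein_length_range[2], nc, replace = TRUE)
  core_anc <- vapply(core_len, .random_protein, "")
  heg_anc <- lapply(seq_len(cfg$n_loci), function(l) {
    fam <- cfg$family_of_locus[l]
    s <- mutate_protein(refs[[fam]]$protein_seq, cfg$family_divergence)
    .restore_positions(s, refs[[fam]]$protein_seq, protected[[fam]])
  })
  lin_acc <- lapply(seq_len(cfg$n_lineages), function(l) {
    k <- cfg$n_lineage_accessory
    if (k == 0) return(NULL)
    data.frame(fam_id = sprintf("L%dacc%02d", l, seq_len(k)),
               gap = sample.int(nc - 1, k, replace = TRUE),
               len = sample(80:200, k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  lin_acc_anc <- lapply(lin_acc, function(df)
    if (is.null(df)) NULL else vapply(df$len, .random_protein, ""))

  # lineage ancestors
  lin_core <- lapply(seq_len(cfg$n_lineages), function(l)
    unname(vapply(core_anc, mutate_protein, "", rate = cfg$mutation_rate)))
  lin_heg <- lapply(seq_len(cfg$n_lineages), function(l)
    lapply(seq_len(cfg$n_loci), function(k) {
      fam <- cfg$family_of_locus[k]
      s <- mutate_protein(heg_anc[[k]], cfg$mutation_rate)
      .restore_positions(s, refs[[fam]]$protein_seq, protected[[fam]])
    }))

  lineage_of <- rep(seq_len(cfg$n_lineages), length.out = n)
  genome_ids <- sprintf("phi%02d", seq_len(n))

  genomes <- vector("list", n)
  gene_rows <- list()
  for (gi in seq_len(n)) {
    l <- lineage_of[gi]
    gid <- genome_ids[gi]
    # assemble the gene plan: one row per emitted gene, in genome order
    plan <- list()
    deleted <- if (cfg$core_deletion_prob > 0)
      which(c(FALSE, stats::runif(nc - 1) < cfg$core_deletion_prob)) else
      integer()
    acc <- lin_acc[[l]]
    keep_acc <- if (is.null(acc)) integer() else
      which(stats::runif(nrow(acc)) < cfg$lineage_accessory_retention)
    n_priv <- stats::rpois(1, cfg$accessory_gene_rate)
    priv <- if (n_priv > 0)
      data.frame(gap = sample.int(nc - 1, n_priv, replace = TRUE),
                 len = sample(80:200, n_priv, replace = TRUE)) else NULL

    for (r in seq_len(nc)) {
      if (!(r %in% deleted)) {
        prod <- {
          m <- match(r, mod$markers$rank)
          if (!is.na(m)) mod$markers$product[m] else
            sprintf("core protein %02d", r)
        }
        plan[[length(plan) + 1]] <- list(
          protein = mutate_protein(lin_core[[l]][r], cfg$mutation_rate),
          product = prod, role = "core", core_rank = r,
          heg_family = NA, heg_locus = NA, truncated = FALSE,
          strand = if (r == nc) "-" else "+")
      }
      if (r >= nc) next
      gap_genes <- list()
      for (k in which(cfg$locus_positions == r)) {
        if (stats::runif(1) >= cfg$heg_presence_prob) next
        fam <- cfg$family_of_locus[k]
        p <- mutate_protein(lin_heg[[l]][[k]], cfg$mutation_rate)
        p <- .restore_positions(p, refs[[fam]]$protein_seq,
                                protected[[fam]])
        truncated <- stats::runif(1) < cfg$truncation_prob
        if (truncated) {
          keep <- max(10L, round(stats::runif(1, 0.20, 0.55) * nchar(p)))
          p <- substring(p, 1, keep)
        }
        gap_genes[[length(gap_genes) + 1]] <- list(
          protein = p, product = "HNH endonuclease", role = "heg",
          core_rank = NA, heg_family = fam, heg_locus = k,
          truncated = truncated, strand = "+")
      }
      for (a in keep_acc[acc$gap[keep_acc] == r]) {
        gap_genes[[length(gap_genes) + 1]] <- list(
          protein = mutate_protein(lin_acc_anc[[l]][a], cfg$mutation_rate),
          product = "hypothetical protein", role = "accessory",
          core_rank = NA, heg_family = NA, heg_locus = NA,
          truncated = FALSE, strand = "+")
      }
      if (!is.null(priv)) for (pr in which(priv$gap == r)) {
        gap_genes[[length(gap_genes) + 1]] <- list(
          protein = .random_protein(priv$len[pr]),
          product = "hypothetical protein", role = "accessory",
          core_rank = NA, heg_family = NA, heg_locus = NA,
          truncated = FALSE, strand = "+")
      }
      if (length(gap_genes) > 1)
        gap_genes <- gap_genes[sample.int(length(gap_genes))]
      plan <- c(plan, gap_genes)
    }

    # lay the genes onto a sequence with random intergenic spacers
    seq_parts <- character()
    pos <- 0L
    rows <- vector("list", length(plan))
    for (i in seq_along(plan)) {
      spacer <- .random_dna(sample(5:20, 1))
      seq_parts <- c(seq_parts, spacer)
      pos <- pos + nchar(spacer)
      cds <- .back_translate(plan[[i]]$protein)
      emitted <- if (plan[[i]]$strand == "-") .revcomp(cds) else cds
      seq_parts <- c(seq_parts, emitted)
      start <- pos
      pos <- pos + nchar(cds)
      tag <- sprintf("%s_%03d", gid, i)
      rows[[i]] <- data.frame(
        gene_id = paste0(gid, "|", tag), start = start, end = pos,
        strand = plan[[i]]$strand, protein_seq = plan[[i]]$protein,
        product = plan[[i]]$product, stringsAsFactors = FALSE)
    }
    seq_parts <- c(seq_parts, .random_dna(sample(5:20, 1)))
    genes <- do.call(rbind, rows)
    g <- phage_genome(gid, paste(seq_parts, collapse = ""), genes,
                      metadata = list(
                        starter = sprintf("SM%d", l),
                        factory = sprintf("F%d", sample.int(4, 1)),
                        year = sample(2020:2024, 1)))
    genomes[[gi]] <- g
    gene_rows[[gi]] <- data.frame(
      gene_id = genes$gene_id, genome_id = gid,
      role = vapply(plan, `[[`, "", "role"),
      core_rank = vapply(plan, function(x)
        if (is.na(x$core_rank[1])) NA_integer_ else as.integer(x$core_rank),
        0L),
      heg_family = vapply(plan, function(x)
        if (is.na(x$heg_family[1])) NA_character_ else x$heg_family, ""),
      heg_locus = vapply(plan, function(x)
        if (is.na(x$heg_locus[1])) NA_integer_ else as.integer(x$heg_locus),
        0L),
      is_truncated = vapply(plan, `[[`, TRUE, "truncated"),
      stringsAsFactors = FALSE)
  }
  names(genomes) <- genome_ids

  truth <- list(
    genomes = data.frame(
      genome_id = genome_ids, lineage = lineage_of,
      starter = sprintf("SM%d", lineage_of),
      factory = vapply(genomes, function(g) g$metadata$factory, ""),
      year = vapply(genomes, function(g) as.integer(g$metadata$year), 0L),
      stringsAsFactors = FALSE),
    genes = do.call(rbind, gene_rows),
    loci = if (cfg$n_loci > 0) data.frame(
      locus = seq_len(cfg$n_loci),
      gap_after_rank = cfg$locus_positions,
      family = cfg$family_of_locus,
      module = mod$module_of_rank[cfg$locus_positions],
      stringsAsFactors = FALSE) else
      data.frame(locus = integer(), gap_after_rank = integer(),
                 family = character(), module = character()),
    modules = data.frame(rank = seq_len(nc),
                         module = mod$module_of_rank,
                         stringsAsFactors = FALSE),
    config = cfg)
  list(genomes = genomes, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.gbk` (all genomes, GenBank flat file), `metadata.tsv`, and
#' truth tables `truth_genes.tsv` / `truth_loci.tsv`.
#'
#' @param cohort result of [simulate_phage_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genbank(cohort$genomes, file.path(dir, "cohort.gbk"))
  write_metadata(cohort$genomes, file.path(dir, "metadata.tsv"))
  write.table(cohort$truth$genes, file.path(dir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  write.table(cohort$truth$loci, file.path(dir, "truth_loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(dir)
}
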