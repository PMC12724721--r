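# In-code fixtures: toy genomes/partitions for the scaffold and anchoring
# logic, random protein families, additive trees, and small GenBank text.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                    collapse = "")

mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  paste(chars, collapse = "")
}

# a genome whose genes are placeholders for ortholog-cluster members;
# cluster_seq entries are cluster ids (or NA for unclustered accessory)
toy_genome <- function(genome_id, cluster_seq, strands = NULL,
                       products = NULL) {
  k <- length(cluster_seq)
  if (is.null(strands)) strands <- rep("+", k)
  if (is.null(products)) products <- rep("hypothetical protein", k)
  starts <- seq(10L, by = 40L, length.out = k)
  genes <- data.frame(
    gene_id = sprintf("%s|g%02d", genome_id, seq_len(k)),
    start = starts, end = starts + 30L, strand = strands,
    protein_seq = rep("MKVAL", k), product = products,
    stringsAsFactors = FALSE)
  phage_genome(genome_id,
               paste(rep("ACGT", (max(starts) + 40) / 4 + 10), collapse = ""),
               genes)
}

# ortholog_partition from an explicit gene -> cluster mapping
toy_partition <- function(membership) {
  clusters <- lapply(split(names(membership), membership), sort)
  ord <- order(-vapply(clusters, length, 0L), vapply(clusters, `[`, "", 1L))
  clusters <- clusters[ord]
  # keep the caller's cluster ids rather than renumbering
  structure(list(clusters = clusters, membership = membership,
                 converged = TRUE, n_iter = 0L),
            class = "ortholog_partition")
}

# membership vector for a list of toy genomes built with toy_genome():
# cluster of gene i of genome g = cluster_seq[[g]][i]
toy_membership <- function(genomes, cluster_seqs) {
  out <- character()
  for (g in seq_along(genomes)) {
    ids <- genomes[[g]]$genes$gene_id
    cl <- cluster_seqs[[g]]
    keep <- !is.na(cl)
    out <- c(out, setNames(cl[keep], ids[keep]))
  }
  out
}

random_additive_tree <- function(n) {
  ape::rtree(n, rooted = FALSE, br = function(nb) runif(nb, 0.1, 2))
}

# small hand-written GenBank record text
toy_genbank_text <- function() {
  c("LOCUS       toyphage                 600 bp    DNA     linear   PHG 01-JAN-2026",
    "DEFINITION  toy phage.",
    "ACCESSION   toyphage",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "                     /organism=\"toy phage\"",
    "     CDS             101..160",
    "                     /locus_tag=\"t1\"",
    "                     /product=\"terminase large subunit\"",
    "                     /translation=\"MKVALKVALKVALKVALKV\"",
    "     CDS             complement(201..260)",
    "                     /locus_tag=\"t2\"",
    "                     /product=\"portal protein\"",
    "                     /translation=\"MWYRAWYRAWYRAWYRAWY\"",
    "ORIGIN",
    vapply(seq(1, 600, by = 60), function(p)
      sprintf("%9d %s", p, paste(rep("acgtacgtac", 6), collapse = " ")), ""),
    "//")
}

# random scaffold guaranteed free of spacing-compatible motif triples:
# H and N excluded entirely
.rand_no_motif <- function(len) {
  if (len == 0) return("")
  paste(sample(setdiff(AA20, c("H", "N")), len, replace = TRUE),
        collapse = "")
}
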