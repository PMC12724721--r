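test_that("HEG anchoring walks to the nearest core genes", {
  seqs <- list(c("c05", "HEG", "c06"))
  g <- toy_genome("G1", seqs[[1]])
  memb <- toy_membership(list(g), seqs)
  part <- toy_partition(memb)
  core <- c("c05", "c06")
  a <- anchor_heg(g, "G1|g02", core, part)
  expect_equal(a$upstream_core, "c05")
  expect_equal(a$downstream_core, "c06")
  expect_equal(a$intervening_upstream, 0L)
  expect_equal(a$intervening_downstream, 0L)

  seqs2 <- list(c("c05", "acc1", "acc2", "HEG", "c06"))
  g2 <- toy_genome("G2", seqs2[[1]])
  part2 <- toy_partition(toy_membership(list(g2), seqs2))
  a2 <- anchor_heg(g2, "G2|g04", c("c05", "c06"), part2)
  expect_equal(a2$intervening_upstream, 2L)
  expect_equal(a2$intervening_downstream, 0L)

  # terminus on the left
  seqs3 <- list(c("HEG", "acc", "c05"))
  g3 <- toy_genome("G3", seqs3[[1]])
  part3 <- toy_partition(toy_membership(list(g3), seqs3))
  a3 <- anchor_heg(g3, "G3|g01", "c05", part3)
  expect_equal(a3$upstream_core, "terminus")
  expect_equal(a3$downstream_core, "c05")

  expect_error(anchor_heg(g, "G1|g01", core, part), "core and mobile")
  expect_error(anchor_heg(g, "G1|g02", character(), part), "empty")
})

test_that("the GVE2-family HEG anchors between terminase and portal", {
  sim <- simulate_phage_cohort(synthetic_config(
    n_genomes = 8, n_core = 10, n_loci = 2, n_lineages = 2,
    heg_presence_prob = 1, truncation_prob = 0, seed = 51))
  stopifnot(sim$truth$loci$family[1] == "GVE2",
            sim$truth$loci$gap_after_rank[1] == 1)
  pr <- cohort_proteins(sim$genomes)
  part <- mcl(all_vs_all_similarity(pr), nodes = names(pr))
  terl <- find_cluster_by_product(part, sim$genomes,
                                  "terminase large subunit")
  portal <- find_cluster_by_product(part, sim$genomes, "portal protein")
  asn <- classify_cohort(sim$genomes)
  core <- identify_core_clusters(
    part, sim$genomes,
    exclude_genes = asn$gene_id[asn$family != "UNCLASSIFIED"])
  gve2 <- asn$gene_id[asn$family == "GVE2"]
  for (id in gve2) {
    g <- sim$genomes[[asn$genome_id[asn$gene_id == id]]]
    a <- anchor_heg(g, id, core, part)
    expect_equal(a$upstream_core, terl)
    expect_equal(a$downstream_core, portal)
  }
})

test_that("anchors group into loci ordered along the scaffold", {
  ord <- sprintf("c%02d", 1:12)
  anchors <- data.frame(
    gene_id = sprintf("h%d", 1:5),
    genome_id = "G1",
    family = c("IHMU", "IHMU", "IHMU", "PACI", "PACI"),
    upstream_core = c("c09", "c09", "c05", "c05", "c09"),
    downstream_core = c("c10", "c10", "c06", "c06", "c10"),
    intervening_upstream = 0L, intervening_downstream = 0L,
    stringsAsFactors = FALSE)
  sc <- structure(list(ordered_core = ord,
                       module_of = setNames(rep("unassigned", 12), ord),
                       anchor = "c01",
                       outliers = data.frame()), class = "core_scaffold")
  asn <- data.frame(gene_id = anchors$gene_id, family = anchors$family,
                    stringsAsFactors = FALSE)
  res <- consolidate_loci(anchors, sc, asn)
  expect_equal(res$loci$locus_id, c("H1", "H2"))
  expect_equal(res$loci$upstream_core, c("c05", "c09"))
  expect_equal(res$loci$n_IHMU, c(1L, 2L))
  expect_equal(res$loci$n_PACI, c(1L, 1L))
})

test_that("nested flank pairs merge by containment", {
  ord <- sprintf("c%02d", 1:8)
  anchors <- data.frame(
    gene_id = c("h1", "h2", "h3"), genome_id = "G",
    family = "IHMU",
    upstream_core = c("c05", "c05", "c05"),
    downstream_core = c("c06", "c07", "c06"),  # c06 lost in one genome
    intervening_upstream = 0L, intervening_downstream = 0L,
    stringsAsFactors = FALSE)
  sc <- structure(list(ordered_core = ord,
                       module_of = setNames(rep("unassigned", 8), ord),
                       anchor = "c01", outliers = data.frame()),
                  class = "core_scaffold")
  asn <- data.frame(gene_id = anchors$gene_id, family = "IHMU",
                    stringsAsFactors = FALSE)
  res <- consolidate_loci(anchors, sc, asn)
  expect_equal(nrow(res$loci), 1)
  expect_equal(res$loci$n_IHMU, 3L)
  expect_equal(res$loci$upstream_core, "c05")
  expect_equal(res$loci$downstream_core, "c06")

  bad <- anchors; bad$upstream_core[1] <- "zz"
  expect_error(consolidate_loci(bad, sc, asn), "unknown cluster")
})

test_that("planted loci are recovered under sporadic core deletion", {
  sim <- simulate_phage_cohort(synthetic_config(
    n_genomes = 12, n_core = 12, n_loci = 3, n_lineages = 3,
    core_deletion_prob = 0.08, seed = 52))
  pr <- cohort_proteins(sim$genomes)
  part <- mcl(all_vs_all_similarity(pr), nodes = names(pr))
  asn <- classify_cohort(sim$genomes)
  core <- identify_core_clusters(
    part, sim$genomes, presence_fraction = 0.75,
    exclude_genes = asn$gene_id[asn$family != "UNCLASSIFIED"])
  anchor <- find_cluster_by_product(part, sim$genomes,
                                    "terminase large subunit")
  sc <- consensus_core_order(sim$genomes, part, core, anchor)
  anchors <- cohort_anchors(sim$genomes, asn, core, part)
  res <- consolidate_loci(anchors, sc, asn)
  tg <- sim$truth$genes
  present_loci <- sort(unique(tg$heg_locus[tg$role == "heg" &
                                             !tg$is_truncated]))
  expect_equal(nrow(res$loci), length(present_loci))
  # memberships: every intact HEG is in exactly one locus, matching truth
  members <- strsplit(res$loci$members, ",")
  expect_equal(sum(lengths(members)), length(unique(unlist(members))))
  got_by_locus <- lapply(members, function(m)
    sort(intersect(m, tg$gene_id[!tg$is_truncated & tg$role == "heg"])))
  truth_by_locus <- lapply(present_loci, function(l)
    sort(tg$gene_id[tg$role == "heg" & !tg$is_truncated &
                      tg$heg_locus == l]))
  expect_equal(partition_canon(got_by_locus),
               partition_canon(truth_by_locus))
})

test_that("locus ids are stable under genome input order permutation", {
  sim <- simulate_phage_cohort(synthetic_config(
    n_genomes = 8, n_core = 10, n_loci = 3, n_lineages = 2, seed = 53))
  run <- function(genomes) {
    pr <- cohort_proteins(genomes)
    part <- mcl(all_vs_all_similarity(pr), nodes = names(pr))
    asn <- classify_cohort(genomes)
    core <- identify_core_clusters(
      part, genomes,
      exclude_genes = asn$gene_id[asn$family != "UNCLASSIFIED"])
    anchor <- find_cluster_by_product(part, genomes,
                                      "terminase large subunit")
    sc <- consensus_core_order(genomes, part, core, anchor)
    consolidate_loci(cohort_anchors(genomes, asn, core, part), sc, asn)$loci
  }
  l1 <- run(sim$genomes)
  set.seed(1)
  l2 <- run(sim$genomes[sample(length(sim$genomes))])
  expect_equal(l1$locus_id, l2$locus_id)
  expect_equal(sort(l1$members), sort(l2$members))
})

test_that("flank-to-reference DNA comparison reports identity and coverage", {
  set.seed(54)
  gene <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  r <- compare_flank_to_reference(gene, gene)
  expect_equal(r$pct_identity, 100)
  expect_equal(r$coverage, 1.0)

  # randomise 20% of codons; identity close to an independent DP aligner
  codons <- substring(gene, seq(1, 298, 3), seq(3, 300, 3))
  idx <- sample(100, 20)
  codons[idx] <- vapply(idx, function(i)
    paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = ""),
    "")
  mutated <- paste(codons, collapse = "")
  r2 <- compare_flank_to_reference(mutated, gene)
  dna_sub <- matrix(-3, 5, 5, dimnames = list(c("A","C","G","T","N"),
                                              c("A","C","G","T","N")))
  diag(dna_sub) <- 2; dna_sub["N", ] <- 0; dna_sub[, "N"] <- 0
  ref <- oracle_align(mutated, gene, dna_sub, 5, 2, local = TRUE)
  expect_lte(abs(r2$pct_identity - ref$pct_identity), 2)

  # 30% shared prefix: coverage reported, not filtered
  part30 <- paste0(substring(gene, 1, 90),
                   paste(sample(c("A","C","G","T"), 210, replace = TRUE),
                         collapse = ""))
  r3 <- compare_flank_to_reference(part30, gene)
  expect_lt(abs(r3$coverage - 0.3), 0.1)
  expect_error(compare_flank_to_reference("", gene), "empty")
})
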