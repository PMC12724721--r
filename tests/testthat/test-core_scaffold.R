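test_that("core clusters are single-copy families present in all genomes", {
  # OC1 core; OC2 duplicated in G2; OC3 missing from G2
  g1 <- toy_genome("G1", c("OC1", "OC2", "OC3"))
  g2 <- toy_genome("G2", c("OC1", "OC2", "OC2x"))
  seqs <- list(c("OC1", "OC2", "OC3"), c("OC1", "OC2", "OC2"))
  part <- toy_partition(toy_membership(list(g1, g2), seqs))
  genomes <- list(g1, g2)
  expect_equal(identify_core_clusters(part, genomes), "OC1")
  # duplicated cluster admitted when single_copy is off and threshold lowered
  expect_setequal(identify_core_clusters(part, genomes,
                                         presence_fraction = 0.5,
                                         single_copy = FALSE),
                  c("OC1", "OC2", "OC3"))
  # presence_fraction = 0 returns every cluster (no multi-copy here)
  g3 <- toy_genome("G3", c("OC1", "OC3"))
  part3 <- toy_partition(toy_membership(list(g1, g3),
                                        list(c("OC1", "OC2", "OC3"),
                                             c("OC1", "OC3"))))
  expect_setequal(identify_core_clusters(part3, list(g1, g3),
                                         presence_fraction = 0),
                  c("OC1", "OC2", "OC3"))
  expect_no_error(identify_core_clusters(part, genomes))
  expect_error(identify_core_clusters(toy_partition(
    toy_membership(list(g2), list(c("OC2", "OC2", "OC2")))), list(g2)),
    "relaxing")
})

test_that("planted core families are recovered exactly on a cohort", {
  sim <- simulate_phage_cohort(synthetic_config(
    n_genomes = 8, n_core = 12, n_loci = 2, n_lineages = 2, seed = 21))
  pr <- cohort_proteins(sim$genomes)
  part <- mcl(all_vs_all_similarity(pr), nodes = names(pr))
  core <- identify_core_clusters(part, sim$genomes)
  truth_core_genes <- sim$truth$genes$gene_id[sim$truth$genes$role == "core"]
  got_core_genes <- names(part$membership)[part$membership %in% core]
  expect_setequal(got_core_genes, truth_core_genes)
  expect_length(core, 12)
})

test_that("consensus core order is unanimous on concordant genomes", {
  ord <- sprintf("c%02d", 1:6)
  gs <- lapply(sprintf("G%d", 1:5), toy_genome, cluster_seq = ord)
  part <- toy_partition(toy_membership(gs, rep(list(ord), 5)))
  sc <- consensus_core_order(gs, part, ord, anchor = "c01")
  expect_equal(sc$ordered_core, ord)
  expect_equal(nrow(sc$outliers), 0)
  expect_error(consensus_core_order(gs, part, ord, anchor = "nope"),
               "not in the core set")
})

test_that("a planted inversion is reported as an outlier with breakpoints", {
  ord <- sprintf("c%02d", 1:8)
  inv <- ord; inv[4:5] <- inv[5:4]
  seqs <- c(rep(list(ord), 6), list(inv))
  gs <- mapply(toy_genome, sprintf("G%d", 1:7), seqs, SIMPLIFY = FALSE)
  part <- toy_partition(toy_membership(gs, seqs))
  sc <- consensus_core_order(gs, part, ord, anchor = "c01")
  expect_equal(sc$ordered_core, ord)
  expect_equal(sc$outliers$genome_id, "G7")
  # a 2-gene inversion breaks 3 adjacencies of the consensus
  expect_equal(sc$outliers$breakpoints, 3L)
})

test_that("consensus order is invariant to genome input order and rotation", {
  ord <- sprintf("c%02d", 1:6)
  rot <- function(x, k) x[c((k + 1):length(x), 1:k)]
  seqs <- list(ord, rot(ord, 2), rot(ord, 4))
  gs <- mapply(toy_genome, sprintf("G%d", 1:3), seqs, SIMPLIFY = FALSE)
  part <- toy_partition(toy_membership(gs, seqs))
  sc1 <- consensus_core_order(gs, part, ord, anchor = "c01")
  sc2 <- consensus_core_order(rev(gs), part, ord, anchor = "c01")
  expect_equal(sc1$ordered_core, ord)
  expect_equal(sc2$ordered_core, ord)
})

test_that("module labels follow the nearest-marker midpoint rule", {
  ord <- sprintf("c%02d", 1:25)
  gs <- list(toy_genome("G1", ord))
  part <- toy_partition(toy_membership(gs, list(ord)))
  sc <- consensus_core_order(gs, part, ord, anchor = "c01")
  sc <- assign_functional_modules(sc, list(morphogenesis = "c01",
                                           replication = "c15"))
  # markers at ranks 1 and 15: midpoint 8 -> 1..7 morphogenesis, 8..25 repl
  expect_equal(unname(sc$module_of[1:7]), rep("morphogenesis", 7))
  expect_equal(unname(sc$module_of[8:25]), rep("replication", 18))
  expect_false(any(sc$module_of == "regulation"))
  expect_error(assign_functional_modules(sc, list(replication = "zz")),
               "not in the core scaffold")
})

test_that("planted module labels are recovered on a cohort", {
  sim <- simulate_phage_cohort(synthetic_config(
    n_genomes = 6, n_core = 15, n_loci = 2, n_lineages = 2, seed = 23))
  pr <- cohort_proteins(sim$genomes)
  part <- mcl(all_vs_all_similarity(pr), nodes = names(pr))
  core <- identify_core_clusters(part, sim$genomes)
  anchor <- find_cluster_by_product(part, sim$genomes,
                                    "terminase large subunit")
  sc <- consensus_core_order(sim$genomes, part, core, anchor)
  sc <- assign_functional_modules(
    sc, default_marker_map(part, sim$genomes, core))
  # map consensus rank -> truth rank through any one genome
  tg <- sim$truth$genes
  g1 <- sim$genomes[[1]]
  cl_of_rank <- part$membership[
    tg$gene_id[tg$genome_id == g1$genome_id & tg$role == "core"]]
  names(cl_of_rank) <- tg$core_rank[tg$genome_id == g1$genome_id &
                                      tg$role == "core"]
  truth_mod <- setNames(sim$truth$modules$module, sim$truth$modules$rank)
  for (r in names(cl_of_rank))
    expect_equal(unname(sc$module_of[cl_of_rank[[r]]]),
                 unname(truth_mod[[r]]))
})
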