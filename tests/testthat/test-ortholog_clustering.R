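test_that("similarity edges pass identity and bidirectional coverage gates", {
  set.seed(41)
  a <- rand_protein(100)
  prots <- c(g1 = a, g2 = a)
  edges <- all_vs_all_similarity(prots)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$pct_identity, 100)
  expect_equal(edges$cov_a, 1.0)
  expect_equal(edges$cov_b, 1.0)

  # B embedded exactly in A: cov of the long sequence is 0.3 < 0.5
  b <- rand_protein(60)
  a_long <- paste0(rand_protein(70), b, rand_protein(70))
  edges2 <- all_vs_all_similarity(c(gA = a_long, gB = b))
  expect_equal(nrow(edges2), 0)

  expect_error(all_vs_all_similarity(c(g1 = "MKV", g2 = "MK9")), "g2")
  expect_error(all_vs_all_similarity(c(x = "MKVL")), "at least two")
})

test_that("aligner agrees with the independent DP oracle on random pairs", {
  set.seed(42)
  sub <- oracle_sub_protein()
  for (i in 1:12) {
    a <- rand_protein(sample(40:90, 1))
    b <- if (i %% 3 == 0) mutate_seq(a, runif(1, 0.1, 0.6)) else
      rand_protein(sample(40:90, 1))
    for (local in c(TRUE, FALSE)) {
      mine <- align_pair(a, b, type = if (local) "local" else "global")
      ref <- oracle_align(a, b, sub, 10, 0.5, local)
      expect_equal(mine$score, ref$score)
      expect_equal(mine$n_match, ref$n_match)
      expect_equal(mine$align_len, ref$align_len)
      expect_equal(mine$pct_identity, ref$pct_identity)
      expect_equal(mine$cov_a, ref$cov_a)
      expect_equal(mine$cov_b, ref$cov_b)
    }
  }
})

test_that("similarity is symmetric in the sequence pair", {
  set.seed(43)
  a <- rand_protein(80)
  b <- mutate_seq(a, 0.3)
  r1 <- align_pair(a, b)
  r2 <- align_pair(b, a)
  expect_equal(r1$score, r2$score)
  expect_equal(r1$pct_identity, r2$pct_identity)
  expect_equal(r1$cov_a, r2$cov_b)
  expect_equal(r1$cov_b, r2$cov_a)
})

test_that("mcl separates disjoint cliques and leaves isolated nodes single", {
  clique_edges <- function(ids, score = 100) {
    p <- t(combn(ids, 2))
    data.frame(a = p[, 1], b = p[, 2], score = score,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(clique_edges(c("a1", "a2", "a3")),
                 clique_edges(c("b1", "b2", "b3")))
  part <- mcl(edges)
  expect_equal(partition_canon(part$clusters),
               c("a1,a2,a3", "b1,b2,b3"))

  part2 <- mcl(data.frame(a = character(), b = character(),
                          score = numeric()),
               nodes = c("n1", "n2", "n3", "n4"))
  expect_length(part2$clusters, 4)
  expect_true(all(lengths(part2$clusters) == 1))

  # clique = component across the inflation range
  edges3 <- rbind(clique_edges(letters[1:4]), clique_edges(c("x", "y")),
                  clique_edges(c("p", "q", "r", "s", "t")))
  for (infl in c(1.5, 2, 3, 4)) {
    p3 <- mcl(edges3, inflation = infl)
    expect_equal(partition_canon(p3$clusters),
                 c("a,b,c,d", "p,q,r,s,t", "x,y"))
  }
  expect_error(mcl(edges3, inflation = 1), "inflation")
})

test_that("mcl output is a partition of the node set", {
  set.seed(44)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    ids <- sprintf("n%02d", 1:n)
    m <- sample(5:30, 1)
    ab <- t(replicate(m, sample(ids, 2)))
    edges <- unique(data.frame(a = pmin(ab[, 1], ab[, 2]),
                               b = pmax(ab[, 1], ab[, 2]),
                               stringsAsFactors = FALSE))
    edges$score <- runif(nrow(edges), 10, 100)
    part <- mcl(edges, nodes = ids)
    expect_setequal(unlist(part$clusters), ids)
    expect_equal(sum(lengths(part$clusters)), n)
    expect_equal(sort(names(part$membership)), sort(ids))
  }
})

test_that("gene content matrix counts genes per genome and cluster", {
  g1 <- toy_genome("G1", c("OC1", "OC2"))
  g2 <- toy_genome("G2", c("OC1", "OC3"))
  part <- toy_partition(toy_membership(list(g1, g2),
                                       list(c("OC1", "OC2"),
                                            c("OC1", "OC3"))))
  m <- build_gene_content_matrix(part, list(g1, g2))
  expect_equal(m[c("G1", "G2"), c("OC1", "OC2", "OC3")],
               matrix(c(1L, 1L, 1L, 0L, 0L, 1L), 2, 3,
                      dimnames = list(c("G1", "G2"), c("OC1", "OC2", "OC3"))))

  bad <- toy_partition(c(`GX|g01` = "OC9"))
  expect_error(build_gene_content_matrix(bad, list(g1, g2)), "not found")
})

test_that("row sums of the gene-content matrix equal genome gene counts", {
  sim <- simulate_phage_cohort(synthetic_config(
    n_genomes = 6, n_core = 10, n_loci = 2, n_lineages = 2, seed = 5))
  pr <- cohort_proteins(sim$genomes)
  part <- mcl(all_vs_all_similarity(pr), nodes = names(pr))
  m <- build_gene_content_matrix(part, sim$genomes)
  counts <- vapply(sim$genomes, function(g) nrow(g$genes), 0L)
  expect_equal(rowSums(m)[names(counts)], counts)
  # planted core families are one column each summing to n_genomes
  core <- identify_core_clusters(part, sim$genomes)
  expect_true(all(colSums(m)[core] == length(sim$genomes)))
})

test_that("two-way HCL recovers planted lineages and is order-invariant", {
  sim <- simulate_phage_cohort(synthetic_config(
    n_genomes = 12, n_core = 10, n_loci = 2, n_lineages = 3, seed = 6))
  pr <- cohort_proteins(sim$genomes)
  part <- mcl(all_vs_all_similarity(pr), nodes = names(pr))
  m <- build_gene_content_matrix(part, sim$genomes)
  cl <- two_way_hcl(m, k = 3)
  truth <- setNames(sim$truth$genomes$starter, sim$truth$genomes$genome_id)
  expect_equal(length(unique(cl$labels)), 3)
  # identical partitions up to label names
  expect_equal(partition_canon(split(names(cl$labels), cl$labels)),
               partition_canon(split(names(truth), truth)))

  set.seed(9)
  perm <- sample(nrow(m))
  cl2 <- two_way_hcl(m[perm, ], k = 3)
  expect_equal(cl2$labels, cl$labels)

  # boundaries
  expect_error(two_way_hcl(m, k = 0), "k must be")
  expect_error(two_way_hcl(m, k = nrow(m) + 1), "cannot exceed")
  cln <- two_way_hcl(m, k = nrow(m))
  expect_equal(length(unique(cln$labels)), nrow(m))
})

test_that("genomes with identical presence vectors merge at height zero", {
  m <- rbind(A = c(1L, 1L, 0L), B = c(1L, 1L, 0L), C = c(0L, 1L, 1L))
  colnames(m) <- c("OC1", "OC2", "OC3")
  cl <- two_way_hcl(m, k = 2)
  expect_equal(cl$labels[["A"]], cl$labels[["B"]])
  expect_equal(min(cl$row_hclust$height), 0)
})
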