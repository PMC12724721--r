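test_that("p-distances follow the gap-excluded definition", {
  prots <- c(a = "MKVLWAAG", b = "MKVLWAAG", c = "MKVLWAAT")
  D <- pairwise_distance_matrix(prots)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1 / 8)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), setNames(rep(0, 3), names(prots)))

  # 10 differing among 100 aligned, gap-free columns
  set.seed(61)
  x <- rand_protein(100)
  y <- x
  idx <- sample(100, 10)
  for (i in idx) substring(y, i, i) <- sample(setdiff(AA20,
                                               substring(x, i, i)), 1)
  D2 <- pairwise_distance_matrix(c(a = x, b = y, c = x), aligned = TRUE)
  expect_equal(D2["a", "b"], 0.10)
  expect_error(pairwise_distance_matrix(c(a = x, b = y)), "at least 3")
})

test_that("pairwise distances equal an independent aligner's recomputation", {
  set.seed(62)
  anc <- rand_protein(60)
  fam <- setNames(c(anc, replicate(7, mutate_seq(anc, runif(1, 0.05, 0.3)))),
                  sprintf("s%d", 1:8))
  D <- pairwise_distance_matrix(fam)
  sub <- oracle_sub_protein()
  for (i in 1:7) for (j in (i + 1):8) {
    r <- oracle_align(fam[[i]], fam[[j]], sub, 10, 0.5, local = FALSE)
    expect_equal(D[i, j], 1 - r$n_match / r$align_len, tolerance = 1e-12)
  }
})

test_that("NJ resolves three taxa by the closed-form star", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd[rownames(D), colnames(D)], D, tolerance = 1e-12)
  # a = (d12 + d13 - d23)/2 = 1
  edge_of <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(edge_of["A"]), 1)
  expect_equal(unname(edge_of["B"]), 2)
  expect_equal(unname(edge_of["C"]), 3)
})

test_that("NJ recovers a known additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)) -> path metric
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 3
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 4
  D["C", "D"] <- D["D", "C"] <- 4
  tr <- neighbor_joining(D)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-12)
  truth <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), truth)), 0)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ leaf path lengths reproduce any additive 5-taxon metric", {
  set.seed(63)
  for (rep in 1:5) {
    tr0 <- random_additive_tree(5)
    D <- ape::cophenetic.phylo(tr0)
    tr <- neighbor_joining(D)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
})

test_that("bootstrap saturates on well-separated clades and is seed-stable", {
  set.seed(64)
  cladeA <- rand_protein(120)
  cladeB <- mutate_seq(cladeA, 0.6)
  aln <- c(a1 = cladeA, a2 = mutate_seq(cladeA, 0.03),
           a3 = mutate_seq(cladeA, 0.03),
           b1 = cladeB, b2 = mutate_seq(cladeB, 0.03),
           b3 = mutate_seq(cladeB, 0.03))
  bs <- bootstrap_support(aln, n_replicates = 100, seed = 7)
  # the a|b bipartition is an internal edge with full support
  lab <- bs$tree$node.label
  expect_true(any(lab == "100", na.rm = TRUE))
  bs2 <- bootstrap_support(aln, n_replicates = 100, seed = 7)
  expect_identical(bs$supports, bs2$supports)
  expect_identical(ape::write.tree(bs$tree), ape::write.tree(bs2$tree))
  expect_error(bootstrap_support(aln, n_replicates = 0, seed = 1), ">= 1")
  expect_error(bootstrap_support(c(a = "MK", b = "MKV", c = "M"),
                                 n_replicates = 1, seed = 1),
               "equal-length")
})

test_that("bootstrap supports are invariant to leaf input order", {
  set.seed(65)
  anc <- rand_protein(100)
  aln <- setNames(vapply(1:5, function(i) mutate_seq(anc, 0.1), ""),
                  sprintf("t%d", 1:5))
  b1 <- bootstrap_support(aln, n_replicates = 50, seed = 3)
  b2 <- bootstrap_support(aln[c(3, 1, 5, 2, 4)], n_replicates = 50, seed = 3)
  key <- function(b) {
    tr <- b$tree
    ntip <- length(tr$tip.label)
    vapply((ntip + 2):(ntip + tr$Nnode), function(nd) {
      tips <- sort(ape::extract.clade(tr, nd)$tip.label)
      paste(paste(tips, collapse = ","), tr$node.label[nd - ntip])
    }, "")
  }
  expect_setequal(key(b1), key(b2))
})

test_that("tree clusters honour the leaf-distance cut", {
  set.seed(66)
  anc <- rand_protein(150)
  lin <- replicate(3, mutate_seq(anc, 0.25))
  prots <- setNames(unlist(lapply(1:3, function(l)
    replicate(4, mutate_seq(lin[l], 0.03)))),
    sprintf("L%d_%d", rep(1:3, each = 4), rep(1:4, 3)))
  tr <- neighbor_joining(pairwise_distance_matrix(prots, aligned = TRUE))

  one <- extract_tree_clusters(tr, cut_distance = 10)
  expect_equal(length(unique(one$labels)), 1)

  singles <- extract_tree_clusters(tr, cut_distance = 1e-9)
  expect_equal(length(unique(singles$labels)), length(prots))

  mid <- extract_tree_clusters(tr, cut_distance = 0.25)
  expect_equal(length(unique(mid$labels)), 3)
  expect_equal(partition_canon(split(names(mid$labels), mid$labels)),
               partition_canon(split(names(prots),
                                     sub("_.*", "", names(prots)))))
  # roman numerals, largest first, and a partition of the leaves
  expect_setequal(names(mid$labels), names(prots))
  expect_error(extract_tree_clusters(tr, 0), "> 0")
})

test_that("association test matches closed forms and permutation logic", {
  a <- rep(c("x", "y"), each = 10)
  r <- association_test(a, a, n_perm = 200, seed = 5)
  expect_equal(r$cramers_v, 1)
  expect_equal(r$p_value, 1 / 201)

  # 2x2 table [[10,0],[0,10]] via distinct label alphabets
  b <- rep(c("p", "q"), each = 10)
  expect_equal(association_test(a, b, n_perm = 10, seed = 1)$cramers_v, 1)

  expect_error(association_test(rep("x", 10), rep(c("u", "v"), 5)),
               "single category")
  lab1 <- setNames(a, sprintf("i%02d", 1:20))
  expect_error(association_test(lab1, setNames(b, sprintf("j%02d", 1:20))),
               "different item sets")
})
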