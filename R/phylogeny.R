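# Distance-based phylogenetics for HNHE families: gap-excluded p-distances
# from pairwise global alignments (or from a supplied multiple alignment),
# Saitou-Nei neighbour joining with deterministic tie-breaks, bootstrap
# support by column resampling (MSA mode), leaf-distance cluster extraction,
# and a permutation test for cluster-metadata association.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# gap-excluded p-distance between two aligned rows (character vectors)
.p_dist_cols <- function(x, y) {
  ok <- x != "-" & y != "-"
  if (!any(ok)) return(NA_real_)
  sum(x[ok] != y[ok]) / sum(ok)
}

#' Pairwise distance matrix for a protein family
#'
#' Distances are gap-excluded p-distances (fraction of differing residues
#' among columns where both sequences have a residue), optionally
#' Poisson-corrected (`-log(1 - p)`). With `aligned = TRUE` the sequences
#' must be equal-length rows of a multiple alignment (gap character `-`);
#' otherwise each pair is globally aligned with affine gaps first.
#'
#' @param proteins named character vector (>= 3 sequences).
#' @param aligned are the sequences pre-aligned rows of an MSA?
#' @param model `"p"` (default) or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal, dimnames = sequence
#'   names.
#' @export
pairwise_distance_matrix <- function(proteins, aligned = FALSE,
                                     model = c("p", "poisson")) {
  model <- match.arg(model)
  n <- length(proteins)
  if (n < 3) stop("need at least 3 sequences", call. = FALSE)
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must be uniquely named", call. = FALSE)
  labels <- names(proteins)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (aligned) {
    if (length(unique(nchar(proteins))) != 1)
      stop("aligned sequences must have equal length", call. = FALSE)
    rows <- strsplit(unname(proteins), "", fixed = TRUE)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- .p_dist_cols(rows[[i]], rows[[j]])
  } else {
    sub <- .protein_sub_matrix()
    enc <- lapply(seq_len(n), function(i)
      .encode_seq(proteins[[i]], .AA_LETTERS, what = "sequence",
                  id = labels[i]))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- .align_core(enc[[i]], enc[[j]], sub, 10, 0.5, FALSE)
      both <- !is.na(r$a_idx) & !is.na(r$b_idx)
      d[i, j] <- d[j, i] <- 1 - r$n_match / sum(both)
    }
  }
  if (model == "poisson") {
    off <- row(d) != col(d)
    d[off] <- -log(pmax(1 - d[off], .Machine$double.eps))
  }
  d
}

#' Neighbour-joining tree (Saitou-Nei)
#'
#' Iteratively joins the pair minimising the Q criterion
#' `(r - 2) d_ij - R_i - R_j`; branch lengths come from the standard
#' two-point formulas. Negative branch lengths are clipped to zero with the
#' deficit moved to the sister branch. Ties in Q are broken by the
#' lexicographically smallest pair of subtree labels (smallest leaf label in
#' each subtree), so the result does not depend on input order. The final
#' three nodes are resolved by the three-point formulas, giving the usual
#' unrooted tree with a basal trifurcation.
#'
#' @param D symmetric distance matrix with dimnames (n >= 3).
#' @return an [ape::phylo] tree (unrooted).
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  if (any(!is.finite(D))) stop("non-finite distances", call. = FALSE)

  d <- unname(D)
  newick <- labels           # growing subtree serialisations
  rep_label <- labels        # smallest leaf label per subtree (tie-breaks)
  active <- seq_len(n)

  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 3) {
    r <- length(active)
    dd <- d[active, active]
    R <- rowSums(dd)
    Q <- (r - 2) * dd - outer(R, R, `+`)
    diag(Q) <- Inf
    minQ <- min(Q)
    cand <- which(Q <= minQ + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- vapply(seq_len(nrow(cand)), function(k) {
      a <- rep_label[active[cand[k, 1]]]; b <- rep_label[active[cand[k, 2]]]
      paste(sort(c(a, b)), collapse = "\r")
    }, "")
    pick <- cand[order(keys)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    dij <- d[i, j]
    vi <- dij / 2 + (R[pick[1]] - R[pick[2]]) / (2 * (r - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }

    # new node distances (Saitou-Nei reduction)
    rest <- setdiff(active, c(i, j))
    dnew <- (d[i, rest] + d[j, rest] - dij) / 2
    d <- rbind(d, 0); d <- cbind(d, 0)
    k <- nrow(d)
    d[k, rest] <- dnew; d[rest, k] <- dnew
    newick <- c(newick, sprintf("(%s:%s,%s:%s)", newick[i], fmt(vi),
                                newick[j], fmt(vj)))
    rep_label <- c(rep_label, min(rep_label[i], rep_label[j]))
    active <- c(rest, k)
  }

  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (d[a, b] + d[a, c3] - d[b, c3]) / 2
  vb <- (d[a, b] + d[b, c3] - d[a, c3]) / 2
  vc <- (d[a, c3] + d[b, c3] - d[a, b]) / 2
  if (va < 0) { vb <- vb + va; vc <- vc + va; va <- 0 }
  if (vb < 0) { va <- va + vb; vc <- vc + vb; vb <- 0 }
  if (vc < 0) { va <- va + vc; vb <- vb + vc; vc <- 0 }
  # deterministic serialisation: children ordered by representative label
  parts <- data.frame(nw = newick[c(a, b, c3)], v = c(va, vb, vc),
                      key = rep_label[c(a, b, c3)], stringsAsFactors = FALSE)
  parts <- parts[order(parts$key), ]
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", parts$nw[1], fmt(parts$v[1]),
                 parts$nw[2], fmt(parts$v[2]), parts$nw[3], fmt(parts$v[3]))
  ape::read.tree(text = txt)
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Requires multiple-alignment input (equal-length sequences): alignment
#' columns are resampled with replacement per replicate, distances and the
#' NJ tree recomputed, and each internal edge of the full-data tree scored
#' by the percentage of replicates containing the same bipartition.
#' (Pairwise-alignment mode has no common column set to resample, so
#' bootstrap is defined for MSA input only.)
#'
#' @param alignment named character vector of equal-length aligned sequences.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed (required, for reproducibility).
#' @param model distance model, see [pairwise_distance_matrix()].
#' @return list with `tree` (the full-data NJ tree, `node.label` holding
#'   integer percent supports, `NA` on the basal node) and `supports`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed,
                              model = "p") {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1)
    stop("bootstrap requires equal-length aligned sequences", call. = FALSE)
  ref <- neighbor_joining(pairwise_distance_matrix(alignment, aligned = TRUE,
                                                   model = model))
  L <- nchar(alignment[[1]])
  rows <- strsplit(unname(alignment), "", fixed = TRUE)
  names(rows) <- names(alignment)
  trees <- .with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      boot <- vapply(rows, function(x) paste(x[cols], collapse = ""), "")
      neighbor_joining(pairwise_distance_matrix(boot, aligned = TRUE,
                                                model = model))
    })
  })
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  supports <- round(100 * counts / n_replicates)
  ref$node.label <- as.character(supports)
  list(tree = ref, supports = supports)
}

#' Cut a tree into leaf-distance clusters
#'
#' Clusters are maximal subtrees in which every leaf-to-leaf path length is
#' at most `cut_distance`. The unrooted tree is midpoint-rooted first so
#' "subtree" is well defined; clusters are named by Roman numerals in
#' decreasing size order (ties by smallest member label).
#'
#' @param tree an [ape::phylo] tree.
#' @param cut_distance positive path-length threshold.
#' @return A `cluster_labeling`: list with `labels` (named character vector
#'   leaf -> cluster name) and `threshold`.
#' @export
extract_tree_clusters <- function(tree, cut_distance) {
  if (cut_distance <= 0) stop("cut_distance must be > 0", call. = FALSE)
  rt <- phangorn::midpoint(tree)
  D <- ape::cophenetic.phylo(rt)
  ntip <- length(rt$tip.label)
  children <- split(rt$edge[, 2], rt$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(rt$tip.label[node])
    unlist(lapply(children[[as.character(node)]], tips_under))
  }
  clusters <- list()
  descend <- function(node) {
    tips <- tips_under(node)
    if (length(tips) == 1 || max(D[tips, tips]) <= cut_distance) {
      clusters[[length(clusters) + 1]] <<- tips
    } else {
      for (ch in children[[as.character(node)]]) descend(ch)
    }
  }
  descend(ntip + 1L)
  ord <- order(-lengths(clusters),
               vapply(clusters, function(x) sort(x)[1], ""))
  clusters <- clusters[ord]
  labels <- unlist(lapply(seq_along(clusters), function(i)
    setNames(rep(as.character(utils::as.roman(i)), length(clusters[[i]])),
             clusters[[i]])))
  structure(list(labels = labels[tree$tip.label], threshold = cut_distance),
            class = "cluster_labeling")
}

#' Permutation test of association between two labelings
#'
#' Cramer's V on the contingency table of `labelsA` x `labelsB`, with a
#' permutation p-value: `labelsB` is permuted `n_perm` times and
#' `p = (count of permuted V >= observed + 1) / (n_perm + 1)`.
#'
#' @param labelsA,labelsB character vectors over the same items (matched by
#'   names when both are named, otherwise by position).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with `cramers_v`, `p_value`, `table`.
#' @export
association_test <- function(labelsA, labelsB, n_perm = 10000L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.null(names(labelsA)) && !is.null(names(labelsB))) {
    if (!setequal(names(labelsA), names(labelsB)))
      stop("labelings cover different item sets", call. = FALSE)
    labelsB <- labelsB[names(labelsA)]
  } else if (length(labelsA) != length(labelsB)) {
    stop("labelings have different lengths", call. = FALSE)
  }
  if (length(unique(labelsA)) < 2 || length(unique(labelsB)) < 2)
    stop("Cramer's V undefined with a single category", call. = FALSE)
  v_obs <- .cramers_v(labelsA, labelsB)
  count_ge <- .with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      .cramers_v(labelsA, sample(labelsB)), 0) >= v_obs - 1e-12)
  })
  list(cramers_v = v_obs, p_value = (count_ge + 1) / (n_perm + 1),
       table = table(labelsA, labelsB))
}

.cramers_v <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  chisq <- sum((tab - E)^2 / E)
  sqrt(chisq / (n * (min(dim(tab)) - 1)))
}
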