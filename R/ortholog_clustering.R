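# Protein ortholog families: all-vs-all local alignment gated at 50%
# identity / 50% bidirectional coverage, Markov clustering of the resulting
# similarity graph, the genome x family gene-content matrix, and two-way
# hierarchical clustering of phages by gene content.

#' All-vs-all protein similarity graph
#'
#' Computes local affine-gap alignments for every candidate protein pair and
#' keeps an edge when percent identity and coverage pass the thresholds on
#' BOTH sequences (the bidirectional criterion). Edges are stored once per
#' unordered pair with `a < b` lexicographically.
#'
#' A shared-k-mer pre-filter (exact 4-mers, at least one shared) skips pairs
#' that cannot plausibly reach the identity gate; with `prefilter = "auto"`
#' (default) it engages only for cohorts of more than 200 proteins, so small
#' inputs are always aligned exhaustively.
#'
#' @param proteins named character vector of amino-acid sequences (names are
#'   gene ids).
#' @param min_identity minimum percent identity over alignment columns.
#' @param min_coverage minimum aligned fraction required of each sequence.
#' @param prefilter `"auto"`, `"on"` or `"off"`.
#' @param prefilter_k k-mer length for the pre-filter.
#' @return data.frame with columns `a`, `b`, `pct_identity`, `cov_a`,
#'   `cov_b`, `score`.
#' @export
all_vs_all_similarity <- function(proteins, min_identity = 50,
                                  min_coverage = 0.5,
                                  prefilter = c("auto", "on", "off"),
                                  prefilter_k = 4L) {
  prefilter <- match.arg(prefilter)
  n <- length(proteins)
  if (n < 2) stop("need at least two protein sequences", call. = FALSE)
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must be uniquely named by gene id", call. = FALSE)
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 1)
  for (id in names(proteins))
    .encode_seq(proteins[[id]], .AA_LETTERS, what = "gene", id = id)

  use_filter <- prefilter == "on" || (prefilter == "auto" && n > 200)
  pairs <- if (use_filter) {
    .shared_kmer_pairs(proteins, prefilter_k)
  } else {
    t(combn(sort(names(proteins)), 2))
  }

  sub <- .protein_sub_matrix()
  enc <- lapply(proteins, .encode_seq, letters = .AA_LETTERS)
  rows <- vector("list", nrow(pairs))
  m <- 0L
  for (i in seq_len(nrow(pairs))) {
    ida <- pairs[i, 1]; idb <- pairs[i, 2]
    r <- .align_core(enc[[ida]], enc[[idb]], sub, 10, 0.5, TRUE)
    if (r$pct_identity >= min_identity && r$cov_a >= min_coverage &&
        r$cov_b >= min_coverage) {
      m <- m + 1L
      rows[[m]] <- data.frame(a = ida, b = idb,
                              pct_identity = r$pct_identity,
                              cov_a = r$cov_a, cov_b = r$cov_b,
                              score = r$score, stringsAsFactors = FALSE)
    }
  }
  if (m == 0L)
    return(data.frame(a = character(), b = character(),
                      pct_identity = numeric(), cov_a = numeric(),
                      cov_b = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows[seq_len(m)])
  out[order(out$a, out$b), , drop = FALSE]
}

# Candidate unordered pairs by shared exact k-mer count (sparse seq x k-mer
# crossproduct). The count threshold scales with the shorter sequence
# (2% of its length, at least 2 shared k-mers), which keeps pairs capable of
# reaching ~50% identity while discarding the unrelated bulk.
.shared_kmer_pairs <- function(proteins, k) {
  ids <- sort(names(proteins))
  kml <- lapply(proteins[ids], function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  kmf <- factor(unlist(kml, use.names = FALSE))
  if (!length(kmf)) return(matrix(character(), 0, 2))
  Mx <- Matrix::sparseMatrix(i = rep(seq_along(ids), lengths(kml)),
                             j = as.integer(kmf), x = 1)
  shared <- as.matrix(Matrix::tcrossprod(Mx))
  lens <- nchar(proteins[ids])
  thresh <- pmax(2, floor(0.02 * outer(lens, lens, pmin)))
  keep <- which(upper.tri(shared) & shared >= thresh, arr.ind = TRUE)
  if (!nrow(keep)) return(matrix(character(), 0, 2))
  cbind(ids[keep[, 1]], ids[keep[, 2]])
}

#' Markov clustering of a similarity graph
#'
#' A from-scratch implementation of MCL: a column-stochastic matrix is built
#' from edge weights with self-loops (each node's loop weighted by its
#' maximum incident edge weight, 1 when isolated), then expansion (matrix
#' power), inflation (entry-wise power followed by column renormalisation)
#' and pruning of entries below `prune_threshold` (with renormalisation)
#' alternate until the matrix changes by less than `tol` or `max_iter` is
#' reached. Clusters are read from the limit matrix as connected components
#' linking attractor rows (positive diagonal) to the columns they support;
#' singletons are allowed.
#'
#' @param edges data.frame as returned by [all_vs_all_similarity()] (columns
#'   `a`, `b` and the weight column).
#' @param nodes optional character vector of node ids; defaults to the union
#'   of edge endpoints. Nodes without edges become singleton clusters.
#' @param inflation inflation exponent (> 1).
#' @param expansion expansion power (integer >= 2).
#' @param prune_threshold entries below this are dropped each iteration.
#' @param max_iter iteration cap; non-convergence raises a warning and the
#'   current matrix is interpreted.
#' @param tol convergence threshold on the maximum absolute entry change.
#' @param weight name of the edge-weight column (default `"score"`;
#'   `"pct_identity"` is the common alternative).
#' @return An `ortholog_partition`: list with `clusters` (named list of gene
#'   id vectors, ids `OC0001`... ordered by decreasing size then smallest
#'   member), `membership` (named character vector gene id -> cluster id),
#'   `converged`, `n_iter`.
#' @export
mcl <- function(edges, nodes = NULL, inflation = 2.0, expansion = 2L,
                prune_threshold = 1e-5, max_iter = 200L, tol = 1e-8,
                weight = "score") {
  if (inflation <= 1) stop("inflation must be > 1", call. = FALSE)
  if (expansion < 2) stop("expansion must be >= 2", call. = FALSE)
  nodes <- sort(unique(c(nodes, edges$a, edges$b)))
  n <- length(nodes)
  if (n < 1) stop("no nodes to cluster", call. = FALSE)

  w <- if (nrow(edges)) edges[[weight]] else numeric()
  ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
  loops <- rep(1, n)
  if (length(w)) {
    mx <- tapply(c(w, w), c(ia, ib), max)
    loops[as.integer(names(mx))] <- as.numeric(mx)
  }
  M <- Matrix::sparseMatrix(i = c(ia, ib, seq_len(n)),
                            j = c(ib, ia, seq_len(n)),
                            x = c(w, w, loops), dims = c(n, n))
  M <- .mcl_colnorm(M)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp
    Minf@x <- Minf@x^inflation
    Minf <- .mcl_colnorm(Minf)
    Minf@x[Minf@x < prune_threshold] <- 0
    Minf <- Matrix::drop0(Minf)
    Minf <- .mcl_colnorm(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge in %d iterations; interpreting the current matrix",
                    max_iter))

  .partition_from_mcl_matrix(as.matrix(M), nodes, converged, iter)
}

.mcl_colnorm <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

.partition_from_mcl_matrix <- function(M, nodes, converged, n_iter) {
  n <- length(nodes)
  attractors <- which(diag(M) > 0)
  el <- which(M > 0, arr.ind = TRUE)
  el <- el[el[, 1] %in% attractors & el[, 1] != el[, 2], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)$membership
  clusters <- split(names(comp), comp)
  clusters <- lapply(clusters, sort)
  ord <- order(-vapply(clusters, length, 0L),
               vapply(clusters, `[`, "", 1L))
  clusters <- clusters[ord]
  names(clusters) <- sprintf("OC%04d", seq_along(clusters))
  membership <- unlist(lapply(names(clusters), function(cid)
    setNames(rep(cid, length(clusters[[cid]])), clusters[[cid]])))
  structure(list(clusters = clusters, membership = membership[nodes],
                 converged = converged, n_iter = n_iter),
            class = "ortholog_partition")
}

#' @export
print.ortholog_partition <- function(x, ...) {
  sizes <- vapply(x$clusters, length, 0L)
  cat(sprintf("<ortholog_partition> %d genes in %d clusters (largest %d, singletons %d)\n",
              length(x$membership), length(x$clusters), max(sizes),
              sum(sizes == 1)))
  invisible(x)
}

#' Genome x ortholog-family gene-content matrix
#'
#' @param partition an `ortholog_partition`.
#' @param genomes list of `phage_genome` covering every gene in the
#'   partition.
#' @return integer matrix, rows genomes (sorted by id), columns cluster ids;
#'   `counts[g, c]` = number of genes of genome g in cluster c.
#' @export
build_gene_content_matrix <- function(partition, genomes) {
  g_of <- gene_genome_map(genomes)
  genes <- names(partition$membership)
  orphan <- setdiff(genes, names(g_of))
  if (length(orphan))
    stop("genes not found in any genome: ",
         paste(head(orphan, 5), collapse = ", "), call. = FALSE)
  rows <- sort(vapply(genomes, `[[`, "", "genome_id"))
  cols <- names(partition$clusters)
  counts <- matrix(0L, length(rows), length(cols),
                   dimnames = list(rows, cols))
  tab <- table(g_of[genes], partition$membership)
  counts[rownames(tab), colnames(tab)] <- tab
  counts
}

#' Two-way hierarchical clustering of phages by gene content
#'
#' Genomes are clustered by average-linkage agglomeration on the Jaccard
#' distance between presence/absence profiles (counts are binarised); the
#' ortholog-family side is clustered the same way for reporting. Rows are
#' sorted by genome id before clustering, so results do not depend on input
#' order. Cluster letters A, B, C, ... are assigned by decreasing cluster
#' size, ties broken by smallest member id.
#'
#' @param counts matrix from [build_gene_content_matrix()].
#' @param k number of phage clusters to cut (1 <= k <= genomes); an analyst
#'   decision. [suggest_k()] reports a silhouette-based suggestion that is
#'   never auto-applied.
#' @return A `phage_clustering`: list with `labels` (named character vector
#'   genome -> letter), `row_hclust`, `col_hclust`, `k`.
#' @export
two_way_hcl <- function(counts, k) {
  n <- nrow(counts)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of genomes", call. = FALSE)
  bin <- (counts[sort(rownames(counts)), , drop = FALSE] > 0) * 1
  d <- dist(bin, method = "binary")
  hr <- hclust(d, method = "average")
  hc <- hclust(dist(t(bin), method = "binary"), method = "average")
  memb <- cutree(hr, k = k)
  groups <- split(names(memb), memb)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, 0L), vapply(groups, `[`, "", 1L))
  labels <- unlist(lapply(seq_along(ord), function(i)
    setNames(rep(LETTERS[i], length(groups[[ord[i]]])), groups[[ord[i]]])))
  structure(list(labels = labels[sort(rownames(counts))], row_hclust = hr,
                 col_hclust = hc, k = k),
            class = "phage_clustering")
}

#' Silhouette-based suggestion for the number of phage clusters
#'
#' Mean silhouette width of the average-linkage Jaccard clustering over a
#' range of k; reported for guidance only.
#'
#' @param counts gene-content matrix.
#' @param k_range candidate values of k.
#' @return named numeric vector of mean silhouette widths; the suggested k is
#'   `names(which.max(...))`.
#' @export
suggest_k <- function(counts, k_range = 2:min(10, nrow(counts) - 1)) {
  bin <- (counts[sort(rownames(counts)), , drop = FALSE] > 0) * 1
  d <- as.matrix(dist(bin, method = "binary"))
  hr <- hclust(as.dist(d), method = "average")
  out <- vapply(k_range, function(k) {
    memb <- cutree(hr, k = k)
    mean(vapply(seq_along(memb), function(i) {
      own <- memb[i]
      a <- mean(d[i, memb == own & seq_along(memb) != i])
      if (is.nan(a)) return(0)
      b <- min(vapply(setdiff(unique(memb), own), function(cl)
        mean(d[i, memb == cl]), 0))
      (b - a) / max(a, b)
    }, 0))
  }, 0)
  setNames(out, k_range)
}
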