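# Independent oracle implementations used to cross-check the package:
# a pure-R affine-gap DP aligner (same scoring scheme and tie-break rules as
# the package's C++ aligner, written separately) and a dense, loop-based
# Markov clustering. These never call into the package's own code paths.

oracle_sub_protein <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  e$BLOSUM62[aa, aa]
}

# Gotoh DP, matrices indexed 1..n+1 (cell [i+1, j+1] = prefix lengths i, j).
# Tie-breaks: M sources M > X > Y > local-stop; gap states close (M) before
# extend; local best cell = first maximum in row-major order; local
# traceback stops in state M at a zero-valued cell.
oracle_align <- function(a, b, sub, gap_open, gap_ext, local) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  go <- gap_open + gap_ext; ge <- gap_ext
  M <- matrix(-Inf, n + 1, m + 1); X <- M; Y <- M
  tM <- matrix(3L, n + 1, m + 1); tX <- tM; tY <- tM
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1)) { X[i, 1] <- -go - (i - 2) * ge
                           tX[i, 1] <- if (i == 2) 0L else 1L }
    for (j in 2:(m + 1)) { Y[1, j] <- -go - (j - 2) * ge
                           tY[1, j] <- if (j == 2) 0L else 2L }
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  best <- if (local) 0 else -Inf; bi <- 0L; bj <- 0L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[A[i - 1], B[j - 1]]
      vm <- M[i - 1, j - 1]; vx <- X[i - 1, j - 1]; vy <- Y[i - 1, j - 1]
      mv <- vm; msrc <- 0L
      if (vx > mv) { mv <- vx; msrc <- 1L }
      if (vy > mv) { mv <- vy; msrc <- 2L }
      cand <- if (is.infinite(mv)) -Inf else mv + s
      if (local && cand < 0) { cand <- 0; msrc <- 3L }
      M[i, j] <- cand; tM[i, j] <- msrc
      xo <- M[i - 1, j] - go; xe <- X[i - 1, j] - ge
      if (xo >= xe) { X[i, j] <- xo; tX[i, j] <- 0L }
      else          { X[i, j] <- xe; tX[i, j] <- 1L }
      yo <- M[i, j - 1] - go; ye <- Y[i, j - 1] - ge
      if (yo >= ye) { Y[i, j] <- yo; tY[i, j] <- 0L }
      else          { Y[i, j] <- ye; tY[i, j] <- 2L }
      if (local && M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
    }
  }
  if (local) {
    state <- 0L
  } else {
    bi <- n + 1L; bj <- m + 1L
    best <- M[bi, bj]; state <- 0L
    if (X[bi, bj] > best) { best <- X[bi, bj]; state <- 1L }
    if (Y[bi, bj] > best) { best <- Y[bi, bj]; state <- 2L }
  }
  cols_a <- integer(); cols_b <- integer()
  i <- bi; j <- bj
  run <- !(local && best == 0)
  while (run) {
    if (local) { if (state == 0L && M[i, j] == 0) break }
    else if (i == 1L && j == 1L) break
    if (state == 0L) {
      src <- tM[i, j]
      cols_a <- c(cols_a, i - 1L); cols_b <- c(cols_b, j - 1L)
      i <- i - 1L; j <- j - 1L
      state <- if (src == 3L) 0L else src
    } else if (state == 1L) {
      src <- tX[i, j]
      cols_a <- c(cols_a, i - 1L); cols_b <- c(cols_b, 0L)
      i <- i - 1L
      state <- src
    } else {
      src <- tY[i, j]
      cols_a <- c(cols_a, 0L); cols_b <- c(cols_b, j - 1L)
      j <- j - 1L
      state <- src
    }
  }
  cols_a <- rev(cols_a); cols_b <- rev(cols_b)
  L <- length(cols_a)
  n_match <- sum(cols_a > 0 & cols_b > 0 &
                   A[pmax(cols_a, 1)] == B[pmax(cols_b, 1)] &
                   cols_a > 0 & cols_b > 0)
  aa <- cols_a[cols_a > 0]; bb <- cols_b[cols_b > 0]
  list(score = best, n_match = n_match, align_len = L,
       a_start = if (length(aa)) min(aa) else 0L,
       a_end = if (length(aa)) max(aa) else 0L,
       b_start = if (length(bb)) min(bb) else 0L,
       b_end = if (length(bb)) max(bb) else 0L,
       pct_identity = if (L > 0) 100 * n_match / L else 0,
       cov_a = if (length(aa)) (max(aa) - min(aa) + 1) / n else 0,
       cov_b = if (length(bb)) (max(bb) - min(bb) + 1) / m else 0)
}

# the 50%/50% bidirectional similarity gate recomputed from scratch
oracle_similarity_edges <- function(proteins, min_identity = 50,
                                    min_coverage = 0.5) {
  sub <- oracle_sub_protein()
  ids <- sort(names(proteins))
  out <- character()
  for (i in 1:(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      r <- oracle_align(proteins[[ids[i]]], proteins[[ids[j]]], sub,
                        10, 0.5, local = TRUE)
      if (r$pct_identity >= min_identity && r$cov_a >= min_coverage &&
          r$cov_b >= min_coverage)
        out <- c(out, paste(ids[i], ids[j]))
    }
  }
  sort(out)
}

# dense, loop-based Markov clustering (expansion / inflation / prune), with
# the same cluster interpretation: attractor rows link their supported
# columns; connected components by breadth-first search.
oracle_mcl_partition <- function(edges, nodes = NULL, inflation = 2,
                                 expansion = 2, prune = 1e-5,
                                 max_iter = 200, tol = 1e-8,
                                 weight = "score") {
  nodes <- sort(unique(c(nodes, edges$a, edges$b)))
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    w <- edges[[weight]][r]
    W[edges$a[r], edges$b[r]] <- w
    W[edges$b[r], edges$a[r]] <- w
  }
  loops <- apply(W, 1, max)
  loops[loops == 0] <- 1
  diag(W) <- loops
  colnorm <- function(M) {
    cs <- colSums(M); cs[cs == 0] <- 1
    sweep(M, 2, cs, "/")
  }
  M <- colnorm(W)
  for (it in seq_len(max_iter)) {
    Me <- M
    for (e in seq_len(expansion - 1)) Me <- Me %*% M
    Mi <- colnorm(Me^inflation)
    Mi[Mi < prune] <- 0
    Mi <- colnorm(Mi)
    delta <- max(abs(Mi - M))
    M <- Mi
    if (delta < tol) break
  }
  attractors <- which(diag(M) > 0)
  G <- matrix(FALSE, n, n)
  for (i in attractors) for (j in which(M[i, ] > 0)) if (j != i) {
    G[i, j] <- TRUE; G[j, i] <- TRUE
  }
  comp <- integer(n); cc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cc <- cc + 1L
    queue <- s; comp[s] <- cc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(G[v, ])) if (comp[w] == 0) {
        comp[w] <- cc; queue <- c(queue, w)
      }
    }
  }
  unname(lapply(split(nodes, comp), sort))
}

# canonical form of a partition for set comparison
partition_canon <- function(clusters) {
  unname(sort(vapply(clusters, function(x) paste(sort(x), collapse = ","),
                     "")))
}
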