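# Core-genome scaffold: which ortholog families are single-copy core, their
# consensus gene order (anchored on the terminase large subunit cluster so
# every genome is rotated/flipped into a common frame), and functional-module
# labels (morphogenesis / replication / regulation) propagated from marker
# genes. The scaffold is the coordinate system insertion loci are named in.

#' Identify single-copy core ortholog clusters
#'
#' @param partition an `ortholog_partition`.
#' @param genomes list of `phage_genome`.
#' @param presence_fraction minimum fraction of genomes that must carry
#'   exactly one member (default 1 = fully conserved).
#' @param single_copy exclude clusters duplicated in any genome.
#' @param exclude_genes gene ids whose clusters must never be called core.
#'   Pass the classified HEG genes here: a mobile family can be universally
#'   present and single-copy (the GVE2-like HNHE is) yet is an insertion,
#'   not part of the core scaffold.
#' @return sorted character vector of core cluster ids.
#' @export
identify_core_clusters <- function(partition, genomes,
                                   presence_fraction = 1.0,
                                   single_copy = TRUE,
                                   exclude_genes = character()) {
  counts <- build_gene_content_matrix(partition, genomes)
  n <- nrow(counts)
  single <- colSums(counts == 1L)
  multi <- colSums(counts > 1L) > 0
  keep <- single >= presence_fraction * n
  if (single_copy) keep <- keep & !multi
  if (length(exclude_genes)) {
    banned <- unique(partition$membership[
      intersect(exclude_genes, names(partition$membership))])
    keep <- keep & !(colnames(counts) %in% banned)
  }
  core <- sort(colnames(counts)[keep])
  if (!length(core))
    stop("no core clusters at presence_fraction=", presence_fraction,
         "; consider relaxing the threshold", call. = FALSE)
  core
}

#' Find an ortholog cluster by product annotation
#'
#' Convenience resolver for marker genes: returns the cluster whose members'
#' product annotations match `pattern` most often.
#'
#' @param partition an `ortholog_partition`.
#' @param genomes list of `phage_genome`.
#' @param pattern regular expression matched (case-insensitively) against
#'   product annotations.
#' @return a cluster id.
#' @export
find_cluster_by_product <- function(partition, genomes, pattern) {
  products <- unlist(unname(lapply(genomes, function(g)
    setNames(g$genes$product, g$genes$gene_id))))
  hit_genes <- names(products)[grepl(pattern, products, ignore.case = TRUE)]
  hit_genes <- intersect(hit_genes, names(partition$membership))
  if (!length(hit_genes))
    stop(sprintf("no gene product matches '%s'", pattern), call. = FALSE)
  tab <- sort(table(partition$membership[hit_genes]), decreasing = TRUE)
  names(tab)[1]
}

# project one genome onto its sequence of core cluster ids, flipped when the
# anchor gene lies on the minus strand, then rotated so the anchor is first
.core_projection <- function(g, membership, core_set, anchor) {
  gn <- g$genes
  cl <- membership[gn$gene_id]
  keep <- !is.na(cl) & cl %in% core_set
  seq_cl <- cl[keep]
  strands <- gn$strand[keep]
  a <- which(seq_cl == anchor)
  if (!length(a)) return(NULL)
  if (strands[a[1]] == "-") {
    seq_cl <- rev(seq_cl)
    a <- which(seq_cl == anchor)
  }
  # circular rotation: phage genome deposits are arbitrary linearisations
  idx <- c(a[1]:length(seq_cl), if (a[1] > 1) 1:(a[1] - 1))
  unname(seq_cl[idx])
}

.count_breakpoints <- function(order_x, consensus) {
  adj <- paste(consensus[-length(consensus)], consensus[-1])
  if (length(order_x) < 2) return(0L)
  cand <- paste(order_x[-length(order_x)], order_x[-1])
  sum(!cand %in% adj)
}

#' Consensus core-gene order across a cohort
#'
#' Each genome's core genes are projected to a sequence of cluster ids,
#' flipped when the anchor lies on the minus strand and rotated so the anchor
#' comes first (phage genome records are arbitrary linearisations of a
#' circularly permuted chromosome). The consensus order is the order shared
#' by the plurality of genomes carrying the complete core; genomes whose
#' order disagrees are reported with their breakpoint count (adjacencies not
#' present in the consensus).
#'
#' @param genomes list of `phage_genome`.
#' @param partition an `ortholog_partition`.
#' @param core_set core cluster ids from [identify_core_clusters()].
#' @param anchor core cluster id used for orientation (typically the
#'   terminase large subunit cluster, see [find_cluster_by_product()]).
#' @return A `core_scaffold`: list with `ordered_core`, `module_of` (all
#'   `"unassigned"` until [assign_functional_modules()]), `anchor`,
#'   `outliers` (data.frame genome_id, breakpoints).
#' @export
consensus_core_order <- function(genomes, partition, core_set, anchor) {
  if (!anchor %in% core_set)
    stop(sprintf("anchor cluster '%s' is not in the core set", anchor),
         call. = FALSE)
  proj <- lapply(genomes, .core_projection, membership = partition$membership,
                 core_set = core_set, anchor = anchor)
  names(proj) <- vapply(genomes, `[[`, "", "genome_id")
  proj <- proj[!vapply(proj, is.null, TRUE)]
  if (!length(proj))
    stop("no genome carries the anchor cluster", call. = FALSE)
  complete <- proj[vapply(proj, function(p)
    length(p) == length(core_set) && !anyDuplicated(p), TRUE)]
  if (!length(complete))
    stop("no genome carries the complete single-copy core", call. = FALSE)
  keys <- vapply(complete, paste, "", collapse = "|")
  tab <- sort(table(keys), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) {
    stop("no plurality core order; conflicting orders:\n  ",
         paste(names(tab)[tab == tab[1]], collapse = "\n  "), call. = FALSE)
  }
  consensus <- strsplit(names(tab)[1], "|", fixed = TRUE)[[1]]
  outliers <- do.call(rbind, lapply(names(proj), function(id) {
    p <- proj[[id]]
    if (identical(unname(p), consensus)) return(NULL)
    data.frame(genome_id = id, breakpoints = .count_breakpoints(p, consensus),
               stringsAsFactors = FALSE)
  }))
  if (is.null(outliers))
    outliers <- data.frame(genome_id = character(), breakpoints = integer(),
                           stringsAsFactors = FALSE)
  structure(list(ordered_core = consensus,
                 module_of = setNames(rep("unassigned", length(consensus)),
                                      consensus),
                 anchor = anchor, outliers = outliers),
            class = "core_scaffold")
}

#' @export
print.core_scaffold <- function(x, ...) {
  cat(sprintf("<core_scaffold> %d core clusters, anchor %s, %d outlier genome(s)\n",
              length(x$ordered_core), x$anchor, nrow(x$outliers)))
  tab <- table(x$module_of)
  cat("  modules:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Label functional modules along the core scaffold
#'
#' Marker clusters carry known module membership (e.g. terminase/portal for
#' morphogenesis, DNA polymerase for replication). Every scaffold position is
#' assigned the module of its nearest marker along the consensus order; at
#' exact midpoints the downstream marker wins, which places a boundary at the
#' midpoint between consecutive markers of different modules. Modules with no
#' marker receive no positions.
#'
#' @param scaffold a `core_scaffold`.
#' @param marker_map named list: module name -> character vector of core
#'   cluster ids.
#' @return the scaffold with `module_of` filled in.
#' @export
assign_functional_modules <- function(scaffold, marker_map) {
  ord <- scaffold$ordered_core
  marks <- data.frame(
    cluster = unlist(marker_map, use.names = FALSE),
    module = rep(names(marker_map), lengths(marker_map)),
    stringsAsFactors = FALSE)
  bad <- setdiff(marks$cluster, ord)
  if (length(bad))
    stop("marker cluster(s) not in the core scaffold: ",
         paste(bad, collapse = ", "), call. = FALSE)
  marks$pos <- match(marks$cluster, ord)
  module_of <- vapply(seq_along(ord), function(p) {
    d <- abs(marks$pos - p)
    best <- which(d == min(d))
    # tie at an exact midpoint: the downstream marker's module wins
    marks$module[best[which.max(marks$pos[best])]]
  }, "")
  scaffold$module_of <- setNames(module_of, ord)
  scaffold
}

#' Write a core scaffold as TSV
#' @param scaffold a `core_scaffold`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scaffold <- function(scaffold, path) {
  df <- data.frame(rank = seq_along(scaffold$ordered_core),
                   cluster_id = scaffold$ordered_core,
                   module = unname(scaffold$module_of),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
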