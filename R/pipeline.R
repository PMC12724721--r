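# End-to-end orchestration: ortholog clustering -> core scaffold -> HNHE
# classification -> insertion loci -> per-family phylogeny with
# cluster-metadata association. Each stage is an exported function; this
# wrapper just wires the default path through them.

#' Run the full HEG-mapping pipeline on a cohort
#'
#' @param genomes named list of `phage_genome` (metadata attached).
#' @param k_phage number of phage gene-content clusters to cut (fixed by the
#'   analyst; see [suggest_k()]).
#' @param references HNHE references, see [load_hnhe_references()].
#' @param min_identity,min_coverage similarity-gate thresholds.
#' @param inflation MCL inflation.
#' @param presence_fraction core presence threshold.
#' @param anchor_pattern product regex resolving the orientation anchor
#'   cluster (terminase large subunit by default).
#' @param marker_map module markers; default resolves standard product
#'   annotations via [default_marker_map()].
#' @param tree_cut leaf-distance threshold for phylogenetic clusters.
#' @param tree_family HNHE family to build the tree for (the most abundant,
#'   I-HmuI-like, by default).
#' @param n_perm,perm_seed permutation-test settings.
#' @return list with `edges`, `partition`, `counts`, `phage_clusters`,
#'   `core_set`, `scaffold`, `assignments`, `anchors`, `loci`, `tree`,
#'   `tree_clusters`, `association` (tree cluster vs starter; `NULL` when no
#'   tree could be built).
#' @export
run_heg_pipeline <- function(genomes, k_phage,
                             references = load_hnhe_references(),
                             min_identity = 50, min_coverage = 0.5,
                             inflation = 2.0, presence_fraction = 1.0,
                             anchor_pattern = "terminase large subunit",
                             marker_map = NULL,
                             tree_cut = 0.22, tree_family = "IHMU",
                             n_perm = 1000L, perm_seed = 1L) {
  proteins <- cohort_proteins(genomes)
  edges <- all_vs_all_similarity(proteins, min_identity = min_identity,
                                 min_coverage = min_coverage)
  partition <- mcl(edges, nodes = names(proteins), inflation = inflation)
  counts <- build_gene_content_matrix(partition, genomes)
  phage_clusters <- two_way_hcl(counts, k = k_phage)

  assignments <- classify_cohort(genomes, references)
  heg_genes <- assignments$gene_id[assignments$family != "UNCLASSIFIED"]
  core_set <- identify_core_clusters(partition, genomes,
                                     presence_fraction = presence_fraction,
                                     exclude_genes = heg_genes)
  anchor <- find_cluster_by_product(partition, genomes, anchor_pattern)
  scaffold <- consensus_core_order(genomes, partition, core_set, anchor)
  if (is.null(marker_map))
    marker_map <- default_marker_map(partition, genomes, core_set)
  if (length(marker_map))
    scaffold <- assign_functional_modules(scaffold, marker_map)
  anchors <- cohort_anchors(genomes, assignments, core_set, partition)
  loci <- consolidate_loci(anchors, scaffold, assignments)

  tree <- NULL; tree_clusters <- NULL; association <- NULL
  fam_genes <- assignments$gene_id[assignments$family == tree_family]
  if (length(fam_genes) >= 4) {
    fam_prot <- cohort_proteins(genomes)[fam_genes]
    same_len <- length(unique(nchar(fam_prot))) == 1
    D <- pairwise_distance_matrix(fam_prot, aligned = same_len)
    tree <- neighbor_joining(D)
    tree_clusters <- extract_tree_clusters(tree, tree_cut)
    g_of <- gene_genome_map(genomes)
    starter_of <- vapply(genomes, function(g) g$metadata$starter, "")
    starters <- setNames(starter_of[g_of[fam_genes]], fam_genes)
    if (length(unique(tree_clusters$labels)) > 1 &&
        length(unique(starters)) > 1)
      association <- association_test(tree_clusters$labels, starters,
                                      n_perm = n_perm, seed = perm_seed)
  }

  list(edges = edges, partition = partition, counts = counts,
       phage_clusters = phage_clusters, core_set = core_set,
       scaffold = scaffold, assignments = assignments, anchors = anchors,
       loci = loci, tree = tree, tree_clusters = tree_clusters,
       association = association)
}
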