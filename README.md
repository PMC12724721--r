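# hegatlas

Comparative genomics of **HNH endonuclease genes (HNHEs)** in phage
cohorts — built for the lactococcal *Skunavirus* setting, usable for any
cohort of annotated phage genomes.

Dairy *Skunavirus* phages carry 1–8 HNHE genes apiece, most of them
free-standing homing endonuclease genes (HEGs): selfish elements that
home into cognate alleles lacking them and can exclude a coinfecting
phage's markers. Asking *where* these genes insert, *which family* each
belongs to, and *how* they track phage lineages takes a chain of
analyses that `hegatlas` provides as tested, deterministic R functions:

- **Ortholog families** by all-vs-all local protein alignment (affine-gap
  Smith–Waterman, BLOSUM62) gated at ≥ 50% identity over ≥ 50% coverage
  of *both* sequences, partitioned with a from-scratch **Markov
  clustering (MCL)** implementation.
- **Phage clusters** from the genome × family gene-content matrix
  (average-linkage on Jaccard distance of presence/absence).
- A **core scaffold**: single-copy, fully conserved families in consensus
  order, anchored on the terminase large subunit (TerL) and labelled with
  morphogenesis / replication / regulation modules via marker genes.
- **HNHE classification** into I-HmuI-like, PacI-like, GVE2-like,
  truncated, or unclassified, by scoring against packaged reference
  proteins plus an **H-x(10–35)-N-x(10–35)-(H|N)** active-site motif scan
  (the I-HmuI-like reference carries the catalytic D74, H75, N96).
- **Insertion loci H1..Hn**: each HEG anchored to its nearest flanking
  core genes, anchors consolidated cohort-wide by flank-pair containment
  on the consensus order.
- **Neighbour-joining phylogenies** (Saitou–Nei, deterministic
  tie-breaks) per HNHE family with bootstrap supports, leaf-distance
  clusters (Roman numerals), and a **Cramér's V permutation test** of
  cluster–metadata association (e.g. starter culture).
- **Efficiency of plaquing**: titres from plaque-count dilution series
  and EOP = test titre / control titre, with geometric-mean replicate
  reduction.
- A **synthetic cohort generator** with complete ground truth (core
  order, module labels, lineages, HEG families/loci/truncations), so the
  whole pipeline is testable end to end with no downloads.

Inputs are GenBank flat files (CDS features with translations) or
in-memory `phage_genome` objects, plus TSV metadata and plaque-count
tables. Trees are `ape::phylo`; everything tabular is plain data frames
and TSV.

## Worked example

```r
library(hegatlas)

sim <- simulate_phage_cohort(synthetic_config(seed = 1))
sim$genomes[[1]]
#> <phage_genome> phi01: 25,486 bp, 31 genes (starter=SM1 factory=F3 year=2020)

res <- run_heg_pipeline(sim$genomes, k_phage = 3)

res$loci$loci[, 1:8]
#> locus_id upstream_core downstream_core        module n_IHMU n_PACI n_GVE2 n_truncated
#>       H1        OC0002          OC0003 morphogenesis      0      0     14           3
#>       H2        OC0010          OC0011 morphogenesis      0     15      0           3
#>       H3        OC0017          OC0018   replication     11      0      0           3
#>       H4        OC0025          OC0026    regulation     10      0      0           4

table(res$assignments$family)
#>  GVE2  IHMU  PACI TRUNCATED UNCLASSIFIED
#>    14    21    15        13          630
```

Reading this: the cohort's HEGs occupy four insertion loci named in
scaffold order. H1 is the TerL–portal gap — every genome carries a
GVE2-like HNHE there, mirroring the universal, packaging-associated
member of that family. The two I-HmuI-like loci sit in the replication
and regulation modules; 13 remnants are flagged truncated; the 630
`UNCLASSIFIED` rows are ordinary genes that entered candidate screening
and were correctly rejected. The I-HmuI-like tree splits into
locus × lineage clusters that track the starter culture perfectly
(`res$association$cramers_v` is 1, permutation p ≈ 0.001).

The EOP arithmetic reproduces the canonical control ratio:

```r
efficiency_of_plaquing(7.9e6, 1.0e9,
                       phage_label = "sk1", host_label = "NZ9000/pHNH7",
                       control_host_label = "NZ9000/pPTPi")
#> <eop_record> sk1 on NZ9000/pHNH7 vs NZ9000/pPTPi: EOP = 0.0079 (127-fold reduction, 1 replicate(s))
```

## Notes on scope

Classification scores queries against packaged *synthetic* reference
homologs (see `inst/extdata/hnhe_references_synthetic.fasta` and the
vignette) rather than a profile-profile search — self-contained and
deterministic, at the cost of remote-homology sensitivity. Structure
prediction, ORF calling, assembly and wet-lab protocols are out of
scope; annotated genomes are the input. See
`vignettes/heg-atlas-methods.Rmd` for the model, parameter meanings,
numerical choices and known limitations.
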