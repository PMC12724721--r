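# Regenerates the packaged synthetic HNHE reference homologs (one per
# family, catalytic architecture designed; see the methods vignette).
# Run from the package root; output is frozen under inst/extdata.
set.seed(20260925)
aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
rand_prot <- function(n) paste(sample(aa, n, replace = TRUE), collapse = "")
set_pos <- function(s, pos, res) { for (i in seq_along(pos)) substring(s, pos[i], pos[i]) <- res[i]; s }

ihmu <- set_pos(rand_prot(190), c(74, 75, 86, 96), c("D", "H", "N", "N"))
gve2 <- set_pos(rand_prot(220), c(99, 100, 115, 130), c("D", "H", "N", "H"))
paci <- set_pos(rand_prot(160), c(49, 50, 65, 80), c("D", "H", "N", "N"))

wrap <- function(s) paste(substring(s, seq(1, nchar(s), 60), pmin(seq(1, nchar(s), 60) + 59, nchar(s))), collapse = "\n")
writeLines(c(
  ">IHMU synthetic I-HmuI-like reference (catalytic D74 H75 N96)", wrap(ihmu),
  ">PACI synthetic PacI-like reference (catalytic D49 H50 N80)", wrap(paci),
  ">GVE2 synthetic GVE2-like reference (catalytic D99 H100 H130)", wrap(gve2)),
  "inst/extdata/hnhe_references_synthetic.fasta")

writeLines(c("family\tposition\tresidue",
  "IHMU\t74\tD", "IHMU\t75\tH", "IHMU\t96\tN",
  "PACI\t49\tD", "PACI\t50\tH", "PACI\t80\tN",
  "GVE2\t99\tD", "GVE2\t100\tH", "GVE2\t130\tH"),
  "inst/extdata/hnhe_reference_catalytic_synthetic.tsv")
cat("done\n")
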