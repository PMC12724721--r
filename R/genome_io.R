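# Genome, annotation and tabular I/O. Establishes the two conventions every
# downstream stage relies on: gene coordinates are 0-based half-open on the
# forward strand internally (GenBank's 1-based inclusive only at the file
# boundary), and gene identifiers are "<genome_id>|<locus_tag-or-index>" so
# they are unique cohort-wide without renaming inputs.

#' Construct an annotated phage genome
#'
#' @param genome_id character scalar.
#' @param sequence DNA string (A/C/G/T/N).
#' @param genes data.frame with columns `gene_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `protein_seq`, `product`. Rows are
#'   re-sorted by `start`.
#' @param metadata list with entries `starter`, `factory`, `year`; missing
#'   entries default to `"unknown"`.
#' @return An object of class `phage_genome`.
#' @export
phage_genome <- function(genome_id, sequence, genes,
                         metadata = list()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop(sprintf("genome '%s': sequence contains non-ACGTN symbols", genome_id),
         call. = FALSE)
  need <- c("gene_id", "start", "end", "strand", "protein_seq", "product")
  if (!all(need %in% names(genes)))
    stop("genes table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)[, need]
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  md <- list(starter = "unknown", factory = "unknown", year = "unknown")
  md[names(metadata)] <- metadata
  g <- structure(list(genome_id = genome_id, sequence = sequence,
                      genes = genes, metadata = md),
                 class = "phage_genome")
  validate_genome(g)
  g
}

#' Check the invariants of a phage_genome
#'
#' Coordinates in range and half-open, genes sorted by start with distinct
#' coordinates, unique gene identifiers, non-empty protein sequences, valid
#' strands, metadata keys present.
#'
#' @param g a `phage_genome`.
#' @return `g`, invisibly; errors otherwise.
#' @export
validate_genome <- function(g) {
  stopifnot(inherits(g, "phage_genome"))
  len <- nchar(g$sequence)
  gn <- g$genes
  if (nrow(gn)) {
    if (any(gn$start < 0) || any(gn$start >= gn$end) || any(gn$end > len))
      stop(sprintf("genome '%s': gene coordinates out of range", g$genome_id),
           call. = FALSE)
    if (anyDuplicated(gn$gene_id))
      stop(sprintf("genome '%s': duplicated gene_id", g$genome_id),
           call. = FALSE)
    if (anyDuplicated(gn[, c("start", "end")]))
      stop(sprintf("genome '%s': genes with identical coordinates",
                   g$genome_id), call. = FALSE)
    if (!all(gn$strand %in% c("+", "-")))
      stop(sprintf("genome '%s': strand must be '+' or '-'", g$genome_id),
           call. = FALSE)
    if (any(!nzchar(gn$protein_seq)))
      stop(sprintf("genome '%s': empty protein_seq for gene %s", g$genome_id,
                   gn$gene_id[!nzchar(gn$protein_seq)][1]), call. = FALSE)
  }
  if (!all(c("starter", "factory", "year") %in% names(g$metadata)))
    stop(sprintf("genome '%s': metadata keys starter/factory/year required",
                 g$genome_id), call. = FALSE)
  invisible(g)
}

#' @export
print.phage_genome <- function(x, ...) {
  cat(sprintf("<phage_genome> %s: %s bp, %d genes (starter=%s factory=%s year=%s)\n",
              x$genome_id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$genes), x$metadata$starter, x$metadata$factory,
              x$metadata$year))
  invisible(x)
}

#' G+C content of a genome
#' @param g a `phage_genome`.
#' @return fraction of G or C among A/C/G/T bases.
#' @export
gc_content <- function(g) {
  b <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
  sum(b %in% c("G", "C")) / sum(b %in% c("A", "C", "G", "T"))
}

#' Collect all proteins of a cohort
#' @param genomes list of `phage_genome`.
#' @return named character vector, names are cohort-wide gene ids.
#' @export
cohort_proteins <- function(genomes) {
  out <- unlist(unname(lapply(genomes, function(g)
    setNames(g$genes$protein_seq, g$genes$gene_id))))
  if (anyDuplicated(names(out)))
    stop("gene_id values are not unique cohort-wide", call. = FALSE)
  out
}

#' Map every gene id to its genome id
#' @param genomes list of `phage_genome`.
#' @return named character vector gene_id -> genome_id.
#' @export
gene_genome_map <- function(genomes) {
  unlist(unname(lapply(genomes, function(g)
    setNames(rep(g$genome_id, nrow(g$genes)), g$genes$gene_id))))
}

# ---- GenBank flat files -----------------------------------------------------

#' Read annotated phage genomes from a GenBank flat file
#'
#' Parses a (possibly multi-record) GenBank flat file whose CDS features carry
#' `/translation` qualifiers. CDS coordinates are converted from 1-based
#' inclusive to the package's 0-based half-open convention;
#' `complement(a..b)` gives strand `"-"`. Compound (`join`/`order`) locations
#' are rejected: the cohorts this package targets have no spliced genes.
#'
#' @param path file path.
#' @return A named list of `phage_genome`, one per record, metadata all
#'   `"unknown"` (attach with [attach_metadata()]).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stop(sprintf("'%s' is empty or not a GenBank flat file", path),
         call. = FALSE)
  starts <- grep("^LOCUS", lines)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) < length(starts))
    stop("GenBank record without terminating '//'", call. = FALSE)
  genomes <- lapply(seq_along(starts), function(k) {
    .parse_genbank_record(lines[starts[k]:ends[k]])
  })
  setNames(genomes, vapply(genomes, `[[`, "", "genome_id"))
}

.parse_genbank_record <- function(rec) {
  locus <- strsplit(trimws(sub("^LOCUS", "", rec[1])), "\\s+")[[1]]
  genome_id <- locus[1]

  ori <- grep("^ORIGIN", rec)
  if (!length(ori)) stop(sprintf("record '%s': no ORIGIN section", genome_id),
                         call. = FALSE)
  seq_lines <- rec[(ori + 1):(length(rec) - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat0 <- grep("^FEATURES", rec)
  feats <- if (length(feat0)) rec[(feat0 + 1):(ori - 1)] else character()
  # split feature block at feature keys (5-space indent, non-blank key)
  keys <- grep("^ {5}\\S", feats)
  cds <- list()
  idx <- 0L
  for (k in seq_along(keys)) {
    key <- trimws(substr(feats[keys[k]], 1, 20))
    if (key != "CDS") next
    to <- if (k < length(keys)) keys[k + 1] - 1 else length(feats)
    block <- feats[keys[k]:to]
    loc <- trimws(substr(block[1], 21, nchar(block[1])))
    # location may continue on following lines until the first qualifier
    qual0 <- grep("^ {21}/", block)
    if (length(qual0) && qual0[1] > 2)
      loc <- paste0(loc, paste(trimws(block[2:(qual0[1] - 1)]), collapse = ""))
    idx <- idx + 1L
    quals <- .parse_genbank_qualifiers(block[-1])
    tag <- if (!is.null(quals$locus_tag)) quals$locus_tag
           else sprintf("%03d", idx)
    if (grepl("join|order", loc))
      stop(sprintf("record '%s', CDS %s: compound location '%s' not supported",
                   genome_id, tag, loc), call. = FALSE)
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    if (length(nums) != 2)
      stop(sprintf("record '%s', CDS %s: cannot parse location '%s'",
                   genome_id, tag, loc), call. = FALSE)
    a <- as.integer(nums[1]); b <- as.integer(nums[2])
    if (is.null(quals$translation))
      stop(sprintf("record '%s': CDS %s has no /translation", genome_id, tag),
           call. = FALSE)
    cds[[idx]] <- data.frame(
      gene_id = paste0(genome_id, "|", tag),
      start = a - 1L, end = b, strand = strand,
      protein_seq = quals$translation,
      product = if (is.null(quals$product)) "" else quals$product,
      stringsAsFactors = FALSE)
  }
  genes <- if (length(cds)) do.call(rbind, cds) else
    data.frame(gene_id = character(), start = integer(), end = integer(),
               strand = character(), protein_seq = character(),
               product = character(), stringsAsFactors = FALSE)
  phage_genome(genome_id, sequence, genes)
}

.parse_genbank_qualifiers <- function(lines) {
  lines <- trimws(lines)
  starts <- grep("^/", lines)
  out <- list()
  for (k in seq_along(starts)) {
    to <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    txt <- paste(lines[starts[k]:to], collapse = "")
    m <- regmatches(txt, regexec('^/([A-Za-z_]+)(="?([^"]*)"?)?$', txt))[[1]]
    if (length(m) >= 2 && nzchar(m[2])) out[[m[2]]] <- m[4]
  }
  out
}

#' Write phage genomes as a GenBank flat file
#'
#' Emits one record per genome with a `source` feature and one CDS per gene
#' (with `/locus_tag`, `/product`, `/translation`). Round-trips through
#' [read_genbank()] field for field.
#'
#' @param genomes list of `phage_genome` (a single genome is accepted).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genomes, path) {
  if (inherits(genomes, "phage_genome")) genomes <- list(genomes)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (g in genomes) .write_genbank_record(g, con)
  invisible(path)
}

.wrap_qualifier <- function(text, width = 58) {
  n <- nchar(text)
  starts <- seq(1, n, by = width)
  substring(text, starts, pmin(starts + width - 1, n))
}

.write_genbank_record <- function(g, con) {
  len <- nchar(g$sequence)
  writeLines(sprintf("LOCUS       %-16s %11d bp    DNA     linear   PHG 01-JAN-2026",
                     g$genome_id, len), con)
  writeLines(sprintf("DEFINITION  phage %s.", g$genome_id), con)
  writeLines(sprintf("ACCESSION   %s", g$genome_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  writeLines(sprintf("                     /organism=\"phage %s\"", g$genome_id),
             con)
  for (i in seq_len(nrow(g$genes))) {
    gn <- g$genes[i, ]
    loc <- sprintf("%d..%d", gn$start + 1L, gn$end)
    if (gn$strand == "-") loc <- sprintf("complement(%s)", loc)
    tag <- sub(paste0("^", g$genome_id, "\\|"), "", gn$gene_id)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", tag), con)
    writeLines(sprintf("                     /product=\"%s\"", gn$product), con)
    tr <- .wrap_qualifier(sprintf("/translation=\"%s\"", gn$protein_seq))
    writeLines(paste0("                     ", tr), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$sequence)
  pos <- seq(1, len, by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, len))
    blocks <- .wrap_qualifier(chunk, 10)
    writeLines(sprintf("%9d %s", p, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
}

# ---- tabular inputs ---------------------------------------------------------

#' Read per-genome metadata
#'
#' TSV with header `genome_id`, `starter`, `factory`, `year`. Blank or NA
#' cells are normalised to `"unknown"`.
#'
#' @param path file path.
#' @param genome_ids optional character vector; every id listed gets an entry,
#'   defaulting to all-unknown when absent from the file.
#' @return named list (by genome_id) of lists with `starter`, `factory`,
#'   `year` (`year` integer or `"unknown"`).
#' @export
read_metadata <- function(path, genome_ids = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   na.strings = c("", "NA"))
  need <- c("genome_id", "starter", "factory", "year")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dup <- unique(df$genome_id[duplicated(df$genome_id)])
  if (length(dup))
    stop("duplicate genome_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  norm <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), "unknown",
                             trimws(x))
  out <- lapply(seq_len(nrow(df)), function(i) {
    yr <- norm(df$year[i])
    if (yr != "unknown") yr <- as.integer(yr)
    list(starter = norm(df$starter[i]), factory = norm(df$factory[i]),
         year = yr)
  })
  names(out) <- df$genome_id
  for (id in setdiff(genome_ids, names(out)))
    out[[id]] <- list(starter = "unknown", factory = "unknown",
                      year = "unknown")
  out
}

#' Attach metadata entries to genomes
#' @param genomes list of `phage_genome`.
#' @param metadata result of [read_metadata()].
#' @return the genomes, metadata slots filled (all-unknown when missing).
#' @export
attach_metadata <- function(genomes, metadata) {
  lapply(genomes, function(g) {
    if (!is.null(metadata[[g$genome_id]]))
      g$metadata[names(metadata[[g$genome_id]])] <- metadata[[g$genome_id]]
    g
  })
}

#' Write per-genome metadata as TSV
#' @param genomes list of `phage_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(genomes, path) {
  df <- do.call(rbind, lapply(genomes, function(g)
    data.frame(genome_id = g$genome_id, starter = g$metadata$starter,
               factory = g$metadata$factory, year = g$metadata$year,
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plaque-count table
#'
#' TSV with header `host_label`, `phage_label`, `dilution_exponent`,
#' `plaques`, `plated_volume_ml`. Dilution exponents must be `<= 0` (e.g. -6
#' for a 10^-6 dilution) and distinct within each host x phage assay.
#'
#' @param path file path.
#' @return data.frame with typed columns.
#' @export
read_plaque_counts <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("host_label", "phage_label", "dilution_exponent", "plaques",
            "plated_volume_ml")
  if (!all(need %in% names(df)))
    stop("plaque counts must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$dilution_exponent <- as.integer(df$dilution_exponent)
  df$plaques <- as.integer(df$plaques)
  df$plated_volume_ml <- as.numeric(df$plated_volume_ml)
  if (any(df$dilution_exponent > 0))
    stop("dilution_exponent must be <= 0", call. = FALSE)
  if (any(df$plaques < 0)) stop("plaques must be non-negative", call. = FALSE)
  if (any(df$plated_volume_ml <= 0))
    stop("plated_volume_ml must be positive", call. = FALSE)
  key <- paste(df$host_label, df$phage_label)
  for (k in unique(key)) {
    d <- df$dilution_exponent[key == k]
    if (anyDuplicated(d))
      stop(sprintf("assay '%s': duplicated dilution exponents", k),
           call. = FALSE)
  }
  df
}

#' Write protein sequences as FASTA
#' @param proteins named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#' @param path file path.
#' @return named character vector.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
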