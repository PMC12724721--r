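# Pairwise affine-gap alignment used by the similarity graph, the HNHE
# classifier and the distance computations. The dynamic program itself lives
# in src/align.cpp; this file handles encoding, scoring schemes and the
# derived statistics (percent identity, coverage).

# amino acids accepted in protein sequences (strict 20-letter alphabet plus
# X for unknown residues; X scores via BLOSUM62's X row)
.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
.DNA_LETTERS <- c("A", "C", "G", "T", "N")

.protein_sub_matrix <- function() {
  if (is.null(.hegatlas_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .hegatlas_env$blosum62 <- e$BLOSUM62[.AA_LETTERS, .AA_LETTERS]
  }
  .hegatlas_env$blosum62
}

.dna_sub_matrix <- function(match = 2, mismatch = -3) {
  m <- matrix(mismatch, 5, 5, dimnames = list(.DNA_LETTERS, .DNA_LETTERS))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

.encode_seq <- function(seq, letters, what = "sequence", id = NULL) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, letters)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    who <- if (is.null(id)) what else sprintf("%s '%s'", what, id)
    stop(sprintf("invalid symbol(s) %s in %s",
                 paste(sQuote(bad), collapse = ", "), who), call. = FALSE)
  }
  idx
}

#' Pairwise sequence alignment with affine gap penalties
#'
#' Aligns two sequences with the Gotoh algorithm. `type = "local"` gives a
#' Smith-Waterman alignment (used for the all-vs-all similarity graph and for
#' scoring queries against packaged HNHE references); `type = "global"` gives
#' a Needleman-Wunsch alignment (used for distance matrices and for mapping
#' catalytic residues between reference and query).
#'
#' Protein alignments use BLOSUM62 with gap open 10 and gap extension 0.5;
#' DNA alignments use match +2 / mismatch -3 with gap open 5 and extension 2.
#' Traceback tie-breaks are fixed, so results are fully deterministic.
#'
#' @param a,b character scalars, the two sequences.
#' @param type `"local"` or `"global"`.
#' @param alphabet `"protein"` or `"dna"`.
#' @param gap_open,gap_ext gap penalties (positive numbers); a gap of length
#'   L costs `gap_open + L * gap_ext`. Defaults depend on `alphabet`.
#' @param id_a,id_b optional identifiers used in error messages.
#' @return A list with elements `score`, `pct_identity` (percent identical
#'   over all alignment columns, gap columns included), `cov_a`, `cov_b`
#'   (aligned span as a fraction of each sequence length), `n_match`,
#'   `align_len`, `a_start`, `a_end`, `b_start`, `b_end` (1-based, 0 when the
#'   alignment is empty) and `a_idx`, `b_idx` (per-column 1-based residue
#'   indices, `NA` at gaps).
#' @export
align_pair <- function(a, b, type = c("local", "global"),
                       alphabet = c("protein", "dna"),
                       gap_open = NULL, gap_ext = NULL,
                       id_a = NULL, id_b = NULL) {
  type <- match.arg(type)
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("cannot align an empty sequence", call. = FALSE)
  if (alphabet == "protein") {
    sub <- .protein_sub_matrix()
    letters <- .AA_LETTERS
    if (is.null(gap_open)) gap_open <- 10
    if (is.null(gap_ext)) gap_ext <- 0.5
  } else {
    sub <- .dna_sub_matrix()
    letters <- .DNA_LETTERS
    if (is.null(gap_open)) gap_open <- 5
    if (is.null(gap_ext)) gap_ext <- 2
  }
  ea <- .encode_seq(a, letters, what = "sequence", id = id_a)
  eb <- .encode_seq(b, letters, what = "sequence", id = id_b)
  .align_core(ea, eb, sub, gap_open, gap_ext, type == "local")
}

# encoded-sequence fast path shared by the batch operations
.align_core <- function(ea, eb, sub, gap_open, gap_ext, local) {
  r <- .align_pair_cpp(ea, eb, sub, gap_open, gap_ext, local)
  r$pct_identity <- if (r$align_len > 0) 100 * r$n_match / r$align_len else 0
  r$cov_a <- if (r$a_start > 0) (r$a_end - r$a_start + 1) / length(ea) else 0
  r$cov_b <- if (r$b_start > 0) (r$b_end - r$b_start + 1) / length(eb) else 0
  r
}
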