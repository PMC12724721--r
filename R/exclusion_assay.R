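# Titres and efficiency of plaquing from double-agar overlay plaque counts.

#' Phage titre from a dilution series of plaque counts
#'
#' Per countable plate (plaques within `countable`), the single-plate titre
#' is `plaques / (plated_volume_ml * 10^dilution_exponent)`; the reported
#' titre is the mean of single-plate titres weighted by plaque count.
#'
#' @param counts data.frame with columns `dilution_exponent`, `plaques`,
#'   `plated_volume_ml` (one assay, distinct exponents).
#' @param countable inclusive countable range of plaques per plate.
#' @return titre in PFU per ml.
#' @export
titre_from_counts <- function(counts, countable = c(3L, 300L)) {
  need <- c("dilution_exponent", "plaques", "plated_volume_ml")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(counts$dilution_exponent))
    stop("dilution exponents must be distinct within an assay", call. = FALSE)
  ok <- counts$plaques >= countable[1] & counts$plaques <= countable[2]
  if (!any(ok))
    stop(sprintf("no dilution in the countable range [%d, %d]",
                 countable[1], countable[2]), call. = FALSE)
  p <- counts$plaques[ok]
  t <- p / (counts$plated_volume_ml[ok] * 10^counts$dilution_exponent[ok])
  sum(p * t) / sum(p)
}

#' Efficiency of plaquing
#'
#' `eop = test_titre / control_titre`, `fold_reduction = 1 / eop`. With
#' replicate titre vectors, per-replicate EOPs are reduced by geometric mean
#' (EOP is a ratio); an arithmetic-mean option is available for comparison
#' with common lab practice.
#'
#' @param test_titre,control_titre positive titres (PFU/ml); equal-length
#'   vectors are treated as paired replicates.
#' @param phage_label,host_label,control_host_label optional annotations.
#' @param aggregate `"geometric"` or `"arithmetic"` replicate reduction.
#' @return An `eop_record`: list with `eop`, `fold_reduction`, `test_titre`,
#'   `control_titre`, `replicate_eops`, and the labels.
#' @export
efficiency_of_plaquing <- function(test_titre, control_titre,
                                   phage_label = NA_character_,
                                   host_label = NA_character_,
                                   control_host_label = NA_character_,
                                   aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  if (any(test_titre <= 0) || any(control_titre <= 0))
    stop("titres must be positive", call. = FALSE)
  if (length(test_titre) != length(control_titre))
    stop("replicate titre vectors must have equal length", call. = FALSE)
  reps <- test_titre / control_titre
  eop <- if (aggregate == "geometric") exp(mean(log(reps))) else mean(reps)
  structure(list(eop = eop, fold_reduction = 1 / eop,
                 test_titre = test_titre, control_titre = control_titre,
                 replicate_eops = reps, phage_label = phage_label,
                 host_label = host_label,
                 control_host_label = control_host_label),
            class = "eop_record")
}

#' @export
print.eop_record <- function(x, ...) {
  cat(sprintf("<eop_record> %s on %s vs %s: EOP = %.4g (%.3g-fold reduction, %d replicate(s))\n",
              x$phage_label, x$host_label, x$control_host_label, x$eop,
              x$fold_reduction, length(x$replicate_eops)))
  invisible(x)
}

#' EOP straight from a plaque-count table
#'
#' @param counts table from [read_plaque_counts()].
#' @param phage_label phage to evaluate.
#' @param test_host,control_host host labels; titres are computed per host
#'   with [titre_from_counts()].
#' @param ... passed to [efficiency_of_plaquing()].
#' @return an `eop_record`.
#' @export
eop_from_counts <- function(counts, phage_label, test_host, control_host,
                            ...) {
  pick <- function(host) {
    sub <- counts[counts$phage_label == phage_label &
                    counts$host_label == host, , drop = FALSE]
    if (!nrow(sub))
      stop(sprintf("no counts for phage '%s' on host '%s'", phage_label,
                   host), call. = FALSE)
    titre_from_counts(sub)
  }
  efficiency_of_plaquing(pick(test_host), pick(control_host),
                         phage_label = phage_label, host_label = test_host,
                         control_host_label = control_host, ...)
}
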