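#' Classify ribosome association from polysome-profiling expression
#'
#' A transcript is called `associated` when its polysome-fraction level
#' reaches the detection threshold, `free` when only the ribosome-free
#' fraction does, and `undetected` otherwise.  Association strength is
#' the pseudocounted log2 ratio of polysome to free signal.
#'
#' @param transcript_id Character vector of transcript ids (recycled
#'   names for the output rows).
#' @param polysome_level,free_level Non-negative FPKM vectors.
#' @param detect Detection threshold in FPKM (> 0, default 1).
#' @param pseudocount Pseudocount in FPKM added to both levels before
#'   the log ratio (> 0, default 0.5).
#' @return Data frame with columns `transcript_id`, `polysome_level`,
#'   `free_level`, `strength` (log2), `class`.
#' @examples
#' classify_polysome_association("tx1", 8, 2)
#' @export
classify_polysome_association <- function(transcript_id, polysome_level,
                                          free_level, detect = 1,
                                          pseudocount = 0.5) {
  if (detect <= 0) stop("`detect` must be > 0", call. = FALSE)
  if (pseudocount <= 0) stop("`pseudocount` must be > 0", call. = FALSE)
  if (any(polysome_level < 0) || any(free_level < 0))
    stop("expression levels must be non-negative", call. = FALSE)
  class <- ifelse(polysome_level >= detect, "associated",
                  ifelse(free_level >= detect, "free", "undetected"))
  strength <- log2((polysome_level + pseudocount) /
                   (free_level + pseudocount))
  data.frame(transcript_id = as.character(transcript_id),
             polysome_level = polysome_level, free_level = free_level,
             strength = strength, class = class, stringsAsFactors = FALSE)
}

#' Classify every transcript in a long polysome-fraction table
#'
#' @param tab Data frame with columns `transcript_id`, `fraction`,
#'   `level` (one row per transcript x fraction).
#' @param polysome_fractions,free_fractions Fraction labels summed into
#'   the polysome and ribosome-free signals.
#' @param detect,pseudocount See [classify_polysome_association()].
#' @return Classification data frame, ranked by decreasing
#'   `polysome_level`, with an extra column `rank_by_strength`.
#' @export
classify_polysome_table <- function(tab, polysome_fractions = "polysome",
                                    free_fractions = "free",
                                    detect = 1, pseudocount = 0.5) {
  need <- c("transcript_id", "fraction", "level")
  if (!all(need %in% names(tab)))
    stop("table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  ids <- unique(as.character(tab$transcript_id))
  sum_over <- function(fr) vapply(ids, function(id) {
    sum(tab$level[tab$transcript_id == id & tab$fraction %in% fr])
  }, numeric(1))
  calls <- classify_polysome_association(ids, sum_over(polysome_fractions),
                                         sum_over(free_fractions),
                                         detect, pseudocount)
  calls <- calls[order(-calls$polysome_level), , drop = FALSE]
  calls$rank_by_strength <- rank(-calls$strength, ties.method = "min")
  rownames(calls) <- NULL
  calls
}

#' Distribution of a transcript over ribosome fractions
#'
#' Normalizes per-fraction abundances to percentages over the canonical
#' sucrose-gradient fraction order (free, 40S, 60S, monosome, polysome
#' by default).
#'
#' @param abundances Named non-negative numeric vector, one value per
#'   fraction, at least one positive.
#' @param transcript_id Optional transcript label.
#' @return A `FractionProfile`: list with `transcript_id`, `labels`,
#'   `percent` (sums to 100).
#' @examples
#' fraction_distribution(c(free = 0, `40S` = 10, `60S` = 10,
#'                         monosome = 20, polysome = 60))
#' @export
fraction_distribution <- function(abundances, transcript_id = NA_character_) {
  if (any(abundances < 0)) stop("abundances must be non-negative",
                                call. = FALSE)
  tot <- sum(abundances)
  if (tot == 0) stop("all-zero abundance vector", call. = FALSE)
  labels <- names(abundances) %||% paste0("fraction", seq_along(abundances))
  structure(list(transcript_id = transcript_id, labels = labels,
                 percent = setNames(100 * abundances / tot, labels)),
            class = "FractionProfile")
}

#' @export
print.FractionProfile <- function(x, ...) {
  cat("FractionProfile", if (!is.na(x$transcript_id)) x$transcript_id, "\n")
  print(round(x$percent, 2))
  invisible(x)
}

#' Total-variation distance between two fraction profiles
#'
#' Half the L1 distance between the percentage vectors, rescaled to
#' `[0, 1]`; 0 for identical profiles, 1 for disjoint mass.
#'
#' @param a,b `FractionProfile` objects with identical fraction labels
#'   in identical order.
#' @return Distance in `[0, 1]`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "FractionProfile"), inherits(b, "FractionProfile"))
  if (!identical(a$labels, b$labels))
    stop("fraction labels differ between profiles", call. = FALSE)
  sum(abs(a$percent - b$percent)) / 2 / 100
}

#' Read a long polysome-fraction table from TSV
#'
#' @param path TSV with columns `transcript_id`, `fraction`, `level`.
#' @return Data frame.
#' @export
read_polysome_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
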