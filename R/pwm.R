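DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from site counts
#'
#' Converts per-position nucleotide counts into a position probability
#' matrix with additive pseudocounts:
#' `p(pos, b) = (count(pos, b) + pseudocount) / (sum(counts(pos)) + 4 * pseudocount)`.
#'
#' @param site_counts Numeric 4 x width matrix of non-negative counts,
#'   rows in A, C, G, T order (row names optional but checked when
#'   present).
#' @param pseudocount Positive pseudocount added to every cell.
#' @param background Background nucleotide distribution over A, C, G, T
#'   (sums to 1); default uniform.
#' @return A `PWM`: list with `prob` (4 x width probability matrix),
#'   `background`, `width`, `pseudocount`.
#' @examples
#' counts <- matrix(c(3, 1, 0, 0), nrow = 4,
#'                  dimnames = list(c("A", "C", "G", "T"), NULL))
#' build_pwm(counts, pseudocount = 0.25)
#' @export
build_pwm <- function(site_counts, pseudocount = 0.25,
                      background = rep(0.25, 4)) {
  site_counts <- as.matrix(site_counts)
  if (nrow(site_counts) != 4L)
    stop("site_counts must have 4 rows (A, C, G, T)", call. = FALSE)
  if (ncol(site_counts) == 0L) stop("zero-width motif", call. = FALSE)
  if (!is.null(rownames(site_counts)) &&
      !identical(toupper(rownames(site_counts)), DNA_BASES))
    stop("rows must be in A, C, G, T order", call. = FALSE)
  if (any(site_counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0", call. = FALSE)
  background <- validate_background(background)
  prob <- sweep(site_counts + pseudocount, 2L,
                colSums(site_counts) + 4 * pseudocount, "/")
  dimnames(prob) <- list(DNA_BASES, NULL)
  structure(list(prob = prob, background = background,
                 width = ncol(prob), pseudocount = pseudocount),
            class = "PWM")
}

validate_background <- function(background) {
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be a positive length-4 distribution summing to 1",
         call. = FALSE)
  setNames(as.numeric(background), DNA_BASES)
}

# Internal constructor from an already-normalized probability matrix.
pwm_from_prob <- function(prob, background = rep(0.25, 4),
                          pseudocount = NA_real_) {
  prob <- as.matrix(prob)
  stopifnot(nrow(prob) == 4L)
  if (any(prob <= 0))
    stop("probability matrix must be strictly positive (pseudocount it)",
         call. = FALSE)
  if (any(abs(colSums(prob) - 1) > 1e-9))
    stop("each PWM position must sum to 1", call. = FALSE)
  dimnames(prob) <- list(DNA_BASES, NULL)
  structure(list(prob = prob, background = validate_background(background),
                 width = ncol(prob), pseudocount = pseudocount),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM: width %d, consensus %s\n", x$width, pwm_consensus(x)))
  print(round(x$prob, 3))
  invisible(x)
}

#' Consensus string of a PWM (maximum-probability base per position)
#'
#' @param pwm A `PWM`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$prob, 2L, which.max)], collapse = "")
}

# log2-odds score matrix (4 x width)
pwm_score_matrix <- function(pwm) {
  log2(pwm$prob / pwm$background)
}

#' Reverse complement of a PWM
#'
#' @param pwm A `PWM`.
#' @return A `PWM` scoring the reverse-complement motif.
#' @export
pwm_reverse_complement <- function(pwm) {
  prob <- pwm$prob[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  pwm_from_prob(prob, background = pwm$background[4:1],
                pseudocount = pwm$pseudocount)
}

#' Read a PWM from a whitespace-delimited text matrix
#'
#' Accepts 4-column (positions in rows) or 4-row (positions in columns)
#' layouts; the orientation whose per-position values sum to 1 is
#' chosen.  Values that do not sum to 1 are treated as site counts and
#' passed through [build_pwm()].
#'
#' @param path File path.  Lines starting with `#` or `>` are skipped.
#' @param pseudocount Pseudocount used when the file holds counts.
#' @param background Background distribution (default uniform).
#' @return A `PWM`.
#' @export
read_pwm <- function(path, pseudocount = 0.25, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|>|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  mat <- do.call(rbind, lapply(fields, as.numeric))
  if (any(is.na(mat))) stop("non-numeric PWM entries in ", path, call. = FALSE)
  if (ncol(mat) == 4L && nrow(mat) != 4L) {
    mat <- t(mat)                     # positions were rows
  } else if (nrow(mat) != 4L) {
    stop("PWM file must have 4 rows or 4 columns", call. = FALSE)
  } else if (ncol(mat) == 4L) {
    # ambiguous 4 x 4: prefer the orientation whose columns sum to 1
    if (any(abs(colSums(mat) - 1) > 1e-6) &&
        all(abs(rowSums(mat) - 1) <= 1e-6)) mat <- t(mat)
  }
  if (all(abs(colSums(mat) - 1) <= 1e-6)) {
    if (any(mat == 0)) {
      # re-pseudocount degenerate probability columns
      mat <- sweep(mat + pseudocount / 100, 2L,
                   colSums(mat) + 4 * pseudocount / 100, "/")
    }
    pwm_from_prob(mat, background = background)
  } else {
    build_pwm(mat, pseudocount = pseudocount, background = background)
  }
}

# Discretized per-position score contributions, in integer bins.
pwm_binned_contrib <- function(pwm, bin = 0.01) {
  round(pwm_score_matrix(pwm) / bin)
}

#' Null score distribution of a PWM under its background model
#'
#' Dynamic program over positions: per-position log2-odds contributions
#' are discretized to `bin`-bit steps and convolved under the background
#' distribution, yielding the exact distribution of the discretized
#' score of a random window.  The discretization error of a full-window
#' score is bounded by `width * bin / 2`.
#'
#' @param pwm A `PWM`.
#' @param bin Score bin width in bits (default 0.01).
#' @return List with `score` (bin centers, bits, ascending), `prob`,
#'   and `tail` (`P(S >= score)`), plus `bin`.
#' @export
pwm_null_distribution <- function(pwm, bin = 0.01) {
  k <- pwm_binned_contrib(pwm, bin)         # 4 x width integer bins
  lo <- sum(apply(k, 2L, min)); hi <- sum(apply(k, 2L, max))
  p <- numeric(hi - lo + 1L)                # index = binsum - lo + 1
  # start before any position: all mass at 0
  cur_lo <- 0L
  p[1L] <- 1
  cur <- 1                                  # current vector length
  vec <- c(1)
  for (j in seq_len(pwm$width)) {
    new_lo <- cur_lo + min(k[, j]); new_hi <- cur_lo + (cur - 1L) + max(k[, j])
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + k[b, j] - new_lo
      idx <- seq_len(cur) + off
      new[idx] <- new[idx] + vec * pwm$background[b]
    }
    vec <- new; cur <- length(new); cur_lo <- new_lo
  }
  score <- (seq_len(cur) - 1L + cur_lo) * bin
  list(score = score, prob = vec, tail = rev(cumsum(rev(vec))), bin = bin)
}

#' P-value of a PWM score under the background null
#'
#' The probability that a random background window of the motif's width
#' scores at least `score` bits, from the discretized dynamic program of
#' [pwm_null_distribution()].  Scores below the attainable minimum give
#' p = 1; above the maximum, p = 0.
#'
#' @param pwm A `PWM`.
#' @param score Log2-odds score(s) in bits.
#' @param bin Discretization bin in bits.
#' @param null Optional precomputed [pwm_null_distribution()] (reused
#'   across many queries during scanning).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
score_pvalue <- function(pwm, score, bin = 0.01, null = NULL) {
  if (is.null(null)) null <- pwm_null_distribution(pwm, bin)
  kq <- round(score / null$bin)
  k0 <- round(null$score[1L] / null$bin)
  idx <- kq - k0 + 1L
  out <- numeric(length(score))
  out[idx < 1L] <- 1
  out[idx > length(null$tail)] <- 0
  ok <- idx >= 1L & idx <= length(null$tail)
  out[ok] <- null$tail[idx[ok]]
  out
}

seq_to_index <- function(seq) {
  if (inherits(seq, "XString")) seq <- as.character(seq)
  match(strsplit(toupper(seq), "")[[1L]], DNA_BASES)  # N etc. -> NA
}

# all-offset log2-odds scores; NA where the window contains a non-ACGT base
scan_scores <- function(pwm, idx) {
  w <- pwm$width
  L <- length(idx)
  if (L < w) return(numeric(0))
  S <- pwm_score_matrix(pwm)
  n_off <- L - w + 1L
  sc <- numeric(n_off)
  for (j in seq_len(w)) {
    contrib <- S[, j][idx[j:(j + n_off - 1L)]]
    sc <- sc + contrib                      # NA propagates for N windows
  }
  sc
}

#' Scan a sequence with a PWM (FIMO-style)
#'
#' Scores every offset of `seq` with the log2-odds matrix of `pwm`
#' against its background; optionally also scans the reverse strand via
#' the reverse-complement matrix, reporting coordinates on the forward
#' sequence.  Windows containing non-ACGT characters are skipped.  Hits
#' with p-value at or below `p_threshold` are returned sorted by start
#' position.  Hits are reported per strand; a palindromic motif can
#' legitimately appear on both strands at the same position.
#'
#' @param pwm A `PWM`.
#' @param seq Nucleotide string (character or `Biostrings::DNAString`).
#' @param p_threshold Report hits with `p <= p_threshold` (default 1e-4,
#'   the usual motif-occurrence convention).
#' @param strands `"both"` (default) or `"forward"`.
#' @param sequence_id Label carried into the result.
#' @param bin Score-discretization bin for the p-value null.
#' @return Data frame: `sequence_id`, `start` (0-based), `end`
#'   (exclusive), `strand`, `score` (bits), `p_value`.
#' @export
scan_sequence <- function(pwm, seq, p_threshold = 1e-4,
                          strands = c("both", "forward"),
                          sequence_id = "seq", bin = 0.01) {
  strands <- match.arg(strands)
  stopifnot(inherits(pwm, "PWM"))
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must be in (0, 1]", call. = FALSE)
  idx <- seq_to_index(seq)
  L <- length(idx)
  w <- pwm$width
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (L < w) return(empty)
  null <- pwm_null_distribution(pwm, bin)
  hits <- list()
  fwd <- scan_scores(pwm, idx)
  collect <- function(sc, strand, null) {
    ok <- which(!is.na(sc))
    if (!length(ok)) return(NULL)
    p <- score_pvalue(pwm, sc[ok], null = null)
    keep <- p <= p_threshold
    if (!any(keep)) return(NULL)
    start <- ok[keep] - 1L
    data.frame(sequence_id = sequence_id, start = start, end = start + w,
               strand = strand, score = sc[ok][keep], p_value = p[keep],
               stringsAsFactors = FALSE)
  }
  hits$fwd <- collect(fwd, "+", null)
  if (strands == "both") {
    rc <- pwm_reverse_complement(pwm)
    # scoring the forward sequence with the reverse-complement matrix at
    # offset i equals scoring the reverse complement of that window with
    # the original matrix; p-values use the RC matrix's own null (it
    # differs when the background is not complement-symmetric)
    rev_sc <- scan_scores(rc, idx)
    null_rc <- pwm_null_distribution(rc, bin)
    hits$rev <- collect(rev_sc, "-", null_rc)
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write motif hits or conserved windows as BED6
#'
#' Scores are bits scaled by 100 and truncated, per BED convention of
#' integer scores.
#'
#' @param hits Data frame from [scan_sequence()] (needs `sequence_id`,
#'   `start`, `end`, `score`, `strand`) or conserved windows (strand
#'   filled with `.`).
#' @param path Output path.
#' @param name Feature name column (recycled), e.g. the motif name.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(hits, path, name = "hit") {
  bed <- data.frame(chrom = hits$sequence_id,
                    start = hits$start, end = hits$end,
                    name = rep_len(name, nrow(hits)),
                    score = trunc(hits$score * 100),
                    strand = if ("strand" %in% names(hits)) hits$strand else ".",
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
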