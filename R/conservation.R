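#' Detect conserved promoter windows between two TSS-anchored sequences
#'
#' Slides an ungapped window at matched TSS-relative offsets in both
#' promoters and reports maximal runs where percent identity meets the
#' threshold; overlapping qualifying windows are merged into one region
#' whose identity is recomputed over the merged span.  Coordinates are
#' 0-based, half-open, relative to the common sequence start and apply
#' to both species (the alignment is positional, with no indels).
#'
#' @param seq_a,seq_b Promoter sequences (character or
#'   `Biostrings::DNAString`) anchored at the same TSS-relative start.
#' @param window_len Sliding-window length in nt (default 50).
#' @param identity_min Minimum percent identity per window (default 70;
#'   random sequence averages 25%).
#' @param length_tolerance Maximum tolerated length difference in nt;
#'   the longer sequence is truncated within the tolerance.
#' @return Data frame with columns `start`, `end`, `identity` (percent,
#'   over the merged region).  Zero rows when nothing qualifies.
#' @export
conserved_window_detect <- function(seq_a, seq_b, window_len = 50,
                                    identity_min = 70,
                                    length_tolerance = 0) {
  a <- seq_to_index(seq_a); b <- seq_to_index(seq_b)
  if (abs(length(a) - length(b)) > length_tolerance)
    stop(sprintf("promoter lengths differ by %d nt (> tolerance %d)",
                 abs(length(a) - length(b)), length_tolerance),
         call. = FALSE)
  L <- min(length(a), length(b))
  empty <- data.frame(start = integer(), end = integer(),
                      identity = numeric())
  if (window_len > L)
    stop("window_len exceeds sequence length", call. = FALSE)
  m <- !is.na(a[seq_len(L)]) & !is.na(b[seq_len(L)]) &
    a[seq_len(L)] == b[seq_len(L)]
  # rolling identity over every window start
  cs <- c(0, cumsum(m))
  n_win <- L - window_len + 1L
  ident <- (cs[(window_len + 1L):(L + 1L)] - cs[seq_len(n_win)]) /
    window_len * 100
  qual <- which(ident >= identity_min)
  if (!length(qual)) return(empty)
  # union of qualifying windows -> contiguous runs
  covered <- logical(L)
  for (s in qual) covered[s:(s + window_len - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  data.frame(start = starts[runs] - 1L, end = ends[runs],
             identity = vapply(runs, function(i)
               mean(m[starts[i]:ends[i]]) * 100, numeric(1)))
}

#' Pair same-motif hits shared between species inside conserved windows
#'
#' Emits one pair per combination of a species-A hit and a species-B hit
#' of the same motif that both fall entirely inside the same conserved
#' window and whose TSS-relative intervals overlap by at least 1 nt.
#'
#' @param hits_a,hits_b Motif-hit data frames (from [scan_sequence()])
#'   with an extra `motif` column naming the PWM.
#' @param windows Conserved windows from [conserved_window_detect()].
#' @return Data frame with `motif`, `start_a`, `end_a`, `strand_a`,
#'   `score_a`, `p_a`, the `_b` equivalents, and `window_start`,
#'   `window_end`.
#' @export
cross_species_site_pairs <- function(hits_a, hits_b, windows) {
  empty <- data.frame(motif = character(), start_a = integer(),
                      end_a = integer(), strand_a = character(),
                      score_a = numeric(), p_a = numeric(),
                      start_b = integer(), end_b = integer(),
                      strand_b = character(), score_b = numeric(),
                      p_b = numeric(), window_start = integer(),
                      window_end = integer(), stringsAsFactors = FALSE)
  if (nrow(hits_a) == 0L || nrow(hits_b) == 0L || nrow(windows) == 0L)
    return(empty)
  if (!("motif" %in% names(hits_a)) || !("motif" %in% names(hits_b)))
    stop("hits need a `motif` column", call. = FALSE)
  out <- list()
  for (w in seq_len(nrow(windows))) {
    ws <- windows$start[w]; we <- windows$end[w]
    ina <- hits_a[hits_a$start >= ws & hits_a$end <= we, , drop = FALSE]
    inb <- hits_b[hits_b$start >= ws & hits_b$end <= we, , drop = FALSE]
    if (nrow(ina) == 0L || nrow(inb) == 0L) next
    for (i in seq_len(nrow(ina))) for (j in seq_len(nrow(inb))) {
      if (ina$motif[i] != inb$motif[j]) next
      overlap <- min(ina$end[i], inb$end[j]) - max(ina$start[i], inb$start[j])
      if (overlap < 1L) next
      out[[length(out) + 1L]] <- data.frame(
        motif = ina$motif[i],
        start_a = ina$start[i], end_a = ina$end[i],
        strand_a = ina$strand[i], score_a = ina$score[i],
        p_a = ina$p_value[i],
        start_b = inb$start[j], end_b = inb$end[j],
        strand_b = inb$strand[j], score_b = inb$score[j],
        p_b = inb$p_value[j],
        window_start = ws, window_end = we,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan two species' promoters with named PWMs and pair conserved sites
#'
#' Convenience wrapper: detects conserved windows, scans both promoters
#' with every PWM, and pairs the shared sites.
#'
#' @param promoter_a,promoter_b Promoter sequences (TSS-anchored, same
#'   coordinate frame).
#' @param pwms Named list of `PWM` objects.
#' @param p_threshold,window_len,identity_min See [scan_sequence()] and
#'   [conserved_window_detect()].
#' @return List with `windows`, `hits_a`, `hits_b`, `pairs`.
#' @export
conserved_motif_analysis <- function(promoter_a, promoter_b, pwms,
                                     p_threshold = 1e-4, window_len = 50,
                                     identity_min = 70) {
  if (is.null(names(pwms)) || any(names(pwms) == ""))
    stop("`pwms` must be a named list", call. = FALSE)
  windows <- conserved_window_detect(promoter_a, promoter_b,
                                     window_len, identity_min)
  scan_all <- function(seq, id) {
    res <- lapply(names(pwms), function(nm) {
      h <- scan_sequence(pwms[[nm]], seq, p_threshold, sequence_id = id)
      if (nrow(h)) h$motif <- nm else h$motif <- character(0)
      h
    })
    do.call(rbind, res)
  }
  hits_a <- scan_all(promoter_a, "promoter_a")
  hits_b <- scan_all(promoter_b, "promoter_b")
  list(windows = windows, hits_a = hits_a, hits_b = hits_b,
       pairs = cross_species_site_pairs(hits_a, hits_b, windows))
}

#' Read promoter sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_promoters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
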