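#' Counts-per-million normalization
#'
#' @param raw Raw count vector.
#' @param library_size Total mapped reads (> 0).
#' @return `raw * 1e6 / library_size`.
#' @export
normalize_counts <- function(raw, library_size) {
  if (!is.numeric(library_size) || library_size <= 0)
    stop("library_size must be > 0", call. = FALSE)
  raw * 1e6 / library_size
}

#' Construct a replicated expression time course
#'
#' @param tab Long data frame with columns `timepoint_label`, `hours`,
#'   `replicate`, `level` (normalized expression, e.g. CPM).  Hours must
#'   be strictly increasing across distinct timepoints; at least two
#'   timepoints are required.
#' @param series Optional series label (e.g. `"ribo"`, `"rna"`).
#' @return A `TimeCourse`: list with `series`, `labels`, `hours`,
#'   `levels` (list of replicate vectors per timepoint), `means`.
#' @export
time_course <- function(tab, series = NA_character_) {
  need <- c("timepoint_label", "hours", "replicate", "level")
  if (!all(need %in% names(tab)))
    stop("time course needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(tab$level < 0)) stop("levels must be >= 0", call. = FALSE)
  grid <- unique(tab[, c("timepoint_label", "hours")])
  grid <- grid[order(grid$hours), , drop = FALSE]
  if (nrow(grid) < 2L) stop("need >= 2 timepoints", call. = FALSE)
  if (anyDuplicated(grid$hours) || anyDuplicated(grid$timepoint_label))
    stop("timepoint labels/hours must map one-to-one", call. = FALSE)
  levels <- lapply(seq_len(nrow(grid)), function(i)
    tab$level[tab$hours == grid$hours[i]])
  structure(list(series = series,
                 labels = grid$timepoint_label,
                 hours = grid$hours,
                 levels = levels,
                 means = vapply(levels, mean, numeric(1))),
            class = "TimeCourse")
}

#' Peak timepoint of a time course
#'
#' The timepoint with the maximal replicate mean; ties are broken toward
#' the earliest tied timepoint (the biological-onset reading).
#'
#' @param tc A [time_course()].
#' @return List with `label`, `hours`, `mean`.
#' @export
timecourse_peak <- function(tc) {
  stopifnot(inherits(tc, "TimeCourse"))
  i <- which.max(tc$means)   # first maximum = earliest tie
  list(label = tc$labels[i], hours = tc$hours[i], mean = tc$means[i])
}

#' Peak-timing shift between ribosome-protected and total RNA series
#'
#' Applies [timecourse_peak()] to both series on an identical timepoint
#' grid and reports the lag (ribosome peak minus RNA peak, in hours).
#' A positive lag means ribosome association peaks after transcript
#' abundance.
#'
#' @param ribo,rna [time_course()] objects on the same grid.
#' @return A `DynamicsCall`: list with `ribo_peak`, `rna_peak` (each as
#'   returned by [timecourse_peak()]) and `lag_hours`.
#' @export
translational_shift <- function(ribo, rna) {
  stopifnot(inherits(ribo, "TimeCourse"), inherits(rna, "TimeCourse"))
  if (!identical(ribo$hours, rna$hours) ||
      !identical(ribo$labels, rna$labels))
    stop("timepoint grids differ between series", call. = FALSE)
  pr <- timecourse_peak(ribo); pt <- timecourse_peak(rna)
  structure(list(ribo_peak = pr, rna_peak = pt,
                 lag_hours = pr$hours - pt$hours),
            class = "DynamicsCall")
}

#' @export
print.DynamicsCall <- function(x, ...) {
  cat(sprintf(
    "DynamicsCall: ribo peak %s (%g h), RNA peak %s (%g h), lag %+g h\n",
    x$ribo_peak$label, x$ribo_peak$hours,
    x$rna_peak$label, x$rna_peak$hours, x$lag_hours))
  invisible(x)
}

#' Read a time-course TSV
#'
#' Expected columns: `series`, `timepoint_label`, `hours`, `replicate`,
#' `level`.
#'
#' @param path TSV path.
#' @param series Optional series to filter on.
#' @return A [time_course()] (or, when `series = NULL` and several
#'   series are present, a named list of them).
#' @export
read_time_course <- function(path, series = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(series)) {
    return(time_course(tab[tab$series == series, , drop = FALSE], series))
  }
  ser <- unique(tab$series)
  if (length(ser) == 1L)
    return(time_course(tab, ser))
  setNames(lapply(ser, function(s)
    time_course(tab[tab$series == s, , drop = FALSE], s)), ser)
}

#' Construct a per-position footprint coverage track
#'
#' @param counts Non-negative integer vector of footprint counts,
#'   position 0 first.
#' @param start_codon 0-based position of the annotated start codon
#'   (must lie inside the track).
#' @param transcript_id Transcript label.
#' @return A `CoverageTrack` list.
#' @export
coverage_track <- function(counts, start_codon, transcript_id = "tx") {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (start_codon < 0 || start_codon >= length(counts))
    stop("start codon outside track", call. = FALSE)
  structure(list(transcript_id = transcript_id,
                 counts = as.numeric(counts),
                 start_codon = as.integer(start_codon)),
            class = "CoverageTrack")
}

#' Detect ribosome footprint pile-ups (candidate stall sites)
#'
#' For every position, a robust z-score is computed against its local
#' context: `z = (count - median(window)) / max(MAD(window), mad_floor)`
#' where the window spans `flank` nt either side (inclusive of the
#' position) and MAD is the median absolute deviation with the usual
#' normal-consistency constant 1.4826, so `z` is on the scale of
#' standard deviations.  Positions with
#' `z >= z_min` are reported; calls within `merge_dist` nt are merged
#' keeping the maximal-z position.  The start-proximal ratio contrasts
#' mean coverage over the first `start_codons` codons downstream of the
#' start codon with the mean over the rest of the track.
#'
#' @param track A [coverage_track()].
#' @param flank Half-width of the local window in nt (>= 5, default 25).
#' @param z_min Calling threshold on the robust z (default 5).
#' @param mad_floor Lower bound on the MAD, in counts (default 1),
#'   preventing division by zero on locally flat tracks.
#' @param merge_dist Merge called positions within this many nt
#'   (default 3).
#' @param start_codons Codons counted as "start-proximal" (default 50,
#'   i.e. 150 nt).
#' @return List with `peaks` (data frame `position`, `z`,
#'   `fold_over_median`), `start_proximal_ratio` (NA with a flag when
#'   undefined), `flags`.
#' @export
stall_peak_detect <- function(track, flank = 25, z_min = 5, mad_floor = 1,
                              merge_dist = 3, start_codons = 50) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (flank < 5) stop("flank must be >= 5", call. = FALSE)
  if (z_min <= 0) stop("z_min must be > 0", call. = FALSE)
  x <- track$counts
  L <- length(x)
  if (L < 2 * flank + 1)
    stop("track shorter than 2*flank + 1", call. = FALSE)
  z <- numeric(L); med <- numeric(L)
  for (i in seq_len(L)) {
    lo <- max(1L, i - flank); hi <- min(L, i + flank)
    win <- x[lo:hi]
    m <- median(win)
    s <- max(1.4826 * median(abs(win - m)), mad_floor)
    med[i] <- m
    z[i] <- (x[i] - m) / s
  }
  called <- which(z >= z_min)
  peaks <- data.frame(position = integer(), z = numeric(),
                      fold_over_median = numeric())
  if (length(called)) {
    grp <- cumsum(c(1L, diff(called) > merge_dist))
    keep <- vapply(split(called, grp), function(pos)
      pos[which.max(z[pos])], integer(1))
    peaks <- data.frame(position = unname(keep) - 1L,
                        z = z[keep],
                        fold_over_median =
                          ifelse(med[keep] > 0, x[keep] / med[keep], Inf))
    peaks <- peaks[order(peaks$position), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  sc <- track$start_codon + 1L
  prox_hi <- min(L, sc + 3L * start_codons - 1L)
  prox <- sc:prox_hi
  rest <- setdiff(seq_len(L), prox)
  flags <- character()
  if (length(rest) == 0L || mean(x[rest]) == 0) {
    ratio <- NA_real_
    flags <- c(flags, "start_proximal_ratio_undefined")
  } else {
    ratio <- mean(x[prox]) / mean(x[rest])
  }
  list(peaks = peaks, start_proximal_ratio = ratio, flags = flags)
}

#' Read transcript-relative coverage tracks from a bedGraph file
#'
#' The bedGraph holds 0-based half-open intervals with a count value;
#' one "chromosome" per transcript.  Start-codon offsets come from a
#' companion TSV (`transcript_id`, `start_codon`).
#'
#' @param path bedGraph path (track/comment lines are skipped).
#' @param starts_path TSV of start-codon offsets.
#' @return Named list of [coverage_track()] objects.
#' @export
read_coverage_bedgraph <- function(path, starts_path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bg <- data.frame(tx = vapply(f, `[[`, "", 1L),
                   start = as.integer(vapply(f, `[[`, "", 2L)),
                   end = as.integer(vapply(f, `[[`, "", 3L)),
                   value = as.numeric(vapply(f, `[[`, "", 4L)),
                   stringsAsFactors = FALSE)
  starts <- read.delim(starts_path, stringsAsFactors = FALSE)
  out <- lapply(unique(bg$tx), function(id) {
    b <- bg[bg$tx == id, , drop = FALSE]
    counts <- numeric(max(b$end))
    for (i in seq_len(nrow(b)))
      counts[(b$start[i] + 1L):b$end[i]] <- b$value[i]
    sc <- starts$start_codon[starts$transcript_id == id]
    if (!length(sc)) stop("no start codon for ", id, call. = FALSE)
    coverage_track(counts, sc[1L], id)
  })
  setNames(out, unique(bg$tx))
}

#' Write coverage tracks to bedGraph (plus start-codon TSV)
#'
#' @param tracks Named list of [coverage_track()] objects.
#' @param path bedGraph output path.
#' @param starts_path Start-codon TSV output path.
#' @return Invisibly, `path`.
#' @export
write_coverage_bedgraph <- function(tracks, path, starts_path) {
  con <- file(path, "w"); on.exit(close(con))
  for (tr in tracks) {
    r <- rle(tr$counts)
    end <- cumsum(r$lengths); start <- end - r$lengths
    keep <- TRUE  # keep zero runs: track length is meaningful
    writeLines(sprintf("%s\t%d\t%d\t%g", tr$transcript_id,
                       start[keep], end[keep], r$values[keep]), con)
  }
  starts <- data.frame(
    transcript_id = vapply(tracks, `[[`, "", "transcript_id"),
    start_codon = vapply(tracks, function(t) t$start_codon, integer(1)))
  write.table(starts, starts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
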