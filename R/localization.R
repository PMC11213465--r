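#' Nuclear/cytoplasmic localization from single-molecule FISH spot counts
#'
#' Computes the per-cell cytoplasmic percentage over cells with at least
#' one spot and aggregates by the median (robust to segmentation
#' outliers).  A pooled-spot estimate is reported alongside.  Cells with
#' zero spots are excluded from the statistics and counted in QC; a low
#' cell count raises a QC flag.
#'
#' @param cells Data frame with columns `cell_id`, `nuclear_spots`,
#'   `cytoplasmic_spots` (non-negative integers).
#' @param min_cells Minimum number of informative cells before the
#'   `low_n` QC flag is raised (default 100, the usual smFISH practice
#'   of scoring at least 100 cells).
#' @return A `LocalizationResult`: list with `method = "fish"`,
#'   `percent_cytoplasmic` (median of per-cell percentages),
#'   `percent_nuclear`, `pooled_percent_cytoplasmic`, `per_cell`
#'   (numeric vector), `n_cells` (informative cells), `n_zero_cells`,
#'   `qc_flags` (character vector, empty when clean).
#' @examples
#' cells <- data.frame(cell_id = 1:3, nuclear_spots = c(40, 35, 45),
#'                     cytoplasmic_spots = c(60, 65, 55))
#' fish_localization(cells, min_cells = 3)
#' @export
fish_localization <- function(cells, min_cells = 100) {
  need <- c("cell_id", "nuclear_spots", "cytoplasmic_spots")
  if (!all(need %in% names(cells)))
    stop("cells needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(cells) == 0L) stop("no cells supplied", call. = FALSE)
  nuc <- cells$nuclear_spots; cyt <- cells$cytoplasmic_spots
  if (any(nuc < 0) || any(cyt < 0) ||
      any(nuc != round(nuc)) || any(cyt != round(cyt)))
    stop("spot counts must be non-negative integers", call. = FALSE)
  total <- nuc + cyt
  keep <- total > 0
  if (!any(keep)) stop("no cell has any spot", call. = FALSE)
  per_cell <- 100 * cyt[keep] / total[keep]
  names(per_cell) <- as.character(cells$cell_id[keep])
  qc <- character()
  if (sum(keep) < min_cells) qc <- c(qc, "low_n")
  if (any(!keep)) qc <- c(qc, "zero_spot_cells")
  pct <- unname(median(per_cell))
  structure(list(method = "fish",
                 percent_cytoplasmic = pct,
                 percent_nuclear = 100 - pct,
                 pooled_percent_cytoplasmic =
                   100 * sum(cyt[keep]) / sum(total[keep]),
                 per_cell = per_cell,
                 n_cells = sum(keep),
                 n_zero_cells = sum(!keep),
                 qc_flags = qc),
            class = "LocalizationResult")
}

#' @export
print.LocalizationResult <- function(x, ...) {
  cat(sprintf("LocalizationResult (%s): %.1f%% cytoplasmic / %.1f%% nuclear",
              x$method, x$percent_cytoplasmic, x$percent_nuclear))
  if (!is.null(x$n_cells)) cat(sprintf(" [n = %d cells]", x$n_cells))
  cat("\n")
  if (length(x$qc_flags)) cat("  QC:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Bundle a qPCR measurement (target and reference Ct)
#'
#' @param target_ct,reference_ct Cycle-threshold values (finite).
#' @param efficiency Amplification efficiency as fold per cycle
#'   (default 2, perfect doubling; must be > 1).
#' @return A `QpcrMeasurement` list.
#' @export
qpcr_measurement <- function(target_ct, reference_ct, efficiency = 2) {
  if (!is.finite(target_ct) || !is.finite(reference_ct))
    stop("Ct values must be finite", call. = FALSE)
  if (!is.finite(efficiency) || efficiency <= 1)
    stop("efficiency must be > 1", call. = FALSE)
  structure(list(target_ct = target_ct, reference_ct = reference_ct,
                 efficiency = efficiency), class = "QpcrMeasurement")
}

#' Relative quantification (delta-delta-Ct) of one measurement vs another
#'
#' `fold = E^((Ct_target,b - Ct_ref,b) - (Ct_target,a - Ct_ref,a))`,
#' i.e. how many fold more target RNA measurement `a` contains than `b`
#' after normalizing both to their reference transcript.
#'
#' @param a,b [qpcr_measurement()] objects sharing the same efficiency.
#' @return Fold change of `a` relative to `b` (dimensionless).
#' @examples
#' a <- qpcr_measurement(20, 15)  # delta-Ct 5
#' b <- qpcr_measurement(22, 15)  # delta-Ct 7
#' relative_quantification(a, b)  # 2^2 = 4
#' @export
relative_quantification <- function(a, b) {
  stopifnot(inherits(a, "QpcrMeasurement"), inherits(b, "QpcrMeasurement"))
  if (!isTRUE(all.equal(a$efficiency, b$efficiency)))
    stop("measurements must share the efficiency model", call. = FALSE)
  d_a <- a$target_ct - a$reference_ct
  d_b <- b$target_ct - b$reference_ct
  a$efficiency^(d_b - d_a)
}

#' Nuclear/cytoplasmic localization from fractionation qPCR
#'
#' Converts the cytoplasm-vs-nucleus relative quantification `r` of the
#' target into `percent_cytoplasmic = 100 r / (1 + r)`.  Fractionation
#' quality is checked with control transcripts of known localization:
#' QC fails when any nuclear control computes > 50% cytoplasmic or any
#' cytosolic control < 50%.
#'
#' @param cyto,nuc [qpcr_measurement()] of the target in the cytosolic
#'   and nuclear fractions.
#' @param controls Named list; each element a list with `type` (one of
#'   `"nuclear"`, `"cytosolic"`), `cyto` and `nuc`
#'   ([qpcr_measurement()] objects).  At least one control of each type
#'   is required.
#' @return A `LocalizationResult` with `method = "fractionation"` and a
#'   `controls` data frame (`name`, `type`, `percent_cytoplasmic`,
#'   `pass`).
#' @export
fractionation_localization <- function(cyto, nuc, controls) {
  types <- vapply(controls, function(x) x$type, character(1))
  if (!any(types == "nuclear") || !any(types == "cytosolic"))
    stop("need >= 1 nuclear and >= 1 cytosolic control", call. = FALSE)
  pct_cyto <- function(c_meas, n_meas) {
    r <- relative_quantification(c_meas, n_meas)
    100 * r / (1 + r)
  }
  ctrl <- data.frame(
    name = names(controls) %||% paste0("control", seq_along(controls)),
    type = types,
    percent_cytoplasmic = vapply(controls, function(x)
      pct_cyto(x$cyto, x$nuc), numeric(1)),
    stringsAsFactors = FALSE)
  ctrl$pass <- ifelse(ctrl$type == "nuclear",
                      ctrl$percent_cytoplasmic <= 50,
                      ctrl$percent_cytoplasmic >= 50)
  qc <- character()
  if (any(!ctrl$pass))
    qc <- paste0("control_failed:", ctrl$name[!ctrl$pass])
  pct <- pct_cyto(cyto, nuc)
  structure(list(method = "fractionation",
                 percent_cytoplasmic = pct,
                 percent_nuclear = 100 - pct,
                 controls = ctrl,
                 qc_flags = qc),
            class = "LocalizationResult")
}

#' Read a FISH spot-count table from TSV
#'
#' @param path TSV with columns `cell_id`, `nuclear_spots`,
#'   `cytoplasmic_spots`.
#' @return Data frame.
#' @export
read_fish_table <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Read a long fractionation qPCR Ct table from TSV
#'
#' Expected columns: `target`, `fraction` (`cyto`/`nuc`), `ct`, and
#' `reference_ct` (Ct of the normalization transcript in that fraction).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_qpcr_table <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Run fractionation localization from a long Ct table
#'
#' @param tab Data frame as read by [read_qpcr_table()].
#' @param target Target transcript name.
#' @param nuclear_controls,cytosolic_controls Character vectors of
#'   control transcript names present in `tab`.
#' @param efficiency Amplification efficiency (fold per cycle).
#' @return A `LocalizationResult` (see [fractionation_localization()]).
#' @export
qpcr_localization <- function(tab, target, nuclear_controls,
                              cytosolic_controls, efficiency = 2) {
  meas <- function(name, fraction) {
    row <- tab[tab$target == name & tab$fraction == fraction, , drop = FALSE]
    if (nrow(row) == 0L)
      stop("no Ct row for ", name, " in fraction ", fraction, call. = FALSE)
    qpcr_measurement(row$ct[1L], row$reference_ct[1L], efficiency)
  }
  mk <- function(name, type)
    list(type = type, cyto = meas(name, "cyto"), nuc = meas(name, "nuc"))
  controls <- c(lapply(nuclear_controls, mk, type = "nuclear"),
                lapply(cytosolic_controls, mk, type = "cytosolic"))
  names(controls) <- c(nuclear_controls, cytosolic_controls)
  fractionation_localization(meas(target, "cyto"), meas(target, "nuc"),
                             controls)
}
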