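#' Score tissue specificity of every gene in an expression matrix
#'
#' A gene is called tissue-specific when its expression in the target
#' tissue exceeds a fold threshold over every other sample.  With
#' replicated target samples the strictest reading is used: the MINIMUM
#' over target-tissue samples must be at least `fold` times the MAXIMUM
#' over all non-target samples.  An absolute expression floor guards
#' against noise-only calls on near-silent genes.
#'
#' @param expr An [expression_matrix()].
#' @param target_tissue Tissue label to screen for (must appear in
#'   `expr$sample_meta$tissue`).
#' @param fold Fold threshold (dimensionless, > 0); the boundary is
#'   inclusive, so a ratio exactly equal to `fold` passes.
#' @param floor Minimum target-tissue FPKM (over all target samples)
#'   required before the fold rule is considered.
#' @return Data frame with one row per gene: `gene_id`, `target_min`,
#'   `other_max`, `ratio` (`NA` when `other_max` is 0), `passes_floor`,
#'   `passes_fold`.  When `other_max` is 0 and the floor is met the gene
#'   passes (infinite specificity).
#' @examples
#' m <- matrix(c(10, 1, 12, 0.8, 1.9, 0.9), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("h1", "h2", "l1")))
#' meta <- data.frame(sample_id = c("h1", "h2", "l1"), species = "human",
#'                    tissue = c("heart", "heart", "liver"),
#'                    replicate = c(1L, 2L, 1L))
#' compute_specificity(expression_matrix(m, meta), "heart")
#' @export
compute_specificity <- function(expr, target_tissue, fold = 5, floor = 0.5) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!is.numeric(fold) || fold <= 0) stop("`fold` must be > 0", call. = FALSE)
  if (!is.numeric(floor) || floor < 0) stop("`floor` must be >= 0", call. = FALSE)
  is_target <- expr$sample_meta$tissue == target_tissue
  if (!any(is_target))
    stop("unknown target tissue: ", target_tissue, call. = FALSE)
  if (all(is_target))
    stop("no non-target samples to compare against", call. = FALSE)
  tmat <- expr$values[, is_target, drop = FALSE]
  omat <- expr$values[, !is_target, drop = FALSE]
  target_min <- apply(tmat, 1L, min)
  other_max <- apply(omat, 1L, max)
  ratio <- ifelse(other_max > 0, target_min / other_max, NA_real_)
  passes_floor <- target_min >= floor
  passes_fold <- passes_floor &
    ifelse(other_max > 0, target_min / other_max >= fold, TRUE)
  data.frame(gene_id = expr$gene_ids,
             target_min = unname(target_min),
             other_max = unname(other_max),
             ratio = unname(ratio),
             passes_floor = unname(passes_floor),
             passes_fold = unname(passes_fold),
             stringsAsFactors = FALSE)
}

#' Partition screen candidates by annotation status
#'
#' @param candidates Character vector of candidate gene ids (order is
#'   preserved in the output).
#' @param annotation Character vector (or anything coercible) of
#'   annotated gene ids.
#' @return List with character vectors `retained` (candidates present in
#'   the annotation) and `excluded`.
#' @export
filter_annotation <- function(candidates, annotation) {
  candidates <- as.character(candidates)
  keep <- candidates %in% as.character(annotation)
  list(retained = candidates[keep], excluded = candidates[!keep])
}

#' Partition candidates by ortholog availability
#'
#' @param candidates Character vector of gene ids in species A.
#' @param omap Data frame ortholog map; first column species-A ids,
#'   second column species-B ids (extra columns such as a confidence
#'   score are carried through).  Duplicate pairs are dropped.
#' @return List with `mapped` (data frame `gene_id`, `partner_id`, one
#'   row per retained pair; multi-mapping candidates keep all partners)
#'   and `unmapped` (character vector).
#' @export
map_orthologs <- function(candidates, omap) {
  candidates <- as.character(candidates)
  if (is.null(omap) || nrow(omap) == 0L) {
    return(list(mapped = data.frame(gene_id = character(),
                                    partner_id = character(),
                                    stringsAsFactors = FALSE),
                unmapped = candidates))
  }
  pairs <- data.frame(gene_id = as.character(omap[[1L]]),
                      partner_id = as.character(omap[[2L]]),
                      stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  pairs <- pairs[pairs$gene_id %in% candidates, , drop = FALSE]
  # keep candidate order
  pairs <- pairs[order(match(pairs$gene_id, candidates)), , drop = FALSE]
  rownames(pairs) <- NULL
  list(mapped = pairs,
       unmapped = candidates[!candidates %in% pairs$gene_id])
}

#' Validate candidates by tissue specificity of their orthologs
#'
#' A candidate is validated when at least one of its ortholog partners
#' passes [compute_specificity()] in the second species with the same
#' fold and floor.  Partners absent from the second matrix are rejected
#' with reason `"absent"`.
#'
#' @param pairs Data frame with columns `gene_id`, `partner_id` (the
#'   `mapped` element of [map_orthologs()]).
#' @param expr_b [expression_matrix()] for the second species.
#' @param target_tissue,fold,floor Passed to [compute_specificity()].
#' @return List with `validated` and `rejected`: character vectors of
#'   candidate ids (a partition of `unique(pairs$gene_id)`), and
#'   `detail`: per-pair data frame with `partner_passes` and `reason`.
#' @export
cross_species_validate <- function(pairs, expr_b, target_tissue,
                                   fold = 5, floor = 0.5) {
  if (nrow(pairs) == 0L)
    return(list(validated = character(), rejected = character(),
                detail = cbind(pairs, partner_passes = logical(0),
                               reason = character(0))))
  calls <- compute_specificity(expr_b, target_tissue, fold = fold,
                               floor = floor)
  idx <- match(pairs$partner_id, calls$gene_id)
  passes <- !is.na(idx) & calls$passes_fold[idx]
  reason <- ifelse(is.na(idx), "absent",
                   ifelse(passes, "specific", "not_specific"))
  detail <- cbind(pairs,
                  data.frame(partner_passes = passes, reason = reason,
                             stringsAsFactors = FALSE))
  cand <- unique(pairs$gene_id)
  ok <- vapply(cand, function(g) any(passes[pairs$gene_id == g]), logical(1))
  list(validated = cand[ok], rejected = cand[!ok], detail = detail)
}

#' Assemble a screening funnel report
#'
#' Chains an ordered list of filter stages into a telescoping report:
#' each stage's input size must equal the previous stage's output size,
#' and within every stage `n_out = n_in - n_excluded`.
#'
#' @param stages Named list; each element a list with elements `stage`
#'   (name), `retained` and `excluded` (character vectors of gene ids).
#' @return A `FunnelReport`: list with `table` (data frame `stage`,
#'   `n_in`, `n_excluded`, `n_out`) and `excluded` (named list of
#'   excluded ids per stage).
#' @export
build_funnel_report <- function(stages) {
  if (length(stages) == 0L) stop("no stages supplied", call. = FALSE)
  n_in <- integer(length(stages)); n_ex <- integer(length(stages))
  names <- character(length(stages)); excl <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    s <- stages[[k]]
    names[k] <- s$stage %||% paste0("stage", k)
    n_in[k] <- length(s$retained) + length(s$excluded)
    n_ex[k] <- length(s$excluded)
    excl[[k]] <- s$excluded
    if (k > 1L) {
      prev_out <- n_in[k - 1L] - n_ex[k - 1L]
      if (n_in[k] != prev_out)
        stop(sprintf(
          "funnel chain violation: stage '%s' received %d genes but stage '%s' emitted %d",
          names[k], n_in[k], names[k - 1L], prev_out), call. = FALSE)
    }
  }
  tab <- data.frame(stage = names, n_in = n_in, n_excluded = n_ex,
                    n_out = n_in - n_ex, stringsAsFactors = FALSE)
  structure(list(table = tab, excluded = setNames(excl, names)),
            class = "FunnelReport")
}

#' @export
print.FunnelReport <- function(x, ...) {
  cat("Screening funnel:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Serialize a funnel report to JSON
#'
#' @param report A `FunnelReport` from [build_funnel_report()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
funnel_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "FunnelReport"))
  obj <- list(stages = report$table, excluded = report$excluded)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Run the full cross-species specificity screen
#'
#' Convenience wrapper chaining [compute_specificity()] on species A,
#' [filter_annotation()], [map_orthologs()] and
#' [cross_species_validate()] into a [build_funnel_report()].
#'
#' @param expr_a,expr_b [expression_matrix()] objects for the two
#'   species (`expr_b` may be `NULL` to stop after the ortholog stage).
#' @param target_tissue,fold,floor Screen parameters, applied
#'   identically in both species.
#' @param annotation Character vector of annotated gene ids.
#' @param omap Ortholog map data frame (see [map_orthologs()]).
#' @return List with `report` (`FunnelReport`), `calls` (per-gene
#'   specificity table in species A), `final` (validated candidate ids).
#' @export
run_screen <- function(expr_a, target_tissue, annotation, omap,
                       expr_b = NULL, fold = 5, floor = 0.5) {
  calls <- compute_specificity(expr_a, target_tissue, fold, floor)
  candidates <- calls$gene_id[calls$passes_fold]
  ann <- filter_annotation(candidates, annotation)
  orth <- map_orthologs(ann$retained, omap)
  stages <- list(
    list(stage = "annotation", retained = ann$retained,
         excluded = ann$excluded),
    list(stage = "ortholog",
         retained = setdiff(ann$retained, orth$unmapped),
         excluded = orth$unmapped))
  final <- setdiff(ann$retained, orth$unmapped)
  if (!is.null(expr_b)) {
    xs <- cross_species_validate(orth$mapped, expr_b, target_tissue,
                                 fold, floor)
    stages <- c(stages, list(list(stage = "cross_species",
                                  retained = xs$validated,
                                  excluded = xs$rejected)))
    final <- xs$validated
  }
  list(report = build_funnel_report(stages), calls = calls, final = final)
}
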