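#' Intersect independently derived protein-interactor sets
#'
#' @param sets List (>= 2) of character vectors of protein identifiers,
#'   e.g. the hit lists of independent RNA pull-down designs.
#' @return Character vector of identifiers shared by every set.
#' @examples
#' intersect_interactomes(list(c("A", "B", "DRG1"), c("C", "DRG1"),
#'                             c("D", "DRG1", "E")))
#' @export
intersect_interactomes <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 interactor sets", call. = FALSE)
  Reduce(intersect, lapply(sets, unique))
}

#' Count ribosome-stalling motif occurrences in a protein sequence
#'
#' Occurrences are counted at every offset, so overlapping matches all
#' count (e.g. `PPP` occurs twice in `APPPPK`).  `X` never matches.
#' A category is "present" when at least one of its motifs occurs.
#'
#' @param sequence Amino-acid string (single-letter code; `X` allowed).
#' @param motifs Named list of character vectors: category name ->
#'   fixed amino-acid motif strings (see [example_stalling_motifs()]).
#' @return List with `total` (all occurrences over all categories),
#'   `categories_present` (0..K), `per_category` (named integer).
#' @export
count_stalling_motifs <- function(sequence, motifs) {
  validate_motif_set(motifs)
  sequence <- toupper(as.character(sequence))
  per_cat <- vapply(motifs, function(mset) {
    sum(vapply(mset, function(m) count_overlapping(sequence, m), integer(1)))
  }, numeric(1))
  list(total = sum(per_cat),
       categories_present = sum(per_cat > 0),
       per_category = per_cat)
}

count_overlapping <- function(text, pattern) {
  if (nchar(text) < nchar(pattern) || nchar(text) == 0L) return(0L)
  hits <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) 0L else length(hits)
}

validate_motif_set <- function(motifs) {
  if (!is.list(motifs) || length(motifs) < 1L || is.null(names(motifs)))
    stop("motifs must be a named list with >= 1 category", call. = FALSE)
  bad <- vapply(motifs, function(m)
    length(m) == 0L || any(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", m)),
    logical(1))
  if (any(bad))
    stop("invalid motif strings in categories: ",
         paste(names(motifs)[bad], collapse = ", "), call. = FALSE)
  invisible(motifs)
}

#' Per-protein stalling-motif counts for a whole set of sequences
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param motifs Named motif-category list.
#' @return Data frame: `protein_id`, `total`, `categories_present`, and
#'   one column per category.
#' @export
count_stalling_motifs_set <- function(sequences, motifs) {
  validate_motif_set(motifs)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("protein", seq_along(sequences))
  seqs <- toupper(as.character(sequences))
  # gregexpr is vectorized over the text argument: one pass per motif
  per_motif <- lapply(unlist(motifs, use.names = FALSE), function(m) {
    res <- gregexpr(paste0("(?=", m, ")"), seqs, perl = TRUE)
    vapply(res, function(h) if (h[1L] == -1L) 0L else length(h), integer(1))
  })
  cat_of <- rep(names(motifs), lengths(motifs))
  cat_counts <- sapply(names(motifs), function(cn) {
    cols <- per_motif[cat_of == cn]
    Reduce(`+`, cols)
  })
  cat_counts <- matrix(cat_counts, nrow = length(seqs),
                       dimnames = list(NULL, names(motifs)))
  out <- data.frame(protein_id = names(sequences),
                    total = rowSums(cat_counts),
                    categories_present = rowSums(cat_counts > 0),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cat_counts))
}

#' Compare stalling-motif category distributions between protein groups
#'
#' Builds the 2 x (K+1) contingency table of `categories_present`
#' (0..K) for the test group versus the rest and applies a chi-square
#' test without continuity correction.  When any expected cell is below
#' 5 the p-value is replaced by Monte-Carlo resampling of tables with
#' fixed margins.
#'
#' @param group,rest Data frames from [count_stalling_motifs_set()] (or
#'   anything with a `categories_present` column).
#' @param K Number of motif categories.
#' @param mc_reps Monte-Carlo replicates for the sparse-table fallback.
#' @return List with `table`, `proportions` (rows sum to 1),
#'   `statistic`, `df`, `p_value`, `method`.
#' @export
enrichment_categories <- function(group, rest, K, mc_reps = 10000) {
  if (nrow(group) == 0L || nrow(rest) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  lev <- 0:K
  tab <- rbind(group = table(factor(group$categories_present, levels = lev)),
               rest = table(factor(rest$categories_present, levels = lev)))
  # drop all-zero category columns: they contribute nothing and break
  # the chi-square machinery
  nonzero <- colSums(tab) > 0
  tab_used <- tab[, nonzero, drop = FALSE]
  if (ncol(tab_used) < 2L) {
    return(list(table = tab, proportions = prop.table(tab, 1L),
                statistic = 0, df = 0, p_value = 1,
                method = "degenerate"))
  }
  expected <- outer(rowSums(tab_used), colSums(tab_used)) / sum(tab_used)
  sparse <- any(expected < 5)
  ct <- suppressWarnings(chisq.test(tab_used, correct = FALSE))
  if (sparse) {
    mc <- suppressWarnings(chisq.test(tab_used, correct = FALSE,
                                      simulate.p.value = TRUE, B = mc_reps))
    p <- mc$p.value
    method <- "chisq_monte_carlo"
  } else {
    p <- ct$p.value
    method <- "chisq"
  }
  list(table = tab, proportions = prop.table(tab, 1L),
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = p, method = method)
}

#' Compare total stalling-motif counts between protein groups
#'
#' Mann-Whitney U on the per-protein total occurrence counts, group
#' versus rest (see [mw_test()]); the one-sided alternative is that the
#' test group carries more motifs.
#'
#' @param group_totals,rest_totals Integer vectors of per-protein total
#'   motif counts.
#' @return The [mw_test()] result (alternative `"greater"`).
#' @export
enrichment_counts <- function(group_totals, rest_totals) {
  mw_test(group_totals, rest_totals, alternative = "greater")
}

#' Full stalling-motif enrichment analysis of a labeled proteome
#'
#' Counts motif occurrences per protein, then contrasts the designated
#' test group against all remaining proteins: category-distribution
#' chi-square ([enrichment_categories()]) and Mann-Whitney on total
#' counts ([enrichment_counts()]).  The same machinery serves both an
#' "upregulated vs remaining" contrast and a gene-set contrast.
#'
#' @param sequences Named character vector of protein sequences.
#' @param groups Data frame with columns `protein_id`, `label`.
#'   Proteins labeled but absent from `sequences` are dropped with a
#'   warning; proteins without a label fall into the "rest" side.
#' @param test_group Label designating the test group.
#' @param motifs Named motif-category list.
#' @param mc_reps Monte-Carlo replicates for sparse category tables.
#' @return An `EnrichmentStats` list: `counts` (per-protein data
#'   frame with a `group` column), `categories`
#'   ([enrichment_categories()] result), `count_test` ([mw_test()]
#'   result; `p_value` is one-sided greater, `p_two_sided` is the
#'   default headline number), `n_group`, `n_rest`, `flags`.
#' @export
run_enrichment <- function(sequences, groups, test_group, motifs,
                           mc_reps = 10000) {
  need <- c("protein_id", "label")
  if (!all(need %in% names(groups)))
    stop("groups needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!test_group %in% groups$label)
    stop("unknown group label: ", test_group, call. = FALSE)
  missing <- setdiff(groups$protein_id, names(sequences))
  if (length(missing)) {
    warning(length(missing),
            " labeled protein(s) absent from the sequence set; dropped")
    groups <- groups[!groups$protein_id %in% missing, , drop = FALSE]
  }
  counts <- count_stalling_motifs_set(sequences, motifs)
  in_group <- counts$protein_id %in%
    groups$protein_id[groups$label == test_group]
  counts$group <- ifelse(in_group, test_group, "rest")
  grp <- counts[in_group, , drop = FALSE]
  rest <- counts[!in_group, , drop = FALSE]
  if (nrow(grp) == 0L || nrow(rest) == 0L)
    stop("test group and rest must both be nonempty", call. = FALSE)
  flags <- character()
  if (all(counts$total == 0)) flags <- c(flags, "motif_free_proteome")
  categories <- enrichment_categories(grp, rest, K = length(motifs),
                                      mc_reps = mc_reps)
  count_test <- enrichment_counts(grp$total, rest$total)
  if (count_test$degenerate) flags <- c(flags, "degenerate_count_test")
  structure(list(counts = counts, categories = categories,
                 count_test = count_test,
                 n_group = nrow(grp), n_rest = nrow(rest),
                 flags = flags),
            class = "EnrichmentStats")
}

#' @export
print.EnrichmentStats <- function(x, ...) {
  cat(sprintf("EnrichmentStats: %d group vs %d rest proteins\n",
              x$n_group, x$n_rest))
  cat(sprintf("  categories: chi-square %.3f (df %d), p = %.3g [%s]\n",
              x$categories$statistic, x$categories$df,
              x$categories$p_value, x$categories$method))
  cat(sprintf("  counts: U = %g, one-sided p = %.3g, two-sided p = %.3g\n",
              x$count_test$U_group, x$count_test$p_greater,
              x$count_test$p_two_sided))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Example stalling-motif categories (synthetic stand-in)
#'
#' A small illustrative catalogue of four motif categories of the kind
#' associated with ribosome stalling (poly-proline runs, proline-glycine
#' junctions, poly-basic runs, poly-acidic runs).  It is a synthetic
#' example for testing and demonstration, NOT a curated canonical set;
#' real analyses should supply their own catalogue via
#' [read_motif_set()].
#'
#' @return Named list of motif-string vectors (K = 4 categories).
#' @export
example_stalling_motifs <- function() {
  list(
    polyproline = c("PPP", "PPG"),
    proline_glycine = c("GPG", "PGP"),
    polybasic = c("KKK", "KKR", "KRK", "RKK", "RRR"),
    polyacidic = c("DDD", "EEE", "DED", "EDE")
  )
}

#' Read a stalling-motif catalogue from YAML or JSON
#'
#' The file maps category names to lists of fixed amino-acid motif
#' strings.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of motif-string vectors.
#' @export
read_motif_set <- function(path) {
  ext <- tolower(tools::file_ext(path))
  motifs <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("motif set must be YAML or JSON", call. = FALSE)
  }
  motifs <- lapply(motifs, function(m) toupper(unlist(m)))
  validate_motif_set(motifs)
  motifs
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_proteins <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))   # first token of the header
  setNames(as.character(x), nm)
}

#' Read interactor sets from per-experiment files or a long TSV
#'
#' @param paths Character vector of file paths.  A one-column file is
#'   one set (one protein id per line, named after the file); a
#'   two-column TSV with columns `experiment`, `protein_id` holds
#'   several sets in long format.
#' @return Named list of character vectors.
#' @export
read_interactor_sets <- function(paths) {
  out <- list()
  for (p in paths) {
    first <- readLines(p, n = 1L)
    if (grepl("\t", first)) {
      tab <- read.delim(p, stringsAsFactors = FALSE)
      for (e in unique(tab$experiment))
        out[[e]] <- unique(tab$protein_id[tab$experiment == e])
    } else {
      ids <- readLines(p)
      ids <- trimws(ids[nzchar(trimws(ids))])
      out[[tools::file_path_sans_ext(basename(p))]] <- unique(ids)
    }
  }
  out
}
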