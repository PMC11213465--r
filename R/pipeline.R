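#' Read a gene annotation list (one id per line, or first column of a TSV)
#'
#' @param path File path.
#' @return Character vector of annotated gene ids.
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    as.character(tab[[1L]])
  } else {
    x <- trimws(readLines(path))
    x[nzchar(x)]
  }
}

#' Read a two-column ortholog map TSV
#'
#' @param path TSV path (species-A id, species-B id; header optional
#'   but recommended).
#' @return Data frame.
#' @export
read_ortholog_map <- function(path) read.delim(path, stringsAsFactors = FALSE)

stage_runner <- function(log_level = "info") {
  function(name, report, fun) {
    t0 <- Sys.time()
    res <- tryCatch(
      list(status = "ok", result = fun()),
      error = function(e) {
        message(sprintf("[%s] FAILED: %s", name, conditionMessage(e)))
        list(status = "failed", error = conditionMessage(e))
      })
    if (res$status == "ok" && log_level != "quiet")
      message(sprintf("[%s] ok (%.2f s)", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    report[[name]] <- res
    report
  }
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages (`screen`, `polysome`, `localization`, `motifs`, `dynamics`,
#' `stalls`, `stalling`) run independently; a stage with no
#' configuration block is skipped, and a stage failure is recorded in
#' the report without aborting the others.  The report is serialized to
#' `report.json` with TSV/BED sidecars in `out_dir`.
#'
#' @param config Path to a YAML configuration or an equivalent named
#'   list.  Relative input paths are resolved against the directory of
#'   the YAML file (or `input_dir` when the config is a list).
#' @param out_dir Output directory.
#' @param seed Seed recorded in the report and used for any randomized
#'   procedure (Monte-Carlo category test).
#' @param log_level `"info"` or `"quiet"`.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config, out_dir, seed = 1, log_level = "info") {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  } else if (!is.null(config$input_dir)) {
    base_dir <- config$input_dir
  }
  rp <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- stage_runner(log_level)
  report <- list()

  if (!is.null(config$screen)) {
    report <- run("screen", report, function() {
      cfg <- config$screen
      expr_a <- read_expression_matrix(rp(cfg$expr), rp(cfg$meta))
      expr_b <- if (!is.null(cfg$expr_b))
        read_expression_matrix(rp(cfg$expr_b), rp(cfg$meta_b)) else NULL
      res <- run_screen(expr_a, cfg$target_tissue,
                        read_annotation(rp(cfg$annotation)),
                        read_ortholog_map(rp(cfg$orthologs)),
                        expr_b = expr_b,
                        fold = cfg$fold %||% 5, floor = cfg$floor %||% 0.5)
      funnel_report_json(res$report, file.path(out_dir, "funnel.json"))
      write.table(res$calls, file.path(out_dir, "specificity_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(funnel = res$report$table, final = res$final)
    })
  } else report$screen <- list(status = "skipped", reason = "not configured")

  if (!is.null(config$polysome)) {
    report <- run("polysome", report, function() {
      cfg <- config$polysome
      calls <- classify_polysome_table(
        read_polysome_table(rp(cfg$table)),
        detect = cfg$detect %||% 1, pseudocount = cfg$pseudocount %||% 0.5)
      write.table(calls, file.path(out_dir, "polysome_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      calls
    })
  } else report$polysome <- list(status = "skipped", reason = "not configured")

  if (!is.null(config$localization)) {
    report <- run("localization", report, function() {
      cfg <- config$localization
      out <- list()
      if (!is.null(cfg$fish)) {
        r <- fish_localization(read_fish_table(rp(cfg$fish)),
                               min_cells = cfg$min_cells %||% 100)
        out$fish <- r[c("percent_cytoplasmic", "percent_nuclear",
                        "pooled_percent_cytoplasmic", "n_cells",
                        "qc_flags")]
      }
      if (!is.null(cfg$qpcr)) {
        r <- qpcr_localization(read_qpcr_table(rp(cfg$qpcr)), cfg$target,
                               cfg$nuclear_controls, cfg$cytosolic_controls,
                               efficiency = cfg$efficiency %||% 2)
        out$fractionation <- r[c("percent_cytoplasmic", "percent_nuclear",
                                 "controls", "qc_flags")]
      }
      if (!length(out)) stop("localization block needs `fish` or `qpcr`")
      out
    })
  } else report$localization <- list(status = "skipped",
                                     reason = "not configured")

  if (!is.null(config$motifs)) {
    report <- run("motifs", report, function() {
      cfg <- config$motifs
      proms <- read_promoters(rp(cfg$promoters))
      if (length(proms) < 2L) stop("promoter FASTA needs 2 records")
      pwms <- if (!is.null(cfg$pwm)) {
        ps <- unlist(cfg$pwm)
        setNames(lapply(ps, function(f) read_pwm(rp(f))),
                 tools::file_path_sans_ext(basename(ps)))
      } else example_pwms()
      res <- conserved_motif_analysis(
        proms[[1L]], proms[[2L]], pwms,
        p_threshold = cfg$p_threshold %||% 1e-4,
        window_len = cfg$window %||% 50,
        identity_min = cfg$identity %||% 70)
      if (nrow(res$pairs))
        write_bed(data.frame(sequence_id = "promoter",
                             start = res$pairs$start_a,
                             end = res$pairs$end_a,
                             score = res$pairs$score_a,
                             strand = res$pairs$strand_a),
                  file.path(out_dir, "site_pairs.bed"),
                  name = res$pairs$motif)
      list(windows = res$windows, n_pairs = nrow(res$pairs),
           pairs = res$pairs)
    })
  } else report$motifs <- list(status = "skipped", reason = "not configured")

  if (!is.null(config$dynamics)) {
    report <- run("dynamics", report, function() {
      cfg <- config$dynamics
      ribo <- read_time_course(rp(cfg$timecourse), "ribo")
      rna <- read_time_course(rp(cfg$timecourse), "rna")
      call <- translational_shift(ribo, rna)
      list(ribo_peak = call$ribo_peak, rna_peak = call$rna_peak,
           lag_hours = call$lag_hours)
    })
  } else report$dynamics <- list(status = "skipped", reason = "not configured")

  if (!is.null(config$stalls)) {
    report <- run("stalls", report, function() {
      cfg <- config$stalls
      tracks <- read_coverage_bedgraph(rp(cfg$coverage), rp(cfg$starts))
      lapply(tracks, function(tr) {
        r <- stall_peak_detect(tr, flank = cfg$flank %||% 25,
                               z_min = cfg$z_min %||% 5)
        list(peaks = r$peaks, start_proximal_ratio = r$start_proximal_ratio,
             flags = r$flags)
      })
    })
  } else report$stalls <- list(status = "skipped", reason = "not configured")

  if (!is.null(config$stalling)) {
    report <- run("stalling", report, function() {
      cfg <- config$stalling
      set.seed(cfg$seed %||% seed)
      motifs <- if (!is.null(cfg$motifs)) read_motif_set(rp(cfg$motifs))
                else example_stalling_motifs()
      res <- run_enrichment(read_proteins(rp(cfg$proteins)),
                            read.delim(rp(cfg$groups),
                                       stringsAsFactors = FALSE),
                            cfg$test_group, motifs)
      write.table(res$counts, file.path(out_dir, "motif_counts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(categories = res$categories[c("statistic", "df", "p_value",
                                         "method")],
           count_test = res$count_test[c("U_group", "U_rest", "p_value",
                                         "p_two_sided", "method")],
           n_group = res$n_group, n_rest = res$n_rest, flags = res$flags)
    })
  } else report$stalling <- list(status = "skipped", reason = "not configured")

  report$meta <- list(seed = seed,
                      package_version =
                        as.character(utils::packageVersion("riboseek")))
  body <- report
  body$meta$timestamp <- NULL
  writeLines(jsonlite::toJSON(body, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, force = TRUE),
             file.path(out_dir, "report.json"))
  invisible(report)
}
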