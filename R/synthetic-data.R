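# Synthetic-data generators.  Every generator is a pure function of its
# arguments (seed included): same inputs, bit-identical outputs.  Each
# returns the in-memory objects the analysis modules consume plus a
# `truth` list recording what was planted.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Generate a two-species multi-organ expression matrix pair
#'
#' Background genes share one cross-tissue mean and scatter lognormally
#' around it; planted target-specific genes receive a target-tissue mean
#' equal to `true_fold` times the maximum of their other-tissue means
#' (other-tissue means themselves vary between tissues, as organ
#' expression does).  Replicate noise has standard deviation `sigma` on
#' the log2 scale.  Annotation and ortholog tables are emitted with
#' configurable dropout so the downstream screening funnel can be
#' exercised: of the planted genes, `n_unannotated` are withheld from
#' the annotation, `n_unmapped` further ones from the ortholog map, and
#' `n_cross_fail` have their species-B orthologs planted as
#' NON-specific; all remaining orthologs are planted specific in
#' species B as well.
#'
#' @param seed Integer seed.
#' @param n_genes Genes per species (background + planted).
#' @param n_specific Planted target-specific genes in species A.
#' @param true_fold Planted specificity fold (target-tissue mean over
#'   max other-tissue mean).
#' @param sigma Replicate noise SD on the log2 scale (default 0.3).
#' @param tissues Tissue panel (first entry is the target tissue).
#' @param n_rep Replicates per tissue (default 2).
#' @param tissue_spread SD (natural log) of per-tissue mean variation
#'   for planted genes' non-target tissues.
#' @param n_unannotated,n_unmapped,n_cross_fail Funnel dropout counts
#'   (must sum to < `n_specific`).
#' @param base_fpkm Median background expression in FPKM.
#' @return List: `expr_a`, `expr_b` ([expression_matrix()]),
#'   `annotation` (character), `omap` (data frame `gene_id`,
#'   `partner_id`), `truth` (planted ids per funnel stage).
#' @export
generate_expression <- function(seed = 1, n_genes = 2000, n_specific = 96,
                                true_fold = 10, sigma = 0.3,
                                tissues = c("heart", "brain", "liver",
                                            "kidney", "lung", "spleen",
                                            "testis"),
                                n_rep = 2, tissue_spread = 1,
                                n_unannotated = 0, n_unmapped = 0,
                                n_cross_fail = 0, base_fpkm = 5) {
  if (n_specific + 1 > n_genes) stop("n_specific must be < n_genes")
  if (n_unannotated + n_unmapped + n_cross_fail >= n_specific && n_specific > 0)
    stop("funnel dropouts must leave at least one candidate")
  set.seed(derive_seed(seed, "expression"))
  target <- tissues[1L]
  n_t <- length(tissues)
  sd_ln <- sigma * log(2)             # sigma is on the log2 scale

  make_matrix <- function(prefix, specific_ids, specific_flag) {
    gene_ids <- paste0(prefix, "_g", seq_len(n_genes))
    gene_ids[seq_along(specific_ids)] <- specific_ids
    samples <- expand.grid(replicate = seq_len(n_rep), tissue = tissues,
                           stringsAsFactors = FALSE)
    samples$sample_id <- sprintf("%s_%s_r%d", prefix, samples$tissue,
                                 samples$replicate)
    vals <- matrix(0, n_genes, nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
    for (g in seq_len(n_genes)) {
      planted <- g <= length(specific_ids) && specific_flag[g]
      if (planted) {
        other_means <- base_fpkm * exp(rnorm(n_t - 1L, 0, tissue_spread))
        mu <- c(true_fold * max(other_means), other_means)
      } else {
        mu <- rep(base_fpkm * exp(rnorm(1L, 0, 1)), n_t)
      }
      names(mu) <- c(target, tissues[-1L])
      vals[g, ] <- mu[samples$tissue] * exp(rnorm(nrow(samples), 0, sd_ln))
    }
    meta <- data.frame(sample_id = samples$sample_id,
                       species = prefix, tissue = samples$tissue,
                       replicate = samples$replicate,
                       stringsAsFactors = FALSE)
    expression_matrix(vals, meta)
  }

  spec_a <- paste0("A_spec", seq_len(n_specific))
  flag_a <- rep(TRUE, n_specific)
  expr_a <- make_matrix("A", spec_a, flag_a)

  # funnel structure on the planted genes
  unannotated <- head(spec_a, n_unannotated)
  annotated <- setdiff(spec_a, unannotated)
  unmapped <- head(annotated, n_unmapped)
  mapped <- setdiff(annotated, unmapped)
  cross_fail <- head(mapped, n_cross_fail)
  cross_ok <- setdiff(mapped, cross_fail)

  partner <- setNames(paste0("B_orth", seq_along(mapped)), mapped)
  # species B: orthologs of cross_ok planted specific, of cross_fail not
  spec_b <- unname(partner[cross_ok])
  nonspec_b <- unname(partner[cross_fail])
  ids_b <- c(spec_b, nonspec_b)
  flag_b <- c(rep(TRUE, length(spec_b)), rep(FALSE, length(nonspec_b)))
  expr_b <- make_matrix("B", ids_b, flag_b)

  annotation <- c(annotated,
                  setdiff(expr_a$gene_ids, spec_a))   # background annotated
  omap <- data.frame(gene_id = mapped, partner_id = unname(partner[mapped]),
                     stringsAsFactors = FALSE)
  list(expr_a = expr_a, expr_b = expr_b, annotation = annotation,
       omap = omap,
       truth = list(target_tissue = target, specific = spec_a,
                    unannotated = unannotated, unmapped = unmapped,
                    cross_fail = cross_fail, final = cross_ok,
                    true_fold = true_fold, sigma = sigma))
}

#' Generate the packaged screening-funnel fixture
#'
#' A deterministic end-to-end fixture whose funnel counts mirror the
#' canonical screening structure: 96 target-specific candidates, 70
#' lacking annotation, 18 of the remainder lacking an ortholog, 3 of the
#' mapped 8 failing cross-species validation, 5 surviving.  Planted with
#' a large specificity fold so the initial screen recovers all 96
#' candidates with probability indistinguishable from 1.
#'
#' @param seed Integer seed.
#' @return See [generate_expression()].
#' @export
generate_funnel_fixture <- function(seed = 1) {
  generate_expression(seed = seed, n_genes = 1000, n_specific = 96,
                      true_fold = 50, sigma = 0.3,
                      n_unannotated = 70, n_unmapped = 18, n_cross_fail = 3)
}

#' Generate a polysome-fraction expression table
#'
#' Emits the canonical five-candidate structure: four transcripts
#' planted as ribosome-associated with graded polysome levels (so the
#' strongest association is unambiguous), one detected only in the
#' ribosome-free fraction, plus a polysome-heavy housekeeping-like
#' control and a free-only control.  Lognormal measurement noise.
#'
#' @param seed Integer seed.
#' @param polysome_means Named numeric: planted polysome-fraction means
#'   per candidate (FPKM).
#' @param free_means Matching free-fraction means.
#' @param noise_sigma Lognormal noise SD (natural log, default 0.1).
#' @return List with `table` (long data frame `transcript_id`,
#'   `fraction`, `level`) and `truth` (planted classes, strongest
#'   candidate).
#' @export
generate_polysome <- function(seed = 1,
                              polysome_means = c(cand1 = 8, cand2 = 3,
                                                 cand3 = 2, cand4 = 1.5,
                                                 cand5 = 0),
                              free_means = c(cand1 = 2, cand2 = 1.5,
                                             cand3 = 1, cand4 = 1,
                                             cand5 = 5),
                              noise_sigma = 0.1) {
  set.seed(derive_seed(seed, "polysome"))
  ids <- c(names(polysome_means), "control_ribosomal", "control_free")
  poly <- c(polysome_means, control_ribosomal = 80, control_free = 0)
  free <- c(free_means, control_ribosomal = 2, control_free = 10)
  noisy <- function(mu) ifelse(mu > 0, mu * exp(rnorm(length(mu), 0,
                                                      noise_sigma)), 0)
  tab <- rbind(
    data.frame(transcript_id = ids, fraction = "polysome",
               level = noisy(poly), stringsAsFactors = FALSE),
    data.frame(transcript_id = ids, fraction = "free",
               level = noisy(free), stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  truth_class <- ifelse(poly >= 1, "associated",
                        ifelse(free >= 1, "free", "undetected"))
  list(table = tab,
       truth = list(class = setNames(truth_class, ids),
                    strongest = names(which.max(poly[names(polysome_means)])),
                    n_associated_candidates =
                      sum(truth_class[names(polysome_means)] == "associated")))
}

#' Generate single-molecule FISH spot counts
#'
#' Spots per cell are Poisson around `spots_per_cell`; each spot falls
#' in the cytoplasm with probability `p_cyto` (binomial split).
#'
#' @param seed Integer seed.
#' @param n_cells Number of cells (default 100).
#' @param spots_per_cell Mean total spots per cell (default 50).
#' @param p_cyto True cytoplasmic probability (default 0.6).
#' @return List with `cells` (data frame `cell_id`, `nuclear_spots`,
#'   `cytoplasmic_spots`) and `truth`.
#' @export
generate_fish <- function(seed = 1, n_cells = 100, spots_per_cell = 50,
                          p_cyto = 0.6) {
  set.seed(derive_seed(seed, "fish"))
  total <- rpois(n_cells, spots_per_cell)
  cyto <- rbinom(n_cells, total, p_cyto)
  list(cells = data.frame(cell_id = sprintf("cell%03d", seq_len(n_cells)),
                          nuclear_spots = total - cyto,
                          cytoplasmic_spots = cyto,
                          stringsAsFactors = FALSE),
       truth = list(p_cyto = p_cyto, n_cells = n_cells,
                    spots_per_cell = spots_per_cell))
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "")[[1L]]
  hit <- runif(length(s)) < rate
  if (any(hit))
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
  paste(s, collapse = "")
}

#' Generate a cross-species promoter pair with conserved blocks and
#' planted motif instances
#'
#' Both promoters are independent random sequence (25% per base) except
#' inside the conserved blocks, which are copied from species A to
#' species B with a per-base mismatch rate.  Motif instances (the PWM
#' consensus) are planted at the same TSS-relative offset in both
#' species, inside the designated blocks.
#'
#' @param seed Integer seed.
#' @param length Promoter length in nt (default 2200, covering
#'   TSS-2000 .. TSS+200).
#' @param blocks Data frame `start`, `end` (0-based half-open) of
#'   conserved blocks; default two 80-nt blocks near the TSS.
#' @param mismatch_rate Per-base mismatch rate inside blocks
#'   (default 0.02).
#' @param pwms Named list of `PWM`s to plant; each is planted once, in
#'   block `1 + (i-1) %% nrow(blocks)`.
#' @return List with `promoter_a`, `promoter_b` (character), `blocks`,
#'   `planted` (data frame `motif`, `start`, `end`), `truth`.
#' @export
generate_promoters <- function(seed = 1, length = 2200,
                               blocks = data.frame(start = c(1500, 1850),
                                                   end = c(1580, 1930)),
                               mismatch_rate = 0.02,
                               pwms = example_pwms()) {
  set.seed(derive_seed(seed, "promoters"))
  if (any(blocks$end > length) || any(blocks$start < 0))
    stop("blocks outside promoter", call. = FALSE)
  a <- strsplit(random_dna(length), "")[[1L]]
  b <- strsplit(random_dna(length), "")[[1L]]
  planted <- NULL
  for (i in seq_along(pwms)) {
    blk <- 1L + (i - 1L) %% nrow(blocks)
    w <- pwms[[i]]$width
    lo <- blocks$start[blk]; hi <- blocks$end[blk] - w
    if (hi < lo) stop("block too short for motif", call. = FALSE)
    pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L       # 0-based
    cons <- strsplit(pwm_consensus(pwms[[i]]), "")[[1L]]
    a[(pos + 1L):(pos + w)] <- cons
    planted <- rbind(planted,
                     data.frame(motif = names(pwms)[i], start = pos,
                                end = pos + w, stringsAsFactors = FALSE))
  }
  # copy blocks A -> B with mismatches; planted motif footprints are
  # exempt (they model binding sites under purifying selection, and the
  # truth table promises an intact instance in both species)
  protected <- logical(length)
  for (i in seq_len(nrow(planted)))
    protected[(planted$start[i] + 1L):planted$end[i]] <- TRUE
  for (k in seq_len(nrow(blocks))) {
    idx <- (blocks$start[k] + 1L):blocks$end[k]
    blk_seq <- mutate_dna(paste(a[idx], collapse = ""), mismatch_rate)
    mut <- strsplit(blk_seq, "")[[1L]]
    mut[protected[idx]] <- a[idx][protected[idx]]
    b[idx] <- mut
  }
  list(promoter_a = paste(a, collapse = ""),
       promoter_b = paste(b, collapse = ""),
       blocks = blocks, planted = planted,
       truth = list(n_blocks = nrow(blocks), mismatch_rate = mismatch_rate,
                    planted = planted))
}

#' Example transcription-factor PWMs (synthetic stand-ins)
#'
#' Two illustrative PWMs built from consensus-weighted counts: a
#' MEF2-like A/T-rich box (consensus `CTAAAAATAG`) and an NFAT-like
#' site (consensus `ATGGAAAA`).  Widths stay at 8+ nt so a perfect
#' match can clear the default 1e-4 scanning threshold (a width-w
#' motif's best attainable p is 4^-w).  Synthetic stand-ins for
#' demonstration, not curated database matrices.
#'
#' @param strength Count weight of the consensus base per position.
#' @return Named list of `PWM` objects.
#' @export
example_pwms <- function(strength = 20) {
  from_consensus <- function(cons) {
    s <- strsplit(cons, "")[[1L]]
    counts <- matrix(0, 4, length(s), dimnames = list(DNA_BASES, NULL))
    counts[cbind(match(s, DNA_BASES), seq_along(s))] <- strength
    build_pwm(counts, pseudocount = 1)
  }
  list(MEF2_like = from_consensus("CTAAAAATAG"),
       NFAT_like = from_consensus("ATGGAAAA"))
}

#' Generate ribosome-protected and total-RNA time courses plus footprint
#' coverage tracks
#'
#' The time courses share a pressure-overload-style grid (sham, 3 h,
#' 2 d, 1 w, 2 w); the total-RNA series is planted to peak at 48 h and
#' the ribosome-protected series at 336 h.  Coverage tracks carry a
#' Poisson background with (i) a single-position stall pile-up of
#' configurable fold and (ii) a separate track with elevated
#' start-proximal coverage.
#'
#' @param seed Integer seed.
#' @param hours Timepoint grid in hours.
#' @param labels Matching timepoint labels.
#' @param rna_peak_hours,ribo_peak_hours Planted peak positions.
#' @param n_rep Replicates per timepoint (default 3).
#' @param tc_noise_sigma Lognormal noise SD on the time-course levels.
#' @param track_length Coverage-track length in nt.
#' @param base_lambda Poisson mean of background coverage.
#' @param stall_position 0-based planted stall position.
#' @param stall_fold Planted pile-up fold over background.
#' @param start_codon 0-based start-codon offset.
#' @return List with `ribo`, `rna` ([time_course()]), `tracks` (named
#'   list of [coverage_track()]: `stall_tx` with the planted pile-up,
#'   `startprox_tx` with 3x coverage over the first 150 nt after the
#'   start), `truth`.
#' @export
generate_dynamics_and_coverage <- function(seed = 1,
                                           hours = c(0, 3, 48, 168, 336),
                                           labels = c("sham", "3 h", "2 d",
                                                      "1 w", "2 w"),
                                           rna_peak_hours = 48,
                                           ribo_peak_hours = 336,
                                           n_rep = 3, tc_noise_sigma = 0.1,
                                           track_length = 1500,
                                           base_lambda = 20,
                                           stall_position = 600,
                                           stall_fold = 10,
                                           start_codon = 100) {
  set.seed(derive_seed(seed, "dynamics"))
  shape <- function(peak_hours) {
    # unimodal profile peaking at the planted timepoint; the peak mean
    # is well separated (5/3 of the runner-up) so replicate noise does
    # not move the argmax
    d <- abs(match(peak_hours, hours) - seq_along(hours))
    5 + 20 * 2^(-d)
  }
  course <- function(series, peak_hours) {
    means <- shape(peak_hours)
    tab <- expand.grid(replicate = seq_len(n_rep),
                       i = seq_along(hours))
    tab <- data.frame(series = series,
                      timepoint_label = labels[tab$i],
                      hours = hours[tab$i], replicate = tab$replicate,
                      level = means[tab$i] *
                        exp(rnorm(nrow(tab), 0, tc_noise_sigma)),
                      stringsAsFactors = FALSE)
    time_course(tab, series)
  }
  rna <- course("rna", rna_peak_hours)
  ribo <- course("ribo", ribo_peak_hours)
  stall_counts <- rpois(track_length, base_lambda)
  stall_counts[stall_position + 1L] <- rpois(1L, stall_fold * base_lambda)
  prox_counts <- rpois(track_length, base_lambda)
  prox <- (start_codon + 1L):(start_codon + 150L)
  prox_counts[prox] <- rpois(150L, 3 * base_lambda)
  list(ribo = ribo, rna = rna,
       tracks = list(
         stall_tx = coverage_track(stall_counts, start_codon, "stall_tx"),
         startprox_tx = coverage_track(prox_counts, start_codon,
                                       "startprox_tx")),
       truth = list(rna_peak_hours = rna_peak_hours,
                    ribo_peak_hours = ribo_peak_hours,
                    lag_hours = ribo_peak_hours - rna_peak_hours,
                    stall_position = stall_position,
                    stall_fold = stall_fold))
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

#' Generate a labeled synthetic proteome with planted stalling motifs
#'
#' Background sequences are uniform over the 20 amino acids; each
#' protein additionally receives a Poisson number of planted motif
#' instances (drawn uniformly from the catalogue) written at random
#' positions, with the planting rate differing between the test group
#' and the rest.
#'
#' @param seed Integer seed.
#' @param n_group,n_rest Proteins per group (default 200 each).
#' @param protein_length Sequence length (default 300).
#' @param rate_group,rate_rest Mean planted motif instances per protein.
#' @param motifs Motif catalogue (default [example_stalling_motifs()]).
#' @param test_label Label of the test group (default "upregulated").
#' @return List with `sequences` (named character), `groups` (data
#'   frame `protein_id`, `label`), `truth`.
#' @export
generate_proteome <- function(seed = 1, n_group = 200, n_rest = 200,
                              protein_length = 300, rate_group = 6,
                              rate_rest = 3,
                              motifs = example_stalling_motifs(),
                              test_label = "upregulated") {
  set.seed(derive_seed(seed, "proteome"))
  all_motifs <- unlist(motifs, use.names = FALSE)
  gen <- function(n, rate, prefix) {
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- strsplit(random_protein(protein_length), "")[[1L]]
      k <- rpois(1L, rate)
      for (j in seq_len(k)) {
        m <- strsplit(sample(all_motifs, 1L), "")[[1L]]
        pos <- sample.int(protein_length - length(m) + 1L, 1L)
        s[pos:(pos + length(m) - 1L)] <- m
      }
      seqs[i] <- paste(s, collapse = "")
    }
    setNames(seqs, sprintf("%s_%03d", prefix, seq_len(n)))
  }
  g <- gen(n_group, rate_group, "grp")
  r <- gen(n_rest, rate_rest, "rest")
  groups <- data.frame(protein_id = c(names(g), names(r)),
                       label = c(rep(test_label, n_group),
                                 rep("remaining", n_rest)),
                       stringsAsFactors = FALSE)
  list(sequences = c(g, r), groups = groups,
       truth = list(rate_group = rate_group, rate_rest = rate_rest,
                    test_label = test_label))
}

#' Write a full synthetic fixture directory
#'
#' Emits every input file the pipeline reads, in its on-disk format,
#' plus `truth.json` recording all planted ground truth.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed expanded into per-generator substreams.
#' @return Invisibly, the list of generated objects.
#' @export
simulate_all <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  ex <- generate_funnel_fixture(seed)
  write_expression_matrix(ex$expr_a, p("expr_a.tsv"), p("expr_a.meta.tsv"))
  write_expression_matrix(ex$expr_b, p("expr_b.tsv"), p("expr_b.meta.tsv"))
  writeLines(ex$annotation, p("annotation.txt"))
  write.table(ex$omap, p("orthologs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  po <- generate_polysome(seed)
  write.table(po$table, p("polysome.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  fi <- generate_fish(seed)
  write.table(fi$cells, p("fish.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pr <- generate_promoters(seed)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(promoter_a = pr$promoter_a,
                               promoter_b = pr$promoter_b)),
    p("promoters.fa"))
  dy <- generate_dynamics_and_coverage(seed)
  tc <- rbind(
    do.call(rbind, lapply(seq_along(dy$rna$hours), function(i)
      data.frame(series = "rna", timepoint_label = dy$rna$labels[i],
                 hours = dy$rna$hours[i],
                 replicate = seq_along(dy$rna$levels[[i]]),
                 level = dy$rna$levels[[i]]))),
    do.call(rbind, lapply(seq_along(dy$ribo$hours), function(i)
      data.frame(series = "ribo", timepoint_label = dy$ribo$labels[i],
                 hours = dy$ribo$hours[i],
                 replicate = seq_along(dy$ribo$levels[[i]]),
                 level = dy$ribo$levels[[i]]))))
  write.table(tc, p("timecourse.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_coverage_bedgraph(dy$tracks, p("coverage.bedgraph"),
                          p("start_codons.tsv"))
  pro <- generate_proteome(seed)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(pro$sequences), p("proteins.fa"))
  write.table(pro$groups, p("groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(lapply(example_stalling_motifs(), as.list),
                   p("motifs.yaml"))
  truth <- list(expression = ex$truth, polysome = po$truth,
                fish = fi$truth, promoters = pr$truth,
                dynamics = dy$truth, proteome = pro$truth, seed = seed)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             p("truth.json"))
  invisible(list(expression = ex, polysome = po, fish = fi,
                 promoters = pr, dynamics = dy, proteome = pro))
}
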