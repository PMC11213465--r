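test_that("interactome intersection isolates the shared protein", {
  sets <- list(pulldown1 = c("A", "B", "DRG1"),
               pulldown2 = c("C", "DRG1"),
               pulldown3 = c("D", "DRG1", "E"))
  expect_identical(intersect_interactomes(sets), "DRG1")
  expect_identical(intersect_interactomes(list(c("A", "B"), c("C"))),
                   character(0))
  expect_setequal(intersect_interactomes(list(sets[[1]], sets[[1]])),
                  sets[[1]])
  expect_error(intersect_interactomes(list(c("A"))), ">= 2")
})

test_that("motif occurrences count overlaps and categories correctly", {
  cats <- list(polyP = "PPP")
  r <- count_stalling_motifs("APPPPK", cats)
  expect_equal(r$total, 2)            # offsets 1 and 2
  expect_equal(r$categories_present, 1)

  two <- count_stalling_motifs("PPPKKK", list(polyP = "PPP", polyK = "KKK"))
  expect_equal(two$total, 2)
  expect_equal(two$categories_present, 2)

  empty <- count_stalling_motifs("", cats)
  expect_equal(empty$total, 0)
  expect_equal(empty$categories_present, 0)

  # X never matches
  expect_equal(count_stalling_motifs("PPXPP", cats)$total, 0)
  expect_error(count_stalling_motifs("PPP", list(bad = "PPX")), "invalid")
})

test_that("set-level counting agrees with per-sequence counting", {
  g <- generate_proteome(3, n_group = 15, n_rest = 15)
  motifs <- example_stalling_motifs()
  tab <- count_stalling_motifs_set(g$sequences, motifs)
  for (i in sample(nrow(tab), 5)) {
    single <- count_stalling_motifs(g$sequences[[tab$protein_id[i]]], motifs)
    expect_equal(tab$total[i], single$total)
    expect_equal(tab$categories_present[i], single$categories_present)
  }
})

test_that("counting is superadditive under concatenation", {
  set.seed(5)
  motifs <- example_stalling_motifs()
  for (i in 1:10) {
    s1 <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWYPPPKKK", "")[[1]],
                       40, replace = TRUE), collapse = "")
    s2 <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWYDDDGPG", "")[[1]],
                       40, replace = TRUE), collapse = "")
    c1 <- count_stalling_motifs(s1, motifs)$total
    c2 <- count_stalling_motifs(s2, motifs)$total
    cc <- count_stalling_motifs(paste0(s1, s2), motifs)$total
    expect_gte(cc, c1 + c2)
  }
})

test_that("category chi-square matches hand computation and label swap", {
  grp <- data.frame(categories_present = rep(c(0, 1), c(10, 0)))
  rst <- data.frame(categories_present = rep(c(0, 1), c(0, 10)))
  r <- enrichment_categories(grp, rst, K = 1)
  expect_equal(r$statistic, 20)
  swapped <- enrichment_categories(rst, grp, K = 1)
  expect_equal(swapped$statistic, r$statistic)

  same <- enrichment_categories(
    data.frame(categories_present = rep(0:2, 10)),
    data.frame(categories_present = rep(0:2, 10)), K = 2)
  expect_equal(same$statistic, 0)
  expect_gte(same$p_value, 0.99)
})

test_that("Monte-Carlo p matches exhaustive fixed-margin enumeration", {
  # 2x2 with small margins: exhaust all tables with both margins fixed
  grp <- data.frame(categories_present = rep(c(0, 1), c(6, 2)))
  rst <- data.frame(categories_present = rep(c(0, 1), c(2, 5)))
  set.seed(11)
  r <- enrichment_categories(grp, rst, K = 1, mc_reps = 20000)
  expect_equal(r$method, "chisq_monte_carlo")

  # enumeration oracle over the hypergeometric table distribution
  r1 <- 8; r2 <- 7; c1 <- 8
  stat_of <- function(a) {
    tab <- matrix(c(a, c1 - a, r1 - a, r2 - (c1 - a)), 2)
    suppressWarnings(unname(chisq.test(tab, correct = FALSE)$statistic))
  }
  a_range <- max(0, c1 - r2):min(r1, c1)
  stats_all <- vapply(a_range, stat_of, numeric(1))
  probs <- dhyper(a_range, r1, r2, c1)
  obs <- stat_of(6)
  p_exact <- sum(probs[stats_all >= obs - 1e-9])
  expect_lt(abs(r$p_value - p_exact), 0.02)
})

test_that("full enrichment detects a planted rate difference and flags degeneracy", {
  g <- generate_proteome(21, n_group = 100, n_rest = 100,
                         rate_group = 6, rate_rest = 3)
  res <- run_enrichment(g$sequences, g$groups, "upregulated",
                        example_stalling_motifs())
  expect_lt(res$count_test$p_value, 0.01)
  expect_lt(res$categories$p_value, 0.05)
  expect_equal(res$n_group, 100)

  # motif-free proteome: no matches, degenerate count test, flagged
  seqs <- setNames(rep(strrep("ACDEF", 20), 10), paste0("p", 1:10))
  groups <- data.frame(protein_id = names(seqs),
                       label = rep(c("upregulated", "remaining"), each = 5))
  r0 <- run_enrichment(seqs, groups, "upregulated",
                       list(polyP = "PPP"))
  expect_true(all(r0$counts$total == 0))
  expect_true("motif_free_proteome" %in% r0$flags)
  expect_equal(r0$count_test$p_value, 1)

  expect_error(run_enrichment(seqs, groups, "nosuch", list(polyP = "PPP")),
               "unknown group label")
  # labeled proteins missing from the FASTA are dropped with a warning
  groups2 <- rbind(groups, data.frame(protein_id = "ghost",
                                      label = "upregulated"))
  expect_warning(run_enrichment(seqs, groups2, "upregulated",
                                list(polyP = "PPP")), "dropped")
})

test_that("motif catalogues round-trip through YAML and JSON", {
  motifs <- example_stalling_motifs()
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(motifs, as.list), fy)
  expect_equal(read_motif_set(fy), motifs)
  fj <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(motifs), fj)
  expect_equal(read_motif_set(fj), motifs)
  # packaged example file parses and is a valid catalogue
  shipped <- read_motif_set(system.file("extdata",
                                        "example_stalling_motifs.yaml",
                                        package = "riboseek"))
  expect_equal(shipped, motifs)
})
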