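test_that("compute_specificity applies fold and floor rules", {
  m <- matrix(c(10, 10, 0.1,
                12, 12, 0.2,
                1.9, 2.5, 0), nrow = 3, byrow = FALSE,
              dimnames = list(c("hit", "near", "silent"),
                              c("h1", "h2", "l1")))
  expr <- tiny_expression(m, c("heart", "heart", "liver"))
  calls <- compute_specificity(expr, "heart", fold = 5, floor = 0.5)

  hit <- calls[calls$gene_id == "hit", ]
  expect_equal(hit$ratio, 10 / 1.9, tolerance = 1e-12)
  expect_true(hit$passes_fold)

  near <- calls[calls$gene_id == "near", ]
  expect_equal(near$ratio, 10 / 2.5)   # 4.0 < 5
  expect_false(near$passes_fold)

  # below the floor: other_max = 0 must not rescue a noise-only gene
  silent <- calls[calls$gene_id == "silent", ]
  expect_false(silent$passes_floor)
  expect_false(silent$passes_fold)
  expect_true(is.na(silent$ratio))
})

test_that("zero denominator passes only above the floor; boundary is inclusive", {
  m <- matrix(c(2, 2, 0,
                5, 5, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("inf_spec", "exact5"), c("h1", "h2", "l1")))
  expr <- tiny_expression(m, c("heart", "heart", "liver"))
  calls <- compute_specificity(expr, "heart")
  expect_true(calls$passes_fold[calls$gene_id == "inf_spec"])
  expect_true(calls$passes_fold[calls$gene_id == "exact5"])  # ratio == fold
})

test_that("unknown tissue and empty input raise errors", {
  expr <- random_expression(1)
  expect_error(compute_specificity(expr, "pancreas"), "unknown target tissue")
  expect_error(expression_matrix(matrix(numeric(0), 0, 0),
                                 data.frame()), "empty")
})

test_that("compute_specificity agrees with the brute-force oracle", {
  for (seed in 1:5) {
    expr <- random_expression(seed, n_genes = 50)
    # mix in a few strong genes so both outcomes occur
    expr$values[1:3, expr$sample_meta$tissue == "heart"] <-
      expr$values[1:3, expr$sample_meta$tissue == "heart"] * 100
    calls <- compute_specificity(expr, "heart", fold = 5, floor = 0.5)
    expect_identical(calls$passes_fold,
                     unname(brute_specificity(expr, "heart", 5, 0.5)))
  }
})

test_that("raising the fold threshold never enlarges the hit set", {
  expr <- random_expression(7, n_genes = 100)
  hits <- lapply(c(2, 5, 10, 20), function(f)
    with(compute_specificity(expr, "heart", fold = f), gene_id[passes_fold]))
  for (k in 2:length(hits))
    expect_true(all(hits[[k]] %in% hits[[k - 1]]))
})

test_that("annotation and ortholog partitions preserve order and cover input", {
  cand <- paste0("g", 1:10)
  ann <- filter_annotation(cand, c("g2", "g5", "g9", "other"))
  expect_identical(ann$retained, c("g2", "g5", "g9"))
  expect_identical(sort(c(ann$retained, ann$excluded)), sort(cand))
  expect_identical(filter_annotation(cand, cand)$retained, cand)
  expect_identical(filter_annotation(cand, character())$retained, character())

  omap <- data.frame(a = c("g2", "g2", "g5"), b = c("m1", "m2", "m3"))
  mo <- map_orthologs(cand, omap)
  expect_identical(sort(unique(mo$mapped$gene_id)), c("g2", "g5"))
  expect_equal(nrow(mo$mapped), 3)   # multi-mapping keeps all partners
  expect_identical(mo$unmapped, setdiff(cand, c("g2", "g5")))
  expect_identical(map_orthologs(cand, NULL)$unmapped, cand)
})

test_that("cross-species validation accepts any passing partner and flags absentees", {
  m <- matrix(c(50, 50, 1,
                1, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("m_spec", "m_flat"), c("h1", "h2", "l1")))
  expr_b <- tiny_expression(m, c("heart", "heart", "liver"))
  pairs <- data.frame(gene_id = c("gA", "gA", "gB", "gC"),
                      partner_id = c("m_flat", "m_spec", "m_flat", "m_gone"),
                      stringsAsFactors = FALSE)
  res <- cross_species_validate(pairs, expr_b, "heart")
  expect_identical(res$validated, "gA")      # one passing partner suffices
  expect_identical(sort(res$rejected), c("gB", "gC"))
  expect_identical(res$detail$reason[res$detail$partner_id == "m_gone"],
                   "absent")
})

test_that("funnel reports telescope and reject broken chains", {
  stages <- list(
    list(stage = "annotation", retained = paste0("g", 1:26),
         excluded = paste0("x", 1:70)),
    list(stage = "ortholog", retained = paste0("g", 1:8),
         excluded = paste0("g", 9:26)),
    list(stage = "cross_species", retained = paste0("g", 1:5),
         excluded = paste0("g", 6:8)))
  rep <- build_funnel_report(stages)
  expect_identical(rep$table$n_in, c(96L, 26L, 8L))
  expect_identical(rep$table$n_excluded, c(70L, 18L, 3L))
  expect_identical(rep$table$n_out, c(26L, 8L, 5L))
  # telescoping: exclusions plus final output account for the input
  expect_equal(sum(rep$table$n_excluded) + rep$table$n_out[3],
               rep$table$n_in[1])
  # single stage, no exclusions
  one <- build_funnel_report(list(list(stage = "s",
                                       retained = "g1",
                                       excluded = character())))
  expect_equal(one$table$n_in, one$table$n_out)
  # chain violation
  bad <- stages
  bad[[3]]$retained <- paste0("g", 1:4)   # 4 + 3 != 8
  expect_error(build_funnel_report(bad), "chain violation")
  # serializes to parseable JSON
  js <- funnel_report_json(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$stages$n_out, c(26, 8, 5))
})

test_that("telescoping holds on randomly built funnels", {
  set.seed(42)
  for (i in 1:10) {
    ids <- paste0("g", seq_len(sample(20:80, 1)))
    stages <- list(); pool <- ids
    for (s in 1:3) {
      drop <- sample(length(pool) - 1, 1)
      excl <- sample(pool, drop)
      stages[[s]] <- list(stage = paste0("s", s),
                          retained = setdiff(pool, excl), excluded = excl)
      pool <- setdiff(pool, excl)
    }
    rep <- build_funnel_report(stages)
    expect_equal(sum(rep$table$n_excluded) + rep$table$n_out[3],
                 length(ids))
    expect_identical(rep$table$n_out, rep$table$n_in - rep$table$n_excluded)
  }
})
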