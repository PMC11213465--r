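test_that("FISH localization aggregates per-cell percentages", {
  cells <- data.frame(cell_id = 1:100, nuclear_spots = 40,
                      cytoplasmic_spots = 60)
  r <- fish_localization(cells)
  expect_equal(r$percent_cytoplasmic, 60)
  expect_equal(r$percent_nuclear, 40)
  expect_length(r$qc_flags, 0)

  one <- fish_localization(data.frame(cell_id = 1, nuclear_spots = 10,
                                      cytoplasmic_spots = 0))
  expect_equal(one$percent_cytoplasmic, 0)
  expect_true("low_n" %in% one$qc_flags)

  expect_error(fish_localization(data.frame(cell_id = 1, nuclear_spots = 0,
                                            cytoplasmic_spots = 0)),
               "no cell has any spot")
})

test_that("zero-spot cells are excluded but counted in QC", {
  cells <- data.frame(cell_id = 1:101,
                      nuclear_spots = c(rep(40, 100), 0),
                      cytoplasmic_spots = c(rep(60, 100), 0))
  r <- fish_localization(cells)
  expect_equal(r$n_cells, 100)
  expect_equal(r$n_zero_cells, 1)
  expect_true("zero_spot_cells" %in% r$qc_flags)
  expect_false("low_n" %in% r$qc_flags)
})

test_that("FISH aggregate is invariant to cell order and duplication", {
  g <- generate_fish(3)
  base <- fish_localization(g$cells)$percent_cytoplasmic
  set.seed(1)
  shuffled <- g$cells[sample(nrow(g$cells)), ]
  expect_equal(fish_localization(shuffled)$percent_cytoplasmic, base)
  doubled <- rbind(g$cells, transform(g$cells, cell_id = paste0(cell_id, "b")))
  expect_equal(fish_localization(doubled)$percent_cytoplasmic, base)
})

test_that("seeded FISH simulations recover the true cytoplasmic fraction", {
  for (f in c(0.3, 0.6, 0.9)) {
    for (seed in 1:3) {
      g <- generate_fish(seed, n_cells = 100, spots_per_cell = 50,
                         p_cyto = f)
      r <- fish_localization(g$cells)
      expect_lt(abs(r$percent_cytoplasmic - 100 * f), 3)
    }
  }
})

test_that("swapping compartments mirrors the percentage (both methods)", {
  g <- generate_fish(5)
  swapped <- data.frame(cell_id = g$cells$cell_id,
                        nuclear_spots = g$cells$cytoplasmic_spots,
                        cytoplasmic_spots = g$cells$nuclear_spots)
  expect_equal(fish_localization(swapped)$percent_cytoplasmic,
               100 - fish_localization(g$cells)$percent_cytoplasmic)

  cy <- qpcr_measurement(18, 15); nu <- qpcr_measurement(19, 15)
  ctrl <- list(
    neat1_like = list(type = "nuclear", cyto = qpcr_measurement(25, 15),
                      nuc = qpcr_measurement(18, 15)),
    gapdh = list(type = "cytosolic", cyto = qpcr_measurement(16, 15),
                 nuc = qpcr_measurement(20, 15)))
  fwd <- fractionation_localization(cy, nu, ctrl)
  rev <- fractionation_localization(nu, cy, ctrl)
  expect_equal(rev$percent_cytoplasmic, 100 - fwd$percent_cytoplasmic)
})

test_that("delta-delta-Ct relative quantification is correct", {
  a <- qpcr_measurement(20, 15)   # delta-Ct 5
  b <- qpcr_measurement(22, 15)   # delta-Ct 7
  expect_equal(relative_quantification(a, b), 4)
  expect_equal(relative_quantification(a, a), 1)
  a19 <- qpcr_measurement(20, 15, efficiency = 1.9)
  b19 <- qpcr_measurement(22, 15, efficiency = 1.9)
  expect_equal(relative_quantification(a19, b19), 1.9^2)
  expect_error(qpcr_measurement(NA, 15), "finite")
  expect_error(relative_quantification(a, a19), "efficiency")
})

test_that("fractionation localization converts ratios and runs control QC", {
  ctrl <- list(
    neat1_like = list(type = "nuclear", cyto = qpcr_measurement(25, 15),
                      nuc = qpcr_measurement(18, 15)),
    gapdh = list(type = "cytosolic", cyto = qpcr_measurement(16, 15),
                 nuc = qpcr_measurement(20, 15)))
  # r = 1.5 -> 60%: need delta-Ct difference log2(1.5)
  cy <- qpcr_measurement(15 + 5 - log2(1.5), 15)
  nu <- qpcr_measurement(20, 15)
  r <- fractionation_localization(cy, nu, ctrl)
  expect_equal(r$percent_cytoplasmic, 60, tolerance = 1e-9)
  expect_length(r$qc_flags, 0)

  # r = 1 -> 50%
  r50 <- fractionation_localization(nu, nu, ctrl)
  expect_equal(r50$percent_cytoplasmic, 50)

  # a nuclear control measuring 80% cytoplasmic must fail QC
  bad <- ctrl
  bad$neat1_like$cyto <- qpcr_measurement(16, 15)  # now cyto-skewed
  rb <- fractionation_localization(cy, nu, bad)
  expect_true(any(grepl("control_failed:neat1_like", rb$qc_flags)))

  expect_error(fractionation_localization(cy, nu,
                                          ctrl["gapdh"]), "control")
})
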