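test_that("PWM construction pseudocounts and normalizes", {
  counts <- matrix(c(3, 1, 0, 0), 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- build_pwm(counts, pseudocount = 0.25)
  expect_equal(unname(pwm$prob[, 1]), c(0.65, 0.25, 0.05, 0.05))

  uniform <- build_pwm(matrix(0, 4, 1), pseudocount = 0.25)
  expect_equal(unname(uniform$prob[, 1]), rep(0.25, 4))

  expect_error(build_pwm(counts, pseudocount = 0), "pseudocount")
  expect_error(build_pwm(matrix(0, 4, 0)), "zero-width")
  expect_equal(colSums(random_pwm(1, 8)$prob), rep(1, 8))
})

test_that("scanning scores log2 odds and handles short sequences and Ns", {
  # width-2 PWM: each position half the mass on one base -> 1 bit each
  prob <- matrix(c(0.5, 0.5 / 3, 0.5 / 3, 0.5 / 3,
                   0.5 / 3, 0.5, 0.5 / 3, 0.5 / 3), 4)
  pwm <- riboseek:::pwm_from_prob(prob)
  hits <- scan_sequence(pwm, "AC", p_threshold = 1, strands = "forward")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, 2, tolerance = 1e-9)
  expect_equal(hits$start, 0)

  expect_equal(nrow(scan_sequence(pwm, "A")), 0)   # shorter than width
  # N-containing windows are skipped, not penalized
  h2 <- scan_sequence(pwm, "ACNAC", p_threshold = 1, strands = "forward")
  expect_identical(h2$start, c(0L, 3L))
})

test_that("palindromic motifs hit both strands at equal score and position", {
  # ACGT consensus is its own reverse complement
  counts <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(1:4, 1:4)] <- 10
  pwm <- build_pwm(counts, pseudocount = 1)
  hits <- scan_sequence(pwm, "GGACGTGG", p_threshold = 0.05)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$start, c(2L, 2L))
  expect_equal(hits$score[1], hits$score[2], tolerance = 1e-9)
})

test_that("scan hits match an exhaustive per-offset brute force on 1 kb", {
  pwm <- random_pwm(11, 6)
  seq <- random_dna_seq(12, 1000)
  hits <- scan_sequence(pwm, seq, p_threshold = 1e-2)

  # independent brute force: loop over every offset and strand
  S <- log2(pwm$prob / pwm$background)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(seq, "")[[1]]
  brute <- list()
  for (i in seq_len(1000 - 6 + 1)) {
    win <- ch[i:(i + 5)]
    sc_f <- sum(S[cbind(match(win, c("A", "C", "G", "T")), 1:6)])
    rc <- rev(unname(comp[win]))
    sc_r <- sum(S[cbind(match(rc, c("A", "C", "G", "T")), 1:6)])
    brute[[i]] <- data.frame(start = i - 1L,
                             fwd = sc_f, rev = sc_r)
  }
  brute <- do.call(rbind, brute)
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") brute$fwd else brute$rev
    p <- score_pvalue(pwm, sc)
    keep <- which(p <= 1e-2)
    got <- hits[hits$strand == strand, ]
    expect_identical(got$start, brute$start[keep])
    expect_equal(got$score, sc[keep], tolerance = 1e-9)
  }
})

test_that("DP null p-values equal exhaustive enumeration for widths <= 6", {
  for (w in c(2, 4, 6)) {
    pwm <- random_pwm(w * 13, w)
    # query at a spread of attainable scores plus the extremes
    null <- pwm_null_distribution(pwm)
    scores <- unname(c(quantile(null$score, c(0, 0.25, 0.5, 0.9, 0.99, 1)),
                       min(null$score) - 1, max(null$score) + 1))
    expect_equal(score_pvalue(pwm, scores, null = null),
                 enum_pwm_tail(pwm, scores), tolerance = 1e-6)
  }
  # width-2 hand case: 1 bit per matched position, uniform elsewhere
  prob <- matrix(c(0.5, 0.5 / 3, 0.5 / 3, 0.5 / 3,
                   0.5 / 3, 0.5, 0.5 / 3, 0.5 / 3), 4)
  pwm2 <- riboseek:::pwm_from_prob(prob)
  expect_equal(score_pvalue(pwm2, 2), 1 / 16)
  expect_equal(score_pvalue(pwm2, min(pwm_null_distribution(pwm2)$score)), 1)
  expect_equal(score_pvalue(pwm2, 100), 0)
})

test_that("p-values are monotone in score and hit count in threshold", {
  pwm <- random_pwm(21, 5)
  null <- pwm_null_distribution(pwm)
  s <- seq(min(null$score), max(null$score), length.out = 50)
  p <- score_pvalue(pwm, s, null = null)
  expect_true(all(diff(p) <= 1e-12))
  seq1 <- random_dna_seq(22, 500)
  counts <- vapply(c(1e-4, 1e-3, 1e-2, 0.1, 1), function(th)
    nrow(scan_sequence(pwm, seq1, p_threshold = th)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("reverse-complementing the sequence mirrors hits and keeps scores", {
  pwm <- random_pwm(31, 5)
  seq <- random_dna_seq(32, 300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h1 <- scan_sequence(pwm, seq, p_threshold = 0.05)
  h2 <- scan_sequence(pwm, rc, p_threshold = 0.05)
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
  # a forward hit at s maps to a reverse hit at L - s - w
  L <- 300; w <- 5
  mapped <- sort(L - h1$end[h1$strand == "+"])
  expect_identical(sort(h2$start[h2$strand == "-"]), as.integer(mapped))
})

test_that("PWM text files round-trip in both orientations", {
  pwm <- random_pwm(41, 7)
  f1 <- tempfile(fileext = ".mat")
  # positions as rows, A C G T columns
  write.table(t(pwm$prob), f1, row.names = FALSE, col.names = FALSE)
  r1 <- read_pwm(f1)
  expect_equal(r1$prob, pwm$prob, tolerance = 1e-6)
  # 4 rows x width columns
  f2 <- tempfile(fileext = ".mat")
  write.table(pwm$prob, f2, row.names = FALSE, col.names = FALSE)
  expect_equal(read_pwm(f2)$prob, pwm$prob, tolerance = 1e-6)
  # count matrices are pseudocounted
  f3 <- tempfile(fileext = ".mat")
  writeLines(c("# comment", "0 20 0 0", "20 0 0 0"), f3)
  r3 <- read_pwm(f3, pseudocount = 1)
  expect_equal(r3$width, 2)
  expect_equal(unname(r3$prob[2, 1]), 21 / 24)
  # packaged example matrices load
  mef2 <- read_pwm(system.file("extdata", "mef2_like.mat",
                               package = "riboseek"))
  expect_equal(mef2$width, 10)
})
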