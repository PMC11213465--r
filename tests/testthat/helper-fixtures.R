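# Shared fixture builders for the test suite.  Everything is generated
# in code under explicit seeds; no files are read from disk.

# tiny expression matrix: values is a tissue -> per-gene list helper
tiny_expression <- function(values, tissues, n_rep = NULL) {
  # values: genes x samples matrix; tissues: per-sample tissue labels
  meta <- data.frame(sample_id = colnames(values), species = "test",
                     tissue = tissues,
                     replicate = stats::ave(seq_along(tissues), tissues,
                                            FUN = seq_along),
                     stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}

random_expression <- function(seed, n_genes = 30, tissues = c("heart",
                              "heart", "liver", "brain", "kidney")) {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * length(tissues), log(5), 1), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_along(tissues))))
  tiny_expression(m, tissues)
}

# brute-force specificity oracle: per gene, compare every target sample
# against every other sample directly
brute_specificity <- function(expr, target_tissue, fold, floor) {
  is_t <- expr$sample_meta$tissue == target_tissue
  vapply(seq_along(expr$gene_ids), function(g) {
    tv <- expr$values[g, is_t]
    ov <- expr$values[g, !is_t]
    if (min(tv) < floor) return(FALSE)
    all(vapply(tv, function(t) all(t >= fold * ov | ov == 0), logical(1))) &&
      (all(ov == 0) || min(tv) / max(ov) >= fold)
  }, logical(1))
}

random_profile <- function(seed) {
  set.seed(seed)
  x <- runif(5)
  fraction_distribution(setNames(x, c("free", "40S", "60S", "monosome",
                                      "polysome")))
}

random_pwm <- function(seed, width) {
  set.seed(seed)
  counts <- matrix(rpois(4 * width, 5), 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  build_pwm(counts, pseudocount = 0.5)
}

random_dna_seq <- function(seed, n) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-window binned-score enumeration oracle for the PWM null: walks all
# 4^w windows, sums the per-position contributions discretized exactly
# as the DP does, and accumulates background probabilities
enum_pwm_tail <- function(pwm, score, bin = 0.01) {
  w <- pwm$width
  S <- log2(pwm$prob / pwm$background)
  k <- round(S / bin)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  binsum <- numeric(nrow(grid))
  prob <- numeric(nrow(grid)) + 1
  for (j in seq_len(w)) {
    binsum <- binsum + k[cbind(grid[, j], j)]
    prob <- prob * pwm$background[grid[, j]]
  }
  kq <- round(score / bin)
  vapply(kq, function(q) sum(prob[binsum >= q]), numeric(1))
}
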