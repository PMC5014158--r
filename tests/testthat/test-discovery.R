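test_that("enrichment_test matches pbinom arithmetic and validates input", {
  expect_equal(enrichment_test(5, 10, 0.5), 0.623046875)
  expect_equal(enrichment_test(0, 10, 0.2), 1)
  expect_equal(enrichment_test(c(1, 5), 10, 0.5),
               c(1 - 0.5^10, 0.623046875))
  expect_error(enrichment_test(1, 10, 0), "bg_rate")
  expect_error(enrichment_test(1, 10, 1), "bg_rate")
  expect_error(enrichment_test(11, 10, 0.5), "exceed")
})

test_that("count_words equals a brute-force substring count", {
  set.seed(21)
  seqs <- replicate(5, paste(sample(c("A","C","G","T","N"), 40,
                                    replace = TRUE,
                                    prob = c(.24,.24,.24,.24,.04)),
                             collapse = ""))
  w <- 3L
  cw <- count_words(seqs, w)
  words <- code_to_word(seq_len(4^w), w)
  brute <- vapply(words, function(wd) {
    tot <- 0L
    for (s in c(seqs, vapply(seqs, revcomp_chr, character(1)))) {
      for (i in seq_len(max(0L, nchar(s) - w + 1L)))
        if (substr(s, i, i + w - 1L) == wd) tot <- tot + 1L
    }
    tot
  }, integer(1))
  expect_equal(unname(cw$counts), unname(brute))
  # windows: valid (N-free) windows per strand
  nwin <- sum(vapply(seqs, function(s) {
    x <- seq_to_int(s)
    length(window_codes(x, w))
  }, integer(1)))
  expect_equal(cw$windows, 2L * nwin)
})

test_that("word_enumerate recovers a planted word and ranks it first", {
  set.seed(31)
  bg <- default_background(0.5)
  fg <- vapply(1:12, function(i) {
    s <- markov_seq(150, bg)
    paste0(substr(s, 1, 60), "TGCCAG", substr(s, 67, 150))
  }, character(1))
  res <- word_enumerate(fg, bg, widths = 6L, max_word_mm = 0L)
  expect_true(res$word[1] %in% c("TGCCAG", revcomp_chr("TGCCAG")))
  expect_lte(res$p_adj[1], 0.05)
  expect_true(all(diff(res$p) >= 0))
})

test_that("word_enumerate mismatch counting equals neighborhood sums", {
  fg <- c("AAAAAAT", "AAAAAAA")
  bg <- default_background(0.5)
  res <- word_enumerate(fg, bg, widths = 6L, max_word_mm = 1L,
                        correct = "none", alpha = 1, top_n = Inf)
  # oracle: exact counts, then 1-mm neighborhood sum for word AAAAAA
  cw <- count_words(fg, 6L)
  nb_sum <- 0
  for (code in seq_len(4^6)) {
    wd <- code_to_word(code, 6L)
    if (sum(strsplit(wd, "")[[1]] != strsplit("AAAAAA", "")[[1]]) <= 1)
      nb_sum <- nb_sum + cw$counts[code]
  }
  expect_equal(res$fg_hits[res$word == "AAAAAA"], unname(nb_sum))
})

test_that("word_enumerate raw p-values are calibrated under the null", {
  set.seed(41)
  bg <- default_background(0.44)
  fg <- vapply(1:10, function(i) markov_seq(200, bg), character(1))
  res <- word_enumerate(fg, bg, widths = 6L, max_word_mm = 0L)
  p <- attr(res, "all_p")[["6"]]
  # one-sided binomial p-values are super-uniform; FPR at 0.05 must not
  # exceed the nominal level by more than Monte-Carlo slack
  expect_lt(mean(p <= 0.05), 0.08)
  expect_equal(nrow(res[res$p_adj <= 0.05, ]), 0L)
})

test_that("word_enumerate validates input and handles empty results", {
  bg <- default_background(0.5)
  expect_error(word_enumerate(character(0), bg), "nonempty")
  res <- word_enumerate("ACGTACGTAC", bg, widths = 6L, max_word_mm = 0L)
  expect_s3_class(res, "data.frame")
})

test_that("em_discover recovers a planted motif with monotone loglik", {
  set.seed(51)
  bg <- default_background(0.5)
  site <- "TTGACCGA"
  seqs <- vapply(1:15, function(i) {
    s <- markov_seq(80, bg)
    off <- sample(1:70, 1)
    paste0(substr(s, 1, off - 1), site, substr(s, off + 8, 80))
  }, character(1))
  m <- em_discover(seqs, 8L, seed = 3, n_seeds = 4)
  expect_true(m$consensus %in% c(site, revcomp_chr(site)))
  tr <- m$provenance$loglik_trace
  expect_true(all(diff(tr) >= -1e-8))
  expect_gt(m$provenance$gamma, 0.5)
  # determinism
  m2 <- em_discover(seqs, 8L, seed = 3, n_seeds = 4)
  expect_equal(m$mat, m2$mat)
  expect_error(em_discover(c("ACG", "TTT"), 8L), "shorter")
})

test_that("trap_affinity equals the direct per-window oracle", {
  set.seed(61)
  for (i in 1:10) {
    seq <- paste(sample(c("A","C","G","T"), 60, replace = TRUE),
                 collapse = "")
    mat <- matrix(stats::runif(4 * 6), 4)
    mat <- sweep(mat, 2, colSums(mat), "/")
    pwm <- new_pwm(mat, name = "t")
    expect_equal(trap_affinity(seq, pwm), oracle_trap(seq, pwm),
                 tolerance = 1e-10)
  }
  pwm <- word_to_pwm("ACGTAC")
  expect_equal(trap_affinity("ACG", pwm), 0)
  # windows with N contribute nothing
  expect_equal(trap_affinity(paste0("AC", strrep("N", 10)), pwm), 0)
})

test_that("library_enrichment flags the planted motif, not decoys", {
  set.seed(71)
  bg <- default_background(0.5)
  site <- "TGCCAGTA"
  fg <- vapply(1:12, function(i) {
    s <- markov_seq(100, bg)
    paste0(substr(s, 1, 40), site, substr(s, 49, 100))
  }, character(1))
  bgseq <- vapply(1:30, function(i) markov_seq(100, bg), character(1))
  lib <- list(planted_pwm(site, name = "hit"),
              planted_pwm("CAGTTGAC", name = "decoy"))
  res <- library_enrichment(fg, bgseq, lib)
  expect_true("hit" %in% res$motif)
  expect_false("decoy" %in% res$motif)
  expect_true("hit" %in% names(attr(res, "pwms")))
  # bonferroni doubles the p for a 2-PWM library
  res2 <- library_enrichment(fg, bgseq, lib, correct = "bonferroni",
                             alpha = 1)
  expect_equal(res2$p_adj, pmin(res2$p * 2, 1))
  expect_error(library_enrichment(character(0), bgseq, lib), "nonempty")
})

test_that("motif_enrichment_p detects planted occurrences", {
  set.seed(81)
  bg <- default_background(0.5)
  site <- "TGCCAGTA"
  fg <- vapply(1:10, function(i) {
    s <- markov_seq(100, bg)
    paste0(substr(s, 1, 40), site, substr(s, 49, 100))
  }, character(1))
  bgseq <- vapply(1:30, function(i) markov_seq(100, bg), character(1))
  res <- motif_enrichment_p(fg, site, site, bg_seqs = bgseq, max_mm = 0)
  expect_gte(res$fg_hits, 10)
  expect_lt(res$p, 1e-6)
  expect_error(motif_enrichment_p(fg, site, site), "bg_seqs or bg_rate")
})

test_that("analytic_scan_rate is exact under a uniform background", {
  unif <- structure(list(init = rep(0.25, 4),
                         trans = matrix(0.25, 4, 4)),
                    class = "bg_markov")
  # degenerate = consensus gates matching to the exact word, whatever
  # the mismatch allowance
  expect_equal(analytic_scan_rate("ACGTAC", "ACGTAC", unif, max_mm = 1),
               1 / 4^6)
  expect_equal(analytic_scan_rate("ACGTAC", "ACGTAC", unif, max_mm = 2),
               1 / 4^6)
  # fully degenerate first two positions: conforming words vary there;
  # within 1 mismatch of the consensus that allows 1 + 3 + 3 words
  expect_equal(analytic_scan_rate("ACGTAC", "NNGTAC", unif, max_mm = 1),
               7 / 4^6)
  expect_equal(analytic_scan_rate("ACGTAC", "NNGTAC", unif, max_mm = 2),
               16 / 4^6)
  # degenerate R at position 1 restricts conforming words to exactly
  # {ACGTAC, GCGTAC}; both are within 1 mismatch of the consensus
  expect_equal(analytic_scan_rate("ACGTAC", "RCGTAC", unif, max_mm = 1),
               2 / 4^6)
})

test_that("analytic_scan_rate agrees with empirical scanning", {
  set.seed(91)
  bg <- default_background(0.44)
  rate <- analytic_scan_rate("TGCCAG", "TGCCAG", bg, max_mm = 1)
  seqs <- vapply(1:60, function(i) markov_seq(500, bg), character(1))
  hits <- 0; trials <- 0
  for (s in seqs) {
    hits <- hits + nrow(scan_consensus(s, "TGCCAG", max_mm = 1))
    trials <- trials + 2 * (nchar(s) - 6 + 1)
  }
  # binomial 99.9% interval around the analytic rate
  ci <- qbinom(c(5e-4, 1 - 5e-4), trials, rate)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})
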