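test_that("mutual_information equals the direct contingency oracle", {
  set.seed(201)
  for (i in 1:25) {
    x <- rnorm(7); y <- rnorm(7)
    got <- mutual_information(x, y)
    want <- oracle_mi_norm(x, y)
    expect_equal(got$mi_norm, want, tolerance = 1e-12)
  }
})

test_that("normalized MI is 1 for identical and monotone profiles", {
  x <- c(3, 1, 7, 2, 9, 4, 8)
  expect_equal(mutual_information(x, x)$mi_norm, 1)
  expect_equal(mutual_information(x, exp(x))$mi_norm, 1)
  expect_equal(mutual_information(x, -x^3)$mi_norm,
               mutual_information(x, -x)$mi_norm)
})

test_that("MI is symmetric and invariant to monotone transforms", {
  set.seed(202)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    a <- mutual_information(x, y)$mi_norm
    expect_equal(mutual_information(y, x)$mi_norm, a, tolerance = 1e-12)
    expect_equal(mutual_information(2 * x + 5, y)$mi_norm, a)
    expect_equal(mutual_information(x, exp(y))$mi_norm, a)
  }
})

test_that("constant profiles are flagged with MI 0", {
  r <- mutual_information(rep(2, 7), rnorm(7))
  expect_true(r$constant)
  expect_equal(r$mi_norm, 0)
  expect_error(mutual_information(1:3, 1:4), "equal length")
  expect_error(mutual_information(1:2, 2:1), "at least")
})

test_that("permutation null equals the exhaustive 5040-permutation mean", {
  set.seed(203)
  x <- c(0.3, 1.2, 2.9, 0.7, 4.1, 3.3, 2.2)
  y <- c(1.1, 0.2, 3.8, 2.5, 0.9, 4.4, 3.1)
  exact <- oracle_perm_mi_exhaustive(x, y)
  # the exact mean for untied 7-vectors sits in a narrow known band
  expect_gte(exact, 0.30)
  expect_lte(exact, 0.50)
  est <- permutation_null_mi(x, y, n_perm = 2000, seed = 5)
  expect_equal(est, exact, tolerance = 0.02)
})

make_clusters <- function(centroids, labels) {
  structure(list(k = nrow(centroids), labels = labels,
                 centroids = centroids, wcss = 0, seed = 1L,
                 dropped = character(0)),
            class = "cluster_result")
}

test_that("classify_pattern calls identical profiles similar", {
  x <- c(1, 2, 4, 7, 9, 12, 15)
  cents <- matrix(rep(0, 25), 1)
  clA <- make_clusters(cents, c(a = 1L))
  clB <- make_clusters(cents, c(b = 1L))
  exprA <- matrix(x, 1, dimnames = list("a", NULL))
  exprB <- matrix(x, 1, dimnames = list("b", NULL))
  out <- classify_pattern("a", "b", clA, clB, exprA, exprB)
  expect_equal(out$class, "similar")
  expect_equal(out$centroid_distance, 0)
  expect_equal(out$rank_correlation, 1)
  expect_equal(out$mi_norm, 1)
})

test_that("classify_pattern calls bin-preserving rearrangements shifted", {
  # same 3-bin occupancy (mi_norm = 1) but far-apart cluster centroids,
  # so the similar rule cannot fire and the MI rule must
  x <- c(1, 2, 3, 7, 6, 5, 4)
  y <- c(3, 2, 1, 6, 7, 4, 5)
  cents <- rbind(rep(0, 25), rep(10, 25))
  clA <- make_clusters(cents, c(a = 1L))
  clB <- make_clusters(cents, c(b = 2L))  # far centroid -> not similar
  exprA <- matrix(x, 1, dimnames = list("a", NULL))
  exprB <- matrix(y, 1, dimnames = list("b", NULL))
  out <- classify_pattern("a", "b", clA, clB, exprA, exprB, seed = 11)
  expect_equal(out$class, "shifted")
  expect_equal(out$mi_norm, 1)
  expect_gte(out$mi_norm - out$mi_null_mean, 0.2)
})

test_that("classify_pattern calls unrelated noise distinct", {
  set.seed(204)
  cents <- rbind(rep(0, 25), rep(10, 25))
  clA <- make_clusters(cents, c(a = 1L))
  clB <- make_clusters(cents, c(b = 2L))
  n_distinct <- 0L
  for (i in 1:10) {
    exprA <- matrix(rnorm(7), 1, dimnames = list("a", NULL))
    exprB <- matrix(rnorm(7), 1, dimnames = list("b", NULL))
    out <- classify_pattern("a", "b", clA, clB, exprA, exprB, seed = i)
    if (out$class == "distinct") n_distinct <- n_distinct + 1L
  }
  expect_gte(n_distinct, 6L)
  expect_error(classify_pattern("zz", "b", clA, clB,
                                matrix(0, 1, 7), matrix(0, 1, 7)),
               "not clustered")
})

mk_segset <- function(gene, promoter) {
  structure(list(gene = gene, strand = "+",
                 segments = c(promoter = promoter, utr5 = "", utr3 = "",
                              cds = "", intron = ""),
                 clipped = FALSE, missing = character(0)),
            class = "segment_set")
}

test_that("call_recruited applies both criteria on a toy case", {
  site <- "TGCCAGTA"
  bgstr <- strrep("ACGGTTCAAGGCTTAGCGCT", 10)
  withsite <- function() paste0(substr(bgstr, 1, 96), site,
                                substr(bgstr, 105, 200))
  segsA <- list(c4 = mk_segset("c4", withsite()),
                co1 = mk_segset("co1", withsite()),
                co2 = mk_segset("co2", bgstr))
  segB_clean <- mk_segset("ort", bgstr)
  segB_with <- mk_segset("ort", withsite())
  m <- planted_pwm(site, name = "m")
  rate <- 1e-4

  call1 <- call_recruited(m, "c4", "promoter", c("co1", "co2"),
                          segsA, segB_clean, bg_rate = rate, max_mm = 0)
  expect_true(call1$criterion1)
  expect_true(call1$criterion2)
  expect_true(call1$verdict)
  expect_equal(call1$occ_A, 1L)
  expect_equal(call1$occ_B, 0L)
  expect_equal(call1$criterion1_evidence$gene, "co1")

  # criterion 2 fails when the B ortholog carries the site
  call2 <- call_recruited(m, "c4", "promoter", c("co1"),
                          segsA, segB_with, bg_rate = rate, max_mm = 0)
  expect_false(call2$criterion2)
  expect_false(call2$verdict)

  # criterion 1 fails with no enriched co-expressed gene
  call3 <- call_recruited(m, "c4", "promoter", c("co2"),
                          segsA, segB_clean, bg_rate = rate, max_mm = 0)
  expect_false(call3$criterion1)
  expect_false(call3$verdict)

  # missing ortholog -> not callable
  call4 <- call_recruited(m, "c4", "promoter", c("co1"),
                          segsA, NULL, bg_rate = rate, max_mm = 0)
  expect_true(is.na(call4$verdict))
  expect_true(is.na(call4$criterion2))
})

test_that("evaluate_recruitment scores precision and recall", {
  truth <- list(planted_pwm("TGCCAGTA", name = "t1"),
                planted_pwm("CGATAAGC", name = "t2"))
  called <- list(planted_pwm("TGCCAGTA", name = "c1"),
                 planted_pwm("AGGTCCAT", name = "c2"))
  ev <- evaluate_recruitment(called, truth, null_size = 500)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$truth_hit, c(TRUE, FALSE))
  # empty calls
  ev0 <- evaluate_recruitment(list(), truth, null_size = 100)
  expect_true(is.na(ev0$precision))
  expect_equal(ev0$recall, 0)
})
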