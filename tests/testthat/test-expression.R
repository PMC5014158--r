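test_that("compute_rpkm matches the definition", {
  counts <- matrix(c(100, 250, 30, 0), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  r <- compute_rpkm(counts, gene_lengths = c(2000, 500),
                    library_sizes = c(1e6, 2e6))
  # direct arithmetic oracle
  expect_equal(r["g1", "s1"], 100 * 1e9 / (2000 * 1e6))
  expect_equal(r["g2", "s2"], 0)
  expect_equal(r["g2", "s1"], 250 * 1e9 / (500 * 1e6))
  expect_error(compute_rpkm(counts, c(0, 10), c(1, 1)), "length")
  expect_error(compute_rpkm(counts, c(10, 10), c(0, 1)), "librar")
})

test_that("filter_expressed applies a strict mean > threshold", {
  m <- rbind(lo = rep(1, 7), hi = rep(1.01, 7), zero = rep(0, 7))
  expect_identical(filter_expressed(m, 1), "hi")
})

test_that("spline smoothing interpolates the observed points", {
  vals <- c(1, 5, 2, 7, 3, 8, 4)
  cur <- smooth_curve(vals, "spline")
  # grid points 0,1,3,6,12,24 coincide with sampling hours
  for (h in c(0, 1, 3, 6, 12, 24)) {
    j <- which(abs(EVAL_GRID - h) < 1e-9)
    expect_equal(cur[j], vals[which(TIMEPOINT_HOURS == h)],
                 tolerance = 1e-9)
  }
})

test_that("poly3 regression reproduces an exact cubic", {
  beta <- c(0.5, -1, 0.2, -0.005)
  vals <- drop(outer(TIMEPOINT_HOURS, 0:3, "^") %*% beta)
  cur <- smooth_curve(vals, "poly3")
  expect_equal(cur, drop(outer(EVAL_GRID, 0:3, "^") %*% beta),
               tolerance = 1e-8)
})

test_that("normalize_sd yields unit-SD curves and flags constants", {
  x <- normalize_sd(c(1, 3, 7, 2, 9))
  expect_equal(sd(x), 1, tolerance = 1e-12)
  expect_false(attr(x, "constant"))
  y <- normalize_sd(rep(4, 5))
  expect_true(attr(y, "constant"))
  expect_equal(as.numeric(y), rep(0, 5))
})

test_that("k-means recovers a noiseless planted partition exactly", {
  hours <- TIMEPOINT_HOURS
  shapes <- rbind(0.2 + hours / 24, 1.2 - hours / 24,
                  0.2 + exp(-((hours - 6) / 4)^2),
                  0.2 + exp(-((hours - 16) / 5)^2))
  m <- shapes[rep(1:4, each = 12), ] * rep(exp(runif(48, 0, 2)), 7)
  rownames(m) <- sprintf("g%02d", 1:48)
  cs <- curve_set(m, "spline")
  cl <- kmeans_cluster(cs, 4, seed = 3)
  expect_true(same_partition(cl$labels, rep(1:4, each = 12)))
  # determinism
  cl2 <- kmeans_cluster(cs, 4, seed = 3)
  expect_identical(cl$labels, cl2$labels)
})

test_that("kmeans_cluster leaves the global RNG state untouched", {
  m <- matrix(rnorm(200), 20)
  set.seed(99); before <- .Random.seed
  kmeans_cluster(m, 2, seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("compute_fom decreases toward the true k on separable data", {
  hours <- TIMEPOINT_HOURS
  shapes <- rbind(0.2 + hours / 24, 1.2 - hours / 24,
                  0.2 + exp(-((hours - 6) / 4)^2))
  m <- shapes[rep(1:3, each = 10), ] + matrix(rnorm(210, sd = 0.01), 30)
  cs <- curve_set(m, "spline")
  fom <- compute_fom(cs, k_values = c(1, 3), seed = 5)
  expect_equal(fom$k, c(1, 3))
  expect_lt(fom$fom[2], fom$fom[1])
})

test_that("select_coexpressed applies the strict Z threshold", {
  set.seed(7)
  base <- runif(25)
  m <- rbind(t = base,
             t(vapply(1:30, function(i) base + rnorm(25, sd = 0.1 + i / 30),
                      numeric(25))))
  rownames(m) <- c("t", sprintf("g%02d", 1:30))
  cl <- structure(list(k = 1L,
                       labels = stats::setNames(rep(1L, 31), rownames(m)),
                       centroids = matrix(colMeans(m), 1), wcss = 0,
                       seed = 1L, dropped = character(0)),
                  class = "cluster_result")
  cs <- list(curves = m, constant = rep(FALSE, 31))
  co <- select_coexpressed("t", cl, cs, z_threshold = -1.644853)
  # oracle: direct distance + Z computation
  d <- sqrt(rowSums((m[-1, ] - matrix(m[1, ], 30, 25, byrow = TRUE))^2))
  z <- (d - mean(d)) / sd(d)
  expect_setequal(co$gene, names(which(z < -1.644853)))
  expect_true(all(co$z < -1.644853))
})

test_that("select_coexpressed warns and returns empty for tiny clusters", {
  m <- matrix(rnorm(50), 2, dimnames = list(c("a", "b"), NULL))
  cl <- structure(list(labels = c(a = 1L, b = 1L)), class = "cluster_result")
  cs <- list(curves = m, constant = c(FALSE, FALSE))
  expect_warning(co <- select_coexpressed("a", cl, cs), "unstable")
  expect_equal(nrow(co), 0L)
})

test_that("aggregate_pathways averages member genes per time point", {
  m <- rbind(g1 = 1:7, g2 = 3:9, g3 = rep(10, 7))
  bins <- c(g1 = "P1", g2 = "P1", g3 = "P2")
  out <- aggregate_pathways(m, bins)
  expect_equal(out["P1", ], colMeans(m[1:2, ]))
  expect_equal(unname(out["P2", ]), rep(10, 7))
  # empty pathway level yields NA row
  bins2 <- factor(bins, levels = c("P1", "P2", "P3"))
  names(bins2) <- names(bins)
  out2 <- aggregate_pathways(m, bins2)
  expect_true(all(is.na(out2["P3", ])))
})
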