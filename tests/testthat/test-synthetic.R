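small_cfg <- function(...) {
  synth_config(seed = 7L, n_genes_per_species = 40L, n_clusters = 4L,
               segment_lengths = c(promoter = 120L, utr5 = 60L,
                                   utr3 = 60L, cds = 120L, intron = 90L),
               ...)
}

test_that("synth_config validates its arguments", {
  expect_s3_class(small_cfg(), "synth_config")
  expect_error(synth_config(n_c4_genes = 5, n_genes_per_species = 3),
               "exceed")
  expect_error(small_cfg(core_fraction = 0), "core_fraction")
  expect_error(small_cfg(core_fraction = 1.2), "core_fraction")
  expect_error(small_cfg(peripheral_sd = -1), "peripheral_sd")
  expect_error(small_cfg(noise_sd = -0.1), "noise_sd")
  expect_error(small_cfg(ortholog_conflict_rate = 1.5), "probabilities")
  expect_error(small_cfg(gc = 1), "gc")
  expect_error(synth_config(segment_lengths = c(promoter = 300L)),
               "segment_lengths")
  expect_error(
    synth_config(segment_lengths = c(promoter = 5L, utr5 = 120L,
                                     utr3 = 120L, cds = 360L,
                                     intron = 240L)),
    "too short")
  expect_error(
    small_cfg(planted_motifs = list(
      planted_motif_spec(planted_pwm("ACGTACGT"), "promoter",
                         cluster = 9L))),
    "cluster")
})

test_that("generation is byte-identical across repeat runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- generate_dataset(small_cfg(), d1)
  ds2 <- generate_dataset(small_cfg(), d2)
  for (nm in names(ds1$files)) {
    f1 <- ds1$files[[nm]]; f2 <- ds2$files[[nm]]
    expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)),
                 label = nm)
  }
  expect_equal(ds1$exprA, ds2$exprA)
  expect_equal(ds1$truth, ds2$truth)
})

test_that("generation leaves the global RNG state untouched", {
  set.seed(999); before <- .Random.seed
  generate_dataset(small_cfg(), withr::local_tempdir())
  expect_identical(.Random.seed, before)
})

test_that("every truth row names a verbatim planted site", {
  ds <- generate_dataset(small_cfg(), withr::local_tempdir())
  expect_gt(nrow(ds$truth), 0L)
  pwms <- lapply(ds$planted, `[[`, "pwm")
  names(pwms) <- vapply(ds$planted, `[[`, character(1), "name")
  for (r in seq_len(nrow(ds$truth))) {
    row <- ds$truth[r, ]
    segs <- if (row$species == "A") ds$segsA else ds$segsB
    seg <- segs[[row$gene_id]]$segments[[row$segment]]
    pwm <- pwms[[row$motif_id]]
    hits <- scan_consensus(seg, pwm$consensus,
                           degenerate = pwm$degenerate,
                           max_mm = pwm$width)
    expect_true(any(hits$offset == row$offset & hits$strand == row$strand),
                label = paste("truth row", r))
  }
})

test_that("segments extracted from genome + GFF match the generator", {
  ds <- generate_dataset(small_cfg(), withr::local_tempdir())
  for (sp in c("A", "B")) {
    gff <- ds$files[[paste0("models", sp)]]
    fa <- ds$files[[paste0("genome", sp)]]
    want <- if (sp == "A") ds$segsA else ds$segsB
    sub <- names(want)[c(1, 2, 20, 40)]
    got <- extract_segments(gff, fa, genes = sub, promoter_bp = 120)
    for (g in sub) {
      expect_identical(got[[g]]$segments, want[[g]]$segments)
      expect_identical(got[[g]]$strand, want[[g]]$strand)
      expect_length(got[[g]]$missing, 0L)
    }
  }
})

test_that("recruited motifs are absent from species-B C4 orthologs", {
  ds <- generate_dataset(small_cfg(), withr::local_tempdir())
  rec <- Filter(function(s) s$recruited, ds$planted)
  expect_gte(length(rec), 2L)
  rec_names <- vapply(rec, `[[`, character(1), "name")
  # no truth rows at all for recruited motifs in species B
  expect_equal(nrow(ds$truth[ds$truth$species == "B" &
                               ds$truth$motif_id %in% rec_names, ]), 0L)
  # and the orthologous segments are scrubbed even of 1-mm near-sites
  bmap <- stats::setNames(ds$ortholog_truth$geneB, ds$ortholog_truth$geneA)
  for (g in ds$c4_genes) {
    segB <- ds$segsB[[bmap[[g]]]]
    for (spec in rec) {
      cons <- spec$pwm$consensus
      hits <- scan_consensus(segB$segments[[spec$target_segment]], cons,
                             degenerate = strrep("N", nchar(cons)),
                             max_mm = 1L)
      expect_equal(nrow(hits), 0L)
    }
  }
})

test_that("C4 genes host every planted motif and are core members", {
  ds <- generate_dataset(small_cfg(), withr::local_tempdir())
  for (spec in ds$planted) {
    tr <- ds$truth[ds$truth$motif_id == spec$name &
                     ds$truth$species == "A", ]
    expect_true(all(ds$c4_genes %in% tr$gene_id), label = spec$name)
    expect_true(all(tr$segment == spec$target_segment))
  }
  expect_true(all(ds$core[ds$c4_genes]))
  # each cluster keeps at least two core exemplars
  expect_true(all(tapply(ds$core, ds$cluster_id, sum) >= 2))
})

test_that("archetypes stay well separated after SD normalization", {
  hours <- c(0, 0.5, 1, 3, 6, 12, 24)
  grid <- seq(0, 24, length.out = 25)
  sh <- archetype_matrix(grid, 4L)
  sh <- sh / apply(sh, 1, stats::sd)
  # naive up/down/peak sets collapse to ~3.5 here; require a clear margin
  expect_gte(min(stats::dist(sh)), 5)
  expect_equal(dim(archetype_matrix(hours, 6L)), c(6L, 7L))
})

test_that("a noise-free dataset clusters back to the planted partition", {
  ds <- generate_dataset(small_cfg(noise_sd = 0, peripheral_sd = 1e-4),
                         withr::local_tempdir())
  cs <- curve_set(log2(ds$exprA + 1), mode = "spline")
  cl <- kmeans_cluster(cs, 4L, seed = 1)
  expect_true(same_partition(cl$labels[names(ds$cluster_id)],
                             ds$cluster_id))
})

test_that("default-scale config recovers the documented structure", {
  cfg <- synth_config(seed = 1)
  expect_equal(cfg$n_genes_per_species, 1000L)
  expect_equal(cfg$n_clusters, 4L)
  expect_length(cfg$planted_motifs, 4L)
  expect_setequal(
    vapply(cfg$planted_motifs, function(s) s$recruited, logical(1)),
    c(TRUE, FALSE))
})
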