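test_that("scan_consensus finds planted exact and mismatched sites", {
  seq <- paste0(strrep("A", 20), "TGCCAGTA", strrep("A", 20))
  hits <- scan_consensus(seq, "TGCCAGTA", max_mm = 0, both_strands = FALSE)
  expect_equal(hits$offset, 20L)
  expect_equal(hits$mismatches, 0L)
  # reverse-strand occurrence
  seq2 <- paste0(strrep("C", 10), revcomp_chr("TGCCAGTA"), strrep("C", 10))
  hits2 <- scan_consensus(seq2, "TGCCAGTA", max_mm = 0)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$offset, 10L)
})

test_that("degenerate consensus gates matches regardless of Hamming", {
  # window differs from consensus at one position, but the degenerate
  # consensus restricts that position to the consensus base -> no hit
  expect_equal(nrow(scan_consensus("TGCCAGTT", "TGCCAGTA", "TGCCAGTA",
                                   max_mm = 2, both_strands = FALSE)), 0L)
  # degenerate W = A/T at the last position allows it
  h <- scan_consensus("TGCCAGTT", "TGCCAGTA", "TGCCAGTW",
                      max_mm = 2, both_strands = FALSE)
  expect_equal(h$mismatches, 1L)
})

test_that("windows containing N never match", {
  seq <- paste0("TGCC", SEGMENT_SPACER, "AGTA")
  expect_equal(nrow(scan_consensus(seq, "TGCCAGTA", max_mm = 2)), 0L)
})

test_that("scan_consensus equals the brute-force oracle on random seqs", {
  set.seed(11)
  for (i in 1:50) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    cons <- paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                  collapse = "")
    degen <- paste(vapply(strsplit(cons, "")[[1]], function(b) {
      if (runif(1) < 0.3)
        IUPAC_FROM_SET[[paste(sort(union(b, sample(c("A", "C", "G", "T"),
                                                   1))), collapse = "")]]
      else b
    }, character(1)), collapse = "")
    got <- scan_consensus(seq, cons, degen, max_mm = 2)
    want <- oracle_scan(seq, cons, degen, max_mm = 2)
    expect_identical(got, want, label = paste("iteration", i))
  }
})

test_that("revcomp_iupac complements degenerate codes", {
  expect_equal(revcomp_iupac("ACGT"), "ACGT")
  expect_equal(revcomp_iupac("RYN"), "NRY")
  expect_equal(revcomp_iupac(revcomp_iupac("WSKM")), "WSKM")
})

make_toy_gff <- function(dir) {
  # plus-strand gene: promoter 6bp | utr5 4 | cds 6+intron 5+cds 6 | utr3 4
  # layout on chr1 (1-based):
  # 1-6 upstream, 7-10 utr5, 11-16 cds1, 17-21 intron, 22-27 cds2, 28-31 utr3
  chr1 <- "ACGTAC GATC AAACCC GGGGG TTTAAA CTAG"
  chr1 <- gsub(" ", "", chr1)
  # minus-strand gene on chr2: exact mirror of the same transcript
  chr2 <- revcomp_chr(chr1)
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chr1", chr1, ">chr2", chr2), fa)
  L <- nchar(chr1)
  rows <- list(
    c("chr1", "gene", 7, 31, "+", "ID=gp"),
    c("chr1", "mRNA", 7, 31, "+", "ID=gp.t;Parent=gp"),
    c("chr1", "exon", 7, 16, "+", "ID=gp.e1;Parent=gp.t"),
    c("chr1", "exon", 22, 31, "+", "ID=gp.e2;Parent=gp.t"),
    c("chr1", "five_prime_UTR", 7, 10, "+", "ID=gp.u5;Parent=gp.t"),
    c("chr1", "CDS", 11, 16, "+", "ID=gp.c1;Parent=gp.t"),
    c("chr1", "CDS", 22, 27, "+", "ID=gp.c2;Parent=gp.t"),
    c("chr1", "three_prime_UTR", 28, 31, "+", "ID=gp.u3;Parent=gp.t"))
  flip <- function(s, e) c(L - as.integer(e) + 1L, L - as.integer(s) + 1L)
  mrows <- lapply(rows, function(r) {
    se <- flip(r[3], r[4])
    c("chr2", r[2], se[1], se[2], "-", gsub("gp", "gm", r[6]))
  })
  gff <- file.path(dir, "toy.gff3")
  lines <- vapply(c(rows, mrows), function(r)
    paste(r[1], "test", r[2], r[3], r[4], ".", r[5], ".", r[6],
          sep = "\t"), character(1))
  writeLines(c("##gff-version 3", lines), gff)
  list(fa = fa, gff = gff, chr1 = chr1)
}

test_that("extract_segments recovers plus-strand segments verbatim", {
  d <- withr::local_tempdir()
  toy <- make_toy_gff(d)
  segs <- extract_segments(toy$gff, toy$fa, promoter_bp = 6)
  sp <- segs[["gp"]]$segments
  expect_equal(unname(sp["promoter"]), substr(toy$chr1, 1, 6))
  expect_equal(unname(sp["utr5"]), "GATC")
  expect_equal(unname(sp["cds"]),
               paste0("AAACCC", SEGMENT_SPACER, "TTTAAA"))
  expect_equal(unname(sp["intron"]), "GGGGG")
  expect_equal(unname(sp["utr3"]), "CTAG")
  expect_equal(segs[["gp"]]$missing, character(0))
})

test_that("minus-strand genes read 5' to 3' identically to the mirror", {
  d <- withr::local_tempdir()
  toy <- make_toy_gff(d)
  segs <- extract_segments(toy$gff, toy$fa, promoter_bp = 6)
  expect_equal(unname(segs[["gm"]]$segments),
               unname(segs[["gp"]]$segments))
  expect_equal(segs[["gm"]]$strand, "-")
})

test_that("promoter clipping at the contig edge is flagged", {
  d <- withr::local_tempdir()
  toy <- make_toy_gff(d)
  segs <- extract_segments(toy$gff, toy$fa, promoter_bp = 500)
  expect_true(segs[["gp"]]$clipped)
  expect_equal(unname(segs[["gp"]]$segments["promoter"]),
               substr(toy$chr1, 1, 6))
})

test_that("genes lacking a UTR annotation yield empty, flagged segments", {
  d <- withr::local_tempdir()
  chr <- strrep("ACGT", 10)
  writeLines(c(">c1", chr), file.path(d, "g.fa"))
  lines <- c("##gff-version 3",
             paste("c1", "t", "gene", 11, 30, ".", "+", ".", "ID=g1",
                   sep = "\t"),
             paste("c1", "t", "mRNA", 11, 30, ".", "+", ".",
                   "ID=g1.t;Parent=g1", sep = "\t"),
             paste("c1", "t", "exon", 11, 30, ".", "+", ".",
                   "ID=g1.e;Parent=g1.t", sep = "\t"),
             paste("c1", "t", "CDS", 11, 30, ".", "+", ".",
                   "ID=g1.c;Parent=g1.t", sep = "\t"))
  writeLines(lines, file.path(d, "g.gff3"))
  segs <- extract_segments(file.path(d, "g.gff3"), file.path(d, "g.fa"),
                           promoter_bp = 10)
  expect_setequal(segs[["g1"]]$missing, c("utr5", "utr3", "intron"))
  expect_equal(unname(segs[["g1"]]$segments["utr5"]), "")
})

test_that("write_segments_fasta round-trips with <gene>|<class> names", {
  d <- withr::local_tempdir()
  toy <- make_toy_gff(d)
  segs <- extract_segments(toy$gff, toy$fa, promoter_bp = 6)
  out <- file.path(d, "segs.fa")
  write_segments_fasta(segs, out)
  back <- Biostrings::readDNAStringSet(out)
  expect_true("gp|cds" %in% names(back))
  expect_equal(as.character(back[["gp|cds"]]),
               unname(segs[["gp"]]$segments["cds"]))
})
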