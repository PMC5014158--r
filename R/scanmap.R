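#' @importFrom Biostrings readDNAStringSet DNAStringSet subseq
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom S4Vectors mcols
#' @importFrom IRanges IRanges
NULL

SEGMENT_CLASSES <- c("promoter", "utr5", "utr3", "cds", "intron")
SEGMENT_SPACER <- strrep("N", 10)

iupac_complement <- function(code) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(code, "")[[1]], function(ch) {
    bases <- sort(comp[IUPAC_SETS[[ch]]])
    IUPAC_FROM_SET[[paste(bases, collapse = "")]]
  }, character(1), USE.NAMES = FALSE)
}

revcomp_iupac <- function(code) {
  paste(rev(iupac_complement(code)), collapse = "")
}

# transcript-order concatenation with the 10-N spacer
join_spacer <- function(parts) {
  parts <- parts[nchar(parts) > 0]
  if (length(parts) == 0L) return("")
  paste(parts, collapse = SEGMENT_SPACER)
}

#' Extract the five genomic segment classes for each gene
#'
#' Per gene: promoter (up to `promoter_bp` upstream of the transcription
#' start site, clipped at contig boundaries), 5'UTR, 3'UTR, CDS and
#' intron. Multi-part CDS and intron segments are concatenated in
#' transcript order with a spacer of exactly 10 `N`s between parts.
#' Minus-strand genes are reverse complemented so every segment reads
#' 5' to 3' of the gene. Genes missing a UTR annotation get an empty
#' segment (recorded in the `missing` field, not an error).
#'
#' @param gff path to a GFF3 file (1-based inclusive coordinates) with
#'   gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features, or an
#'   already-imported `GRanges`.
#' @param genome path to genome FASTA or a `DNAStringSet` (one record
#'   per chromosome).
#' @param genes optional character vector restricting extraction.
#' @param promoter_bp upstream window size, default 3000.
#' @return named list of `segment_set` objects; each is a list with
#'   `gene`, `strand`, `segments` (named character vector over the five
#'   classes), `clipped` (TRUE if the promoter hit a contig edge),
#'   `missing` (classes with no annotation).
#' @export
extract_segments <- function(gff, genome, genes = NULL, promoter_bp = 3000) {
  gr <- if (is.character(gff)) rtracklayer::import(gff) else gff
  dna <- if (is.character(genome)) Biostrings::readDNAStringSet(genome) else genome
  names(dna) <- sub("\\s.*", "", names(dna))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parents <- vapply(md$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))

  gene_idx <- which(type == "gene")
  gene_ids <- ids[gene_idx]
  if (!is.null(genes)) {
    keep <- gene_ids %in% genes
    gene_idx <- gene_idx[keep]
    gene_ids <- gene_ids[keep]
  }

  fetch <- function(chr, s, e) {
    if (e < s) return("")
    as.character(Biostrings::subseq(dna[[chr]], start = s, end = e))
  }

  out <- lapply(seq_along(gene_idx), function(gi) {
    g <- gene_idx[[gi]]
    gid <- gene_ids[[gi]]
    chr <- as.character(GenomicRanges::seqnames(gr))[g]
    strand_g <- as.character(GenomicRanges::strand(gr))[g]
    mrna <- which(type == "mRNA" & parents == gid)
    if (length(mrna) == 0L) stop("gene ", gid, " has no mRNA feature")
    m <- mrna[[1L]]
    mid <- ids[[m]]
    kids <- which(parents == mid)
    part <- function(what) {
      k <- kids[type[kids] == what]
      k[order(GenomicRanges::start(gr)[k])]
    }
    exons <- part("exon")
    cdss <- part("CDS")
    u5 <- part("five_prime_UTR")
    u3 <- part("three_prime_UTR")
    if (length(exons) == 0L) stop("gene ", gid, " has no exon features")

    chr_len <- length(dna[[chr]])
    mstart <- GenomicRanges::start(gr)[m]
    mend <- GenomicRanges::end(gr)[m]
    clipped <- FALSE
    if (strand_g == "-") {
      ps <- mend + 1L
      pe <- mend + promoter_bp
      if (pe > chr_len) { pe <- chr_len; clipped <- TRUE }
      promoter <- revcomp_chr(fetch(chr, ps, pe))
    } else {
      ps <- mstart - promoter_bp
      pe <- mstart - 1L
      if (ps < 1L) { ps <- 1L; clipped <- TRUE }
      promoter <- fetch(chr, ps, pe)
    }

    seqs_of <- function(idxs) {
      if (length(idxs) == 0L) return(character(0))
      parts <- vapply(idxs, function(k)
        fetch(chr, GenomicRanges::start(gr)[k], GenomicRanges::end(gr)[k]),
        character(1))
      if (strand_g == "-") rev(revcomp_chr(parts)) else parts
    }

    # introns: genomic gaps between consecutive exons
    intron_parts <- character(0)
    if (length(exons) >= 2L) {
      st <- GenomicRanges::start(gr)[exons]
      en <- GenomicRanges::end(gr)[exons]
      intron_parts <- vapply(seq_len(length(exons) - 1L), function(i)
        fetch(chr, en[i] + 1L, st[i + 1L] - 1L), character(1))
      if (strand_g == "-") intron_parts <- rev(revcomp_chr(intron_parts))
    }

    segs <- c(
      promoter = promoter,
      utr5 = join_spacer(seqs_of(u5)),
      utr3 = join_spacer(seqs_of(u3)),
      cds = join_spacer(seqs_of(cdss)),
      intron = join_spacer(intron_parts)
    )
    missing <- SEGMENT_CLASSES[!nzchar(segs[SEGMENT_CLASSES])]
    structure(list(gene = gid, strand = strand_g, segments = segs,
                   clipped = clipped, missing = missing),
              class = "segment_set")
  })
  names(out) <- gene_ids
  out
}

#' Write segment sequences to FASTA
#'
#' One record per gene x segment class, named `<gene>|<class>`.
#'
#' @param segsets list of `segment_set` from [extract_segments()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_segments_fasta <- function(segsets, path) {
  recs <- unlist(lapply(unname(segsets), function(ss) {
    s <- ss$segments[nzchar(ss$segments)]
    stats::setNames(s, paste(ss$gene, names(s), sep = "|"))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(recs), path)
  invisible(path)
}

#' Map a motif consensus onto a sequence under mismatch rules
#'
#' Slides the motif over the sequence (both strands by default); a
#' window is reported as an occurrence iff its Hamming distance to the
#' consensus is at most `max_mm` AND every window base is allowed by the
#' degenerate IUPAC consensus at that position (zero mismatch to the
#' degenerate consensus). Windows overlapping `N` spacer characters
#' never match.
#'
#' @param seq DNA string to scan.
#' @param consensus motif consensus string (A/C/G/T).
#' @param degenerate degenerate IUPAC consensus, same width.
#' @param max_mm maximum mismatches to the consensus (default 2).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return data.frame with columns `offset` (0-based position of the
#'   window on the given sequence), `strand` (`+`/`-`), `mismatches`.
#' @export
scan_consensus <- function(seq, consensus, degenerate = consensus,
                           max_mm = 2L, both_strands = TRUE) {
  consensus <- toupper(consensus)
  degenerate <- toupper(degenerate)
  if (nchar(consensus) != nchar(degenerate))
    stop("consensus and degenerate consensus must have equal width")
  w <- nchar(consensus)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      mismatches = integer(0))
  if (nchar(seq) < w) return(empty)
  x <- seq_to_int(seq)
  W <- window_matrix(x, w)

  scan_one <- function(cons, degen, strand) {
    cidx <- seq_to_int(cons)
    allowed <- matrix(FALSE, nrow = 5, ncol = w)  # rows: N,A,C,G,T
    dg <- strsplit(degen, "")[[1]]
    for (j in seq_len(w)) {
      allowed[match(IUPAC_SETS[[dg[j]]], DNA_BASES) + 1L, j] <- TRUE
    }
    ok <- matrix(allowed[cbind(as.vector(W) + 1L,
                               rep(seq_len(w), each = nrow(W)))],
                 nrow = nrow(W))
    pass_degen <- rowSums(ok) == w
    mm <- rowSums(W != matrix(cidx, nrow(W), w, byrow = TRUE))
    hit <- pass_degen & mm <= max_mm
    if (!any(hit)) return(empty)
    data.frame(offset = which(hit) - 1L, strand = strand,
               mismatches = as.integer(mm[hit]))
  }

  res <- scan_one(consensus, degenerate, "+")
  if (both_strands) {
    rc_cons <- revcomp_chr(consensus)
    rc_degen <- revcomp_iupac(degenerate)
    res <- rbind(res, scan_one(rc_cons, rc_degen, "-"))
  }
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
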