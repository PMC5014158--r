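#' @import methods
#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate codes keyed by the sorted base set they stand for
IUPAC_FROM_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B",
  "ACGT" = "N"
)

IUPAC_SETS <- local({
  sets <- lapply(names(IUPAC_FROM_SET), function(s) strsplit(s, "")[[1]])
  names(sets) <- unname(IUPAC_FROM_SET)
  sets
})

#' Construct a position weight matrix motif
#'
#' A PWM is a 4 x width base-frequency matrix (rows A, C, G, T; every
#' column sums to 1). The object carries the consensus (per-column argmax
#' base), the degenerate IUPAC consensus, per-column information content
#' in bits, and free-form provenance (engine, k-run, gene, segment).
#'
#' @param mat numeric matrix, 4 rows (A, C, G, T) by motif width; columns
#'   must each sum to 1 within 1e-9. Row names are set to the bases.
#' @param name motif identifier.
#' @param pseudocount pseudocount recorded as having been applied upstream
#'   (informational; no pseudocount is added here).
#' @param provenance named list of free-form origin details.
#' @param degenerate_threshold per-column frequency at or above which a
#'   base enters the degenerate IUPAC consensus (see
#'   [degenerate_consensus()]).
#' @return An object of class `pwm_motif`: a list with elements `mat`,
#'   `width`, `consensus`, `degenerate`, `ic` (bits per column), `name`,
#'   `pseudocount`, `provenance`.
#' @examples
#' m <- matrix(c(1, 0, 0, 0, 0, 0, 0, 1), nrow = 4)
#' new_pwm(m, name = "AT")$consensus
#' @export
new_pwm <- function(mat, name = "motif", pseudocount = 0,
                    provenance = list(), degenerate_threshold = 0.25) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 1L) stop("PWM width must be >= 1")
  if (any(mat < -1e-12)) stop("PWM frequencies must be nonnegative")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) stop("every PWM column must sum to 1")
  rownames(mat) <- DNA_BASES
  structure(
    list(
      mat = mat,
      width = ncol(mat),
      consensus = pwm_consensus(mat),
      degenerate = degenerate_consensus(mat,
                                        include_threshold = degenerate_threshold),
      ic = pwm_ic(mat),
      name = name,
      pseudocount = pseudocount,
      provenance = provenance
    ),
    class = "pwm_motif"
  )
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat(sprintf("<pwm_motif> %s  width=%d  consensus=%s  degenerate=%s  mean IC=%.2f bits\n",
              x$name, x$width, x$consensus, x$degenerate, mean(x$ic)))
  invisible(x)
}

is_pwm <- function(x) inherits(x, "pwm_motif")

# per-column argmax string; ties broken by base order A < C < G < T
pwm_consensus <- function(mat) {
  paste(DNA_BASES[apply(mat, 2, which.max)], collapse = "")
}

# information content per column in bits, relative to uniform background
pwm_ic <- function(mat) {
  apply(mat, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Degenerate IUPAC consensus of a PWM
#'
#' Per column, all bases with frequency at or above `include_threshold`
#' enter the code set and are written as the matching IUPAC symbol. If no
#' base reaches the threshold the column falls back to its argmax base.
#'
#' @param pwm a `pwm_motif` or bare 4 x width frequency matrix.
#' @param include_threshold inclusion frequency, default 0.25 (so a
#'   uniform column becomes `N`).
#' @return IUPAC string of the motif width.
#' @examples
#' degenerate_consensus(matrix(c(0.5, 0.5, 0, 0), nrow = 4))  # "M"
#' @export
degenerate_consensus <- function(pwm, include_threshold = 0.25) {
  mat <- if (is_pwm(pwm)) pwm$mat else as.matrix(pwm)
  codes <- apply(mat, 2, function(p) {
    keep <- DNA_BASES[p >= include_threshold]
    if (length(keep) == 0L) keep <- DNA_BASES[which.max(p)]
    IUPAC_FROM_SET[[paste(keep, collapse = "")]]
  })
  paste(codes, collapse = "")
}

#' Reverse complement of a PWM
#'
#' @param pwm a `pwm_motif`.
#' @return a `pwm_motif` for the opposite strand (columns reversed, A/T
#'   and C/G rows swapped).
#' @export
revcomp_pwm <- function(pwm) {
  stopifnot(is_pwm(pwm))
  mat <- pwm$mat[c(4, 3, 2, 1), rev(seq_len(pwm$width)), drop = FALSE]
  new_pwm(mat, name = paste0(pwm$name, "_rc"),
          pseudocount = pwm$pseudocount, provenance = pwm$provenance)
}

#' Lift a word to a one-hot PWM with pseudocount
#'
#' Used when comparing enumerated words with PWMs from other engines.
#'
#' @param word DNA string over A/C/G/T.
#' @param pseudocount mass spread over the three non-word bases per column
#'   (default 0.01 total per base).
#' @param name motif name; defaults to the word.
#' @return a `pwm_motif`.
#' @export
word_to_pwm <- function(word, pseudocount = 0.01, name = word) {
  chars <- strsplit(toupper(word), "")[[1]]
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) stop("word must contain only A/C/G/T")
  w <- length(idx)
  mat <- matrix(pseudocount, nrow = 4, ncol = w)
  mat[cbind(idx, seq_len(w))] <- 1
  mat <- sweep(mat, 2, colSums(mat), "/")
  new_pwm(mat, name = name, pseudocount = pseudocount,
          provenance = list(engine = "word", word = word))
}

#' Read motifs from MEME minimal format
#'
#' Parses the MEME minimal motif text format (the `MEME version`,
#' `ALPHABET`, `Background letter frequencies` and
#' `MOTIF ... letter-probability matrix` blocks).
#'
#' @param path file path.
#' @return list of `pwm_motif`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, "MOTIF")) {
      toks <- strsplit(ln, "[[:space:]]+")[[1]]
      name <- if (length(toks) >= 2) toks[[2]] else sprintf("motif_%d", length(out) + 1L)
      # find the letter-probability header
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", trimws(lines[[j]]))) j <- j + 1L
      if (j > length(lines)) stop("malformed MEME file: missing letter-probability matrix for ", name)
      hdr <- trimws(lines[[j]])
      wm <- regmatches(hdr, regexpr("w=[[:space:]]*[0-9]+", hdr))
      width <- if (length(wm)) as.integer(sub("w=[[:space:]]*", "", wm)) else NA_integer_
      rows <- list()
      j <- j + 1L
      while (j <= length(lines)) {
        rl <- trimws(lines[[j]])
        if (rl == "" || grepl("^(MOTIF|URL)", rl)) break
        vals <- suppressWarnings(as.numeric(strsplit(rl, "[[:space:]]+")[[1]]))
        if (anyNA(vals) || length(vals) != 4L) break
        rows[[length(rows) + 1L]] <- vals
        j <- j + 1L
      }
      if (!is.na(width) && length(rows) != width)
        warning("MEME motif ", name, ": stated width ", width,
                " but ", length(rows), " matrix rows")
      mat <- t(do.call(rbind, rows))
      mat <- sweep(mat, 2, colSums(mat), "/")  # guard rounding in the file
      out[[name]] <- new_pwm(mat, name = name)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms list of `pwm_motif`.
#' @param path output file path.
#' @param bg background base frequencies written to the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, bg = c(A = 0.28, C = 0.22, G = 0.22, T = 0.28)) {
  if (is_pwm(pwms)) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg[["A"]], bg[["C"]], bg[["G"]], bg[["T"]]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$width), con)
    for (j in seq_len(p$width)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         p$mat[1, j], p$mat[2, j], p$mat[3, j], p$mat[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
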