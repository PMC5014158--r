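# Internal sequence utilities: integer encoding (A=1, C=2, G=3, T=4,
# anything else 0), windows, reverse complements, and first-order Markov
# background models shared by the generator and the discovery engines.

seq_to_int <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], DNA_BASES)
  x[is.na(x)] <- 0L
  as.integer(x)
}

int_to_seq <- function(x) {
  chars <- c("N", DNA_BASES)[x + 1L]
  paste(chars, collapse = "")
}

revcomp_chr <- function(s) {
  vapply(s, function(one) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", one), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

revcomp_int <- function(x) {
  y <- rev(x)
  out <- integer(length(y))
  nz <- y != 0L
  out[nz] <- 5L - y[nz]
  out
}

# all windows of width w as an (n - w + 1) x w integer matrix
window_matrix <- function(intseq, w) {
  n <- length(intseq)
  if (n < w) return(matrix(integer(0), nrow = 0, ncol = w))
  nwin <- n - w + 1L
  idx <- outer(seq_len(nwin), 0:(w - 1L), "+")
  matrix(intseq[idx], nrow = nwin, ncol = w)
}

#' First-order Markov background model
#'
#' Estimates initial and transition base frequencies from a set of
#' sequences (positions containing non-ACGT characters are skipped).
#' Used as the "genome background" that discovery engines test
#' enrichment against.
#'
#' @param seqs character vector of DNA sequences.
#' @param pseudocount added to every transition/initial count.
#' @param class optional segment-class label carried along.
#' @return object of class `bg_markov`: list with `init` (length-4
#'   probability vector), `trans` (4 x 4 row-stochastic matrix), `class`.
#' @export
fit_background <- function(seqs, pseudocount = 1, class = NA_character_) {
  init <- rep(pseudocount, 4)
  trans <- matrix(pseudocount, 4, 4)
  for (s in seqs) {
    x <- seq_to_int(s)
    x <- x[x != 0L]        # drop N runs; transitions across them are skipped
    if (length(x) == 0L) next
    init <- init + tabulate(x, 4L)
    if (length(x) >= 2L) {
      from <- x[-length(x)]
      to <- x[-1L]
      trans <- trans + table(factor(from, 1:4), factor(to, 1:4))
    }
  }
  trans <- sweep(trans, 1, rowSums(trans), "/")
  structure(list(init = init / sum(init), trans = unname(trans), class = class),
            class = "bg_markov")
}

# sample one sequence of length n from a bg_markov model
markov_seq <- function(n, bg) {
  if (n <= 0L) return("")
  cum_init <- cumsum(bg$init)[1:3]
  cum_trans <- t(apply(bg$trans, 1, cumsum))[, 1:3, drop = FALSE]
  u <- stats::runif(n)
  x <- integer(n)
  x[1L] <- findInterval(u[1L], cum_init) + 1L
  if (n > 1L) {
    for (i in 2:n) x[i] <- findInterval(u[i], cum_trans[x[i - 1L], ]) + 1L
  }
  paste(DNA_BASES[x], collapse = "")
}

# default background with configurable GC content, mild CpG-like structure
default_background <- function(gc = 0.44) {
  at <- (1 - gc) / 2
  g <- gc / 2
  init <- c(A = at, C = g, G = g, T = at)
  trans <- matrix(rep(init, each = 4), 4, 4)
  # mild first-order structure: favour same-class neighbours slightly
  for (i in 1:4) trans[i, i] <- trans[i, i] + 0.05
  trans <- sweep(trans, 1, rowSums(trans), "/")
  structure(list(init = unname(init), trans = unname(trans),
                 class = NA_character_), class = "bg_markov")
}

# probability of a specific word (integer-encoded) under a bg_markov model
word_prob <- function(widx, bg) {
  p <- bg$init[widx[1L]]
  if (length(widx) > 1L) {
    for (i in 2:length(widx)) p <- p * bg$trans[widx[i - 1L], widx[i]]
  }
  p
}

# Deterministic per-stage seed derived from a root seed and a stream name,
# kept in [0, 2^31). All pipeline randomness flows through this.
substream_seed <- function(root, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1986917
  as.integer((as.numeric(root) * 2654435 + h * 97 + 13) %% 2147483647)
}
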