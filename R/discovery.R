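#' @importFrom stats pbinom plogis runif wilcox.test p.adjust median
#' @importFrom Matrix sparseMatrix rowSums
NULL

# package-level cache for mismatch-neighborhood matrices and
# reverse-complement permutations, keyed by width/mismatch
.c4_cache <- new.env(parent = emptyenv())

# integer codes (1-based) of all valid windows of width w; windows
# containing non-ACGT characters are dropped
window_codes <- function(intseq, w) {
  W <- window_matrix(intseq, w)
  if (nrow(W) == 0L) return(integer(0))
  ok <- rowSums(W == 0L) == 0L
  W <- W[ok, , drop = FALSE]
  if (nrow(W) == 0L) return(integer(0))
  drop((W - 1L) %*% 4L^(seq_len(w) - 1L)) + 1L
}

# digit matrix (4^w x w) of base indices 1..4 for every word code
word_digits <- function(w) {
  key <- paste0("digits", w)
  if (!is.null(.c4_cache[[key]])) return(.c4_cache[[key]])
  n <- 4L^w
  D <- matrix(0L, n, w)
  x <- 0:(n - 1L)
  for (j in seq_len(w)) {
    D[, j] <- (x %% 4L) + 1L
    x <- x %/% 4L
  }
  .c4_cache[[key]] <- D
  D
}

code_to_word <- function(code, w) {
  D <- word_digits(w)
  apply(D[code, , drop = FALSE], 1, function(d)
    paste(DNA_BASES[d], collapse = ""))
}

word_to_code <- function(word) {
  d <- seq_to_int(word)
  if (any(d == 0L)) stop("word must be A/C/G/T only")
  drop((d - 1L) %*% 4L^(seq_along(d) - 1L)) + 1L
}

# permutation mapping each word code to its reverse complement's code
rc_permutation <- function(w) {
  key <- paste0("rcperm", w)
  if (!is.null(.c4_cache[[key]])) return(.c4_cache[[key]])
  D <- word_digits(w)
  RC <- 5L - D[, rev(seq_len(w)), drop = FALSE]
  perm <- drop((RC - 1L) %*% 4L^(seq_len(w) - 1L)) + 1L
  .c4_cache[[key]] <- perm
  perm
}

# sparse 4^w x 4^w matrix linking each word to all words within
# `mm` mismatches (including itself)
neighborhood_matrix <- function(w, mm) {
  key <- paste0("nbhd", w, "_", mm)
  if (!is.null(.c4_cache[[key]])) return(.c4_cache[[key]])
  n <- 4L^w
  codes <- seq_len(n)
  ii <- list(codes)
  jj <- list(codes)
  if (mm >= 1L) {
    D <- word_digits(w)
    for (pos in seq_len(w)) {
      for (delta in 1:3) {
        newdig <- ((D[, pos] - 1L + delta) %% 4L) + 1L
        jn <- codes + (newdig - D[, pos]) * 4L^(pos - 1L)
        ii[[length(ii) + 1L]] <- codes
        jj[[length(jj) + 1L]] <- jn
      }
    }
  }
  if (mm >= 2L) {
    D <- word_digits(w)
    pos_pairs <- utils::combn(w, 2)
    for (pp in seq_len(ncol(pos_pairs))) {
      p1 <- pos_pairs[1, pp]; p2 <- pos_pairs[2, pp]
      for (d1 in 1:3) for (d2 in 1:3) {
        n1 <- ((D[, p1] - 1L + d1) %% 4L) + 1L
        n2 <- ((D[, p2] - 1L + d2) %% 4L) + 1L
        jn <- codes + (n1 - D[, p1]) * 4L^(p1 - 1L) +
          (n2 - D[, p2]) * 4L^(p2 - 1L)
        ii[[length(ii) + 1L]] <- codes
        jj[[length(jj) + 1L]] <- jn
      }
    }
  }
  if (mm > 2L) stop("max_word_mm > 2 is not supported")
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(n, n))
  .c4_cache[[key]] <- M
  M
}

# exact word occurrence counts over a set of sequences, both strands;
# returns list(counts = length-4^w vector, windows = windows scanned)
count_words <- function(seqs, w, both_strands = TRUE) {
  counts <- numeric(4L^w)
  nwin <- 0
  for (s in seqs) {
    cd <- window_codes(seq_to_int(s), w)
    if (length(cd)) counts <- counts + tabulate(cd, 4L^w)
    nwin <- nwin + length(cd)
  }
  if (both_strands) {
    counts <- counts + counts[rc_permutation(w)]
    nwin <- 2 * nwin
  }
  list(counts = counts, windows = nwin)
}

#' One-sided binomial enrichment test
#'
#' Upper-tail probability that at least `fg_hits` successes occur in
#' `fg_trials` Bernoulli trials at the background rate:
#' p = P(X >= fg_hits), X ~ Binomial(fg_trials, bg_rate).
#'
#' @param fg_hits observed foreground hit count(s).
#' @param fg_trials number of foreground trials (windows scanned).
#' @param bg_rate background per-trial hit probability, in (0, 1).
#' @return p-value(s) in [0, 1]; vectorized over `fg_hits`.
#' @examples
#' enrichment_test(5, 10, 0.5)  # 0.623046875
#' @export
enrichment_test <- function(fg_hits, fg_trials, bg_rate) {
  if (any(bg_rate <= 0) || any(bg_rate >= 1))
    stop("bg_rate must be strictly inside (0, 1)")
  if (any(fg_hits > fg_trials)) stop("fg_hits cannot exceed fg_trials")
  stats::pbinom(fg_hits - 1, fg_trials, bg_rate, lower.tail = FALSE)
}

# analytic stationary probability of every w-word under a first-order
# Markov background (both-strand average)
markov_word_probs <- function(bg, w) {
  D <- word_digits(w)
  p <- bg$init[D[, 1]]
  for (j in 2:w) p <- p * bg$trans[cbind(D[, j - 1], D[, j])]
  (p + p[rc_permutation(w)]) / 2
}

#' Exhaustive word enumeration with mismatch counting
#'
#' For every word of the given widths, counts occurrences within
#' `max_word_mm` mismatches across the foreground sequences (both
#' strands) and tests enrichment against the background occurrence rate
#' with a one-sided binomial test. The background rate per word is
#' estimated empirically when background sequences are supplied, or
#' analytically from a first-order Markov model.
#'
#' Because the whole word space is tested, reported words are filtered
#' on a Bonferroni-adjusted p-value by default; raw per-word p-values
#' are returned alongside and are calibrated against the background
#' (use `correct = "none"` for an uncorrected 0.05 filter).
#'
#' @param fg character vector of foreground sequences (nonempty).
#' @param bg background: either a character vector of background
#'   sequences or a `bg_markov` model from [fit_background()].
#' @param widths word widths to enumerate (default c(6, 8)).
#' @param max_word_mm mismatch tolerance for counting (default 1; 0-2).
#' @param alpha significance level on the (corrected) p-value.
#' @param correct multiplicity handling over the enumerated word space:
#'   "bonferroni" (default), "BH", or "none".
#' @param top_n cap on reported words per width (by p-value; default 10,
#'   mirroring the report length of word-enumeration discovery tools).
#' @return data.frame with columns `word`, `width`, `fg_hits`,
#'   `fg_trials`, `bg_rate`, `p`, `p_adj`, ranked by `p`. The attribute
#'   `"all_p"` holds the raw p-values of every enumerated word (named
#'   list by width) for calibration checks.
#' @export
word_enumerate <- function(fg, bg, widths = c(6L, 8L), max_word_mm = 1L,
                           alpha = 0.05,
                           correct = c("bonferroni", "BH", "none"),
                           top_n = 10L) {
  correct <- match.arg(correct)
  if (length(fg) == 0L) stop("foreground must be nonempty")
  out <- list()
  all_p <- list()
  for (w in widths) {
    n_words <- 4L^w
    fgc <- count_words(fg, w)
    if (fgc$windows == 0L) next
    N <- if (max_word_mm == 0L) NULL else neighborhood_matrix(w, max_word_mm)
    fg_hits <- if (is.null(N)) fgc$counts else
      as.numeric(N %*% fgc$counts)
    if (inherits(bg, "bg_markov")) {
      pw <- markov_word_probs(bg, w)
      rate <- if (is.null(N)) pw else as.numeric(N %*% pw)
      rate <- pmin(pmax(rate, 1e-12), 1 - 1e-12)
    } else {
      bgc <- count_words(bg, w)
      bg_hits <- if (is.null(N)) bgc$counts else
        as.numeric(N %*% bgc$counts)
      rate <- (bg_hits + 0.5) / (bgc$windows + 1)
      rate <- pmin(rate, 1 - 1e-12)
    }
    p <- enrichment_test(fg_hits, fgc$windows, rate)
    all_p[[as.character(w)]] <- p
    p_adj <- switch(correct,
                    bonferroni = pmin(p * n_words, 1),
                    BH = stats::p.adjust(p, "BH"),
                    none = p)
    keep <- which(fg_hits >= 1 & p_adj <= alpha)
    if (length(keep)) {
      keep <- keep[order(p[keep], keep)]
      if (is.finite(top_n) && length(keep) > top_n) keep <- keep[seq_len(top_n)]
      out[[as.character(w)]] <- data.frame(
        word = code_to_word(keep, w),
        width = w,
        fg_hits = fg_hits[keep],
        fg_trials = fgc$windows,
        bg_rate = rate[keep],
        p = p[keep],
        p_adj = p_adj[keep],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(word = character(0), width = integer(0), fg_hits = numeric(0),
               fg_trials = numeric(0), bg_rate = numeric(0), p = numeric(0),
               p_adj = numeric(0))
  res <- res[order(res$p, res$word), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "all_p") <- all_p
  res
}

#' ZOOPS expectation-maximization motif discovery
#'
#' Fits a PWM under the "zero or one occurrence per sequence" model:
#' each sequence carries a motif site at an unknown offset/strand with
#' probability gamma, or is pure background. The E-step computes the
#' posterior over {no site, site at each offset x strand} per sequence
#' under the current PWM against a 0th-order background; the M-step
#' updates the PWM from expected site counts (with a pseudocount) and
#' gamma. EM runs to convergence (log-likelihood change < `tol`) or
#' `max_iter` iterations; the best of `n_seeds` random restarts by final
#' log-likelihood is returned.
#'
#' @param seqs character vector of sequences (those shorter than
#'   `width` are dropped).
#' @param width motif width.
#' @param seed integer seed.
#' @param n_seeds random restarts (default 5).
#' @param max_iter,tol convergence controls.
#' @param pseudocount per-cell pseudocount in the M-step (default 0.01).
#' @param both_strands consider sites on either strand (default TRUE).
#' @return a `pwm_motif`; `$provenance` carries `engine = "em"`, the
#'   final `loglik`, `gamma`, and the per-iteration `loglik_trace` of
#'   the winning restart (non-decreasing).
#' @export
em_discover <- function(seqs, width, seed = 1L, n_seeds = 5L,
                        max_iter = 200L, tol = 1e-6, pseudocount = 0.01,
                        both_strands = TRUE) {
  seqs <- seqs[nchar(seqs) >= width]
  if (length(seqs) == 0L) stop("all sequences shorter than the motif width")
  ints <- lapply(seqs, seq_to_int)
  # window matrices per sequence and strand; windows with N dropped
  winlist <- lapply(ints, function(x) {
    Wf <- window_matrix(x, width)
    Wf <- Wf[rowSums(Wf == 0L) == 0L, , drop = FALSE]
    if (both_strands) {
      Wr <- window_matrix(revcomp_int(x), width)
      Wr <- Wr[rowSums(Wr == 0L) == 0L, , drop = FALSE]
      rbind(Wf, Wr)
    } else Wf
  })
  winlist <- winlist[vapply(winlist, nrow, integer(1)) > 0L]
  if (length(winlist) == 0L) stop("no valid windows at this width")

  # 0th-order background from all sequences
  base_tab <- rep(1, 4)
  for (x in ints) base_tab <- base_tab + tabulate(x[x != 0L], 4L)
  theta0 <- base_tab / sum(base_tab)

  n <- length(winlist)
  score_windows <- function(W, logratio) {
    nr <- nrow(W)
    rowSums(matrix(logratio[cbind(as.vector(W),
                                  rep(seq_len(width), each = nr))],
                   nrow = nr))
  }

  run_once <- function() {
    ws <- winlist[[sample.int(n, 1L)]]
    seed_win <- ws[sample.int(nrow(ws), 1L), ]
    pwm <- matrix(0.1, 4, width)
    pwm[cbind(seed_win, seq_len(width))] <- 0.7
    gamma <- 0.5
    trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      logratio <- log(pwm) - log(theta0)
      ll <- 0
      counts <- matrix(pseudocount, 4, width)
      gamma_acc <- 0
      for (i in seq_len(n)) {
        W <- winlist[[i]]
        m_i <- nrow(W)
        lr <- score_windows(W, logratio)
        lw <- c(log1p(-gamma), log(gamma / m_i) + lr)
        mx <- max(lw)
        pz <- exp(lw - mx)
        tot <- sum(pz)
        ll <- ll + mx + log(tot)
        z <- pz[-1L] / tot
        gamma_acc <- gamma_acc + sum(z)
        for (j in seq_len(width)) {
          counts[, j] <- counts[, j] +
            vapply(1:4, function(b) sum(z[W[, j] == b]), numeric(1))
        }
      }
      trace <- c(trace, ll)
      pwm <- sweep(counts, 2, colSums(counts), "/")
      gamma <- min(max(gamma_acc / n, 1e-6), 1 - 1e-6)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(pwm = pwm, loglik = trace[length(trace)], gamma = gamma,
         trace = trace)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_seeds)) {
    fit <- run_once()
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  new_pwm(best$pwm, name = sprintf("em_w%d", width),
          pseudocount = pseudocount,
          provenance = list(engine = "em", seed = seed,
                            loglik = best$loglik, gamma = best$gamma,
                            loglik_trace = best$trace))
}

#' Biophysical binding affinity of a sequence for a PWM
#'
#' Per window l, the mismatch energy is
#' E(l) = (1/lambda) * sum_i ln(p_max,i / p_i(base)) with pseudocounted
#' PWM frequencies, and the window's occupancy contribution is
#' 1 / (1 + exp(E(l) - ln_R0)). The affinity is the sum over all
#' windows on both strands. Windows overlapping non-ACGT characters
#' contribute 0.
#'
#' @param seq DNA string.
#' @param pwm a `pwm_motif`.
#' @param lam energy scaling lambda (default 0.7).
#' @param ln_r0 chemical-potential offset; default 0.584 * width - 5.66.
#' @param pseudocount added to PWM frequencies before the log-ratio.
#' @param both_strands sum both strands (default TRUE).
#' @return nonnegative affinity value (0 for sequences shorter than the
#'   motif).
#' @export
trap_affinity <- function(seq, pwm, lam = 0.7, ln_r0 = NULL,
                          pseudocount = 0.01, both_strands = TRUE) {
  stopifnot(is_pwm(pwm))
  w <- pwm$width
  if (is.null(ln_r0)) ln_r0 <- 0.584 * w - 5.66
  if (nchar(seq) < w) return(0)
  mat <- sweep(pwm$mat + pseudocount, 2,
               colSums(pwm$mat + pseudocount), "/")
  pen <- rbind(Inf, log(matrix(apply(mat, 2, max), 4, w, byrow = TRUE) / mat) / lam)
  # pen rows: N, A, C, G, T
  x <- seq_to_int(seq)
  aff_one <- function(xi) {
    W <- window_matrix(xi, w)
    if (nrow(W) == 0L) return(0)
    E <- rowSums(matrix(pen[cbind(as.vector(W) + 1L,
                                  rep(seq_len(w), each = nrow(W)))],
                        nrow = nrow(W)))
    sum(stats::plogis(ln_r0 - E))
  }
  a <- aff_one(x)
  if (both_strands) a <- a + aff_one(revcomp_int(x))
  a
}

#' PWM-library enrichment by affinity rank-sum
#'
#' For each library PWM, per-sequence affinities ([trap_affinity()]) in
#' the foreground are compared with the background by a one-sided
#' Wilcoxon rank-sum test; PWMs with p <= alpha are reported.
#'
#' @param fg,bg character vectors of foreground and background
#'   sequences (nonempty).
#' @param library list of `pwm_motif`.
#' @param alpha reporting threshold on the (corrected) p-value.
#' @param correct multiplicity handling over the library:
#'   "none" (default) or "bonferroni".
#' @param lam,ln_r0 passed to [trap_affinity()].
#' @return data.frame with columns `motif`, `p`, `p_adj`, `median_fg`,
#'   `median_bg`; the attribute `"pwms"` holds the reported `pwm_motif`
#'   objects.
#' @export
library_enrichment <- function(fg, bg, library, alpha = 0.05,
                               correct = c("none", "bonferroni"),
                               lam = 0.7, ln_r0 = NULL) {
  correct <- match.arg(correct)
  if (length(fg) == 0L || length(bg) == 0L) stop("fg and bg must be nonempty")
  empty <- data.frame(motif = character(0), p = numeric(0),
                      p_adj = numeric(0), median_fg = numeric(0),
                      median_bg = numeric(0))
  if (length(library) == 0L) return(structure(empty, pwms = list()))
  mult <- if (correct == "bonferroni") length(library) else 1L
  rows <- list()
  pwms <- list()
  for (pwm in library) {
    fa <- vapply(fg, trap_affinity, numeric(1), pwm = pwm, lam = lam,
                 ln_r0 = ln_r0, USE.NAMES = FALSE)
    ba <- vapply(bg, trap_affinity, numeric(1), pwm = pwm, lam = lam,
                 ln_r0 = ln_r0, USE.NAMES = FALSE)
    p <- suppressWarnings(
      stats::wilcox.test(fa, ba, alternative = "greater")$p.value)
    p_adj <- min(p * mult, 1)
    if (is.finite(p) && p_adj <= alpha) {
      rows[[length(rows) + 1L]] <- data.frame(
        motif = pwm$name, p = p, p_adj = p_adj,
        median_fg = stats::median(fa), median_bg = stats::median(ba),
        stringsAsFactors = FALSE)
      pwms[[pwm$name]] <- pwm
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, pwms = pwms)
}

#' Occurrence enrichment of a motif consensus in a sequence set
#'
#' Counts occurrences of the motif (consensus + degenerate consensus
#' mismatch rules, see [scan_consensus()]) in the foreground and tests
#' them against a background per-window occurrence rate with
#' [enrichment_test()].
#'
#' @param seqs foreground sequences.
#' @param consensus,degenerate motif strings.
#' @param bg_seqs background sequences used to estimate the per-window
#'   rate (ignored if `bg_rate` is given).
#' @param bg_rate optional precomputed background per-window rate.
#' @param max_mm mismatch allowance (default 2).
#' @return list with `p`, `fg_hits`, `fg_trials`, `bg_rate`.
#' @export
motif_enrichment_p <- function(seqs, consensus, degenerate = consensus,
                               bg_seqs = NULL, bg_rate = NULL, max_mm = 2L) {
  w <- nchar(consensus)
  count_in <- function(ss) {
    hits <- 0; trials <- 0
    for (s in ss) {
      if (nchar(s) < w) next
      occ <- scan_consensus(s, consensus, degenerate, max_mm = max_mm)
      hits <- hits + nrow(occ)
      trials <- trials + 2L * (nchar(s) - w + 1L)
    }
    c(hits, trials)
  }
  fgc <- count_in(seqs)
  if (is.null(bg_rate)) {
    if (is.null(bg_seqs)) stop("need bg_seqs or bg_rate")
    bgc <- count_in(bg_seqs)
    bg_rate <- (bgc[1] + 0.5) / (bgc[2] + 1)
  }
  bg_rate <- min(max(bg_rate, 1e-12), 1 - 1e-12)
  p <- if (fgc[2] == 0) 1 else enrichment_test(fgc[1], fgc[2], bg_rate)
  list(p = p, fg_hits = fgc[1], fg_trials = fgc[2], bg_rate = bg_rate)
}

#' Analytic per-window occurrence rate of a consensus scan
#'
#' Probability that a single strand-window matches the motif under the
#' [scan_consensus()] rule (conforms to the degenerate consensus AND is
#' within `max_mm` mismatches of the consensus), computed exactly under
#' a first-order Markov background by enumerating the conforming words.
#' Forward and reverse-complement window rates are averaged, matching
#' the both-strand trial counting of [motif_enrichment_p()].
#'
#' @param consensus,degenerate motif strings (equal width).
#' @param bg a `bg_markov` background model.
#' @param max_mm mismatch allowance (default 2).
#' @return per-strand-window match probability.
#' @export
analytic_scan_rate <- function(consensus, degenerate = consensus, bg,
                               max_mm = 2L) {
  consensus <- toupper(consensus)
  degenerate <- toupper(degenerate)
  w <- nchar(consensus)
  if (nchar(degenerate) != w)
    stop("consensus and degenerate consensus must have equal width")
  sets <- lapply(strsplit(degenerate, "")[[1]], function(ch) {
    b <- IUPAC_SETS[[ch]]
    if (is.null(b)) stop("unknown IUPAC code: ", ch)
    match(b, DNA_BASES)
  })
  grid <- as.matrix(expand.grid(sets, KEEP.OUT.ATTRS = FALSE))
  cidx <- seq_to_int(consensus)
  mm <- rowSums(grid != matrix(cidx, nrow(grid), w, byrow = TRUE))
  grid <- grid[mm <= max_mm, , drop = FALSE]
  if (nrow(grid) == 0L) return(0)
  pf <- sum(apply(grid, 1, word_prob, bg = bg))
  pr <- sum(apply(grid, 1, function(x) word_prob(revcomp_int(x), bg = bg)))
  (pf + pr) / 2
}
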