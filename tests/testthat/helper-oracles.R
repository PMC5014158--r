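# Independent oracle implementations used to validate the package's
# optimized routines. These deliberately use naive, transparent logic
# (character loops, explicit contingency tables, exhaustive searches).

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force consensus scanner: explicit per-window character checks
oracle_scan <- function(seq, consensus, degenerate = consensus,
                        max_mm = 2, both_strands = TRUE) {
  w <- nchar(consensus)
  res <- data.frame(offset = integer(0), strand = character(0),
                    mismatches = integer(0))
  pats <- list(list(consensus, degenerate, "+"))
  if (both_strands) {
    rc_deg <- paste(rev(vapply(strsplit(degenerate, "")[[1]], function(ch) {
      bases <- sort(unname(vapply(IUPAC_ORACLE[[ch]], function(b)
        c(A = "T", C = "G", G = "C", T = "A")[[b]], character(1))))
      for (code in names(IUPAC_ORACLE))
        if (identical(sort(IUPAC_ORACLE[[code]]), bases)) return(code)
      stop("no code")
    }, character(1))), collapse = "")
    pats[[2]] <- list(oracle_revcomp(consensus), rc_deg, "-")
  }
  if (nchar(seq) < w) return(res)
  for (p in pats) {
    cons <- strsplit(p[[1]], "")[[1]]
    deg <- strsplit(p[[2]], "")[[1]]
    for (off in 0:(nchar(seq) - w)) {
      win <- strsplit(substr(seq, off + 1, off + w), "")[[1]]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      conforms <- all(vapply(seq_len(w), function(j)
        win[j] %in% IUPAC_ORACLE[[deg[j]]], logical(1)))
      mm <- sum(win != cons)
      if (conforms && mm <= max_mm)
        res <- rbind(res, data.frame(offset = off, strand = p[[3]],
                                     mismatches = mm))
    }
  }
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# direct per-window TRAP affinity summation
oracle_trap <- function(seq, pwm, lam = 0.7, ln_r0 = NULL,
                        pseudocount = 0.01) {
  w <- pwm$width
  if (is.null(ln_r0)) ln_r0 <- 0.584 * w - 5.66
  mat <- pwm$mat + pseudocount
  mat <- sweep(mat, 2, colSums(mat), "/")
  bases <- c("A", "C", "G", "T")
  one_strand <- function(s) {
    if (nchar(s) < w) return(0)
    total <- 0
    for (off in 0:(nchar(s) - w)) {
      win <- strsplit(substr(s, off + 1, off + w), "")[[1]]
      if (any(!win %in% bases)) next
      E <- 0
      for (j in seq_len(w)) {
        pj <- mat[match(win[j], bases), j]
        E <- E + log(max(mat[, j]) / pj) / lam
      }
      total <- total + 1 / (1 + exp(E - ln_r0))
    }
    total
  }
  unname(one_strand(seq) + one_strand(oracle_revcomp(seq)))
}

# exhaustive PWM alignment over all offsets and both orientations,
# scoring each column pair with stats::cor and summing
oracle_align <- function(a, b, min_overlap = 4) {
  col_cor <- function(x, y) {
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(0)
    stats::cor(x, y)
  }
  best <- list(score = -Inf)
  for (orient in c("forward", "revcomp")) {
    bm <- if (orient == "forward") b$mat else b$mat[4:1, ncol(b$mat):1]
    wa <- ncol(a$mat); wb <- ncol(bm)
    for (d in (-(wb - min_overlap)):(wa - min_overlap)) {
      cols_a <- intersect(seq_len(wa), seq_len(wb) + d)
      if (length(cols_a) < min_overlap) next
      sc <- sum(vapply(cols_a, function(i)
        col_cor(a$mat[, i], bm[, i - d]), numeric(1)))
      if (sc > best$score + 1e-12)
        best <- list(score = sc, offset = d, orientation = orient,
                     overlap = length(cols_a))
    }
  }
  best
}

# direct contingency-table normalized MI (natural log), using the same
# documented binning rule implemented independently
oracle_mi_norm <- function(x, y, bins = 3) {
  assign_bins <- function(v) {
    n <- length(v)
    base <- n %/% bins
    extra <- n %% bins
    sizes <- rep(base, bins) + c(rep(1, extra), rep(0, bins - extra))
    out <- integer(n)
    ord <- order(v)  # stable: ties keep original order
    pos <- 1
    for (b in seq_len(bins)) {
      out[ord[pos:(pos + sizes[b] - 1)]] <- b
      pos <- pos + sizes[b]
    }
    out
  }
  bx <- assign_bins(x); by <- assign_bins(y)
  n <- length(x)
  tab <- matrix(0, bins, bins)
  for (i in seq_len(n)) tab[bx[i], by[i]] <- tab[bx[i], by[i]] + 1
  H <- function(p) { p <- p[p > 0] / sum(p); -sum(p / 1 * log(p)) }
  hx <- H(rowSums(tab)); hy <- H(colSums(tab))
  mi <- 0
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    pij <- tab[i, j] / n
    if (pij > 0) mi <- mi + pij * log(pij / (sum(tab[i, ]) / n *
                                               sum(tab[, j]) / n))
  }
  mi / min(hx, hy)
}

# exhaustive permutation-null mean MI over all permutations of y
oracle_perm_mi_exhaustive <- function(x, y, bins = 3) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      for (r in rest) out[[length(out) + 1]] <- c(v[i], r)
    }
    out
  }
  ps <- perms(y)
  mean(vapply(ps, function(py) oracle_mi_norm(x, py, bins), numeric(1)))
}

# Rand-style exact partition agreement: TRUE if two labelings induce the
# same partition
same_partition <- function(a, b) {
  ta <- split(seq_along(a), a)
  tb <- split(seq_along(b), b)
  setequal(lapply(ta, sort), lapply(tb, sort))
}
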