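# PWM-PWM alignment and consensus across methods, k-runs and species.

# centered columns scaled to unit norm; zero-variance columns (e.g. a
# uniform 0.25 column) become zero vectors, so their Pearson score with
# anything is 0 by convention
centered_cols <- function(mat) {
  z <- sweep(mat, 2, colMeans(mat))
  nrm <- sqrt(colSums(z^2))
  nz <- nrm > 1e-12
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, nrm[nz], "/")
  z[, !nz] <- 0
  z
}

# per-offset linear index pairs into a wa x wb score matrix, for all
# ungapped offsets with overlap >= min_overlap. Offset d places column 1
# of b against column (1 + d) of a.
offset_index_list <- function(wa, wb, min_overlap) {
  ds <- (-(wb - min_overlap)):(wa - min_overlap)
  lapply(ds, function(d) {
    i <- intersect(seq_len(wa), seq_len(wb) + d)
    j <- i - d
    list(d = d, idx = (j - 1L) * wa + i, n = length(i))
  })
}

best_alignment_score <- function(Sf, Sr, wa, wb, min_overlap) {
  best <- list(score = -Inf)
  for (orient in c("forward", "revcomp")) {
    S <- if (orient == "forward") Sf else Sr
    for (o in offset_index_list(wa, wb, min_overlap)) {
      sc <- sum(S[o$idx])
      if (sc > best$score + 1e-12) {
        best <- list(score = sc, offset = o$d, orientation = orient,
                     idx = o$idx, n = o$n)
      }
    }
  }
  best
}

#' Align two PWMs over all ungapped offsets and both orientations
#'
#' Each overlapping column pair is scored by the Pearson correlation of
#' the two base-frequency 4-vectors (zero-variance columns score 0 by
#' convention); the alignment summary is the sum of column scores over
#' the overlap (so longer faithful overlaps outscore short coincidental
#' ones), and the best (offset, orientation) by summary is returned.
#' Only overlaps of at least `min_overlap` columns are considered.
#'
#' @param a,b `pwm_motif` objects, both of width >= 4.
#' @param min_overlap minimum overlapping columns (default 4).
#' @return object of class `motif_alignment`: list with `a`, `b` (the
#'   motifs), `offset` (position of b's first column relative to a's),
#'   `orientation` (`"forward"`/`"revcomp"`), `column_scores`, `score`
#'   (summary), `overlap`.
#' @export
align_pwms <- function(a, b, min_overlap = 4L) {
  stopifnot(is_pwm(a), is_pwm(b))
  if (a$width < 4L || b$width < 4L) stop("PWM width must be >= 4")
  Ca <- centered_cols(a$mat)
  Cb <- centered_cols(b$mat)
  Cbr <- centered_cols(revcomp_pwm(b)$mat)
  Sf <- crossprod(Ca, Cb)
  Sr <- crossprod(Ca, Cbr)
  best <- best_alignment_score(Sf, Sr, a$width, b$width, min_overlap)
  S <- if (best$orientation == "forward") Sf else Sr
  structure(list(a = a, b = b, offset = best$offset,
                 orientation = best$orientation,
                 column_scores = S[best$idx], score = best$score,
                 overlap = best$n,
                 Sf = Sf, Sr = Sr, min_overlap = min_overlap),
            class = "motif_alignment")
}

#' @export
print.motif_alignment <- function(x, ...) {
  cat(sprintf("<motif_alignment> %s ~ %s  score=%.3f  offset=%d  %s  overlap=%d\n",
              x$a$name, x$b$name, x$score, x$offset, x$orientation, x$overlap))
  invisible(x)
}

#' Empirical match p-value for a PWM alignment
#'
#' Null model: the columns of both PWMs are independently shuffled and
#' the pair is realigned (best score over all offsets/orientations);
#' p = (r + 1) / (n + 1) where r is the number of null scores at or
#' above the observed summary. If either PWM is entirely uninformative
#' (all columns zero-variance) the correlation score is undefined and
#' p = 1 is returned.
#'
#' @param alignment a `motif_alignment` from [align_pwms()].
#' @param null_size number of null shuffles (default 10000).
#' @param seed integer seed.
#' @return p-value in [1/(null_size+1), 1].
#' @export
match_pvalue <- function(alignment, null_size = 10000L, seed = 1L) {
  stopifnot(inherits(alignment, "motif_alignment"))
  wa <- alignment$a$width
  wb <- alignment$b$width
  Sf <- alignment$Sf
  Sr <- alignment$Sr
  if (all(abs(Sf) < 1e-12) && all(abs(Sr) < 1e-12)) return(1)
  offsets <- offset_index_list(wa, wb, alignment$min_overlap)
  obs <- alignment$score
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  r <- 0L
  for (i in seq_len(null_size)) {
    pa <- sample.int(wa)
    pb <- sample.int(wb)
    Spf <- Sf[pa, pb, drop = FALSE]
    Spr <- Sr[pa, pb, drop = FALSE]
    best <- -Inf
    for (o in offsets) {
      s1 <- sum(Spf[o$idx])
      s2 <- sum(Spr[o$idx])
      m <- max(s1, s2)
      if (m > best) best <- m
    }
    if (best >= obs - 1e-12) r <- r + 1L
  }
  (r + 1) / (null_size + 1)
}

#' Percentage mapping rate
#'
#' `100 * mapped / total`, reported to one decimal place — the unit used
#' for cross-k motif mapping summaries.
#'
#' @param total total motif count (> 0).
#' @param mapped mapped motif count.
#' @return percentage, rounded to 1 decimal; `NA` if `total` is 0.
#' @examples
#' mapping_rate(747, 645)  # 86.3
#' @export
mapping_rate <- function(total, mapped) {
  if (length(total) == 0L || total == 0) return(NA_real_)
  round(100 * mapped / total, 1)
}

# normalize heterogeneous motif inputs (pwm_motif, consensus_motif,
# word string) to pwm_motif
as_pwm_list <- function(motifs) {
  lapply(motifs, function(m) {
    if (is_pwm(m)) m
    else if (inherits(m, "consensus_motif")) m$pwm
    else if (is.character(m)) word_to_pwm(m)
    else stop("cannot interpret motif of class ", class(m)[1])
  })
}

match_pair <- function(a, b, match_alpha, null_size, seed) {
  al <- align_pwms(a, b)
  p <- match_pvalue(al, null_size = null_size, seed = seed)
  list(alignment = al, p = p, matched = p <= match_alpha)
}

#' Consensus motifs across prediction methods
#'
#' Motifs found by different engines on the same gene list are aligned
#' pairwise ([align_pwms()] + [match_pvalue()]); groups of mutually
#' linked motifs supported by at least `min_engines` distinct engines
#' are merged into consensus motifs. Plain words are lifted to
#' one-hot-with-pseudocount PWMs before matching.
#'
#' @param hits_by_engine named list (engine name -> list of motifs:
#'   `pwm_motif`, `consensus_motif`, or word strings).
#' @param match_alpha maximum match p-value (default 0.01).
#' @param null_size shuffles per match p-value (default 1000).
#' @param seed integer seed.
#' @param min_engines minimum distinct supporting engines (default 2).
#' @return list of `consensus_motif` objects (possibly empty); each has
#'   `pwm` (familial profile: members aligned to the highest-information
#'   member and column-averaged), `engines`, `members` (all member
#'   motifs), `name`.
#' @export
cross_method_consensus <- function(hits_by_engine, match_alpha = 0.01,
                                   null_size = 1000L, seed = 1L,
                                   min_engines = 2L) {
  engines <- names(hits_by_engine)
  if (is.null(engines) || any(engines == ""))
    stop("hits_by_engine must be a named list (engine -> motif list)")
  pwms <- list()
  eng <- character(0)
  for (e in engines) {
    ms <- as_pwm_list(hits_by_engine[[e]])
    for (m in ms) {
      pwms[[length(pwms) + 1L]] <- m
      eng <- c(eng, e)
    }
  }
  n <- length(pwms)
  if (n == 0L) return(list())
  # union-find over cross-engine matches
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (eng[i] == eng[j]) next
      mp <- match_pair(pwms[[i]], pwms[[j]], match_alpha, null_size,
                       seed = substream_seed(seed, paste0("cmc", i, "_", j)))
      if (mp$matched) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    idx <- which(roots == r)
    engs <- unique(eng[idx])
    if (length(engs) < min_engines) next
    members <- pwms[idx]
    rep_pwm <- familial_pwm(members)
    out[[length(out) + 1L]] <- structure(
      list(pwm = rep_pwm, engines = engs, members = members,
           name = rep_pwm$name),
      class = "consensus_motif")
  }
  out
}

# familial consensus profile: anchor on the highest-information member,
# align every other member to it and average the overlapping columns
# (columns each member does not reach are skipped). Averaging makes the
# representative robust to individual near-miss members (e.g. one-off
# word variants), in the spirit of STAMP's familial binding profiles.
familial_pwm <- function(members) {
  ics <- vapply(members, function(m) mean(m$ic), numeric(1))
  anchor <- members[[which.max(ics)]]
  if (length(members) == 1L)
    return(new_pwm(anchor$mat, name = paste0("consensus_", anchor$name),
                   provenance = list(engine = "consensus", n_members = 1L)))
  acc <- anchor$mat
  cnt <- rep(1, anchor$width)
  for (i in seq_along(members)) {
    m <- members[[i]]
    if (identical(m, anchor)) next
    al <- align_pwms(anchor, m)
    bmat <- if (al$orientation == "revcomp") revcomp_pwm(m)$mat else m$mat
    for (jb in seq_len(ncol(bmat))) {
      ja <- jb + al$offset
      if (ja >= 1L && ja <= anchor$width) {
        acc[, ja] <- acc[, ja] + bmat[, jb]
        cnt[ja] <- cnt[ja] + 1
      }
    }
  }
  avg <- sweep(acc, 2, cnt, "/")
  new_pwm(avg, name = paste0("consensus_", anchor$name),
          provenance = list(engine = "consensus",
                            n_members = length(members),
                            anchor = anchor$name))
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(sprintf("<consensus_motif> %s  consensus=%s  engines=%s  members=%d\n",
              x$name, x$pwm$consensus, paste(x$engines, collapse = "+"),
              length(x$members)))
  invisible(x)
}

#' Cross-k motif mapping
#'
#' Checks how consistently motifs found with one k-means granularity are
#' recovered with the other: each motif from the first list is "mapped"
#' iff it matches at least one motif from the second list at
#' p <= `match_alpha` (many-to-one mapping allowed).
#'
#' @param k80_motifs,k30_motifs motif lists (`pwm_motif`,
#'   `consensus_motif` or words) from the two k runs.
#' @param match_alpha maximum match p-value (default 0.01).
#' @param null_size,seed see [match_pvalue()].
#' @return list with `mapped_flags` (logical per first-list motif),
#'   `total`, `mapped`, `rate` (percentage to 1 decimal; `NA` when the
#'   first list is empty), `overlap` (the mapped motifs).
#' @export
cross_k_consensus <- function(k80_motifs, k30_motifs, match_alpha = 0.01,
                              null_size = 1000L, seed = 1L) {
  a <- as_pwm_list(k80_motifs)
  b <- as_pwm_list(k30_motifs)
  total <- length(a)
  if (total == 0L)
    return(list(mapped_flags = logical(0), total = 0L, mapped = 0L,
                rate = NA_real_, overlap = list()))
  flags <- vapply(seq_along(a), function(i) {
    for (j in seq_along(b)) {
      mp <- match_pair(a[[i]], b[[j]], match_alpha, null_size,
                       seed = substream_seed(seed, paste0("ckc", i, "_", j)))
      if (mp$matched) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(mapped_flags = flags, total = total, mapped = sum(flags),
       rate = mapping_rate(total, sum(flags)), overlap = a[flags])
}

#' Cross-species motif conservation matrix
#'
#' For each (ortholog gene pair, segment class), the cell is conserved
#' (TRUE) iff at least one species-A motif matches a species-B motif at
#' p <= `match_alpha`. Inputs are keyed by `"<gene>|<segment>"`.
#'
#' @param motifsA named list keyed `"<geneA>|<segment>"` -> motif list.
#' @param motifsB named list keyed `"<geneB>|<segment>"` -> motif list.
#' @param pairs data.frame with columns `geneA`, `geneB`.
#' @param segments segment classes to assess (default the five classes).
#' @param match_alpha,null_size,seed see [match_pvalue()].
#' @return list with `matrix` (logical, gene pairs x segments, rownames
#'   `geneA`) and `detail` (data.frame of matched motif pairs).
#' @export
cross_species_conservation <- function(motifsA, motifsB, pairs,
                                       segments = SEGMENT_CLASSES,
                                       match_alpha = 0.01,
                                       null_size = 1000L, seed = 1L) {
  mat <- matrix(FALSE, nrow(pairs), length(segments),
                dimnames = list(pairs$geneA, segments))
  detail <- list()
  for (r in seq_len(nrow(pairs))) {
    ga <- pairs$geneA[r]; gb <- pairs$geneB[r]
    for (sg in segments) {
      la <- as_pwm_list(if (is.null(motifsA[[paste(ga, sg, sep = "|")]]))
        list() else motifsA[[paste(ga, sg, sep = "|")]])
      lb <- as_pwm_list(if (is.null(motifsB[[paste(gb, sg, sep = "|")]]))
        list() else motifsB[[paste(gb, sg, sep = "|")]])
      if (length(la) == 0L || length(lb) == 0L) next
      for (i in seq_along(la)) {
        for (j in seq_along(lb)) {
          mp <- match_pair(la[[i]], lb[[j]], match_alpha, null_size,
                           seed = substream_seed(seed,
                                                 paste0("csc", r, sg, i, "_", j)))
          if (mp$matched) {
            mat[r, sg] <- TRUE
            detail[[length(detail) + 1L]] <- data.frame(
              geneA = ga, geneB = gb, segment = sg,
              motifA = la[[i]]$name, motifB = lb[[j]]$name,
              consensusA = la[[i]]$consensus, consensusB = lb[[j]]$consensus,
              p = mp$p, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(geneA = character(0), geneB = character(0),
               segment = character(0), motifA = character(0),
               motifB = character(0), consensusA = character(0),
               consensusB = character(0), p = numeric(0))
  list(matrix = mat, detail = detail)
}
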