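#' @importFrom stats cor
NULL

# equal-frequency rank binning: ranks (ties broken by order) split into
# `bins` groups of near-equal size (earlier bins take the remainder)
rank_bins <- function(x, bins) {
  n <- length(x)
  sizes <- rep(n %/% bins, bins) + c(rep(1L, n %% bins),
                                     rep(0L, bins - n %% bins))
  rep(seq_len(bins), times = sizes)[rank(x, ties.method = "first")]
}

entropy_nats <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information between two expression profiles
#'
#' Both vectors are discretized into `bins` equal-frequency bins (ties
#' broken by rank order); mutual information is computed from the joint
#' contingency table in natural log and normalized by the smaller
#' marginal entropy, so that a monotone relationship scores 1. The
#' maximum attainable value under this normalization (`mi_max_norm`) is
#' 1. A constant input vector has zero entropy; its normalized MI is
#' defined as 0 and flagged.
#'
#' @param x,y numeric vectors of equal length >= `bins`.
#' @param bins number of bins (default 3).
#' @return list with `mi` (nats), `mi_norm`, `mi_max_norm` (= 1), `hx`,
#'   `hy`, `constant` (flag).
#' @export
mutual_information <- function(x, y, bins = 3L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < bins) stop("need at least `bins` observations")
  constant <- stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12
  if (constant)
    return(list(mi = 0, mi_norm = 0, mi_max_norm = 1,
                hx = 0, hy = 0, constant = TRUE))
  bx <- rank_bins(x, bins)
  by <- rank_bins(y, bins)
  joint <- table(factor(bx, seq_len(bins)), factor(by, seq_len(bins)))
  n <- sum(joint)
  hx <- entropy_nats(rowSums(joint))
  hy <- entropy_nats(colSums(joint))
  hxy <- entropy_nats(as.vector(joint))
  mi <- hx + hy - hxy
  list(mi = mi, mi_norm = mi / min(hx, hy), mi_max_norm = 1,
       hx = hx, hy = hy, constant = FALSE)
}

#' Permutation null for normalized mutual information
#'
#' Mean normalized MI between `x` and random permutations of `y` across
#' time points; the reference level that an observed MI must exceed to
#' indicate structure beyond binning artifacts.
#'
#' @param x,y numeric vectors.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param bins passed to [mutual_information()].
#' @return mean null `mi_norm`.
#' @export
permutation_null_mi <- function(x, y, n_perm = 100L, seed = 1L, bins = 3L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mean(vapply(seq_len(n_perm), function(i)
    mutual_information(x, sample(y), bins = bins)$mi_norm, numeric(1)))
}

#' Classify the cross-species expression relationship of a gene pair
#'
#' Computes the metrics used to compare a C4 gene with its C3 ortholog:
#' Euclidean distance between the centroids of the clusters the two
#' genes fall into, Spearman rank correlation of the two RPKM series
#' across the time points, normalized mutual information and its
#' permutation-null mean. The pattern class is then assigned:
#' \itemize{
#'   \item similar — centroid distance <= `d_sim` and rank correlation
#'     >= `r_sim`;
#'   \item shifted — not similar, but `mi_norm >= mi_shift` and
#'     `mi_norm` exceeds the permutation-null mean by at least `margin`
#'     (high mutual dependence despite a phase shift);
#'   \item distinct — otherwise.
#' }
#'
#' @param geneA,geneB gene ids of the ortholog pair.
#' @param clustersA,clustersB `cluster_result` objects per species (both
#'   genes must be clustered).
#' @param exprA,exprB RPKM matrices (genes x time points).
#' @param thresholds list with `d_sim`, `r_sim`, `mi_shift`, `margin`
#'   (defaults 5.0, 0.4, 0.7, 0.2).
#' @param bins MI bins (default 3).
#' @param n_perm permutations for the MI null (default 100).
#' @param seed integer seed.
#' @return one-row data.frame with columns `geneA`, `geneB`,
#'   `centroid_distance`, `rank_correlation`, `mi_norm`, `mi_max_norm`,
#'   `mi_null_mean`, `class`.
#' @export
classify_pattern <- function(geneA, geneB, clustersA, clustersB,
                             exprA, exprB,
                             thresholds = list(d_sim = 5.0, r_sim = 0.4,
                                               mi_shift = 0.7, margin = 0.2),
                             bins = 3L, n_perm = 100L, seed = 1L) {
  if (!geneA %in% names(clustersA$labels)) stop(geneA, " is not clustered")
  if (!geneB %in% names(clustersB$labels)) stop(geneB, " is not clustered")
  ca <- clustersA$centroids[clustersA$labels[[geneA]], ]
  cb <- clustersB$centroids[clustersB$labels[[geneB]], ]
  d <- sqrt(sum((ca - cb)^2))
  xa <- as.numeric(exprA[geneA, ])
  xb <- as.numeric(exprB[geneB, ])
  rc <- suppressWarnings(stats::cor(xa, xb, method = "spearman"))
  if (!is.finite(rc)) rc <- 0
  mi <- mutual_information(xa, xb, bins = bins)
  null_mean <- permutation_null_mi(xa, xb, n_perm = n_perm, seed = seed,
                                   bins = bins)
  cls <- if (d <= thresholds$d_sim && rc >= thresholds$r_sim) {
    "similar"
  } else if (mi$mi_norm >= thresholds$mi_shift &&
             (mi$mi_norm - null_mean) >= thresholds$margin) {
    "shifted"
  } else {
    "distinct"
  }
  data.frame(geneA = geneA, geneB = geneB,
             centroid_distance = d, rank_correlation = rc,
             mi_norm = mi$mi_norm, mi_max_norm = mi$mi_max_norm,
             mi_null_mean = null_mean, class = cls,
             stringsAsFactors = FALSE)
}

#' Call a candidate recruited motif for a C4 gene
#'
#' A motif is called "recruited" when both criteria hold:
#' \enumerate{
#'   \item the motif is enriched (occurrence enrichment p <= `alpha`)
#'     in the C4 gene's segment AND in the same segment class of at
#'     least one co-expressed non-C4 gene — evidence that the motif is
#'     tied to the shared expression pattern;
#'   \item the motif has at least one occurrence in the species-A (C4)
#'     gene's segment and zero occurrences in the corresponding segment
#'     of the species-B (C3) ortholog — evidence that the element is
#'     absent from the C3 ancestor state.
#' }
#'
#' @param motif `pwm_motif` or `consensus_motif` (needs a consensus and
#'   degenerate consensus).
#' @param c4_gene species-A target gene id.
#' @param segment segment class (one of promoter/utr5/utr3/cds/intron).
#' @param coexpr_genes co-expressed non-C4 gene ids (a
#'   `coexpression_list` or character vector).
#' @param segsA named list of `segment_set` for species A covering the
#'   C4 gene and the co-expressed genes.
#' @param segB `segment_set` of the species-B ortholog, or NULL if the
#'   ortholog is unknown (verdict is then not callable).
#' @param bg_rate background per-window occurrence rate for the
#'   enrichment test (or supply `bg_seqs`).
#' @param bg_seqs background sequences (used when `bg_rate` is NULL).
#' @param alpha enrichment threshold (default 0.05).
#' @param max_mm consensus-mapping mismatch allowance (default 2).
#' @return object of class `recruitment_call`: list with `motif`,
#'   `gene`, `segment`, `criterion1` (logical), `criterion1_evidence`
#'   (data.frame of enriched co-expressed genes), `criterion2`,
#'   `occ_A`, `occ_B`, `verdict` (logical, NA if not callable).
#' @export
call_recruited <- function(motif, c4_gene, segment, coexpr_genes,
                           segsA, segB, bg_rate = NULL, bg_seqs = NULL,
                           alpha = 0.05, max_mm = 2L) {
  pwm <- if (inherits(motif, "consensus_motif")) motif$pwm else motif
  stopifnot(is_pwm(pwm))
  if (is.character(coexpr_genes)) genes <- coexpr_genes
  else genes <- coexpr_genes$gene
  genes <- setdiff(genes, c4_gene)

  seg_of <- function(ss) {
    if (is.null(ss)) return("")
    s <- ss$segments[[segment]]
    if (is.null(s)) "" else s
  }
  enrich <- function(seqstr) {
    if (!nzchar(seqstr)) return(1)
    motif_enrichment_p(seqstr, pwm$consensus, pwm$degenerate,
                       bg_seqs = bg_seqs, bg_rate = bg_rate,
                       max_mm = max_mm)$p
  }

  p_c4 <- enrich(seg_of(segsA[[c4_gene]]))
  ev <- data.frame(gene = character(0), p = numeric(0))
  for (g in genes) {
    pg <- enrich(seg_of(segsA[[g]]))
    if (pg <= alpha)
      ev <- rbind(ev, data.frame(gene = g, p = pg, stringsAsFactors = FALSE))
  }
  criterion1 <- (p_c4 <= alpha) && nrow(ev) > 0L

  segA_str <- seg_of(segsA[[c4_gene]])
  occ_A <- if (nzchar(segA_str))
    nrow(scan_consensus(segA_str, pwm$consensus, pwm$degenerate,
                        max_mm = max_mm)) else 0L
  if (is.null(segB)) {
    return(structure(list(motif = pwm, gene = c4_gene, segment = segment,
                          criterion1 = criterion1, criterion1_evidence = ev,
                          criterion2 = NA, occ_A = occ_A, occ_B = NA_integer_,
                          verdict = NA),
                     class = "recruitment_call"))
  }
  segB_str <- seg_of(segB)
  occ_B <- if (nzchar(segB_str))
    nrow(scan_consensus(segB_str, pwm$consensus, pwm$degenerate,
                        max_mm = max_mm)) else 0L
  criterion2 <- occ_A >= 1L && occ_B == 0L
  structure(list(motif = pwm, gene = c4_gene, segment = segment,
                 criterion1 = criterion1, criterion1_evidence = ev,
                 criterion2 = criterion2, occ_A = occ_A, occ_B = occ_B,
                 verdict = criterion1 && criterion2),
            class = "recruitment_call")
}

#' @export
print.recruitment_call <- function(x, ...) {
  cat(sprintf("<recruitment_call> %s @ %s/%s  c1=%s c2=%s  verdict=%s\n",
              x$motif$consensus, x$gene, x$segment,
              x$criterion1, x$criterion2, x$verdict))
  invisible(x)
}

#' Precision and recall of recruited-motif calls against planted truth
#'
#' Matches each positively called motif against the planted recruited
#' PWMs by alignment ([align_pwms()] + [match_pvalue()]). Precision is
#' the fraction of positive calls whose motif matches some planted
#' recruited motif; recall is the fraction of planted recruited motifs
#' matched by at least one positive call.
#'
#' @param called_pwms list of `pwm_motif` from calls with verdict TRUE.
#' @param truth_pwms list of planted recruited `pwm_motif`.
#' @param match_alpha match threshold (default 0.01).
#' @param null_size,seed see [match_pvalue()].
#' @return list with `precision`, `recall`, `n_called`, `n_truth`,
#'   `truth_hit` (logical per planted motif).
#' @export
evaluate_recruitment <- function(called_pwms, truth_pwms,
                                 match_alpha = 0.01, null_size = 1000L,
                                 seed = 1L) {
  called_pwms <- as_pwm_list(called_pwms)
  truth_pwms <- as_pwm_list(truth_pwms)
  if (length(called_pwms) == 0L)
    return(list(precision = NA_real_,
                recall = if (length(truth_pwms)) 0 else NA_real_,
                n_called = 0L, n_truth = length(truth_pwms),
                truth_hit = rep(FALSE, length(truth_pwms))))
  hit_mat <- matrix(FALSE, length(called_pwms), length(truth_pwms))
  for (i in seq_along(called_pwms)) {
    for (j in seq_along(truth_pwms)) {
      mp <- match_pair(called_pwms[[i]], truth_pwms[[j]], match_alpha,
                       null_size,
                       seed = substream_seed(seed, paste0("ev", i, "_", j)))
      hit_mat[i, j] <- mp$matched
    }
  }
  list(precision = mean(rowSums(hit_mat) > 0),
       recall = mean(colSums(hit_mat) > 0),
       n_called = length(called_pwms), n_truth = length(truth_pwms),
       truth_hit = colSums(hit_mat) > 0)
}
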