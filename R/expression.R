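#' @importFrom stats kmeans qnorm sd lm spline cor
NULL

#' Sampling times (hours) of the de-etiolation series
#'
#' Leaves are sampled in darkness (0h) and after 0.5, 1, 3, 6, 12 and 24
#' hours of illumination.
#' @export
TIMEPOINT_HOURS <- c(0, 0.5, 1, 3, 6, 12, 24)

#' @rdname TIMEPOINT_HOURS
#' @export
TIMEPOINT_LABELS <- c("0h", "0.5h", "1h", "3h", "6h", "12h", "24h")

#' Evaluation grid for smoothed expression curves
#'
#' The seven sampling times are unevenly spaced; smoothed curves are
#' resampled on 25 evenly spaced points over [0, 24] h so that Euclidean
#' distances between genes are comparable.
#' @export
EVAL_GRID <- seq(0, 24, length.out = 25)

#' Compute RPKM from raw counts
#'
#' RPKM = counts x 1e9 / (gene length in bp x library size).
#'
#' @param counts integer matrix, genes x samples.
#' @param gene_lengths bp per gene (recycled along rows), all > 0.
#' @param library_sizes mapped reads per sample (recycled along columns),
#'   all > 0.
#' @return numeric matrix of RPKM values, same dimnames as `counts`.
#' @examples
#' compute_rpkm(matrix(10), 1000, 1e6)  # 10
#' @export
compute_rpkm <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (length(gene_lengths) == 1L) gene_lengths <- rep(gene_lengths, nrow(counts))
  if (length(library_sizes) == 1L) library_sizes <- rep(library_sizes, ncol(counts))
  stopifnot(length(gene_lengths) == nrow(counts),
            length(library_sizes) == ncol(counts))
  out <- counts * 1e9 / outer(gene_lengths, library_sizes)
  dimnames(out) <- dimnames(counts)
  out
}

#' Filter genes by average expression
#'
#' Retains genes whose mean RPKM across the time course is strictly
#' greater than `min_avg` (default 1).
#'
#' @param m RPKM matrix, genes x time points, with gene ids as row names.
#' @param min_avg retention threshold on the row mean (strict `>`).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(m, min_avg = 1) {
  m <- as.matrix(m)
  rownames(m)[rowMeans(m) > min_avg]
}

#' Smooth a seven-point expression series onto the evaluation grid
#'
#' Two smoothing modes are supported: `"spline"` (cubic interpolating
#' spline through the (hour, value) pairs, as given by [stats::spline()])
#' used before clustering, and `"poly3"` (least-squares degree-3
#' polynomial) used for gene-gene distance calculations.
#'
#' @param values expression values at `hours`.
#' @param mode `"spline"` or `"poly3"`.
#' @param hours sampling times; default [TIMEPOINT_HOURS].
#' @param grid evaluation grid; default [EVAL_GRID].
#' @return numeric vector of the curve on `grid`.
#' @export
smooth_curve <- function(values, mode = c("spline", "poly3"),
                         hours = TIMEPOINT_HOURS, grid = EVAL_GRID) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (length(values) != length(hours))
    stop("values and hours must have equal length")
  if (mode == "spline") {
    if (length(values) < 2L) stop("spline smoothing needs >= 2 points")
    stats::spline(hours, values, xout = grid, method = "fmm")$y
  } else {
    if (length(values) < 4L) stop("poly3 needs >= 4 points")
    X <- outer(hours, 0:3, "^")
    beta <- qr.coef(qr(X), values)
    drop(outer(grid, 0:3, "^") %*% beta)
  }
}

#' Normalize a curve by its standard deviation
#'
#' Divides the curve by its SD so every gene contributes on the same
#' scale to k-means. A constant curve (SD ~ 0) is mapped to the zero
#' vector and flagged via the `"constant"` attribute; such genes are
#' excluded from clustering.
#'
#' @param curve numeric vector.
#' @return curve with SD 1 (or zeros), with attributes `"sd"` and
#'   `"constant"`.
#' @export
normalize_sd <- function(curve) {
  s <- stats::sd(curve)
  if (!is.finite(s) || s < 1e-12) {
    out <- rep(0, length(curve))
    attr(out, "sd") <- 0
    attr(out, "constant") <- TRUE
  } else {
    out <- curve / s
    attr(out, "sd") <- s
    attr(out, "constant") <- FALSE
  }
  out
}

#' Build a set of smoothed, SD-normalized curves
#'
#' @param m RPKM matrix (genes x time points, gene ids as row names).
#' @param mode smoothing mode, see [smooth_curve()].
#' @param normalize divide each smoothed curve by its SD (default TRUE).
#' @param hours,grid passed to [smooth_curve()].
#' @return object of class `curve_set`: list with `curves` (genes x grid
#'   matrix), `sd`, `constant` (logical per gene), `mode`, `grid`,
#'   `normalized`.
#' @export
curve_set <- function(m, mode = c("spline", "poly3"), normalize = TRUE,
                      hours = TIMEPOINT_HOURS, grid = EVAL_GRID) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  curves <- t(apply(m, 1, smooth_curve, mode = mode, hours = hours, grid = grid))
  sds <- apply(curves, 1, stats::sd)
  constant <- !is.finite(sds) | sds < 1e-12
  if (normalize) {
    curves[!constant, ] <- curves[!constant, , drop = FALSE] / sds[!constant]
    curves[constant, ] <- 0
  }
  structure(list(curves = curves, sd = ifelse(constant, 0, sds),
                 constant = constant, mode = mode, grid = grid,
                 normalized = normalize),
            class = "curve_set")
}

# k-means++ seeding: spread initial centers, then Lloyd iterations
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j] <- sample.int(n, 1L)
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2)
      }
      dj <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, dj)
    }
  }
  centers
}

#' k-means clustering of expression curves
#'
#' Euclidean k-means with k-means++ initialization; the best of
#' `n_restarts` runs by within-cluster sum of squares is returned.
#' Constant-curve genes are excluded (their SD-normalized curve is
#' undefined) and reported in `dropped`.
#'
#' @param curves a `curve_set` or a plain genes x grid matrix.
#' @param k number of clusters.
#' @param seed integer seed (deterministic result for a fixed seed).
#' @param n_restarts restarts (default 10).
#' @return object of class `cluster_result`: list with `k`, `labels`
#'   (named integer vector, values in 1..k), `centroids` (k x grid),
#'   `wcss`, `seed`, `dropped`.
#' @export
kmeans_cluster <- function(curves, k, seed = 1L, n_restarts = 10L) {
  if (k < 1L) stop("k must be >= 1")
  if (inherits(curves, "curve_set")) {
    x <- curves$curves[!curves$constant, , drop = FALSE]
    dropped <- rownames(curves$curves)[curves$constant]
  } else {
    x <- as.matrix(curves)
    dropped <- character(0)
  }
  if (nrow(x) < k) stop("need at least k genes to form k clusters")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- x[kmeanspp_centers(x, k), , drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  labels <- best$cluster
  names(labels) <- rownames(x)
  structure(list(k = k, labels = labels, centroids = best$centers,
                 wcss = best$tot.withinss, seed = seed, dropped = dropped),
            class = "cluster_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Figure of merit for choosing the number of clusters
#'
#' Leave-one-column-out cluster-quality score: for each grid column,
#' genes are clustered on the remaining columns and the FOM for that
#' column is the root-mean-square deviation of each gene from its
#' cluster mean in the left-out column. The reported FOM per k is the
#' mean over left-out columns. Lower is better; an elbow suggests k.
#'
#' @param curves a `curve_set` or genes x grid matrix.
#' @param k_values integer vector of cluster numbers to evaluate.
#' @param seed integer seed.
#' @param n_restarts k-means restarts per fit (default 3; FOM is a
#'   diagnostic, not a final clustering).
#' @return data.frame with columns `k` and `fom`.
#' @export
compute_fom <- function(curves, k_values, seed = 1L, n_restarts = 3L) {
  x <- if (inherits(curves, "curve_set"))
    curves$curves[!curves$constant, , drop = FALSE] else as.matrix(curves)
  if (ncol(x) < 2L) stop("FOM needs >= 2 columns")
  fom <- vapply(k_values, function(k) {
    per_col <- vapply(seq_len(ncol(x)), function(j) {
      cl <- kmeans_cluster(x[, -j, drop = FALSE], k,
                           seed = substream_seed(seed, paste0("fom", k, "_", j)),
                           n_restarts = n_restarts)
      mu <- tapply(x[, j], cl$labels, mean)
      sqrt(mean((x[, j] - mu[as.character(cl$labels)])^2))
    }, numeric(1))
    mean(per_col)
  }, numeric(1))
  data.frame(k = k_values, fom = fom)
}

#' Select genes co-expressed with a target gene
#'
#' Within the target's cluster, Euclidean distances between the target's
#' curve and every other member's curve are computed (on degree-3
#' polynomial regressed, SD-normalized curves by default), Z-score
#' transformed ((d - mean)/SD over the cluster), and genes in the 5%
#' lower tail (Z strictly below the threshold, default -1.644853) are
#' retained.
#'
#' @param target gene id; must carry a cluster label.
#' @param clusters a `cluster_result`.
#' @param curves a `curve_set` (poly3 mode recommended).
#' @param z_threshold retention threshold (strict `<`).
#' @return object of class `coexpression_list`: data.frame with columns
#'   `gene`, `distance`, `z`, plus attributes `target`, `threshold`,
#'   `cluster`.
#' @export
select_coexpressed <- function(target, clusters, curves,
                               z_threshold = -1.644853) {
  labels <- clusters$labels
  if (!target %in% names(labels)) stop("target gene has no cluster label")
  cl <- labels[[target]]
  members <- setdiff(names(labels)[labels == cl], target)
  empty <- structure(
    data.frame(gene = character(0), distance = numeric(0), z = numeric(0)),
    target = target, threshold = z_threshold, cluster = cl,
    class = c("coexpression_list", "data.frame"))
  if (length(members) < 2L) {
    warning("cluster of size < 3: Z-scores are unstable, returning empty list")
    return(empty)
  }
  x <- curves$curves
  tv <- x[target, ]
  d <- sqrt(rowSums((x[members, , drop = FALSE] -
                       matrix(tv, length(members), length(tv), byrow = TRUE))^2))
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd < 1e-12) {
    warning("all within-cluster distances identical; returning empty list")
    return(empty)
  }
  z <- (d - mean(d)) / sdd
  keep <- z < z_threshold
  out <- data.frame(gene = members[keep], distance = d[keep], z = z[keep],
                    row.names = NULL)
  out <- out[order(out$distance), , drop = FALSE]
  structure(out, target = target, threshold = z_threshold, cluster = cl,
            class = c("coexpression_list", "data.frame"))
}

#' Pathway-level average expression
#'
#' Per pathway and time point, the arithmetic mean RPKM over member
#' genes; used to summarize whole-pathway responses to illumination.
#'
#' @param m RPKM matrix (genes x time points).
#' @param bins named character vector mapping gene id to pathway, or a
#'   factor with levels for all pathways of interest (empty pathways get
#'   `NA` rows).
#' @return pathway x time point matrix of mean RPKM.
#' @export
aggregate_pathways <- function(m, bins) {
  m <- as.matrix(m)
  if (is.null(names(bins))) stop("bins must be named by gene id")
  f <- if (is.factor(bins)) bins else factor(bins)
  genes <- intersect(names(bins), rownames(m))
  out <- matrix(NA_real_, nlevels(f), ncol(m),
                dimnames = list(levels(f), colnames(m)))
  for (p in levels(f)) {
    g <- genes[f[match(genes, names(bins))] == p]
    if (length(g)) out[p, ] <- colMeans(m[g, , drop = FALSE])
  }
  out
}
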