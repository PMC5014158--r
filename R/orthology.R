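#' Construct an ortholog call-set
#'
#' One call-set per calling method, with a priority rank. Rank 1 is
#' reserved for the basis method (the most stringent caller, whose
#' pairs are always kept).
#'
#' @param method method name.
#' @param rank priority rank (1 = basis).
#' @param pairs data.frame with columns `geneA`, `geneB` (optionally
#'   `score`).
#' @return object of class `callset`.
#' @export
callset <- function(method, rank, pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("geneA", "geneB") %in% names(pairs)))
  pairs$geneA <- as.character(pairs$geneA)
  pairs$geneB <- as.character(pairs$geneB)
  structure(list(method = method, rank = as.integer(rank),
                 pairs = pairs[c("geneA", "geneB")]),
            class = "callset")
}

#' Read ortholog call-sets from TSV files
#'
#' Each file holds one method's pair list with columns
#' `geneA, geneB, method, score`. Files are assigned priority rank by
#' their order (first = basis).
#'
#' @param paths character vector of TSV paths, priority-ordered.
#' @return list of `callset`.
#' @export
read_callsets <- function(paths) {
  lapply(seq_along(paths), function(i) {
    df <- utils::read.delim(paths[[i]], stringsAsFactors = FALSE)
    method <- if ("method" %in% names(df) && nrow(df)) df$method[[1]] else
      sub("\\.tsv$", "", basename(paths[[i]]))
    callset(method, i, df)
  })
}

mean_expr <- function(gene, expr) {
  if (gene %in% rownames(expr)) mean(expr[gene, ]) else 0
}

# keep, per key gene, the pair whose partner has the higher mean
# expression; ties broken lexicographically by partner id
resolve_side <- function(pairs, key, partner, expr) {
  split_idx <- split(seq_len(nrow(pairs)), pairs[[key]])
  keep <- vapply(split_idx, function(idx) {
    if (length(idx) == 1L) return(idx)
    partners <- pairs[[partner]][idx]
    e <- vapply(partners, mean_expr, numeric(1), expr = expr)
    winners <- idx[e == max(e)]
    winners[order(pairs[[partner]][winners])][1L]
  }, integer(1))
  dup_keys <- names(split_idx)[lengths(split_idx) > 1L]
  out <- pairs[sort(unname(keep)), c("geneA", "geneB"), drop = FALSE]
  out$resolved <- out[[key]] %in% dup_keys
  out
}

#' Reconcile multiple ortholog call-sets into one-to-one pairs
#'
#' Applies four priority rules: (1) all pairs from the basis (rank-1,
#' most stringent) call-set are kept; (2) pairs reported only by
#' lower-priority methods are added when they do not touch a
#' basis-matched gene; (3) when methods disagree (the same gene matched
#' to different partners), the partner with the higher mean expression
#' is retained, on the assumption that functional genes are more highly
#' expressed (ties broken lexicographically by partner id); (4) any
#' residual relation that is still not one-to-one is dropped.
#'
#' Genes present in a call-set but absent from the expression matrix are
#' treated as having expression 0.
#'
#' @param callsets list of `callset`, priority-ordered (or carrying
#'   ranks); rank 1 is the basis.
#' @param exprA,exprB RPKM matrices for species A and B (gene ids as row
#'   names), used to resolve conflicts.
#' @return data.frame with columns `geneA`, `geneB`, `methods`
#'   (comma-separated supporting methods), `note`
#'   (`basis`/`supplemented`/`expression-resolved`).
#' @export
reconcile_orthologs <- function(callsets, exprA, exprB) {
  callsets <- callsets[order(vapply(callsets, `[[`, integer(1), "rank"))]
  basis <- unique(callsets[[1L]]$pairs)
  key <- function(df) paste(df$geneA, df$geneB, sep = "\r")
  support <- list()
  add_support <- function(k, method) {
    for (kk in k) support[[kk]] <<- union(support[[kk]], method)
  }
  add_support(key(basis), callsets[[1L]]$method)

  # candidate pairs from non-basis methods that do not touch basis genes
  cand <- data.frame(geneA = character(0), geneB = character(0))
  if (length(callsets) > 1L) {
    for (cs in callsets[-1L]) {
      p <- unique(cs$pairs)
      add_support(key(p), cs$method)
      free <- !(p$geneA %in% basis$geneA) & !(p$geneB %in% basis$geneB)
      cand <- unique(rbind(cand, p[free, , drop = FALSE]))
    }
  }
  note <- rep("supplemented", nrow(cand))
  if (nrow(cand)) {
    resA <- resolve_side(cand, "geneA", "geneB", exprB)
    resB <- resolve_side(resA, "geneB", "geneA", exprA)
    resolved_flag <- resA$resolved[match(key(resB), key(resA))] | resB$resolved
    cand <- resB[c("geneA", "geneB")]
    # rule 4: drop anything still not one-to-one
    okA <- !(cand$geneA %in% cand$geneA[duplicated(cand$geneA)])
    okB <- !(cand$geneB %in% cand$geneB[duplicated(cand$geneB)])
    keep <- okA & okB
    cand <- cand[keep, , drop = FALSE]
    note <- ifelse(resolved_flag[keep], "expression-resolved", "supplemented")
  }

  out <- rbind(
    data.frame(geneA = basis$geneA, geneB = basis$geneB,
               note = rep("basis", nrow(basis)), stringsAsFactors = FALSE),
    data.frame(geneA = cand$geneA, geneB = cand$geneB, note = note,
               stringsAsFactors = FALSE))
  # basis itself must be one-to-one too
  okA <- !(out$geneA %in% out$geneA[duplicated(out$geneA)])
  okB <- !(out$geneB %in% out$geneB[duplicated(out$geneB)])
  out <- out[okA & okB, , drop = FALSE]
  out$methods <- vapply(key(out), function(k)
    paste(support[[k]], collapse = ","), character(1))
  rownames(out) <- NULL
  out[c("geneA", "geneB", "methods", "note")]
}

#' Pick the C4 isoform within a paralog family
#'
#' If cell-specificity information annotates a family member, that gene
#' is returned; otherwise the member with the highest mean expression
#' across the time course is taken as the C4 isoform (ties broken
#' lexicographically by gene id).
#'
#' @param family character vector of paralog gene ids (nonempty).
#' @param expr RPKM matrix with gene ids as row names.
#' @param known_specificity optional character vector of genes with
#'   known cell-specific expression.
#' @return a single gene id.
#' @export
pick_c4_isoform <- function(family, expr, known_specificity = NULL) {
  if (length(family) == 0L) stop("empty paralog family")
  if (!is.null(known_specificity)) {
    hit <- intersect(family, known_specificity)
    if (length(hit)) return(sort(hit)[1L])
  }
  e <- vapply(family, mean_expr, numeric(1), expr = expr)
  winners <- sort(family[e == max(e)])
  winners[1L]
}
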