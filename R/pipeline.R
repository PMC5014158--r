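# End-to-end orchestration: expression -> clustering -> orthology ->
# segments -> three-engine discovery -> cross-method/cross-k/
# cross-species consensus -> recruitment calls, plus the random-gene
# negative control.

#' Pipeline configuration
#'
#' @param synth a `synth_config` describing the synthetic dataset the
#'   run operates on.
#' @param k_values two (or more) k-means granularities; motifs are
#'   discovered once per k and reconciled by [cross_k_consensus()].
#'   Default: the synthetic cluster count and half of it (the study's
#'   k80/k30 pair presumes genome-scale gene counts, so k scales with
#'   the generated cluster structure).
#' @param z_threshold co-expression retention threshold on the distance
#'   Z-score (default -1.644853, the standard-normal 5\% quantile).
#' @param enrichment_alpha per-engine enrichment significance level.
#' @param match_alpha motif-motif match p-value threshold.
#' @param max_mm consensus-scan mismatch allowance.
#' @param word_mm word-enumeration counting mismatches (default 0:
#'   exact-word counting; see the package vignette for the power
#'   analysis behind this default).
#' @param word_widths word-enumeration widths (default c(6, 8)).
#' @param em_width EM motif width (default 8).
#' @param em_seeds,em_max_iter EM restart/iteration controls.
#' @param null_size shuffles per motif-match p-value (default 500;
#'   p-value floor 1/501, below `match_alpha`).
#' @param n_bg_genes background genes sampled (from outside the target
#'   cluster) per discovery run.
#' @param seed root seed; all stage randomness derives named substreams
#'   from it.
#' @return validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            k_values = NULL,
                            z_threshold = -1.644853,
                            enrichment_alpha = 0.05,
                            match_alpha = 0.01,
                            max_mm = 2L,
                            word_mm = 0L,
                            word_widths = c(6L, 8L),
                            em_width = 8L,
                            em_seeds = 3L,
                            em_max_iter = 100L,
                            null_size = 500L,
                            n_bg_genes = 50L,
                            seed = 1L) {
  stopifnot(inherits(synth, "synth_config"))
  if (is.null(k_values))
    k_values <- c(synth$n_clusters, max(2L, synth$n_clusters %/% 2L))
  if (length(k_values) < 2L) stop("need >= 2 k values for consensus")
  for (a in c(enrichment_alpha, match_alpha))
    if (a <= 0 || a >= 1) stop("alphas must be in (0, 1)")
  if (1 / (null_size + 1) > match_alpha)
    stop("null_size too small: the p-value floor exceeds match_alpha")
  structure(list(synth = synth, k_values = as.integer(k_values),
                 z_threshold = z_threshold,
                 enrichment_alpha = enrichment_alpha,
                 match_alpha = match_alpha, max_mm = as.integer(max_mm),
                 word_mm = as.integer(word_mm),
                 word_widths = as.integer(word_widths),
                 em_width = as.integer(em_width),
                 em_seeds = as.integer(em_seeds),
                 em_max_iter = as.integer(em_max_iter),
                 null_size = as.integer(null_size),
                 n_bg_genes = as.integer(n_bg_genes),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

# one three-engine discovery run on a foreground sequence set, followed
# by cross-method consensus
discover_consensus <- function(fg, bg_seqs, bgm, library, cfg, seed) {
  hits <- list()
  words <- word_enumerate(fg, bgm, widths = cfg$word_widths,
                          max_word_mm = cfg$word_mm,
                          alpha = cfg$enrichment_alpha,
                          correct = "bonferroni")
  hits$word <- as.list(words$word)
  hits$em <- list(em_discover(fg, cfg$em_width,
                              seed = substream_seed(seed, "em"),
                              n_seeds = cfg$em_seeds,
                              max_iter = cfg$em_max_iter))
  lib <- library_enrichment(fg, bg_seqs, library,
                            alpha = cfg$enrichment_alpha,
                            correct = "bonferroni")
  hits$library <- unname(attr(lib, "pwms"))
  consensus <- cross_method_consensus(hits, match_alpha = cfg$match_alpha,
                                      null_size = cfg$null_size,
                                      seed = substream_seed(seed, "cmc"))
  list(consensus = consensus, words = words, library = lib, hits = hits)
}

# nonempty segment strings of the given class across a gene list
class_seqs <- function(segsets, gene_list, class) {
  out <- vapply(gene_list, function(g) {
    ss <- segsets[[g]]
    if (is.null(ss)) "" else ss$segments[[class]]
  }, character(1))
  out[nzchar(out)]
}

#' Run the full motif-recruitment analysis
#'
#' Stages: synthetic data generation; expression filtering and curve
#' fitting; k-means clustering at each configured k; ortholog call-set
#' reconciliation; segment extraction from the generated FASTA/GFF3;
#' per-C4-target co-expression lists and three-engine motif discovery
#' per segment class; cross-method consensus; cross-k mapping (Table-2
#' style rates); species-B discovery and the cross-species conservation
#' matrix; expression-pattern classification; recruited-motif calls and
#' (for synthetic data) evaluation against the planted truth.
#' Intermediate tables are written to `out_dir` as each stage finishes.
#'
#' @param cfg a `pipeline_config`.
#' @param out_dir output directory (default: fresh temporary directory).
#' @return object of class `run_report`.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("c4run")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ds <- with_stage("synthetic_data",
                   generate_dataset(cfg$synth, file.path(out_dir, "data")))

  ## expression
  exprA <- with_stage("expression",
    ds$exprA[filter_expressed(ds$exprA), , drop = FALSE])
  exprB <- with_stage("expression",
    ds$exprB[filter_expressed(ds$exprB), , drop = FALSE])
  csA_spline <- with_stage("expression", curve_set(exprA, "spline"))
  csA_poly <- with_stage("expression", curve_set(exprA, "poly3"))
  csB_spline <- with_stage("expression", curve_set(exprB, "spline"))
  csB_poly <- with_stage("expression", curve_set(exprB, "poly3"))

  ## clustering (per k for species A; k1 for species B)
  clA <- with_stage("clustering", lapply(cfg$k_values, function(k)
    kmeans_cluster(csA_spline, k,
                   seed = substream_seed(cfg$seed, paste0("cluster_kA", k)))))
  names(clA) <- as.character(cfg$k_values)
  k1 <- as.character(cfg$k_values[1])
  clB <- with_stage("clustering",
    kmeans_cluster(csB_spline, cfg$k_values[1],
                   seed = substream_seed(cfg$seed, "cluster_kB")))

  ## orthology
  ortho <- with_stage("orthology", {
    cs <- read_callsets(ds$files$callsets)
    reconcile_orthologs(cs, exprA, exprB)
  })
  utils::write.table(ortho, file.path(out_dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ortho_map <- stats::setNames(ortho$geneB, ortho$geneA)

  ## segments (re-extracted from the generated FASTA/GFF3)
  segsA <- with_stage("scanmap",
    extract_segments(ds$files$modelsA, ds$files$genomeA,
                     promoter_bp = cfg$synth$segment_lengths[["promoter"]]))
  segsB <- with_stage("scanmap",
    extract_segments(ds$files$modelsB, ds$files$genomeB,
                     promoter_bp = cfg$synth$segment_lengths[["promoter"]]))

  ## background: genes outside the C4 cluster, plus a fitted Markov model
  targets <- ds$c4_genes
  old <- .Random.seed_save()
  set.seed(substream_seed(cfg$seed, "background"))
  non_target_cluster <- names(ds$cluster_id)[
    ds$cluster_id != ds$cluster_id[[targets[1]]]]
  bg_genesA <- sample(non_target_cluster,
                      min(cfg$n_bg_genes, length(non_target_cluster)))
  bg_genesB <- ortho_map[bg_genesA]
  bg_genesB <- bg_genesB[!is.na(bg_genesB)]
  .Random.seed_restore(old)
  bg_seqsA <- lapply(stats::setNames(nm = SEGMENT_CLASSES), function(cl)
    class_seqs(segsA, bg_genesA, cl))
  bg_seqsB <- lapply(stats::setNames(nm = SEGMENT_CLASSES), function(cl)
    class_seqs(segsB, unname(bg_genesB), cl))
  bgmA <- fit_background(unlist(bg_seqsA))
  bgmB <- fit_background(unlist(bg_seqsB))

  ## per-target discovery, per k and segment class (species A)
  coexprA <- list()
  consA <- list()
  for (k in names(clA)) {
    consA[[k]] <- list()
    for (tg in targets) {
      co <- with_stage("coexpression",
        select_coexpressed(tg, clA[[k]], csA_poly,
                           z_threshold = cfg$z_threshold))
      coexprA[[paste(k, tg)]] <- co
      fg_genes <- c(tg, co$gene)
      consA[[k]][[tg]] <- list()
      for (cl in SEGMENT_CLASSES) {
        fg <- class_seqs(segsA, fg_genes, cl)
        if (length(fg) == 0L) {
          consA[[k]][[tg]][[cl]] <- list()
          next
        }
        d <- with_stage("motif_discovery",
          discover_consensus(fg, bg_seqsA[[cl]], bgmA, ds$library, cfg,
                             seed = substream_seed(
                               cfg$seed, paste("discA", k, tg, cl))))
        consA[[k]][[tg]][[cl]] <- d$consensus
      }
    }
  }

  ## cross-k mapping, aggregated per segment class (Table-2 style)
  k2 <- as.character(cfg$k_values[2])
  tab2 <- with_stage("motif_compare", {
    rows <- lapply(SEGMENT_CLASSES, function(cl) {
      total <- 0L; mapped <- 0L
      for (tg in targets) {
        ck <- cross_k_consensus(consA[[k1]][[tg]][[cl]],
                                consA[[k2]][[tg]][[cl]],
                                match_alpha = cfg$match_alpha,
                                null_size = cfg$null_size,
                                seed = substream_seed(
                                  cfg$seed, paste("ck", tg, cl)))
        total <- total + ck$total
        mapped <- mapped + ck$mapped
      }
      data.frame(segment = cl, total = total, mapped = mapped,
                 rate = mapping_rate(total, mapped),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.table(tab2, file.path(out_dir, "cross_k.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## species-B discovery for the C4 orthologs
  pairs <- data.frame(geneA = targets,
                      geneB = unname(ortho_map[targets]),
                      stringsAsFactors = FALSE)
  pairs <- pairs[!is.na(pairs$geneB), , drop = FALSE]
  consB <- list()
  coexprB <- list()
  for (gb in pairs$geneB) {
    co <- with_stage("coexpression",
      select_coexpressed(gb, clB, csB_poly, z_threshold = cfg$z_threshold))
    coexprB[[gb]] <- co
    fg_genes <- c(gb, co$gene)
    for (cl in SEGMENT_CLASSES) {
      fg <- class_seqs(segsB, fg_genes, cl)
      key <- paste(gb, cl, sep = "|")
      if (length(fg) == 0L) { consB[[key]] <- list(); next }
      d <- with_stage("motif_discovery",
        discover_consensus(fg, bg_seqsB[[cl]], bgmB, ds$library, cfg,
                           seed = substream_seed(
                             cfg$seed, paste("discB", gb, cl))))
      consB[[key]] <- d$consensus
    }
  }
  motifsA_keyed <- list()
  for (tg in targets) for (cl in SEGMENT_CLASSES)
    motifsA_keyed[[paste(tg, cl, sep = "|")]] <- consA[[k1]][[tg]][[cl]]
  conservation <- with_stage("motif_compare",
    cross_species_conservation(motifsA_keyed, consB, pairs,
                               match_alpha = cfg$match_alpha,
                               null_size = cfg$null_size,
                               seed = substream_seed(cfg$seed, "cons")))
  utils::write.table(conservation$detail,
                     file.path(out_dir, "conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## expression-pattern classification for the C4 ortholog pairs
  patterns <- with_stage("recruitment", {
    rows <- lapply(seq_len(nrow(pairs)), function(r)
      classify_pattern(pairs$geneA[r], pairs$geneB[r], clA[[k1]], clB,
                       exprA, exprB,
                       seed = substream_seed(cfg$seed,
                                             paste0("mi", pairs$geneA[r]))))
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  if (!is.null(patterns))
    utils::write.table(patterns, file.path(out_dir, "patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## recruitment calls on the k1 consensus motifs
  calls <- list()
  call_rows <- list()
  with_stage("recruitment", for (tg in targets) {
    gb <- if (tg %in% names(ortho_map)) ortho_map[[tg]] else NA_character_
    co <- coexprA[[paste(k1, tg)]]
    for (cl in SEGMENT_CLASSES) {
      for (cm in consA[[k1]][[tg]][[cl]]) {
        rate <- analytic_scan_rate(cm$pwm$consensus, cm$pwm$degenerate,
                                   bgmA, max_mm = cfg$max_mm)
        rate <- min(max(rate, 1e-12), 1 - 1e-12)
        call <- call_recruited(cm, tg, cl, co$gene, segsA,
                               segB = if (is.na(gb)) NULL else segsB[[gb]],
                               bg_rate = rate,
                               alpha = cfg$enrichment_alpha,
                               max_mm = cfg$max_mm)
        calls[[length(calls) + 1L]] <- call
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          motif = cm$name, consensus = cm$pwm$consensus, gene = tg,
          segment = cl, engines = paste(cm$engines, collapse = "+"),
          criterion1 = call$criterion1, criterion2 = call$criterion2,
          occ_A = call$occ_A, occ_B = call$occ_B,
          verdict = call$verdict, stringsAsFactors = FALSE)
      }
    }
  })
  call_df <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(motif = character(0), consensus = character(0),
               gene = character(0), segment = character(0),
               engines = character(0), criterion1 = logical(0),
               criterion2 = logical(0), occ_A = integer(0),
               occ_B = integer(0), verdict = logical(0))
  utils::write.table(call_df, file.path(out_dir, "recruitment_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  recruited <- Filter(function(x) isTRUE(x$verdict), calls)

  ## evaluation against the planted truth
  evaluation <- with_stage("evaluation", {
    rec_specs <- Filter(function(s) s$recruited, ds$planted)
    shd_specs <- Filter(function(s) !s$recruited, ds$planted)
    eval_rec <- evaluate_recruitment(
      lapply(recruited, `[[`, "motif"),
      lapply(rec_specs, `[[`, "pwm"),
      match_alpha = cfg$match_alpha, null_size = cfg$null_size,
      seed = substream_seed(cfg$seed, "eval"))
    shared_conserved <- vapply(shd_specs, function(spec) {
      sgl <- spec$target_segment
      for (r in seq_len(nrow(pairs))) {
        if (!conservation$matrix[r, sgl]) next
        for (m in motifsA_keyed[[paste(pairs$geneA[r], sgl, sep = "|")]]) {
          mp <- match_pair(spec$pwm, m$pwm, cfg$match_alpha,
                           cfg$null_size,
                           seed = substream_seed(cfg$seed,
                                                 paste0("shd", spec$name)))
          if (mp$matched) return(TRUE)
        }
      }
      FALSE
    }, logical(1))
    names(shared_conserved) <- vapply(shd_specs, `[[`, character(1), "name")
    list(recruited = eval_rec, shared_conserved = shared_conserved)
  })

  structure(list(
    config = cfg, out_dir = out_dir, data = ds,
    counts = list(
      genes = nrow(exprA), orthologs = nrow(ortho),
      targets = length(targets),
      coexpr_sizes = vapply(coexprA, nrow, integer(1)),
      consensus_k1 = sum(vapply(unlist(consA[[k1]], recursive = FALSE),
                                length, integer(1))),
      calls = nrow(call_df), recruited = length(recruited)),
    clusters = clA, clustersB = clB, orthologs = ortho,
    coexprA = coexprA, consensusA = consA, consensusB = consB,
    table2 = tab2, conservation = conservation, patterns = patterns,
    calls = call_df, recruited = recruited, evaluation = evaluation),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  genes: %d   orthologs: %d   C4 targets: %d\n",
              x$counts$genes, x$counts$orthologs, x$counts$targets))
  cat(sprintf("  consensus motifs (k=%d): %d   recruitment calls: %d   recruited: %d\n",
              x$config$k_values[1], x$counts$consensus_k1,
              x$counts$calls, x$counts$recruited))
  cat("  cross-k mapping rates per segment:\n")
  for (r in seq_len(nrow(x$table2)))
    cat(sprintf("    %-9s total=%3d mapped=%3d rate=%s\n",
                x$table2$segment[r], x$table2$total[r], x$table2$mapped[r],
                ifelse(is.na(x$table2$rate[r]), "NA",
                       sprintf("%.1f%%", x$table2$rate[r]))))
  if (!is.null(x$evaluation))
    cat(sprintf("  recruited-motif precision=%.2f recall=%.2f; shared conserved: %s\n",
                x$evaluation$recruited$precision,
                x$evaluation$recruited$recall,
                paste(names(which(x$evaluation$shared_conserved)),
                      collapse = ", ")))
  invisible(x)
}

#' Random-gene negative control
#'
#' Generates a background-only dataset (no planted motifs) under the
#' run's synthetic configuration, draws `n_sets` random gene lists of
#' `set_size` genes, and puts each list through the same three-engine
#' discovery plus cross-method consensus per segment class. With no
#' planted signal, no cross-method consensus motifs are expected.
#'
#' @param cfg a `pipeline_config`.
#' @param n_sets number of random gene lists (default 3).
#' @param set_size genes per list (default 50).
#' @param seed integer seed (default: the pipeline seed).
#' @param out_dir directory for the background-only dataset.
#' @return data.frame with columns `set`, `n_consensus`; attribute
#'   `"by_segment"` holds the per-segment counts.
#' @export
run_negative_control <- function(cfg, n_sets = 3L, set_size = 50L,
                                 seed = cfg$seed,
                                 out_dir = tempfile("c4negctrl")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (set_size < 1L) stop("set_size must be >= 1")
  synth0 <- cfg$synth
  synth0$planted_motifs <- list()
  ds <- generate_dataset(synth0, file.path(out_dir, "data"))
  N <- synth0$n_genes_per_species
  if (set_size > N) stop("set_size exceeds the gene universe")
  library_pwms <- c(lapply(cfg$synth$planted_motifs, `[[`, "pwm"),
                    default_decoy_motifs())

  old <- .Random.seed_save()
  set.seed(substream_seed(seed, "negctrl_bg"))
  bg_genes <- sample(names(ds$segsA), min(cfg$n_bg_genes, N))
  .Random.seed_restore(old)
  bg_seqs <- lapply(stats::setNames(nm = SEGMENT_CLASSES), function(cl)
    class_seqs(ds$segsA, bg_genes, cl))
  bgm <- fit_background(unlist(bg_seqs))

  counts <- integer(n_sets)
  by_segment <- matrix(0L, n_sets, length(SEGMENT_CLASSES),
                       dimnames = list(NULL, SEGMENT_CLASSES))
  for (s in seq_len(n_sets)) {
    old <- .Random.seed_save()
    set.seed(substream_seed(seed, paste0("negctrl_set", s)))
    gene_list <- sample(names(ds$segsA), set_size)
    .Random.seed_restore(old)
    for (cl in SEGMENT_CLASSES) {
      fg <- class_seqs(ds$segsA, gene_list, cl)
      if (length(fg) == 0L) next
      d <- discover_consensus(fg, bg_seqs[[cl]], bgm, library_pwms, cfg,
                              seed = substream_seed(
                                seed, paste("negctrl", s, cl)))
      by_segment[s, cl] <- length(d$consensus)
    }
    counts[s] <- sum(by_segment[s, ])
  }
  structure(data.frame(set = seq_len(n_sets), n_consensus = counts),
            by_segment = by_segment)
}
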