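# Synthetic two-species benchmark generator with planted ground truth.

#' Build a planted motif PWM from a consensus word
#'
#' Each column puts `dominant` probability mass on the consensus base
#' and spreads the rest uniformly over the other three bases.
#'
#' @param consensus A/C/G/T word.
#' @param dominant consensus-base frequency per column (default 0.94).
#' @param name motif name.
#' @return a `pwm_motif`.
#' @export
planted_pwm <- function(consensus, dominant = 0.94, name = consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) stop("consensus must be A/C/G/T only")
  w <- length(idx)
  mat <- matrix((1 - dominant) / 3, 4, w)
  mat[cbind(idx, seq_len(w))] <- dominant
  new_pwm(mat, name = name, provenance = list(engine = "planted"))
}

#' Specification of one planted motif
#'
#' @param pwm a `pwm_motif` (width 6-12, columns summing to 1).
#' @param target_segment segment class receiving the sites (one of
#'   promoter/utr5/utr3/cds/intron).
#' @param host_gene_fraction fraction of the target cluster's genes
#'   carrying a site (C4 genes in the target cluster always carry one,
#'   so recruitment calls are well defined).
#' @param recruited if TRUE, sites are planted in species A only and the
#'   species-B segments of C4-gene orthologs are additionally kept free
#'   of chance occurrences; if FALSE the motif is shared (planted in the
#'   species-B ortholog of every species-A host as well).
#' @param cluster index of the hosting co-expression cluster (default 1,
#'   the C4 cluster).
#' @param name motif id used in the truth table.
#' @return object of class `planted_motif_spec`.
#' @export
planted_motif_spec <- function(pwm, target_segment,
                               host_gene_fraction = 0.9,
                               recruited = FALSE, cluster = 1L,
                               name = pwm$name) {
  stopifnot(is_pwm(pwm))
  if (pwm$width < 6L || pwm$width > 12L)
    stop("planted PWM width must be in [6, 12]")
  if (!target_segment %in% SEGMENT_CLASSES)
    stop("target_segment must be one of: ",
         paste(SEGMENT_CLASSES, collapse = ", "))
  if (host_gene_fraction < 0 || host_gene_fraction > 1)
    stop("host_gene_fraction must be in [0, 1]")
  structure(list(pwm = pwm, target_segment = target_segment,
                 host_gene_fraction = host_gene_fraction,
                 recruited = isTRUE(recruited),
                 cluster = as.integer(cluster), name = name),
            class = "planted_motif_spec")
}

#' Default planted motifs: two recruited, two shared
#'
#' All four target the C4 cluster (cluster 1): a recruited promoter
#' motif, a recruited intron motif, a shared promoter motif and a shared
#' 5'UTR motif. Consensus words were chosen mutually dissimilar (no
#' high-identity ungapped alignment in either orientation).
#'
#' @return list of `planted_motif_spec`.
#' @export
default_planted_motifs <- function() {
  list(
    planted_motif_spec(planted_pwm("TGCCAGTA", name = "rec_prom"),
                       "promoter", recruited = TRUE),
    planted_motif_spec(planted_pwm("CGATAAGC", name = "rec_intron"),
                       "intron", recruited = TRUE),
    planted_motif_spec(planted_pwm("AGGTCCAT", name = "shd_prom"),
                       "promoter", recruited = FALSE),
    planted_motif_spec(planted_pwm("TTCAGCGA", name = "shd_utr5"),
                       "utr5", recruited = FALSE)
  )
}

# decoy library PWMs with no planted sites anywhere
default_decoy_motifs <- function() {
  list(planted_pwm("CAGTTGAC", name = "decoy1"),
       planted_pwm("GGATACCA", name = "decoy2"),
       planted_pwm("TCGTGCTT", name = "decoy3"),
       planted_pwm("ATCCGCAG", name = "decoy4"))
}

#' Configuration of the synthetic benchmark
#'
#' @param seed root seed; every generation stage derives a named
#'   substream from it, so a fixed seed gives byte-identical output.
#' @param n_genes_per_species gene count per species (split into
#'   contiguous equal-size cluster blocks).
#' @param n_clusters number of expression clusters.
#' @param n_timepoints number of sampling times (default 7, at 0, 0.5,
#'   1, 3, 6, 12 and 24 hours; other counts use an even 0-24 h grid).
#' @param noise_sd Gaussian measurement-noise SD on the normalized-curve
#'   scale, applied to every gene and time point independently.
#' @param core_fraction fraction of each cluster generated as tight
#'   "core" members whose true curve equals the cluster archetype
#'   exactly. Core genes are the first genes of each cluster block, so
#'   C4 genes (and their species-B orthologs) are always core.
#' @param peripheral_sd maximum amplitude, relative to the archetype's
#'   own variation, of the per-gene systematic deviation carried by
#'   non-core (peripheral) members. Each peripheral gene deviates by a
#'   smooth random cubic curve, orthogonal to the archetype, with
#'   amplitude `peripheral_sd * sd(archetype) * U^(1/4)`,
#'   U ~ Uniform(0, 1), so membership tightness is a continuum with
#'   density increasing in deviation. Real co-expression clusters are
#'   not exchangeable: any target gene has a few near-identical
#'   profiles and many looser ones. Without that structure,
#'   target-to-member distances are pure noise — a right-skewed
#'   chi-like distribution whose Z < -1.645 left tail is nearly
#'   empty — and distance-Z co-expression lists degenerate.
#' @param n_c4_genes number of C4 genes (the first genes of cluster 1).
#' @param segment_lengths named bp lengths for the five segment classes.
#' @param planted_motifs list of [planted_motif_spec()].
#' @param ortholog_conflict_rate fraction of a non-basis call-set's
#'   pairs rewired to a wrong partner (creates method conflicts).
#' @param many_to_many_rate fraction of a call-set's pairs duplicated
#'   with a second partner (creates many-to-many records).
#' @param gc background GC content of the first-order Markov genome.
#' @param intergenic_bp gap between consecutive gene blocks.
#' @param amplitude_meanlog,amplitude_sdlog log-normal parameters of the
#'   per-gene expression amplitude (RPKM scale).
#' @return validated object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_genes_per_species = 1000L,
                         n_clusters = 4L,
                         n_timepoints = 7L,
                         noise_sd = 0.03,
                         core_fraction = 0.08,
                         peripheral_sd = 0.5,
                         n_c4_genes = 3L,
                         segment_lengths = c(promoter = 300L, utr5 = 120L,
                                             utr3 = 120L, cds = 360L,
                                             intron = 240L),
                         planted_motifs = default_planted_motifs(),
                         ortholog_conflict_rate = 0.05,
                         many_to_many_rate = 0.03,
                         gc = 0.44,
                         intergenic_bp = 60L,
                         amplitude_meanlog = log(8),
                         amplitude_sdlog = 0.5) {
  if (n_c4_genes > n_genes_per_species)
    stop("n_c4_genes cannot exceed n_genes_per_species")
  if (!all(SEGMENT_CLASSES %in% names(segment_lengths)))
    stop("segment_lengths must name all of: ",
         paste(SEGMENT_CLASSES, collapse = ", "))
  if (any(segment_lengths <= 0)) stop("all segment lengths must be > 0")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (core_fraction <= 0 || core_fraction > 1)
    stop("core_fraction must be in (0, 1]")
  if (peripheral_sd < 0) stop("peripheral_sd must be nonnegative")
  for (p in c(ortholog_conflict_rate, many_to_many_rate))
    if (p < 0 || p > 1) stop("rates must be probabilities in [0, 1]")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (n_clusters < 1L || n_genes_per_species < n_clusters)
    stop("need at least one gene per cluster")
  for (spec in planted_motifs) {
    if (!inherits(spec, "planted_motif_spec"))
      stop("planted_motifs must be a list of planted_motif_spec")
    if (spec$cluster > n_clusters)
      stop("planted motif '", spec$name, "' targets cluster ", spec$cluster,
           " but there are only ", n_clusters, " clusters")
    # usable planting span: first CDS part for cds, whole part otherwise
    usable <- if (spec$target_segment == "cds")
      ceiling(segment_lengths[["cds"]] / 2) else
        segment_lengths[[spec$target_segment]]
    if (usable < spec$pwm$width)
      stop("configuration error: segment '", spec$target_segment,
           "' is too short for planted motif '", spec$name,
           "' of width ", spec$pwm$width)
  }
  structure(list(seed = as.integer(seed),
                 n_genes_per_species = as.integer(n_genes_per_species),
                 n_clusters = as.integer(n_clusters),
                 n_timepoints = as.integer(n_timepoints),
                 noise_sd = noise_sd,
                 core_fraction = core_fraction,
                 peripheral_sd = peripheral_sd,
                 n_c4_genes = as.integer(n_c4_genes),
                 segment_lengths = segment_lengths,
                 planted_motifs = planted_motifs,
                 ortholog_conflict_rate = ortholog_conflict_rate,
                 many_to_many_rate = many_to_many_rate,
                 gc = gc,
                 intergenic_bp = as.integer(intergenic_bp),
                 amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog),
            class = "synth_config")
}

# curve archetypes over hours: sustained induction, sharp early peak,
# transient early repression, and a 3-hour peak. Chosen to be mutually
# well separated AFTER per-curve SD normalization (pairwise normalized
# distance >= 5.2 on the evaluation grid); naive sets like
# up/down/peak/late-peak collapse to one dimension once normalized
# (up ~ -peak, down ~ -late-peak) and are not clusterable. Clusters
# beyond four get additional peaked shapes with staggered peak times.
archetype_matrix <- function(hours, k) {
  base <- list(
    function(t) 0.2 + t / 24,
    function(t) 0.2 + exp(-((t - 1) / 1.5)^2),
    function(t) 1.2 - exp(-((t - 3) / 2)^2),
    function(t) 0.2 + exp(-((t - 3) / 2)^2)
  )
  shapes <- lapply(seq_len(k), function(i) {
    if (i <= 4L) base[[i]]
    else {
      peak <- 2 + 20 * ((i - 4) %% 7) / 7
      function(t) 0.2 + exp(-((t - peak) / 3)^2)
    }
  })
  t(vapply(shapes, function(f) f(hours), numeric(length(hours))))
}

# sample one site from a PWM conditional on conforming to its degenerate
# consensus (guarantees the truth-table sequence invariant)
sample_site <- function(pwm) {
  dg <- strsplit(pwm$degenerate, "")[[1]]
  chars <- vapply(seq_len(pwm$width), function(j) {
    allowed <- match(IUPAC_SETS[[dg[j]]], DNA_BASES)
    p <- pwm$mat[allowed, j]
    DNA_BASES[allowed[sample.int(length(allowed), 1L, prob = p)]]
  }, character(1))
  paste(chars, collapse = "")
}

# regenerate-and-plant loop for one gene x segment class. Returns the
# updated parts plus truth rows (offsets are 0-based within the
# *extracted* segment string, i.e. the string scan_consensus sees).
plant_class <- function(class, parts, specs, avoid, bg, lens, gene, species) {
  part_names <- if (class == "cds") c("cds1", "cds2") else class
  usable_len <- if (class == "cds") nchar(parts$cds1) else
    nchar(parts[[class]])
  extract <- function(p) {
    if (class == "cds") paste(p$cds1, SEGMENT_SPACER, p$cds2, sep = "")
    else p[[class]]
  }
  if (length(specs) == 0L && length(avoid) == 0L)
    return(list(parts = parts, sites = NULL))
  for (attempt in seq_len(200L)) {
    p <- parts
    for (nm in part_names) p[[nm]] <- markov_seq(nchar(parts[[nm]]), bg)
    occupied <- rep(FALSE, usable_len)
    rows <- list()
    ok <- TRUE
    for (spec in specs) {
      w <- spec$pwm$width
      free <- vapply(0:(usable_len - w), function(s)
        !any(occupied[(s + 1L):(s + w)]), logical(1))
      cand <- which(free) - 1L
      if (length(cand) == 0L) { ok <- FALSE; break }
      off <- cand[sample.int(length(cand), 1L)]
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      site <- sample_site(spec$pwm)
      ins <- if (strand == "-") revcomp_chr(site) else site
      target_part <- if (class == "cds") "cds1" else class
      substr(p[[target_part]], off + 1L, off + w) <- ins
      occupied[(off + 1L):(off + w)] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = spec$name, species = species, gene_id = gene,
        segment = class, offset = off, strand = strand,
        stringsAsFactors = FALSE)
    }
    if (!ok) next
    seg_str <- extract(p)
    clean <- TRUE
    for (av in avoid) {
      hits <- scan_consensus(seg_str, av,
                             degenerate = strrep("N", nchar(av)),
                             max_mm = 1L)
      if (nrow(hits) > 0L) { clean <- FALSE; break }
    }
    if (!clean) next
    return(list(parts = p,
                sites = if (length(rows)) do.call(rbind, rows) else NULL))
  }
  stop("could not place planted sites in ", class, " of ", gene,
       " after 200 attempts")
}

#' Generate the synthetic two-species benchmark
#'
#' Produces, per species: a one-chromosome genome FASTA (first-order
#' Markov background with genes laid out on sampled strands), gene
#' models GFF3 (gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR, two
#' exons separated by one intron), and an expression TSV over the time
#' points. A gene's expression is a log-normal per-gene amplitude times
#' (cluster archetype + smooth per-gene deviation for peripheral
#' members + Gaussian measurement noise). Shared files: three priority-ordered ortholog
#' call-set TSVs (with deliberate conflicting and many-to-many records
#' at the configured rates), the planted-site truth table TSV, and a
#' toy PWM library (planted motifs plus decoys) in MEME minimal format.
#'
#' Planted sites are sampled from the motif PWM conditional on its
#' degenerate consensus, placed without overlap at uniform offsets on a
#' uniform strand. Recruited motifs are planted in species A only, and
#' the species-B target segments of C4-gene orthologs are regenerated
#' until they contain no window within one mismatch of the recruited
#' consensus on either strand, so absence in the C3 ortholog holds by
#' construction rather than by chance.
#'
#' @param config a `synth_config`.
#' @param out_dir output directory (created if missing).
#' @return list with `files` (named paths), `exprA`/`exprB` (RPKM
#'   matrices), `truth` (planted-site table), `ortholog_truth` (true
#'   one-to-one pairs), `c4_genes`, `cluster_id` (named true cluster per
#'   species-A gene), `core` (named logical: tight core member),
#'   `segsA`/`segsB` (named lists of `segment_set`),
#'   `library` (list of `pwm_motif`), `planted` (the motif specs),
#'   `config`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  N <- config$n_genes_per_species
  K <- config$n_clusters
  lens <- config$segment_lengths
  cluster_id <- rep(seq_len(K), each = ceiling(N / K))[seq_len(N)]
  genes <- list(A = sprintf("gA%04d", seq_len(N)),
                B = sprintf("gB%04d", seq_len(N)))
  c4_idx <- seq_len(config$n_c4_genes)
  c4_genes <- genes$A[c4_idx]
  bg <- default_background(config$gc)

  hours <- if (config$n_timepoints == 7L) TIMEPOINT_HOURS else
    seq(0, 24, length.out = config$n_timepoints)
  labels <- paste0(hours, "h")

  ## expression matrices: each cluster has a tight "core" (true curve =
  ## archetype; includes the C4 genes and, in species B, their
  ## orthologs) while peripheral members carry a smooth per-gene cubic
  ## deviation of continuously varying amplitude, so target-centred
  ## distance Z-scores have a genuine left tail and co-expression lists
  ## are non-degenerate
  shapes <- archetype_matrix(hours, K)
  is_core <- logical(N)
  for (cc in seq_len(K)) {
    members <- which(cluster_id == cc)
    n_core <- min(length(members),
                  max(2L, ceiling(config$core_fraction * length(members))))
    is_core[members[seq_len(n_core)]] <- TRUE
  }
  is_core[c4_idx] <- TRUE
  ## deviations are cubic curves handled on a dense grid: a cubic
  ## sampled on the grid maps exactly back to hour values through the
  ## pseudo-inverse transfer matrix below
  grid <- seq(0, 24, length.out = 25L)
  gbasis <- cbind(1, stats::poly(grid, degree = 3))
  hbasis <- cbind(1, stats::predict(stats::poly(grid, degree = 3), hours))
  transfer <- hbasis %*% solve(crossprod(gbasis)) %*% t(gbasis)
  shape_grid <- t(apply(shapes, 1, function(v) {
    g <- stats::lm.fit(cbind(1, stats::poly(hours, 3)), v)$coefficients
    drop(cbind(1, stats::predict(stats::poly(hours, 3), grid)) %*% g)
  }))
  expr <- list()
  for (sp in c("A", "B")) {
    set.seed(substream_seed(config$seed, paste0("expr", sp)))
    a <- stats::rlnorm(N, config$amplitude_meanlog, config$amplitude_sdlog)
    eps <- matrix(stats::rnorm(N * length(hours)), N)
    dev_amp <- ifelse(is_core, 0,
                      config$peripheral_sd * stats::runif(N)^0.25 *
                        apply(shape_grid, 1, stats::sd)[cluster_id])
    ## random cubic on the grid, centred and orthogonalised against the
    ## gene's archetype so distance depends only on amplitude
    devg <- matrix(stats::rnorm(N * 3L), N) %*% t(gbasis[, 2:4])
    devg <- sweep(devg, 1, rowMeans(devg))
    sgc <- shape_grid[cluster_id, , drop = FALSE]
    sgc <- sweep(sgc, 1, rowMeans(sgc))
    devg <- devg - sgc * (rowSums(devg * sgc) / rowSums(sgc * sgc))
    devg <- devg * (dev_amp / pmax(apply(devg, 1, stats::sd), 1e-12))
    dev <- devg %*% t(transfer)
    m <- a * (shapes[cluster_id, , drop = FALSE] + dev +
                config$noise_sd * eps)
    m <- pmax(m, 0.001)
    dimnames(m) <- list(genes[[sp]], labels)
    expr[[sp]] <- m
  }

  ## host assignment per planted motif (species-A gene indices)
  set.seed(substream_seed(config$seed, "hosts"))
  hosts <- lapply(config$planted_motifs, function(spec) {
    members <- which(cluster_id == spec$cluster)
    h <- members[stats::runif(length(members)) < spec$host_gene_fraction]
    if (spec$cluster == 1L) h <- union(h, intersect(c4_idx, members))
    sort(h)
  })
  names(hosts) <- vapply(config$planted_motifs, `[[`, character(1), "name")

  ## per-gene segments with planted sites
  lens_parts <- c(promoter = as.integer(lens[["promoter"]]),
                  utr5 = as.integer(lens[["utr5"]]),
                  cds1 = as.integer(ceiling(lens[["cds"]] / 2)),
                  cds2 = as.integer(lens[["cds"]] -
                                      ceiling(lens[["cds"]] / 2)),
                  intron = as.integer(lens[["intron"]]),
                  utr3 = as.integer(lens[["utr3"]]))
  segparts <- list()
  truth <- list()
  for (sp in c("A", "B")) {
    set.seed(substream_seed(config$seed, paste0("segments", sp)))
    sp_parts <- vector("list", N)
    for (i in seq_len(N)) {
      parts <- lapply(lens_parts, function(L) markov_seq(L, bg))
      for (class in SEGMENT_CLASSES) {
        specs <- Filter(function(spec) {
          spec$target_segment == class &&
            i %in% hosts[[spec$name]] &&
            (sp == "A" || !spec$recruited)
        }, config$planted_motifs)
        avoid <- if (sp == "B" && i %in% c4_idx)
          vapply(Filter(function(spec)
            spec$recruited && spec$target_segment == class,
            config$planted_motifs),
            function(spec) spec$pwm$consensus, character(1))
        else character(0)
        res <- plant_class(class, parts, specs, avoid, bg, lens,
                           genes[[sp]][i], sp)
        parts <- res$parts
        if (!is.null(res$sites)) truth[[length(truth) + 1L]] <- res$sites
      }
      sp_parts[[i]] <- parts
    }
    segparts[[sp]] <- sp_parts
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(motif_id = character(0), species = character(0),
               gene_id = character(0), segment = character(0),
               offset = integer(0), strand = character(0))
  rownames(truth) <- NULL

  ## genome assembly + GFF3
  L5 <- lens[["utr5"]]; Lc1 <- lens_parts[["cds1"]]
  Lc2 <- lens_parts[["cds2"]]; Li <- lens[["intron"]]
  L3 <- lens[["utr3"]]; Lp <- lens[["promoter"]]
  Lg <- L5 + Lc1 + Li + Lc2 + L3
  files <- list()
  segsets <- list()
  for (sp in c("A", "B")) {
    set.seed(substream_seed(config$seed, paste0("genome", sp)))
    chrom <- paste0("chr", sp)
    pieces <- character(0)
    gff <- character(0)
    cursor <- 1L
    strands <- ifelse(stats::runif(N) < 0.5, "+", "-")
    sp_sets <- vector("list", N)
    gap <- markov_seq(config$intergenic_bp, bg)
    pieces <- c(pieces, gap); cursor <- cursor + nchar(gap)
    feat <- function(type, s, e, strand, attrs, phase = ".") {
      paste(chrom, "synth", type, sprintf("%d", as.integer(s)),
            sprintf("%d", as.integer(e)), ".", strand, phase, attrs,
            sep = "\t")
    }
    for (i in seq_len(N)) {
      g <- genes[[sp]][i]
      p <- segparts[[sp]][[i]]
      st <- strands[i]
      tid <- paste0(g, ".t1")
      ph2 <- (3L - (Lc1 %% 3L)) %% 3L
      if (st == "+") {
        block <- paste0(p$promoter, p$utr5, p$cds1, p$intron, p$cds2, p$utr3)
        G <- cursor + Lp
        X <- G + L5 + Lc1 + Li
        gff <- c(gff,
          feat("gene", G, G + Lg - 1L, "+", paste0("ID=", g)),
          feat("mRNA", G, G + Lg - 1L, "+",
               paste0("ID=", tid, ";Parent=", g)),
          feat("exon", G, G + L5 + Lc1 - 1L, "+",
               paste0("ID=", tid, ".exon1;Parent=", tid)),
          feat("exon", X, X + Lc2 + L3 - 1L, "+",
               paste0("ID=", tid, ".exon2;Parent=", tid)),
          feat("five_prime_UTR", G, G + L5 - 1L, "+",
               paste0("ID=", tid, ".u5;Parent=", tid)),
          feat("CDS", G + L5, G + L5 + Lc1 - 1L, "+",
               paste0("ID=", tid, ".cds1;Parent=", tid), phase = "0"),
          feat("CDS", X, X + Lc2 - 1L, "+",
               paste0("ID=", tid, ".cds2;Parent=", tid),
               phase = as.character(ph2)),
          feat("three_prime_UTR", X + Lc2, X + Lc2 + L3 - 1L, "+",
               paste0("ID=", tid, ".u3;Parent=", tid)))
      } else {
        block <- paste0(revcomp_chr(p$utr3), revcomp_chr(p$cds2),
                        revcomp_chr(p$intron), revcomp_chr(p$cds1),
                        revcomp_chr(p$utr5), revcomp_chr(p$promoter))
        P <- cursor
        E <- P + Lg - 1L
        Y <- P + L3 + Lc2 + Li
        gff <- c(gff,
          feat("gene", P, E, "-", paste0("ID=", g)),
          feat("mRNA", P, E, "-", paste0("ID=", tid, ";Parent=", g)),
          feat("exon", Y, E, "-",
               paste0("ID=", tid, ".exon1;Parent=", tid)),
          feat("exon", P, P + L3 + Lc2 - 1L, "-",
               paste0("ID=", tid, ".exon2;Parent=", tid)),
          feat("five_prime_UTR", Y + Lc1, E, "-",
               paste0("ID=", tid, ".u5;Parent=", tid)),
          feat("CDS", Y, Y + Lc1 - 1L, "-",
               paste0("ID=", tid, ".cds1;Parent=", tid), phase = "0"),
          feat("CDS", P + L3, P + L3 + Lc2 - 1L, "-",
               paste0("ID=", tid, ".cds2;Parent=", tid),
               phase = as.character(ph2)),
          feat("three_prime_UTR", P, P + L3 - 1L, "-",
               paste0("ID=", tid, ".u3;Parent=", tid)))
      }
      pieces <- c(pieces, block)
      cursor <- cursor + nchar(block)
      gap <- markov_seq(config$intergenic_bp, bg)
      pieces <- c(pieces, gap)
      cursor <- cursor + nchar(gap)
      segs <- c(promoter = p$promoter, utr5 = p$utr5, utr3 = p$utr3,
                cds = paste(p$cds1, SEGMENT_SPACER, p$cds2, sep = ""),
                intron = p$intron)
      sp_sets[[i]] <- structure(
        list(gene = g, strand = st, segments = segs, clipped = FALSE,
             missing = character(0)),
        class = "segment_set")
    }
    names(sp_sets) <- genes[[sp]]
    segsets[[sp]] <- sp_sets
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(pieces, collapse = ""), chrom))
    fa <- file.path(out_dir, paste0("genome", sp, ".fa"))
    Biostrings::writeXStringSet(genome, fa)
    gff_path <- file.path(out_dir, paste0("models", sp, ".gff3"))
    writeLines(c("##gff-version 3", gff), gff_path)
    files[[paste0("genome", sp)]] <- fa
    files[[paste0("models", sp)]] <- gff_path
  }

  ## expression TSVs
  for (sp in c("A", "B")) {
    path <- file.path(out_dir, paste0("expr", sp, ".tsv"))
    df <- data.frame(gene_id = rownames(expr[[sp]]), expr[[sp]],
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[paste0("expr", sp)]] <- path
  }

  ## ortholog call-sets (priority order: bbh basis, then mcl, then inp)
  set.seed(substream_seed(config$seed, "callsets"))
  idx <- seq_len(N)
  make_set <- function(method, coverage, conflict_rate, m2m_rate) {
    keep <- sort(unique(c(c4_idx,
                          sample(idx, round(coverage * N)))))
    df <- data.frame(geneA = genes$A[keep], geneB = genes$B[keep],
                     stringsAsFactors = FALSE)
    non_c4 <- which(!keep %in% c4_idx)
    n_cf <- round(conflict_rate * nrow(df))
    if (n_cf > 0L && length(non_c4) >= n_cf) {
      rows <- sample(non_c4, n_cf)
      for (r in rows) {
        j <- sample(setdiff(idx, keep[r]), 1L)
        df$geneB[r] <- genes$B[j]
      }
    }
    n_mm <- round(m2m_rate * nrow(df))
    if (n_mm > 0L && length(non_c4) >= n_mm) {
      rows <- sample(non_c4, n_mm)
      extra <- data.frame(geneA = df$geneA[rows],
                          geneB = genes$B[sample(idx, length(rows))],
                          stringsAsFactors = FALSE)
      df <- rbind(df, extra)
    }
    df$method <- method
    df$score <- round(stats::runif(nrow(df)), 3)
    df
  }
  sets <- list(bbh = make_set("bbh", 0.85, 0, 0),
               mcl = make_set("mcl", 0.80, config$ortholog_conflict_rate,
                              config$many_to_many_rate),
               inp = make_set("inp", 0.70, config$ortholog_conflict_rate,
                              config$many_to_many_rate))
  callset_paths <- character(0)
  for (nm in names(sets)) {
    path <- file.path(out_dir, paste0("callset_", nm, ".tsv"))
    utils::write.table(sets[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    callset_paths <- c(callset_paths, path)
  }
  files$callsets <- callset_paths

  ## truth table + PWM library
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$truth <- truth_path
  library_pwms <- c(lapply(config$planted_motifs, `[[`, "pwm"),
                    default_decoy_motifs())
  names(library_pwms) <- vapply(library_pwms, `[[`, character(1), "name")
  lib_path <- file.path(out_dir, "library.meme")
  write_meme(library_pwms, lib_path)
  files$library <- lib_path

  list(files = files,
       exprA = expr$A, exprB = expr$B,
       truth = truth,
       ortholog_truth = data.frame(geneA = genes$A, geneB = genes$B,
                                   stringsAsFactors = FALSE),
       c4_genes = c4_genes,
       cluster_id = stats::setNames(cluster_id, genes$A),
       core = stats::setNames(is_core, genes$A),
       segsA = segsets$A, segsB = segsets$B,
       library = library_pwms,
       planted = config$planted_motifs,
       hosts = hosts,
       config = config)
}
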