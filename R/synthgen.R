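# Synthetic-genome generator: multi-chromosome genomes with planted
# non-methylated islands, in two regimes.
#
# The background emulates a vertebrate genome body: a first-order Markov
# chain with ~40% GC and strong CpG depletion (methylated CpGs deaminate,
# so the background carries far fewer CpGs than base composition
# predicts), with GC content drifting across 5 kb blocks the way real
# genomes vary in isochores. A slice of the background consists of
# CpG-rich but methylated "decoy" regions — the classical false-positive
# class that keeps ratio-based island callers imperfect; decoys are part
# of the genome but absent from the NMI annotation. WARM islands emulate
# warm-blooded NMIs: elevated (island-to-island variable) GC, with CpG
# undepleted in most islands but partially depleted in a minority — real
# NMI sets contain CpG-poor members, which is what separates a richer
# sequence model from the bare CpG ratio. COLD islands emulate the
# cold-blooded regime: near-background base composition with only weak
# CpG enrichment, plus embedded AT-rich repeating motifs at
# island-variable density over a background that itself carries sparse
# motif instances (microsatellite-like noise); the signal lives in longer
# k-mers, so short-k classifiers and the CpG ratio degrade while a k >= 6
# spectrum machine does not. The composition parameters are calibrated so
# that trained-model and baseline performance fall in the regime the
# framework targets (high but imperfect AUROC, clearly sub-1 AUPRC), not
# at perfect separation.

#' Specification of a synthetic genome
#'
#' @param n_chrom Number of chromosomes (default 10).
#' @param chrom_length Length of each chromosome in bp (scalar or vector;
#'   default 5e5, i.e. a 5 Mb genome at the defaults).
#' @param gc Mean background GC content (default 0.40).
#' @param gc_sd Standard deviation of per-block background GC (default
#'   0.05; blocks of `block_len` bp emulate isochore-scale variation).
#' @param block_len Background composition block length in bp (default
#'   5000).
#' @param cpg_depletion Multiplier on the background C->G transition
#'   relative to independence (default 0.2, a ~5-fold CpG depletion).
#' @param island_model `"warm"` or `"cold"`.
#' @param decoy_coverage Fraction of the genome covered by CpG-rich
#'   methylated decoy regions (default 0.02). Decoys share the NMI length
#'   distribution but are background (label -1): they emulate the
#'   methylated CpG islands that ratio-based callers report as false
#'   positives.
#' @param decoy_gc,decoy_cpg Decoy composition (defaults 0.52 and 0.9:
#'   clearly CpG-enriched, but less GC-rich than warm NMIs).
#' @param nmi_coverage Fraction of the genome covered by planted NMIs
#'   (default 0.028; vertebrate NMIs occupy roughly 2-4% of the genome,
#'   and this value puts the held-out 750 bp window prevalence near 1.5%
#'   after border exclusion and coverage labeling).
#' @param nmi_length Two-element range of island lengths, sampled
#'   uniformly (default c(750, 3000) so most islands exceed the 750 bp
#'   window width).
#' @param min_gap Minimum distance between islands and to chromosome ends
#'   (default 2000 bp, so 500 bp border-exclusion zones never touch).
#' @param warm_gc Mean GC content inside WARM islands (default 0.65).
#' @param warm_gc_sd Island-to-island GC standard deviation (default
#'   0.04).
#' @param warm_cpg CpG multiplier inside typical WARM islands (default
#'   1.2: mildly enriched beyond independence).
#' @param warm_cpg_poor Range of the CpG multiplier for the CpG-poor
#'   island minority (default c(0.3, 0.5)): still GC-rich, but with an
#'   observed/expected CpG ratio overlapping the background tail.
#' @param warm_poor_frac Fraction of WARM islands drawn from the CpG-poor
#'   minority (default 0.25).
#' @param cold_cpg CpG multiplier inside COLD islands (default 0.3: only a
#'   modest enrichment over the 0.2 background).
#' @param cold_motifs Character vector of AT-patterned repeating motifs
#'   embedded in COLD islands.
#' @param motif_density Mean fraction of COLD island bases covered by
#'   motif instances (default 0.10; per-island density is drawn uniformly
#'   from 0.5 to 1.5 times this value).
#' @param bg_motif_density Fraction of COLD background bases covered by
#'   sparse motif instances (default 0.01), emulating microsatellite-like
#'   repeats outside islands.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chrom = 10,
                           chrom_length = 5e5,
                           gc = 0.40,
                           gc_sd = 0.05,
                           block_len = 5000,
                           cpg_depletion = 0.2,
                           island_model = c("warm", "cold"),
                           nmi_coverage = 0.028,
                           nmi_length = c(750, 3000),
                           min_gap = 2000,
                           decoy_coverage = 0.02,
                           decoy_gc = 0.52,
                           decoy_cpg = 0.9,
                           warm_gc = 0.65,
                           warm_gc_sd = 0.04,
                           warm_cpg = 1.2,
                           warm_cpg_poor = c(0.3, 0.5),
                           warm_poor_frac = 0.25,
                           cold_cpg = 0.3,
                           cold_motifs = c("TGTGTGTGTGTG",
                                           "ATCTATATCTAT",
                                           "TATTTGTATTTG",
                                           "ATGTATATGTAT",
                                           "TTTGCATTTGCA"),
                           motif_density = 0.10,
                           bg_motif_density = 0.01) {
  island_model <- match.arg(island_model)
  chrom_length <- rep_len(chrom_length, n_chrom)
  stopifnot(n_chrom >= 2, all(chrom_length > 0),
            gc > 0, gc < 1, gc_sd >= 0, block_len >= 1000,
            cpg_depletion > 0, decoy_coverage >= 0,
            length(nmi_length) == 2, nmi_length[1] <= nmi_length[2],
            min_gap > 500, motif_density >= 0, motif_density < 0.5,
            bg_motif_density >= 0, bg_motif_density < 0.5)
  if (nmi_coverage <= 0) stop("nmi_coverage must be positive")
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_length = as.numeric(chrom_length),
                 gc = gc, gc_sd = gc_sd, block_len = as.numeric(block_len),
                 cpg_depletion = cpg_depletion,
                 island_model = island_model,
                 nmi_coverage = nmi_coverage,
                 nmi_length = as.numeric(nmi_length),
                 min_gap = as.numeric(min_gap),
                 decoy_coverage = decoy_coverage,
                 decoy_gc = decoy_gc, decoy_cpg = decoy_cpg,
                 warm_gc = warm_gc, warm_gc_sd = warm_gc_sd,
                 warm_cpg = warm_cpg,
                 warm_cpg_poor = as.numeric(warm_cpg_poor),
                 warm_poor_frac = warm_poor_frac,
                 cold_cpg = cold_cpg, cold_motifs = toupper(cold_motifs),
                 motif_density = motif_density,
                 bg_motif_density = bg_motif_density),
            class = "synthetic_spec")
}

# First-order transition matrix: independence rows from base composition,
# with the C->G entry multiplied by cpg_factor and the C row renormalized.
make_transition <- function(gc, cpg_factor = 1) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  tm <- matrix(rep(p, times = 4), nrow = 4, byrow = TRUE,
               dimnames = list(names(p), names(p)))
  tm["C", "G"] <- tm["C", "G"] * cpg_factor
  tm["C", ] <- tm["C", ] / sum(tm["C", ])
  tm
}

.codes_to_string <- function(codes) {
  intToUtf8(c(65L, 67L, 71L, 84L)[codes + 1L])
}

# Place m intervals of the given lengths on [0, L) with at least `gap`
# between them and to both ends; stick-breaking over the free slack.
.place_intervals <- function(L, lengths, gap) {
  m <- length(lengths)
  if (m == 0L) return(numeric(0))
  slack <- L - sum(lengths) - (m + 1) * gap
  if (slack < 0) {
    stop("requested NMI coverage does not fit the chromosome at min_gap")
  }
  u <- sort(stats::runif(m))
  extra <- diff(c(0, u, 1)) * slack
  starts <- numeric(m)
  pos <- 0
  for (i in seq_len(m)) {
    pos <- pos + gap + extra[i]
    starts[i] <- pos
    pos <- pos + lengths[i]
  }
  floor(starts)
}

#' Generate a synthetic genome with planted NMIs
#'
#' Fully seeded and reproducible: the same spec and seed give a
#' byte-identical genome and island set. Planted island coordinates are
#' returned exactly as written into the sequence.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed.
#' @return List with `genome` (a `DNAStringSet`), `nmis` (regions
#'   data.frame of the planted islands), `decoys` (regions data.frame of
#'   the planted CpG-rich non-NMI regions), and `spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_chrom = 2, chrom_length = 5e4)
#' g <- generate_synthetic_genome(spec, seed = 1)
generate_synthetic_genome <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  G <- sum(spec$chrom_length)
  mean_len <- mean(spec$nmi_length)
  n_nmi <- round(spec$nmi_coverage * G / mean_len)
  if (n_nmi < 1) {
    stop("nmi_coverage times genome length is too small for even one NMI")
  }
  n_decoy <- round(spec$decoy_coverage * G / mean_len)
  bg_init <- rep(0.25, 4)

  # composition of one planted region, drawn per region
  region_trans <- function(type) {
    if (type == "decoy") {
      make_transition(spec$decoy_gc, spec$decoy_cpg)
    } else if (spec$island_model == "warm") {
      gc <- min(0.72, max(0.52, stats::rnorm(1, spec$warm_gc,
                                             spec$warm_gc_sd)))
      cpg <- if (stats::runif(1) < spec$warm_poor_frac) {
        stats::runif(1, spec$warm_cpg_poor[1], spec$warm_cpg_poor[2])
      } else {
        spec$warm_cpg
      }
      make_transition(gc, cpg)
    } else {
      make_transition(spec$gc, spec$cold_cpg)
    }
  }

  with_seed(seed, {
    chrom_names <- paste0("chr", seq_len(spec$n_chrom))
    # planted regions per chromosome, proportional to length
    n_regions <- n_nmi + n_decoy
    type <- sample(c(rep("nmi", n_nmi), rep("decoy", n_decoy)))
    owner <- sample(seq_len(spec$n_chrom), n_regions, replace = TRUE,
                    prob = spec$chrom_length / G)
    seqs <- character(spec$n_chrom)
    nmi_rows <- vector("list", spec$n_chrom)
    decoy_rows <- vector("list", spec$n_chrom)
    for (ci in seq_len(spec$n_chrom)) {
      L <- spec$chrom_length[ci]
      codes <- .sample_background(L, spec)
      mine <- which(owner == ci)
      if (length(mine) > 0) {
        lens <- round(stats::runif(length(mine), spec$nmi_length[1],
                                   spec$nmi_length[2]))
        starts <- .place_intervals(L, lens, spec$min_gap)
        for (j in seq_along(mine)) {
          ty <- type[mine[j]]
          icodes <- .markov_sample_codes(as.integer(lens[j]),
                                         region_trans(ty), bg_init)
          if (ty == "nmi" && spec$island_model == "cold" &&
                spec$motif_density > 0) {
            dens <- stats::runif(1, 0.5, 1.5) * spec$motif_density
            icodes <- .embed_motifs(icodes, spec$cold_motifs, dens)
          }
          codes[(starts[j] + 1):(starts[j] + lens[j])] <- icodes
        }
        is_nmi <- type[mine] == "nmi"
        if (any(is_nmi)) {
          nmi_rows[[ci]] <- data.frame(chrom = chrom_names[ci],
                                       start = starts[is_nmi],
                                       end = starts[is_nmi] + lens[is_nmi],
                                       stringsAsFactors = FALSE)
        }
        if (any(!is_nmi)) {
          decoy_rows[[ci]] <- data.frame(chrom = chrom_names[ci],
                                         start = starts[!is_nmi],
                                         end = starts[!is_nmi] + lens[!is_nmi],
                                         stringsAsFactors = FALSE)
        }
      }
      seqs[ci] <- .codes_to_string(codes)
    }
    genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chrom_names))
    sort_rows <- function(rows) {
      d <- do.call(rbind, rows)
      if (is.null(d)) return(.empty_regions())
      d <- d[order(d$chrom, d$start), , drop = FALSE]
      rownames(d) <- NULL
      d
    }
    list(genome = genome, nmis = sort_rows(nmi_rows),
         decoys = sort_rows(decoy_rows), spec = spec)
  })
}

# Background chromosome: blockwise first-order Markov with per-block GC
# drawn around the genome mean; for the cold regime, sparse motif
# instances are scattered over the background before islands overwrite it.
.sample_background <- function(L, spec) {
  bg_init <- rep(0.25, 4)
  n_blocks <- ceiling(L / spec$block_len)
  sizes <- rep(spec$block_len, n_blocks)
  sizes[n_blocks] <- L - (n_blocks - 1) * spec$block_len
  gcs <- pmin(0.55, pmax(0.28, stats::rnorm(n_blocks, spec$gc, spec$gc_sd)))
  parts <- lapply(seq_len(n_blocks), function(b) {
    .markov_sample_codes(as.integer(sizes[b]),
                         make_transition(gcs[b], spec$cpg_depletion),
                         bg_init)
  })
  codes <- unlist(parts, use.names = FALSE)
  if (spec$island_model == "cold" && spec$bg_motif_density > 0) {
    codes <- .embed_motifs(codes, spec$cold_motifs, spec$bg_motif_density)
  }
  codes
}

# Overwrite island codes with motif instances at random non-overlapping
# positions until ~density of the island bases carry motif sequence.
.embed_motifs <- function(codes, motifs, density) {
  L <- length(codes)
  mlens <- nchar(motifs)
  n_inst <- floor(density * L / mean(mlens))
  if (n_inst < 1L) return(codes)
  pick <- sample(seq_along(motifs), n_inst, replace = TRUE)
  lens <- mlens[pick]
  slack <- L - sum(lens)
  if (slack < 0) {
    keep <- cumsum(lens) <= L
    pick <- pick[keep]
    lens <- lens[keep]
    slack <- L - sum(lens)
    if (length(pick) == 0L) return(codes)
  }
  u <- sort(stats::runif(length(pick)))
  extra <- diff(c(0, u)) * slack
  pos <- 0
  for (i in seq_along(pick)) {
    pos <- pos + extra[i]
    s <- floor(pos)
    mcodes <- seq_to_codes(motifs[pick[i]])
    codes[(s + 1):(s + lens[i])] <- mcodes
    pos <- pos + lens[i]
  }
  codes
}

#' Diagnostics for a generated genome
#'
#' Reports realized island coverage and the composition contrasts between
#' island and background sequence: GC content, observed/expected CpG
#' ratio, and target-motif frequency per kb. Contrasts are flagged
#' "strong" (ratio >= 3) or "weak"; a WARM genome should show a strong
#' CpG-ratio contrast and weak motif contrast, a COLD genome the reverse.
#' Spec violations (realized coverage off by more than 20%) are flagged.
#'
#' @param genome,nmis A generated pair.
#' @param spec The [synthetic_spec()] used.
#' @param n_background Number of background windows sampled for the
#'   contrast estimates (default 200).
#' @param seed Seed for background sampling.
#' @return List of class `synth_validation` with coverage, contrast and
#'   flag fields.
#' @export
validate_synthetic <- function(genome, nmis, spec, n_background = 200,
                               seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  G <- sum(Biostrings::width(genome))
  coverage <- regions_total_length(nmis) / G
  island_seqs <- region_sequences(genome, nmis)
  # background windows: tile outside the islands, sample a subset
  bg_region <- complement_regions(merge_regions(nmis), genome)
  bg <- tile_windows(bg_region, genome, width = 750, max_n_frac = 1)
  if (nrow(bg) > n_background) {
    bg <- bg[with_seed(seed, sample.int(nrow(bg), n_background)), ,
             drop = FALSE]
  }
  stat <- function(seqs, f) mean(vapply(seqs, f, numeric(1)))
  motif_rate <- function(seqs) {
    hits <- vapply(seqs, function(s) {
      sum(vapply(spec$cold_motifs, function(m) {
        g <- gregexpr(m, s, fixed = TRUE)[[1]]
        if (g[1] == -1L) 0 else length(g)
      }, numeric(1)))
    }, numeric(1))
    1000 * sum(hits) / sum(nchar(seqs))
  }
  res <- list(
    island_model = spec$island_model,
    requested_coverage = spec$nmi_coverage,
    realized_coverage = coverage,
    n_nmis = nrow(nmis),
    gc_island = stat(island_seqs, gc_fraction),
    gc_background = stat(bg$seq, gc_fraction),
    cpg_ratio_island = stat(island_seqs, cpg_obs_exp_ratio),
    cpg_ratio_background = stat(bg$seq, cpg_obs_exp_ratio),
    motif_per_kb_island = motif_rate(island_seqs),
    motif_per_kb_background = motif_rate(bg$seq)
  )
  res$cpg_contrast <- res$cpg_ratio_island /
    max(res$cpg_ratio_background, 1e-9)
  res$motif_contrast <- res$motif_per_kb_island /
    max(res$motif_per_kb_background, 1e-3)
  res$cpg_contrast_label <- if (res$cpg_contrast >= 3) "strong" else "weak"
  res$motif_contrast_label <- if (res$motif_contrast >= 3) "strong" else "weak"
  res$coverage_ok <- abs(coverage - spec$nmi_coverage) <=
    0.2 * spec$nmi_coverage
  class(res) <- "synth_validation"
  res
}

#' Print a synth_validation report
#' @param x A `synth_validation`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.synth_validation <- function(x, ...) {
  cat("Synthetic genome validation (", x$island_model, " islands)\n", sep = "")
  cat(sprintf("  coverage: realized %.4f vs requested %.4f [%s]\n",
              x$realized_coverage, x$requested_coverage,
              if (x$coverage_ok) "ok" else "VIOLATION"))
  cat(sprintf("  GC: island %.3f vs background %.3f\n",
              x$gc_island, x$gc_background))
  cat(sprintf("  CpG obs/exp: island %.3f vs background %.3f (%s)\n",
              x$cpg_ratio_island, x$cpg_ratio_background,
              x$cpg_contrast_label))
  cat(sprintf("  motifs/kb: island %.2f vs background %.2f (%s)\n",
              x$motif_per_kb_island, x$motif_per_kb_background,
              x$motif_contrast_label))
  invisible(x)
}
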