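# Genome preprocessing: from (genome, NMI annotation, optional mappability
# mask) to labeled fixed-width training windows.
#
# Window sets are data.frames with columns chrom/start/end (0-based
# half-open), seq (the window sequence) and, after labeling, label (+1 for
# NMI windows, -1 for background).

#' Build the analysis region for window tiling
#'
#' Starts from the uniquely-mappable region (the whole genome when no mask
#' is supplied), then removes a `border_bp`-wide zone centered at each NMI
#' border. Sequencing-based NMI calls locate borders only approximately, so
#' windows straddling a border would carry uncertain labels; excising the
#' border neighbourhood keeps both classes clean.
#'
#' @param genome A `DNAStringSet`.
#' @param nmis Regions data.frame of true NMIs.
#' @param mask Optional regions data.frame of uniquely mappable regions.
#' @param border_bp Width of the exclusion zone centered at each NMI border
#'   (even; default 500, i.e. 250 bp to each side).
#' @return Regions data.frame of the retained analysis region.
#' @export
build_analysis_region <- function(genome, nmis, mask = NULL, border_bp = 500) {
  stopifnot(border_bp >= 0, border_bp %% 2 == 0)
  sl <- .genome_seqlengths(genome)
  if (nrow(nmis) > 0L && !all(nmis$chrom %in% names(sl))) {
    stop("NMI on chromosome absent from genome: ",
         setdiff(unique(nmis$chrom), names(sl))[1])
  }
  base <- regions(names(sl), rep(0, length(sl)), as.numeric(sl))
  if (!is.null(mask) && nrow(mask) > 0L) {
    base <- intersect_regions(base, mask)
  }
  if (nrow(nmis) == 0L || border_bp == 0) return(merge_regions(base))
  half <- border_bp / 2
  borders <- c(nmis$start, nmis$end)
  chroms <- c(nmis$chrom, nmis$chrom)
  zs <- pmax(0, borders - half)
  ze <- pmin(as.numeric(sl[chroms]), borders + half)
  keep <- zs < ze
  zones <- regions(chroms[keep], zs[keep], ze[keep])
  subtract_regions(base, zones)
}

#' Tile a region into fixed-width windows
#'
#' Each maximal sub-region is tiled left-to-right without overlap; trailing
#' fragments shorter than `width` are discarded, as are windows whose
#' N-base fraction exceeds `max_n_frac` (assembly gaps distort the k-mer
#' spectrum).
#'
#' @param region Regions data.frame (will be normalized).
#' @param genome A `DNAStringSet` supplying sequence.
#' @param width Window width in bp (default 750).
#' @param max_n_frac Maximum tolerated fraction of N bases (default 0.1).
#' @return Window data.frame with columns chrom/start/end/seq.
#' @export
tile_windows <- function(region, genome, width = 750, max_n_frac = 0.1) {
  stopifnot(width > 0)
  region <- merge_regions(region)
  if (nrow(region) == 0L) {
    return(cbind(.empty_regions(), data.frame(seq = character())))
  }
  nw <- (region$end - region$start) %/% width
  keep <- nw > 0
  region <- region[keep, , drop = FALSE]
  nw <- nw[keep]
  if (nrow(region) == 0L) {
    return(cbind(.empty_regions(), data.frame(seq = character())))
  }
  idx <- rep(seq_len(nrow(region)), nw)
  off <- unlist(lapply(nw, function(m) width * (seq_len(m) - 1)), use.names = FALSE)
  win <- data.frame(chrom = region$chrom[idx],
                    start = region$start[idx] + off,
                    stringsAsFactors = FALSE)
  win$end <- win$start + width
  win <- win[order(win$chrom, win$start), , drop = FALSE]
  rownames(win) <- NULL
  win$seq <- region_sequences(genome, win)
  if (max_n_frac < 1) {
    nfrac <- .count_char_n(win$seq) / width
    win <- win[nfrac <= max_n_frac, , drop = FALSE]
    rownames(win) <- NULL
  }
  win
}

.count_char_n <- function(seqs) {
  if (length(seqs) == 0L) return(integer(0))
  ss <- Biostrings::DNAStringSet(seqs)
  as.integer(Biostrings::letterFrequency(ss, "N"))
}

#' Label windows by NMI coverage
#'
#' A window is labeled +1 (NMI) iff at least `min_frac` of its length is
#' covered by an NMI interval, else -1; the boundary case (exactly
#' `min_frac`) counts as positive.
#'
#' @param windows Window data.frame.
#' @param nmis Regions data.frame of true NMIs.
#' @param min_frac Minimum covered fraction for a positive label (default 0.5).
#' @return The window data.frame with an integer `label` column in {-1, +1}.
#' @export
label_windows <- function(windows, nmis, min_frac = 0.5) {
  stopifnot(min_frac > 0, min_frac <= 1)
  if (nrow(windows) == 0L) {
    windows$label <- integer(0)
    return(windows)
  }
  ov <- region_overlap_length(windows, nmis)
  frac <- ov / (windows$end - windows$start)
  windows$label <- ifelse(frac >= min_frac, 1L, -1L)
  windows
}

#' Assign chromosomes to a held-out test side
#'
#' Chromosomes are visited in seeded random order and accumulated into the
#' test side until the accumulated analysis-region length first reaches
#' `test_frac` of the total; the rest are the train side. Splitting at
#' chromosome granularity keeps training and test windows on disjoint
#' chromosomes.
#'
#' @param genome A `DNAStringSet` (>= 2 chromosomes).
#' @param region Analysis region used to weigh chromosomes.
#' @param test_frac Target fraction of analysis-region length on the test
#'   side (default 0.5).
#' @param seed Seed for the random chromosome order.
#' @return List with `test_chroms`, `train_chroms` and `seed`.
#' @export
split_chromosomes <- function(genome, region, test_frac = 0.5, seed = 1) {
  chroms <- names(genome)
  if (length(chroms) < 2L) stop("cannot split a single-chromosome genome")
  stopifnot(test_frac > 0)
  m <- merge_regions(region)
  len <- vapply(chroms, function(ch) {
    sum(m$end[m$chrom == ch] - m$start[m$chrom == ch])
  }, numeric(1))
  total <- sum(len)
  ord <- with_seed(seed, sample(chroms))
  cum <- cumsum(len[ord])
  n_test <- which(cum >= test_frac * total)[1]
  if (is.na(n_test)) n_test <- length(chroms)
  if (n_test >= length(chroms)) {
    stop("test_frac leaves no training chromosomes")
  }
  list(test_chroms = sort(ord[seq_len(n_test)]),
       train_chroms = sort(ord[-seq_len(n_test)]),
       seed = seed)
}

#' Partition windows into tuning and training sets
#'
#' Seeded uniform partition without replacement: `floor(frac * n)` windows
#' go to the tuning set, the rest to training; disjoint and exhaustive.
#'
#' @param windows Window data.frame.
#' @param frac Fraction assigned to the tuning set (default 0.5).
#' @param seed Seed.
#' @return List with `tuning` and `training` window data.frames.
#' @export
split_tuning_training <- function(windows, frac = 0.5, seed = 1) {
  stopifnot(frac > 0, frac < 1)
  n <- nrow(windows)
  n_tune <- floor(frac * n)
  idx <- with_seed(seed, sample.int(n, n_tune))
  tuning <- windows[sort(idx), , drop = FALSE]
  training <- windows[setdiff(seq_len(n), idx), , drop = FALSE]
  rownames(tuning) <- rownames(training) <- NULL
  list(tuning = tuning, training = training)
}

#' Subsample windows to a fixed size and class ratio
#'
#' Draws exactly `total * ratio / (ratio + 1)` negatives and
#' `total / (ratio + 1)` positives uniformly without replacement. When
#' fewer positives are available, all positives are taken and the negative
#' count is scaled down to preserve the ratio (with a warning); likewise if
#' negatives then run short.
#'
#' @param windows Labeled window data.frame.
#' @param total Target total window count (default 30000); must be
#'   divisible by `ratio + 1`.
#' @param ratio Background:NMI ratio (default 5).
#' @param seed Seed.
#' @return Subsampled labeled window data.frame.
#' @export
subsample_balanced <- function(windows, total = 30000, ratio = 5, seed = 1) {
  stopifnot(total > 0, ratio >= 1, total %% (ratio + 1) == 0)
  pos <- which(windows$label == 1L)
  neg <- which(windows$label == -1L)
  if (length(pos) == 0L) stop("no positive windows to subsample from")
  n_pos <- total %/% (ratio + 1)
  if (length(pos) < n_pos) {
    warning("only ", length(pos), " positive windows available; ",
            "scaling subsample down at the requested ratio")
    n_pos <- length(pos)
  }
  n_neg <- ratio * n_pos
  if (length(neg) < n_neg) {
    warning("only ", length(neg), " negative windows available; ",
            "scaling subsample down at the requested ratio")
    n_pos <- max(1L, length(neg) %/% ratio)
    n_neg <- ratio * n_pos
  }
  seeds <- derive_seeds(seed, c("pos", "neg"))
  take_pos <- with_seed(seeds[["pos"]], sample(pos, n_pos))
  take_neg <- with_seed(seeds[["neg"]], sample(neg, n_neg))
  out <- windows[sort(c(take_pos, take_neg)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export windows as BED6
#'
#' The BED score column carries the class label (or a supplied score); the
#' name column indexes the windows.
#'
#' @param windows Window data.frame (labeled or scored).
#' @param path Output path.
#' @param score Optional numeric vector overriding the score column.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path, score = NULL) {
  score <- score %||% windows$score %||% windows$label %||%
    rep(0, nrow(windows))
  out <- data.frame(chrom = windows$chrom,
                    start = windows$start,
                    end = windows$end,
                    name = paste0("win", seq_len(nrow(windows))),
                    score = score,
                    strand = ".",
                    stringsAsFactors = FALSE)
  write_bed(out, path)
}
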