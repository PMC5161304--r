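# Classical CpG-island baselines: the observed/expected CpG ratio, the
# Gardiner-Garden & Frommer predicate, and the UCSC running-score island
# caller. These are the comparison scorers the SVM is measured against.

.seq_base_counts <- function(sequence) {
  codes <- seq_to_codes(sequence)
  L <- sum(!is.na(codes)) # non-N length
  nc <- sum(codes == 1L, na.rm = TRUE)
  ng <- sum(codes == 2L, na.rm = TRUE)
  n <- length(codes)
  ncg <- if (n >= 2L) {
    sum(codes[-n] == 1L & codes[-1L] == 2L, na.rm = TRUE)
  } else 0L
  list(L = L, nc = nc, ng = ng, ncg = ncg)
}

#' Observed/expected CpG ratio of a sequence
#'
#' `(n_CpG * L) / (n_C * n_G)` where `L` is the sequence length excluding
#' N bases; returns 0 when the sequence has no C or no G. CpG depletion by
#' deamination of methylated cytosines makes this ratio the classical
#' proxy for non-methylated regions.
#'
#' @param sequence Non-empty sequence string.
#' @return Non-negative numeric scalar.
#' @export
#' @examples
#' cpg_obs_exp_ratio("CGCG") # 2
cpg_obs_exp_ratio <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  s <- .seq_base_counts(sequence)
  if (s$nc == 0L || s$ng == 0L) return(0)
  # numeric arithmetic: counts on Mb-scale sequences overflow integers
  (as.numeric(s$ncg) * s$L) / (as.numeric(s$nc) * s$ng)
}

#' GC fraction of a sequence
#'
#' `(n_C + n_G) / L` over non-N bases.
#'
#' @param sequence Non-empty sequence string.
#' @return Numeric in \[0, 1\].
#' @export
gc_fraction <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  s <- .seq_base_counts(sequence)
  if (s$L == 0L) stop("all-N sequence has no defined GC fraction")
  (s$nc + s$ng) / s$L
}

#' Score windows by observed/expected CpG ratio
#'
#' The CpG-ratio genome-wide classifier: each window's score is its
#' observed/expected CpG ratio. The conventional classification cutoff is
#' 0.6 (the Gardiner-Garden & Frommer threshold).
#'
#' @param windows Window data.frame with a `seq` column.
#' @return The window data.frame with a numeric `score` column.
#' @export
score_windows_cpg_ratio <- function(windows) {
  windows$score <- vapply(windows$seq, cpg_obs_exp_ratio, numeric(1),
                          USE.NAMES = FALSE)
  windows
}

#' Gardiner-Garden & Frommer island predicate
#'
#' TRUE iff the sequence, taken as one region, satisfies all three strict
#' criteria: length > 200 bp, GC content > 50%, observed/expected CpG
#' ratio > 0.6.
#'
#' @param sequence Sequence string.
#' @return Logical scalar.
#' @export
ggf_predicate <- function(sequence) {
  if (!nzchar(sequence)) return(FALSE)
  nchar(sequence) > 200 &&
    gc_fraction(sequence) > 0.5 &&
    cpg_obs_exp_ratio(sequence) > 0.6
}

# Running-score contributions: +17 at the C of each CpG (the dinucleotide
# is one scoring event consuming both bases, so its G contributes 0), -1
# for every other base including N.
.running_contrib <- function(codes) {
  n <- length(codes)
  contrib <- rep(-1, n)
  if (n >= 2L) {
    cg <- which(codes[-n] == 1L & codes[-1L] == 2L)
    contrib[cg] <- 17
    contrib[cg + 1L] <- 0
  }
  contrib
}

#' UCSC-style CpG island caller
#'
#' Reimplementation of the running-score variant of the Gardiner-Garden &
#' Frommer method used for the UCSC Genome Browser island track. Scanning
#' left to right, each CpG adds 17 (consuming both bases) and every other
#' base subtracts 1. A candidate starts at a CpG and extends while the
#' running score stays above 0, then is trimmed back to the rightmost
#' running-score maximum (so trailing score-positive flanks never inflate
#' a call). Each candidate meeting all three thresholds (length >= 200 bp,
#' GC >= 0.5, observed/expected >= 0.6) is emitted; otherwise it is cut at
#' the leftmost position of maximum running score and each half is
#' re-evaluated recursively, stopping below 200 bp.
#'
#' @param sequence Chromosome sequence string.
#' @param chrom Optional chromosome name attached to the output.
#' @return data.frame of island calls with columns chrom (if given),
#'   start/end (0-based half-open), length, gc_fraction, obs_exp_ratio,
#'   max_running_score, cpg_count; ordered by start.
#' @export
#' @examples
#' ucsc_island_scan(strrep("CG", 150))
ucsc_island_scan <- function(sequence, chrom = NULL) {
  codes <- seq_to_codes(sequence)
  contrib <- .running_contrib(codes)
  n <- length(codes)
  cg_start <- which(contrib == 17)
  calls <- list()

  eval_candidate <- function(from, to) {
    # from/to are 1-based inclusive positions within the sequence
    len <- to - from + 1L
    if (len < 200L) return(NULL)
    sl <- codes[from:to]
    L <- sum(!is.na(sl))
    nc <- sum(sl == 1L, na.rm = TRUE)
    ng <- sum(sl == 2L, na.rm = TRUE)
    ncg <- sum(sl[-length(sl)] == 1L & sl[-1L] == 2L, na.rm = TRUE)
    gc <- if (L > 0) (nc + ng) / L else 0
    oe <- if (nc > 0 && ng > 0) (as.numeric(ncg) * L) / (as.numeric(nc) * ng) else 0
    cs <- cumsum(contrib[from:to])
    if (len >= 200L && gc >= 0.5 && oe >= 0.6) {
      return(data.frame(start = from - 1L, end = to, length = len,
                        gc_fraction = gc, obs_exp_ratio = oe,
                        max_running_score = max(cs), cpg_count = ncg))
    }
    # split at the leftmost maximum of the running score
    m <- which.max(cs)
    if (m >= len) m <- len - 1L
    if (m < 1L) return(NULL)
    rbind(eval_candidate(from, from + m - 1L),
          eval_candidate(from + m, to))
  }

  ptr <- 1L
  while (ptr <= length(cg_start)) {
    s <- cg_start[ptr]
    # extend while the cumulative score from s stays > 0 (chunked scan)
    base <- 0
    pos <- s
    stop_at <- NA_integer_
    while (is.na(stop_at) && pos <= n) {
      hi <- min(n, pos + 8191L)
      cs <- base + cumsum(contrib[pos:hi])
      z <- which(cs <= 0)
      if (length(z) > 0L) {
        stop_at <- pos + z[1L] - 1L
      } else {
        base <- cs[length(cs)]
        pos <- hi + 1L
      }
    }
    raw_end <- if (is.na(stop_at)) n else stop_at - 1L
    # trim to the rightmost running-score maximum; a maximum is always
    # attained at the C of a CpG, so include its G
    cs <- cumsum(contrib[s:raw_end])
    m <- s + max(which(cs == max(cs))) - 1L
    cand_end <- if ((m + 1L) <= raw_end && contrib[m] == 17) m + 1L else m
    res <- eval_candidate(s, cand_end)
    if (!is.null(res)) calls[[length(calls) + 1L]] <- res
    # resume after the end of the raw segment
    nxt <- raw_end + 1L
    while (ptr <= length(cg_start) && cg_start[ptr] < nxt) ptr <- ptr + 1L
  }

  out <- if (length(calls) == 0L) {
    data.frame(start = integer(), end = integer(), length = integer(),
               gc_fraction = numeric(), obs_exp_ratio = numeric(),
               max_running_score = numeric(), cpg_count = integer())
  } else {
    do.call(rbind, calls)
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(chrom)) {
    out <- cbind(chrom = rep(chrom, nrow(out)), out,
                 stringsAsFactors = FALSE)
  }
  out
}

#' Call CpG islands genome-wide
#'
#' Runs [ucsc_island_scan()] on every chromosome and concatenates the
#' calls.
#'
#' @param genome A `DNAStringSet`.
#' @param chroms Optional subset of chromosome names.
#' @return data.frame of island calls with a `chrom` column.
#' @export
ucsc_islands_genome <- function(genome, chroms = names(genome)) {
  res <- lapply(chroms, function(ch) {
    ucsc_island_scan(as.character(genome[[ch]]), chrom = ch)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export island calls as BED4
#'
#' Name column is "CpG:<count>", mirroring the browser track convention.
#'
#' @param calls Island call data.frame from [ucsc_islands_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom, start = calls$start,
                    end = calls$end,
                    name = paste0("CpG:", calls$cpg_count),
                    stringsAsFactors = FALSE)
  write_bed(out, path)
}
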