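# Genomes and genomic interval sets.
#
# A genome is a Biostrings::DNAStringSet with unique chromosome names over
# the alphabet {A,C,G,T,N}. Interval sets ("regions") are plain data.frames
# with columns chrom/start/end in 0-based half-open BED coordinates — the
# distribution format of NMI sets — and are converted to GRanges internally
# for arithmetic. Chromosome names are matched exactly (no "chr" aliasing).

#' Construct a region set
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open (BED convention);
#'   `start < end` is required.
#' @return A data.frame with columns `chrom`, `start`, `end`, sorted by
#'   chromosome then start.
#' @export
#' @examples
#' regions("chr1", 10, 20)
regions <- function(chrom = character(), start = integer(), end = integer()) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start < 0)) stop("region start must be non-negative")
  if (any(start >= end)) stop("region start must be < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

.empty_regions <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

#' Convert regions to/from GRanges
#'
#' Regions are 0-based half-open; GRanges are 1-based closed. These two
#' helpers are the only place the conversion happens.
#'
#' @param x A regions data.frame (for `regions_to_granges`) or a
#'   `GenomicRanges::GRanges` (for `granges_to_regions`).
#' @param seqlengths Optional named vector of chromosome lengths.
#' @return A `GRanges`, or a regions data.frame.
#' @export
regions_to_granges <- function(x, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' @rdname regions_to_granges
#' @export
granges_to_regions <- function(x) {
  if (length(x) == 0L) return(.empty_regions())
  x <- GenomicRanges::sort(x)
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
             start = GenomicRanges::start(x) - 1,
             end = GenomicRanges::end(x),
             stringsAsFactors = FALSE)
}

.genome_seqlengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read a genome from FASTA
#'
#' Every record becomes one chromosome; lowercase bases are uppercased on
#' load; characters outside {A,C,G,T,N} (including IUPAC ambiguity codes)
#' are rejected, as are duplicate chromosome names. Plain or gzipped FASTA.
#'
#' @param path Path to a FASTA file.
#' @return A `Biostrings::DNAStringSet`, one entry per chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("malformed FASTA (", conditionMessage(e), ")")
    ),
    # the reader silently drops characters outside its alphabet; treat
    # such records as format errors rather than truncating them
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("sequence contains characters outside {A,C,G,T,N}")
      }
      invokeRestart("muffleWarning")
    }
  )
  # keep only the first whitespace-delimited token of each header
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    stop("duplicate chromosome name in FASTA: ",
         names(genome)[duplicated(names(genome))][1])
  }
  if (any(names(genome) == "")) stop("empty FASTA header")
  af <- Biostrings::alphabetFrequency(genome)
  ok <- c("A", "C", "G", "T", "N")
  bad <- rowSums(af[, !(colnames(af) %in% ok), drop = FALSE])
  if (any(bad > 0)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         names(genome)[bad > 0][1])
  }
  genome
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Read / write BED interval files
#'
#' BED3+ tab-separated; extra columns are ignored on read. Coordinates are
#' validated (`0 <= start < end`). `write_bed` emits BED3, optionally with
#' extra columns taken from `x`.
#'
#' @param path File path.
#' @param x Regions data.frame; extra columns beyond chrom/start/end are
#'   written after the coordinates in their data.frame order.
#' @return `read_bed`: a regions data.frame. `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(.empty_regions())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "", fill = TRUE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 tab-separated columns")
  chrom <- as.character(df[[1]])
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinates")
  if (any(start < 0)) stop("negative BED start coordinate")
  if (any(start >= end)) stop("BED interval with start >= end")
  regions(chrom, start, end)
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  core <- c("chrom", "start", "end")
  extra <- setdiff(colnames(x), core)
  out <- x[, c(core, extra), drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interval arithmetic on region sets
#'
#' All operations work in 0-based half-open coordinates and return
#' normalized (sorted, merged where applicable) region sets.
#' `merge_regions` unions overlapping or bookended intervals;
#' `subtract_regions` removes every base of `b` from `a`;
#' `intersect_regions` keeps bases present in both;
#' `complement_regions` returns exactly the genome bases not covered by `x`
#' (every chromosome of `x` must exist in the genome);
#' `region_overlap_length` returns, for each interval of `x`, the number of
#' its bases covered by `set`.
#'
#' @param a,b,x,set Regions data.frames.
#' @param genome A `DNAStringSet` (for chromosome bounds), or a named vector
#'   of chromosome lengths.
#' @return A regions data.frame, or for `region_overlap_length` a numeric
#'   vector parallel to the rows of `x`.
#' @export
merge_regions <- function(x) {
  if (nrow(x) == 0L) return(.empty_regions())
  granges_to_regions(GenomicRanges::reduce(regions_to_granges(x)))
}

#' @rdname merge_regions
#' @export
subtract_regions <- function(a, b) {
  if (nrow(a) == 0L) return(.empty_regions())
  if (nrow(b) == 0L) return(merge_regions(a))
  ga <- regions_to_granges(a)
  gb <- regions_to_granges(b)
  lev <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lev
  GenomeInfoDb::seqlevels(gb) <- lev
  granges_to_regions(GenomicRanges::setdiff(ga, gb))
}

#' @rdname merge_regions
#' @export
intersect_regions <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(.empty_regions())
  ga <- regions_to_granges(a)
  gb <- regions_to_granges(b)
  lev <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lev
  GenomeInfoDb::seqlevels(gb) <- lev
  granges_to_regions(GenomicRanges::intersect(ga, gb))
}

#' @rdname merge_regions
#' @export
complement_regions <- function(x, genome) {
  sl <- if (is.numeric(genome)) genome else .genome_seqlengths(genome)
  if (nrow(x) > 0L && !all(x$chrom %in% names(sl))) {
    stop("region chromosome absent from genome: ",
         setdiff(unique(x$chrom), names(sl))[1])
  }
  full <- regions(names(sl), rep(0, length(sl)), as.numeric(sl))
  subtract_regions(full, x)
}

#' @rdname merge_regions
#' @export
region_overlap_length <- function(x, set) {
  if (nrow(x) == 0L) return(numeric(0))
  out <- numeric(nrow(x))
  if (nrow(set) == 0L) return(out)
  gx <- regions_to_granges(x)
  gs <- regions_to_granges(merge_regions(set))
  ov <- GenomicRanges::findOverlaps(gx, gs)
  if (length(ov) > 0L) {
    qi <- S4Vectors::queryHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gx)[qi],
      GenomicRanges::ranges(gs)[S4Vectors::subjectHits(ov)]
    ))
    agg <- rowsum(w, qi)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Total length of a region set
#'
#' Length is computed after merging, so overlapping input intervals are not
#' double-counted.
#'
#' @param x Regions data.frame.
#' @return Total covered bases (numeric scalar).
#' @export
regions_total_length <- function(x) {
  m <- merge_regions(x)
  sum(m$end - m$start)
}

#' Extract the sequence of each region from a genome
#'
#' @param genome A `DNAStringSet`.
#' @param x Regions data.frame.
#' @return Character vector of uppercase sequences, parallel to rows of `x`.
#' @export
region_sequences <- function(genome, x) {
  if (nrow(x) == 0L) return(character(0))
  if (!all(x$chrom %in% names(genome))) {
    stop("region chromosome absent from genome: ",
         setdiff(unique(x$chrom), names(genome))[1])
  }
  out <- character(nrow(x))
  for (chrom in unique(x$chrom)) {
    i <- which(x$chrom == chrom)
    if (any(x$end[i] > length(genome[[chrom]]))) {
      stop("region beyond chromosome end on ", chrom)
    }
    v <- Biostrings::Views(genome[[chrom]], start = x$start[i] + 1,
                           end = x$end[i])
    out[i] <- as.character(v)
  }
  out
}
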