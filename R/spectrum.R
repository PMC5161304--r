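# The spectrum feature map: sparse k-mer counts over {A,C,G,T}.
#
# A k-mer is encoded as a base-4 integer (A=0, C=1, G=2, T=3), so the
# spectrum of a sequence is a sparse vector of dimension 4^k. K-mers are
# counted on the given strand only, as raw integer counts; any k-mer
# containing an N is skipped.

.DNA_LETTERS <- c("A", "C", "G", "T")

# Map a sequence string to integer codes 0..3 (NA for N). Characters
# outside {A,C,G,T,N} are rejected.
seq_to_codes <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  v <- utf8ToInt(sequence)
  codes <- rep(NA_integer_, length(v))
  codes[v == 65L] <- 0L # A
  codes[v == 67L] <- 1L # C
  codes[v == 71L] <- 2L # G
  codes[v == 84L] <- 3L # T
  if (any(is.na(codes) & v != 78L)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  codes
}

# 0-based k-mer index at every position of a code vector (NA where the
# k-mer contains an N). Rolling base-4 evaluation: k vector operations.
.kmer_indices <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n <= 0L) return(integer(0))
  idx <- codes[seq_len(n)]
  if (k > 1L) {
    for (i in 2:k) idx <- idx * 4L + codes[i:(n + i - 1L)]
  }
  idx
}

#' Decode / enumerate k-mer strings
#'
#' `kmer_index_to_string` maps 0-based base-4 indices (A=0,C=1,G=2,T=3) to
#' k-mer strings; `all_kmers` enumerates all 4^k k-mers in index
#' (lexicographic) order.
#'
#' @param index Integer vector of 0-based k-mer indices.
#' @param k K-mer length.
#' @return Character vector of k-mers.
#' @export
#' @examples
#' kmer_index_to_string(c(0, 27), 3) # "AAA", "CGT"
kmer_index_to_string <- function(index, k) {
  stopifnot(k >= 1)
  out <- matrix("", nrow = length(index), ncol = k)
  rem <- as.integer(index)
  for (j in k:1) {
    out[, j] <- .DNA_LETTERS[rem %% 4L + 1L]
    rem <- rem %/% 4L
  }
  apply(out, 1, paste0, collapse = "")
}

#' @rdname kmer_index_to_string
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1, k <= 12)
  kmer_index_to_string(seq_len(4^k) - 1, k)
}

#' Count k-mers in a sequence
#'
#' Counts every overlapping k-length substring on the given strand (no
#' reverse-complement folding); substrings containing N are skipped. For an
#' N-free sequence of length L >= k the counts sum to L - k + 1.
#'
#' @param sequence A single sequence string.
#' @param k K-mer length (>= 1).
#' @return Named integer vector of counts for the k-mers observed (sparse:
#'   absent k-mers are zero). A sequence shorter than k gives an empty
#'   spectrum.
#' @export
#' @examples
#' count_kmers("ACGTCG", 2)
count_kmers <- function(sequence, k) {
  stopifnot(length(k) == 1L, k >= 1)
  k <- as.integer(k)
  idx <- .kmer_indices(seq_to_codes(sequence), k)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(stats::setNames(integer(0), character(0)))
  r <- rle(sort(idx))
  stats::setNames(r$lengths, kmer_index_to_string(r$values, k))
}

#' Sparse spectrum matrix for a set of sequences
#'
#' The explicit feature map of the spectrum kernel: row i is the k-mer
#' spectrum of sequence i, as a sparse matrix with 4^k columns in
#' lexicographic k-mer order.
#'
#' @param sequences Character vector of sequences, or a window data.frame
#'   with a `seq` column.
#' @param k K-mer length (1..12; dimension 4^k).
#' @return A `Matrix::dgCMatrix` of dimension length(sequences) x 4^k.
#'   Column names are attached for k <= 6; for larger k use
#'   [kmer_index_to_string()] on column indices.
#' @export
kmer_matrix <- function(sequences, k) {
  if (is.data.frame(sequences)) sequences <- sequences$seq
  stopifnot(is.character(sequences), k >= 1, k <= 12)
  k <- as.integer(k)
  n <- length(sequences)
  ii <- vector("list", n)
  jj <- vector("list", n)
  xx <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- .kmer_indices(seq_to_codes(sequences[i]), k)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    r <- rle(sort(idx))
    jj[[i]] <- r$values + 1L
    xx[[i]] <- r$lengths
    ii[[i]] <- rep.int(i, length(r$values))
  }
  m <- Matrix::sparseMatrix(i = unlist(ii) %||% integer(0),
                            j = unlist(jj) %||% integer(0),
                            x = as.numeric(unlist(xx) %||% numeric(0)),
                            dims = c(n, 4^k))
  if (k <= 6L) colnames(m) <- all_kmers(k)
  m
}

#' Spectrum kernel between two sequences
#'
#' The dot product of the two k-mer count vectors: symmetric, non-negative,
#' zero when the spectra share no k-mer.
#'
#' @param seq_a,seq_b Sequence strings.
#' @param k Shared k-mer length.
#' @return Non-negative numeric scalar.
#' @export
#' @examples
#' spectrum_kernel("ACGT", "ACGT", 2) # 3
spectrum_kernel <- function(seq_a, seq_b, k) {
  ca <- count_kmers(seq_a, k)
  cb <- count_kmers(seq_b, k)
  shared <- intersect(names(ca), names(cb))
  if (length(shared) == 0L) return(0)
  sum(as.numeric(ca[shared]) * as.numeric(cb[shared]))
}

#' Highest- (or lowest-) weighted k-mers of a feature-weight vector
#'
#' @param weights Named numeric vector of k-mer weights (e.g. from
#'   [coef.spectrum_svm()]).
#' @param n Number of k-mers to return.
#' @param decreasing `TRUE` for the most positive weights (sequence
#'   features pulling a window toward the NMI class), `FALSE` for the most
#'   negative. Ties are broken lexicographically.
#' @return data.frame with columns `kmer` and `weight`, ordered.
#' @export
top_kmers <- function(weights, n = 20, decreasing = TRUE) {
  stopifnot(n >= 1, !is.null(names(weights)))
  weights <- weights[weights != 0]
  if (n > length(weights)) {
    warning("only ", length(weights), " nonzero-weight k-mers; returning all")
    n <- length(weights)
  }
  ord <- order(if (decreasing) -weights else weights, names(weights))
  sel <- ord[seq_len(n)]
  data.frame(kmer = names(weights)[sel], weight = unname(weights[sel]),
             stringsAsFactors = FALSE)
}

#' Write feature weights as a two-column table
#'
#' @param weights Named numeric vector of k-mer weights.
#' @param path Output path (tab-separated: kmer, weight).
#' @return `path`, invisibly.
#' @export
write_feature_weights <- function(weights, path) {
  df <- data.frame(kmer = names(weights), weight = unname(weights),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
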