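# Shared fixtures, all built in code.

# random DNA sequence of length n (optionally with Ns)
random_dna <- function(n, seed = NULL, letters = c("A", "C", "G", "T")) {
  draw <- function() paste(sample(letters, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else nmiscan:::with_seed(seed, draw())
}

# a small two-chromosome genome from fixed strings
tiny_genome <- function(c1 = "ACGTACGTACGT", c2 = "GGGGCCCCAAAA") {
  Biostrings::DNAStringSet(c(c1 = c1, c2 = c2))
}

# per-base membership mask of a region set on one chromosome of length L
region_mask <- function(x, chrom, L) {
  m <- logical(L)
  x <- x[x$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(x))) {
    lo <- max(0, x$start[i])
    hi <- min(L, x$end[i])
    if (lo < hi) m[(lo + 1):hi] <- TRUE
  }
  m
}

# regions data.frame from a per-base mask (brute-force inverse)
mask_to_regions <- function(m, chrom) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(nmiscan:::.empty_regions())
  regions(rep(chrom, sum(keep)), starts[keep], ends[keep])
}

# brute-force spectrum kernel: count equal substring pairs directly
brute_spectrum_kernel <- function(a, b, k) {
  subs <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    v <- substring(s, 1:(L - k + 1), k:L)
    v[!grepl("N", v, fixed = TRUE)]
  }
  sa <- subs(a)
  sb <- subs(b)
  if (length(sa) == 0 || length(sb) == 0) return(0)
  sum(outer(sa, sb, "=="))
}

# brute-force AUROC: all positive/negative pairs, ties get half credit
brute_auroc <- function(scores, labels) {
  p <- scores[labels == 1]
  n <- scores[labels == -1]
  cmp <- outer(p, n, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force stepwise AUPRC at every distinct threshold
brute_auprc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

# cache shared across test files (heavy synthetic runs computed once)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small generated genome shared by several files
small_synth <- function(model = "warm", seed = 101) {
  cached(paste0("small_", model, "_", seed), {
    spec <- synthetic_spec(n_chrom = 6, chrom_length = 2e5,
                           island_model = model)
    generate_synthetic_genome(spec, seed = seed)
  })
}
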