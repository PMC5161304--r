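# The spectrum-kernel support vector machine.
#
# spectrum_svm() is the central fitting function of the package. The
# soft-margin SVM dual problem is solved exactly on the precomputed
# spectrum kernel matrix K = Phi X Phi' (kernlab's C-svc solver); the
# equivalent primal weight vector over explicit k-mer features,
#
#   w = sum over support vectors i of alpha_i y_i Phi(x_i),
#
# is then derived from the dual solution, so every trained model carries
# both scoring routes: the cheap primal path w . Phi(x) + b used by
# predict(), and the dual expansion sum_i alpha_i y_i K(x_i, x) + b kept
# for consistency checking (the two must agree to numerical precision).

#' Fit a spectrum-kernel SVM
#'
#' Trains a standard soft-margin SVM (hinge loss, penalty `C`, no class
#' re-weighting) on the k-mer spectra of labeled windows. Class imbalance
#' is expected to be controlled upstream by subsampling
#' ([subsample_balanced()]), not by loss re-weighting.
#'
#' @param x Labeled window data.frame (columns `seq` and `label`), or a
#'   character vector of sequences with `labels` supplied.
#' @param labels Integer labels in {-1, +1} (ignored when `x` is a labeled
#'   window data.frame).
#' @param k K-mer length (default 6).
#' @param C Soft-margin penalty (default 1).
#' @param tol Solver termination tolerance (default 1e-4).
#' @return An object of class `spectrum_svm` with components `k`, `C`,
#'   `w` (primal weight vector, length 4^k), `b` (bias), `alpha_y` (signed
#'   dual coefficients alpha_i y_i of the support vectors), `sv_index`,
#'   `sv_spectra` (sparse support-vector spectra), `n_train`, `n_sv`.
#' @export
#' @examples
#' pos <- strrep("CG", 20); neg <- strrep("AT", 20)
#' fit <- spectrum_svm(c(rep(pos, 5), rep(neg, 5)),
#'                     labels = c(rep(1, 5), rep(-1, 5)), k = 2, C = 1)
#' predict(fit, c(pos, neg))
spectrum_svm <- function(x, labels = NULL, k = 6, C = 1, tol = 1e-4) {
  if (is.data.frame(x)) {
    seqs <- x$seq
    labels <- labels %||% x$label
  } else {
    seqs <- x
  }
  stopifnot(!is.null(labels), length(labels) == length(seqs),
            k >= 1, C > 0, tol > 0)
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be -1 or +1")
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes")
  }
  X <- kmer_matrix(seqs, k)
  fit <- .fit_spectrum(X, labels, C, tol)
  structure(c(list(k = as.integer(k), C = C, tol = tol,
                   n_train = length(seqs), call = match.call()),
              fit),
            class = "spectrum_svm")
}

# Core solver on a precomputed spectrum matrix; shared with the
# cross-validation loops so spectra (and optionally the kernel matrix)
# are computed once per k.
.fit_spectrum <- function(X, labels, C, tol = 1e-4, K = NULL) {
  if (is.null(K)) K <- as.matrix(Matrix::tcrossprod(X))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K),
                       y = factor(labels, levels = c(-1, 1)),
                       type = "C-svc", C = C, tol = tol)
  ai <- unlist(kernlab::alphaindex(fit))
  co <- unlist(kernlab::coef(fit))
  b0 <- kernlab::b(fit)
  # Orient so that positive decision scores mean the +1 (NMI) class:
  # kernlab's internal coding of the two classes is not part of its API,
  # so recover the sign from its own fitted classes.
  f <- as.numeric(K[, ai, drop = FALSE] %*% co) - b0
  pred <- kernlab::predict(fit)
  s <- if (mean((f > 0) == (pred == "1")) >= 0.5) 1 else -1
  alpha_y <- s * co
  b <- -s * b0
  w <- as.numeric(Matrix::crossprod(X[ai, , drop = FALSE], alpha_y))
  list(w = w, b = b, alpha_y = alpha_y, sv_index = ai,
       sv_spectra = X[ai, , drop = FALSE], n_sv = length(ai))
}

.check_model <- function(object) {
  if (!inherits(object, "spectrum_svm") || is.null(object$w)) {
    stop("not a trained spectrum_svm model")
  }
  invisible(object)
}

#' Decision scores and class predictions for new windows
#'
#' The decision score is `w . Phi(x) + b`, computed via the primal weight
#' vector. The conventional classification cutoff is a score of 0.
#'
#' @param object A trained `spectrum_svm`.
#' @param newdata Character vector of sequences or a window data.frame
#'   with a `seq` column.
#' @param type `"score"` for continuous decision scores (default),
#'   `"class"` for labels in {-1, +1} at the 0 cutoff.
#' @param ... Unused.
#' @return Numeric scores or integer labels, parallel to `newdata`.
#' @export
predict.spectrum_svm <- function(object, newdata,
                                 type = c("score", "class"), ...) {
  .check_model(object)
  type <- match.arg(type)
  X <- kmer_matrix(newdata, object$k)
  f <- as.numeric(X %*% object$w) + object$b
  if (type == "class") ifelse(f >= 0, 1L, -1L) else f
}

#' Decision scores via the dual expansion
#'
#' Computes `sum_i alpha_i y_i K(x_i, x) + b` over the stored support
#' vectors — the route the kernel formulation defines. Mathematically
#' identical to [predict.spectrum_svm()]; kept as an independent path so
#' the equivalence can be asserted.
#'
#' @param object A trained `spectrum_svm`.
#' @param newdata Sequences or window data.frame.
#' @return Numeric decision scores.
#' @export
score_dual <- function(object, newdata) {
  .check_model(object)
  if (is.null(object$sv_spectra)) {
    stop("model carries no dual expansion (e.g. reloaded from file)")
  }
  X <- kmer_matrix(newdata, object$k)
  Kx <- as.matrix(X %*% Matrix::t(object$sv_spectra))
  as.numeric(Kx %*% object$alpha_y) + object$b
}

#' Feature weights of a trained model
#'
#' Extracts the k-mer feature weights `w = sum_i alpha_i y_i Phi(x_i)`
#' from the dual solution. Positive weights pull a window toward the NMI
#' class.
#'
#' @param object A trained `spectrum_svm`.
#' @param ... Unused.
#' @return Named numeric vector of the nonzero k-mer weights (sparse:
#'   k-mers never seen in a support vector have weight zero).
#' @export
coef.spectrum_svm <- function(object, ...) {
  .check_model(object)
  nz <- which(object$w != 0)
  stats::setNames(object$w[nz], kmer_index_to_string(nz - 1, object$k))
}

#' Print a spectrum_svm model
#' @param x A `spectrum_svm`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.spectrum_svm <- function(x, ...) {
  cat("Spectrum-kernel SVM\n")
  cat("  k-mer length: ", x$k, "  (", format(4^x$k, big.mark = ","),
      " features)\n", sep = "")
  cat("  soft-margin C:", format(x$C), "\n")
  cat("  training windows:", x$n_train,
      " support vectors:", x$n_sv, "\n")
  cat("  bias b:", format(x$b, digits = 4), "\n")
  invisible(x)
}

#' Summarize a spectrum_svm model
#' @param object A `spectrum_svm`.
#' @param n_top Number of top k-mers to show.
#' @param ... Unused.
#' @return `object`, invisibly.
#' @exportS3Method base::summary
summary.spectrum_svm <- function(object, n_top = 10, ...) {
  print(object)
  w <- coef(object)
  if (length(w) > 0) {
    cat("\nTop", min(n_top, length(w)), "k-mers by feature weight:\n")
    tk <- top_kmers(w, min(n_top, length(w)))
    print(tk, row.names = FALSE)
  }
  invisible(object)
}

#' Shuffle class labels
#'
#' Permutes the labels uniformly at random among windows, preserving the
#' exact class counts — the randomly-trained control: a model fit on
#' shuffled labels should perform like a random classifier.
#'
#' @param x Labeled window data.frame, or a label vector.
#' @param seed Seed.
#' @return Object of the same type with labels permuted.
#' @export
shuffle_labels <- function(x, seed = 1) {
  if (is.data.frame(x)) {
    x$label <- with_seed(seed, sample(x$label))
    x
  } else {
    with_seed(seed, sample(x))
  }
}

#' Save / load a trained model as a plain-text file
#'
#' Self-describing tab-separated format: header lines (k, C, bias,
#' training size) followed by the nonzero primal weights. Reloaded models
#' support prediction and feature-weight inspection; the dual expansion is
#' not serialized.
#'
#' @param object A trained `spectrum_svm`.
#' @param path File path.
#' @return `write_spectrum_svm`: `path` invisibly; `read_spectrum_svm`:
#'   a `spectrum_svm` object.
#' @export
write_spectrum_svm <- function(object, path) {
  .check_model(object)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#nmiscan_spectrum_svm\tversion=1"),
               paste0("#k\t", object$k),
               paste0("#C\t", format(object$C, digits = 17)),
               paste0("#b\t", format(object$b, digits = 17)),
               paste0("#n_train\t", object$n_train),
               paste0("#n_sv\t", object$n_sv)), con)
  nz <- which(object$w != 0)
  df <- data.frame(kmer = kmer_index_to_string(nz - 1, object$k),
                   weight = format(object$w[nz], digits = 17))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_svm
#' @export
read_spectrum_svm <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#nmiscan_spectrum_svm")) {
    stop("not a nmiscan model file")
  }
  hdr <- lines[startsWith(lines, "#")][-1]
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t"))
  vals <- stats::setNames(kv[, 2], kv[, 1])
  k <- as.integer(vals[["k"]])
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  w <- numeric(4^k)
  if (length(body) > 0) {
    parts <- do.call(rbind, strsplit(body, "\t"))
    idx <- match(parts[, 1], all_kmers(k))
    w[idx] <- as.numeric(parts[, 2])
  }
  structure(list(k = k, C = as.numeric(vals[["C"]]),
                 b = as.numeric(vals[["b"]]),
                 n_train = as.integer(vals[["n_train"]]),
                 n_sv = as.integer(vals[["n_sv"]]),
                 w = w, alpha_y = NULL, sv_index = NULL,
                 sv_spectra = NULL),
            class = "spectrum_svm")
}
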