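# The spectrum-kernel SVM: training, scoring, Eq.-style primal/dual
# consistency, and the shuffled-label control.

# GC-rich vs AT-rich random training windows: linearly separable at k = 2
separable_windows <- function(n_per_class = 50, len = 200, seed = 1) {
  nmiscan:::with_seed(seed, {
    pos <- vapply(seq_len(n_per_class), function(i) {
      paste(sample(c("C", "G", "A", "T"), len, replace = TRUE,
                   prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
    }, character(1))
    neg <- vapply(seq_len(n_per_class), function(i) {
      paste(sample(c("C", "G", "A", "T"), len, replace = TRUE,
                   prob = c(0.1, 0.1, 0.4, 0.4)), collapse = "")
    }, character(1))
    data.frame(seq = c(pos, neg),
               label = rep(c(1L, -1L), each = n_per_class),
               stringsAsFactors = FALSE)
  })
}

test_that("a separable construction is fit perfectly", {
  w <- separable_windows()
  fit <- spectrum_svm(w, k = 2, C = 1)
  sc <- predict(fit, w)
  expect_equal(roc_auc(sc, w$label)$area, 1.0)
  expect_equal(predict(fit, w, type = "class"), w$label)
})

test_that("training is deterministic", {
  w <- separable_windows(n_per_class = 30, seed = 5)
  f1 <- spectrum_svm(w, k = 3, C = 0.1)
  f2 <- spectrum_svm(w, k = 3, C = 0.1)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$b, f2$b)
  expect_identical(predict(f1, w), predict(f2, w))
})

test_that("degenerate training inputs error", {
  expect_error(spectrum_svm(c("ACGT", "ACGG"), labels = c(1, 1)),
               "both classes")
  expect_error(spectrum_svm(c("ACGT", "ACGG"), labels = c(1, 2)),
               "labels")
  expect_error(spectrum_svm(c("ACGT"), labels = 1, C = -1))
})

test_that("primal scores equal the dual expansion on random inputs", {
  for (k in c(2, 4, 6)) {
    w <- separable_windows(n_per_class = 25, seed = k)
    fit <- spectrum_svm(w, k = k, C = 1)
    newdata <- vapply(1:50, function(i) random_dna(180, seed = 1000 + i),
                      character(1))
    p <- predict(fit, newdata)
    d <- score_dual(fit, newdata)
    expect_lt(max(abs(p - d) / pmax(abs(d), 1e-12)), 1e-6)
  }
})

test_that("feature weights reproduce the dual-expansion weight vector", {
  w <- separable_windows(n_per_class = 20, seed = 9)
  fit <- spectrum_svm(w, k = 2, C = 1)
  # recompute w independently from the stored dual pieces
  w_ref <- as.numeric(Matrix::crossprod(fit$sv_spectra, fit$alpha_y))
  expect_equal(fit$w, w_ref)
  cw <- coef(fit)
  expect_true(all(nchar(names(cw)) == 2))
  expect_equal(unname(cw), fit$w[fit$w != 0])
})

test_that("hand-built weight vectors score sequences as w . Phi(x) + b", {
  w <- numeric(16)
  w[which(all_kmers(2) == "CG")] <- 1
  model <- structure(list(k = 2L, C = 1, w = w, b = 0, alpha_y = NULL,
                          sv_index = NULL, sv_spectra = NULL,
                          n_train = 0L, n_sv = 0L),
                     class = "spectrum_svm")
  expect_equal(predict(model, "CGCG"), 2)
  expect_equal(predict(model, "AAAA"), 0)
})

test_that("raising C does not increase training hinge loss on a separable set", {
  w <- separable_windows(n_per_class = 20, seed = 3)
  hinge <- vapply(c(0.01, 0.1, 1, 10), function(C) {
    fit <- spectrum_svm(w, k = 2, C = C)
    sum(pmax(0, 1 - w$label * predict(fit, w)))
  }, numeric(1))
  expect_true(all(diff(hinge) <= 1e-6))
})

test_that("shuffle_labels preserves exact class counts and is seeded", {
  w <- data.frame(seq = "A", label = c(rep(-1L, 250), rep(1L, 50)))
  s1 <- shuffle_labels(w, seed = 4)
  expect_equal(sum(s1$label == 1), 50)
  expect_equal(sum(s1$label == -1), 250)
  expect_identical(s1, shuffle_labels(w, seed = 4))
  expect_false(identical(s1$label, w$label))
})

test_that("models round-trip through the plain-text serialization", {
  w <- separable_windows(n_per_class = 15, seed = 11)
  fit <- spectrum_svm(w, k = 3, C = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_svm(fit, f)
  fit2 <- read_spectrum_svm(f)
  expect_equal(fit2$k, fit$k)
  expect_equal(fit2$w, fit$w, tolerance = 1e-12)
  expect_equal(predict(fit2, w), predict(fit, w), tolerance = 1e-10)
  expect_error(score_dual(fit2, "ACGTACGT"), "dual")
})
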