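# Experiment orchestration: repeated random chromosome splits, grid-search
# tuning with stratified 5-fold CV, within-species evaluation on 50 bp
# windows, the shuffled-label control, and the cross-species transfer
# matrix. Every run is a pure function of (inputs, config, master seed).

#' Experiment configuration
#'
#' Defaults reproduce the protocol the package implements: 750 bp
#' classification windows evaluated on 50 bp windows, 500 bp NMI border
#' exclusion, a 30,000-window 5:1 tuning/training subsample, a grid over C
#' in {0.01, 0.1, 1} and k in 2..9 selected by 5-fold CV AUROC, 5
#' repetitions over random chromosome splits, and fixed (k = 6, C = 1)
#' for cross-species transfer and the shuffled-label control.
#'
#' @param window_width Classification window width (bp).
#' @param eval_width Evaluation window width (bp); must divide
#'   `window_width`.
#' @param border_bp NMI border exclusion width (bp).
#' @param subsample_total Tuning/training subsample size.
#' @param neg_pos_ratio Background:NMI ratio of the subsample.
#' @param grid_C,grid_k Grid-search values.
#' @param n_folds Cross-validation folds.
#' @param n_repeats Number of random-split repetitions.
#' @param test_frac Fraction of analysis-region length held out by
#'   chromosome.
#' @param tuning_frac Fraction of train-side windows used for tuning.
#' @param min_frac Coverage fraction for positive labels.
#' @param max_n_frac Maximum N fraction per window.
#' @param fixed_k,fixed_C Parameters for cross-species / control runs.
#' @param svm_cutoff,cpg_cutoff Fixed-cutoff metric thresholds.
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(window_width = 750,
                              eval_width = 50,
                              border_bp = 500,
                              subsample_total = 30000,
                              neg_pos_ratio = 5,
                              grid_C = c(0.01, 0.1, 1),
                              grid_k = 2:9,
                              n_folds = 5,
                              n_repeats = 5,
                              test_frac = 0.5,
                              tuning_frac = 0.5,
                              min_frac = 0.5,
                              max_n_frac = 0.1,
                              fixed_k = 6,
                              fixed_C = 1.0,
                              svm_cutoff = 0,
                              cpg_cutoff = 0.6,
                              seed = 1) {
  stopifnot(window_width %% eval_width == 0,
            subsample_total %% (neg_pos_ratio + 1) == 0,
            n_folds >= 2, n_repeats >= 1)
  structure(as.list(environment()), class = "experiment_config")
}

#' Print an experiment_config
#' @param x An `experiment_config`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.experiment_config <- function(x, ...) {
  cat("Experiment configuration\n")
  cat(sprintf("  windows %d bp (evaluated at %d bp), border exclusion %d bp\n",
              x$window_width, x$eval_width, x$border_bp))
  cat(sprintf("  subsample %d at %d:1; grid C {%s} x k {%s}; %d-fold CV; %d repetitions\n",
              x$subsample_total, x$neg_pos_ratio,
              paste(x$grid_C, collapse = ","),
              paste(range(x$grid_k), collapse = ".."),
              x$n_folds, x$n_repeats))
  cat(sprintf("  fixed parameters k = %d, C = %g; master seed %d\n",
              x$fixed_k, x$fixed_C, x$seed))
  invisible(x)
}

#' Write / read a flat key-value configuration file
#'
#' @param config An `experiment_config`.
#' @param path File path (tab-separated `key value` lines).
#' @return `path` invisibly, or an `experiment_config`.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste(names(config), vals, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  kv <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  args <- lapply(stats::setNames(kv[[2]], kv[[1]]), function(v) {
    as.numeric(strsplit(v, ",")[[1]])
  })
  do.call(experiment_config, args)
}

#' Stratified cross-validation folds
#'
#' Assigns a fold id to every window, stratified by class so that each
#' fold carries both classes even at 5:1 imbalance.
#'
#' @param labels Labels in {-1, +1}.
#' @param n_folds Number of folds.
#' @param seed Seed.
#' @return Integer fold ids in 1..n_folds.
#' @export
stratified_folds <- function(labels, n_folds = 5, seed = 1) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}

# Mean held-out-fold AUROC of a (k, C) cell given a precomputed spectrum
# matrix, its kernel matrix, and a fixed fold assignment.
.cv_cell_auroc <- function(X, labels, C, folds, tol = 1e-4, K = NULL) {
  if (is.null(K)) K <- as.matrix(Matrix::tcrossprod(X))
  per_fold <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- .fit_spectrum(X[tr, , drop = FALSE], labels[tr], C, tol,
                         K = K[tr, tr, drop = FALSE])
    sc <- as.numeric(X[!tr, , drop = FALSE] %*% fit$w) + fit$b
    roc_auc(sc, labels[!tr])$area
  }, numeric(1))
  mean(per_fold)
}

#' Grid search over (k, C) by cross-validated AUROC
#'
#' Evaluates every combination of `ks` and `Cs` by mean held-out-fold
#' AUROC under stratified `n_folds`-fold CV (folds fixed across cells),
#' and selects the maximum; ties break toward smaller k, then smaller C.
#'
#' @param tuning_windows Labeled window data.frame (both classes present).
#' @param config An [experiment_config()].
#' @param ks,Cs Grid values (default from `config`).
#' @param seed Seed for fold assignment (default derived from
#'   `config$seed`).
#' @return List with `best_k`, `best_C`, and `cv` (data.frame of k, C,
#'   mean_auroc for every cell).
#' @export
grid_search <- function(tuning_windows, config = experiment_config(),
                        ks = config$grid_k, Cs = config$grid_C,
                        seed = NULL) {
  labels <- tuning_windows$label
  if (length(unique(labels)) < 2L) stop("tuning windows must carry both classes")
  seed <- seed %||% derive_seeds(config$seed, "folds")[[1]]
  folds <- stratified_folds(labels, config$n_folds, seed)
  cells <- expand.grid(k = sort(ks), C = sort(Cs))
  cells <- cells[order(cells$k, cells$C), , drop = FALSE]
  cells$mean_auroc <- NA_real_
  for (k in unique(cells$k)) {
    X <- kmer_matrix(tuning_windows$seq, k)
    K <- as.matrix(Matrix::tcrossprod(X))
    for (i in which(cells$k == k)) {
      cells$mean_auroc[i] <- .cv_cell_auroc(X, labels, cells$C[i], folds,
                                            K = K)
    }
  }
  best <- which.max(cells$mean_auroc) # first max in (k, C) order
  rownames(cells) <- NULL
  list(best_k = cells$k[best], best_C = cells$C[best], cv = cells)
}

# Shared per-repetition preprocessing: split chromosomes, tile and label
# both sides, partition the train side, subsample tuning and training
# sets. Returns all intermediate window sets.
.prepare_repetition <- function(genome, nmis, mask, config, rep_seed) {
  seeds <- derive_seeds(rep_seed, c("split", "tt", "tune_sub", "train_sub",
                                    "folds", "shuffle"))
  region <- build_analysis_region(genome, nmis, mask, config$border_bp)
  split <- split_chromosomes(genome, region, config$test_frac,
                             seeds[["split"]])
  reg_train <- region[region$chrom %in% split$train_chroms, , drop = FALSE]
  reg_test <- region[region$chrom %in% split$test_chroms, , drop = FALSE]
  win_train_side <- label_windows(
    tile_windows(reg_train, genome, config$window_width, config$max_n_frac),
    nmis, config$min_frac)
  tt <- split_tuning_training(win_train_side, config$tuning_frac,
                              seeds[["tt"]])
  tuning <- subsample_balanced(tt$tuning, config$subsample_total,
                               config$neg_pos_ratio, seeds[["tune_sub"]])
  training <- subsample_balanced(tt$training, config$subsample_total,
                                 config$neg_pos_ratio, seeds[["train_sub"]])
  test_windows <- label_windows(
    tile_windows(reg_test, genome, config$window_width, config$max_n_frac),
    nmis, config$min_frac)
  list(seeds = seeds, split = split, tuning = tuning, training = training,
       test_windows = test_windows)
}

.eval_scores <- function(windows, scores, nmis, config, cutoff = NULL) {
  ev <- explode_to_eval_windows(windows, nmis, config$eval_width,
                                config$min_frac, score = scores)
  roc <- roc_auc(ev$score, ev$label)
  pr <- pr_auc(ev$score, ev$label)
  mc <- if (!is.null(cutoff)) metrics_at_cutoff(ev$score, ev$label, cutoff)
  list(auroc = roc$area, auprc = pr$area, at_cutoff = mc,
       n_eval = nrow(ev), prevalence = pr$n_pos / (pr$n_pos + pr$n_neg))
}

#' Within-species experiment
#'
#' For each repetition: random chromosome split, analysis-region build,
#' tiling and labeling, tuning/training partition, 5:1 subsampling,
#' grid-search parameter selection, training, prediction of every held-out
#' test window, explosion to 50 bp evaluation windows, and evaluation of
#' the SVM, the CpG-ratio scorer, the UCSC island caller, and any imported
#' interval predictions on identical evaluation windows. A fixed
#' (`fixed_k`, `fixed_C`) model is also trained per repetition for
#' feature-weight (top k-mer) extraction.
#'
#' @param genome A `DNAStringSet`.
#' @param nmis Regions data.frame of true NMIs.
#' @param mask Optional mappability mask.
#' @param config An [experiment_config()].
#' @param methods Subset of `c("svm", "cpg_ratio", "ucsc")`.
#' @param extra_predictions Optional named list of regions data.frames
#'   (externally produced island predictions) evaluated alongside.
#' @param top_n Top k-mer table size (default 20).
#' @return List of class `experiment_result`: `per_rep` (one row per
#'   method and repetition), `summary` (means per method), `selected`
#'   (chosen (k, C) per repetition), `top_kmers` (per repetition), and
#'   `config`.
#' @export
run_within_species <- function(genome, nmis, mask = NULL,
                               config = experiment_config(),
                               methods = c("svm", "cpg_ratio", "ucsc"),
                               extra_predictions = NULL, top_n = 20) {
  methods <- match.arg(methods, several.ok = TRUE)
  rep_seeds <- derive_seeds(config$seed, paste0("rep", seq_len(config$n_repeats)))
  rows <- list()
  selected <- list()
  topk <- list()
  for (r in seq_len(config$n_repeats)) {
    prep <- .prepare_repetition(genome, nmis, mask, config, rep_seeds[[r]])
    tw <- prep$test_windows
    # train/test hygiene: no shared chromosomes
    stopifnot(!any(tw$chrom %in% unique(c(prep$tuning$chrom,
                                          prep$training$chrom))))
    if ("svm" %in% methods) {
      gs <- grid_search(prep$tuning, config, seed = prep$seeds[["folds"]])
      model <- spectrum_svm(prep$training, k = gs$best_k, C = gs$best_C)
      sc <- predict(model, tw)
      ev <- .eval_scores(tw, sc, nmis, config, config$svm_cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "svm", rep = r, k = gs$best_k, C = gs$best_C,
        auroc = ev$auroc, auprc = ev$auprc,
        tpr = ev$at_cutoff$TPR, fpr = ev$at_cutoff$FPR,
        precision = ev$at_cutoff$precision, stringsAsFactors = FALSE)
      selected[[r]] <- data.frame(rep = r, k = gs$best_k, C = gs$best_C,
                                  cv_auroc = max(gs$cv$mean_auroc))
      fixed_model <- spectrum_svm(prep$training, k = config$fixed_k,
                                  C = config$fixed_C)
      topk[[r]] <- cbind(rep = r, top_kmers(coef(fixed_model), top_n))
    }
    if ("cpg_ratio" %in% methods) {
      sc <- score_windows_cpg_ratio(tw)$score
      ev <- .eval_scores(tw, sc, nmis, config, config$cpg_cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "cpg_ratio", rep = r, k = NA_real_, C = NA_real_,
        auroc = ev$auroc, auprc = ev$auprc,
        tpr = ev$at_cutoff$TPR, fpr = ev$at_cutoff$FPR,
        precision = ev$at_cutoff$precision, stringsAsFactors = FALSE)
    }
    interval_preds <- list()
    if ("ucsc" %in% methods) {
      interval_preds$ucsc <- ucsc_islands_genome(genome,
                                                 prep$split$test_chroms)
    }
    for (nm in names(extra_predictions %||% list())) {
      interval_preds[[nm]] <- extra_predictions[[nm]]
    }
    for (nm in names(interval_preds)) {
      ev_win <- explode_to_eval_windows(tw, nmis, config$eval_width,
                                        config$min_frac,
                                        score = rep(0, nrow(tw)))
      bs <- intervals_to_window_scores(interval_preds[[nm]], ev_win,
                                       config$min_frac)
      roc <- roc_auc(bs, ev_win$label)
      pr <- pr_auc(bs, ev_win$label)
      mc <- metrics_at_cutoff(bs, ev_win$label, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        method = nm, rep = r, k = NA_real_, C = NA_real_,
        auroc = roc$area, auprc = pr$area,
        tpr = mc$TPR, fpr = mc$FPR, precision = mc$precision,
        stringsAsFactors = FALSE)
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- stats::aggregate(per_rep[, c("auroc", "auprc", "tpr", "fpr")],
                          by = list(method = per_rep$method), FUN = mean)
  structure(list(per_rep = per_rep, summary = agg,
                 selected = do.call(rbind, selected),
                 top_kmers = do.call(rbind, topk),
                 config = config),
            class = "experiment_result")
}

#' Print an experiment_result
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.experiment_result <- function(x, ...) {
  cat("Experiment result (", length(unique(x$per_rep$rep)),
      " repetitions)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Shuffled-label control experiment
#'
#' Runs the within-species pipeline with class labels randomly shuffled
#' after subsampling: (a) grid-cell CV AUROC on the shuffled tuning set
#' (expected ~0.50 everywhere), and (b) a fixed (`fixed_k`, `fixed_C`)
#' model trained on the shuffled training subsample and scored on every
#' held-out 750 bp test window against the true labels (expected AUPRC ~
#' the positive-window prevalence; AUROC in a wide band around 0.5 because
#' the training imbalance no longer matches the test imbalance).
#'
#' @param genome,nmis,mask,config As in [run_within_species()].
#' @param ks,Cs Grid cells probed in the CV part (default the full grid).
#' @param n_shuffles Number of independent label shuffles averaged.
#' @return List with `cv` (per shuffle and cell), `test` (per shuffle) and
#'   `config`.
#' @export
run_random_control <- function(genome, nmis, mask = NULL,
                               config = experiment_config(),
                               ks = config$grid_k, Cs = config$grid_C,
                               n_shuffles = 1) {
  rep_seeds <- derive_seeds(config$seed, paste0("rep", seq_len(config$n_repeats)))
  cv_rows <- list()
  test_rows <- list()
  for (r in seq_len(config$n_repeats)) {
    prep <- .prepare_repetition(genome, nmis, mask, config, rep_seeds[[r]])
    shuf_seeds <- derive_seeds(prep$seeds[["shuffle"]],
                               paste0("s", seq_len(n_shuffles)))
    for (s in seq_len(n_shuffles)) {
      tune_shuf <- shuffle_labels(prep$tuning, shuf_seeds[[s]])
      gs <- grid_search(tune_shuf, config, ks = ks, Cs = Cs,
                        seed = prep$seeds[["folds"]])
      cv_rows[[length(cv_rows) + 1L]] <- cbind(rep = r, shuffle = s, gs$cv)
      train_shuf <- shuffle_labels(prep$training, shuf_seeds[[s]] + 1L)
      model <- spectrum_svm(train_shuf, k = config$fixed_k, C = config$fixed_C)
      sc <- predict(model, prep$test_windows)
      prev <- mean(prep$test_windows$label == 1L)
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        rep = r, shuffle = s,
        auroc = roc_auc(sc, prep$test_windows$label)$area,
        auprc = pr_auc(sc, prep$test_windows$label)$area,
        prevalence = prev, n_test = nrow(prep$test_windows))
    }
  }
  list(cv = do.call(rbind, cv_rows), test = do.call(rbind, test_rows),
       config = config)
}

#' Pool training sets from several datasets
#'
#' Builds a combined training set by drawing an equal-size seeded
#' subsample from each dataset (each internally at the configured
#' background:NMI ratio) and concatenating.
#'
#' @param sets Named list (>= 2) of labeled window data.frames.
#' @param total Total pooled size (default 30000).
#' @param ratio Background:NMI ratio within each share (default 5).
#' @param seed Seed.
#' @return A labeled window data.frame of (up to) `total` rows.
#' @export
pool_training_sets <- function(sets, total = 30000, ratio = 5, seed = 1) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  share <- total %/% length(sets)
  share <- (share %/% (ratio + 1)) * (ratio + 1) # keep the ratio exact
  seeds <- derive_seeds(seed, names(sets))
  out <- lapply(names(sets), function(nm) {
    subsample_balanced(sets[[nm]], share, ratio, seeds[[nm]])
  })
  do.call(rbind, out)
}

#' Cross-species transfer matrix
#'
#' Reuses the per-repetition training and test window sets of each dataset
#' (byte-identical to the within-species fixed-parameter runs): for every
#' ordered (train, test) dataset pair and every repetition, a model is
#' trained at fixed (`fixed_k`, `fixed_C`) on the train dataset's training
#' subsample and its AUPRC measured on the test dataset's 50 bp evaluation
#' windows; entries are means over repetitions. Pools of training sets
#' (equal allocation per member) can be added as extra rows.
#'
#' @param datasets Named list of `list(genome =, nmis =, mask = NULL)`.
#' @param config An [experiment_config()].
#' @param pools Optional named list of character vectors naming member
#'   datasets, e.g. `list(warm = c("a", "b"))`.
#' @return List with `auprc` (train x test matrix), `per_rep` (long
#'   data.frame) and `config`.
#' @export
run_cross_species <- function(datasets, config = experiment_config(),
                              pools = NULL) {
  stopifnot(length(datasets) >= 2, !is.null(names(datasets)))
  preps <- lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    rep_seeds <- derive_seeds(config$seed, paste0(nm, "_rep",
                                                  seq_len(config$n_repeats)))
    lapply(seq_len(config$n_repeats), function(r) {
      .prepare_repetition(d$genome, d$nmis, d$mask %||% NULL, config,
                          rep_seeds[[r]])
    })
  })
  names(preps) <- names(datasets)
  train_names <- c(names(datasets), names(pools %||% list()))
  rows <- list()
  for (r in seq_len(config$n_repeats)) {
    models <- list()
    for (nm in names(datasets)) {
      models[[nm]] <- spectrum_svm(preps[[nm]][[r]]$training,
                                   k = config$fixed_k, C = config$fixed_C)
    }
    for (pn in names(pools %||% list())) {
      members <- pools[[pn]]
      stopifnot(all(members %in% names(datasets)))
      pooled <- pool_training_sets(
        stats::setNames(lapply(members, function(m) preps[[m]][[r]]$training),
                        members),
        config$subsample_total, config$neg_pos_ratio,
        derive_seeds(config$seed, paste0("pool_", pn, "_", r))[[1]])
      models[[pn]] <- spectrum_svm(pooled, k = config$fixed_k,
                                   C = config$fixed_C)
    }
    for (tr in train_names) {
      for (te in names(datasets)) {
        tw <- preps[[te]][[r]]$test_windows
        sc <- predict(models[[tr]], tw)
        ev <- .eval_scores(tw, sc,
                           nmis = datasets[[te]]$nmis, config)
        rows[[length(rows) + 1L]] <- data.frame(
          train = tr, test = te, rep = r, auprc = ev$auprc,
          auroc = ev$auroc, stringsAsFactors = FALSE)
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- stats::aggregate(per_rep$auprc,
                          by = list(train = per_rep$train,
                                    test = per_rep$test), FUN = mean)
  mat <- matrix(NA_real_, length(train_names), length(datasets),
                dimnames = list(train_names, names(datasets)))
  for (i in seq_len(nrow(agg))) mat[agg$train[i], agg$test[i]] <- agg$x[i]
  list(auprc = mat, per_rep = per_rep, config = config)
}
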