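#' Extract per-window spectral/complexity features
#'
#' For every window of a [segment()]ed recording, computes the FFT amplitude
#' spectrum, the PSD and the wavelet scalogram magnitudes, and summarises
#' each representation by its mean, maximum, minimum, variance, skewness and
#' kurtosis (18 raw features), plus the window's approximate entropy
#' (m = 2, r = 0.2 x window SD) as a 19th column.
#'
#' @param ws a `WindowSet`, or a list of WindowSets (one per recording).
#' @param n_scales wavelet scales per window.
#' @param entropy_max_n sub-window cap for the per-window entropy.
#' @return A data.frame of class `FeatureMatrix`: 18 raw feature columns,
#'   `entropy`, plus `label` (class) and `group_id` (source recording).
#'   Constant windows are dropped with a warning.
#' @export
extract_window_features <- function(ws, n_scales = 32L, entropy_max_n = 5000L) {
  if (inherits(ws, "WindowSet")) ws <- list(ws)
  rows <- list()
  for (w in ws) {
    rec <- w$parent
    label <- rec$class %||% paste(rec$treatment, rec$phase, sep = "-")
    for (i in seq_along(w$starts)) {
      x <- window_samples(w, i)
      if (sd(x) == 0) {
        warning("constant window ", i, " of ", rec$plant_id, " dropped")
        next
      }
      sub <- recording(x, fs = rec$fs)
      feats <- c(
        rep_stats(fft_spectrum(sub)$values, "fft"),
        rep_stats(psd(sub, seg_len = min(256L, 2^floor(log2(length(x)))))$values, "psd"),
        rep_stats(as.numeric(cwt_scalogram(sub, n_scales = n_scales)$magnitude), "cwt")
      )
      feats["entropy"] <- as.numeric(apen(x, m = 2L, r = 0.2 * sd(x),
                                          max_n = entropy_max_n))
      rows[[length(rows) + 1L]] <-
        data.frame(as.list(feats), label = label, group_id = rec$plant_id,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no usable windows")
  out <- do.call(rbind, rows)
  class(out) <- c("FeatureMatrix", class(out))
  out
}

# six summary statistics of one spectral representation
rep_stats <- function(v, prefix) {
  d <- dispersion(v)
  s <- c(mean(v), max(v), min(v), var(v), d$skewness, d$kurtosis)
  names(s) <- paste(prefix, c("mean", "max", "min", "var", "skew", "kurt"),
                    sep = "_")
  s
}

#' Reduce raw features to PCA1-3 + entropy
#'
#' Standardises the 18 raw spectral features (z-score per column), projects
#' them onto their first three principal components, and returns the final
#' four-feature matrix (PCA1, PCA2, PCA3, entropy). Component signs follow a
#' deterministic convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param fm a raw `FeatureMatrix` from [extract_window_features()].
#' @param n_components number of components (default 3).
#' @return A `FeatureMatrix` data.frame with columns `PCA1..PCAk`, `entropy`,
#'   `label`, `group_id`; explained-variance ratios in
#'   `attr(, "explained_variance")`.
#' @export
pca_features <- function(fm, n_components = 3L) {
  raw_cols <- setdiff(names(fm), c("entropy", "label", "group_id"))
  X <- as.matrix(fm[, raw_cols])
  if (nrow(X) < n_components + 1L) stop("fewer rows than components + 1")
  keep <- apply(X, 2L, sd) > 0
  X <- scale(X[, keep, drop = FALSE])
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |loading| positive
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- X %*% rot
  colnames(scores) <- paste0("PCA", seq_len(k))
  out <- data.frame(scores, entropy = fm$entropy, label = fm$label,
                    group_id = fm$group_id, stringsAsFactors = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "explained_variance") <- ev[seq_len(k)]
  class(out) <- c("FeatureMatrix", class(out))
  out
}

#' The default classifier battery
#'
#' Seven standard classifiers plus a stratified dummy baseline, each a
#' `(fit, predict)` pair with frozen default hyperparameters: decision tree,
#' RBF and linear support-vector classifiers, Gaussian-process classifier,
#' k-nearest neighbours (k = 5), random forest (200 trees), and Gaussian
#' naive Bayes. The dummy predicts labels at random in proportion to the
#' training class frequencies and is the chance-level reference.
#'
#' @return Named list of model definitions for [evaluate_models()].
#' @export
default_models <- function() {
  list(
    decision_tree = list(
      fit = function(X, y) rpart::rpart(y ~ ., data = data.frame(X, y = y),
                                        method = "class",
                                        control = rpart::rpart.control(minsplit = 5)),
      predict = function(fit, X) as.character(predict(fit, data.frame(X), type = "class"))),
    svc_rbf = list(
      fit = function(X, y) e1071::svm(X, y, kernel = "radial"),
      predict = function(fit, X) as.character(predict(fit, X))),
    linear_svc = list(
      fit = function(X, y) e1071::svm(X, y, kernel = "linear"),
      predict = function(fit, X) as.character(predict(fit, X))),
    gaussian_process = list(
      fit = function(X, y) {
        # sigest chatters on stdout; keep battery output clean
        utils::capture.output(
          m <- suppressWarnings(kernlab::gausspr(X, y)))
        m
      },
      predict = function(fit, X) as.character(kernlab::predict(fit, X))),
    knn = list(
      fit = function(X, y) list(X = X, y = y, k = 5L),
      predict = function(fit, X)
        as.character(class::knn(fit$X, X, fit$y, k = min(fit$k, nrow(fit$X))))),
    random_forest = list(
      fit = function(X, y) randomForest::randomForest(X, y, ntree = 200L),
      predict = function(fit, X) as.character(predict(fit, X))),
    naive_bayes = list(
      fit = function(X, y) e1071::naiveBayes(X, y),
      predict = function(fit, X) as.character(predict(fit, data.frame(X)))),
    dummy_stratified = list(
      fit = function(X, y) table(y) / length(y),
      predict = function(fit, X)
        sample(names(fit), nrow(X), replace = TRUE, prob = as.numeric(fit)))
  )
}

# stratified k-fold assignment: within each class, shuffled indices are dealt
# round-robin to folds, so every fold holds ~1/k of each class
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

feature_columns <- function(fm)
  setdiff(names(fm), c("label", "group_id"))

#' Evaluate a classifier battery by repeated stratified k-fold CV
#'
#' For each model and each of `n_repeats` repeats: draw a freshly shuffled
#' stratified k-fold split, train on k-1 folds, predict the held-out fold,
#' and record the mean fold accuracy. Reports the mean and SD of the repeat
#' accuracies (in percent), plus per-class sensitivity `TP/(TP+FN)` and
#' precision `TP/(TP+FP)` pooled over the folds of the first repeat. The
#' whole evaluation is deterministic given `seed`.
#'
#' @param fm a final `FeatureMatrix` (from [pca_features()], or any
#'   data.frame with feature columns + `label`).
#' @param models named list of model definitions (default [default_models()]).
#' @param k_folds folds per repeat (default 5); every class must have at
#'   least `k_folds` rows.
#' @param n_repeats CV repeats (default 50).
#' @param seed master seed.
#' @return A data.frame of class `ModelReport` with one row per model:
#'   `model`, `accuracy_mean`, `accuracy_sd` (percent), `n_repeats`,
#'   `k_folds`, `seed`; per-class rates in `attr(, "rates")`.
#' @export
evaluate_models <- function(fm, models = default_models(), k_folds = 5L,
                            n_repeats = 50L, seed = 1L) {
  y <- as.character(fm$label)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes")
  tab <- table(y)
  if (any(tab < k_folds))
    stop("class '", names(tab)[which.min(tab)], "' has fewer rows (",
         min(tab), ") than k_folds (", k_folds, ")")
  X <- as.matrix(fm[, feature_columns(fm), drop = FALSE])
  reports <- list()
  rates <- list()
  for (mi in seq_along(models)) {
    mname <- names(models)[mi]
    mod <- models[[mi]]
    accs <- numeric(n_repeats)
    conf <- matrix(0, length(classes), length(classes),
                   dimnames = list(truth = classes, pred = classes))
    for (rep_i in seq_len(n_repeats)) {
      with_seed(derive_seed(seed, mi * 100000L + rep_i), {
        fold <- stratified_folds(y, k_folds)
        fold_acc <- numeric(k_folds)
        for (f in seq_len(k_folds)) {
          tr <- fold != f
          fit <- mod$fit(X[tr, , drop = FALSE], factor(y[tr], levels = classes))
          pr <- mod$predict(fit, X[!tr, , drop = FALSE])
          fold_acc[f] <- mean(pr == y[!tr])
          if (rep_i == 1L)
            for (ii in seq_along(pr))
              conf[y[!tr][ii], pr[ii]] <- conf[y[!tr][ii], pr[ii]] + 1
        }
        accs[rep_i] <- mean(fold_acc)
      })
    }
    sens <- diag(conf) / rowSums(conf)
    prec <- diag(conf) / colSums(conf)
    reports[[mi]] <- data.frame(model = mname,
                                accuracy_mean = 100 * mean(accs),
                                accuracy_sd = 100 * sd(accs),
                                n_repeats = n_repeats, k_folds = k_folds,
                                seed = seed, stringsAsFactors = FALSE)
    rates[[mname]] <- list(sensitivity = 100 * sens, precision = 100 * prec,
                           confusion = conf)
  }
  out <- do.call(rbind, reports)
  attr(out, "rates") <- rates
  class(out) <- c("ModelReport", class(out))
  out
}

#' Per-class sensitivity and precision from predictions
#'
#' `sensitivity = TP/(TP+FN)` and `precision = TP/(TP+FP)` per class, from a
#' confusion matrix pooled over whatever holdout scheme produced the
#' predictions. A class absent from the truth (sensitivity) or never
#' predicted (precision) gets `NaN` (undefined).
#'
#' @param truth character/factor vector of true labels.
#' @param pred predicted labels, same length.
#' @return List with `sensitivity`, `precision` (percent, named by class) and
#'   the `confusion` matrix.
#' @export
sensitivity_precision <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  classes <- sort(unique(c(truth, pred)))
  conf <- table(factor(truth, classes), factor(pred, classes))
  tp <- diag(conf)
  list(sensitivity = 100 * tp / rowSums(conf),
       precision = 100 * tp / colSums(conf),
       confusion = conf)
}

#' Scatter plot of two features coloured by class
#'
#' @param fm a `FeatureMatrix`.
#' @param coords pair of feature names to plot (default PCA1 vs entropy).
#' @param path output file (png or svg, by extension).
#' @param width,height,dpi device geometry.
#' @return Invisibly, `path`.
#' @export
scatter_plot <- function(fm, coords = c("PCA1", "entropy"), path,
                         width = 6, height = 4, dpi = 150) {
  if (nrow(fm) == 0L) stop("empty feature matrix")
  if (!all(coords %in% names(fm)))
    stop("unknown feature(s): ", paste(setdiff(coords, names(fm)), collapse = ", "))
  p <- ggplot2::ggplot(fm, ggplot2::aes(
         x = .data[[coords[1]]], y = .data[[coords[2]]], colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "class") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}

#' Build and evaluate the standard condition comparisons
#'
#' Given a labelled set of recordings (classes `bean-before`, `bean-after`,
#' `wheat-before`, `wheat-after`), builds the five standard two-class
#' comparisons — each before/after pair, before-vs-before, after-vs-after,
#' and pooled bean-vs-wheat — extracts windowed features for each, and runs
#' the classifier battery.
#'
#' @param recs list of labelled recordings (e.g. from [gen_experiment()]).
#' @param comparisons named list of class-label pairs; `NULL` for the five
#'   defaults. For the pooled comparison, labels are matched by prefix.
#' @param n_windows,overlap_fraction window layout per recording.
#' @param models,k_folds,n_repeats,seed passed to [evaluate_models()].
#' @return Named list of `ModelReport` data.frames, one per comparison.
#' @export
compare_conditions <- function(recs, comparisons = NULL, n_windows = 10L,
                               overlap_fraction = 0.3,
                               models = default_models(), k_folds = 5L,
                               n_repeats = 50L, seed = 1L) {
  labels <- vapply(recs, function(r) r$class %||%
                     paste(r$treatment, r$phase, sep = "-"), character(1))
  if (is.null(comparisons))
    comparisons <- list(
      "CB-before_vs_CB-after" = c("bean-before", "bean-after"),
      "CW-before_vs_CW-after" = c("wheat-before", "wheat-after"),
      "CB-before_vs_CW-before" = c("bean-before", "wheat-before"),
      "CB-after_vs_CW-after" = c("bean-after", "wheat-after"),
      "CB_vs_CW" = c("bean", "wheat")
    )
  out <- list()
  for (nm in names(comparisons)) {
    pair <- comparisons[[nm]]
    sel <- lapply(pair, function(p) {
      hit <- which(labels == p)
      if (!length(hit)) hit <- which(startsWith(labels, p))
      if (!length(hit)) stop("no recordings for group '", p, "'")
      hit
    })
    sub <- recs[unlist(sel)]
    # pooled comparisons relabel by prefix
    for (i in seq_along(sub)) {
      l <- sub[[i]]$class %||% ""
      sub[[i]]$class <- pair[which(vapply(pair, function(p)
        l == p || startsWith(l, p), logical(1)))[1L]]
    }
    ws <- lapply(sub, segment, n_windows = n_windows,
                 overlap_fraction = overlap_fraction)
    fm <- pca_features(extract_window_features(ws))
    out[[nm]] <- evaluate_models(fm, models = models, k_folds = k_folds,
                                 n_repeats = n_repeats,
                                 seed = derive_seed(seed, match(nm, names(comparisons))))
  }
  out
}
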