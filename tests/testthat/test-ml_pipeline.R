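# small labelled feature matrix with well-separated clusters
make_fm <- function(n_per_class = 25, gap = 6, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n_per_class * 4), ncol = 4)
  b <- matrix(rnorm(n_per_class * 4, mean = gap), ncol = 4)
  fm <- data.frame(rbind(a, b))
  names(fm) <- c("PCA1", "PCA2", "PCA3", "entropy")
  fm$label <- rep(c("A", "B"), each = n_per_class)
  fm$group_id <- paste0("g", seq_len(nrow(fm)))
  fm
}

test_that("window features have the documented shape and determinism", {
  rec <- gen_colored_noise(1, n = 6000, seed = 81)
  rec$class <- "x"
  ws <- segment(rec, 10, 0.3)
  fm <- extract_window_features(ws)
  expect_equal(nrow(fm), 10L)
  raw <- setdiff(names(fm), c("label", "group_id"))
  expect_length(raw, 19L)  # 3 representations x 6 stats + entropy
  expect_false(anyNA(fm[raw]))
  fm2 <- extract_window_features(ws)
  expect_identical(fm, fm2)
})

test_that("window summary statistics match the descriptive-module oracle", {
  rec <- gen_colored_noise(1.2, n = 4000, seed = 83)
  ws <- segment(rec, 10, 0.3)
  fm <- extract_window_features(ws)
  x <- window_samples(ws, 3)
  v <- fft_spectrum(recording(x, fs = rec$fs))$values
  d <- dispersion(v)
  expect_equal(fm$fft_mean[3], mean(v), tolerance = 1e-9)
  expect_equal(fm$fft_max[3], max(v), tolerance = 1e-9)
  expect_equal(fm$fft_var[3], var(v), tolerance = 1e-9)
  expect_equal(fm$fft_skew[3], d$skewness, tolerance = 1e-9)
  expect_equal(fm$fft_kurt[3], d$kurtosis, tolerance = 1e-9)
})

test_that("pca_features returns orthogonal, variance-ordered components", {
  rec1 <- gen_colored_noise(0.5, n = 6000, seed = 85); rec1$class <- "a"
  rec2 <- gen_colored_noise(2, n = 6000, seed = 86); rec2$class <- "b"
  fm <- pca_features(extract_window_features(lapply(list(rec1, rec2), segment)))
  expect_named(fm, c("PCA1", "PCA2", "PCA3", "entropy", "label", "group_id"))
  S <- as.matrix(fm[, 1:3])
  cp <- crossprod(S)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  ev <- attr(fm, "explained_variance")
  expect_true(all(diff(ev) <= 1e-12))
})

test_that("rank-3 data is fully explained by three components", {
  set.seed(87)
  basis <- matrix(rnorm(18 * 3), ncol = 3)
  scores <- matrix(rnorm(40 * 3), ncol = 3)
  raw <- data.frame(scores %*% t(basis))
  raw$entropy <- rnorm(40)
  raw$label <- rep(c("a", "b"), 20)
  raw$group_id <- "g"
  fm <- pca_features(raw)
  expect_equal(sum(attr(fm, "explained_variance")), 1, tolerance = 1e-9)
})

test_that("separable clusters are classified nearly perfectly by all real models", {
  fm <- make_fm(gap = 6)
  rep <- evaluate_models(fm, k_folds = 5, n_repeats = 3, seed = 5)
  real <- rep[rep$model != "dummy_stratified", ]
  expect_true(all(real$accuracy_mean >= 95))
  expect_lt(rep$accuracy_mean[rep$model == "dummy_stratified"], 70)
})

test_that("evaluation is reproducible bit-for-bit given the seed", {
  fm <- make_fm(gap = 1, seed = 2)
  r1 <- evaluate_models(fm, n_repeats = 4, seed = 11)
  r2 <- evaluate_models(fm, n_repeats = 4, seed = 11)
  expect_identical(r1, r2)
  r3 <- evaluate_models(fm, n_repeats = 4, seed = 12)
  expect_false(identical(r1$accuracy_mean, r3$accuracy_mean))
})

test_that("permuted labels give chance-level accuracy", {
  fm <- make_fm(gap = 5, seed = 3)
  set.seed(91)
  fm$label <- sample(fm$label)
  rep <- evaluate_models(fm, n_repeats = 20, seed = 7)
  expect_true(all(abs(rep$accuracy_mean - 50) <= 12))
})

test_that("stratified dummy converges to the sum of squared class proportions", {
  set.seed(93)
  fm <- data.frame(PCA1 = rnorm(100), entropy = rnorm(100),
                   label = rep(c("maj", "min"), times = c(60, 40)),
                   group_id = "g")
  rep <- evaluate_models(fm, models = default_models()["dummy_stratified"],
                         n_repeats = 50, seed = 9)
  # expected accuracy of proportional random assignment: 0.6^2 + 0.4^2 = 52%
  expect_lt(abs(rep$accuracy_mean - 52), 5)
  expect_error(evaluate_models(fm[1:62, ], n_repeats = 2, seed = 1), "min")
})

test_that("sensitivity and precision follow the confusion-matrix arithmetic", {
  sp <- sensitivity_precision(c("a", "a", "b", "b"), c("a", "a", "b", "b"))
  expect_equal(unname(sp$sensitivity), c(100, 100))
  expect_equal(unname(sp$precision), c(100, 100))

  # constant single-class predictor on balanced binary
  sp2 <- sensitivity_precision(rep(c("a", "b"), 5), rep("a", 10))
  expect_equal(unname(sp2$sensitivity), c(100, 0))
  expect_equal(unname(sp2$precision[1]), 50)
  expect_true(is.nan(sp2$precision[2]))

  # hand-counted 10-row fixture
  truth <- c("a", "a", "a", "a", "b", "b", "b", "c", "c", "c")
  pred  <- c("a", "a", "b", "c", "b", "b", "a", "c", "c", "a")
  sp3 <- sensitivity_precision(truth, pred)
  # confusion: a-row (a:2, b:1, c:1), b-row (a:1, b:2), c-row (a:1, c:2)
  expect_equal(unname(sp3$sensitivity), 100 * c(2/4, 2/3, 2/3))
  expect_equal(unname(sp3$precision), 100 * c(2/4, 2/3, 2/3))
})

test_that("scatter_plot writes a file and validates features", {
  fm <- make_fm()
  f <- file.path(withr::local_tempdir(), "sc.png")
  scatter_plot(fm, path = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_error(scatter_plot(fm, coords = c("nope", "entropy"), path = f),
               "unknown feature")
  expect_error(scatter_plot(fm[0, ], path = f), "empty")
})

test_that("compare_conditions builds the five standard comparisons", {
  recs <- gen_experiment(experiment_configs(n = 4200), n_per_class = 5, seed = 95)
  reps <- compare_conditions(recs, n_repeats = 2,
                             models = default_models()[c("knn", "dummy_stratified")])
  expect_length(reps, 5L)
  expect_named(reps, c("CB-before_vs_CB-after", "CW-before_vs_CW-after",
                       "CB-before_vs_CW-before", "CB-after_vs_CW-after",
                       "CB_vs_CW"))
  for (r in reps) expect_s3_class(r, "ModelReport")
  expect_error(compare_conditions(recs[1:5], n_repeats = 1), "no recordings")
})
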