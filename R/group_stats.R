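#' Paired before/after comparison with normality-gated test choice
#'
#' Tests whether a parameter changed after the stimulus, on paired
#' observations. The paired differences are screened with Shapiro-Wilk
#' (alpha = 0.05): normal-looking differences go to the paired t-test,
#' otherwise the Wilcoxon signed-rank test. Two-sided throughout.
#'
#' @param before,after numeric vectors of equal length (>= 3), one value per
#'   plant.
#' @param alpha significance level for reporting (default 0.05).
#' @return List of class `ComparisonResult`: `parameter`-free fields `test`
#'   (`"paired_t"` or `"wilcoxon_signed_rank"`), `statistic`, `p_value`,
#'   `n_a`, `n_b`, `normality_p`, `alpha`, `significant`, `degenerate`.
#' @export
paired_compare <- function(before, after, alpha = 0.05) {
  if (length(before) != length(after)) stop("paired groups must have equal length")
  if (length(before) < 3L) stop("need at least 3 pairs")
  d <- after - before
  if (all(d == d[1L])) {
    return(structure(list(test = "degenerate", statistic = NA_real_,
                          p_value = if (all(d == 0)) 1 else NA_real_,
                          n_a = length(before), n_b = length(after),
                          normality_p = NA_real_, alpha = alpha,
                          significant = FALSE, degenerate = TRUE),
                     class = "ComparisonResult"))
  }
  sw <- shapiro.test(d)
  if (sw$p.value > 0.05) {
    tt <- t.test(after, before, paired = TRUE)
    test <- "paired_t"
  } else {
    tt <- suppressWarnings(wilcox.test(after, before, paired = TRUE))
    test <- "wilcoxon_signed_rank"
  }
  structure(list(test = test, statistic = unname(tt$statistic),
                 p_value = tt$p.value, n_a = length(before),
                 n_b = length(after), normality_p = sw$p.value, alpha = alpha,
                 significant = tt$p.value <= alpha, degenerate = FALSE),
            class = "ComparisonResult")
}

#' Independent two-group comparison with normality-gated test choice
#'
#' Compares a parameter between two treatments. Each group is screened with
#' Shapiro-Wilk (alpha = 0.05); when both look normal a Student's t-test
#' (pooled variance) is used, otherwise the Mann-Whitney U test. Two-sided.
#'
#' @param group_a,group_b numeric vectors (each >= 3 values).
#' @param alpha significance level (default 0.05).
#' @return A `ComparisonResult` (see [paired_compare()]); `test` is
#'   `"students_t"` or `"mann_whitney_u"`, `normality_p` holds both groups'
#'   Shapiro-Wilk p-values.
#' @export
independent_compare <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("each group needs at least 3 values")
  if (var(group_a) == 0 && var(group_b) == 0 && group_a[1L] == group_b[1L]) {
    return(structure(list(test = "degenerate", statistic = NA_real_,
                          p_value = 1, n_a = length(group_a),
                          n_b = length(group_b),
                          normality_p = c(NA_real_, NA_real_), alpha = alpha,
                          significant = FALSE, degenerate = TRUE),
                     class = "ComparisonResult"))
  }
  sw_a <- if (var(group_a) > 0) shapiro.test(group_a)$p.value else 0
  sw_b <- if (var(group_b) > 0) shapiro.test(group_b)$p.value else 0
  if (sw_a > 0.05 && sw_b > 0.05) {
    tt <- t.test(group_a, group_b, var.equal = TRUE)
    test <- "students_t"
  } else {
    tt <- suppressWarnings(wilcox.test(group_a, group_b))
    test <- "mann_whitney_u"
  }
  structure(list(test = test, statistic = unname(tt$statistic),
                 p_value = tt$p.value, n_a = length(group_a),
                 n_b = length(group_b), normality_p = c(a = sw_a, b = sw_b),
                 alpha = alpha, significant = tt$p.value <= alpha,
                 degenerate = FALSE),
            class = "ComparisonResult")
}

significance_stars <- function(p) {
  if (!is.finite(p)) return("")
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
}

# the seven per-recording signal parameters the summary table reports
recording_parameters <- function(rec, psd_band = c(0.01, 10),
                                 apen_max_n = 20000L, acf_max_lag = NULL) {
  if (is.null(acf_max_lag)) acf_max_lag <- min(rec$n - 1L, 5000L)
  d <- dispersion(rec)
  L <- correlation_time(acf_recording(rec, max_lag = acf_max_lag))$L
  pf <- fit_psd_exponent(psd(rec), band = psd_band)
  tf <- tryCatch(pdf_tail_fit(rec), error = function(e) list(slope = NA_real_))
  ae <- as.numeric(apen(rec, m = 2L, r = 0.2 * d$sd, max_n = apen_max_n))
  c(asymmetry = d$skewness, kurtosis = d$kurtosis, mean_uV = d$mean,
    L = L, ApEn = ae, PSD_slope = pf$slope, PDF_slope = tf$slope)
}

#' Parameter summary table with before/after and between-treatment tests
#'
#' Computes seven signal parameters (asymmetry, kurtosis, mean µV,
#' correlation time L, ApEn, PSD log-log slope, PDF tail slope) for every
#' recording, then reports per treatment x phase cell means with
#' [paired_compare()] p-values for each treatment's before-vs-after contrast
#' and [independent_compare()] p-values between treatments within each phase.
#'
#' @param recs list of labelled recordings; labels must distinguish two
#'   treatments x `before`/`after` (e.g. from [gen_experiment()]). Pairing of
#'   before/after values is by `plant_id`.
#' @param alpha significance level for the stars.
#' @param apen_max_n,acf_max_lag computation caps forwarded to the
#'   per-recording parameter extraction.
#' @return List with `values` (long data.frame: parameter, class, plant_id,
#'   value), `table` (parameter x class cell means with stars), and `tests`
#'   (data.frame of contrasts with chosen test and p-value).
#' @export
table_report <- function(recs, alpha = 0.05, apen_max_n = 20000L,
                         acf_max_lag = NULL) {
  labels <- vapply(recs, function(r) r$class %||%
                     paste(r$treatment, r$phase, sep = "-"), character(1))
  params <- lapply(recs, recording_parameters, apen_max_n = apen_max_n,
                   acf_max_lag = acf_max_lag)
  long <- do.call(rbind, lapply(seq_along(recs), function(i)
    data.frame(parameter = names(params[[i]]), value = as.numeric(params[[i]]),
               class = labels[i], plant_id = recs[[i]]$plant_id,
               phase = recs[[i]]$phase, treatment = recs[[i]]$treatment,
               stringsAsFactors = FALSE)))
  pnames <- unique(long$parameter)
  classes <- unique(long$class)
  cell <- function(p, cl) long$value[long$parameter == p & long$class == cl]
  tab <- sapply(classes, function(cl) sapply(pnames, function(p) mean(cell(p, cl))))
  tests <- list()
  treatments <- unique(long$treatment)
  for (p in pnames) {
    # before vs after within each treatment (paired by plant_id)
    for (tr in treatments) {
      sub <- long[long$parameter == p & long$treatment == tr, ]
      if (!all(c("before", "after") %in% sub$phase)) next
      b <- sub[sub$phase == "before", ]
      a <- sub[sub$phase == "after", ]
      ids <- intersect(b$plant_id, a$plant_id)
      if (length(ids) < 3L) next
      cmp <- paired_compare(b$value[match(ids, b$plant_id)],
                            a$value[match(ids, a$plant_id)], alpha = alpha)
      tests[[length(tests) + 1L]] <- data.frame(
        parameter = p, contrast = sprintf("%s: before vs after", tr),
        test = cmp$test, p_value = cmp$p_value,
        stars = significance_stars(cmp$p_value), stringsAsFactors = FALSE)
    }
    # treatment vs treatment within each phase
    if (length(treatments) >= 2L) {
      for (ph in intersect(c("before", "after"), unique(long$phase))) {
        g <- lapply(treatments[1:2], function(tr)
          long$value[long$parameter == p & long$treatment == tr &
                       long$phase == ph])
        if (any(lengths(g) < 3L)) next
        cmp <- independent_compare(g[[1]], g[[2]], alpha = alpha)
        tests[[length(tests) + 1L]] <- data.frame(
          parameter = p,
          contrast = sprintf("%s vs %s (%s)", treatments[1], treatments[2], ph),
          test = cmp$test, p_value = cmp$p_value,
          stars = significance_stars(cmp$p_value), stringsAsFactors = FALSE)
      }
    }
  }
  list(values = long, table = tab,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(parameter = character(), contrast = character(),
                    test = character(), p_value = numeric(),
                    stars = character()))
}
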