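#' Summarize a parameter as mean +/- SD or median [Q1, Q3]
#'
#' Normally distributed parameters are reported as mean and sample standard
#' deviation (n - 1 denominator), skewed ones as median and interquartile
#' range with linear-interpolation quantiles.
#'
#' @param x Numeric vector, `NA`s dropped.
#' @param distribution `"normal"` or `"non_normal"`.
#' @return Named list: `n`, then `mean`/`sd` or `median`/`q1`/`q3`, plus a
#'   formatted `label`.
#' @export
summarize_values <- function(x, distribution = c("normal", "non_normal")) {
  distribution <- match.arg(distribution)
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    stop_rimquant("cannot summarize an empty vector", class = "rimquant_validation")
  if (distribution == "normal") {
    s <- if (length(x) > 1L) sd(x) else 0
    list(n = length(x), mean = mean(x), sd = s,
         label = sprintf("%.2f ± %.2f", mean(x), s))
  } else {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
         label = sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3]))
  }
}

new_group_comparison <- function(parameter, groups, summaries, test, statistic, p) {
  structure(list(parameter = parameter, groups = groups, summaries = summaries,
                 test = test, statistic = statistic, p_value = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  labs <- vapply(x$summaries, function(s) s$label, character(1))
  cat(sprintf("%s: %s | %s (stat %.4g, p %s)\n", x$parameter,
              paste(sprintf("%s %s", x$groups, labs), collapse = " vs "),
              x$test, x$statistic, format_p(x$p_value)))
  invisible(x)
}

#' One-way ANOVA for two groups (raw data)
#'
#' Pooled-variance one-way ANOVA; with two groups F equals the square of
#' the pooled two-sample t statistic, on (1, n1 + n2 - 2) degrees of
#' freedom.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector with exactly two levels, each n >= 2.
#' @param parameter Label carried into the result.
#' @return A `group_comparison`.
#' @export
anova_two_group <- function(values, groups, parameter = "parameter") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) != 2L)
    stop_rimquant("exactly two groups required", class = "rimquant_validation")
  ns <- tabulate(groups)
  if (any(ns < 2L))
    stop_rimquant("each group needs n >= 2", class = "rimquant_validation")
  sp <- split(values, groups)
  fp <- anova_from_summary(mean(sp[[1]]), sd(sp[[1]]), ns[1],
                           mean(sp[[2]]), sd(sp[[2]]), ns[2])
  new_group_comparison(parameter, levels(groups),
                       lapply(sp, summarize_values, distribution = "normal"),
                       "anova", fp[["F"]], fp[["p"]])
}

#' One-way two-group ANOVA from group summaries
#'
#' Computes the identical pooled-variance F and p from per-group mean, SD
#' and n alone, which lets published summary tables be checked without the
#' raw data.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Per-group summaries; `n >= 2`, `sd >= 0`.
#' @return Named vector `c(F =, p =)`.
#' @export
anova_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    f <- if (mean1 == mean2) 0 else Inf
  } else {
    f <- (mean1 - mean2)^2 / (sp2 * (1 / n1 + 1 / n2))
  }
  c(F = f, p = pf(f, 1, n1 + n2 - 2, lower.tail = FALSE))
}

#' Two-sided Mann-Whitney U test
#'
#' When the combined sample size is at most `exact_max_n` the exact null
#' distribution of U is obtained by enumerating every assignment of the
#' observations to the two groups (tie-averaged ranks, so tied data are
#' handled exactly too); the two-sided p is twice the smaller tail, capped
#' at 1. Larger samples use the normal approximation with tie and
#' continuity corrections. The reported statistic is U for the first group.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector, each group non-empty.
#' @param parameter Label carried into the result.
#' @param exact_max_n Largest combined n for the exact path (default 12).
#' @return A `group_comparison` whose statistic is U for the first group.
#' @export
mann_whitney_u <- function(values, groups, parameter = "parameter",
                           exact_max_n = 12) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) != 2L || any(tabulate(groups) < 1L))
    stop_rimquant("two non-empty groups required", class = "rimquant_validation")
  sp <- split(values, groups)
  n1 <- length(sp[[1]]); n <- length(values)
  rk <- rank(values)
  u_obs <- sum(rk[groups == levels(groups)[1]]) - n1 * (n1 + 1) / 2
  if (n <= exact_max_n) {
    idx <- utils::combn(n, n1)
    u_all <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                        mean(u_all >= u_obs - eps)))
  } else {
    wt <- suppressWarnings(wilcox.test(sp[[1]], sp[[2]], exact = FALSE,
                                       correct = TRUE))
    p <- wt$p.value
  }
  new_group_comparison(parameter, levels(groups),
                       lapply(sp, summarize_values, distribution = "non_normal"),
                       "mann_whitney_u", u_obs, p)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's statistic without continuity correction. All-zero rows or
#' columns are dropped with a warning before testing.
#'
#' @param table Matrix of non-negative integer counts.
#' @param parameter Label carried into the result.
#' @return A `group_comparison` (summaries empty).
#' @export
pearson_chi_square <- function(table, parameter = "parameter") {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_rimquant("counts must be non-negative integers", class = "rimquant_validation")
  zr <- rowSums(table) == 0; zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero row(s)/column(s) before testing", call. = FALSE)
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (any(dim(table) < 2L))
    stop_rimquant("need at least a 2 x 2 table after dropping zero margins",
                  class = "rimquant_validation")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  new_group_comparison(parameter, colnames(table), list(),
                       "pearson_chi_square", unname(ct$statistic), ct$p.value)
}

#' Kruskal-Wallis test across steatosis (or other) groups
#'
#' H statistic with tie correction; p from the chi-square approximation on
#' groups - 1 degrees of freedom.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector, at least two non-empty levels.
#' @param parameter Label carried into the result.
#' @return A `group_comparison`.
#' @export
kruskal_wallis <- function(values, groups, parameter = "parameter") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2L)
    stop_rimquant("need at least two non-empty groups", class = "rimquant_validation")
  kt <- kruskal.test(values, groups)
  new_group_comparison(parameter, levels(groups),
                       lapply(split(values, groups), summarize_values,
                              distribution = "non_normal"),
                       "kruskal_wallis", unname(kt$statistic), kt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks; two-sided p from the
#' t approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3 after `NA` removal.
#' @return Named list `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop_rimquant("need at least 3 complete pairs", class = "rimquant_validation")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Multiple linear regression of a fluorescence parameter on covariates
#'
#' Ordinary least squares with intercept: dependent fluorescence parameter
#' on pretreatment (0/1), superficiality (0/1, capsular = 1) and tumor size
#' in cm. Per-coefficient two-sided t tests on n - 4 degrees of freedom.
#'
#' @param y Dependent fluorescence parameter.
#' @param pretreatment,superficiality 0/1 (or logical) covariates.
#' @param size_cm Tumor size in cm.
#' @param dependent Name of the dependent parameter, for reporting.
#' @return Object of class `regression_fit`: coefficient table
#'   (estimate, SE, t, p), `n`, the underlying `lm` fit.
#' @export
fit_ols <- function(y, pretreatment, superficiality, size_cm,
                    dependent = "parameter") {
  df <- data.frame(y = y, pretreatment = as.numeric(pretreatment),
                   superficiality = as.numeric(superficiality),
                   size_cm = as.numeric(size_cm))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) <= 4L)
    stop_rimquant("need more than 4 complete rows", class = "rimquant_validation")
  X <- model.matrix(~ pretreatment + superficiality + size_cm, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_rimquant("rank-deficient design; collinear column(s): ",
                  paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                        collapse = ", "),
                  class = "rimquant_validation")
  fit <- lm(y ~ pretreatment + superficiality + size_cm, data = df)
  sm <- summary(fit)$coefficients
  structure(list(dependent = dependent,
                 coefficients = data.frame(
                   term = c("intercept", "pretreatment", "superficiality",
                            "size_cm"),
                   estimate = unname(sm[, 1]), se = unname(sm[, 2]),
                   t = unname(sm[, 3]), p_value = unname(sm[, 4])),
                 n = nrow(df), lm = fit),
            class = "regression_fit")
}

#' @export
coef.regression_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s ~ pretreatment + superficiality + size_cm (n = %d)\n",
              x$dependent, x$n))
  tab <- x$coefficients
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-15s %8.4f (SE %.4f)  p %s\n", tab$term[i],
                tab$estimate[i], tab$se[i], format_p(tab$p_value[i])))
  invisible(x)
}

#' Format a p value for reporting
#'
#' Half-up rounding to three decimals; values below 0.001 print as
#' `"<0.001"`.
#'
#' @param p Numeric p value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  out <- ifelse(p < 0.001, "<0.001",
                sprintf("%.3f", floor(p * 1000 + 0.5) / 1000))
  out[is.na(p)] <- "NA"
  out
}

#' Default statistical configuration for the cohort analysis
#'
#' Chooses the test per fluorescence parameter the way the reporting style
#' implies: maximum intensity (and demographic continuous covariates) are
#' treated as normal and compared by one-way ANOVA; MSFI, MBFI and SBR are
#' skewed and compared by Mann-Whitney U.
#'
#' @param tests Named character vector mapping parameter column to
#'   `"anova"` or `"mann_whitney_u"`.
#' @param alpha Significance threshold (reporting only).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(tests = c(msfi_au = "mann_whitney_u",
                                    mbfi_au = "mann_whitney_u",
                                    sbr = "mann_whitney_u",
                                    max_intensity_au = "anova"),
                          alpha = 0.05) {
  stopifnot(all(tests %in% c("anova", "mann_whitney_u")))
  structure(list(tests = tests, alpha = alpha), class = "cohort_config")
}

compare_parameter <- function(values, groups, parameter, test) {
  switch(test,
         anova = anova_two_group(values, groups, parameter),
         mann_whitney_u = mann_whitney_u(values, groups, parameter))
}

#' Run the full cohort statistical battery
#'
#' Produces, from a per-lesion record table (see [lesion_records()]):
#' per-parameter comparisons by pretreatment and by superficiality (test
#' chosen per the configuration), the Kruskal-Wallis test of MBFI across
#' steatosis grades, Spearman correlations of tumor size with each
#' parameter, four OLS fits (one per fluorescence parameter), and the
#' RECIST stratification as descriptive summaries only — group sizes there
#' are too small for testing, so none is performed.
#'
#' @param records Data frame with columns `msfi_au`, `mbfi_au`, `sbr`,
#'   `max_intensity_au`, `pretreated`, `superficiality`,
#'   `steatosis_grade`, `diameter_baseline_mm`, and optionally `recist`.
#' @param config A [cohort_config()].
#' @return List of class `cohort_report`.
#' @export
run_paper_analyses <- function(records, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  params <- names(config$tests)
  if (!is.null(records$excluded_insufficient_tissue))
    records <- records[!(records$excluded_insufficient_tissue %in% TRUE), ,
                       drop = FALSE]
  size_cm <- records$diameter_baseline_mm / 10
  log <- character()
  cmp_by <- function(groups, label) {
    g <- factor(groups)
    out <- list()
    for (p in params) {
      if (nlevels(droplevels(g[!is.na(records[[p]])])) < 2L) {
        log <<- c(log, sprintf("skipped %s by %s: fewer than two groups", p, label))
        next
      }
      out[[p]] <- tryCatch(
        compare_parameter(records[[p]], g, p, config$tests[[p]]),
        error = function(e) {
          log <<- c(log, sprintf("skipped %s by %s: %s", p, label,
                                 conditionMessage(e)))
          NULL
        })
    }
    out
  }
  chemo <- cmp_by(ifelse(records$pretreated, "pretreated", "untreated"),
                  "pretreatment")
  superf <- cmp_by(records$superficiality, "superficiality")
  steatosis <- tryCatch(
    kruskal_wallis(records$mbfi_au, records$steatosis_grade, "mbfi_au"),
    error = function(e) {
      log <<- c(log, paste("steatosis Kruskal-Wallis skipped:",
                           conditionMessage(e)))
      NULL
    })
  spearman <- lapply(setNames(params, params), function(p)
    tryCatch(spearman_cor(size_cm, records[[p]]),
             error = function(e) {
               log <<- c(log, sprintf("Spearman for %s skipped: %s", p,
                                      conditionMessage(e)))
               NULL
             }))
  capsular <- as.numeric(records$superficiality == "capsular")
  ols <- lapply(setNames(params, params), function(p)
    tryCatch(fit_ols(records[[p]], records$pretreated, capsular, size_cm,
                     dependent = p),
             error = function(e) {
               log <<- c(log, sprintf("OLS for %s skipped: %s", p,
                                      conditionMessage(e)))
               NULL
             }))
  recist_groups <- if (!is.null(records$recist))
    split(records, ifelse(is.na(records$recist), "no_chemotherapy",
                          records$recist))
  else list()
  recist <- lapply(recist_groups, function(g) {
    c(list(n = nrow(g)),
      lapply(setNames(params, params), function(p)
        if (sum(!is.na(g[[p]]))) summarize_values(g[[p]], "non_normal")$label
        else NA_character_))
  })
  structure(list(by_pretreatment = chemo, by_superficiality = superf,
                 steatosis_mbfi = steatosis, spearman_size = spearman,
                 ols = ols, recist_descriptive = recist, log = log,
                 config = config),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("== Comparison by pretreatment ==\n")
  for (g in x$by_pretreatment) print(g)
  cat("== Comparison by superficiality ==\n")
  for (g in x$by_superficiality) print(g)
  if (!is.null(x$steatosis_mbfi)) {
    cat("== MBFI across steatosis grades ==\n"); print(x$steatosis_mbfi)
  }
  cat("== Spearman: tumor size vs parameter ==\n")
  for (p in names(x$spearman_size)) {
    s <- x$spearman_size[[p]]
    if (!is.null(s))
      cat(sprintf("  %s: rho %.4f, p %s (n %d)\n", p, s$rho,
                  format_p(s$p_value), s$n))
  }
  cat("== Multiple linear regression ==\n")
  for (f in x$ols) if (!is.null(f)) print(f)
  if (length(x$recist_descriptive)) {
    cat("== RECIST strata (descriptive only) ==\n")
    for (nm in names(x$recist_descriptive)) {
      r <- x$recist_descriptive[[nm]]
      cat(sprintf("  %s (n %d): MSFI %s, SBR %s\n", nm, r$n,
                  r$msfi_au, r$sbr))
    }
  }
  if (length(x$log)) cat("log:\n ", paste(x$log, collapse = "\n  "), "\n")
  invisible(x)
}
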