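#' Descriptive statistics with a normality diagnostic
#'
#' Sample descriptives in the layout of a session-level summary table:
#' n, missing count, mean, median, sample SD (n - 1), range, and the
#' Shapiro-Wilk normality diagnostic (reported, never used to switch tests
#' automatically; it requires 3 <= n <= 5000 and is `NA` otherwise).
#'
#' @param values Numeric vector; `NA`s are excluded and counted.
#' @return A `descriptive_stats` object (also a one-row data.frame-able
#'   list): `n`, `n_missing`, `mean`, `median`, `sd`, `min`, `max`,
#'   `shapiro_w`, `shapiro_p`, `small_n` flag.
#' @export
describe_values <- function(values) {
  n_missing <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("empty-input error: all values missing")
  sw <- if (length(v) >= 3L && length(v) <= 5000L && sd(v) > 0)
    shapiro.test(v) else list(statistic = NA_real_, p.value = NA_real_)
  structure(list(n = length(v), n_missing = n_missing,
                 mean = mean(v), median = median(v),
                 sd = if (length(v) > 1L) sd(v) else 0,
                 min = min(v), max = max(v),
                 shapiro_w = unname(sw$statistic),
                 shapiro_p = unname(sw$p.value),
                 small_n = length(v) < 2L),
            class = "descriptive_stats")
}

#' Paired Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Differences are taken as `pre - post`; zero differences are dropped and
#' tied absolute differences mid-ranked. The reported statistic `W` is the
#' smaller of the positive and negative rank sums. The two-sided p-value is
#' exact (`2 * P(V <= W)` from the signed-rank distribution, equal to the
#' exhaustive sign-flip enumeration) for n <= 25 without ties, otherwise a
#' normal approximation with tie correction. The matched-pairs rank-biserial
#' correlation is `(T+ - T-) / (T+ + T-)`, negative when post > pre
#' dominates. The mean difference, its standard error and 95% confidence
#' interval (t-based, on the raw differences including zeros) are reported
#' alongside.
#'
#' @param pre,post Equal-length numeric vectors of paired observations.
#' @return A `paired_test_result`: `wilcoxon_w`, `p_wilcoxon`, `exact`,
#'   `rank_biserial_r`, `mean_difference`, `se_difference`, `ci_low`,
#'   `ci_high`, `n_pairs`, `n_zero_dropped`.
#' @export
paired_wilcoxon <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  d_all <- pre - post
  if (anyNA(d_all)) stop("missing values in paired data")
  d <- d_all[d_all != 0]
  if (length(d) == 0L) stop("degenerate-test error: all differences zero")
  n <- length(d)
  rk <- rank(abs(d))
  t_pos <- sum(rk[d > 0])
  t_neg <- sum(rk[d < 0])
  w <- min(t_pos, t_neg)
  ties <- anyDuplicated(rk) > 0L
  if (n <= 25L && !ties) {
    p <- min(1, 2 * psignrank(w, n))
    exact <- TRUE
  } else {
    nties <- table(rk)
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(nties^3 - nties) / 48
    z <- (t_pos - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  m <- length(d_all)
  se <- sd(d_all) / sqrt(m)
  tcrit <- qt(0.975, m - 1)
  structure(list(wilcoxon_w = w, p_wilcoxon = p, exact = exact,
                 rank_biserial_r = (t_pos - t_neg) / (t_pos + t_neg),
                 mean_difference = mean(d_all), se_difference = se,
                 ci_low = mean(d_all) - tcrit * se,
                 ci_high = mean(d_all) + tcrit * se,
                 n_pairs = m, n_zero_dropped = m - n),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  if (!is.null(x$wilcoxon_w))
    cat(sprintf("Wilcoxon signed-rank: W = %g, p = %.4g (%s), rank-biserial r = %.3f\n",
                x$wilcoxon_w, x$p_wilcoxon,
                if (isTRUE(x$exact)) "exact" else "normal approx.",
                x$rank_biserial_r))
  if (!is.null(x$student_t))
    cat(sprintf("Paired t: t(%d) = %.3f, p = %.4g\n", x$df, x$student_t, x$p_t))
  cat(sprintf("Mean difference %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$mean_difference, x$se_difference, x$ci_low, x$ci_high))
  invisible(x)
}

#' Paired Student's t-test
#'
#' Standard paired t-test on `pre - post` differences with the 95%
#' confidence interval of the mean difference. A zero-variance difference
#' vector (all differences identical) is surfaced as an error, not a silent
#' infinite statistic.
#'
#' @inheritParams paired_wilcoxon
#' @return A `paired_test_result`: `student_t`, `df`, `p_t`,
#'   `mean_difference`, `se_difference`, `ci_low`, `ci_high`, `n_pairs`.
#' @export
paired_ttest <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  d <- pre - post
  if (anyNA(d)) stop("missing values in paired data")
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  if (sd(d) == 0) stop("degenerate error: zero variance in differences")
  se <- sd(d) / sqrt(n)
  tstat <- mean(d) / se
  tcrit <- qt(0.975, n - 1)
  structure(list(student_t = tstat, df = n - 1L,
                 p_t = 2 * pt(-abs(tstat), n - 1),
                 mean_difference = mean(d), se_difference = se,
                 ci_low = mean(d) - tcrit * se,
                 ci_high = mean(d) + tcrit * se,
                 n_pairs = n),
            class = "paired_test_result")
}

#' Simple linear regression of synchrony on therapy readiness
#'
#' Ordinary least squares with intercept, `y ~ x`; rows with missing values
#' in either variable are dropped. Reports the overall F statistic with its
#' degrees of freedom, R-squared, and the slope t statistic (signed, so a
#' negative association shows as a negative t).
#'
#' @param y Response, e.g. a synchrony summary per dyad.
#' @param x Predictor, e.g. VAS therapy-readiness percentages.
#' @return A `regression_result`: `f_stat`, `df1`, `df2`, `p`, `r_squared`,
#'   `t_slope`, `slope`, `intercept`, `n`.
#' @export
regress_on_readiness <- function(y, x) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (var(x) == 0) stop("degenerate error: zero variance in predictor")
  if (var(y) == 0) {               # constant response: no association
    return(structure(list(f_stat = 0, df1 = 1L, df2 = length(x) - 2L,
                          p = 1, r_squared = 0, t_slope = 0, slope = 0,
                          intercept = y[1L], n = length(x)),
                     class = "regression_result"))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fs <- sm$fstatistic
  f <- if (is.null(fs)) 0 else unname(fs[1L])
  p <- if (is.null(fs)) 1 else pf(f, fs[2L], fs[3L], lower.tail = FALSE)
  structure(list(f_stat = f, df1 = 1L, df2 = length(x) - 2L,
                 p = unname(p), r_squared = sm$r.squared,
                 t_slope = sm$coefficients["x", "t value"],
                 slope = unname(coef(fit)["x"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: F(%d, %d) = %.3f, p = %.4g, R2 = %.3f, slope t = %.3f\n",
              x$df1, x$df2, x$f_stat, x$p, x$r_squared, x$t_slope))
  invisible(x)
}

#' Score a visual analogue scale mark as therapy readiness
#'
#' The readiness VAS is a 10 cm line whose left end means absolute
#' readiness for therapy and whose right end means the contrary; the
#' patient marks a position. Readiness percent is therefore
#' `100 * (1 - mark / scale)`: a mark at the left end scores 100, at the
#' right end 0.
#'
#' @param mark_cm Distance of the mark from the left end, in cm.
#' @param scale_cm Length of the line (default 10 cm).
#' @return Readiness in percent, 0-100.
#' @export
score_vas <- function(mark_cm, scale_cm = 10) {
  if (any(mark_cm < 0 | mark_cm > scale_cm, na.rm = TRUE))
    stop("range error: mark outside [0, scale_cm]")
  100 * (1 - mark_cm / scale_cm)
}

#' Parse "hh:mm:ss" durations to seconds
#'
#' @param x Character vector of `hh:mm:ss` strings.
#' @return Numeric vector of seconds.
#' @export
parse_hms <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE), function(p) {
    if (length(p) != 3L) stop(sprintf("malformed duration '%s'", paste(p, collapse = ":")))
    sum(as.numeric(p) * c(3600, 60, 1))
  }, numeric(1L))
}

#' Bundled example session-metadata table
#'
#' Per-dyad segment durations, session lengths, intervention descriptions
#' and diagnoses for an 11-dyad music-therapy study, in the layout the
#' session-statistics layer consumes (`dyad_id`, `pretalk`, `intervention`,
#' `posttalk` as `hh:mm:ss`, `session_min`, `diagnosis`).
#'
#' @return data.frame with 11 rows.
#' @export
session_table <- function() {
  path <- system.file("extdata", "sessions.csv", package = "dyadsync",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
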