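#' Percent reduction between two group means
#'
#' `(mean_ref - mean_test) / mean_ref * 100`, rounded half away from zero to
#' an integer percent — the rounding that reproduces the reported regional
#' percent changes from their printed group means.
#'
#' @param mean_ref_group reference (e.g. sham) group mean, `> 0`.
#' @param mean_test_group test (e.g. SCI) group mean.
#' @return Integer percent reduction (negative for an increase).
#' @examples
#' percent_reduction(0.72, 0.28)  # 61
#' percent_reduction(0.77, 0.70)  # 9
#' @export
percent_reduction <- function(mean_ref_group, mean_test_group) {
  if (any(mean_ref_group <= 0)) stop("reference group mean must be positive")
  as.integer(round_half_away((mean_ref_group - mean_test_group) /
                               mean_ref_group * 100))
}

#' Unpaired two-sample t test
#'
#' Two-sided unpaired t test, pooled-variance (Student) by default with
#' Welch-Satterthwaite as an option. Zero-variance degenerate inputs return
#' contractual limits instead of erroring: identical constant groups give
#' `t = 0, p = 1`; constant groups with different means give `t = +/-Inf,
#' p = 0` — so edge-case simulated cohorts do not crash pipelines.
#'
#' @param group_a,group_b numeric vectors, each `n >= 2`.
#' @param variance_mode `"pooled"` or `"welch"`.
#' @return List `t`, `df`, `p`.
#' @export
unpaired_t <- function(group_a, group_b, variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    d <- mean(group_a) - mean(group_b)
    df <- na + nb - 2
    if (d == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(d) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = variance_mode == "pooled")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition via [stats::aov()].
#' With two groups `F` equals the squared pooled t statistic. Degenerate
#' inputs return limits: all groups identical constants give `F = 0, p = 1`;
#' zero within-group variance with distinct means gives `F = Inf, p = 0`.
#'
#' @param groups list of numeric vectors (`>= 2` groups, each `n >= 2`).
#' @return List `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least 2 observations")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  k <- length(groups)
  n <- length(y)
  df_b <- k - 1L
  df_w <- n - k
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - mean(y))^2,
                    numeric(1)))
  if (ssb + ssw == 0) return(list(F = 0, df_between = df_b, df_within = df_w, p = 1))
  if (ssw == 0) return(list(F = Inf, df_between = df_b, df_within = df_w, p = 0))
  s <- summary(stats::aov(y ~ g))[[1]]
  list(F = s[["F value"]][1], df_between = df_b, df_within = df_w,
       p = s[["Pr(>F)"]][1])
}

#' Agreement between two outcome measures
#'
#' Ordinary least-squares line of `y` on `x` with `R^2 = 1 - RSS/TSS`; used
#' to check that the windowed SUVR is a faithful surrogate of the DVR.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`; `x` must not be
#'   constant.
#' @return List `slope`, `intercept`, `r_squared`, `n`.
#' @export
agreement <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("agreement needs at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant; agreement undefined")
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = min(max(r2, 0), 1), n = length(x))
}

#' Per-region group comparison table
#'
#' One row per region: group means/SDs/ns, unpaired pooled t test, and the
#' integer percent change sham -> SCI ([percent_reduction()]). P values are
#' deliberately uncorrected for multiple comparisons (the `corrected` column
#' is an explicit flag). Every animal must carry every region.
#'
#' @param values data frame with columns `animal_id`, `group`, `region` and
#'   the value column.
#' @param value_col name of the value column (e.g. `"DVR"`, `"SUVR"`).
#' @param sham_label,sci_label group labels of the reference and test group.
#' @param metric,reference,timepoint annotation columns copied into every row.
#' @param variance_mode passed to [unpaired_t()].
#' @param require_complete error when an animal lacks a region (default);
#'   `FALSE` tolerates exclusions (e.g. non-converged fits dropped upstream).
#' @return Data frame: `region, metric, reference, timepoint, mean_sham,
#'   sd_sham, n_sham, mean_scis, sd_scis, n_scis, t, df, p, percent_change,
#'   corrected` (always `FALSE`).
#' @export
build_comparison_table <- function(values, value_col = "DVR",
                                   sham_label = "sham", sci_label = "SCI",
                                   metric = value_col, reference = NA_character_,
                                   timepoint = NA_character_,
                                   variance_mode = "pooled",
                                   require_complete = TRUE) {
  need <- c("animal_id", "group", "region", value_col)
  if (!all(need %in% names(values))) {
    stop(sprintf("values table needs columns: %s", paste(need, collapse = ", ")))
  }
  regions <- unique(values$region)
  if (require_complete) {
    for (id in unique(values$animal_id)) {
      have <- values$region[values$animal_id == id]
      miss <- setdiff(regions, have)
      if (length(miss)) {
        stop(sprintf("animal %s is missing region %s", id, miss[1]))
      }
    }
  }
  rows <- list()
  for (r in regions) {
    a <- values[values$region == r & values$group == sham_label, value_col]
    b <- values[values$region == r & values$group == sci_label, value_col]
    tt <- unpaired_t(a, b, variance_mode = variance_mode)
    pct <- if (mean(a) > 0) percent_reduction(mean(a), mean(b)) else NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(
      region = r, metric = metric, reference = reference, timepoint = timepoint,
      mean_sham = mean(a), sd_sham = stats::sd(a), n_sham = length(a),
      mean_scis = mean(b), sd_scis = stats::sd(b), n_scis = length(b),
      t = tt$t, df = tt$df, p = tt$p, percent_change = pct,
      corrected = FALSE)
  }
  do.call(rbind, rows)
}
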