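#' Statistical test result container
#'
#' One row per test: name, statistic, degrees of freedom (NA where
#' undefined), two-sided p-value and the significance flag at the study's
#' threshold p <= 0.05.
#'
#' @param test test name.
#' @param statistic statistic value.
#' @param df degrees of freedom (scalar, vector, or NA).
#' @param p two-sided p-value.
#' @param alpha significance threshold.
#' @return A one-row data frame of class `stat_result`.
#' @export
stat_result <- function(test, statistic, df = NA_real_, p, alpha = 0.05) {
  stopifnot(p >= 0, p <= 1)
  structure(data.frame(test = test, statistic = statistic,
                       df = paste(df, collapse = ","), p = p,
                       significant = p <= alpha,
                       stringsAsFactors = FALSE),
            class = c("stat_result", "data.frame"))
}

#' Balanced two-way ANOVA from first principles
#'
#' Fixed-effects two-way analysis of variance for the balanced
#' treatment-by-age design, computed directly from cell and marginal
#' means: `SS_A`, `SS_B` and `SS_AB` from the balanced decomposition,
#' `SS_error` from within-cell deviations, F statistics against the
#' residual mean square and p-values from the F distribution. The
#' decomposition satisfies `SS_total = SS_A + SS_B + SS_AB + SS_error`
#' identically. Unbalanced input is rejected (the study design is
#' balanced; sums of squares would no longer be orthogonal).
#'
#' @param frame data frame of per-animal rows.
#' @param endpoint name of the response column.
#' @param factor_a,factor_b names of the two factor columns.
#' @return Data frame with one row per source (`factor_a`, `factor_b`,
#'   interaction, residuals): df, SS, MS, F, p and the significance flag.
#' @export
two_way_anova <- function(frame, endpoint, factor_a = "treatment",
                          factor_b = "age") {
  y <- frame[[endpoint]]
  A <- factor(frame[[factor_a]])
  B <- factor(frame[[factor_b]])
  if (any(!is.finite(y))) stop("endpoint contains non-finite values")
  a <- nlevels(A); b <- nlevels(B)
  if (a < 2 || b < 2) stop("each factor needs at least two levels")
  counts <- table(A, B)
  if (length(unique(c(counts))) != 1)
    stop("unsupported design: cells are unbalanced")
  n <- counts[1, 1]
  if (n < 2) stop("at least two replicates per cell are required")
  grand <- mean(y)
  cellm <- tapply(y, list(A, B), mean)
  am <- rowMeans(cellm); bm <- colMeans(cellm)
  ss_a <- n * b * sum((am - grand)^2)
  ss_b <- n * a * sum((bm - grand)^2)
  ss_ab <- n * sum((cellm - outer(am, rep(1, b)) -
                      outer(rep(1, a), bm) + grand)^2)
  ss_err <- sum((y - cellm[cbind(as.integer(A), as.integer(B))])^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (n - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_err)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  data.frame(source = c(factor_a, factor_b,
                        paste0(factor_a, ":", factor_b), "residuals"),
             df = df, ss = ss, ms = ms, statistic = f, p = p,
             significant = !is.na(p) & p <= 0.05,
             stringsAsFactors = FALSE)
}

#' Pooled-variance two-sample Student t test
#'
#' Classical post hoc t: pooled variance across the two groups, two-sided
#' p from the t distribution with `n_a + n_b - 2` degrees of freedom.
#' When the pooled variance is zero, identical group means give `t = 0`,
#' `p = 1`; different means with zero variance are a degenerate input and
#' raise an error.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @return A [stat_result()].
#' @export
student_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least two values")
  ma <- mean(group_a); mb <- mean(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) {
    if (ma == mb) return(stat_result("student_t", 0, na + nb - 2, 1))
    stop("degenerate input: zero pooled variance with unequal means")
  }
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  stat_result("student_t", t, df, 2 * pt(-abs(t), df))
}

# Exact null distribution of the Mann-Whitney U statistic of group A by
# complete enumeration of rank assignments (no ties).
mw_exact_distribution <- function(na, nb) {
  N <- na + nb
  sets <- combn(N, na)
  apply(sets, 2, sum) - na * (na + 1) / 2
}

#' Mann-Whitney rank-sum test
#'
#' U is computed from rank sums with midranks for ties. In exact mode
#' (the default for `n_a + n_b <= 12` without ties) the two-sided p-value
#' comes from complete enumeration of all rank assignments, using the
#' symmetry of the null U distribution:
#' `p = P(|U - n_a n_b / 2| >= |u - n_a n_b / 2|)`. Otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param group_a,group_b numeric vectors (n >= 1 each).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A [stat_result()] whose statistic is U (for group A).
#' @export
mann_whitney <- function(group_a, group_b, mode = c("auto", "exact",
                                                    "normal")) {
  mode <- match.arg(mode)
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 1, nb >= 1)
  all_v <- c(group_a, group_b)
  r <- rank(all_v)
  ties <- any(duplicated(all_v))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (mode == "exact" || (mode == "auto" && na + nb <= 12 && !ties)) {
    if (ties) stop("exact mode requires untied data")
    dist <- mw_exact_distribution(na, nb)
    p <- mean(abs(dist - mu) >= abs(u - mu))
    return(stat_result("mann_whitney_exact", u, NA_real_, p))
  }
  N <- na + nb
  tie_tab <- table(all_v)
  correction <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - correction)
  if (sigma2 <= 0) return(stat_result("mann_whitney_normal", u, NA_real_, 1))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  stat_result("mann_whitney_normal", u, NA_real_, p)
}

#' Per-group mean and SD summary
#'
#' "Mean +/- SD" table in the style of the study's summary tables: sample
#' SD with the n - 1 denominator (animals are sampled units). A group
#' with a single value has no defined SD; it is reported as 0 with the
#' `degenerate` flag set.
#'
#' @param frame data frame of per-animal rows.
#' @param endpoint response column name.
#' @param group_col grouping column name.
#' @return Data frame: group, mean, sd, n, degenerate.
#' @export
group_summary <- function(frame, endpoint, group_col = "group") {
  g <- frame[[group_col]]
  y <- frame[[endpoint]]
  groups <- unique(g)
  out <- data.frame(group = groups, stringsAsFactors = FALSE)
  out$mean <- vapply(groups, function(k) mean(y[g == k]), numeric(1))
  out$sd <- vapply(groups, function(k) {
    v <- y[g == k]
    if (length(v) < 2) 0 else sd(v)
  }, numeric(1))
  out$n <- vapply(groups, function(k) sum(g == k), numeric(1))
  out$degenerate <- out$n < 2
  out
}
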