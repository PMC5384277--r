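# Cohort statistics: paired comparisons with step-down Bonferroni (Holm)
# correction, Pearson correlation, Dahlberg method error, and intraclass
# correlation reliability.

#' Paired t test
#'
#' Two-sided paired t test on matched samples; the difference is `y - x`.
#' Zero variance of the differences is flagged degenerate and reported as
#' t = 0, p = 1.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2)
#' @return list: `t`, `p`, `df`, `mean_diff`, `degenerate`
#' @export
paired_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("paired_t: unequal lengths")
  n <- length(x)
  if (n < 2) stop("paired_t: need n >= 2")
  d <- y - x
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(list(t = 0, p = 1, df = n - 1, mean_diff = mean(d),
                degenerate = TRUE))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Holm step-down Bonferroni correction
#'
#' Sorts the m raw p-values ascending, multiplies the i-th smallest by
#' (m - i + 1), enforces monotone non-decreasing corrected values, caps at
#' 1, and returns them in the original order.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\]
#' @return corrected p-values, same order as the input
#' @export
holm_correct <- function(pvals) {
  stopifnot(is.numeric(pvals))
  if (any(pvals < 0 | pvals > 1 | is.na(pvals))) {
    stop("holm_correct: p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals)
  adj <- pvals[o] * (m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors, n >= 3
#' @return list: `r`, `p` (two-sided, t transform with n - 2 df), `n`
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("pearson_r: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r: zero variance input")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}

#' Dahlberg method error
#'
#' ME = sqrt(sum(d^2) / (2n)) over n repeated measurement pairs, the
#' standard orthodontic reliability statistic; d is the deviation between
#' the two measurements of each object.
#'
#' @param first,second the two measurement sessions, equal length
#' @return the method error (same units as the measurements)
#' @export
dahlberg_me <- function(first, second) {
  if (length(first) != length(second)) {
    stop("dahlberg_me: sessions have unequal lengths")
  }
  if (length(first) < 1) stop("dahlberg_me: need n >= 1")
  d <- first - second
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Intraclass correlation coefficient, ICC(3,1)
#'
#' Two-way mixed-effects, single-measure, consistency ICC — the standard
#' intra-examiner reliability choice: (MS_between - MS_error) /
#' (MS_between + (k - 1) MS_error) from the two-way ANOVA of n objects by
#' k sessions.
#'
#' @param ratings numeric matrix, n objects x k sessions (k >= 2, n >= 3)
#' @return the ICC, in \[-1, 1\]
#' @export
icc_consistency <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3) stop("icc_consistency: need at least 3 objects")
  if (k < 2) stop("icc_consistency: need at least 2 sessions")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows <= 0) {
    stop("icc_consistency: degenerate ratings (no between-object variance)")
  }
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

#' Paired pre/post tests across a cohort table with Holm correction
#'
#' Runs a paired t test for every variable present at both time points and
#' applies the step-down Bonferroni correction across the family.
#'
#' @param tab a data.frame with columns `<var>_t1` and `<var>_t2`
#' @param variables base variable names; default: all with both columns
#' @param alpha significance level for the flag (default 0.05)
#' @return data.frame: variable, means/SDs at T1/T2, t, p, corrected p,
#'   significance flag
#' @export
cohort_paired_tests <- function(tab, variables = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(tab))
  if (is.null(variables)) {
    t1 <- sub("_t1$", "", grep("_t1$", names(tab), value = TRUE))
    t2 <- sub("_t2$", "", grep("_t2$", names(tab), value = TRUE))
    variables <- intersect(t1, t2)
  }
  rows <- lapply(variables, function(v) {
    x <- tab[[paste0(v, "_t1")]]; y <- tab[[paste0(v, "_t2")]]
    tt <- paired_t(x, y)
    data.frame(variable = v, mean_t1 = mean(x), sd_t1 = stats::sd(x),
               mean_t2 = mean(y), sd_t2 = stats::sd(y),
               t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- holm_correct(out$p)
  out$significant <- out$p_corrected < alpha
  out
}

#' Correlation table between pressure-drop changes and their covariates
#'
#' Pearson correlations of the T2 - T1 changes in the pressure-drop
#' metrics against the changes in the anatomic covariates and the incisor
#' retraction amount, with a significance mask.
#'
#' @param tab cohort table with `<var>_t1`/`<var>_t2` columns and `ice`
#' @param dp_vars pressure-drop variables (changes are correlated)
#' @param covar_vars anatomic covariates (changes are correlated)
#' @param alpha significance level
#' @return data.frame: dp_variable, covariate, r, p, significant
#' @export
cohort_correlations <- function(tab,
                                dp_vars = c("dP_max", "dP_or", "dP_hy"),
                                covar_vars = c("V_or", "V_hy", "A_min",
                                               "a_ratio"),
                                alpha = 0.05) {
  delta <- function(v) tab[[paste0(v, "_t2")]] - tab[[paste0(v, "_t1")]]
  rows <- list()
  for (dv in dp_vars) {
    for (cv in c(covar_vars, "ice")) {
      x <- if (cv == "ice") tab$ice else delta(cv)
      pr <- pearson_r(x, delta(dv))
      rows[[length(rows) + 1]] <- data.frame(
        dp_variable = dv, covariate = cv, r = pr$r, p = pr$p)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out
}
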