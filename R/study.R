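# Study-level aggregation and small-sample nonparametric method
# comparison.

#' Collect trial fits into a flat table
#'
#' @param trials List of [heel_strike()] fits (or of their `energetics`
#'   lists, or JSON trial files readable by [read_trial_json()]).
#' @param subject Subject identifier per trial (recycled if length 1).
#' @return Data frame with one row per trial: `subject` plus every
#'   scalar energetics field.
#' @export
trial_table <- function(trials, subject) {
  rows <- lapply(trials, function(tr) {
    if (is.character(tr)) tr <- read_trial_json(tr)
    e <- if (inherits(tr, "heel_strike")) tr$energetics
         else if (!is.null(tr$energetics)) tr$energetics else tr
    as.data.frame(e[vapply(e, is.numeric, logical(1))])
  })
  out <- do.call(rbind, rows)
  cbind(subject = rep_len(subject, nrow(out)), out)
}

#' Aggregate trials per subject and across subjects
#'
#' Three-level summary: per-subject mean and SD over that subject's
#' trials; then across subjects the overall mean (mean of subject
#' means), the intra-subject variability (mean of subject SDs), the
#' inter-subject variability (SD of subject means), and the range of
#' subject means.  Sample SDs (n-1 denominator) throughout; a subject
#' with a single trial has its SD flagged absent (`NA`).
#'
#' @param trials A data frame from [trial_table()] (column `subject`
#'   plus numeric variables), or a list of fits together with
#'   `subject`.
#' @param subject Subject ids when `trials` is a list.
#' @return An object of class `study_summary`: list with
#'   `subject_summary` (long data frame: subject, variable, n_trials,
#'   mean, sd) and `summary` (data frame: variable, overall_mean,
#'   intra_subject, inter_subject, min_subject_mean, max_subject_mean,
#'   n_subjects).
#' @export
aggregate_trials <- function(trials, subject = NULL) {
  df <- if (is.data.frame(trials)) trials else trial_table(trials, subject)
  if (!nrow(df))
    hs_stop("no trials to aggregate", "heelstrike_input_error",
            stage = "study")
  vars <- setdiff(names(df), "subject")
  vars <- vars[vapply(df[vars], is.numeric, logical(1))]
  subj <- unique(df$subject)
  ss <- do.call(rbind, lapply(subj, function(s) {
    d <- df[df$subject == s, vars, drop = FALSE]
    data.frame(subject = s, variable = vars, n_trials = nrow(d),
               mean = vapply(d, mean, numeric(1)),
               sd = if (nrow(d) >= 2L) vapply(d, stats::sd, numeric(1))
                    else rep(NA_real_, length(vars)),
               row.names = NULL)
  }))
  sm <- do.call(rbind, lapply(vars, function(v) {
    m <- ss$mean[ss$variable == v]
    s <- ss$sd[ss$variable == v]
    data.frame(variable = v,
               overall_mean = mean(m),
               intra_subject = if (all(is.na(s))) NA_real_
                               else mean(s, na.rm = TRUE),
               inter_subject = stats::sd(m),
               min_subject_mean = min(m), max_subject_mean = max(m),
               n_subjects = length(m), row.names = NULL)
  }))
  structure(list(subject_summary = ss, summary = sm),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Study summary over %d subject(s)\n",
              x$summary$n_subjects[1]))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Friedman rank test across methods
#'
#' Within-subject ranking of `k` methods over `n` subjects (mid-ranks
#' for ties), with the chi-squared approximation
#' `chi2 = 12 / (n k (k+1)) * sum(R_j^2) - 3 n (k+1)` on `k - 1`
#' degrees of freedom.
#'
#' @param values `n`-by-`k` matrix: rows are subjects, columns methods.
#' @return List `chi2`, `df`, `p`.
#' @export
friedman_statistic <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values))
    hs_stop("missing values in the method matrix",
            "heelstrike_input_error", stage = "study")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L)
    hs_stop("need at least 2 subjects and 2 methods",
            "heelstrike_input_error", stage = "study")
  R <- t(apply(values, 1, rank))
  chi2 <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  list(chi2 = chi2, df = k - 1L,
       p = stats::pchisq(chi2, k - 1L, lower.tail = FALSE))
}

# Exact null distribution of the signed-rank statistic for the given
# (possibly tied) absolute-value ranks: generating-function convolution
# over all 2^n sign assignments.  Ranks are doubled so mid-ranks become
# integers.
signed_rank_null <- function(r2) {
  counts <- c(1, numeric(sum(r2)))
  for (v in r2) {
    shifted <- c(numeric(v), counts[seq_len(length(counts) - v)])
    counts <- counts + shifted
  }
  counts / 2^length(r2)
}

#' Exact Wilcoxon signed-rank test for paired differences
#'
#' Two-sided signed-rank test on paired differences.  Zero differences
#' are dropped; ties in the absolute values receive mid-ranks.  For
#' `n <= 20` retained pairs the p value is exact, from the full
#' enumeration of the `2^n` sign assignments (computed by
#' generating-function convolution, which sums the same `2^n` terms);
#' above that a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param paired_diffs Vector of paired differences.
#' @param alpha Significance level applied to the returned p value
#'   (supply the Bonferroni-adjusted level for families of
#'   comparisons).
#' @return List `W_stat` (sum of ranks of positive differences), `p`,
#'   `significant`, `n` (pairs retained), `exact`.
#' @export
signed_rank_exact <- function(paired_diffs, alpha = 0.01) {
  d <- paired_diffs[paired_diffs != 0]
  if (!length(d))
    hs_stop("all paired differences are zero",
            "heelstrike_degenerate_error", stage = "study")
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  exact <- n <= 20L
  if (exact) {
    null <- signed_rank_null(as.integer(round(2 * r)))
    w2 <- as.integer(round(2 * W))
    p_le <- sum(null[seq_len(w2 + 1L)])
    p_ge <- sum(null[(w2 + 1L):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- sum(r^2) / 4
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(W_stat = W, p = p, significant = p < alpha, n = n, exact = exact)
}
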