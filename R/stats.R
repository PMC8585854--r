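# Group-comparison statistics: eye averaging, Wilcoxon tests, Hedges g,
# Bonferroni-Holm adjustment, check-size ratios, relative reduction.

#' Average the two eyes per subject and condition
#'
#' Binocular recordings are collapsed to one value per subject and
#' condition by averaging the available eyes; when one eye was excluded
#' (e.g. electrode displacement) the remaining eye passes through
#' unchanged. Rows with NA in the averaged column count as missing eyes.
#'
#' @param records cohort data frame with one row per subject x eye x
#'   condition (columns `subject`, `group`, `eye`, `check_size_deg`,
#'   `reversal_rate_rps`, plus the measure columns).
#' @param cols measure columns to average (defaults to those present
#'   among amplitude_uV, noise_uV, snr, response_time_ms).
#' @return Data frame with one row per subject x condition, the measure
#'   columns eye-averaged, and `n_eyes` recording how many eyes entered
#'   each mean.
#' @export
average_eyes <- function(records, cols = NULL) {
  if (is.null(cols)) {
    cols <- intersect(c("amplitude_uV", "noise_uV", "snr",
                        "response_time_ms"), names(records))
  }
  stopifnot(length(cols) >= 1, all(cols %in% names(records)))
  key <- interaction(records$subject, records$check_size_deg,
                     records$reversal_rate_rps, drop = TRUE)
  first <- !duplicated(key)
  out <- records[first, c("subject", "group", "check_size_deg",
                          "reversal_rate_rps")]
  lev <- key[first]
  n_eyes <- as.vector(tapply(!is.na(records[[cols[1]]]), key, sum))[lev]
  if (any(n_eyes == 0)) {
    bad <- which(n_eyes == 0)[1]
    stop(sprintf("subject %s, condition %g deg / %g rps: no eyes available",
                 out$subject[bad], out$check_size_deg[bad],
                 out$reversal_rate_rps[bad]))
  }
  out$n_eyes <- n_eyes
  for (cl in cols) {
    out[[cl]] <- as.vector(tapply(records[[cl]], key,
                                  function(v) mean(v, na.rm = TRUE)))[lev]
  }
  rownames(out) <- NULL
  out[order(out$group, out$subject, out$reversal_rate_rps,
            out$check_size_deg), , drop = FALSE]
}

#' Wilcoxon tests
#'
#' Thin wrappers around [stats::wilcox.test()] returning the statistic,
#' the p-value and the method actually used (exact for small untied
#' samples, normal approximation with tie correction otherwise).
#' `wilcoxon_signed_rank` operates on paired differences; all-zero
#' differences carry no information and return p = 1 with a warning.
#'
#' @param x,y numeric samples.
#' @param diffs paired differences.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (for the
#'   first sample relative to the second).
#' @return A list: `statistic`, `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater")) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  alternative <- match.arg(alternative)
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' @rdname wilcoxon_rank_sum
#' @export
wilcoxon_signed_rank <- function(diffs,
                                 alternative = c("two.sided", "less", "greater")) {
  stopifnot(length(diffs) >= 1)
  alternative <- match.arg(alternative)
  if (all(diffs == 0)) {
    warning("all paired differences are zero; test carries no information",
            call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1,
                method = "Wilcoxon signed rank test (degenerate)"))
  }
  ht <- suppressWarnings(stats::wilcox.test(diffs, alternative = alternative))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' Hedges-corrected standardized mean difference
#'
#' Cohen's d on the pooled SD,
#' `d = diff / sqrt(((n1-1)*sd1^2 + (n2-1)*sd2^2) / (n1+n2-2))`,
#' multiplied by the small-sample bias correction
#' `J = 1 - 3 / (4*(n1+n2) - 9)`.
#'
#' @param mean_diff difference of group means (reference minus
#'   comparison, so reduced responses in the comparison group give
#'   positive values).
#' @param sd1,sd2 group standard deviations (not both zero).
#' @param n1,n2 group sizes (>= 2).
#' @return Hedges g.
#' @export
hedges_g <- function(mean_diff, sd1, n1, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled SD is zero; effect size undefined")
  (mean_diff / pooled) * (1 - 3 / (4 * (n1 + n2) - 9))
}

#' Bonferroni-Holm step-down adjustment
#'
#' The classical step-down procedure: sort the m p-values ascending,
#' compare the i-th against `alpha / (m - i + 1)` and stop at the first
#' failure; everything before the stop is significant. Adjusted p-values
#' are the running maximum of `(m - i + 1) * p_(i)`, capped at 1, so
#' `adjusted <= alpha` reproduces the flags.
#'
#' @param p p-values in `[0, 1]`.
#' @param alpha familywise error rate (default 0.05).
#' @return A list: `adjusted` (in the input order), `significant`
#'   (logical flags).
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  stopifnot(length(p) >= 1, all(p >= 0 & p <= 1))
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, significant = adjusted <= alpha)
}

#' PERG check-size ratio
#'
#' Per-subject normalization borrowed from the early-glaucoma "PERG
#' ratio protocol": the amplitude at the finest check size divided by
#' the amplitude at the coarsest. A floor on the denominator guards
#' against near-zero noise-corrected amplitudes; engagements of the
#' floor are flagged.
#'
#' @param amplitude_small amplitude at the finest check size, uV.
#' @param amplitude_large amplitude at the coarsest check size, uV.
#' @param floor_uV denominator floor (default 0.05 uV).
#' @return A list: `ratio`, `floored` (logical).
#' @export
perg_ratio <- function(amplitude_small, amplitude_large, floor_uV = 0.05) {
  stopifnot(all(amplitude_small >= 0), all(amplitude_large >= 0),
            floor_uV > 0)
  floored <- amplitude_large < floor_uV
  list(ratio = amplitude_small / pmax(amplitude_large, floor_uV),
       floored = floored)
}

#' Per-subject ratio table
#'
#' Computes the check-size ratio for every subject and reversal rate of
#' an eye-averaged cohort table, using the smallest and largest check
#' sizes present.
#'
#' @param records eye-averaged cohort table (see [average_eyes()]).
#' @param floor_uV denominator floor passed to [perg_ratio()].
#' @return Data frame: `subject`, `group`, `reversal_rate_rps`, `ratio`,
#'   `floored`.
#' @export
ratio_table <- function(records, floor_uV = 0.05) {
  cs_lo <- min(records$check_size_deg)
  cs_hi <- max(records$check_size_deg)
  if (cs_lo == cs_hi) stop("need at least two check sizes for a ratio")
  key <- interaction(records$subject, records$reversal_rate_rps, drop = TRUE)
  pieces <- lapply(split(records, key), function(d) {
    a_lo <- d$amplitude_uV[abs(d$check_size_deg - cs_lo) < 1e-9]
    a_hi <- d$amplitude_uV[abs(d$check_size_deg - cs_hi) < 1e-9]
    if (length(a_lo) != 1 || length(a_hi) != 1) {
      stop("subject ", d$subject[1], ": ratio needs exactly one record per ",
           "extreme check size and rate")
    }
    r <- perg_ratio(a_lo, a_hi, floor_uV)
    data.frame(subject = d$subject[1], group = d$group[1],
               reversal_rate_rps = d$reversal_rate_rps[1],
               ratio = r$ratio, floored = r$floored)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$group, out$subject, out$reversal_rate_rps), , drop = FALSE]
}

#' Relative response reduction
#'
#' `100 * (mean_control - mean_patient) / mean_control`, the percentage
#' by which the patient group's mean falls short of the control mean.
#'
#' @param mean_control control-group mean (> 0).
#' @param mean_patient patient-group mean.
#' @return Reduction in percent.
#' @export
relative_reduction <- function(mean_control, mean_patient) {
  stopifnot(all(mean_control > 0))
  100 * (mean_control - mean_patient) / mean_control
}
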