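# Split-plot (mixed) repeated-measures ANOVA with Greenhouse-Geisser
# correction, implemented from sums of squares and contrast covariances.
#
# Design: one between-subject factor (group) and two fully crossed
# within-subject factors, each subject measured once in every cell.
# Four error strata: subjects within groups (tests the group effect),
# and one factor-by-subject stratum per within effect (tests that
# effect and its group interaction). Greenhouse-Geisser epsilon is
# computed per within effect from the pooled within-group covariance of
# its orthonormal contrast scores and applied multiplicatively to both
# degrees of freedom.

# orthonormal contrast rows spanning the (p-1)-dim contrast space
.orthonormal_contrasts <- function(p) {
  if (p < 2) return(matrix(numeric(0), nrow = 0, ncol = p))
  C <- stats::contr.helmert(p)          # p x (p-1), columns are contrasts
  C <- apply(C, 2, function(v) v / sqrt(sum(v^2)))
  t(C)                                   # (p-1) x p orthonormal rows
}

# Greenhouse-Geisser epsilon from subject-level scores on an effect's
# orthonormal contrasts; scores is an n_subjects x c matrix, group a
# factor splitting the rows. Pools covariance within groups.
.gg_epsilon <- function(scores, group) {
  c_dim <- ncol(scores)
  if (c_dim <= 1) return(1)
  centred <- scores
  for (g in unique(group)) {
    idx <- group == g
    centred[idx, ] <- sweep(scores[idx, , drop = FALSE], 2,
                            colMeans(scores[idx, , drop = FALSE]))
  }
  S <- crossprod(centred) / (nrow(scores) - length(unique(group)))
  if (sum(S * S) < 1e-300) return(1)  # no within-effect variance: sphericity moot
  eps <- sum(diag(S))^2 / (c_dim * sum(S * S))
  min(1, max(1 / c_dim, eps))
}

.safe_f_p <- function(ss_eff, df_eff, ss_err, df_err) {
  ms_eff <- ss_eff / df_eff
  ms_err <- ss_err / df_err
  if (ms_err <= 1e-300) {
    if (ss_eff <= 1e-12) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  f <- ms_eff / ms_err
  list(F = f, p = stats::pf(f, df_eff, df_err, lower.tail = FALSE))
}

#' Split-plot mixed ANOVA for the fully crossed PERG design
#'
#' Decomposes a balanced two-group repeated-measures design (every
#' subject observed once in every within-factor cell) into its classical
#' split-plot strata and tests each effect against its own error term.
#' Within-subject effects and their group interactions additionally get
#' Greenhouse-Geisser-corrected degrees of freedom and p-values
#' (epsilon is 1 for 2-level effects, so the correction is inert there).
#'
#' @param data eye-averaged cohort table, one row per subject x cell.
#' @param dv name of the dependent-variable column (e.g. `amplitude_uV`
#'   or `response_time_ms`).
#' @param between name of the grouping column (default `group`).
#' @param within names of the within-subject factor columns (default
#'   check size and reversal rate).
#' @return A data frame of class `"perg_anova"` with one row per effect
#'   (and one per error stratum): `effect`, `ss`, `df_num`, `df_den`,
#'   `F`, `p_uncorrected`, `gg_epsilon`, `df_num_gg`, `df_den_gg`,
#'   `p_gg`. Error strata are carried in attribute `"errors"` (used for
#'   the pooled post-hoc SE) and `ss_total` in attribute `"ss_total"`.
#' @export
mixed_anova <- function(data, dv = "amplitude_uV", between = "group",
                        within = c("check_size_deg", "reversal_rate_rps")) {
  stopifnot(dv %in% names(data), between %in% names(data),
            all(within %in% names(data)), length(within) == 2)
  subj <- as.character(data$subject)
  grp <- as.character(data[[between]])
  w1 <- factor(data[[within[1]]])
  w2 <- factor(data[[within[2]]])
  y <- data[[dv]]
  if (anyNA(y)) stop("missing values in ", dv, "; imputation is out of scope")
  p <- nlevels(w1); q <- nlevels(w2)
  subjects <- unique(subj)
  n_subj <- length(subjects)
  subj_group <- vapply(subjects, function(s) grp[subj == s][1], "")
  if (any(table(subj_group) < 2)) stop("need >= 2 subjects per group")
  # balance: every subject exactly once per cell
  tab <- table(subj, w1, w2)
  if (any(tab != 1)) {
    stop("unbalanced design: every subject needs exactly one observation ",
         "per within-factor cell")
  }

  mu <- mean(y)
  m_g <- tapply(y, grp, mean)
  m_s <- tapply(y, subj, mean)
  m_w1 <- tapply(y, w1, mean)
  m_w2 <- tapply(y, w2, mean)
  m_gw1 <- tapply(y, list(grp, w1), mean)
  m_gw2 <- tapply(y, list(grp, w2), mean)
  m_w12 <- tapply(y, list(w1, w2), mean)
  m_gw12 <- tapply(y, list(grp, w1, w2), mean)
  m_sw1 <- tapply(y, list(subj, w1), mean)
  m_sw2 <- tapply(y, list(subj, w2), mean)
  n_g <- table(subj_group)[names(m_g)]
  a <- length(m_g)

  ss_total <- sum((y - mu)^2)
  ss_group <- p * q * sum(n_g * (m_g - mu)^2)
  ss_subj <- p * q * sum((m_s[subjects] - m_g[subj_group])^2)
  df_subj <- n_subj - a

  ss_w1 <- n_subj * q * sum((m_w1 - mu)^2)
  ss_w1g <- q * sum(outer(as.numeric(n_g), rep(1, p)) *
                      (m_gw1 - outer(as.numeric(m_g), rep(1, p)) -
                         outer(rep(1, a), as.numeric(m_w1)) + mu)^2)
  res_w1 <- m_sw1[subjects, , drop = FALSE] -
    matrix(m_s[subjects], n_subj, p) -
    m_gw1[subj_group, , drop = FALSE] + matrix(m_g[subj_group], n_subj, p)
  ss_w1s <- q * sum(res_w1^2)
  df_w1s <- (p - 1) * df_subj

  ss_w2 <- n_subj * p * sum((m_w2 - mu)^2)
  ss_w2g <- p * sum(outer(as.numeric(n_g), rep(1, q)) *
                      (m_gw2 - outer(as.numeric(m_g), rep(1, q)) -
                         outer(rep(1, a), as.numeric(m_w2)) + mu)^2)
  res_w2 <- m_sw2[subjects, , drop = FALSE] -
    matrix(m_s[subjects], n_subj, q) -
    m_gw2[subj_group, , drop = FALSE] + matrix(m_g[subj_group], n_subj, q)
  ss_w2s <- p * sum(res_w2^2)
  df_w2s <- (q - 1) * df_subj

  int_w12 <- m_w12 - outer(as.numeric(m_w1), rep(1, q)) -
    outer(rep(1, p), as.numeric(m_w2)) + mu
  ss_w12 <- n_subj * sum(int_w12^2)
  ss_w12g <- 0
  for (gi in seq_len(a)) {
    g <- names(m_g)[gi]
    int_g <- m_gw12[g, , ] - outer(as.numeric(m_gw1[g, ]), rep(1, q)) -
      outer(rep(1, p), as.numeric(m_gw2[g, ])) + m_g[g]
    ss_w12g <- ss_w12g + n_g[g] * sum((int_g - int_w12)^2)
  }
  ss_w12g <- as.numeric(ss_w12g)
  # residual stratum by subtraction from the total
  ss_w12s <- ss_total - (ss_group + ss_subj + ss_w1 + ss_w1g + ss_w1s +
                           ss_w2 + ss_w2g + ss_w2s + ss_w12 + ss_w12g)
  ss_w12s <- max(0, ss_w12s)
  df_w12s <- (p - 1) * (q - 1) * df_subj

  # Greenhouse-Geisser epsilons from per-subject contrast scores
  C1 <- .orthonormal_contrasts(p)
  C2 <- .orthonormal_contrasts(q)
  eps_w1 <- .gg_epsilon(m_sw1[subjects, , drop = FALSE] %*% t(C1), subj_group)
  eps_w2 <- .gg_epsilon(m_sw2[subjects, , drop = FALSE] %*% t(C2), subj_group)
  # cell matrix per subject, w2 within w1, for the interaction contrasts
  cells <- matrix(NA_real_, n_subj, p * q,
                  dimnames = list(subjects, NULL))
  idx <- (as.integer(w1) - 1L) * q + as.integer(w2)
  for (i in seq_along(y)) cells[subj[i], idx[i]] <- y[i]
  C12 <- kronecker(C1, C2)
  eps_w12 <- .gg_epsilon(cells %*% t(C12), subj_group)

  eff <- function(name, ss, df1, ss_err, df2, eps = NA_real_) {
    fp <- .safe_f_p(ss, df1, ss_err, df2)
    row <- data.frame(effect = name, ss = ss, df_num = df1, df_den = df2,
                      F = fp$F, p_uncorrected = fp$p, gg_epsilon = eps,
                      df_num_gg = NA_real_, df_den_gg = NA_real_,
                      p_gg = NA_real_)
    if (!is.na(eps)) {
      row$df_num_gg <- eps * df1
      row$df_den_gg <- eps * df2
      row$p_gg <- if (!is.finite(row$F)) fp$p else
        if (row$F == 0) 1 else
          stats::pf(row$F, row$df_num_gg, row$df_den_gg, lower.tail = FALSE)
    }
    row
  }
  err <- function(name, ss, df) {
    data.frame(effect = name, ss = ss, df_num = df, df_den = NA_real_,
               F = NA_real_, p_uncorrected = NA_real_,
               gg_epsilon = NA_real_, df_num_gg = NA_real_,
               df_den_gg = NA_real_, p_gg = NA_real_)
  }
  w1n <- within[1]; w2n <- within[2]
  out <- rbind(
    eff(between, ss_group, a - 1, ss_subj, df_subj),
    err(paste0("subjects(", between, ")"), ss_subj, df_subj),
    eff(w1n, ss_w1, p - 1, ss_w1s, df_w1s, eps_w1),
    eff(paste0(w1n, ":", between), ss_w1g, (p - 1) * (a - 1),
        ss_w1s, df_w1s, eps_w1),
    err(paste0(w1n, ":subjects(", between, ")"), ss_w1s, df_w1s),
    eff(w2n, ss_w2, q - 1, ss_w2s, df_w2s, eps_w2),
    eff(paste0(w2n, ":", between), ss_w2g, (q - 1) * (a - 1),
        ss_w2s, df_w2s, eps_w2),
    err(paste0(w2n, ":subjects(", between, ")"), ss_w2s, df_w2s),
    eff(paste0(w1n, ":", w2n), ss_w12, (p - 1) * (q - 1),
        ss_w12s, df_w12s, eps_w12),
    eff(paste0(w1n, ":", w2n, ":", between),
        ss_w12g, (p - 1) * (q - 1) * (a - 1), ss_w12s, df_w12s, eps_w12),
    err(paste0(w1n, ":", w2n, ":subjects(", between, ")"),
        ss_w12s, df_w12s))
  rownames(out) <- NULL
  attr(out, "errors") <- data.frame(
    stratum = c("subjects", "w1_subjects", "w2_subjects", "w12_subjects"),
    ss = c(ss_subj, ss_w1s, ss_w2s, ss_w12s),
    df = c(df_subj, df_w1s, df_w2s, df_w12s))
  attr(out, "ss_total") <- ss_total
  attr(out, "n_per_group") <- as.numeric(n_g)
  class(out) <- c("perg_anova", "data.frame")
  out
}

#' One-within-factor split-plot ANOVA
#'
#' Reduced variant for designs with a single within factor (used for
#' the check-size ratio, where only the reversal rate remains within
#' subject). Same strata logic as [mixed_anova()].
#'
#' @inheritParams mixed_anova
#' @param within name of the single within-subject factor column.
#' @return A `perg_anova` data frame with effects `group`, the within
#'   factor, their interaction, and the two error strata.
#' @export
mixed_anova_1w <- function(data, dv = "ratio", between = "group",
                           within = "reversal_rate_rps") {
  subj <- as.character(data$subject)
  grp <- as.character(data[[between]])
  w <- factor(data[[within]])
  y <- data[[dv]]
  p <- nlevels(w)
  subjects <- unique(subj)
  n_subj <- length(subjects)
  subj_group <- vapply(subjects, function(s) grp[subj == s][1], "")
  if (any(table(subj, w) != 1)) stop("unbalanced design")
  mu <- mean(y)
  m_g <- tapply(y, grp, mean); m_s <- tapply(y, subj, mean)
  m_w <- tapply(y, w, mean); m_gw <- tapply(y, list(grp, w), mean)
  n_g <- table(subj_group)[names(m_g)]
  a <- length(m_g)
  ss_total <- sum((y - mu)^2)
  ss_group <- p * sum(n_g * (m_g - mu)^2)
  ss_subj <- p * sum((m_s[subjects] - m_g[subj_group])^2)
  df_subj <- n_subj - a
  ss_w <- n_subj * sum((m_w - mu)^2)
  ss_wg <- sum(outer(as.numeric(n_g), rep(1, p)) *
                 (m_gw - outer(as.numeric(m_g), rep(1, p)) -
                    outer(rep(1, a), as.numeric(m_w)) + mu)^2)
  ss_ws <- max(0, ss_total - ss_group - ss_subj - ss_w - ss_wg)
  df_ws <- (p - 1) * df_subj
  Cw <- .orthonormal_contrasts(p)
  m_sw <- tapply(y, list(subj, w), mean)[subjects, , drop = FALSE]
  eps <- .gg_epsilon(m_sw %*% t(Cw), subj_group)
  fp_g <- .safe_f_p(ss_group, a - 1, ss_subj, df_subj)
  fp_w <- .safe_f_p(ss_w, p - 1, ss_ws, df_ws)
  fp_wg <- .safe_f_p(ss_wg, (p - 1) * (a - 1), ss_ws, df_ws)
  out <- data.frame(
    effect = c(between, paste0("subjects(", between, ")"), within,
               paste0(within, ":", between),
               paste0(within, ":subjects(", between, ")")),
    ss = c(ss_group, ss_subj, ss_w, ss_wg, ss_ws),
    df_num = c(a - 1, df_subj, p - 1, (p - 1) * (a - 1), df_ws),
    df_den = c(df_subj, NA, df_ws, df_ws, NA),
    F = c(fp_g$F, NA, fp_w$F, fp_wg$F, NA),
    p_uncorrected = c(fp_g$p, NA, fp_w$p, fp_wg$p, NA),
    gg_epsilon = c(NA, NA, eps, eps, NA))
  attr(out, "errors") <- data.frame(
    stratum = c("subjects", "w_subjects"),
    ss = c(ss_subj, ss_ws), df = c(df_subj, df_ws))
  attr(out, "ss_total") <- ss_total
  class(out) <- c("perg_anova", "data.frame")
  out
}

#' Per-condition group contrasts on estimated marginal means
#'
#' In a balanced design the estimated marginal mean of a group x
#' condition cell is its raw mean, so the contrast per condition is the
#' plain difference of group means (reference group minus comparison
#' group). The standard error pools all error strata of the split-plot
#' model into one mean square, giving a single SE for every condition
#' and t tests on the summed error degrees of freedom; p-values are
#' two-sided, Holm-adjusted across conditions. Hedges g is computed
#' from the raw per-condition group means and SDs.
#'
#' @param data eye-averaged cohort table.
#' @param dv dependent-variable column name.
#' @param between,within as in [mixed_anova()].
#' @param reference_group label of the reference (minuend) group;
#'   defaults to the first group level encountered.
#' @param alpha familywise error rate for the Holm flags.
#' @return Data frame with one row per condition: group means and SDs,
#'   `emm_diff`, `se`, `t`, `df`, `p_uncorrected`, `p_holm`,
#'   `holm_significant`, `hedges_g`.
#' @export
emm_posthoc <- function(data, dv = "amplitude_uV", between = "group",
                        within = c("check_size_deg", "reversal_rate_rps"),
                        reference_group = NULL, alpha = 0.05) {
  an <- mixed_anova(data, dv, between, within)
  errs <- attr(an, "errors")
  ms_pooled <- sum(errs$ss) / sum(errs$df)
  df_pooled <- sum(errs$df)
  grp <- as.character(data[[between]])
  groups <- unique(grp)
  if (is.null(reference_group)) reference_group <- groups[1]
  other <- setdiff(groups, reference_group)
  stopifnot(length(other) == 1)
  n_ref <- length(unique(data$subject[grp == reference_group]))
  n_oth <- length(unique(data$subject[grp == other]))
  se <- sqrt(ms_pooled * (1 / n_ref + 1 / n_oth))
  key <- interaction(data[[within[1]]], data[[within[2]]], drop = TRUE)
  pieces <- lapply(split(data, key), function(d) {
    yr <- d[[dv]][d[[between]] == reference_group]
    yo <- d[[dv]][d[[between]] == other]
    diff <- mean(yr) - mean(yo)
    tval <- diff / se
    data.frame(check_size_deg = d[[within[1]]][1],
               reversal_rate_rps = d[[within[2]]][1],
               mean_ref = mean(yr), sd_ref = stats::sd(yr),
               mean_other = mean(yo), sd_other = stats::sd(yo),
               emm_diff = diff, se = se, t = tval, df = df_pooled,
               p_uncorrected = 2 * stats::pt(abs(tval), df_pooled,
                                             lower.tail = FALSE),
               hedges_g = hedges_g(diff, stats::sd(yr), n_ref,
                                   stats::sd(yo), n_oth))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$reversal_rate_rps, out$check_size_deg), , drop = FALSE]
  hb <- holm_adjust(out$p_uncorrected, alpha)
  out$p_holm <- hb$adjusted
  out$holm_significant <- hb$significant
  names(out)[names(out) == "mean_ref"] <- paste0("mean_", reference_group)
  names(out)[names(out) == "sd_ref"] <- paste0("sd_", reference_group)
  names(out)[names(out) == "mean_other"] <- paste0("mean_", other)
  names(out)[names(out) == "sd_other"] <- paste0("sd_", other)
  out
}
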