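test_that("split-plot strata match the base aov decomposition", {
  for (n in c(5, 8)) {
    d <- make_balanced(n = n, group_shift = 0.4, seed = n)
    mine <- mixed_anova(d, "amplitude_uV")
    sm <- aov_oracle(d)
    checks <- list(
      list("group", "Error: s", "g"),
      list("check_size_deg", "Error: s:cs", "cs"),
      list("check_size_deg:group", "Error: s:cs", "g:cs"),
      list("reversal_rate_rps", "Error: s:fr", "fr"),
      list("reversal_rate_rps:group", "Error: s:fr", "g:fr"),
      list("check_size_deg:reversal_rate_rps", "Error: s:cs:fr", "cs:fr"),
      list("check_size_deg:reversal_rate_rps:group", "Error: s:cs:fr",
           "g:cs:fr"))
    for (ck in checks) {
      row <- mine[mine$effect == ck[[1]], ]
      ora <- pull_aov(sm, ck[[2]], ck[[3]])
      expect_equal(row$ss, ora$ss, tolerance = 1e-8, label = ck[[1]])
      expect_equal(row$df_num, ora$df, label = ck[[1]])
      expect_equal(row$F, ora$F, tolerance = 1e-8, label = ck[[1]])
      expect_equal(row$p_uncorrected, ora$p, tolerance = 1e-8,
                   label = ck[[1]])
    }
  }
})

test_that("Greenhouse-Geisser epsilon and corrected p match car::Anova", {
  skip_if_not_installed("car")
  d <- make_balanced(n = 7, group_shift = 0.3, seed = 2)
  mine <- mixed_anova(d, "amplitude_uV")
  d$cell <- paste0("c", as.integer(factor(d$check_size_deg)),
                   "_f", as.integer(factor(d$reversal_rate_rps)))
  wide <- stats::reshape(d[, c("subject", "group", "cell", "amplitude_uV")],
                         idvar = c("subject", "group"), timevar = "cell",
                         direction = "wide")
  Y <- as.matrix(wide[, grep("amplitude", names(wide))])
  cn <- colnames(Y)
  idata <- data.frame(
    cs = factor(sub(".*\\.c([0-9]+)_f[0-9]+$", "\\1", cn)),
    fr = factor(sub(".*_f([0-9]+)$", "\\1", cn)))
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  mlm <- stats::lm(Y ~ group, data = wide)
  s <- suppressWarnings(summary(car::Anova(mlm, idata = idata,
                                           idesign = ~ cs * fr, type = 3),
                                multivariate = FALSE))
  adj <- s$pval.adjustments
  expect_equal(mine$gg_epsilon[mine$effect == "check_size_deg"],
               unname(adj["cs", "GG eps"]), tolerance = 1e-9)
  expect_equal(
    mine$gg_epsilon[mine$effect == "check_size_deg:reversal_rate_rps"],
    unname(adj["cs:fr", "GG eps"]), tolerance = 1e-9)
  expect_equal(mine$p_gg[mine$effect == "check_size_deg"],
               unname(adj["cs", "Pr(>F[GG])"]), tolerance = 1e-8)
  expect_equal(
    mine$p_gg[mine$effect == "check_size_deg:reversal_rate_rps:group"],
    unname(adj["group:cs:fr", "Pr(>F[GG])"]), tolerance = 1e-8)
  # 2-level within effects need no correction
  expect_equal(mine$gg_epsilon[mine$effect == "reversal_rate_rps"], 1)
})

test_that("constant responses give zero SS, F = 0, p = 1", {
  d <- make_balanced(n = 4, subj_sd = 0, noise_sd = 0, seed = 1)
  d$amplitude_uV <- 2
  an <- mixed_anova(d, "amplitude_uV")
  eff <- an[!grepl("subjects", an$effect), ]
  expect_true(all(abs(eff$ss) < 1e-12))
  expect_true(all(eff$F == 0))
  expect_true(all(eff$p_uncorrected == 1))
})

test_that("two-level split-plot F equals the squared two-sample t", {
  set.seed(6)
  n <- 8
  subj <- sprintf("s%02d", 1:(2 * n))
  grp <- rep(c("control", "patient"), each = n)
  d <- expand.grid(subject = subj, reversal_rate_rps = c(12.5, 18.75),
                   stringsAsFactors = FALSE)
  d$group <- grp[match(d$subject, subj)]
  d$ratio <- rnorm(nrow(d), 1.2, 0.2) +
    ifelse(d$group == "patient", -0.15, 0)
  an <- mixed_anova_1w(d, dv = "ratio", within = "reversal_rate_rps")
  # between-group F = squared t on subject means
  means <- tapply(d$ratio, d$subject, mean)
  g_of <- grp[match(names(means), subj)]
  t_between <- stats::t.test(means[g_of == "control"],
                             means[g_of == "patient"],
                             var.equal = TRUE)$statistic
  expect_equal(an$F[an$effect == "group"], unname(t_between)^2,
               tolerance = 1e-10)
  # within x group F = squared t on subject differences
  diffs <- tapply(d$ratio[d$reversal_rate_rps == 18.75],
                  d$subject[d$reversal_rate_rps == 18.75], mean) -
    tapply(d$ratio[d$reversal_rate_rps == 12.5],
           d$subject[d$reversal_rate_rps == 12.5], mean)
  t_within <- stats::t.test(diffs[g_of == "control"],
                            diffs[g_of == "patient"],
                            var.equal = TRUE)$statistic
  expect_equal(an$F[an$effect == "reversal_rate_rps:group"],
               unname(t_within)^2, tolerance = 1e-10)
})

test_that("exact compound symmetry yields epsilon 1", {
  # whiten the within-group residual covariance of the 8 cell scores to
  # the identity, a special case of sphericity
  set.seed(4)
  n <- 10
  cells <- expand.grid(check_size_deg = c(0.8, 1.6, 3.2, 16),
                       reversal_rate_rps = c(12.5, 18.75))
  rows <- list()
  for (g in c("control", "patient")) {
    E <- matrix(rnorm(n * 8), n, 8)
    E <- sweep(E, 2, colMeans(E))
    W <- E %*% solve(chol(crossprod(E) / (n - 1)))  # sample cov = I
    for (s in seq_len(n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = paste0(g, s), group = g, cells,
        amplitude_uV = 2 + W[s, ])
    }
  }
  d <- do.call(rbind, rows)
  an <- mixed_anova(d, "amplitude_uV")
  eps <- an$gg_epsilon[!is.na(an$gg_epsilon)]
  expect_true(all(abs(eps - 1) < 1e-9))
})

test_that("SS are additive and F invariant under shift and relabeling", {
  d <- make_balanced(n = 6, group_shift = 0.5, seed = 10)
  an <- mixed_anova(d, "amplitude_uV")
  expect_equal(sum(an$ss), attr(an, "ss_total"), tolerance = 1e-8)
  # adding a constant to every observation changes nothing
  d2 <- d; d2$amplitude_uV <- d2$amplitude_uV + 17
  an2 <- mixed_anova(d2, "amplitude_uV")
  expect_equal(an2$F, an$F, tolerance = 1e-8)
  # relabeling within conditions identically for all subjects leaves the
  # group test untouched
  d3 <- d
  d3$check_size_deg <- c(16, 0.8, 3.2, 1.6)[match(d$check_size_deg,
                                                  c(0.8, 1.6, 3.2, 16))]
  an3 <- mixed_anova(d3, "amplitude_uV")
  expect_equal(an3$F[an3$effect == "group"], an$F[an$effect == "group"],
               tolerance = 1e-10)
  # unbalanced input is refused
  expect_error(mixed_anova(d[-1, ], "amplitude_uV"), "unbalanced")
})

test_that("post-hoc contrasts use raw mean differences and one pooled SE", {
  d <- make_balanced(n = 6, group_shift = 0.5, seed = 3)
  ph <- emm_posthoc(d, "amplitude_uV", reference_group = "control")
  expect_equal(nrow(ph), 8)
  # balanced design: EMM difference is the plain difference of means
  for (i in seq_len(nrow(ph))) {
    sel <- d$check_size_deg == ph$check_size_deg[i] &
      d$reversal_rate_rps == ph$reversal_rate_rps[i]
    raw <- mean(d$amplitude_uV[sel & d$group == "control"]) -
      mean(d$amplitude_uV[sel & d$group == "patient"])
    expect_equal(ph$emm_diff[i], raw, tolerance = 1e-10)
  }
  # single SE for every condition
  expect_lt(diff(range(ph$se)), 1e-10)
  # identical groups: all differences 0, all p = 1
  d0 <- d
  pat <- d0$group == "patient"
  key0 <- paste(d0$check_size_deg, d0$reversal_rate_rps,
                sub("s", "", d0$subject))
  ctl <- d0[!pat, ]
  idx <- match(paste(d0$check_size_deg[pat], d0$reversal_rate_rps[pat],
                     as.integer(sub("s", "", d0$subject[pat])) - 6),
               paste(ctl$check_size_deg, ctl$reversal_rate_rps,
                     as.integer(sub("s", "", ctl$subject))))
  d0$amplitude_uV[pat] <- ctl$amplitude_uV[idx]
  ph0 <- emm_posthoc(d0, "amplitude_uV", reference_group = "control")
  expect_true(all(abs(ph0$emm_diff) < 1e-12))
  expect_true(all(ph0$p_uncorrected > 1 - 1e-12))
})
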