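test_that("pooled two-sample t works in raw and summary modes", {
  # hand-computed pooled t for {1,2,3} vs {4,5,6}
  out <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  expect_equal(out$df, 4)
  # identical groups
  same <- two_sample_t(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # summary mode agrees with raw mode
  x <- c(5.1, 6.2, 4.8, 5.9); y <- c(7.3, 6.8, 8.1, 7.7)
  raw <- two_sample_t(x, y)
  summ <- two_sample_t(means = c(mean(x), mean(y)),
                       sds = c(sd(x), sd(y)), ns = c(4, 4))
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_error(two_sample_t(means = c(1, 1), sds = c(0, 0), ns = c(4, 4)),
               "zero variance")
})

test_that("chi-square handles identity, diagonal and degenerate tables", {
  even <- chi_square(matrix(c(9, 7, 9, 7), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)
  diag2 <- chi_square(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag2$statistic, 20)
  expect_equal(diag2$df, 1)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("partial eta squared follows the F identity", {
  expect_equal(partial_eta_sq(0, 1, 28), 0)
  expect_equal(partial_eta_sq(11.077, 1, 28), 11.077 / (11.077 + 28))
  # consistency against an actual lm-based ANOVA
  set.seed(1)
  d <- data.frame(g = rep(c("a", "b"), each = 10), y = rnorm(20))
  d$y[d$g == "b"] <- d$y[d$g == "b"] + 1
  an <- anova(lm(y ~ g, d))
  ss <- an$`Sum Sq`
  expect_equal(partial_eta_sq(an$`F value`[1], an$Df[1], an$Df[2]),
               ss[1] / (ss[1] + ss[2]), tolerance = 1e-12)
})

make_design <- function(n_per_group, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  d <- expand.grid(cond = c("lo", "hi"),
                   subject = sprintf("s%02d", 1:n),
                   stringsAsFactors = FALSE)[, 2:1]
  d$group <- rep(c("a", "b"), each = 2 * n_per_group)
  d$age <- rep(round(runif(n, 11, 17), 1), each = 2)
  d
}

test_that("mixed ANCOVA: within effect equals the paired t-squared", {
  n <- 12
  d <- make_design(n, seed = 7)
  base <- rnorm(2 * n, 10, 2)
  d$y <- rep(base, each = 2) + ifelse(d$cond == "hi", 1.5, 0) +
    rnorm(4 * n, 0, 0.8)
  fit <- mixed_ancova(d, "y", "group", "cond", covariate = NULL,
                      subject = "subject")
  # independent oracle: classical error-stratum decomposition via aov
  oracle <- summary(aov(y ~ group * cond + Error(subject / cond),
                        data = transform(d, subject = factor(subject),
                                         group = factor(group),
                                         cond = factor(cond))))
  within_tab <- oracle[["Error: subject:cond"]][[1]]
  between_tab <- oracle[["Error: subject"]][[1]]
  Fw <- fit$table$F[fit$table$effect == "cond"]
  expect_equal(Fw, within_tab["cond", "F value"], tolerance = 1e-9)
  expect_equal(fit$table$F[fit$table$effect == "group:cond"],
               within_tab["group:cond", "F value"], tolerance = 1e-9)
  expect_equal(fit$table$F[fit$table$effect == "group"],
               between_tab["group", "F value"], tolerance = 1e-9)
  # with no noise on the within contrast, F equals the paired t-squared
  d2 <- d
  d2$y <- rep(base, each = 2) + ifelse(d2$cond == "hi", 1.5, 0)
  fit2 <- mixed_ancova(d2, "y", "group", "cond")
  expect_lt(fit2$table$p[fit2$table$effect == "cond"], 1e-12)
  # self-consistency of the effect-size identity for every row
  with(fit$table, expect_equal(pes, partial_eta_sq(F, df1, df2),
                               tolerance = 1e-12))
})

test_that("mixed ANCOVA: a zero-slope covariate leaves the adjusted group SS unchanged", {
  n <- 10
  d <- make_design(n, seed = 9)
  set.seed(10)
  d$y <- rnorm(nrow(d), ifelse(d$group == "a", 10, 12), 2)
  # covariate with equal group means (centered within group) and, by
  # residualisation, an exactly zero slope against the subject means
  ga <- tapply(d$age, d$group, mean)
  d$age <- d$age - ga[d$group] + 14
  subj <- unique(d$subject)
  m_y <- tapply(d$y, d$subject, mean)[subj]
  ages <- tapply(d$age, d$subject, mean)[subj]
  grp <- tapply(d$group, d$subject, `[`, 1)[subj]
  adj <- fitted(lm(m_y ~ grp + ages)) - fitted(lm(m_y ~ grp))
  names(adj) <- subj
  d$y <- d$y - adj[d$subject]
  fit_cov <- mixed_ancova(d, "y", "group", "cond", covariate = "age")
  fit_nocov <- mixed_ancova(d, "y", "group", "cond", covariate = NULL)
  Fg_cov <- fit_cov$table$F[fit_cov$table$effect == "group"]
  Fg_nocov <- fit_nocov$table$F[fit_nocov$table$effect == "group"]
  df2c <- fit_cov$table$df2[fit_cov$table$effect == "group"]
  df2n <- fit_nocov$table$df2[fit_nocov$table$effect == "group"]
  # the covariate explains nothing, so only the error df (and hence F by
  # the df ratio) differs between ANCOVA and ANOVA
  expect_equal(df2c, df2n - 1)
  expect_equal(Fg_cov * df2n / df2c, Fg_nocov, tolerance = 1e-6)
  expect_lt(abs(fit_cov$table$F[fit_cov$table$effect == "age"]), 1e-9)
})

test_that("mixed ANCOVA validates its design and gates on homogeneity", {
  d <- expand.grid(subject = sprintf("s%d", 1:12), cond = c("lo", "hi"),
                   stringsAsFactors = FALSE)
  d$group <- rep(c("a", "b"), 12)[match(d$subject, sprintf("s%d", 1:12))]
  d$age <- 14
  d$y <- rnorm(24)
  expect_error(mixed_ancova(d, "y", "group", "cond", covariate = "age"),
               "constant")
  d2 <- d[-1, ]
  expect_error(mixed_ancova(d2, "y", "group", "cond"), "exactly one value")

  # strong group x age interaction triggers the downgrade
  set.seed(21)
  n <- 16
  dd <- expand.grid(subject = sprintf("s%02d", 1:(2 * n)),
                    cond = c("lo", "hi"), stringsAsFactors = FALSE)
  dd$group <- rep(c("a", "b"), each = n)[match(dd$subject,
                                               sprintf("s%02d", 1:(2 * n)))]
  age <- rep(seq(11, 17, length.out = 2 * n), 2)
  dd$age <- age[match(dd$subject, sprintf("s%02d", 1:(2 * n)))]
  slope <- ifelse(dd$group == "a", 3, -3)
  dd$y <- 10 + slope * (dd$age - 14) + rnorm(4 * n, 0, 0.5)
  fit <- mixed_ancova(dd, "y", "group", "cond", covariate = "age")
  expect_false(fit$covariate_used)
  expect_lt(fit$homogeneity$p, 0.05)
  expect_false("age" %in% fit$table$effect)
})

test_that("null simulations keep the mixed ANCOVA group effect at its alpha level", {
  set.seed(31)
  n_sims <- 80
  sig <- 0
  for (s in seq_len(n_sims)) {
    n <- 8
    d <- expand.grid(subject = sprintf("s%02d", 1:(2 * n)),
                     cond = c("lo", "hi"), stringsAsFactors = FALSE)
    d$group <- rep(c("a", "b"), each = n)[match(d$subject,
                                                sprintf("s%02d", 1:(2 * n)))]
    d$age <- rnorm(2 * n, 14, 2)[match(d$subject,
                                       sprintf("s%02d", 1:(2 * n)))]
    d$y <- rnorm(4 * n, 10, 2)
    fit <- mixed_ancova(d, "y", "group", "cond", covariate = "age")
    sig <- sig + (fit$table$p[fit$table$effect == "group"] < 0.05)
  }
  expect_gte((n_sims - sig) / n_sims, 0.90)
})

test_that("correlation comparison uses the Fisher r-to-z closed form", {
  # equal correlations: z = 0, p = 1
  set.seed(2)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40, 0, 1)
  g <- rep(c("a", "b"), 20)
  # construct identical pairs in both groups
  xx <- c(x[1:20], x[1:20]); yy <- c(y[1:20], y[1:20])
  gg <- rep(c("a", "b"), each = 20)
  out <- correlate_and_compare(xx, yy, gg)
  expect_equal(out$z, 0)
  expect_equal(out$p, 1)
  expect_equal(out$per_group$r[1], out$per_group$r[2])

  # closed-form oracle: r1 = 0.8, r2 = 0.0, n = 20 each
  # z = (atanh(.8) - atanh(0)) / sqrt(1/17 + 1/17) = 3.203
  make_r <- function(r, n, seed) {
    set.seed(seed)
    x <- rnorm(n); e <- rnorm(n)
    y <- r * x + sqrt(1 - r^2) * e
    # orthogonalize to hit r exactly
    e_o <- residuals(lm(e ~ x)); e_o <- e_o / sd(e_o)
    x_s <- (x - mean(x)) / sd(x)
    cbind(x_s, r * x_s + sqrt(1 - r^2) * e_o)
  }
  a <- make_r(0.8, 20, 3); b <- make_r(0.0, 20, 4)
  out2 <- correlate_and_compare(c(a[, 1], b[, 1]), c(a[, 2], b[, 2]),
                                rep(c("g1", "g2"), each = 20))
  expect_equal(out2$per_group$r, c(0.8, 0.0), tolerance = 1e-9)
  expect_equal(out2$z, (atanh(0.8)) / sqrt(2 / 17), tolerance = 1e-9)
  expect_equal(out2$z, 3.203, tolerance = 1e-3)

  # boundary: perfect correlation flagged, comparison not computable
  xb <- c(1:10, 1:10)
  out3 <- correlate_and_compare(xb, xb, rep(c("a", "b"), each = 10))
  expect_equal(out3$flag, "boundary")
  expect_true(is.na(out3$z))
  expect_error(correlate_and_compare(1:8, rep(1, 8),
                                     rep(c("a", "b"), each = 4)),
               "zero variance")
})

test_that("BH-FDR flags match an exhaustive threshold search and are monotone in q", {
  expect_true(bh_fdr(0.001, 0.10))
  expect_equal(bh_fdr(c(0.5, 0.6, 0.7), 0.10), rep(FALSE, 3))
  bh_oracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    k <- 0
    for (i in seq_len(m)) if (p[ord][i] <= i * q / m) k <- i
    flags <- rep(FALSE, m)
    if (k > 0) flags[ord[seq_len(k)]] <- TRUE
    flags
  }
  set.seed(14)
  for (rep_i in 1:20) {
    p <- runif(10)^2
    expect_equal(bh_fdr(p, 0.10), bh_oracle(p, 0.10))
    # order invariance
    perm <- sample(10)
    expect_equal(bh_fdr(p[perm], 0.10), bh_oracle(p, 0.10)[perm])
    # monotone non-decreasing in q
    expect_true(all(bh_fdr(p, 0.05) <= bh_fdr(p, 0.20)))
  }
})

test_that("AICc comparison: evidence p from supplied AIC pairs and model recovery", {
  # matches the printed 3-dp values
  expect_equal(round(aicc_evidence_p(97.74, 103.82), 3), 0.048)
  expect_equal(round(aicc_evidence_p(80.44, 93.43), 3), 0.002)

  # noiseless linear data: quadratic penalized, linear preferred
  x <- seq(-2, 2, length.out = 16)
  lin <- lin_vs_quad_aicc(x, 2 + 3 * x)
  expect_gte(lin$p_quadratic_better, 1)
  expect_equal(lin$preferred, "linear")
  expect_lt(abs(coef(lin$fit_quadratic)[3]), 1e-6)

  # inverted-U at n = 16 with small noise: quadratic detected
  set.seed(5)
  y <- (x - mean(x))^2 + rnorm(16, 0, 0.15)
  quad <- lin_vs_quad_aicc(x, y)
  expect_lt(quad$p_quadratic_better, 0.05)
  expect_equal(quad$preferred, "quadratic")
  expect_gte(quad$r2_quadratic, quad$r2_linear)

  expect_error(lin_vs_quad_aicc(rep(1, 16), rnorm(16)), "no spread")
})

test_that("AICc model recovery holds across simulated replicates", {
  set.seed(77)
  n <- 16
  hits <- 0
  n_sims <- 40
  for (s in seq_len(n_sims)) {
    x <- runif(n, -2, 2)
    truth_quad <- s %% 2 == 0
    y <- if (truth_quad) 1 + 0.3 * x + 1.2 * x^2 + rnorm(n, 0, 0.6)
         else 1 + 1.2 * x + rnorm(n, 0, 0.6)
    out <- lin_vs_quad_aicc(x, y)
    hits <- hits + ((out$preferred == "quadratic") == truth_quad)
  }
  expect_gte(hits / n_sims, 0.90)
})

test_that("Kaplan-Meier / log-rank on achieved levels matches hand-worked values", {
  # identical multisets: statistic 0, p = 1
  same <- km_logrank(list(a = c(1, 2, 2, 3), b = c(1, 2, 2, 3)))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  # hand-worked log-rank over 4 distinct event levels:
  # O1 = 4, E1 = 1 + 2/3, V = 3/7 + 16/45 -> chisq = (4 - 5/3)^2 / V
  hw <- km_logrank(list(g1 = c(1, 1, 2, 2), g2 = c(3, 3, 4, 4)))
  V <- 2 * (4 / 8) * (4 / 8) * (6 / 7) + 2 * (2 / 6) * (4 / 6) * (4 / 5)
  expect_equal(hw$chisq, (4 - 5 / 3)^2 / V, tolerance = 1e-6)
  expect_equal(hw$df, 1)

  # product-limit arithmetic for {2,2,3}: survival 1/3 after level 2
  km <- km_logrank(list(a = c(2, 2, 3), b = c(2, 3, 4)))
  s_a <- summary(km$fit)
  grp_a <- grepl("a", s_a$strata)
  expect_equal(s_a$surv[grp_a], c(1 / 3, 0))
  expect_error(km_logrank(list(a = c(1, 2))), "length")
})
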