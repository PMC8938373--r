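# Statistical layer: group comparisons, mixed factorial ANCOVA with an
# age covariate and a homogeneity-of-regression gate, effect sizes,
# correlation comparison with FDR, AICc model comparison, and
# Kaplan-Meier / log-rank analysis of achieved n-back level.

#' Pooled-variance two-sample t test
#'
#' Accepts either raw samples or printed summary statistics (means, SDs,
#' group sizes), using the pooled-variance t with df = n1 + n2 - 2 and a
#' two-sided p in both modes.
#'
#' @param x,y numeric samples (raw mode).
#' @param means,sds,ns length-2 numeric vectors (summary mode).
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x = NULL, y = NULL, means = NULL, sds = NULL,
                         ns = NULL) {
  if (!is.null(x)) {
    stopifnot(length(x) >= 2, length(y) >= 2)
    means <- c(mean(x), mean(y))
    sds <- c(stats::sd(x), stats::sd(y))
    ns <- c(length(x), length(y))
  }
  stopifnot(length(means) == 2, length(sds) == 2, length(ns) == 2,
            all(ns >= 2))
  if (all(sds == 0)) stop("zero variance in both groups")
  df <- sum(ns) - 2
  sp2 <- ((ns[1] - 1) * sds[1]^2 + (ns[2] - 1) * sds[2]^2) / df
  tval <- (means[1] - means[2]) / sqrt(sp2 * (1 / ns[1] + 1 / ns[2]))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction, matching the usual reporting for group
#' composition tables.
#'
#' @param contingency_table matrix of non-negative counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square <- function(contingency_table) {
  m <- as.matrix(contingency_table)
  stopifnot(all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("contingency table has an all-zero margin")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Partial eta squared from F and degrees of freedom
#'
#' eta_p^2 = F * df1 / (F * df1 + df2), the SS_effect /
#' (SS_effect + SS_error) ratio expressed through the F statistic.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return partial eta squared.
#' @export
partial_eta_sq <- function(F, df1, df2) {
  stopifnot(all(F >= 0), all(df1 >= 1), all(df2 >= 1))
  ifelse(is.infinite(F), 1, F * df1 / (F * df1 + df2))
}

#' Mixed factorial ANCOVA with two-level within factors
#'
#' Univariate general-linear-model decomposition of a design with one
#' between-subject factor, any number of two-level within-subject
#' factors, and at most one covariate (Type III sums of squares,
#' sum-to-zero contrasts, covariate mean-centered). Each within-effect
#' subset is reduced to a per-subject contrast score; the within effect
#' is the intercept test on that score and its interactions with the
#' between factor / covariate are the corresponding slopes. Sphericity
#' correction is unnecessary because every within factor has 1 df.
#'
#' A homogeneity-of-regression pre-test (between x covariate on the
#' subject means) gates the covariate: if violated at `alpha` the model
#' is downgraded to an ANOVA and flagged.
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param between name of the between-subject factor (one factor).
#' @param within character vector of within-subject factor names (each
#'   with exactly 2 levels).
#' @param covariate optional covariate column name.
#' @param subject subject-identifier column name.
#' @param alpha criterion for the homogeneity gate.
#' @return object of class `mixed_anova_result`: `table` (data.frame
#'   with effect, F, df1, df2, p, pes), `covariate_used`, `homogeneity`
#'   (gate F, df, p), `n_subjects`.
#' @export
mixed_ancova <- function(data, dv, between, within, covariate = NULL,
                         subject = "subject", alpha = 0.05) {
  stopifnot(all(c(dv, between, within, covariate, subject) %in% names(data)))
  data[[between]] <- factor(data[[between]])
  data[[subject]] <- factor(data[[subject]])
  for (f in within) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) != 2)
      stop("within factor '", f, "' must have exactly 2 levels")
  }
  n_cells <- 2^length(within)
  tab <- table(data[[subject]])
  if (any(tab != n_cells))
    stop("each subject must contribute exactly one value per cell")
  if (!is.null(covariate) && stats::sd(data[[covariate]]) == 0)
    stop("covariate is constant")

  subjects <- levels(data[[subject]])
  sub_rows <- split(seq_len(nrow(data)), data[[subject]])
  grp <- vapply(sub_rows, function(r) as.character(data[[between]][r[1]]),
                character(1))
  cov <- if (!is.null(covariate))
    vapply(sub_rows, function(r) data[[covariate]][r[1]], numeric(1))
  else NULL
  if (!is.null(cov)) cov <- cov - mean(cov)

  # per-subject contrast scores for every subset of within factors
  codes <- lapply(within, function(f)
    ifelse(data[[f]] == levels(data[[f]])[1], 1, -1))
  names(codes) <- within
  subsets <- list(character(0))
  for (f in within) subsets <- c(subsets, lapply(subsets, c, f))

  score_for <- function(S, rows) {
    v <- data[[dv]][rows]
    if (length(S)) for (f in S) v <- v * codes[[f]][rows]
    mean(v)
  }

  gdf <- data.frame(group = factor(grp), row.names = NULL)
  if (!is.null(cov)) gdf$cov <- cov

  # homogeneity-of-regression gate on the subject means
  homogeneity <- NULL
  covariate_used <- !is.null(cov)
  if (covariate_used) {
    gdf$m <- vapply(sub_rows, function(r) score_for(character(0), r),
                    numeric(1))
    n_gate_par <- 2 * nlevels(gdf$group)
    if (length(subjects) > n_gate_par) {
      hm <- stats::lm(m ~ group * cov, data = gdf,
                      contrasts = list(group = "contr.sum"))
      ha <- car::Anova(hm, type = 3)
      i <- grep("group:cov", rownames(ha))
      homogeneity <- list(F = ha$`F value`[i], df1 = ha$Df[i],
                          df2 = ha$Df[nrow(ha)], p = ha$`Pr(>F)`[i])
      if (homogeneity$p < alpha) covariate_used <- FALSE
    } else {
      # too few subjects to assess homogeneity of regression
      homogeneity <- list(F = NA_real_, df1 = NA_integer_,
                          df2 = NA_integer_, p = NA_real_)
    }
  }

  # manual Type III decomposition for the degenerate zero-residual case
  # (e.g. a noiseless within-subject contrast), where car::Anova errors
  type3_manual <- function(fit) {
    X <- stats::model.matrix(fit)
    y <- stats::model.response(stats::model.frame(fit))
    rss_full <- sum(stats::residuals(fit)^2)
    df_res <- stats::df.residual(fit)
    asg <- attr(X, "assign")
    terms_lab <- c("(Intercept)", attr(stats::terms(fit), "term.labels"))
    out <- data.frame(Df = integer(0), `F value` = numeric(0),
                      `Pr(>F)` = numeric(0), check.names = FALSE)
    for (ti in seq_along(terms_lab) - 1L) {
      keep <- asg != ti
      rss_red <- if (any(keep))
        sum(stats::lm.fit(X[, keep, drop = FALSE], y)$residuals^2)
      else sum((y - 0)^2)
      ss <- max(rss_red - rss_full, 0)
      dfj <- sum(asg == ti)
      Fv <- if (rss_full < 1e-20 * max(1, sum(y^2))) {
        if (ss > 1e-12) Inf else 0
      } else (ss / dfj) / (rss_full / df_res)
      out[terms_lab[ti + 1L], ] <- c(dfj, Fv,
                                     stats::pf(Fv, dfj, df_res,
                                               lower.tail = FALSE))
    }
    out["Residuals", ] <- c(df_res, NA, NA)
    out
  }

  rows_out <- list()
  for (S in subsets) {
    gdf$score <- vapply(sub_rows, function(r) score_for(S, r), numeric(1))
    fml <- if (covariate_used) score ~ group + cov else score ~ group
    fit <- stats::lm(fml, data = gdf,
                     contrasts = list(group = "contr.sum"))
    an <- tryCatch(car::Anova(fit, type = 3),
                   error = function(e) type3_manual(fit))
    df2 <- an$Df[nrow(an)]
    get_row <- function(term, label) {
      i <- match(term, rownames(an))
      if (is.na(i)) return(NULL)
      Fv <- an$`F value`[i]
      data.frame(effect = label, F = Fv, df1 = an$Df[i], df2 = df2,
                 p = an$`Pr(>F)`[i],
                 pes = partial_eta_sq(Fv, an$Df[i], df2))
    }
    Slab <- paste(S, collapse = ":")
    if (length(S)) {
      rows_out <- c(rows_out, list(
        get_row("(Intercept)", Slab),
        get_row("group", paste(between, Slab, sep = ":")),
        if (covariate_used) get_row("cov", paste(covariate, Slab, sep = ":"))))
    } else {
      rows_out <- c(rows_out, list(
        get_row("group", between),
        if (covariate_used) get_row("cov", covariate)))
    }
  }
  table <- do.call(rbind, rows_out)
  rownames(table) <- NULL
  structure(list(table = table, covariate_used = covariate_used,
                 homogeneity = homogeneity,
                 n_subjects = length(subjects)),
            class = "mixed_anova_result")
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat("Mixed ", if (x$covariate_used) "ANCOVA" else "ANOVA",
      " (n = ", x$n_subjects, " subjects)\n", sep = "")
  if (!is.null(x$homogeneity))
    cat(sprintf("homogeneity-of-regression gate: F(%d,%d) = %.3f, p = %.3f%s\n",
                x$homogeneity$df1, x$homogeneity$df2, x$homogeneity$F,
                x$homogeneity$p,
                if (!x$covariate_used) "  [violated; covariate dropped]" else ""))
  tab <- x$table
  tab$F <- round(tab$F, 3); tab$p <- round(tab$p, 4)
  tab$pes <- round(tab$pes, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-group Pearson correlations and between-group comparison
#'
#' Pearson r with a two-sided p per group; group correlations compared
#' by Fisher's r-to-z with SE = sqrt(1/(n1-3) + 1/(n2-3)). At the r =
#' +/-1 boundary the comparison is undefined and flagged.
#'
#' @param x,y numeric vectors.
#' @param groups factor with two levels aligned to `x`/`y`.
#' @return list: `per_group` (data.frame group, n, r, p), `z`, `p`,
#'   `flag` ("ok" or "boundary").
#' @export
correlate_and_compare <- function(x, y, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(x) == length(y),
            length(x) == length(groups))
  per <- lapply(levels(groups), function(g) {
    i <- groups == g
    if (sum(i) < 4) stop("fewer than 4 pairs in group ", g)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0)
      stop("zero variance in group ", g)
    ct <- stats::cor.test(x[i], y[i])
    data.frame(group = g, n = sum(i), r = unname(ct$estimate),
               p = ct$p.value)
  })
  per <- do.call(rbind, per)
  if (any(abs(per$r) >= 1 - 1e-12)) {
    return(list(per_group = per, z = NA_real_, p = NA_real_,
                flag = "boundary"))
  }
  se <- sqrt(1 / (per$n[1] - 3) + 1 / (per$n[2] - 3))
  z <- (atanh(per$r[1]) - atanh(per$r[2])) / se
  list(per_group = per, z = z, p = 2 * stats::pnorm(-abs(z)), flag = "ok")
}

#' Benjamini-Hochberg FDR survivor flags
#'
#' Step-up BH at level `q`: flags all hypotheses with rank up to the
#' largest i such that p_(i) <= i q / m.
#'
#' @param p_values numeric p-values in [0, 1].
#' @param q FDR level (default 0.10).
#' @return logical vector aligned to `p_values`.
#' @export
bh_fdr <- function(p_values, q = 0.10) {
  stopifnot(length(p_values) >= 1, all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Small-sample corrected AIC of a Gaussian linear model
#'
#' AICc = n log(RSS/n) + 2k + 2k(k+1)/(n-k-1), with k counting the
#' regression coefficients plus the error scale. The additive constant
#' shared by all Gaussian fits cancels in differences.
#'
#' @param fit an `lm`.
#' @return AICc value.
#' @export
aicc_lm <- function(fit) {
  n <- length(stats::residuals(fit))
  k <- length(stats::coef(fit)) + 1
  stopifnot(n - k - 1 > 0)
  rss <- max(sum(stats::residuals(fit)^2), n * 1e-12)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Evidence p from an AIC(c) difference
#'
#' p = exp((AIC_quadratic - AIC_linear) / 2): the relative likelihood of
#' the quadratic model being worse, used to test whether a quadratic fit
#' is significantly better than the linear one.
#'
#' @param aic_quadratic,aic_linear information-criterion values.
#' @return evidence p.
#' @export
aicc_evidence_p <- function(aic_quadratic, aic_linear) {
  exp((aic_quadratic - aic_linear) / 2)
}

#' Linear versus quadratic model comparison by AICc
#'
#' Fits y ~ x and y ~ x + x^2 by least squares, computes AICc for each,
#' and the evidence p = exp((AICc_quadratic - AICc_linear)/2); p < 0.05
#' indicates the quadratic model is significantly better.
#'
#' @param x,y numeric vectors (n >= 6).
#' @return object of class `model_comparison`: `r2_linear`,
#'   `r2_quadratic`, `aicc_linear`, `aicc_quadratic`,
#'   `p_quadratic_better`, `preferred`, and both fits.
#' @export
lin_vs_quad_aicc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 6)
  if (stats::sd(x) == 0) stop("x has no spread")
  d <- data.frame(x = x, y = y)
  fl <- stats::lm(y ~ x, data = d)
  fq <- stats::lm(y ~ x + I(x^2), data = d)
  p <- aicc_evidence_p(aicc_lm(fq), aicc_lm(fl))
  # summary.lm warns on an exactly perfect fit; noiseless input is a
  # legitimate degenerate case here
  r2 <- function(f) suppressWarnings(summary(f)$r.squared)
  structure(list(r2_linear = r2(fl),
                 r2_quadratic = r2(fq),
                 aicc_linear = aicc_lm(fl), aicc_quadratic = aicc_lm(fq),
                 p_quadratic_better = p,
                 preferred = if (p < 0.05) "quadratic" else "linear",
                 fit_linear = fl, fit_quadratic = fq),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("linear R2 = %.3f (AICc %.2f); quadratic R2 = %.3f (AICc %.2f)\n",
              x$r2_linear, x$aicc_linear, x$r2_quadratic, x$aicc_quadratic))
  cat(sprintf("p(quadratic > linear) = %.4f -> %s preferred\n",
              x$p_quadratic_better, x$preferred))
  invisible(x)
}

#' Kaplan-Meier / log-rank comparison of achieved n-back level
#'
#' Treats a larger achieved mean n-back level as longer "survival"; all
#' observations are events (every session reaches a terminal level, so
#' there is no censoring). Produces per-group Kaplan-Meier curves over
#' the level axis and the two-group log-rank chi-square.
#'
#' @param values_by_group named list of two (or more) numeric vectors of
#'   achieved levels, or a data.frame with `value` and `group`.
#' @return object of class `survival_result`: `fit` (a
#'   [survival::survfit] object), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(values_by_group) {
  if (is.data.frame(values_by_group)) {
    d <- data.frame(value = values_by_group$value,
                    group = factor(values_by_group$group))
  } else {
    stopifnot(is.list(values_by_group), length(values_by_group) >= 2)
    d <- data.frame(
      value = unlist(values_by_group, use.names = FALSE),
      group = factor(rep(names(values_by_group),
                         lengths(values_by_group))))
  }
  if (nlevels(d$group) < 2) stop("need at least two groups")
  stopifnot(all(table(d$group) >= 2))
  s <- survival::Surv(d$value, rep(1, nrow(d)))
  fit <- survival::survfit(s ~ group, data = d)
  sd_ <- survival::survdiff(s ~ group, data = d)
  df <- length(sd_$n) - 1
  structure(list(fit = fit, chisq = unname(sd_$chisq), df = df,
                 p = stats::pchisq(unname(sd_$chisq), df,
                                   lower.tail = FALSE)),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.3f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}
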