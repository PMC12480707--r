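#' Cliff's delta
#'
#' Nonparametric effect size `P(a > b) - P(a < b)`, in `[-1, 1]`.
#'
#' @param a,b Numeric vectors.
#' @return Scalar delta.
#' @export
cliffs_delta <- function(a, b) {
  s <- outer(a, b, function(x, y) sign(x - y))
  mean(s)
}

# exact two-sided Mann-Whitney p by enumeration of group assignments,
# valid with ties; p = 2 * min(P(U <= u), P(U >= u)) capped at 1
.mw_exact <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(n, na)
  us <- apply(idx, 2, function(ii) sum(r[ii])) - na * (na + 1) / 2
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(p, 1))
}

# Watson-Williams test for equal mean directions of two circular samples
# (angles in radians); high-concentration F approximation with the usual
# correction factor.
.watson_williams <- function(th1, th2) {
  n1 <- length(th1); n2 <- length(th2); n <- n1 + n2
  Rbar <- function(th) sqrt(sum(cos(th))^2 + sum(sin(th))^2)
  R1 <- Rbar(th1); R2 <- Rbar(th2); R <- Rbar(c(th1, th2))
  rw <- (R1 + R2) / n
  # concentration estimate (Fisher's approximation) and correction
  kappa <- if (rw < 0.53) 2 * rw + rw^3 + 5 * rw^5 / 6
           else if (rw < 0.85) -0.4 + 1.39 * rw + 0.43 / (1 - rw)
           else 1 / (rw^3 - 4 * rw^2 + 3 * rw)
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * (n - 2) * (R1 + R2 - R) / (n - R1 - R2)
  p <- pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(statistic = Fstat, p = p, kappa = kappa)
}

#' Circular mean of clock hours
#'
#' @param hours Clock hours in `[0, 24)`.
#' @param period Period (default 24).
#' @return Circular mean in `[0, period)`.
#' @export
circular_mean_hours <- function(hours, period = 24) {
  th <- 2 * pi * hours / period
  out <- (atan2(mean(sin(th)), mean(cos(th))) * period / (2 * pi)) %% period
  if (out >= period) 0 else out   # guard the floating-point wrap at period
}

#' Compare a cosinor parameter between two groups
#'
#' Linear parameters (MESOR, amplitude) are routed by a Kolmogorov-Smirnov
#' normality check on each group: a Student's t-test when both pass, else a
#' Mann-Whitney U test (exact enumeration when the combined n is at most 20,
#' normal approximation with tie correction otherwise). Acrophases are
#' treated as circular quantities and compared with the Watson-Williams
#' test (a linear route is available for strict replication of linear
#' reporting). Cliff's delta is reported for every comparison, alongside
#' median [IQR] and mean +/- SD summaries.
#'
#' @param values_a,values_b Parameter values for the two groups (clock hours
#'   when `parameter_kind = "acrophase"`); each group needs n >= 3.
#' @param parameter_kind One of `"mesor"`, `"amplitude"`, `"acrophase"`.
#' @param groups Length-2 character vector naming the groups.
#' @param alpha Normality-screen level (default 0.05).
#' @param circular For acrophases: use the circular route (default `TRUE`).
#' @return One-row tibble: test name, statistic, p, Cliff's delta and group
#'   summaries.
#' @export
compare_groups <- function(values_a, values_b,
                           parameter_kind = c("mesor", "amplitude",
                                              "acrophase"),
                           groups = c("a", "b"), alpha = 0.05,
                           circular = TRUE) {
  parameter_kind <- match.arg(parameter_kind)
  a <- values_a[is.finite(values_a)]; b <- values_b[is.finite(values_b)]
  if (length(a) < 3 || length(b) < 3) abort("each group needs n >= 3")
  summ <- function(v) sprintf("%.3g [%.3g] / %.3g +/- %.3g",
                              median(v), stats::IQR(v), mean(v), sd(v))
  base <- tibble::tibble(parameter = parameter_kind,
                         group_a = groups[1], group_b = groups[2],
                         n_a = length(a), n_b = length(b),
                         summary_a = summ(a), summary_b = summ(b))
  if (parameter_kind == "acrophase" && circular) {
    th_a <- 2 * pi * a / 24; th_b <- 2 * pi * b / 24
    ww <- .watson_williams(th_a, th_b)
    diff_h <- ((circular_mean_hours(a) - circular_mean_hours(b) + 12) %% 24) - 12
    return(dplyr::mutate(base, test = "watson_williams",
                         statistic = ww$statistic, p = ww$p,
                         delta = cliffs_delta(a, b),
                         circular_mean_diff_h = diff_h))
  }
  if (sd(a) == 0 && sd(b) == 0 && median(a) == median(b)) {
    return(dplyr::mutate(base, test = "degenerate", statistic = NA_real_,
                         p = 1, delta = 0, circular_mean_diff_h = NA_real_))
  }
  norm_p <- function(v) {
    if (sd(v) == 0) return(0)
    suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v))$p.value)
  }
  # a normality screen is uninformative on tiny samples: go nonparametric
  both_normal <- length(a) >= 8 && length(b) >= 8 &&
    norm_p(a) > alpha && norm_p(b) > alpha
  if (both_normal) {
    tt <- t.test(a, b, var.equal = TRUE)
    res <- dplyr::mutate(base, test = "student_t",
                         statistic = unname(tt$statistic), p = tt$p.value)
  } else if (length(a) + length(b) <= 20) {
    mw <- .mw_exact(a, b)
    res <- dplyr::mutate(base, test = "mann_whitney_exact",
                         statistic = mw$u, p = mw$p)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    res <- dplyr::mutate(base, test = "mann_whitney_normal",
                         statistic = unname(wt$statistic), p = wt$p.value)
  }
  dplyr::mutate(res, delta = cliffs_delta(a, b),
                circular_mean_diff_h = NA_real_)
}

#' Multiplicity adjustment with attached effect sizes
#'
#' @param p_values Numeric vector of p-values.
#' @param method `"benjamini_hochberg"` (default), `"bonferroni"` or
#'   `"none"`.
#' @param q Decision level (default 0.05).
#' @param deltas Optional vector of per-comparison Cliff's deltas to carry
#'   along.
#' @return Tibble: `p`, `p_adjusted`, `reject`, and `delta` when supplied.
#' @export
adjust_multiplicity <- function(p_values,
                                method = c("benjamini_hochberg",
                                           "bonferroni", "none"),
                                q = 0.05, deltas = NULL) {
  method <- match.arg(method)
  padj <- switch(method,
                 benjamini_hochberg = p.adjust(p_values, "BH"),
                 bonferroni = p.adjust(p_values, "bonferroni"),
                 none = p_values)
  out <- tibble::tibble(p = p_values, p_adjusted = padj, reject = padj <= q)
  if (!is.null(deltas)) out$delta <- deltas
  out
}

#' Logistic regression of rhythmicity on covariates
#'
#' Maximum-likelihood logistic fit (IRLS via `glm`) of a binary rhythmicity
#' flag on age, sex and BMI; coefficients are exponentiated to odds ratios
#' with Wald confidence intervals. Perfect separation is detected and
#' raised as an error (a Firth-penalised fit would be the remedy; not
#' provided).
#'
#' @param data Tibble with the outcome and covariates.
#' @param outcome Name of the logical/0-1 outcome column (default
#'   `"rhythmic"`).
#' @param covariates Character vector of covariate columns.
#' @param level Confidence level (default 0.95).
#' @return Tibble: term, odds ratio, CI bounds, p.
#' @export
rhythmicity_logistic <- function(data, outcome = "rhythmic",
                                 covariates = c("age", "sex", "bmi"),
                                 level = 0.95) {
  y <- as.integer(as.logical(data[[outcome]]))
  if (sum(y) < 10 || sum(1 - y) < 10)
    abort("need at least 10 events and 10 non-events")
  form <- stats::as.formula(paste(outcome, "~",
                                  paste(covariates, collapse = " + ")))
  df <- data; df[[outcome]] <- y
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || any(abs(coef(fit)) > 15))
    abort("perfect separation detected; consider a Firth-penalised fit")
  est <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(term = names(est), odds_ratio = exp(est),
                 conf.low = exp(est - zq * se),
                 conf.high = exp(est + zq * se),
                 p = 2 * stats::pnorm(-abs(est / se)))
}

#' Interaction ANOVA for sex-by-age effects on a cosinor parameter
#'
#' Type-II sums of squares (via `car::Anova`) for sex, age group, their
#' interaction, and optionally a third stratum factor (e.g. metric).
#'
#' @param data Tibble with a numeric `value` column and factors `sex`,
#'   `age_group` (and `stratum` when `three_way = TRUE`).
#' @param three_way Include the stratum factor (default `FALSE`).
#' @return Tidy ANOVA table: term, sumsq, df, statistic, p.
#' @export
interaction_anova <- function(data, three_way = FALSE) {
  fcts <- c("sex", "age_group", if (three_way) "stratum")
  for (f in fcts) data[[f]] <- factor(data[[f]])
  cells <- table(data[fcts])
  if (any(cells < 2)) {
    empty <- which(cells < 2, arr.ind = TRUE)[1, ]
    abort(paste0("cell with fewer than 2 observations: ",
                 paste(mapply(function(f, i) dimnames(cells)[[f]][i],
                              seq_along(fcts), empty),
                       collapse = " x ")))
  }
  form <- stats::as.formula(paste("value ~",
                                  paste(fcts, collapse = " * ")))
  fit <- lm(form, data = data)
  tab <- car::Anova(fit, type = 2)
  tibble::tibble(term = rownames(tab), sumsq = tab[["Sum Sq"]],
                 df = tab[["Df"]], statistic = tab[["F value"]],
                 p = tab[["Pr(>F)"]])
}
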