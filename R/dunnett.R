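.imcoh_cache <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch (symmetric
# tridiagonal Jacobi matrix eigendecomposition); cached per order.
gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(.imcoh_cache[[key]])) return(.imcoh_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  rule <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  .imcoh_cache[[key]] <- rule
  rule
}

# cached critical-value lookup (families repeat across analysis sets)
crit_cached <- function(k, df, alpha, lam) {
  key <- paste0("d|", k, "|", df, "|", alpha, "|",
                paste(signif(lam, 12), collapse = ","))
  if (!is.null(.imcoh_cache[[key]])) return(.imcoh_cache[[key]])
  lo <- stats::qt(1 - alpha / 2, df)
  hi <- stats::qt(1 - alpha / (2 * k), df)
  d <- stats::uniroot(function(d) pdunnett(d, lam, df) - (1 - alpha),
                      interval = c(lo * 0.999, hi * 1.001), tol = 1e-7)$root
  .imcoh_cache[[key]] <- d
  d
}

# Map Gauss-Legendre rule to [a, b].
gl_on <- function(rule, a, b) {
  list(nodes = (b - a) / 2 * rule$nodes + (a + b) / 2,
       weights = (b - a) / 2 * rule$weights)
}

# Factor loadings of the many-to-one t statistics: with group sizes n_i
# (treatments) and n_0 (control), T_i = (lam_i Z0 + sqrt(1-lam_i^2) Z_i)/S
# with lam_i = sqrt(n_i/(n_i + n_0)), so rho_ij = lam_i lam_j; balanced
# groups give lam = sqrt(1/2), rho = 0.5 exactly.
dunnett_loadings <- function(n_treat, n_control) {
  sqrt(n_treat / (n_treat + n_control))
}

# P(max_i |T_i| <= d) for the k-variate t with product correlation
# rho_ij = lam_i lam_j and df degrees of freedom, by the one-factor
# reduction: conditioning on the shared standard-normal factor Z0 = z and
# the scale S = sqrt(chi^2_df/df) = s, the T_i are independent with
# P(|T_i| <= d | z, s) = Phi((d s + lam_i z)/w_i) - Phi((-d s + lam_i z)/w_i),
# w_i = sqrt(1 - lam_i^2). The two-dimensional integral over (z, s) is
# evaluated by fixed Gauss-Legendre quadrature; deterministic, absolute
# accuracy ~1e-8 for k <= 50, df >= 2.
pdunnett <- function(d, lam, df, nz = 96, ns = 96) {
  if (d <= 0) return(0)
  k <- length(lam)
  w <- sqrt(1 - lam^2)
  rule <- gauss_legendre(max(nz, ns))
  gz <- gl_on(rule, -9, 9)
  # S = sqrt(chi^2_df/df): integrate over s in (0, s_hi]
  s_hi <- sqrt(stats::qchisq(1 - 1e-14, df) / df)
  gs <- gl_on(rule, .Machine$double.eps, s_hi)
  fs <- 2 * exp((df / 2) * log(df / 2) - lgamma(df / 2) +
                  (df - 1) * log(gs$nodes) - df * gs$nodes^2 / 2)
  phi_z <- stats::dnorm(gz$nodes)
  # inner product over comparisons, outer quadrature over (z, s)
  total <- 0
  for (j in seq_along(gs$nodes)) {
    ds <- d * gs$nodes[j]
    prod_k <- rep(1, length(gz$nodes))
    for (i in seq_len(k)) {
      prod_k <- prod_k *
        (stats::pnorm((ds + lam[i] * gz$nodes) / w[i]) -
           stats::pnorm((-ds + lam[i] * gz$nodes) / w[i]))
    }
    inner <- sum(gz$weights * phi_z * prod_k)
    total <- total + gs$weights[j] * fs[j] * inner
  }
  min(max(total, 0), 1)
}

# loadings from a scalar equicorrelation or a product-structure matrix
corr_to_loadings <- function(corr, k) {
  if (is.matrix(corr)) {
    stopifnot(nrow(corr) == k, ncol(corr) == k)
    if (k == 2) {
      # lam1*lam2 = rho is underdetermined; take the symmetric solution
      return(rep(sqrt(corr[1, 2]), 2))
    }
    # recover lam from rho_ij = lam_i lam_j using the first two rows
    lam1 <- sqrt(corr[1, 2] * corr[1, 3] / corr[2, 3])
    lam <- c(lam1, corr[1, 2:k] / lam1)
    if (max(abs(outer(lam, lam) - corr + diag(1 - lam^2, k))) > 1e-8) {
      stop("correlation matrix lacks the many-to-one product structure rho_ij = lam_i*lam_j")
    }
    lam
  } else {
    stopifnot(corr > 0, corr < 1)
    rep(sqrt(corr), k)
  }
}

#' Dunnett equicoordinate critical value
#'
#' Two-sided critical value `d` of the k-variate t distribution with the
#' many-to-one correlation structure, such that
#' `P(max_i |T_i| <= d) = 1 - alpha`. For `k = 1` this is the ordinary
#' two-sided Student t quantile. Evaluated by deterministic Gaussian
#' quadrature of the one-factor integral representation (absolute accuracy
#' well below 1e-4) and root-finding between the unadjusted and Bonferroni
#' t quantiles; monotone increasing in `k`.
#'
#' @param k Number of comparisons against the control (>= 1).
#' @param df Degrees of freedom of the pooled variance estimate.
#' @param alpha Familywise significance level.
#' @param corr Either a scalar equicorrelation (default 0.5, the balanced
#'   case) or a k x k correlation matrix with the many-to-one product
#'   structure `rho_ij = lam_i * lam_j`.
#' @return Critical value `d > 0`.
#' @examples
#' dunnett_critical_value(5, 24)  # ~2.70
#' @export
dunnett_critical_value <- function(k, df, alpha = 0.05, corr = 0.5) {
  stopifnot(k >= 1, df >= 1, alpha > 0, alpha < 1)
  if (k == 1) {
    return(stats::qt(1 - alpha / 2, df))
  }
  lam <- corr_to_loadings(corr, k)
  crit_cached(k, df, alpha, lam)
}

# Adjusted p for one observed statistic t0 within a family of k two-sided
# many-to-one comparisons: 1 - P(max_i |T_i| <= |t0|).
dunnett_adjusted_p <- function(t0, df, lam) {
  if (!is.finite(t0)) return(NA_real_)
  1 - pdunnett(abs(t0), lam, df)
}

#' Dunnett many-to-one comparisons with simultaneous confidence intervals
#'
#' Compares the mean of every non-baseline condition against the baseline
#' condition using the pooled within-group variance of a one-way layout
#' (`df = N - #groups`). Each comparison reports the mean difference
#' (condition minus baseline), a two-sided simultaneous `1 - alpha`
#' confidence interval `diff +/- d * s_p * sqrt(1/n_i + 1/n_0)` with `d` the
#' equicoordinate multivariate-t critical value, an adjusted p-value from
#' the same distribution, and a significance flag. By construction the
#' interval excludes zero exactly when the adjusted p-value is below
#' `alpha`.
#'
#' If every group has zero variance the family is flagged degenerate: all
#' differences are reported with zero-width intervals, missing p-values and
#' no significant results.
#'
#' @param values Numeric response values (e.g. band coherence, one per
#'   trial).
#' @param condition Condition label per value.
#' @param baseline Label of the control condition.
#' @param alpha Familywise significance level.
#' @param condition_order Optional ordering of the non-baseline conditions
#'   in the output (defaults to order of first appearance).
#' @return A data.frame of class `dunnett_result`, one row per non-baseline
#'   condition: `condition`, `n`, `diff`, `se`, `t`, `ci_lo`, `ci_hi`,
#'   `p_adj`, `significant`, `df`, `crit`, `alpha`, `degenerate`.
#' @export
dunnett_many_to_one <- function(values, condition, baseline = "EOFT",
                                alpha = 0.05, condition_order = NULL) {
  stopifnot(length(values) == length(condition), alpha > 0, alpha < 1)
  if (!baseline %in% condition) {
    stop(sprintf("baseline condition '%s' has no observations", baseline))
  }
  condition <- as.character(condition)
  lev <- if (is.null(condition_order)) {
    unique(condition[condition != baseline])
  } else {
    setdiff(condition_order, baseline)
  }
  if (!setequal(lev, unique(condition[condition != baseline]))) {
    stop("condition_order must contain exactly the observed non-baseline conditions")
  }
  groups <- c(baseline, lev)
  ns <- vapply(groups, function(g) sum(condition == g), integer(1))
  if (any(ns < 2)) {
    stop("every condition needs at least 2 values for pooled-variance inference")
  }
  k <- length(lev)
  N <- sum(ns)
  df <- N - length(groups)
  means <- vapply(groups, function(g) mean(values[condition == g]), numeric(1))
  ss <- vapply(groups, function(g) {
    v <- values[condition == g]
    sum((v - mean(v))^2)
  }, numeric(1))
  sp2 <- sum(ss) / df
  sp <- sqrt(sp2)
  diff <- means[-1] - means[1]
  se <- sp * sqrt(1 / ns[-1] + 1 / ns[1])
  degenerate <- sp2 <= 0

  if (degenerate) {
    out <- data.frame(
      condition = lev, n = ns[-1], diff = diff, se = 0, t = NA_real_,
      ci_lo = diff, ci_hi = diff, p_adj = NA_real_, significant = FALSE,
      df = df, crit = NA_real_, alpha = alpha, degenerate = TRUE,
      stringsAsFactors = FALSE)
  } else {
    lam <- dunnett_loadings(ns[-1], ns[1])
    crit <- if (k == 1) stats::qt(1 - alpha / 2, df)
            else crit_cached(k, df, alpha, lam)
    tstat <- diff / se
    p_adj <- if (k == 1) {
      2 * stats::pt(-abs(tstat), df)
    } else {
      vapply(tstat, dunnett_adjusted_p, numeric(1), df = df, lam = lam)
    }
    signif <- p_adj < alpha
    out <- data.frame(
      condition = lev, n = ns[-1], diff = diff, se = se, t = tstat,
      ci_lo = diff - crit * se, ci_hi = diff + crit * se,
      p_adj = p_adj, significant = signif, df = df, crit = crit,
      alpha = alpha, degenerate = FALSE, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("dunnett_result", "data.frame")
  attr(out, "baseline") <- baseline
  attr(out, "n_baseline") <- ns[1]
  attr(out, "pooled_sd") <- sp
  out
}

#' Assumption screens and omnibus F-test for one analysis set
#'
#' Runs the screens conventionally reported alongside many-to-one inference
#' on coherence values: Shapiro-Wilk normality per condition, Levene's test
#' of variance homogeneity across conditions (classic mean-centered form by
#' default; median-centering available), and the one-way fixed-effects
#' ANOVA F-test. Failures are reported, never auto-remediated.
#'
#' @param values Numeric response values.
#' @param condition Condition label per value.
#' @param center Centering for Levene's test: `"mean"` (classic) or
#'   `"median"` (Brown-Forsythe).
#' @return List with `shapiro` (data.frame: condition, W, p), `levene`
#'   (statistic, df, p), `anova` (F, df_between, df_within, p), and logical
#'   `flags` (`nonnormal`, `heteroscedastic` at the 0.05 screen level).
#' @export
assumption_screen <- function(values, condition, center = c("mean", "median")) {
  center <- match.arg(center)
  condition <- as.character(condition)
  lev <- unique(condition)
  stopifnot(length(lev) >= 2)
  shap <- do.call(rbind, lapply(lev, function(g) {
    v <- values[condition == g]
    if (length(v) < 3 || stats::sd(v) == 0) {
      data.frame(condition = g, W = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      s <- stats::shapiro.test(v)
      data.frame(condition = g, W = unname(s$statistic), p = s$p.value,
                 stringsAsFactors = FALSE)
    }
  }))
  grp <- factor(condition, levels = lev)
  lv <- car::leveneTest(values, grp,
                        center = if (center == "mean") mean else stats::median)
  fit <- stats::aov(values ~ grp)
  an <- summary(fit)[[1]]
  list(
    shapiro = shap,
    levene = list(statistic = lv[1, "F value"], df = unname(lv[["Df"]]),
                  p = lv[1, "Pr(>F)"]),
    anova = list(F = an[1, "F value"], df_between = an[1, "Df"],
                 df_within = an[2, "Df"], p = an[1, "Pr(>F)"]),
    flags = list(
      nonnormal = any(shap$p < 0.05, na.rm = TRUE),
      heteroscedastic = isTRUE(lv[1, "Pr(>F)"] < 0.05)
    )
  )
}

#' Comparison bookkeeping for a many-to-one design
#'
#' Number of comparisons of interest for `g` conditions: `g - 1` many-to-one
#' comparisons against a single baseline versus `choose(g, 2)` all-pairs
#' comparisons (the families an omnibus F-test implicitly screens). With six
#' conditions these are 5 and 15.
#'
#' @param n_conditions Number of conditions including the baseline.
#' @return List with `many_to_one` and `all_pairs` counts.
#' @export
comparison_counts <- function(n_conditions) {
  stopifnot(n_conditions >= 2)
  list(many_to_one = as.integer(n_conditions) - 1L,
       all_pairs = choose(n_conditions, 2))
}
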