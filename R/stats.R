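#' Z-standardize a numeric vector
#'
#' Centre to mean 0 and scale to sample SD 1 over the whole sample (the
#' convention used for ePVS and WMH volumes before regression). Missing
#' values are ignored for the moments and propagated in the output.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L) stop("zscore: constant vector")
  (values - mean(v)) / stats::sd(v)
}

#' Welch/pooled two-sample t-test from summary statistics
#'
#' Recomputes the two-sided t-test from printed group means, SDs and sizes,
#' which is how published comparison tables are checked. Welch
#' (unequal-variance) by default; `pooled = TRUE` gives the classical equal
#' variance test.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param pooled Use pooled variance (default `FALSE` = Welch).
#' @return List: `statistic`, `df`, `p.value`, `estimate` (mean difference).
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1; b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df),
       estimate = mean1 - mean2)
}

#' Two-group comparison of one variable
#'
#' `test = "auto"` follows the usual mapping: continuous variables get the
#' Welch t-test, ordinal (few-valued numeric) variables the Wilcoxon rank-sum
#' test, and categorical variables the chi-square test.
#'
#' @param table Data frame with a two-level `group` column.
#' @param variable Column to compare.
#' @param group Grouping column name (default `"status"`).
#' @param test `"auto"`, `"t"`, `"wilcoxon"` or `"chisq"`.
#' @param pooled Pooled-variance t-test instead of Welch.
#' @param ordinal_max_levels Numeric variables with at most this many unique
#'   values are treated as ordinal under `"auto"` (default 6).
#' @return List: `statistic`, `p.value`, `test`, and per-group `n`.
#' @export
compare_groups <- function(table, variable, group = "status",
                           test = c("auto", "t", "wilcoxon", "chisq"),
                           pooled = FALSE, ordinal_max_levels = 6L) {
  test <- match.arg(test)
  g <- factor(table[[group]])
  if (nlevels(g) != 2L) stop("compare_groups: need exactly two groups")
  x <- table[[variable]]
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (test == "auto") {
    test <- if (!is.numeric(x)) "chisq"
    else if (length(unique(x)) <= ordinal_max_levels) "wilcoxon"
    else "t"
  }
  ns <- table(g)
  if (test == "t") {
    if (any(ns < 2)) stop("t-test needs n >= 2 per group")
    r <- stats::t.test(x ~ g, var.equal = pooled)
    out <- list(statistic = unname(r$statistic), p.value = r$p.value)
  } else if (test == "wilcoxon") {
    r <- suppressWarnings(stats::wilcox.test(x ~ g))
    out <- list(statistic = unname(r$statistic), p.value = r$p.value)
  } else {
    tab <- base::table(factor(x), g)
    r <- suppressWarnings(stats::chisq.test(tab))
    out <- list(statistic = unname(r$statistic), p.value = r$p.value)
  }
  out$test <- test
  out$n <- as.integer(ns)
  out
}

# Variance inflation factors from a fitted lm: 1 / (1 - R^2_j) regressing
# each model-matrix column (intercept excluded) on the others.
model_vif <- function(fit) {
  X <- stats::model.matrix(fit)
  keep <- colnames(X) != "(Intercept)"
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2L) return(stats::setNames(rep(NA_real_, ncol(X)), colnames(X)))
  out <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    out[j] <- 1 / (1 - min(r2, 1 - 1e-12))
  }
  stats::setNames(out, colnames(X))
}

model_result <- function(fit, term, vif_exclude = character()) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) stop("term not estimable (collinearity?): ", term)
  ci <- stats::confint(fit, term, level = 0.95)
  vif <- model_vif(fit)
  p <- sm[term, "Pr(>|t|)"]
  # the collinearity screen concerns the covariates; the focal predictor and
  # interaction terms are intrinsically correlated with their main effects
  chk <- vif[setdiff(names(vif), c(term, vif_exclude))]
  if (any(is.finite(chk) & chk >= 5)) {
    warning("VIF >= 5 for: ",
            paste(names(chk)[is.finite(chk) & chk >= 5], collapse = ", "))
  }
  structure(list(term = term, beta = unname(sm[term, "Estimate"]),
                 se = unname(sm[term, "Std. Error"]),
                 ci_low = ci[1], ci_high = ci[2],
                 p = p, p_fdr = NA_real_, vif = vif,
                 n = stats::nobs(fit), fit = fit,
                 marginal = p > 0.05 && p < 0.10),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (95%% CI %.4g to %.4g), p = %.3g%s, n = %d\n",
              x$term, x$beta, x$ci_low, x$ci_high, x$p,
              if (isTRUE(x$marginal)) " (marginal)" else "", x$n))
  invisible(x)
}

#' Ordinary least-squares association model
#'
#' `outcome ~ predictor + covariates`, reporting the predictor term with a
#' t-based 95% CI, two-sided p, and per-covariate variance inflation factors
#' (warning when any VIF >= 5).
#'
#' @param table Data frame.
#' @param outcome,predictor Column names.
#' @param covariates Character vector of covariate columns (may be empty).
#' @return A `model_result`.
#' @export
fit_linear <- function(table, outcome, predictor, covariates = character()) {
  vars <- c(outcome, predictor, covariates)
  stopifnot(all(vars %in% names(table)))
  df <- stats::na.omit(table[, vars, drop = FALSE])
  npar <- length(vars)  # intercept + slopes (factors may add more)
  if (nrow(df) <= npar + 1L) stop("insufficient n for model")
  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("perfect collinearity among predictors")
  }
  term <- predictor
  if (!term %in% names(stats::coef(fit))) {
    # factor predictor: take its first contrast column
    term <- grep(paste0("^", predictor), names(stats::coef(fit)), value = TRUE)[1]
  }
  model_result(fit, term)
}

#' Disease-status by ePVS interaction model
#'
#' Fits `outcome ~ status + ePVS_z + status:ePVS_z (+ covariates)` with
#' status coded 0 = control, 1 = case, and reports the interaction term. The
#' result also carries per-group fitted lines and partial residuals for
#' interaction plots.
#'
#' @param table Data frame with a two-level status column.
#' @param outcome Outcome column name.
#' @param covariates Covariate column names (may be empty).
#' @param status Status column (default `"status"`); the reference (0) level
#'   is `"control"` when present, otherwise the first factor level.
#' @param epvs Standardized-ePVS column (default `"ePVS_z"`).
#' @return A `model_result`; `$plot_data` holds `lines` (per-group fitted
#'   values over the ePVS range) and `points` (partial residuals).
#' @export
fit_interaction <- function(table, outcome, covariates = character(),
                            status = "status", epvs = "ePVS_z") {
  vars <- c(outcome, status, epvs, covariates)
  stopifnot(all(vars %in% names(table)))
  df <- stats::na.omit(table[, vars, drop = FALSE])
  g <- factor(df[[status]])
  if (nlevels(g) != 2L) stop("interaction model needs both status groups")
  ref <- if ("control" %in% levels(g)) "control" else levels(g)[1]
  df$.status01 <- as.numeric(g != ref)
  df$.epvs <- df[[epvs]]
  fml <- stats::reformulate(c(".status01", ".epvs", ".status01:.epvs", covariates),
                            response = outcome)
  fit <- stats::lm(fml, data = df)
  res <- model_result(fit, ".status01:.epvs",
                      vif_exclude = c(".status01", ".epvs"))
  res$term <- paste0(setdiff(levels(g), ref), " x ", epvs)
  # partial residuals for the (status, ePVS, interaction) block and fitted
  # lines per group at covariate means
  cf <- stats::coef(fit)
  block <- cf[".status01"] * df$.status01 + cf[".epvs"] * df$.epvs +
    cf[".status01:.epvs"] * df$.status01 * df$.epvs
  res$plot_data <- list(
    points = data.frame(epvs = df$.epvs, group = as.character(g),
                        partial_residual = stats::residuals(fit) + block),
    lines = do.call(rbind, lapply(c(0, 1), function(s) {
      xx <- seq(min(df$.epvs), max(df$.epvs), length.out = 50)
      data.frame(group = if (s == 0) ref else setdiff(levels(g), ref),
                 epvs = xx,
                 fitted = cf["(Intercept)"] + cf[".status01"] * s +
                   cf[".epvs"] * xx + cf[".status01:.epvs"] * s * xx)
    }))
  )
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, order-preserving in
#' the input.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Group-comparison summary table
#'
#' One row per requested variable: mean (SD) per group, comparison p-value
#' (per [compare_groups()] `"auto"` mapping), and a significance star at
#' p < 0.05.
#'
#' @param table Data frame.
#' @param variables Columns to summarize.
#' @param group Grouping column (default `"status"`).
#' @return Data frame with columns variable, per-group `mean_sd`, `p`,
#'   `star`.
#' @export
build_table1 <- function(table, variables, group = "status") {
  g <- factor(table[[group]])
  stopifnot(nlevels(g) == 2L)
  lev <- levels(g)
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    cmp <- compare_groups(table, v, group = group)
    fmt <- function(l) {
      xi <- x[g == l]
      if (is.numeric(xi)) {
        sprintf("%.2f ± %.2f", mean(xi, na.rm = TRUE), stats::sd(xi, na.rm = TRUE))
      } else {
        paste0(round(100 * mean(xi == names(sort(table(x), decreasing = TRUE))[1],
                                na.rm = TRUE)), "%")
      }
    }
    data.frame(variable = v, g1 = fmt(lev[1]), g2 = fmt(lev[2]),
               test = cmp$test, p = cmp$p.value,
               star = ifelse(cmp$p.value < 0.05, "*", ""))
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- lev
  out
}
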