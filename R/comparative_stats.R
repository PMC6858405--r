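#' Pearson correlation with two-sided t-test
#'
#' Pairwise-complete Pearson correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (`stats::cor.test`).
#'
#' @param x,y Numeric vectors of equal length; pairs with any `NA` are
#'   dropped.
#' @param through_origin Logical; when `TRUE` the correlation appropriate
#'   for independent contrasts is computed, constraining the relationship
#'   through the origin (`r = sum(xy) / sqrt(sum(x^2) sum(y^2))`, df = n - 1).
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y, through_origin = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (through_origin) {
    if (sum(x^2) == 0 || sum(y^2) == 0) stop("zero variance")
    r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    tt <- r * sqrt((n - 1) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 1)
  } else {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(r = r, p = p, n = n)
}

#' Common-slope ANCOVA across groups
#'
#' Fits the parallel-slopes model `y ~ group + x` (one intercept per group,
#' one shared slope) and reports the shared slope and its t-test p-value.
#' Used to ask whether a within-species predictor (e.g. log sampling time)
#' affects the response once species identity is absorbed. Groups with
#' fewer than 2 points carry no within-group information and are dropped
#' with a warning.
#'
#' @param data Data.frame with the response, predictor and group columns.
#' @param y,x,group Column names (character).
#' @return List of class `ancova_result`: `common_slope`, `p`,
#'   `group_intercepts` (named), `n`, `n_groups`, `dropped` (group names).
#' @export
ancova_common_slope <- function(data, y = "y", x = "x", group = "group") {
  g <- as.character(data[[group]])
  counts <- table(g)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("dropping group(s) with a single point: ", paste(small, collapse = ", "))
    data <- data[!g %in% small, , drop = FALSE]
    g <- as.character(data[[group]])
  }
  if (length(unique(g)) < 2L) stop("need at least 2 groups with >= 2 points")
  df <- data.frame(y = data[[y]], x = data[[x]], g = factor(g))
  fit <- stats::lm(y ~ g + x, data = df)
  sm <- summary(fit)$coefficients
  if (!"x" %in% rownames(sm)) stop("all groups degenerate in x")
  # per-group intercepts on the original scale
  cf <- stats::coef(fit)
  base <- cf[["(Intercept)"]]
  lv <- levels(df$g)
  ints <- stats::setNames(
    base + c(0, cf[paste0("g", lv[-1])]), lv)
  structure(list(common_slope = unname(sm["x", "Estimate"]),
                 p = unname(sm["x", "Pr(>|t|)"]),
                 group_intercepts = ints,
                 n = nrow(df), n_groups = length(lv), dropped = small),
            class = "ancova_result")
}

#' Standardized multiple regression
#'
#' z-scores the response and every predictor, fits ordinary least squares,
#' and reports the standardized coefficients with their t-test p-values —
#' the usual way to compare effect sizes of covariates on different scales.
#'
#' @param X Data.frame or matrix of numeric predictors (no constant column).
#' @param y Numeric response.
#' @return List of class `regression_result`: `coefficients` (standardized,
#'   named), `p_values`, `n`, `r_squared`.
#' @export
multiple_regression_standardized <- function(X, y) {
  X <- as.data.frame(X)
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L) stop("need n > p + 1 observations")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) stop("constant predictor column(s): ",
                          paste(names(X)[sds == 0], collapse = ", "))
  Z <- as.data.frame(scale(X))
  qrX <- qr(cbind(1, as.matrix(Z)))
  if (qrX$rank < p + 1L) {
    drop_idx <- sort(qrX$pivot[(qrX$rank + 1L):(p + 1L)]) - 1L
    stop("collinear predictor column(s): ", paste(names(X)[drop_idx], collapse = ", "))
  }
  df <- data.frame(.y = as.numeric(scale(y)), Z, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  cleanup <- function(v) stats::setNames(v, gsub("^`|`$", "", names(v)))
  structure(list(coefficients = cleanup(sm[keep, "Estimate"]),
                 p_values = cleanup(sm[keep, "Pr(>|t|)"]),
                 n = n, r_squared = summary(fit)$r.squared),
            class = "regression_result")
}

#' Smallest correlation detectable at given power
#'
#' Closed-form power analysis for a Pearson correlation via the Fisher
#' z-transformation: the true correlation detectable with probability
#' `power` by a two-sided level-`alpha` test on `n` points satisfies
#' `atanh(r) = (z_(1 - alpha/2) + z_power) / sqrt(n - 3)`.
#'
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Desired power (default 0.95).
#' @return The detectable correlation, in (0, 1).
#' @export
detectable_correlation <- function(n, alpha = 0.05, power = 0.95) {
  stopifnot(n >= 4, alpha > 0, alpha < 1, power > 0, power < 1)
  z <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3)
  tanh(z)
}

#' Two-group t-test
#'
#' Welch's unequal-variance t-test for independent groups, or a paired
#' t-test when `paired = TRUE` (values must then be matched by position).
#'
#' @param values Numeric vector.
#' @param labels Group labels (exactly two distinct values).
#' @param paired Logical.
#' @return List with `t`, `p`, `df`, `group_means`.
#' @export
group_ttest <- function(values, labels, paired = FALSE) {
  labels <- as.character(labels)
  gs <- unique(labels)
  if (length(gs) != 2L) stop("need exactly two groups")
  a <- values[labels == gs[1]]; b <- values[labels == gs[2]]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (paired && length(a) != length(b)) stop("paired test needs equal group sizes")
  if (paired && stats::sd(a - b) == 0) {
    # degenerate paired case (t.test refuses constant differences)
    tt <- if (mean(a - b) == 0) 0 else sign(mean(a - b)) * Inf
    return(list(t = tt, p = if (tt == 0) 1 else 0, df = length(a) - 1,
                group_means = stats::setNames(c(mean(a), mean(b)), gs)))
  }
  ht <- if (paired) stats::t.test(a, b, paired = TRUE)
        else stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       group_means = stats::setNames(c(mean(a), mean(b)), gs))
}
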