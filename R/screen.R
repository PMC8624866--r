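# Descriptive and multivariate screening of a survey: moments and
# variability classes, Kolmogorov-Smirnov normality, correlation matrix
# with strength labels and significance stars, per the SPSS-style workflow
# common in groundwater-quality studies.

spss_skewness <- function(x) {
  n <- length(x)
  m <- mean(x); s2 <- sum((x - m)^2) / n
  if (s2 == 0) return(NA_real_)
  g1 <- sum((x - m)^3) / n / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

spss_kurtosis <- function(x) {
  # bias-corrected excess kurtosis (SPSS/Excel convention)
  n <- length(x)
  m <- mean(x); s2 <- sum((x - m)^2) / n
  if (s2 == 0) return(NA_real_)
  g2 <- sum((x - m)^4) / n / s2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Classify coefficient-of-variation magnitude
#'
#' Bins: low (CV <= 15%), intermediate (15% < CV < 35%), high (CV >= 35%).
#'
#' @param cv_percent CV in percent (>= 0).
#' @return Factor with levels low/intermediate/high.
#' @export
classify_variability <- function(cv_percent) {
  if (any(is.na(cv_percent)) || any(cv_percent < 0)) {
    abort("cv_percent must be non-negative")
  }
  out <- ifelse(cv_percent >= 35, "high",
                ifelse(cv_percent > 15, "intermediate", "low"))
  factor(out, levels = c("low", "intermediate", "high"))
}

#' Classify correlation strength
#'
#' Bins on |r|: negligible (< 0.10), weak (0.10-0.39), moderate
#' (0.40-0.69), strong (0.70-0.89), very_strong (0.90-1.00). Values in the
#' gaps between printed bin edges (e.g. 0.895) go to the higher bin; each
#' bin includes its lower edge. The sign is not part of the label.
#'
#' @param r Correlations in `[-1, 1]`.
#' @return Factor with the five strength levels.
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) abort("|r| must be <= 1")
  a <- abs(r)
  out <- ifelse(a > 0.89, "very_strong",
                ifelse(a > 0.69, "strong",
                       ifelse(a > 0.39, "moderate",
                              ifelse(a >= 0.10, "weak", "negligible"))))
  factor(out, levels = c("negligible", "weak", "moderate", "strong",
                         "very_strong"))
}

#' Kolmogorov-Smirnov normality test
#'
#' Tests a sample against a normal distribution with estimated mean and
#' standard deviation. The default is the Lilliefors-corrected test (the
#' variant statistical packages apply when parameters are estimated from
#' the data); `variant = "naive"` uses the uncorrected one-sample K-S
#' p-value with plugged-in parameters.
#'
#' @param x Numeric sample, `n >= 5`, non-constant.
#' @param variant `"lilliefors"` (default) or `"naive"`.
#' @return Tibble with `D`, `p_value`, `normal_at_05`.
#' @export
ks_normality <- function(x, variant = c("lilliefors", "naive")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]
  if (length(x) < 5) abort("need at least 5 non-missing values")
  if (sd(x) == 0) abort("constant input: normality test undefined")
  if (variant == "lilliefors") {
    ht <- nortest::lillie.test(x)
  } else {
    ht <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  }
  tibble(D = unname(ht$statistic), p_value = ht$p.value,
         normal_at_05 = ht$p.value >= 0.05)
}

#' Descriptive statistics per parameter
#'
#' For each requested parameter: n, mean, sd, min, max, SPSS-convention
#' (bias-corrected) skewness and excess kurtosis, CV% = 100 sd/mean, the
#' variability class, and the K-S normality verdict at alpha = 0.05.
#'
#' @param s Survey tibble.
#' @param parameters Parameter names (default: all present).
#' @param ks_variant Passed to [ks_normality()].
#' @return One tibble row per parameter.
#' @export
descriptive_stats <- function(s, parameters = NULL,
                              ks_variant = c("lilliefors", "naive")) {
  ks_variant <- match.arg(ks_variant)
  parameters <- parameters %||% intersect(.gw_parameters, names(s))
  purrr::map_dfr(parameters, function(p) {
    v <- s[[p]][!is.na(s[[p]])]
    if (length(v) < 4) {
      abort(paste0(p, ": need at least 4 non-missing values"))
    }
    m <- mean(v); sdev <- sd(v)
    # CV% is only meaningful for strictly positive-mean parameters
    cv <- if (sdev == 0) 0 else if (m > 0) 100 * sdev / m else NA_real_
    ks <- if (sdev > 0) ks_normality(v, ks_variant) else
      tibble(D = NA_real_, p_value = NA_real_, normal_at_05 = NA)
    tibble(
      parameter = p, n = length(v), mean = m, sd = sdev,
      min = min(v), max = max(v),
      skewness = spss_skewness(v), kurtosis = spss_kurtosis(v),
      cv_percent = cv,
      variability = if (is.na(cv)) factor(NA, levels = c("low", "intermediate",
                                                         "high"))
                    else classify_variability(cv),
      ks_D = ks$D, ks_p = ks$p_value, normal_at_05 = ks$normal_at_05
    )
  })
}

#' Pearson correlation matrix with significance
#'
#' Pairwise-complete Pearson correlations between parameters, two-tailed
#' p-values from the t statistic `r * sqrt((n-2)/(1-r^2))`, strength labels
#' from [classify_correlation()], and significance stars (`**` at 0.01,
#' `*` at 0.05).
#'
#' @param s Survey tibble.
#' @param parameters Parameter names (default: all present).
#' @return Object of class `gw_corr`: list of matrices `r`, `p`, `n`,
#'   `label`, `stars`. `tidy()` gives the long form.
#' @export
correlation_matrix <- function(s, parameters = NULL) {
  parameters <- parameters %||% intersect(.gw_parameters, names(s))
  k <- length(parameters)
  if (k < 2) abort("need at least 2 parameters")
  X <- as.matrix(s[parameters])
  r <- matrix(NA_real_, k, k, dimnames = list(parameters, parameters))
  p <- r; nmat <- r
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- complete.cases(X[, i], X[, j])
    n <- sum(ok)
    nmat[i, j] <- n
    if (n < 3) next
    xi <- X[ok, i]; xj <- X[ok, j]
    if (sd(xi) == 0 || sd(xj) == 0) {
      warn(paste0("zero-variance column in pair ", parameters[i], "-",
                  parameters[j], "; correlation undefined"))
      next
    }
    rij <- cor(xi, xj)
    r[i, j] <- rij
    if (i == j) { p[i, j] <- 0; next }
    tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- 2 * pt(-abs(tt), df = n - 2)
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  diag(stars) <- ""
  label <- matrix(NA_character_, k, k, dimnames = dimnames(r))
  label[!is.na(r)] <- as.character(classify_correlation(r[!is.na(r)]))
  structure(list(r = r, p = p, n = nmat, label = label, stars = stars),
            class = "gw_corr")
}

#' @export
print.gw_corr <- function(x, ...) {
  cat("<gw_corr> Pearson correlation matrix (", nrow(x$r), " parameters)\n",
      sep = "")
  disp <- matrix(paste0(sprintf("%.2f", x$r), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "."
  disp[lower.tri(disp)] <- ""
  print(as.data.frame(disp), right = TRUE)
  cat("** p < 0.01, * p < 0.05 (two-tailed)\n")
  invisible(x)
}

#' @export
tidy.gw_corr <- function(x, ...) {
  params <- rownames(x$r)
  out <- tidyr::expand_grid(param1 = params, param2 = params) |>
    dplyr::filter(match(.data$param1, params) < match(.data$param2, params))
  out$r <- x$r[cbind(out$param1, out$param2)]
  out$p_value <- x$p[cbind(out$param1, out$param2)]
  out$n <- x$n[cbind(out$param1, out$param2)]
  out$label <- x$label[cbind(out$param1, out$param2)]
  out$stars <- x$stars[cbind(out$param1, out$param2)]
  out
}
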