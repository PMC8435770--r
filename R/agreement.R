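#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two methods measured on the same individuals,
#' combining precision (Pearson correlation) with accuracy (penalty for mean
#' and variance shifts):
#' \deqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' with n-denominator moment estimators, per Lin's original definition. The
#' standard deviation is the usual first-order asymptotic expression for the
#' CCC estimator.
#'
#' @param x,y Paired numeric vectors (no missing values), length >= 3.
#' @return List with `est`, `sd`, `n`.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("paired values must not be missing", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 <= 0 || sy2 <= 0) {
    stop("CCC undefined: zero variance in x or y", call. = FALSE)
  }
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^0.25
  v <- ccc_asymptotic_var(ccc, r, u, n)
  # perfect agreement sits on the parameter boundary where the asymptotic
  # variance degenerates to zero (tiny negative by rounding)
  list(est = ccc, sd = if (is.na(v)) NA_real_ else sqrt(max(0, v)), n = n)
}

# Lin (1989) asymptotic variance of the CCC estimator.
ccc_asymptotic_var <- function(ccc, r, u, n) {
  if (abs(r) < .Machine$double.eps) return(NA_real_)
  ((1 - r^2) * ccc^2 * (1 - ccc^2) / r^2 +
     2 * ccc^3 * (1 - ccc) * u^2 / r -
     ccc^4 * u^4 / (2 * r^2)) / (n - 2)
}

#' CCC from summary statistics
#'
#' Evaluates Lin's concordance correlation coefficient from means, standard
#' deviations and the Pearson correlation (as printed in summary tables).
#'
#' @param mean_x,mean_y,sd_x,sd_y,r Summary statistics of the two methods.
#' @param n Optional sample size; when given, the asymptotic SD is returned
#'   too.
#' @return List with `est` (and `sd` when `n` is supplied).
#' @export
ccc_from_moments <- function(mean_x, mean_y, sd_x, sd_y, r, n = NULL) {
  if (sd_x <= 0 || sd_y <= 0) stop("CCC undefined: zero SD", call. = FALSE)
  ccc <- 2 * r * sd_x * sd_y / (sd_x^2 + sd_y^2 + (mean_x - mean_y)^2)
  out <- list(est = ccc)
  if (!is.null(n)) {
    u <- (mean_x - mean_y) / sqrt(sd_x * sd_y)
    v <- ccc_asymptotic_var(ccc, r, u, n)
    out$sd <- if (is.na(v)) NA_real_ else sqrt(max(0, v))
  }
  out
}

#' Root mean square error of prediction
#'
#' \eqn{\sqrt{\mathrm{mean}((x_i - y_i)^2)}}: the average difference to be
#' expected between a proxy measurement and the reference value. The
#' "prediction" label reflects use of a proxy calibrated on independent data.
#'
#' @param x,y Paired numeric vectors.
#' @return Nonnegative scalar.
#' @export
rmsep <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  sqrt(mean((x - y)^2))
}

#' Coefficient of variation, percent
#'
#' `100 * sd / mean` with the n-1 denominator SD.
#' @param values Numeric vector with nonzero mean.
#' @return Scalar percent.
#' @export
cv_percent <- function(values) {
  m <- mean(values)
  if (abs(m) < .Machine$double.eps) stop("CV undefined: zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' CV from summary statistics
#' @param mean,sd Printed mean and SD.
#' @return Scalar percent.
#' @export
cv_from_moments <- function(mean, sd) {
  if (abs(mean) < .Machine$double.eps) stop("CV undefined: zero mean", call. = FALSE)
  100 * sd / mean
}

#' Paired t-test with relative bias
#'
#' Two-sided paired t-test on x - y plus the relative bias
#' `100 * (mean(x) - mean(y)) / mean(x)` (percent underestimation of the
#' reference by the proxy when positive). If the differences have zero
#' variance with a nonzero mean the test statistic degenerates; the p-value
#' is reported as 0 by convention and flagged.
#'
#' @param x Reference values.
#' @param y Proxy values (paired with `x`).
#' @return List with `t`, `df`, `p_value`, `mean_diff`, `relative_bias`,
#'   `degenerate`.
#' @export
paired_bias <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  rel_bias <- 100 * (mean(x) - mean(y)) / mean(x)
  if (stats::sd(d) < .Machine$double.eps * max(1, abs(mean(d)))) {
    degen <- TRUE
    if (abs(mean(d)) > 0) {
      t_stat <- Inf; p <- 0
    } else {
      t_stat <- 0; p <- 1
    }
    return(list(t = t_stat, df = length(d) - 1, p_value = p,
                mean_diff = mean(d), relative_bias = rel_bias,
                degenerate = degen))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), relative_bias = rel_bias,
       degenerate = FALSE)
}

#' Test a correlation against a hypothesised value (Fisher z)
#'
#' Two-sided test of H0: rho = rho0 via the Fisher z-transformation. The
#' boundary rho0 = 1 is degenerate: any sample r < 1 is evidence against it
#' and the p-value is 0 (with r = 1 giving p = 1).
#'
#' @param r Sample correlation.
#' @param n Sample size (> 3).
#' @param rho0 Hypothesised correlation.
#' @return List with `z`, `p_value`.
#' @export
fisher_r_test <- function(r, n, rho0 = 0) {
  stopifnot(n > 3, abs(r) <= 1, abs(rho0) <= 1)
  if (abs(rho0) == 1) {
    p <- if (isTRUE(all.equal(r, rho0))) 1 else 0
    return(list(z = if (p == 0) Inf else 0, p_value = p))
  }
  z <- (atanh(r) - atanh(rho0)) * sqrt(n - 3)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Proportional variance reduction from averaging repeated records
#'
#' For a trait with repeatability `t2`, averaging `n` records reduces the
#' total phenotypic variance by
#' \deqn{100 - 100 (1 + t^2 (n - 1)) / n}
#' percent: low-repeatability traits gain proportionally more from extra
#' records.
#'
#' @param t2 Repeatability in \[0, 1\].
#' @param n Number of records averaged (>= 1).
#' @return Percent reduction.
#' @export
averaging_variance_reduction <- function(t2, n) {
  stopifnot(t2 >= 0, t2 <= 1, n >= 1)
  100 - 100 * (1 + t2 * (n - 1)) / n
}

#' Regression of the method difference on body weight
#'
#' Diagnostic for size-dependent bias: ordinary least squares of (x - y) on
#' body weight. A non-significant slope supports size-independence of the
#' proxy's bias.
#'
#' @param x,y Paired reference and proxy values.
#' @param bodyweight Aligned body weights.
#' @return List with `slope`, `se`, `p_value`, `n`.
#' @export
bias_vs_bodyweight <- function(x, y, bodyweight) {
  stopifnot(length(x) == length(y), length(x) == length(bodyweight))
  if (stats::sd(bodyweight) < .Machine$double.eps) {
    stop("slope undefined: constant body weight", call. = FALSE)
  }
  fit <- stats::lm((x - y) ~ bodyweight)
  res_var <- stats::var(stats::residuals(fit))
  if (res_var < 1e-12 * max(stats::var(x - y), 1)) {
    # zero-residual fit: the slope is exact, no sampling test applies
    return(list(slope = unname(stats::coef(fit)[2]), se = NA_real_,
                p_value = NA_real_, n = length(x)))
  }
  cf <- summary(fit)$coefficients
  list(slope = cf["bodyweight", "Estimate"], se = cf["bodyweight", "Std. Error"],
       p_value = cf["bodyweight", "Pr(>|t|)"], n = length(x))
}

#' Method-agreement report per group and pooled
#'
#' Computes, for each group and for the pooled sample, the descriptive and
#' agreement statistics used to benchmark a proxy method against a reference
#' method: n, means, SDs, CVs, ranges, Pearson r with its large-sample SE,
#' Lin's CCC with its asymptotic SD, RMSEP, the paired t-test and the
#' relative bias. Descriptive SDs and CVs use the conventional n-1
#' denominator; the CCC uses n-denominator moments per its definition.
#'
#' @param data Long-format phenotype table (columns id, cohort, trait,
#'   value), or a wide data frame when `wide = TRUE`.
#' @param reference,proxy Trait names to compare (must be single-record
#'   traits; use [make_trait_views()] to derive a per-fish proxy mean).
#' @param group Optional grouping column (default `"cohort"`); `NULL` pools
#'   only.
#' @return A tibble of class `agreement_report`, one row per group plus a
#'   `"pooled"` row.
#' @export
agreement_report <- function(data, reference = "lipid_ref",
                             proxy = "lipid_ds_mean", group = "cohort") {
  wide <- pair_traits(data, reference, proxy, group)
  groups <- if (is.null(group)) character(0) else sort(unique(wide$group))
  blocks <- lapply(groups, function(g) {
    agreement_row(wide[wide$group == g, ], g)
  })
  pooled <- agreement_row(wide, "pooled")
  out <- dplyr::bind_rows(c(blocks, list(pooled)))
  class(out) <- c("agreement_report", class(out))
  out
}

# Align one record per id for each trait; inner join on ids with both.
pair_traits <- function(data, reference, proxy, group) {
  stopifnot(all(c("id", "trait", "value") %in% names(data)))
  pick <- function(tr) {
    d <- data[data$trait == tr & !is.na(data$value), , drop = FALSE]
    if (anyDuplicated(d$id)) {
      stop("trait '", tr, "' has multiple records per individual; ",
           "derive a per-fish summary first (see make_trait_views)",
           call. = FALSE)
    }
    d
  }
  dx <- pick(reference)
  dy <- pick(proxy)
  ids <- intersect(dx$id, dy$id)
  if (length(ids) < 2) stop("fewer than 2 individuals with both traits", call. = FALSE)
  x <- dx$value[match(ids, dx$id)]
  y <- dy$value[match(ids, dy$id)]
  g <- if (is.null(group)) rep("all", length(ids)) else {
    as.character(dx[[group]][match(ids, dx$id)])
  }
  tibble::tibble(id = ids, x = x, y = y, group = g)
}

agreement_row <- function(d, label) {
  n <- nrow(d)
  x <- d$x; y <- d$y
  r <- suppressWarnings(stats::cor(x, y))
  cc <- tryCatch(lin_ccc(x, y),
                 error = function(e) list(est = NA_real_, sd = NA_real_))
  pb <- paired_bias(x, y)
  tibble::tibble(
    group = label, n = n,
    mean_x = mean(x), sd_x = stats::sd(x), cv_x = cv_percent(x),
    min_x = min(x), max_x = max(x),
    mean_y = mean(y), sd_y = stats::sd(y), cv_y = cv_percent(y),
    min_y = min(y), max_y = max(y),
    pearson_r = r, pearson_se = sqrt((1 - r^2) / (n - 2)),
    ccc = cc$est, ccc_sd = cc$sd,
    rmsep = rmsep(x, y),
    t = pb$t, p_value = pb$p_value, relative_bias = pb$relative_bias
  )
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("Method agreement (reference vs proxy)\n")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    cat(sprintf("  %s (n=%d): ref %.1f +/- %.1f (CV %.1f%%), proxy %.1f +/- %.1f (CV %.1f%%)\n",
                r$group, r$n, r$mean_x, r$sd_x, r$cv_x, r$mean_y, r$sd_y, r$cv_y))
    cat(sprintf("      R=%.2f +/- %.2f, CCC=%.2f +/- %.2f, RMSEP=%.2f, bias=%.1f%% (p=%.2g)\n",
                r$pearson_r, r$pearson_se, r$ccc, r$ccc_sd, r$rmsep,
                r$relative_bias, r$p_value))
  }
  invisible(x)
}
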