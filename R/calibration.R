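# Log-linear calibration of residual enzymatic activity on ddG:
# ln(activity%) = a + b * ddG, fitted by unweighted least squares with the
# ddG fit cap applied to the x-values, plus rank correlation and
# permutation-based significance, prediction with the 100% activity cap,
# and pathogenicity/severity calls.

#' Fit the ddG -> activity calibration
#'
#' Fits `ln(activity_pct) = a + b * min(ddg, ddg_fit_cap)` by unweighted
#' least squares. The cap (default 5.5 kcal/mol) clamps the x-values before
#' fitting only: activities saturate near 0% beyond it, so larger predicted
#' destabilizations carry no extra information about the line. Predictions
#' from the fitted model use raw ddG values (see [predict_activity()]).
#' Pairs with non-positive activity are excluded with a message (their
#' logarithm is undefined). Diagnostics: R-squared of the fit, Spearman rank
#' correlation (midrank ties) of the capped pairs, and two-sided permutation
#' p-values for both the rank correlation and the regression slope
#' (exhaustive enumeration up to n = 7, label-permutation sampling above).
#'
#' @param pairs Tibble with numeric columns `ddg` and `activity_pct`
#'   (percent of wild type), optionally `template` and `substrate`.
#' @param cfg An [analysis_config()]; supplies `ddg_fit_cap`.
#' @param n_perm Number of sampled permutations when n > 7.
#' @param seed Seed for the permutation sampling.
#' @return An object of class `ddg_calibration`.
#' @export
fit_calibration <- function(pairs, cfg = analysis_config(),
                            n_perm = 10000L, seed = 1L) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("ddg", "activity_pct") %in% names(pairs)))
  usable <- is.finite(pairs$ddg) & is.finite(pairs$activity_pct) &
    pairs$activity_pct > 0
  if (any(!usable)) {
    inform(sprintf("excluding %d pair(s) with non-positive or missing activity (ln undefined)",
                   sum(!usable)))
  }
  pairs <- pairs[usable, , drop = FALSE]
  if (nrow(pairs) < 3) {
    abort("fit_calibration needs at least 3 usable pairs",
          class = "cyp21act_fit_error")
  }
  x <- pmin(pairs$ddg, cfg$ddg_fit_cap)
  y <- log(pairs$activity_pct)
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (!is.na(b) && b >= 0) {
    warn(sprintf("fitted slope is non-negative (%.3f): activity does not decrease with destabilization",
                 b))
  }
  rho <- spearman_rho(x, y)
  p_rho <- permutation_pvalue(x, y, statistic = "rho", n_perm = n_perm,
                              seed = derive_seed(seed, "perm_rho"))
  p_slope <- permutation_pvalue(x, y, statistic = "slope", n_perm = n_perm,
                                seed = derive_seed(seed, "perm_slope"))
  structure(list(
    intercept_a = a,
    slope_b = b,
    ddg_fit_cap = cfg$ddg_fit_cap,
    n_pairs = nrow(pairs),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    spearman_rho = as.numeric(rho),
    p_spearman = p_rho,
    p_slope = p_slope,
    n_perm = n_perm,
    seed = seed,
    template = unique(col_or(pairs, "template", NA_character_)),
    substrate = unique(col_or(pairs, "substrate", NA_character_)),
    data = tibble(ddg_raw = pairs$ddg, ddg_capped = x,
                  activity_pct = pairs$activity_pct),
    cfg = cfg
  ), class = "ddg_calibration")
}

#' @export
print.ddg_calibration <- function(x, ...) {
  cat(sprintf("ddG -> activity calibration (n = %d, cap %.1f kcal/mol)\n",
              x$n_pairs, x$ddg_fit_cap))
  cat(sprintf("  ln(activity%%) = %.4f %+.4f * ddG\n", x$intercept_a, x$slope_b))
  cat(sprintf("  R^2 = %.3f; Spearman rho = %.3f (p = %.4g); slope p = %.4g\n",
              x$r_squared, x$spearman_rho, x$p_spearman, x$p_slope))
  invisible(x)
}

#' Spearman rank correlation with midrank ties
#'
#' Pearson correlation of the midranks of `x` and `y`. When either variable
#' is constant the correlation is undefined: the result is `NA` carrying the
#' attribute `degenerate = TRUE`, not a number.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A single numeric value in \[-1, 1\], or degenerate `NA`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# All permutations of 1..n (n <= 7 in exhaustive mode; 7! = 5040 rows).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    out[r + seq_len(rows), 1] <- k
    out[r + seq_len(rows), -1] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + rows
  }
  out
}

perm_statistic <- function(x, y, statistic) {
  if (statistic == "rho") as.numeric(spearman_rho(x, y))
  else {
    xc <- x - mean(x)
    sum(xc * y) / sum(xc^2)
  }
}

#' Permutation p-value for the rank correlation or regression slope
#'
#' Two-sided label-permutation test of association between `x` and `y`. For
#' n <= 7 all n! permutations are enumerated and the p-value is the exact
#' fraction of permutations whose absolute statistic reaches the observed
#' one. For larger n, `n_perm` random permutations are drawn under `seed`
#' and the add-one estimator `p = (1 + k) / (1 + n_perm)` is used. A
#' constant `x` or `y` makes the statistic degenerate and the p-value 1.
#'
#' @param x,y Numeric vectors (at least 3 values).
#' @param statistic `"rho"` (Spearman) or `"slope"` (least-squares slope).
#' @param n_perm Number of sampled permutations in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @param mode `"auto"` (exhaustive up to n = 7, sampled above),
#'   `"exhaustive"`, or `"sampled"`.
#' @return A single p-value in (0, 1].
#' @export
permutation_pvalue <- function(x, y, statistic = c("rho", "slope"),
                               n_perm = 10000L, seed = 1L,
                               mode = c("auto", "exhaustive", "sampled")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y), length(x) >= 3, n_perm >= 1)
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(1.0)
  obs <- abs(perm_statistic(x, y, statistic))
  tol <- 1e-12
  exhaustive <- switch(mode, auto = n <= 7L, exhaustive = TRUE,
                       sampled = FALSE)
  if (exhaustive) {
    if (n > 8L) {
      abort("exhaustive enumeration is limited to n <= 8",
            class = "cyp21act_domain_error")
    }
    perms <- permutations_of(n)
    stats <- apply(perms, 1L, function(p) abs(perm_statistic(x, y[p], statistic)))
    return(sum(stats >= obs - tol) / nrow(perms))
  }
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(perm_statistic(x, sample(y), statistic)) >= obs - tol
    }, logical(1)))
  })
  (1 + hits) / (1 + n_perm)
}

#' Predict residual activity from ddG
#'
#' Evaluates `exp(a + b * ddg)` for the fitted model. Predictions use the
#' raw ddG (the fit cap applies to fitting only, so distinct activities are
#' still reported for strongly destabilized variants). Predictions above
#' the 100% activity cap are clamped and flagged (displayed as `">=100"`).
#'
#' @param model A `ddg_calibration`.
#' @param ddg_mean Numeric vector of mean ddG values (kcal/mol).
#' @return Tibble: `ddg_mean`, `activity_pred_pct`, `capped`, `display`.
#' @export
predict_activity <- function(model, ddg_mean) {
  if (!inherits(model, "ddg_calibration")) {
    abort("predict_activity requires a fitted ddg_calibration",
          class = "cyp21act_state_error")
  }
  raw <- exp(model$intercept_a + model$slope_b * ddg_mean)
  cap <- model$cfg$activity_cap
  capped <- raw > cap
  act <- pmin(raw, cap)
  tibble(ddg_mean = ddg_mean,
         activity_pred_pct = act,
         capped = capped,
         display = format_activity_display(act, capped))
}

#' @export
predict.ddg_calibration <- function(object, ddg_mean, ...) {
  predict_activity(object, ddg_mean)
}

#' Severity band edges
#'
#' Residual-activity bands mapping predictions to expected clinical forms:
#' below 1% salt-wasting-like (SW), 1-5% simple-virilizing-like (SV),
#' 10-60% non-classical-like (NC), above 75% normal-like; the gaps
#' (5-10, 60-75) are indeterminate.
#'
#' @param sw_max,sv_max,nc_min,nc_max,normal_min Band edges in percent.
#' @return Named list of edges.
#' @export
severity_bands <- function(sw_max = 1, sv_max = 5, nc_min = 10, nc_max = 60,
                           normal_min = 75) {
  list(sw_max = sw_max, sv_max = sv_max, nc_min = nc_min, nc_max = nc_max,
       normal_min = normal_min)
}

#' Pathogenicity and severity calls
#'
#' A prediction is non-pathogenic iff the predicted activity exceeds the
#' non-pathogenic threshold (default 75%); otherwise it is a pathogenic
#' candidate. The severity band follows [severity_bands()].
#'
#' @param predictions Tibble from [predict_activity()] (or any tibble with
#'   `activity_pred_pct`).
#' @param cfg An [analysis_config()].
#' @param bands A [severity_bands()].
#' @return The input with `pathogenicity_call` and `severity_band` added.
#' @export
call_pathogenicity <- function(predictions, cfg = analysis_config(),
                               bands = severity_bands()) {
  predictions <- as_tibble(predictions)
  a <- predictions$activity_pred_pct
  thr <- cfg$nonpathogenic_activity_threshold
  predictions$pathogenicity_call <- ifelse(a > thr, "non_pathogenic",
                                           "pathogenic_candidate")
  predictions$severity_band <- dplyr::case_when(
    a > bands$normal_min ~ "normal_like",
    a < bands$sw_max ~ "SW_like",
    a <= bands$sv_max ~ "SV_like",
    a >= bands$nc_min & a <= bands$nc_max ~ "NC_like",
    TRUE ~ "indeterminate"
  )
  predictions
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted calibration
#'
#' @param x A `ddg_calibration`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`intercept`, `slope`) and
#'   the permutation p-value of the slope.
#' @export
tidy.ddg_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept_a, x$slope_b),
         p_value = c(NA_real_, x$p_slope))
}

#' One-row model summary of a fitted calibration
#'
#' @param x A `ddg_calibration`.
#' @param ... Unused.
#' @return One-row tibble of fit diagnostics.
#' @export
glance.ddg_calibration <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, r_squared = x$r_squared,
         spearman_rho = x$spearman_rho, p_spearman = x$p_spearman,
         p_slope = x$p_slope, ddg_fit_cap = x$ddg_fit_cap)
}

#' Plot a fitted calibration
#'
#' Scatter of ln(activity%) against capped ddG with the fitted line.
#'
#' @param object A `ddg_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddg_calibration <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ddg_capped,
                                   y = log(.data$activity_pct))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept_a,
                         slope = object$slope_b, linetype = 2) +
    ggplot2::labs(
      x = expression(paste(Delta * Delta * G, " (kcal/mol, capped)")),
      y = "ln(residual activity %)",
      title = sprintf("ln(activity) = %.2f %+.2f ddG (R² = %.2f)",
                      object$intercept_a, object$slope_b, object$r_squared))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
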