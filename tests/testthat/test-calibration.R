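test_that("noiseless pairs recover the generating line exactly", {
  ddg <- seq(-1, 5, by = 0.5)
  pairs <- tibble::tibble(ddg = ddg, activity_pct = exp(5.35 - 1.53 * ddg))
  m <- fit_calibration(pairs, n_perm = 50)
  expect_equal(m$intercept_a, 5.35, tolerance = 1e-10)
  expect_equal(m$slope_b, -1.53, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  # fit/predict round trip is exact on noiseless data (all ddg below cap)
  back <- predict_activity(m, ddg)
  uncapped <- !back$capped
  expect_equal(back$activity_pred_pct[uncapped],
               pairs$activity_pct[uncapped], tolerance = 1e-9)
})

test_that("least squares matches the closed-form oracle on random pairs", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    ddg <- runif(n, -2, 5)
    act <- exp(5 - 1.5 * ddg + rnorm(n, 0, 0.4))
    m <- suppressWarnings(fit_calibration(
      tibble::tibble(ddg = ddg, activity_pct = act), n_perm = 10))
    o <- oracle_lsq(ddg, log(act))
    expect_equal(m$intercept_a, unname(o["intercept"]), tolerance = 1e-10)
    expect_equal(m$slope_b, unname(o["slope"]), tolerance = 1e-10)
  }
})

test_that("the ddG cap clamps fitting but not prediction", {
  base <- tibble::tibble(ddg = c(0, 1, 2, 3, 4, 5),
                         activity_pct = exp(5.35 - 1.53 * c(0, 1, 2, 3, 4, 5)))
  with_out <- dplyr::bind_rows(base,
                               tibble::tibble(ddg = 9.84, activity_pct = 0.03))
  m <- fit_calibration(with_out, n_perm = 10)
  expect_equal(max(m$data$ddg_capped), 5.5)   # 9.84 fitted as 5.5
  # prediction uses the raw ddG: distinct activities beyond the cap
  p <- predict_activity(m, c(7.55, 12.31))
  expect_lt(p$activity_pred_pct[2], p$activity_pred_pct[1])
})

test_that("non-positive activities are excluded and small sets refuse to fit", {
  pairs <- tibble::tibble(ddg = c(1, 2, 3, 4), activity_pct = c(10, 5, 0, 2))
  expect_message(m <- fit_calibration(pairs, n_perm = 10), "non-positive")
  expect_equal(m$n_pairs, 3)
  expect_error(
    fit_calibration(tibble::tibble(ddg = 1:2, activity_pct = c(10, 5)),
                    n_perm = 10),
    class = "cyp21act_fit_error")
})

test_that("Spearman with midrank ties equals brute force up to n = 8", {
  expect_equal(spearman_rho(1:5, c(10, 8, 6, 4, 2)), -1)
  set.seed(33)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    x <- sample(1:4, n, replace = TRUE) + runif(n, 0, 0.01)
    y <- sample(1:3, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(as.numeric(spearman_rho(x, y)), oracle_spearman(x, y),
                 tolerance = 1e-12)
    expect_equal(as.numeric(spearman_rho(x, y)),
                 suppressWarnings(stats::cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
  deg <- spearman_rho(rep(1, 4), 1:4)
  expect_true(is.na(deg))
  expect_true(attr(deg, "degenerate"))
})

test_that("exhaustive permutation p-values equal independent enumeration", {
  # perfectly monotone n = 3: only the two extreme orderings reach |rho| = 1
  expect_equal(permutation_pvalue(1:3, c(3, 2, 1), "rho"), 2 / 6)
  expect_equal(permutation_pvalue(1:3, c(1, 2, 3), "rho"), 2 / 6)
  expect_equal(permutation_pvalue(1:4, rep(2, 4), "rho"), 1.0)  # constant y

  set.seed(55)
  for (stat in c("rho", "slope")) {
    for (i in 1:5) {
      n <- sample(4:6, 1)
      x <- runif(n); y <- runif(n)
      perms <- oracle_permutations(n)
      stat_fn <- function(xx, yy) {
        if (stat == "rho") oracle_spearman(xx, yy)
        else oracle_lsq(xx, yy)[["slope"]]
      }
      obs <- abs(stat_fn(x, y))
      ref <- mean(apply(perms, 1, function(p) abs(stat_fn(x, y[p])) >= obs - 1e-12))
      expect_equal(permutation_pvalue(x, y, stat), ref, tolerance = 1e-12)
    }
  }
})

test_that("sampled permutation mode is deterministic and near the exact value", {
  x <- c(0.2, 1.1, 2.3, 3.0, 4.8, 5.5, 6.1, 7.9)  # n = 8 forces sampling
  y <- c(5.0, 4.2, 4.9, 3.1, 2.5, 2.8, 1.2, 0.7)
  p1 <- permutation_pvalue(x, y, "rho", n_perm = 2000, seed = 7)
  p2 <- permutation_pvalue(x, y, "rho", n_perm = 2000, seed = 7)
  expect_identical(p1, p2)
  # at n = 6, sampling converges to the exhaustive value within Monte-Carlo
  # error (3 SE of a binomial proportion)
  x6 <- x[1:6]; y6 <- y[1:6]
  exact <- permutation_pvalue(x6, y6, "rho")
  sampled <- permutation_pvalue(x6, y6, "rho", n_perm = 5000, seed = 11,
                                mode = "sampled")
  se <- sqrt(exact * (1 - exact) / 5000)
  expect_lt(abs(sampled - exact), 3 * se + 1 / 5000)
})

test_that("predictions cap at 100%, display correctly, and decrease with ddG", {
  pairs <- table2_fit_set()
  m <- fit_calibration(pairs, n_perm = 50)
  p <- predict_activity(m, c(-2.16, 0, 1, 3, 6, 10))
  expect_true(p$capped[1])
  expect_equal(p$activity_pred_pct[1], 100)
  expect_identical(p$display[1], "≥100")
  expect_true(all(diff(p$activity_pred_pct) <= 0))  # monotone for b < 0
  expect_error(predict_activity(list(), 1), class = "cyp21act_state_error")
})

test_that("pathogenicity and severity bands follow the stated edges", {
  pred <- tibble::tibble(activity_pred_pct = c(76, 75, 22.5, 0.1, 3, 7, 65, 100))
  out <- call_pathogenicity(pred)
  expect_equal(out$pathogenicity_call,
               c("non_pathogenic", "pathogenic_candidate",
                 "pathogenic_candidate", "pathogenic_candidate",
                 "pathogenic_candidate", "pathogenic_candidate",
                 "pathogenic_candidate", "non_pathogenic"))
  expect_equal(out$severity_band,
               c("normal_like", "indeterminate", "NC_like", "SW_like",
                 "SV_like", "indeterminate", "indeterminate", "normal_like"))
})

test_that("parameter recovery improves with sample size under fixed seeds", {
  errs <- sapply(c(10, 100, 1000), function(n) {
    spec <- synthetic_spec(a_true = 5.35, b_true = -1.53, noise_sd = 0.35,
                           n_pairs = n, ddg_range = c(-2, 5.4), seed = 101L)
    pairs <- generate_calibration_pairs(spec)
    pairs <- pairs[!pairs$capped, ]
    m <- fit_calibration(pairs, n_perm = 10)
    abs(m$slope_b - (-1.53))
  })
  expect_lt(errs[3], 0.05)
  expect_lt(errs[3], errs[1])
})

test_that("tidy, glance and autoplot expose the fit", {
  m <- fit_calibration(table2_fit_set(), n_perm = 50)
  td <- tidy(m)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(m)
  expect_equal(gl$n_pairs, 19)
  expect_gt(gl$r_squared, 0.99)
  expect_lt(gl$spearman_rho, -0.9)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
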