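# Standardization, collinearity screen, thinning, GLMM fitting, model
# averaging, R-squared, cross-validation and the metric comparisons.

test_that("standardize centres, scales and records the transformation", {
  d <- tibble::tibble(a = c(1, 2, 3), b = c(10, 20, 60))
  s <- standardize(d, c("a", "b"))
  expect_equal(s$a, c(-1, 0, 1))
  scl <- attr(s, "scaling")
  expect_equal(scl$mean[scl$column == "a"], 2)
  expect_equal(scl$sd[scl$column == "a"], 1)
  # idempotent on already standardized data
  s2 <- standardize(s, c("a", "b"))
  expect_equal(s2$a, s$a, tolerance = 1e-12)
  expect_error(standardize(tibble::tibble(a = rep(5, 4)), "a"), "constant")
})

test_that("collinearity screen drops the lower-priority member", {
  set.seed(81)
  n <- 2000
  dT <- stats::rnorm(n)
  d <- tibble::tibble(
    tailwind = stats::rnorm(n),
    delta_T = dT,
    cloud = 0.9 * dT + stats::rnorm(n, 0, 0.55) # r ~ 0.85
  )
  out <- collinearity_screen(d, c("tailwind", "delta_T", "cloud"),
                             priority = c("tailwind", "delta_T", "cloud"))
  expect_equal(out$dropped$dropped, "cloud")
  expect_equal(out$dropped$against, "delta_T")
  expect_gt(abs(out$dropped$r), 0.6)
  expect_setequal(out$retained, c("tailwind", "delta_T"))
})

test_that("independent columns are all retained and duplicates collapse", {
  set.seed(82)
  d <- tibble::tibble(a = stats::rnorm(5000), b = stats::rnorm(5000),
                      c = stats::rnorm(5000))
  expect_equal(collinearity_screen(d)$retained, c("a", "b", "c"))
  d$dup <- d$a
  out <- collinearity_screen(d, c("a", "b", "c", "dup"))
  expect_equal(out$dropped$dropped, "dup")
})

test_that("30-s thinning keeps only complete blocks and averages covariates", {
  lt <- tibble::tibble(
    bird_id = "b1", segment_id = rep(c("s1", "s2"), c(150, 29)),
    behavior = rep(c("soaring", "flapping"), c(150, 29)),
    timestamp = as.POSIXct("2020-10-01", tz = "UTC") + 1:179,
    w = as.numeric(1:179)
  )
  th <- thin_30s(lt, "w")
  expect_equal(nrow(th), 5) # 150/30 blocks; the 29-fix burst yields none
  expect_equal(th$w[1], mean(1:30))
  expect_equal(unique(th$behavior), "soaring")
  const <- lt
  const$w <- 7
  expect_equal(unique(thin_30s(const, "w")$w), 7)
})

test_that("thinning lowers lag-1 residual autocorrelation", {
  cfg <- sim_config(seed = 83, n_birds = 3, n_bursts = 12, burst_s = 120,
                    pattern_mix = c(flapping = 0.5, gliding = 0,
                                    spiral = 0.5, staircase = 0, s_shape = 0))
  lt <- simulate_flight(cfg)
  set.seed(83)
  lt$segment_id <- lt$burst_id
  lt$behavior <- lt$true_behavior
  # a weather covariate correlated with the response at burst level
  lt$tw <- ifelse(lt$behavior == "soaring", 0.8, -0.8) + stats::rnorm(nrow(lt))
  lag1 <- function(d) {
    # the full-rate fit may separate: that is the pathology thinning treats
    fit <- suppressWarnings(
      stats::glm(I(behavior == "soaring") ~ tw, data = d,
                 family = stats::binomial())
    )
    r <- stats::residuals(fit, type = "pearson")
    stats::cor(r[-1], r[-length(r)])
  }
  th <- thin_30s(lt, "tw")
  expect_lt(abs(lag1(th)), abs(lag1(lt)))
})

test_that("a random-intercept model with zero RE matches plain logistic", {
  set.seed(84)
  n <- 1500
  d <- tibble::tibble(bird_id = rep(sprintf("b%d", 1:10), each = n / 10),
                      x = stats::rnorm(n))
  d$y <- stats::rbinom(n, 1, stats::plogis(0.8 * d$x))
  spec <- model_spec("y", "x", random_intercept = TRUE)
  fit <- fit_glmm(spec, d)
  ref <- stats::glm(y ~ x, data = d, family = stats::binomial())
  expect_equal(fit$coefs$estimate[fit$coefs$term == "x"],
               unname(stats::coef(ref)["x"]), tolerance = 0.01 / 0.8)
  expect_true(fit$converged)
})

test_that("fitting refuses non-binary responses and single groups", {
  d <- tibble::tibble(bird_id = "b1", x = stats::rnorm(60),
                      y = stats::rnorm(60))
  expect_error(fit_glmm(model_spec("y", "x"), d), "binary")
  d$y <- stats::rbinom(60, 1, 0.5)
  expect_error(fit_glmm(model_spec("y", "x"), d), "groups")
})

test_that("subset generation respects marginality", {
  subsets <- soarflight:::.term_subsets(c("a", "b", "a:b"))
  has <- function(s) any(vapply(subsets, function(x) setequal(x, s), TRUE))
  expect_true(has(character(0)))
  expect_true(has(c("a", "b", "a:b")))
  expect_false(any(vapply(subsets, function(x) "a:b" %in% x && !("a" %in% x),
                          TRUE)))
  # poly terms carry their variable for marginality purposes
  subsets2 <- soarflight:::.term_subsets(c("poly(a, 2)", "b", "a:b"))
  expect_true(any(vapply(subsets2,
                         function(x) "a:b" %in% x && "poly(a, 2)" %in% x,
                         TRUE)))
  expect_false(any(vapply(subsets2, function(x) "a:b" %in% x && !("b" %in% x),
                          TRUE)))
})

test_that("a single-term spec averages to its own model", {
  set.seed(85)
  d <- tibble::tibble(bird_id = rep(sprintf("b%d", 1:6), each = 100),
                      x = stats::rnorm(600))
  d$y <- stats::rbinom(600, 1, stats::plogis(1.5 * d$x))
  spec <- model_spec("y", "x")
  res <- suppressMessages(dredge_average(spec, d, accuracy = FALSE))
  if (res$n_models_averaged == 1) {
    single <- fit_glmm(spec, d)
    expect_equal(res$coefs$estimate[res$coefs$term == "x"],
                 single$coefs$estimate[single$coefs$term == "x"],
                 tolerance = 1e-9)
  }
  # Akaike weights sum to one
  expect_equal(sum(res$weights), 1, tolerance = 1e-12)
})

test_that("averaged estimates reproduce hand-computed Akaike weights", {
  set.seed(86)
  d <- tibble::tibble(bird_id = rep(sprintf("b%d", 1:6), each = 120),
                      x = stats::rnorm(720), z = stats::rnorm(720))
  d$y <- stats::rbinom(720, 1, stats::plogis(0.9 * d$x))
  spec <- model_spec("y", c("x", "z"))
  res <- suppressMessages(dredge_average(spec, d, delta = 20, accuracy = FALSE))
  # oracle: refit every subset directly and average by hand
  fits <- list(
    fit_glmm(spec, d, character(0)), fit_glmm(spec, d, "x"),
    fit_glmm(spec, d, "z"), fit_glmm(spec, d, c("x", "z"))
  )
  aics <- vapply(fits, function(f) f$aic, 0)
  w <- exp(-(aics - min(aics)) / 2)
  w <- w / sum(w)
  est_x <- sum(w * vapply(fits, function(f) {
    i <- match("x", f$coefs$term)
    if (is.na(i)) 0 else f$coefs$estimate[i]
  }, 0))
  expect_equal(res$coefs$estimate[res$coefs$term == "x"], est_x,
               tolerance = 1e-9)
})

test_that("strong effects keep all true terms in the best model", {
  hits <- 0
  for (r in 1:10) {
    cfg <- sim_config(seed = 900 + r, n_birds = 8, re_sd = 0.3,
                      soaring_logit = c(0, 1.51, 1.65, 1.97, 1.65))
    d <- simulate_soaring_dataset(cfg, 1200)
    spec <- model_spec("soaring", c("tailwind", "sidewind", "delta_T",
                                    "tailwind:delta_T"))
    res <- suppressMessages(dredge_average(spec, d, accuracy = FALSE))
    hits <- hits + (length(res$best$terms) == 4)
  }
  expect_gte(hits, 9)
})

test_that("variance-partition R2 behaves at its anchors", {
  set.seed(87)
  n <- 2000
  d <- tibble::tibble(bird_id = rep(sprintf("b%d", 1:10), each = n / 10),
                      x = stats::rnorm(n))
  d$y0 <- stats::rbinom(n, 1, 0.5)
  spec0 <- model_spec("y0", "x", random_intercept = FALSE)
  r0 <- nakagawa_r2(fit_glmm(spec0, d))
  expect_lt(r0[["r2_marginal"]], 0.01)
  expect_equal(r0[["r2_marginal"]], r0[["r2_conditional"]])
  # R2m grows with effect size on the same covariates
  d$y1 <- stats::rbinom(n, 1, stats::plogis(0.5 * d$x))
  d$y2 <- stats::rbinom(n, 1, stats::plogis(2.0 * d$x))
  r1 <- nakagawa_r2(fit_glmm(model_spec("y1", "x", random_intercept = FALSE), d))
  r2 <- nakagawa_r2(fit_glmm(model_spec("y2", "x", random_intercept = FALSE), d))
  expect_gt(r2[["r2_marginal"]], r1[["r2_marginal"]])
  # with a real random effect, conditional exceeds marginal
  re <- stats::rnorm(10, 0, 1.2)[as.integer(factor(d$bird_id))]
  d$y3 <- stats::rbinom(n, 1, stats::plogis(0.8 * d$x + re))
  r3 <- nakagawa_r2(fit_glmm(model_spec("y3", "x"), d))
  expect_gt(r3[["r2_conditional"]], r3[["r2_marginal"]])
})

test_that("k-fold accuracy hits its separable and chance anchors", {
  set.seed(88)
  n <- 800
  d <- tibble::tibble(bird_id = rep(sprintf("b%d", 1:8), each = n / 8),
                      x = stats::rnorm(n))
  d$sep <- as.integer(d$x > 0)
  spec <- model_spec("sep", "x", random_intercept = FALSE)
  expect_gt(suppressWarnings(kfold_accuracy(spec, d)), 0.95)
  d$noise <- stats::rbinom(n, 1, 0.5)
  acc <- kfold_accuracy(model_spec("noise", "x", random_intercept = FALSE), d)
  expect_lt(abs(acc - 0.5), 0.07)
  expect_length(attr(acc, "per_fold"), 10)
})

test_that("metric comparison reports U, p and normality checks", {
  set.seed(89)
  a <- stats::rnorm(100)
  out_same <- compare_metrics(a, a)
  expect_equal(out_same$u, 100 * 100 / 2)
  expect_gt(out_same$p, 0.9)
  b <- stats::rnorm(100, mean = 2) # shift of 2 SD
  out_shift <- compare_metrics(a, b)
  expect_lt(out_shift$p, 0.05)
  expect_s3_class(out_shift$shapiro_a, "htest")
  chi <- compare_counts(matrix(c(50, 50, 50, 50), 2))
  expect_equal(unname(chi$statistic), 0)
})
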