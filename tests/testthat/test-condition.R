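test_that("length-weight fit recovers exact allometric data and validates input", {
  L <- c(60, 70, 80, 90)
  fish <- data.frame(length_mm = L, weight_g = 2e-5 * L^3)
  fit <- suppressWarnings(fit_length_weight(fish))  # perfect fit warns
  expect_equal(fit$b, 3, tolerance = 1e-10)
  expect_equal(fit$a, 2e-5, tolerance = 1e-10)
  expect_equal(fit$sigma, 0, tolerance = 1e-8)

  expect_error(fit_length_weight(fish[1:2, ]), "at least 3")
  expect_error(fit_length_weight(
    data.frame(length_mm = c(80, 80, 80), weight_g = c(10, 11, 12))),
    "singular")
  expect_error(fit_length_weight(
    data.frame(length_mm = c(-1, 70, 80), weight_g = c(10, 11, 12))),
    "positive")
})

test_that("refitting on its own fitted values reproduces the coefficients", {
  ds <- simulate_dataset(small_config(seed = 21, fish_per_reef = 10))
  fish <- ds$fish[ds$fish$species == "browser", ]
  fit1 <- fit_length_weight(fish)
  fish2 <- data.frame(length_mm = fish$length_mm,
                      weight_g = fit1$a * fish$length_mm^fit1$b)
  fit2 <- suppressWarnings(fit_length_weight(fish2))
  expect_equal(fit2$log_a, fit1$log_a, tolerance = 1e-9)
  expect_equal(fit2$b, fit1$b, tolerance = 1e-9)
})

test_that("K_n is 1 on the curve, scales correctly, and has geometric mean 1", {
  L <- c(60, 70, 80, 90)
  fish <- data.frame(length_mm = L, weight_g = 2e-5 * L^3)
  fit <- suppressWarnings(fit_length_weight(fish))
  kn <- compute_kn(fish, fit)
  expect_equal(kn$kn, rep(1, 4), tolerance = 1e-10)

  # worked example: W = 11.264 g at L = 80 mm against aL^b = 10.24 g
  one <- data.frame(length_mm = 80, weight_g = 11.264)
  expect_equal(compute_kn(one, fit)$kn, 1.1, tolerance = 1e-9)

  ds <- simulate_dataset(small_config(seed = 31, fish_per_reef = 10))
  noisy <- ds$fish[ds$fish$species == "predator", ]
  fitn <- fit_length_weight(noisy)
  knn <- compute_kn(noisy, fitn)
  expect_equal(exp(mean(log(knn$kn))), 1, tolerance = 1e-9)

  # rescaling every weight by c rescales a by c and leaves K_n unchanged
  scaled <- noisy
  scaled$weight_g <- noisy$weight_g * 1000
  fits <- fit_length_weight(scaled)
  expect_equal(fits$a, fitn$a * 1000, tolerance = 1e-9)
  expect_equal(compute_kn(scaled, fits)$kn, knn$kn, tolerance = 1e-9)
})

test_that("identical condition slopes across zones give zero slope contrasts", {
  set.seed(2)
  logl <- log(runif(90, 60, 100))
  cond <- data.frame(kn = 1 + 0.1 * (logl - mean(logl)),
                     log_length = logl,
                     zone = rep(c("a", "b", "c"), each = 30))
  fit <- suppressWarnings(fit_condition_interaction(cond))  # zero residual variance
  expect_equal(fit$contrasts$estimate, rep(0, 3), tolerance = 1e-9)
  expect_equal(fit$slopes$slope, rep(0.1, 3), tolerance = 1e-9)
  # partial eta squared is the sequential SS share against the residual
  with_res <- fit$anova[fit$anova$term != "Residuals", ]
  ss_res <- fit$anova$sum_sq[fit$anova$term == "Residuals"]
  expect_equal(with_res$partial_eta_sq,
               with_res$sum_sq / (with_res$sum_sq + ss_res))
  expect_true(all(with_res$partial_eta_sq >= 0 &
                    with_res$partial_eta_sq <= 1))
})

test_that("opposed generating slopes are detected, in line with a permutation oracle", {
  set.seed(7)
  n <- 60
  logl <- log(runif(2 * n, 60, 100))
  zone <- rep(c("low", "high"), each = n)
  slope <- ifelse(zone == "low", -0.2, 0.2)
  cond <- data.frame(kn = 1 + slope * (logl - mean(logl)) +
                       rnorm(2 * n, 0, 0.02),
                     log_length = logl, zone = zone)
  fit <- fit_condition_interaction(cond)
  p_inter <- fit$anova$p[fit$anova$term == "log_length:zone"]
  expect_lt(p_inter, 0.001)

  # permutation oracle: shuffle zone labels, compare interaction F
  f_obs <- fit$anova$f[fit$anova$term == "log_length:zone"]
  f_perm <- replicate(199, {
    cp <- cond
    cp$zone <- sample(cp$zone)
    a <- anova(lm(kn ~ log_length * zone, data = cp))
    a[["F value"]][3]
  })
  expect_lte((1 + sum(f_perm >= f_obs)) / 200, 0.005)
})

test_that("Tukey adjustment never reports smaller p than the unadjusted contrast", {
  ds <- simulate_dataset(small_config(seed = 13, fish_per_reef = 12))
  fish <- ds$fish[ds$fish$species == "browser", ]
  kn <- compute_kn(fish, fit_length_weight(fish))
  fit <- fit_condition_interaction(kn)
  expect_true(all(fit$contrasts$p_tukey >= fit$contrasts$p_unadjusted - 1e-12))
})

test_that("lnVR is antisymmetric, zero against itself, and exact on a known ratio", {
  set.seed(11)
  x <- rnorm(40)
  self <- lnvr_pairwise(c(x, x), rep(c("g1", "g2"), each = 40),
                        B = 300, seed = 1)
  expect_equal(self$lnvr, 0, tolerance = 1e-12)
  expect_false(self$significant)
  expect_true(self$ci_lower <= 0 && self$ci_upper >= 0)

  y <- rnorm(40, sd = 2)
  ab <- lnvr_pairwise(c(x, y), rep(c("g1", "g2"), each = 40),
                      B = 200, seed = 2)
  ba <- lnvr_pairwise(c(y, x), rep(c("g2", "g1"), each = 40),
                      B = 200, seed = 2)
  # antisymmetry of the point estimate under group order swap
  expect_equal(ab$lnvr, -ba$lnvr, tolerance = 1e-12)

  # SD ratio exactly e with equal n: corrections cancel, estimate = 1
  z <- exp(1) * x
  ratio <- lnvr_pairwise(c(z, x), rep(c("g1", "g2"), each = 40),
                         B = 200, seed = 3)
  expect_equal(ratio$lnvr, 1, tolerance = 1e-12)

  expect_error(lnvr_pairwise(c(rep(1, 10), rnorm(10)),
                             rep(c("g1", "g2"), each = 10), B = 10),
               "zero variance")
  # the fold-change reading used when quoting lnVR contrasts
  expect_equal(lnvr_fold(c(-1.38, 0.96)), exp(c(1.38, 0.96)))
})

test_that("lnVR bias correction is applied unless disabled", {
  set.seed(5)
  x <- rnorm(10); y <- rnorm(25, sd = 1.5)
  vals <- c(x, y); grp <- rep(c("g1", "g2"), c(10, 25))
  with_c <- lnvr_pairwise(vals, grp, B = 50, seed = 1)
  without <- lnvr_pairwise(vals, grp, B = 50, seed = 1,
                           bias_correction = FALSE)
  expect_equal(with_c$lnvr - without$lnvr,
               1 / (2 * 9) - 1 / (2 * 24), tolerance = 1e-12)
})
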