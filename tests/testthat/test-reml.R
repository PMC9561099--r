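test_that("MME-factorised likelihood equals the dense projection form", {
  set.seed(21)
  for (r in 1:10) {
    inst <- random_instance(n_rec = sample(20:50, 1),
                            n_terms = sample(0:3, 1))
    l_mme <- restricted_loglik(inst$design, inst$components, inst$ped,
                               method = "mme")
    l_dense <- restricted_loglik(inst$design, inst$components, inst$ped,
                                 method = "dense")
    expect_lt(abs(l_mme - l_dense), 1e-8)
  }
})

test_that("with no random terms the likelihood is the OLS REML likelihood", {
  set.seed(22)
  d <- tibble::tibble(g = sample(c("a", "b"), 25, TRUE),
                      y = stats::rnorm(25))
  ds <- build_design(d, model_spec("y", fixed = list("g")))
  s2 <- 1.3
  ll <- restricted_loglik(ds, list(sigma2_e = s2))
  X <- ds$X; yv <- ds$y; n <- length(yv); p <- ncol(X)
  rss <- sum(qr.resid(qr(X), yv)^2)
  ll_ols <- -0.5 * ((n - p) * (log(2 * pi) + log(s2)) + rss / s2 +
                      as.numeric(determinant(crossprod(X))$modulus))
  expect_equal(ll, ll_ols, tolerance = 1e-10)
})

test_that("identity kinship with one record per animal matches lme4", {
  # independent cross-check of the one-way random-intercept REML likelihood
  set.seed(23)
  d <- tibble::tibble(animal = rep(sprintf("a%02d", 1:15), times = 3),
                      y = rep(stats::rnorm(15, sd = 0.7), times = 3) +
                        stats::rnorm(45))
  ds <- build_design(d, model_spec("y", random = list(
    animal = list(group_by = "animal", covariance = "identity"))))
  fit <- fit_univariate(ds)
  lf <- lme4::lmer(y ~ 1 + (1 | animal), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$varcomp$estimate[fit$varcomp$component == "animal"],
               vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$varcomp$estimate[fit$varcomp$component == "sigma2_e"],
               vc$vcov[2], tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("balanced identity-kinship design equals ANOVA expected mean squares", {
  set.seed(24)
  na <- 40; m <- 5
  d <- tibble::tibble(
    animal = rep(sprintf("a%02d", 1:na), each = m),
    y = rep(stats::rnorm(na, sd = sqrt(0.4)), each = m) +
      stats::rnorm(na * m, sd = sqrt(0.8)))
  ds <- build_design(d, model_spec("y", random = list(
    animal = list(group_by = "animal", covariance = "identity"))))
  fit <- fit_univariate(ds)
  msw <- sum((d$y - stats::ave(d$y, d$animal))^2) / (na * (m - 1))
  ybar_i <- tapply(d$y, d$animal, mean)
  msb <- m * sum((ybar_i - mean(d$y))^2) / (na - 1)
  expect_lt(abs(fit$varcomp$estimate[1] - (msb - msw) / m), 1e-6)
  expect_lt(abs(fit$varcomp$estimate[2] - msw), 1e-6)
  expect_true(fit$converged)
})

test_that("identity-kinship animal plus PE on the same animals is refused", {
  set.seed(25)
  d <- tibble::tibble(animal = rep(sprintf("a%02d", 1:10), each = 3),
                      y = stats::rnorm(30))
  spec <- model_spec("y", random = list(
    animal = list(group_by = "animal", covariance = "identity"),
    pe = list(group_by = "animal", covariance = "identity")))
  ds <- build_design(d, spec)
  expect_error(fit_univariate(ds), "identifiable")
})

test_that("rescaling the response rescales components but not ratios", {
  cfg <- recovery_config(seed = 31, n_sires = 30)
  fl <- simulate_flock(cfg)
  spec <- chamber_recovery_spec()
  d1 <- build_design(fl$chamber, spec, fl$pedigree)
  f1 <- fit_univariate(d1, fl$pedigree)
  ch2 <- dplyr::mutate(fl$chamber, ch4_g = 10 * ch4_g)
  d2 <- build_design(ch2, spec, fl$pedigree)
  f2 <- fit_univariate(d2, fl$pedigree)
  expect_equal(f2$varcomp$estimate, 100 * f1$varcomp$estimate,
               tolerance = 1e-4)
  r1 <- f1$ratios; r2 <- f2$ratios
  expect_equal(r2$estimate[r2$quantity == "h2"],
               r1$estimate[r1$quantity == "h2"], tolerance = 1e-4)
  expect_equal(r2$estimate[r2$quantity == "repeatability"],
               r1$estimate[r1$quantity == "repeatability"], tolerance = 1e-4)
})

test_that("restricted likelihood is non-decreasing over iterations", {
  cfg <- recovery_config(seed = 32, n_sires = 25)
  fl <- simulate_flock(cfg)
  ds <- build_design(fl$chamber, chamber_recovery_spec(), fl$pedigree)
  fit <- fit_univariate(ds, fl$pedigree)
  tol <- 1e-9 * (1 + abs(fit$loglik)) # line-search acceptance slack
  expect_true(all(diff(fit$trace) >= -tol))
  expect_lt(max(abs(fit$gradient)),
            max(1e-4, 1e-8 * (1 + abs(fit$loglik))))
})

test_that("zero genetic variance keeps h2 near the lower boundary", {
  cfg <- recovery_config(seed = 33, n_sires = 100, h2 = 0,
                         repeatability = 0.3)
  fl <- simulate_flock(cfg)
  ds <- build_design(fl$chamber, chamber_recovery_spec(), fl$pedigree)
  fit <- fit_univariate(ds, fl$pedigree)
  h2 <- fit$ratios$estimate[fit$ratios$quantity == "h2"]
  expect_lt(h2, 0.05)
})

test_that("a variance pinned at the floor raises the boundary flag", {
  # animal means are exactly equal, so the between-animal variance is 0
  d <- tibble::tibble(animal = rep(sprintf("a%02d", 1:10), each = 2),
                      y = rep(c(1, -1), times = 10))
  ds <- build_design(d, model_spec("y", random = list(
    animal = list(group_by = "animal", covariance = "identity"))))
  fit <- fit_univariate(ds)
  expect_true(fit$boundary)
  expect_lt(fit$varcomp$estimate[1], 1e-6)
})

test_that("Wald significance flags match hand-computed z tests", {
  expect_true(significance(0.31, 0.09))   # z = 3.44
  expect_false(significance(0.13, 0.15))  # z = 0.87
  expect_false(significance(0, 1))
  expect_true(significance(-0.21, 0.09))  # sign does not matter
  expect_error(significance(0.1, 0))
})

test_that("a trait paired with itself has unit correlations", {
  cfg <- recovery_config(seed = 34, n_sires = 30)
  fl <- simulate_flock(cfg)
  ch <- dplyr::mutate(fl$chamber,
                      record = paste(animal, ryr, round, day, sep = "_"),
                      y2 = ch4_g)
  spec1 <- chamber_recovery_spec()
  spec2 <- model_spec("y2", fixed = spec1$fixed, random = spec1$random)
  d1 <- build_design(ch, spec1, fl$pedigree)
  d2 <- build_design(ch, spec2, fl$pedigree)
  fit <- fit_bivariate(d1, d2, fl$pedigree, residual_cov = "paired",
                       pair_key = "record",
                       control = reml_control(max_iter = 25))
  # exact duplication makes the joint model degenerate in the limit; the
  # log-Cholesky parameterisation approaches the unit-correlation boundary
  r <- fit$ratios
  expect_gt(r$estimate[r$quantity == "r_g"], 0.9)
  expect_gt(r$estimate[r$quantity == "r_p"], 0.8)
  expect_gt(r$estimate[r$quantity == "r_e"], 0.99)
})

test_that("tidy, glance and autoplot expose the fit", {
  set.seed(35)
  d <- tibble::tibble(animal = rep(sprintf("a%02d", 1:12), each = 3),
                      y = stats::rnorm(36))
  ds <- build_design(d, model_spec("y", random = list(
    animal = list(group_by = "animal", covariance = "identity"))))
  fit <- fit_univariate(ds)
  td <- tidy(fit)
  expect_true(all(c("component", "estimate", "std.error", "type") %in%
                    names(td)))
  expect_true("h2" %in% td$component)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(is.logical(gl$converged))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, which = "trace"), "ggplot")
})
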