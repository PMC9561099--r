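test_that("simulated pedigrees have the requested family structure", {
  cfg <- sim_config(seed = 41, n_sires = 20, progeny_per_sire = 10,
                    ewes_per_sire = 0)
  ped <- simulate_pedigree(cfg)
  expect_equal(sum(ped$role == "chamber", na.rm = TRUE), 200L)
  kids <- ped[ped$role %in% "chamber", ]
  expect_true(all(!is.na(kids$sire)))
  expect_equal(length(unique(kids$sire)), 20L)

  # founders only
  cfg0 <- sim_config(seed = 41, n_sires = 5, progeny_per_sire = 0,
                     ewes_per_sire = 0)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 5L)
  expect_true(all(is.na(ped0$sire)))

  # all-female offspring leave no sire candidates for a second generation
  expect_error(simulate_pedigree(
    sim_config(seed = 1, n_sires = 5, progeny_per_sire = 0,
               ewes_per_sire = 2, n_generations = 2)), "impossible design")
})

test_that("a fixed seed reproduces the whole flock exactly", {
  cfg <- sim_config(seed = 42, n_sires = 6, progeny_per_sire = 4,
                    ewes_per_sire = 4)
  f1 <- simulate_flock(cfg)
  f2 <- simulate_flock(cfg)
  expect_identical(f1$pedigree, f2$pedigree)
  expect_identical(f1$chamber, f2$chamber)
  expect_identical(f1$maternal, f2$maternal)
  expect_identical(f1$egg, f2$egg)
})

test_that("breeding values reproduce the A (x) G covariance", {
  set.seed(43)
  G <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  # founders: empirical covariance ~ G
  founders <- as_pedigree(tibble::tibble(
    animal = sprintf("f%05d", 1:10000), sire = "0", dam = "0"))
  a <- simulate_breeding_values(founders, G, seed = 43)
  expect_lt(max(abs(stats::cov(a) - G)), 0.05)

  # parent-offspring covariance ~ 0.5 G
  n <- 10000
  po <- as_pedigree(tibble::tibble(
    animal = c(sprintf("p%05d", 1:n), sprintf("o%05d", 1:n)),
    sire = c(rep("0", n), sprintf("p%05d", 1:n)),
    dam = "0"))
  b <- simulate_breeding_values(po, matrix(1), seed = 44)
  expect_equal(stats::cov(b[1:n, 1], b[n + 1:n, 1]), 0.5, tolerance = 0.05)
  # zero genetic covariance means identical zero values
  z <- simulate_breeding_values(founders, matrix(0), seed = 45)
  expect_true(all(z == 0))
  expect_error(simulate_breeding_values(founders, matrix(-1)), "definite")
})

test_that("records carry the configured variance and filter violations", {
  cfg <- sim_config(seed = 46, n_sires = 50, progeny_per_sire = 10,
                    ewes_per_sire = 0, refusal_rate = 0.1,
                    seal_break_rate = 0,
                    cg_sd = c(chamber = 0, round = 0, maternal = 0),
                    chamber_trait = list(name = "y", mean = 24,
                                         sigma2_a = 2.32,
                                         sigma2_pe = c(wgpe = 0.43,
                                                       agpe = 1.0),
                                         sigma2_e = 5.19, beta_bdev = 0))
  fl <- simulate_flock(cfg)
  nrec <- nrow(fl$chamber) # 500 animals x 4 days
  expect_equal(nrec, 2000L)
  kept <- filter_chamber_records(fl$chamber)
  nrej <- nrow(rejection_log(kept))
  expect_lt(abs(nrej - 0.1 * nrec), 3 * sqrt(nrec * 0.1 * 0.9))
  # total phenotypic variance ~ sum of generating components
  expect_equal(stats::var(fl$chamber$ch4_g), 2.32 + 0.43 + 1.0 + 5.19,
               tolerance = 0.6)
  # all variances zero, no fixed spread -> constant records
  cfg0 <- sim_config(seed = 47, n_sires = 5, progeny_per_sire = 4,
                     ewes_per_sire = 0, refusal_rate = 0,
                     seal_break_rate = 0,
                     cg_sd = c(chamber = 0, round = 0, maternal = 0),
                     chamber_trait = list(name = "y", mean = 24,
                                          sigma2_a = 0, sigma2_pe = c(agpe = 0),
                                          sigma2_e = 0, beta_bdev = 0))
  fl0 <- simulate_flock(cfg0)
  expect_equal(stats::var(fl0$chamber$ch4_g), 0)
})

test_that("egg counts exercise the offset-log transform", {
  cfg <- sim_config(seed = 48, n_sires = 30, progeny_per_sire = 10,
                    ewes_per_sire = 0)
  fl <- simulate_flock(cfg)
  expect_true(all(fl$egg$fec_raw >= 0))
  tr <- transform_egg_count(fl$egg$fec_raw)
  expect_equal(mean(tr), 6.07, tolerance = 0.2)
})

test_that("phenotype tables round-trip through CSV exactly", {
  cfg <- sim_config(seed = 49, n_sires = 5, progeny_per_sire = 4,
                    ewes_per_sire = 3)
  fl <- simulate_flock(cfg)
  for (tab in list(fl$chamber, fl$maternal, fl$egg)) {
    f <- tempfile(fileext = ".csv")
    write_phenotypes(tab, f)
    back <- read_phenotypes(f)
    expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 0)
  }
})

test_that("divergent selection labels sire lines", {
  cfg <- sim_config(seed = 50, n_sires = 10, progeny_per_sire = 4,
                    ewes_per_sire = 0, divergent_selection = TRUE)
  fl <- simulate_flock(cfg)
  expect_setequal(unique(stats::na.omit(fl$pedigree$line)), c("low", "high"))
  sires <- fl$pedigree[fl$pedigree$role == "sire", ]
  expect_equal(sum(sires$line == "low"), 5L)
})
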