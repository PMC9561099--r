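test_that("contemporary groups are observed combinations, ordered", {
  d <- tibble::tibble(sex = c("M", "F", "M"), byr = c("2010", "2011", "2010"),
                      flk = c("2638", "3633", "2638"))
  expect_equal(levels(build_contemporary_groups(d, "sex")), c("F", "M"))
  full <- tidyr::expand_grid(byr = c("2010", "2011"),
                             flk = c("2638", "3633"))
  expect_equal(nlevels(build_contemporary_groups(full, c("byr", "flk"))), 4L)
  # only observed combinations get a level
  part <- tibble::tibble(a = c("1", "1", "2", "2", "1"),
                         b = c("x", "y", "x", "x", "x"),
                         c = c("u", "u", "v", "u", "v"))
  expect_equal(nlevels(build_contemporary_groups(part, c("a", "b", "c"))),
               length(unique(paste(part$a, part$b, part$c))))
  # missing component flags the record
  miss <- tibble::tibble(a = c("1", NA), b = c("x", "y"))
  expect_true(is.na(build_contemporary_groups(miss, c("a", "b"))[2]))
})

test_that("fixed design is reduced to full column rank", {
  set.seed(3)
  d <- tibble::tibble(f = sample(c("a", "b", "c"), 30, TRUE),
                      y = stats::rnorm(30))
  ds <- build_design(d, model_spec("y", fixed = list("f")))
  expect_equal(ds$p, 3L) # intercept + 3 dummies - 1 aliased
  expect_equal(qr(ds$X)$rank, 3L)
})

test_that("random incidence is one-hot and pedigree-linked", {
  ped <- as_pedigree(tibble::tibble(animal = c("u", "v"), sire = "0",
                                    dam = "0"))
  d <- tibble::tibble(animal = c("u", "u", "v", "v"),
                      round = c("1", "2", "1", "2"),
                      y = stats::rnorm(4))
  spec <- model_spec("y", random = list(
    animal = list(group_by = "animal", covariance = "pedigree"),
    wgpe = list(group_by = c("animal", "round"), covariance = "identity")))
  ds <- build_design(d, spec, ped)
  Za <- ds$random$animal$Z
  expect_equal(dim(Za), c(4L, 2L))
  expect_true(all(Matrix::rowSums(Za) == 1))
  expect_equal(as.numeric(Matrix::colSums(Za)), c(2, 2))
  # 2 rounds x 2 animals -> 4 within-round PE levels, one per record here
  expect_equal(ncol(ds$random$wgpe$Z), 4L)
  expect_true(all(Matrix::rowSums(ds$random$wgpe$Z) == 1))

  expect_error(build_design(d, model_spec("y", random = list(
    animal = list(group_by = "animal", covariance = "pedigree"))),
    pedigree = NULL), "pedigree")
  expect_error(build_design(d, model_spec("y", fixed = list("absent"))),
               "absent")
})

test_that("record order only permutes design rows", {
  set.seed(11)
  d <- tibble::tibble(f = sample(c("a", "b", "c", "d"), 50, TRUE),
                      g = sample(c("p", "q"), 50, TRUE),
                      y = stats::rnorm(50))
  spec <- model_spec("y", fixed = list("f", "g"))
  d1 <- build_design(d, spec)
  prm <- sample.int(50)
  d2 <- build_design(d[prm, ], spec)
  expect_identical(colnames(d1$X), colnames(d2$X))
  expect_equal(unname(d1$X[prm, ]), unname(d2$X))
})

test_that("fixed-effect screening reports sequential F tests", {
  set.seed(5)
  n <- 120
  d <- tibble::tibble(
    f = factor(sample(c("a", "b", "c"), n, TRUE)),
    x = stats::rnorm(n),
    noise = sample(paste0("l", 1:4), n, TRUE)
  )
  d$y <- ifelse(d$f == "a", 1, ifelse(d$f == "b", 3, 7)) # f determines y
  # exact fit: anova warns about the perfect residual, which is the point
  scr <- suppressWarnings(screen_fixed_effects(d, "y", list("f", "x", "noise")))
  expect_equal(scr$term, c("f", "x", "noise"))
  expect_lt(scr$p_value[1], 1e-12) # factor fully determines the response
  expect_true(scr$keep[1])
  expect_lt(scr$sumsq[2], 1e-16)   # zero-slope covariate explains nothing

  # saturated model is refused
  dd <- tibble::tibble(f = factor(c("a", "b")), y = c(1, 2))
  expect_error(screen_fixed_effects(dd, "y", list("f")), "aturated")
})

test_that("screening holds its type-I error rate on pure noise", {
  set.seed(8)
  nrep <- 400
  rejections <- 0L
  for (r in seq_len(nrep)) {
    d <- tibble::tibble(f = sample(paste0("l", 1:5), 200, TRUE),
                        y = stats::rnorm(200))
    scr <- screen_fixed_effects(d, "y", list("f"))
    rejections <- rejections + scr$keep[1]
  }
  rate <- rejections / nrep
  expect_lt(abs(rate - 0.05), 0.03) # ~3 binomial SDs at 400 replicates
})

test_that("model specs round-trip through YAML", {
  spec <- model_spec("ch4_gd",
                     fixed = list("byr.flk.sex", c("ryr", "lot")),
                     covariates = "bdev",
                     random = list(
                       animal = list(group_by = "animal",
                                     covariance = "pedigree"),
                       wgpe = list(group_by = c("animal", "round"),
                                   covariance = "identity")))
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(response = "ch4_gd",
                        fixed = list("byr.flk.sex", "ryr.lot"),
                        covariates = list("bdev"),
                        random = list(
                          animal = list(group_by = list("animal"),
                                        covariance = "pedigree"),
                          wgpe = list(group_by = list("animal", "round"),
                                      covariance = "identity"))), f)
  spec2 <- read_model_spec(f)
  expect_equal(spec2$response, spec$response)
  expect_equal(spec2$fixed, spec$fixed)
  expect_equal(names(spec2$random), names(spec$random))
  expect_error(model_spec("y", random = list(
    bad = list(group_by = c("a", "b"), covariance = "pedigree"))),
    "single animal-id")
})
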