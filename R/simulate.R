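#' Configuration for the synthetic flock generator
#'
#' Describes a multi-flock sire-family study: a pedigree of sire families
#' (chamber-measured progeny plus ewe relatives), respiration-chamber
#' records (2 rounds x 2 days per animal by default), repeated adult-ewe
#' records at ages 2--6, egg-count records, and the true generating
#' parameters of every trait under the repeatability animal model. The
#' defaults are a desk-scale (one-tenth) version of the study design: 22
#' sires with 10 chamber progeny each and ~800 ewe relatives, with
#' generating variance components back-solved from the reported phenotypic
#' SD, heritability and repeatability of each trait.
#'
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param n_sires Number of sires (default 22).
#' @param progeny_per_sire Chamber-measured progeny per sire (default 10).
#' @param ewes_per_sire Adult-ewe daughters per sire carrying maternal
#'   records (default 36, giving ~800 relatives).
#' @param n_generations Offspring generations (default 1; with more, later
#'   sires are drawn from earlier male progeny).
#' @param dams_known If `FALSE`, dams are recorded as unknown founders.
#' @param rounds,days_per_round Chamber measurement layout (2 x 2).
#' @param ages Ages (years) at which ewes can carry adult records.
#' @param present_rate Probability an ewe is recorded at a given age.
#' @param n_byr,n_flk,n_rflk,n_mob Numbers of birth years, birth flocks,
#'   recording flocks and grazing mobs.
#' @param lot_size,group_size Chamber lot (96) and sub-group (24) sizes.
#' @param seal_break_rate,refusal_rate Rates at which chamber days get a
#'   broken seal or a feed refusal below the 95% filter.
#' @param cg_sd Named contemporary-group effect SDs (`chamber`, `round`,
#'   `maternal`), in trait units; unreported in the field, so
#'   order-of-magnitude choices.
#' @param chamber_trait,maternal_trait,egg_trait Per-trait generating
#'   parameter lists: `mean`, `sigma2_a`, named `sigma2_pe` vector,
#'   `sigma2_e` (for the egg trait, parameters on the log scale).
#' @param genetic_cor 3x3 genetic correlation matrix across the chamber,
#'   maternal and egg latent traits (must be PSD).
#' @param divergent_selection If `TRUE`, sires are labelled into high/low
#'   lines by their simulated chamber-trait breeding value.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = NULL,
                       n_sires = 22L, progeny_per_sire = 10L,
                       ewes_per_sire = 36L, n_generations = 1L,
                       dams_known = TRUE,
                       rounds = 2L, days_per_round = 2L,
                       ages = 2:6, present_rate = 0.8,
                       n_byr = 2L, n_flk = 2L, n_rflk = 2L, n_mob = 2L,
                       lot_size = 96L, group_size = 24L,
                       seal_break_rate = 0.02, refusal_rate = 0.05,
                       cg_sd = c(chamber = 1.5, round = 1.0, maternal = 3.0),
                       chamber_trait = list(
                         name = "ch4_gd", mean = 24.0,
                         sigma2_a = 2.32443,
                         sigma2_pe = c(wgpe = 0.43, agpe = 1.00041),
                         sigma2_e = 5.18526,
                         beta_bdev = 0.02),
                       maternal_trait = list(
                         name = "lw_mate", mean = 67.3,
                         sigma2_a = 22.524,
                         sigma2_pe = c(pe = 10.113),
                         sigma2_e = 13.331),
                       egg_trait = list(
                         name = "fec", mean_log = 6.07,
                         sigma2_a = 0.206, sigma2_e = 0.418),
                       genetic_cor = NULL,
                       divergent_selection = FALSE) {
  if (is.null(genetic_cor)) {
    genetic_cor <- matrix(c(1, 0.3, 0.18,
                            0.3, 1, 0.10,
                            0.18, 0.10, 1), 3, 3)
  }
  stopifnot(progeny_per_sire >= 0, n_sires >= 1,
            all(eigen(genetic_cor, symmetric = TRUE,
                      only.values = TRUE)$values > -1e-10))
  cfg <- list(seed = seed, n_sires = as.integer(n_sires),
              progeny_per_sire = as.integer(progeny_per_sire),
              ewes_per_sire = as.integer(ewes_per_sire),
              n_generations = as.integer(n_generations),
              dams_known = dams_known,
              rounds = as.integer(rounds),
              days_per_round = as.integer(days_per_round),
              ages = ages, present_rate = present_rate,
              n_byr = n_byr, n_flk = n_flk, n_rflk = n_rflk, n_mob = n_mob,
              lot_size = lot_size, group_size = group_size,
              seal_break_rate = seal_break_rate, refusal_rate = refusal_rate,
              cg_sd = cg_sd,
              chamber_trait = chamber_trait,
              maternal_trait = maternal_trait,
              egg_trait = egg_trait,
              genetic_cor = genetic_cor,
              divergent_selection = divergent_selection)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a sire-family pedigree
#'
#' Generates founder sires and dams plus offspring cohorts: chamber-measured
#' progeny (`role == "chamber"`, both sexes) and adult-ewe relatives
#' (`role == "ewe"`, daughters of the same sires). Birth year and birth
#' flock are assigned per offspring. With `dams_known = FALSE` dams are
#' unknown, giving pure half-sib families.
#'
#' @param config A [sim_config()].
#' @return A [as_pedigree()] tibble with extra columns `role`, `sex`,
#'   `byr`, `flk` (and `line` under divergent selection).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  per_sire <- config$progeny_per_sire + config$ewes_per_sire
  rows <- list()
  gen_sires <- sprintf("S%04d", seq_len(config$n_sires))
  rows$sires <- tibble::tibble(animal = gen_sires, sire = NA_character_,
                               dam = NA_character_, role = "sire",
                               sex = "M", byr = NA_integer_, flk = NA_integer_)
  did <- 0L
  for (g in seq_len(config$n_generations)) {
    off <- list()
    for (s in gen_sires) {
      nn <- per_sire
      if (nn == 0) next
      dams <- if (config$dams_known) {
        d <- sprintf("D%05d", did + seq_len(nn))
        did <- did + nn
        d
      } else rep(NA_character_, nn)
      ids <- sprintf("G%d%s_%02d", g, s, seq_len(nn))
      role <- c(rep("chamber", config$progeny_per_sire),
                rep("ewe", config$ewes_per_sire))
      sex <- ifelse(role == "ewe", "F",
                    sample(c("M", "F"), nn, replace = TRUE))
      off[[s]] <- tibble::tibble(
        animal = ids, sire = s, dam = dams, role = role, sex = sex,
        byr = sample.int(config$n_byr, nn, replace = TRUE) + 2009L,
        flk = sample.int(config$n_flk, nn, replace = TRUE))
    }
    off <- dplyr::bind_rows(off)
    if (config$dams_known && nrow(off)) {
      rows[[paste0("dams", g)]] <- tibble::tibble(
        animal = stats::na.omit(off$dam), sire = NA_character_,
        dam = NA_character_, role = "dam", sex = "F",
        byr = NA_integer_, flk = NA_integer_)
    }
    rows[[paste0("gen", g)]] <- off
    if (g < config$n_generations) {
      males <- off$animal[off$sex == "M"]
      if (length(males) < config$n_sires) {
        stop("impossible design: not enough male candidates (",
             length(males), ") for ", config$n_sires, " sires")
      }
      gen_sires <- sample(males, config$n_sires)
    }
  }
  tab <- dplyr::bind_rows(rows)
  extras <- tab[c("animal", "role", "sex", "byr", "flk")]
  ped <- as_pedigree(tab[c("animal", "sire", "dam")], unknown = "0")
  j <- match(ped$animal, extras$animal)
  ped$role <- extras$role[j]
  ped$sex <- extras$sex[j]
  ped$byr <- extras$byr[j]
  ped$flk <- extras$flk[j]
  ped
}

#' Simulate breeding values down a pedigree
#'
#' Founders draw from `N(0, G)`; every non-founder is the mean of its
#' parents' values plus an independent Mendelian-sampling deviation with
#' covariance `d_i * G`, where `d_i` is the Mendelian sampling variance
#' given parental inbreeding (an unknown parent contributes 0 with `d_i`
#' inflated accordingly). The joint covariance of the result is exactly
#' `A (x) G`.
#'
#' @param ped Sorted pedigree.
#' @param G Genetic covariance matrix across traits (PSD), or a scalar
#'   variance for one trait.
#' @param seed Optional RNG seed.
#' @return Numeric matrix, one row per animal (rownames = ids), one column
#'   per trait.
#' @export
simulate_breeding_values <- function(ped, G, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!is.null(seed)) set.seed(seed)
  G <- as.matrix(G)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) stop("G is not positive semi-definite")
  nt <- ncol(G)
  n <- nrow(ped)
  ## PSD-safe square root
  eg <- eigen(G, symmetric = TRUE)
  Gh <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nt) %*% t(eg$vectors)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  dvec <- mendelian_variances(ped)
  Z <- matrix(stats::rnorm(n * nt), n, nt) %*% Gh
  a <- matrix(0, n, nt, dimnames = list(ped$animal, colnames(G)))
  founder <- is.na(si) & is.na(di)
  a[founder, ] <- Z[founder, , drop = FALSE]
  for (i in which(!founder)) {
    pa <- numeric(nt)
    if (!is.na(si[i])) pa <- pa + 0.5 * a[si[i], ]
    if (!is.na(di[i])) pa <- pa + 0.5 * a[di[i], ]
    a[i, ] <- pa + sqrt(dvec[i]) * Z[i, ]
  }
  a
}

.pe_var <- function(v, nm) if (!is.null(v) && nm %in% names(v)) v[[nm]] else 0

.draw_effects <- function(levels, sd) {
  stats::setNames(stats::rnorm(length(levels), 0, sd), levels)
}

.round_half <- function(x, lo = 1, hi = 5) pmin(pmax(round(x * 2) / 2, lo), hi)

#' Simulate phenotype tables for a synthetic flock
#'
#' Builds chamber, adult-ewe and egg-count record tables whose statistical
#' structure is exactly the repeatability animal model: record =
#' contemporary-group effect + covariate effect + breeding value + one draw
#' per permanent-environment level (within-round `wgpe`, across-round/year
#' `agpe`) + residual per day. Chamber gas and intake columns are
#' back-composed from the simulated g/day trait so that
#' [derive_methane_traits()] reproduces it; seal breaks and feed refusals
#' are injected at the configured rates for filter testing; egg counts are
#' generated on the count scale so the `log(x + 50)` transform is
#' exercised.
#'
#' @param ped Pedigree from [simulate_pedigree()] (needs `role` etc.).
#' @param config The [sim_config()] used to build `ped`.
#' @param values Optional pre-simulated breeding-value matrix (3 columns:
#'   chamber, maternal, egg latent traits); drawn internally otherwise.
#' @return List with tibbles `chamber`, `maternal`, `egg` and a `truth`
#'   list holding the generating parameters.
#' @export
simulate_records <- function(ped, config, values = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  ct <- config$chamber_trait; mt <- config$maternal_trait
  et <- config$egg_trait
  sa <- c(ct$sigma2_a, mt$sigma2_a, et$sigma2_a)
  G <- diag(sqrt(sa)) %*% config$genetic_cor %*% diag(sqrt(sa))
  dimnames(G) <- list(NULL, c("chamber", "maternal", "egg"))
  if (is.null(values)) values <- simulate_breeding_values(ped, G)

  chamber_idx <- which(ped$role %in% "chamber")
  ewe_idx <- which(ped$role %in% "ewe")

  ## ---- chamber records ----------------------------------------------------
  ch <- NULL
  if (length(chamber_idx)) {
    an <- ped$animal[chamber_idx]
    nanim <- length(an)
    ryr <- ped$byr[chamber_idx] + 1L
    ## lots of lot_size within recording year, groups of group_size within lot
    ord <- order(ryr, an)
    lot <- group <- integer(nanim)
    for (yy in unique(ryr[ord])) {
      id <- ord[ryr[ord] == yy]
      lot[id] <- (seq_along(id) - 1L) %/% config$lot_size + 1L
      group[id] <- ((seq_along(id) - 1L) %% config$lot_size) %/%
        config$group_size + 1L
    }
    bdev <- round(stats::rnorm(nanim, 0, 10))
    lw <- stats::rnorm(nanim, 45, 5)
    grid <- tidyr::expand_grid(k = seq_len(nanim),
                               round = seq_len(config$rounds),
                               day = seq_len(config$days_per_round))
    k <- grid$k
    cg1 <- .draw_effects(unique(paste(ped$byr[chamber_idx],
                                      ped$flk[chamber_idx],
                                      ped$sex[chamber_idx])),
                         config$cg_sd[["chamber"]])
    cg2lev <- unique(paste(ryr[k], lot[k], group[k], grid$round))
    cg2 <- .draw_effects(cg2lev, config$cg_sd[["round"]])
    wgpe <- matrix(stats::rnorm(nanim * config$rounds, 0,
                                sqrt(.pe_var(ct$sigma2_pe, "wgpe"))),
                   nanim, config$rounds)
    agpe <- stats::rnorm(nanim, 0, sqrt(.pe_var(ct$sigma2_pe, "agpe")))
    eps <- stats::rnorm(nrow(grid), 0, sqrt(ct$sigma2_e))
    yv <- ct$mean +
      cg1[paste(ped$byr[chamber_idx], ped$flk[chamber_idx],
                ped$sex[chamber_idx])[k]] +
      cg2[paste(ryr[k], lot[k], group[k], grid$round)] +
      (ct$beta_bdev %||% 0) * bdev[k] +
      values[chamber_idx[k], "chamber"] +
      wgpe[cbind(k, grid$round)] + agpe[k] + eps
    yv <- pmax(yv, 0.1)

    offered <- pmax(1.5 + 0.012 * (lw[k] - 45) +
                      stats::rnorm(nrow(grid), 0, 0.03), 0.5)
    refused <- stats::runif(nrow(grid)) < config$refusal_rate
    frac <- ifelse(refused, stats::runif(nrow(grid), 0.5, 0.9499),
                   stats::runif(nrow(grid), 0.95, 1.0))
    dmi <- offered * frac
    ratio <- pmin(pmax(stats::rnorm(nrow(grid), 0.059, 0.004), 0.03), 0.12)
    co2 <- (yv / 16.04) * (1 / ratio - 1) * 44.01
    seal_ok <- stats::runif(nrow(grid)) >= config$seal_break_rate

    ch <- tibble::tibble(
      animal = an[k],
      byr = as.character(ped$byr[chamber_idx[k]]),
      flk = as.character(ped$flk[chamber_idx[k]]),
      sex = ped$sex[chamber_idx[k]],
      ryr = as.character(ryr[k]),
      lot = as.character(lot[k]), group = as.character(group[k]),
      round = as.character(grid$round), day = as.character(grid$day),
      brr = as.character(sample(1:3, nrow(grid), TRUE,
                                prob = c(0.3, 0.6, 0.1))),
      bdev = bdev[k],
      live_weight_kg = round(lw[k], 1),
      offered_kg = offered, dmi_kg = dmi,
      ch4_g = yv, co2_g = co2, seal_ok = seal_ok
    )
  }

  ## ---- adult ewe records --------------------------------------------------
  ma <- NULL
  if (length(ewe_idx)) {
    an <- ped$animal[ewe_idx]
    nanim <- length(an)
    grid <- tidyr::expand_grid(k = seq_len(nanim), age = config$ages)
    grid <- grid[stats::runif(nrow(grid)) < config$present_rate, ]
    k <- grid$k
    rflk <- sample.int(config$n_rflk, nanim, replace = TRUE)
    mob <- sample.int(config$n_mob, nrow(grid), replace = TRUE)
    ageclass <- pmin(grid$age, 5L)
    ryr <- ped$byr[ewe_idx[k]] + grid$age
    cglev <- unique(paste(rflk[k], ryr, mob, ageclass))
    cgm <- .draw_effects(cglev, config$cg_sd[["maternal"]])
    pe <- stats::rnorm(nanim, 0, sqrt(sum(mt$sigma2_pe)))
    eps <- stats::rnorm(nrow(grid), 0, sqrt(mt$sigma2_e))
    lwv <- mt$mean + cgm[paste(rflk[k], ryr, mob, ageclass)] +
      values[ewe_idx[k], "maternal"] + pe[k] + eps
    nlb <- pmin(stats::rpois(nrow(grid), 1.7), 3L)
    n_weaned <- stats::rbinom(nrow(grid), nlb, 0.8)
    ma <- tibble::tibble(
      animal = an[k],
      ryr = as.character(ryr), rflk = as.character(rflk[k]),
      mob = as.character(mob), ageclass = as.character(ageclass),
      nlb_prev = as.character(pmin(stats::rpois(nrow(grid), 1.5), 3L)),
      lw_mate = lwv,
      bcs_mate = .round_half((lwv - mt$mean) / 12 + 3.57),
      pregsc = pmin(stats::rpois(nrow(grid), 1.8), 3L),
      nlb = nlb, n_weaned = n_weaned
    )
  }

  ## ---- egg counts (single record, count scale) ----------------------------
  eg <- NULL
  eg_idx <- c(chamber_idx, ewe_idx)
  if (length(eg_idx)) {
    lat_f <- et$mean_log + values[eg_idx, "egg"] +
      stats::rnorm(length(eg_idx), 0, sqrt(et$sigma2_e))
    lat_n <- 4.30 + 0.7 * values[eg_idx, "egg"] +
      stats::rnorm(length(eg_idx), 0, sqrt(et$sigma2_e))
    eg <- tibble::tibble(
      animal = ped$animal[eg_idx],
      byr = as.character(ped$byr[eg_idx]),
      flk = as.character(ped$flk[eg_idx]),
      sex = ped$sex[eg_idx],
      fec_raw = pmax(round(exp(lat_f) - 50), 0),
      nem_raw = pmax(round(exp(lat_n) - 50), 0)
    )
  }

  list(chamber = ch, maternal = ma, egg = eg,
       truth = list(config = config, G = G,
                    chamber = ct, maternal = mt, egg = et))
}

#' Simulate a complete synthetic flock
#'
#' Convenience wrapper: pedigree, breeding values and all record tables in
#' one call; under a fixed `config$seed` the output is reproducible.
#'
#' @param config A [sim_config()].
#' @return List: `pedigree`, `values` (breeding-value matrix), plus the
#'   [simulate_records()] tables (`chamber`, `maternal`, `egg`, `truth`).
#' @export
simulate_flock <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  if (isTRUE(config$divergent_selection)) {
    sa <- c(config$chamber_trait$sigma2_a, config$maternal_trait$sigma2_a,
            config$egg_trait$sigma2_a)
    G <- diag(sqrt(sa)) %*% config$genetic_cor %*% diag(sqrt(sa))
    colnames(G) <- c("chamber", "maternal", "egg")
    if (!is.null(config$seed)) set.seed(config$seed + 2L)
    values <- simulate_breeding_values(ped, G)
    sires <- ped$animal[ped$role == "sire"]
    bv <- values[sires, "chamber"]
    ranks <- rank(bv, ties.method = "first")
    line <- ifelse(ranks <= length(sires) / 2, "low", "high")
    ped$line <- line[match(ped$sire, sires)]
    ped$line[ped$animal %in% sires] <- line
    rec <- simulate_records(ped, config, values = values)
  } else {
    values <- NULL
    rec <- simulate_records(ped, config)
  }
  c(list(pedigree = ped, values = values), rec)
}

#' Read / write phenotype tables
#'
#' CSV round-trip helpers for the generated tables; missing values are
#' written as `NA`, numeric columns at full (round-trip exact) precision.
#'
#' @param x Tibble to write.
#' @param path CSV path.
#' @return `write_phenotypes()` returns `x` invisibly; `read_phenotypes()`
#'   the tibble, with `seal_ok` restored to logical when present.
#' @export
write_phenotypes <- function(x, path) {
  out <- x
  for (cl in names(out)) {
    if (is.double(out[[cl]])) {
      ## shortest-exact decimal so the CSV round-trips bit-identically
      v <- sprintf("%.17g", out[[cl]])
      v[is.na(out[[cl]])] <- NA_character_
      out[[cl]] <- v
    }
  }
  readr::write_csv(out, path, na = "NA")
  invisible(x)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ## base parser: exact decimal-to-double conversion, so written tables
  ## round-trip bit-identically
  out <- tibble::as_tibble(utils::read.csv(path, na.strings = "NA",
                                           stringsAsFactors = FALSE))
  chr <- intersect(names(out), c("animal", "byr", "flk", "sex", "ryr", "lot",
                                 "group", "round", "day", "brr", "rflk",
                                 "mob", "ageclass", "nlb_prev"))
  for (cl in chr) out[[cl]] <- as.character(out[[cl]])
  out
}
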