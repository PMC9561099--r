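# Independent oracles and fixture generators used across the suite.

# Random pedigree as a raw triple table (unsorted, shuffled rows).
random_pedigree_table <- function(n, n_founders = max(3L, n %/% 5L),
                                  p_known = 0.9) {
  an <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in seq(n_founders + 1L, n)) {
    if (stats::runif(1) < p_known) sire[i] <- sample(an[seq_len(i - 1L)], 1)
    if (stats::runif(1) < p_known) dam[i] <- sample(an[seq_len(i - 1L)], 1)
  }
  tab <- tibble::tibble(animal = an, sire = sire, dam = dam)
  tab[sample.int(n), ]
}

# Brute-force tabular relationship matrix: direct double-loop recursion on a
# sorted pedigree. Independent of the package's factorisation-based path.
tabular_A <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n)
  rel <- function(i, j) if (is.na(j)) 0 else A[i, j]
  for (j in seq_len(n)) {
    if (j > 1) {
      for (i in seq_len(j - 1L)) {
        A[i, j] <- A[j, i] <- 0.5 * (rel(i, si[j]) + rel(i, di[j]))
      }
    }
    A[j, j] <- 1 + if (is.na(si[j]) || is.na(di[j])) 0 else 0.5 * A[si[j], di[j]]
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

# Small random mixed-model instance for likelihood cross-checks.
random_instance <- function(n_rec = 30L, n_terms = 2L) {
  ped <- as_pedigree(random_pedigree_table(12L))
  dat <- tibble::tibble(
    animal = sample(ped$animal, n_rec, replace = TRUE),
    grp = sample(paste0("g", 1:4), n_rec, replace = TRUE),
    blk = sample(paste0("b", 1:5), n_rec, replace = TRUE),
    y = stats::rnorm(n_rec)
  )
  pool <- list(
    animal = list(group_by = "animal", covariance = "pedigree"),
    pe = list(group_by = "animal", covariance = "identity"),
    blk = list(group_by = "blk", covariance = "identity")
  )
  random <- pool[seq_len(n_terms)]
  spec <- model_spec("y", fixed = list("grp"), random = random)
  s2 <- stats::setNames(stats::runif(length(random), 0.2, 2), names(random))
  list(design = build_design(dat, spec, ped), ped = ped,
       components = list(sigma2 = s2,
                         sigma2_e = stats::runif(1, 0.3, 2)))
}

# Standard recovery-study configuration: sire families with chamber-style
# records (2 rounds x 2 days), optional ewe relatives for bivariate runs.
recovery_config <- function(seed, n_sires = 100L, progeny_per_sire = 10L,
                            ewes_per_sire = 0L, rg = 0,
                            h2 = 0.25, repeatability = 0.40) {
  sim_config(
    seed = seed, n_sires = n_sires, progeny_per_sire = progeny_per_sire,
    ewes_per_sire = ewes_per_sire, dams_known = FALSE,
    ages = 2:4, present_rate = 1.0,
    seal_break_rate = 0, refusal_rate = 0,
    cg_sd = c(chamber = 0.5, round = 0.3, maternal = 3),
    chamber_trait = list(name = "y", mean = 10, sigma2_a = h2,
                         sigma2_pe = c(agpe = repeatability - h2),
                         sigma2_e = 1 - repeatability, beta_bdev = 0),
    genetic_cor = matrix(c(1, rg, 0, rg, 1, 0, 0, 0, 1), 3, 3)
  )
}

chamber_recovery_spec <- function() {
  model_spec("ch4_g",
    fixed = list("byr.flk.sex", "ryr.lot.group.round"),
    random = list(animal = list(group_by = "animal", covariance = "pedigree"),
                  agpe = list(group_by = "animal", covariance = "identity")))
}

maternal_recovery_spec <- function() {
  model_spec("lw_mate",
    fixed = list("rflk.ryr.mob.ageclass"),
    random = list(animal = list(group_by = "animal", covariance = "pedigree"),
                  pe = list(group_by = "animal", covariance = "identity")))
}
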