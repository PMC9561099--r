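test_that("pedigrees parse, sort and promote parents", {
  ped <- as_pedigree(tibble::tibble(animal = c("C", "B", "A"),
                                    sire = c("A", "0", "0"),
                                    dam = c("B", "0", "0")))
  expect_s3_class(ped, "pedigree")
  expect_equal(ped$animal, c("A", "B", "C"))
  expect_identical(ped$sire[3], "A")

  # a single offspring row promotes both parents to founders
  solo <- as_pedigree(tibble::tibble(animal = "C", sire = "A", dam = "B"))
  expect_equal(nrow(solo), 3L)
  expect_true(all(is.na(solo$sire[solo$animal %in% c("A", "B")])))

  # row order never matters
  tab <- random_pedigree_table(40)
  p1 <- as_pedigree(tab)
  p2 <- as_pedigree(tab[rev(seq_len(nrow(tab))), ])
  expect_identical(p1, p2)
})

test_that("invalid pedigrees are refused with structural errors", {
  expect_error(as_pedigree(tibble::tibble(animal = c("A", "B"),
                                          sire = c("B", "A"),
                                          dam = c("0", "0"))),
               "cycle")
  expect_error(as_pedigree(tibble::tibble(animal = c("A", "A"),
                                          sire = c("0", "0"),
                                          dam = c("0", "0"))),
               "duplicate")
  expect_error(as_pedigree(tibble::tibble(animal = "A", sire = "A",
                                          dam = "0")),
               "own parent")
})

test_that("full-sib mating pedigree reproduces hand-computed relationships", {
  ped <- as_pedigree(tibble::tibble(
    animal = c("P1", "P2", "O1", "O2", "C"),
    sire = c("0", "0", "P1", "P1", "O1"),
    dam = c("0", "0", "P2", "P2", "O2")))
  A <- relationship_matrix(ped)
  expect_equal(A["O1", "O2"], 0.5)
  expect_equal(A["C", "C"], 1.25)
  expect_equal(A["C", "O1"], 0.75)
  expect_equal(inbreeding(ped)[["C"]], 0.25)
})

test_that("inbreeding handles founders and parent-offspring matings", {
  ped <- as_pedigree(tibble::tibble(
    animal = c("S", "D", "O", "X"),
    sire = c("0", "0", "S", "S"),
    dam = c("0", "0", "D", "O")))
  f <- inbreeding(ped)
  expect_equal(unname(f[c("S", "D", "O")]), c(0, 0, 0))
  expect_equal(f[["X"]], 0.25) # sire mated to his own daughter
})

test_that("sire with unknown mates gives half relationships", {
  ped <- as_pedigree(tibble::tibble(animal = "O", sire = "S", dam = "0"))
  A <- relationship_matrix(ped)
  expect_equal(A["S", "O"], 0.5)
  expect_equal(A["O", "O"], 1)
})

test_that("relationship matrix matches the brute-force tabular oracle", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(30:200, 1)
    ped <- as_pedigree(random_pedigree_table(n))
    A <- as.matrix(relationship_matrix(ped, sparse_from = 10))
    expect_lt(max(abs(A - tabular_A(ped))), 1e-12)
    # PSD and diagonal identity with inbreeding
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-9)
    expect_lt(max(abs(diag(A) - 1 - ped$f)), 1e-12)
  }
})

test_that("Henderson inverse agrees with dense inversion", {
  set.seed(202)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    ped <- as_pedigree(random_pedigree_table(n))
    A <- as.matrix(relationship_matrix(ped, sparse_from = Inf))
    Ai <- relationship_inverse(ped)
    expect_lt(max(abs(A %*% Ai - diag(n))), 1e-8)
    expect_equal(attr(Ai, "logdet"),
                 as.numeric(determinant(A, logarithm = TRUE)$modulus),
                 tolerance = 1e-8)
  }
})

test_that("sparse and dense containers hold identical values", {
  ped <- as_pedigree(random_pedigree_table(60))
  Ad <- relationship_matrix(ped, sparse_from = Inf)
  As <- relationship_matrix(ped, sparse_from = 1)
  expect_true(methods::is(As, "sparseMatrix"))
  expect_equal(as.matrix(As), Ad)
})

test_that("pedigree files round-trip including headers and commas", {
  tab <- random_pedigree_table(25)
  p0 <- as_pedigree(tab)

  ws <- tempfile(fileext = ".txt")
  writeLines(c("animal sire dam", paste(tab$animal, tab$sire, tab$dam)), ws)
  expect_identical(read_pedigree(ws), p0)

  cs <- tempfile(fileext = ".csv")
  writeLines(paste(tab$animal, tab$sire, tab$dam, sep = ","), cs)
  expect_identical(read_pedigree(cs), p0)
})

test_that("triplet export writes the lower triangle", {
  ped <- as_pedigree(tibble::tibble(animal = "C", sire = "A", dam = "B"))
  f <- tempfile()
  out <- write_relationship_triplets(relationship_matrix(ped), f)
  expect_true(all(out$i >= out$j))
  back <- utils::read.table(f)
  expect_equal(nrow(back), nrow(out))
  A <- relationship_matrix(ped)
  for (r in seq_len(nrow(back))) {
    expect_equal(back$V3[r], A[back$V1[r], back$V2[r]])
  }
})
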