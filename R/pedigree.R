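#' Build a validated, sorted pedigree from a data frame
#'
#' Takes animal/sire/dam triples (any row order), validates them, promotes
#' identifiers that appear only as parents to founder rows, sorts the result
#' so every parent precedes its offspring, and computes inbreeding
#' coefficients exactly by the Meuwissen--Luo tabular recursion.
#'
#' @param x A data frame whose first three columns (or the columns named in
#'   `columns`) are animal, sire and dam identifiers. Unknown parents are
#'   coded by `unknown`.
#' @param unknown Token marking an unknown parent (default `"0"`); `NA` is
#'   always treated as unknown too.
#' @param columns Names or positions of the animal, sire and dam columns.
#' @return A tibble of class `"pedigree"` with columns `animal`, `sire`,
#'   `dam` (character; `NA` = unknown parent) and `f` (inbreeding
#'   coefficient), ordered parents-first.
#' @examples
#' ped <- as_pedigree(data.frame(animal = "C", sire = "A", dam = "B"))
#' ped$f
#' @export
as_pedigree <- function(x, unknown = "0", columns = 1:3) {
  stopifnot(is.data.frame(x), length(columns) == 3)
  x <- as.data.frame(x)[, columns, drop = FALSE]
  names(x) <- c("animal", "sire", "dam")
  for (j in 1:3) {
    v <- trimws(as.character(x[[j]]))
    v[!is.na(v) & v == unknown] <- NA_character_
    x[[j]] <- v
  }
  if (anyNA(x$animal)) stop("missing animal identifier in pedigree")
  if (anyDuplicated(x$animal)) {
    stop("duplicate animal id in pedigree: ",
         x$animal[duplicated(x$animal)][1])
  }
  own <- which(x$animal == x$sire | x$animal == x$dam)
  if (length(own)) {
    stop("animal recorded as its own parent: ", x$animal[own[1]])
  }

  ## promote parents that have no record of their own to founders
  parents <- setdiff(stats::na.omit(c(x$sire, x$dam)), x$animal)
  if (length(parents)) {
    x <- rbind(
      data.frame(animal = parents, sire = NA_character_, dam = NA_character_),
      x
    )
  }

  n <- nrow(x)
  si <- match(x$sire, x$animal)
  di <- match(x$dam, x$animal)

  ## generation numbers by relaxation; failure to converge means a cycle
  gen <- ifelse(is.na(si) & is.na(di), 0L, NA_integer_)
  repeat {
    pg <- function(idx) ifelse(is.na(idx), -1L, gen[idx])
    ready <- is.na(gen) & !is.na(pg(si)) & !is.na(pg(di))
    if (!any(ready)) break
    gen[ready] <- pmax(pg(si)[ready], pg(di)[ready]) + 1L
  }
  if (anyNA(gen)) {
    stop("pedigree cycle detected involving animal: ",
         x$animal[which(is.na(gen))[1]])
  }

  ord <- order(gen, x$animal, method = "radix")
  x <- x[ord, , drop = FALSE]
  ped <- tibble::tibble(animal = x$animal, sire = x$sire, dam = x$dam)
  ped$f <- .ml_inbreeding(ped)
  class(ped) <- c("pedigree", class(ped))
  ped
}

#' Read a pedigree file
#'
#' Reads a whitespace- or comma-delimited text file with animal, sire and dam
#' columns and returns a validated [as_pedigree()] object.
#'
#' @param path Path to the pedigree file.
#' @param unknown Token coding an unknown parent (default `"0"`).
#' @param header `TRUE`/`FALSE`, or `NULL` to auto-detect (a header is
#'   assumed when the first field of line one is non-numeric and repeated
#'   nowhere as a parent).
#' @inherit as_pedigree return
#' @export
read_pedigree <- function(path, unknown = "0", header = NULL) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl(",", first)) "," else "whitespace"
  read1 <- function(skip) {
    if (delim == ",") {
      readr::read_csv(path, col_names = FALSE, skip = skip,
                      col_types = readr::cols(.default = "c"),
                      progress = FALSE)
    } else {
      readr::read_table(path, col_names = FALSE, skip = skip,
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
    }
  }
  if (is.null(header)) {
    f1 <- trimws(strsplit(first, if (delim == ",") "," else "[[:space:]]+")[[1]][1])
    header <- is.na(suppressWarnings(as.numeric(f1))) &&
      tolower(f1) %in% c("animal", "id", "indiv", "individual", "tag")
  }
  tab <- read1(skip = as.integer(header))
  if (ncol(tab) < 3) stop("pedigree file needs at least 3 columns")
  as_pedigree(tab, unknown = unknown)
}

## Meuwissen & Luo (1992) exact inbreeding: a_ii computed per animal by
## tracing path coefficients back to founders; parents precede offspring.
.ml_inbreeding <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  f <- numeric(n)
  dvec <- numeric(n) # Mendelian sampling variance, filled as we go
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dvec[i] <- .mendel_var1(s, d, f)
    if (is.na(s) || is.na(d)) { f[i] <- 0; next }
    ## a_ii = sum_j T_ij^2 d_j over ancestors j (including i itself)
    L <- numeric(n)
    L[i] <- 1
    todo <- i
    aii <- 0
    while (length(todo)) {
      j <- max(todo)
      todo <- todo[todo != j]
      aii <- aii + L[j]^2 * dvec[j]
      for (p in c(si[j], di[j])) {
        if (!is.na(p)) {
          if (L[p] == 0) todo <- c(todo, p)
          L[p] <- L[p] + L[j] / 2
        }
      }
      L[j] <- 0
    }
    f[i] <- aii - 1
  }
  f
}

.mendel_var1 <- function(s, d, f) {
  known <- !is.na(c(s, d))
  if (all(known)) 0.5 - 0.25 * (f[s] + f[d])
  else if (any(known)) 0.75 - 0.25 * f[c(s, d)[known]]
  else 1
}

## Mendelian sampling variances for every animal (parents known => uses their F)
mendelian_variances <- function(ped) {
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  vapply(seq_len(nrow(ped)), function(i) .mendel_var1(si[i], di[i], ped$f), 0)
}

#' Inbreeding coefficients
#'
#' Returns the exact inbreeding coefficient of each animal,
#' `F_i = 0.5 * a(sire_i, dam_i)` (0 when any parent is unknown), as computed
#' during pedigree construction. Equals `diag(relationship_matrix(ped)) - 1`.
#'
#' @param ped A [as_pedigree()] object.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  stats::setNames(ped$f, ped$animal)
}

.check_sorted <- function(ped) {
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  i <- seq_len(nrow(ped))
  if (any(si >= i, na.rm = TRUE) || any(di >= i, na.rm = TRUE)) {
    stop("pedigree is not sorted parents-first; use as_pedigree()")
  }
  invisible(list(si = si, di = di))
}

#' Numerator relationship matrix
#'
#' Builds the additive (numerator) relationship matrix `A` from a sorted
#' pedigree via its generalised Cholesky factorisation
#' `A = (T sqrt(D)) (T sqrt(D))'`, where `T` holds the recursive
#' parent-average path coefficients and `D` the Mendelian sampling variances
#' (which account for inbreeding). The diagonal is `1 + F_i`; off-diagonals
#' are the expected additive relationships.
#'
#' `A` is mathematically dense; below `sparse_from` animals a base dense
#' matrix is returned, above it the same values wrapped as a
#' [Matrix::Matrix()] sparse container.
#'
#' @param ped A sorted [as_pedigree()] object.
#' @param sparse_from Animal count at which the sparse container is used.
#' @return Symmetric matrix with animal ids as dimnames.
#' @export
relationship_matrix <- function(ped, sparse_from = 500L) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- .check_sorted(ped)
  n <- nrow(ped)
  dvec <- mendelian_variances(ped)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- idx$si[i]; d <- idx$di[i]
    if (!is.na(s)) L[i, ] <- L[s, ] / 2
    if (!is.na(d)) L[i, ] <- L[i, ] + L[d, ] / 2
    L[i, i] <- sqrt(dvec[i])
  }
  A <- tcrossprod(L)
  dimnames(A) <- list(ped$animal, ped$animal)
  if (n >= sparse_from) Matrix::Matrix(A, sparse = TRUE) else A
}

#' Inverse of the numerator relationship matrix
#'
#' Builds `A^{-1}` directly by Henderson's recursive rules with exact
#' inbreeding accounting: each animal contributes `1/d_i` to its own
#' diagonal, `-1/(2 d_i)` to animal-parent cells and `1/(4 d_i)` to
#' parent-parent cells, where `d_i` is the Mendelian sampling variance. The
#' result is sparse (non-zeros only within parent-offspring triangles).
#'
#' @param ped A sorted [as_pedigree()] object.
#' @return A [Matrix::sparseMatrix()] (symmetric `dsCMatrix`) with attribute
#'   `"logdet"` holding `log det(A)`.
#' @export
relationship_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- .check_sorted(ped)
  n <- nrow(ped)
  dvec <- mendelian_variances(ped)
  alpha <- 1 / dvec
  # vectorised triplet assembly
  i <- seq_len(n)
  trip_i <- i; trip_j <- i; trip_x <- alpha
  for (pcol in list(idx$si, idx$di)) {
    ok <- !is.na(pcol)
    trip_i <- c(trip_i, pmax(i[ok], pcol[ok]))
    trip_j <- c(trip_j, pmin(i[ok], pcol[ok]))
    trip_x <- c(trip_x, -alpha[ok] / 2)
  }
  both <- !is.na(idx$si) | !is.na(idx$di)
  for (k in which(both)) {
    ps <- c(idx$si[k], idx$di[k])
    ps <- ps[!is.na(ps)]
    if (length(ps) == 1 || ps[1] == ps[2]) {
      trip_i <- c(trip_i, ps[1]); trip_j <- c(trip_j, ps[1])
      trip_x <- c(trip_x, if (length(ps) == 1) alpha[k] / 4 else alpha[k])
    } else {
      pr_i <- c(ps[1], ps[2], max(ps))
      pr_j <- c(ps[1], ps[2], min(ps))
      trip_i <- c(trip_i, pr_i); trip_j <- c(trip_j, pr_j)
      trip_x <- c(trip_x, c(alpha[k] / 4, alpha[k] / 4, alpha[k] / 4))
    }
  }
  # (ps[1], ps[2]) off-diagonal added once with value alpha/4 each direction
  # collapsed by sparseMatrix's duplicate summation below
  Ainv <- Matrix::sparseMatrix(
    i = trip_i, j = trip_j, x = trip_x, dims = c(n, n),
    symmetric = TRUE, dimnames = list(ped$animal, ped$animal)
  )
  attr(Ainv, "logdet") <- sum(log(dvec))
  Ainv
}

#' Export a relationship matrix as coordinate triplets
#'
#' Writes the lower triangle of a (possibly sparse) symmetric matrix as
#' whitespace-delimited `i j value` rows, 1-based, for interoperability with
#' pedigree/BLUP tools.
#'
#' @param A Symmetric matrix as returned by [relationship_matrix()] or
#'   [relationship_inverse()].
#' @param path Output file path.
#' @param zero_tol Entries with absolute value below this are dropped.
#' @return Invisibly, the tibble that was written.
#' @export
write_relationship_triplets <- function(A, path, zero_tol = 0) {
  M <- Matrix::Matrix(A, sparse = TRUE)
  tri <- Matrix::mat2triplet(Matrix::tril(M))
  keep <- abs(tri$x) > zero_tol
  out <- tibble::tibble(i = tri$i[keep], j = tri$j[keep], value = tri$x[keep])
  out <- out[order(out$i, out$j), ]
  readr::write_delim(out, path, delim = " ", col_names = FALSE)
  invisible(out)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("# Pedigree: %d animals (%d founders), mean F = %.4f\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam)), mean(x$f)))
  NextMethod()
}
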