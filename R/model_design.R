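#' Declarative model specification
#'
#' Describes one trait's mixed model: the response column, fixed-effect
#' interaction terms (dot-joined factor combinations acting as contemporary
#' groups), numeric covariates, and random terms with either identity or
#' pedigree (numerator relationship) covariance. This mirrors the way
#' livestock repeatability-model software is configured: e.g. fixed
#' `byr.flk.sex` + `ryr.lot.group.round`, random `animal` (pedigree),
#' `wgpe` = animal-by-round permanent environment, `agpe` = animal-by-year
#' permanent environment.
#'
#' @param response Name of the trait column.
#' @param fixed List of interaction terms; each element a character vector
#'   of factor columns, or a single dot-joined string (`"byr.flk.sex"`).
#' @param covariates Character vector of numeric covariate columns
#'   (centred before fitting).
#' @param random Named list of random terms; each element a list with
#'   `group_by` (character vector of grouping columns; for a pedigree term a
#'   single animal-id column) and `covariance` (`"identity"` or
#'   `"pedigree"`).
#' @return Object of class `"model_spec"`.
#' @examples
#' model_spec("ch4_gd",
#'   fixed = list("byr.flk.sex", "ryr.lot.group.round"),
#'   random = list(
#'     animal = list(group_by = "animal", covariance = "pedigree"),
#'     wgpe = list(group_by = c("animal", "ryr", "round"),
#'                 covariance = "identity")))
#' @export
model_spec <- function(response, fixed = list(), covariates = character(),
                       random = list()) {
  stopifnot(is.character(response), length(response) == 1)
  fixed <- lapply(fixed, function(tm) {
    if (length(tm) == 1 && grepl(".", tm, fixed = TRUE)) {
      strsplit(tm, ".", fixed = TRUE)[[1]]
    } else as.character(tm)
  })
  if (length(random)) {
    if (is.null(names(random)) || anyDuplicated(names(random))) {
      stop("random terms must have distinct names")
    }
    for (nm in names(random)) {
      rt <- random[[nm]]
      if (!is.list(rt) || is.null(rt$group_by)) {
        stop("random term '", nm, "' needs a group_by field")
      }
      rt$covariance <- match.arg(rt$covariance %||% "identity",
                                 c("identity", "pedigree"))
      if (rt$covariance == "pedigree" && length(rt$group_by) != 1) {
        stop("pedigree covariance requires a single animal-id grouping column")
      }
      random[[nm]] <- rt
    }
  }
  structure(list(response = response, fixed = fixed,
                 covariates = as.character(covariates), random = random),
            class = "model_spec")
}

#' Read a model specification from a YAML config
#'
#' Config layout:
#' ```yaml
#' response: ch4_gd
#' fixed: [byr.flk.sex, ryr.lot.group.round]
#' covariates: [bdev]
#' random:
#'   animal: {group_by: [animal], covariance: pedigree}
#'   wgpe:   {group_by: [animal, ryr, round], covariance: identity}
#' ```
#' @param path Path to a YAML file.
#' @return A [model_spec()].
#' @export
read_model_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  model_spec(response = cfg$response,
             fixed = as.list(cfg$fixed %||% list()),
             covariates = unlist(cfg$covariates) %||% character(),
             random = cfg$random %||% list())
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec for response:", x$response, "\n")
  cat("  fixed: ", paste(vapply(x$fixed, paste, "", collapse = "."),
                         collapse = " + "), "\n")
  if (length(x$covariates)) cat("  covariates:",
                                paste(x$covariates, collapse = ", "), "\n")
  for (nm in names(x$random)) {
    cat(sprintf("  random %s: %s (%s)\n", nm,
                paste(x$random[[nm]]$group_by, collapse = "."),
                x$random[[nm]]$covariance))
  }
  invisible(x)
}

#' Contemporary-group factor from factor columns
#'
#' Concatenates the named columns into one factor with a level per observed
#' combination (unobserved crosses absent), levels ordered
#' lexicographically. Rows with a missing component give `NA`.
#'
#' @param data A data frame.
#' @param columns Character vector of factor column names.
#' @param sep Separator between component levels in the level labels.
#' @return A factor of length `nrow(data)`.
#' @export
build_contemporary_groups <- function(data, columns, sep = ".") {
  miss <- setdiff(columns, names(data))
  if (length(miss)) stop("unknown factor column(s): ",
                         paste(miss, collapse = ", "))
  parts <- lapply(data[columns], as.character)
  any_na <- Reduce(`|`, lapply(parts, is.na))
  lab <- do.call(paste, c(parts, sep = sep))
  lab[any_na] <- NA
  factor(lab, levels = sort(unique(lab[!is.na(lab)]), method = "radix"))
}

#' Assemble response and design structures for the repeatability animal model
#'
#' Builds, for one trait, the pieces of the mixed model
#' `y = Xb + Za + W_w pe_w + W_y pe_y + e`: the response vector over usable
#' records, a full-column-rank fixed design `X` (intercept + dummy-coded
#' contemporary-group interactions + centred covariates, aliased columns
#' removed by pivoted QR), and one sparse incidence matrix per random term.
#' A pedigree random term gets one column per pedigree animal so its
#' covariance can be taken as `A * sigma^2`.
#'
#' Records missing the response, any model factor or covariate are dropped
#' for this trait (and reported in the `dropped` element).
#'
#' @param data Phenotype tibble, one row per record.
#' @param spec A [model_spec()].
#' @param pedigree A [as_pedigree()] object; required when any random term
#'   has pedigree covariance.
#' @return Object of class `"design_set"`: list with `y`, `X`, `random`
#'   (per term: `name`, `Z`, `covariance`, `levels`), `response`, `animals`
#'   (ids of recorded animals), `rows` (kept row indices), `dropped`.
#' @export
build_design <- function(data, spec, pedigree = NULL) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  data <- tibble::as_tibble(data)
  all_cols <- unique(c(spec$response, unlist(spec$fixed), spec$covariates,
                       unlist(lapply(spec$random, `[[`, "group_by"))))
  miss <- setdiff(all_cols, names(data))
  if (length(miss)) stop("model spec references absent column(s): ",
                         paste(miss, collapse = ", "))
  needs_ped <- any(vapply(spec$random, function(r) r$covariance == "pedigree",
                          TRUE))
  if (needs_ped && !inherits(pedigree, "pedigree")) {
    stop("a pedigree is required for pedigree-covariance random terms")
  }

  ok <- !is.na(data[[spec$response]])
  for (cl in setdiff(all_cols, spec$response)) ok <- ok & !is.na(data[[cl]])
  if (!any(ok)) stop("no usable records for response ", spec$response)
  d <- data[ok, , drop = FALSE]
  y <- as.numeric(d[[spec$response]])
  n <- length(y)

  ## fixed design: intercept + observed-combination dummies + centred covariates
  Xparts <- list(`(Intercept)` = matrix(1, n, 1))
  for (tm in spec$fixed) {
    fac <- build_contemporary_groups(d, tm)
    nmt <- paste(tm, collapse = ".")
    M <- stats::model.matrix(~ fac - 1)
    colnames(M) <- paste0(nmt, "=", levels(fac))
    Xparts[[nmt]] <- M
  }
  for (cv in spec$covariates) {
    Xparts[[cv]] <- matrix(scale(as.numeric(d[[cv]]), scale = FALSE),
                           n, 1, dimnames = list(NULL, cv))
  }
  X <- do.call(cbind, Xparts)
  qrX <- qr(X)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  X <- X[, keep, drop = FALSE]

  rand <- vector("list", length(spec$random))
  names(rand) <- names(spec$random)
  for (nm in names(spec$random)) {
    rt <- spec$random[[nm]]
    if (rt$covariance == "pedigree") {
      ids <- as.character(d[[rt$group_by]])
      j <- match(ids, pedigree$animal)
      if (anyNA(j)) stop("animal id(s) not in pedigree: ",
                         paste(utils::head(unique(ids[is.na(j)]), 3),
                               collapse = ", "))
      q <- nrow(pedigree)
      lv <- pedigree$animal
    } else {
      fac <- build_contemporary_groups(d, rt$group_by)
      j <- as.integer(fac)
      q <- nlevels(fac)
      lv <- levels(fac)
    }
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1, dims = c(n, q))
    rand[[nm]] <- list(name = nm, Z = Z, covariance = rt$covariance,
                       levels = lv)
  }

  structure(list(
    y = y, X = X, random = rand, response = spec$response,
    n = n, p = ncol(X),
    animals = if ("animal" %in% names(d)) as.character(d$animal) else NULL,
    rows = which(ok), dropped = which(!ok),
    data = d
  ), class = "design_set")
}

#' @export
print.design_set <- function(x, ...) {
  cat(sprintf("Design for '%s': %d records, fixed rank %d, random terms: %s\n",
              x$response, x$n, x$p,
              paste(sprintf("%s[%s]", names(x$random),
                            vapply(x$random, function(r) r$covariance, "")),
                    collapse = ", ")))
  invisible(x)
}

#' Screen candidate fixed effects with a general linear model
#'
#' Fits an ordinary least-squares model with all candidate terms in the
#' given order and reports sequential (type-I) F tests, marking terms
#' significant at `alpha` as keepers. Numeric columns are treated as
#' covariates; everything else is dummy-coded as a single interaction
#' factor.
#'
#' @param data Phenotype tibble.
#' @param response Response column name.
#' @param terms List of candidate terms (character vectors or dot-joined
#'   strings).
#' @param alpha Significance level for the keep flag; default 0.05.
#' @return Tibble with one row per term: `term`, `df`, `sumsq`,
#'   `statistic`, `p_value`, `keep`.
#' @export
screen_fixed_effects <- function(data, response, terms, alpha = 0.05) {
  stopifnot(length(terms) >= 1)
  data <- tibble::as_tibble(data)
  terms <- lapply(terms, function(tm) {
    if (length(tm) == 1 && grepl(".", tm, fixed = TRUE) &&
        !tm %in% names(data)) {
      strsplit(tm, ".", fixed = TRUE)[[1]]
    } else as.character(tm)
  })
  dd <- tibble::tibble(.y = as.numeric(data[[response]]))
  labels <- character(length(terms))
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    labels[k] <- paste(tm, collapse = ".")
    if (length(tm) == 1 && is.numeric(data[[tm]])) {
      dd[[labels[k]]] <- as.numeric(data[[tm]])
    } else {
      dd[[labels[k]]] <- build_contemporary_groups(data, tm)
    }
  }
  dd <- dd[stats::complete.cases(dd), , drop = FALSE]
  fml <- stats::reformulate(sprintf("`%s`", labels), response = ".y")
  fit <- stats::lm(fml, data = dd)
  if (stats::df.residual(fit) <= 0) {
    stop("saturated model: no residual degrees of freedom for screening")
  }
  av <- stats::anova(fit)
  rows <- seq_len(nrow(av) - 1L)
  tibble::tibble(
    term = gsub("`", "", rownames(av)[rows]),
    df = av$Df[rows],
    sumsq = av$`Sum Sq`[rows],
    statistic = av$`F value`[rows],
    p_value = av$`Pr(>F)`[rows],
    keep = av$`Pr(>F)`[rows] < alpha
  )
}
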