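#' Restricted log-likelihood of a repeatability animal model
#'
#' Evaluates the REML log-likelihood of the data in a [build_design()]
#' structure at fixed variance components, either through the sparse
#' mixed-model-equations factorisation (`method = "mme"`, the production
#' path) or by direct dense evaluation of the projection form
#' `-0.5 [ (n-p) log 2pi + log|V| + log|X'V^-1X| + y'Py ]`
#' (`method = "dense"`, an independent cross-check suitable for small
#' instances). Both paths agree to numerical precision.
#'
#' @param design A univariate [build_design()] result.
#' @param components List with `sigma2` (named numeric, one entry per random
#'   term of the design; may be empty) and `sigma2_e` (residual variance).
#' @param pedigree Pedigree, required when the design has a
#'   pedigree-covariance term.
#' @param method `"mme"` or `"dense"`.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(design, components, pedigree = NULL,
                              method = c("mme", "dense")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "design_set"))
  s2 <- components$sigma2 %||% numeric(0)
  s2e <- components$sigma2_e
  stopifnot(is.numeric(s2e), s2e > 0)
  if (length(design$random) && !setequal(names(s2), names(design$random))) {
    stop("components$sigma2 must be named after the design's random terms: ",
         paste(names(design$random), collapse = ", "))
  }
  if (method == "mme") {
    model <- new_mme_model(list(design), pedigree)
    comps <- list(terms = lapply(names(model$terms), function(nm)
      matrix(s2[[nm]], 1, 1)), resid = matrix(s2e, 1, 1))
    names(comps$terms) <- names(model$terms)
    return(mme_eval(model, comps_to_theta(model, comps)))
  }
  ## dense projection-matrix form
  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  V <- diag(s2e, n)
  for (nm in names(design$random)) {
    blk <- design$random[[nm]]
    Zd <- as.matrix(blk$Z)
    K <- if (blk$covariance == "pedigree") {
      as.matrix(relationship_matrix(pedigree, sparse_from = Inf))
    } else diag(ncol(Zd))
    V <- V + s2[[nm]] * Zd %*% K %*% t(Zd)
  }
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  Py <- Vi %*% y - Vi %*% X %*% solve(XtViX, crossprod(X, Vi %*% y))
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
            sum(y * Py))
}

.default_start_uni <- function(design) {
  ry <- qr.resid(qr(design$X), design$y)
  v0 <- stats::var(ry)
  k <- length(design$random)
  s2 <- numeric(0)
  if (k) {
    s2 <- vapply(design$random, function(b)
      if (b$covariance == "pedigree") 0.3 * v0 else 0.15 * v0, 0)
  }
  list(sigma2 = s2, sigma2_e = max(v0 - sum(s2), 0.3 * v0))
}

.additive_term <- function(terms) {
  ped <- names(terms)[vapply(terms, function(t) t$covariance == "pedigree",
                             TRUE)]
  if (length(ped) > 1) stop("more than one pedigree-covariance term")
  if (length(ped) == 1) return(ped)
  ## identity-kinship animal term (e.g. the balanced unrelated-animal design)
  if ("animal" %in% names(terms)) return("animal")
  NA_character_
}

## delta-method SEs of derived quantities: J %*% cov_theta %*% t(J) with J
## the (central finite-difference) Jacobian of the smooth transformation
## theta -> derived.  No refitting involved.
.delta_se <- function(fun, theta, cov_theta, h = 1e-6) {
  d0 <- fun(theta)
  J <- matrix(0, length(d0), length(theta))
  for (m in seq_along(theta)) {
    tp <- theta; tp[m] <- tp[m] + h
    tm <- theta; tm[m] <- tm[m] - h
    J[, m] <- (fun(tp) - fun(tm)) / (2 * h)
  }
  V <- J %*% cov_theta %*% t(J)
  list(value = d0, se = sqrt(pmax(diag(V), 0)))
}

#' Univariate REML fit of the repeatability animal model
#'
#' Maximises the restricted likelihood over the model's variance components
#' by average-information updates on the log-variance scale with a monotone
#' step-halving safeguard, then derives heritability
#' `h2 = sigma2_a / sigma2_p` and repeatability
#' `(sigma2_a + sum sigma2_pe) / sigma2_p` with delta-method standard errors
#' from the inverse average-information matrix.
#'
#' Additive and permanent-environmental variances are separable only through
#' pedigree covariance between animals; a specification with two
#' identity-covariance terms of identical incidence is refused.
#'
#' @param design A [build_design()] result.
#' @param pedigree Pedigree object (needed for pedigree-covariance terms).
#' @param init Optional starting values, `list(sigma2 = c(...), sigma2_e =)`.
#' @param control A [reml_control()].
#' @return An object of class `"reml_fit"`; see [tidy.reml_fit()].
#' @export
fit_univariate <- function(design, pedigree = NULL, init = NULL,
                           control = reml_control()) {
  stopifnot(inherits(design, "design_set"))
  model <- new_mme_model(list(design), pedigree)
  init <- init %||% .default_start_uni(design)
  comps0 <- list(terms = lapply(names(model$terms), function(nm)
    matrix(init$sigma2[[nm]], 1, 1)), resid = matrix(init$sigma2_e, 1, 1))
  names(comps0$terms) <- names(model$terms)
  res <- ai_reml(model, comps_to_theta(model, comps0), control)

  add <- .additive_term(model$terms)
  pe_terms <- setdiff(names(model$terms), add)
  has_repeats <- length(pe_terms) > 0 ||
    (!is.null(design$animals) && any(duplicated(design$animals)))

  derive <- function(theta) {
    cm <- theta_to_comps(model, theta)
    s2 <- vapply(cm$terms, function(S) S[1, 1], 0)
    s2e <- cm$resid[1, 1]
    s2p <- sum(s2) + s2e
    s2a <- if (!is.na(add)) s2[[add]] else 0
    c(s2, sigma2_e = s2e, sigma2_p = s2p,
      h2 = if (!is.na(add)) s2a / s2p else NA_real_,
      repeatability = if (has_repeats) (s2a + sum(s2[pe_terms])) / s2p
                      else NA_real_)
  }
  dd <- .delta_se(derive, res$theta, res$cov_theta)
  nm <- names(derive(res$theta))
  est <- stats::setNames(dd$value, nm)
  se <- stats::setNames(dd$se, nm)
  se[is.na(est)] <- NA_real_

  ratios <- tibble::tibble(
    quantity = c("sigma2_p", "h2", "repeatability"),
    estimate = unname(est[c("sigma2_p", "h2", "repeatability")]),
    std.error = unname(se[c("sigma2_p", "h2", "repeatability")])
  )
  vc_names <- setdiff(nm, c("sigma2_p", "h2", "repeatability"))
  varcomp <- tibble::tibble(component = vc_names,
                            estimate = unname(est[vc_names]),
                            std.error = unname(se[vc_names]))

  structure(list(
    type = "univariate", traits = design$response,
    components = theta_to_comps(model, res$theta),
    varcomp = varcomp, ratios = ratios,
    sigma_p = sqrt(est[["sigma2_p"]]),
    loglik = res$loglik, converged = res$converged,
    iterations = res$iterations, boundary = res$boundary,
    gradient = res$gradient, ai = res$ai, cov_theta = res$cov_theta,
    theta = res$theta, trace = res$trace,
    n = model$n, p = model$p,
    n_animals = if (!is.null(design$animals))
      length(unique(design$animals)) else NA_integer_,
    term_names = names(model$terms), additive_term = add
  ), class = "reml_fit")
}

#' Bivariate REML fit: genetic and phenotypic correlations
#'
#' Jointly fits two traits under the repeatability animal model, estimating
#' 2x2 additive-genetic (and per-term permanent-environmental) covariance
#' matrices with log-Cholesky parameterisation (so they stay positive
#' semi-definite and correlations stay in \[-1, 1\]). The residual
#' covariance is estimated only when the traits are co-recorded on the same
#' record rows (`residual_cov = "paired"`, matched by `pair_key`); for
#' traits never observed together it is fixed at zero and their correlation
#' flows through pedigree links.
#'
#' Derived quantities: `r_g` (genetic correlation), `r_p` (phenotypic
#' correlation from the summed covariance matrices), `r_e` (residual,
#' paired case only), per-trait `h2`, with delta-method standard errors.
#'
#' @param design1,design2 [build_design()] results for the two traits.
#' @param pedigree Pedigree object.
#' @param residual_cov `"independent"` (residual covariance fixed at 0) or
#'   `"paired"`.
#' @param pair_key Column (present in both designs' data) identifying
#'   co-observed records when `residual_cov = "paired"`.
#' @param start Optional list of two univariate `"reml_fit"`s used as
#'   starting values (recommended; they are fitted internally otherwise).
#' @param control A [reml_control()].
#' @return An object of class `"reml_fit"`.
#' @export
fit_bivariate <- function(design1, design2, pedigree = NULL,
                          residual_cov = c("independent", "paired"),
                          pair_key = NULL, start = NULL,
                          control = reml_control()) {
  residual_cov <- match.arg(residual_cov)
  for (d in list(design1, design2)) {
    if (stats::var(d$y) == 0) stop("response '", d$response,
                                   "' has no variance")
  }
  model <- new_mme_model(list(design1, design2), pedigree,
                         residual_cov = residual_cov, pair_key = pair_key)
  if (is.null(start)) {
    start <- list(fit_univariate(design1, pedigree, control = control),
                  fit_univariate(design2, pedigree, control = control))
  }
  uni_s2 <- lapply(start, function(f) {
    s <- vapply(f$components$terms, function(S) S[1, 1], 0)
    c(s, sigma2_e = f$components$resid[1, 1])
  })

  comps0 <- list(terms = list(), resid = NULL)
  for (nm in names(model$terms)) {
    tk <- model$terms[[nm]]
    vs <- vapply(tk$traits, function(t) {
      v <- uni_s2[[t]][nm]
      if (is.na(v)) 0.1 * stats::var(model$designs[[t]]$y) else v
    }, 0)
    S <- diag(vs, nrow = tk$nt)
    ## tiny non-zero start keeps the coefficient-matrix sparsity pattern
    ## stable across evaluations (the symbolic factorisation is cached)
    if (tk$nt == 2) S[1, 2] <- S[2, 1] <- 1e-4 * sqrt(prod(vs))
    comps0$terms[[nm]] <- S
  }
  ve <- vapply(1:2, function(t) uni_s2[[t]][["sigma2_e"]], 0)
  comps0$resid <- if (residual_cov == "paired") {
    matrix(c(ve[1], 0.1 * sqrt(prod(ve)), 0.1 * sqrt(prod(ve)), ve[2]), 2, 2)
  } else diag(ve)

  res <- ai_reml(model, comps_to_theta(model, comps0), control)

  add <- .additive_term(model$terms)
  if (is.na(add)) stop("bivariate fit needs an additive (pedigree) term")
  pe_terms <- setdiff(names(model$terms), add)

  expand2 <- function(S, traits) {
    M <- matrix(0, 2, 2)
    M[traits, traits] <- S
    M
  }
  derive <- function(theta) {
    cm <- theta_to_comps(model, theta)
    Sa <- expand2(cm$terms[[add]], model$terms[[add]]$traits)
    P <- Sa
    if (model$residual_cov == "paired") P <- P + cm$resid
    else P <- P + diag(diag(cm$resid))
    for (nm in pe_terms) {
      P <- P + expand2(cm$terms[[nm]], model$terms[[nm]]$traits)
    }
    r_g <- Sa[1, 2] / sqrt(Sa[1, 1] * Sa[2, 2])
    r_p <- P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    r_e <- if (model$residual_cov == "paired") {
      cm$resid[1, 2] / sqrt(cm$resid[1, 1] * cm$resid[2, 2])
    } else NA_real_
    c(r_g = r_g, r_p = r_p, r_e = r_e,
      h2_1 = Sa[1, 1] / P[1, 1], h2_2 = Sa[2, 2] / P[2, 2],
      sigma_a12 = Sa[1, 2], sigma_p1 = P[1, 1], sigma_p2 = P[2, 2])
  }
  dd <- .delta_se(derive, res$theta, res$cov_theta)
  nm <- names(derive(res$theta))
  est <- stats::setNames(dd$value, nm)
  se <- stats::setNames(dd$se, nm)
  se[is.na(est)] <- NA_real_

  ratios <- tibble::tibble(
    quantity = c("r_g", "r_p", "r_e", "h2_1", "h2_2"),
    estimate = unname(est[c("r_g", "r_p", "r_e", "h2_1", "h2_2")]),
    std.error = unname(se[c("r_g", "r_p", "r_e", "h2_1", "h2_2")])
  )
  cm <- theta_to_comps(model, res$theta)
  vc <- list()
  for (nmt in names(cm$terms)) {
    S <- cm$terms[[nmt]]
    tr <- model$terms[[nmt]]$traits
    lab <- outer(tr, tr, function(i, j) paste0(nmt, "[", i, ",", j, "]"))
    keep <- lower.tri(S, diag = TRUE)
    vc[[nmt]] <- tibble::tibble(component = lab[keep], estimate = S[keep])
  }
  Sr <- cm$resid
  lab <- outer(1:2, 1:2, function(i, j) paste0("residual[", i, ",", j, "]"))
  keepr <- if (model$residual_cov == "paired") lower.tri(Sr, diag = TRUE)
           else diag(2) == 1
  vc$residual <- tibble::tibble(component = lab[keepr], estimate = Sr[keepr])
  varcomp <- dplyr::bind_rows(vc)

  structure(list(
    type = "bivariate", traits = c(design1$response, design2$response),
    components = cm, varcomp = varcomp, ratios = ratios,
    sigma_p = sqrt(est[c("sigma_p1", "sigma_p2")]),
    loglik = res$loglik, converged = res$converged,
    iterations = res$iterations, boundary = res$boundary,
    gradient = res$gradient, ai = res$ai, cov_theta = res$cov_theta,
    theta = res$theta, trace = res$trace,
    n = model$n, p = model$p,
    n_animals = NA_integer_,
    term_names = names(model$terms), additive_term = add
  ), class = "reml_fit")
}

#' Wald significance flag for a correlation (or any estimate)
#'
#' Two-sided z-test: significant when `|estimate/se| > z_(1-alpha/2)`.
#'
#' @param estimate,se Estimate and its standard error (`se > 0`).
#' @param alpha Significance level (default 0.05).
#' @return Logical vector.
#' @examples
#' significance(0.31, 0.09) # TRUE  (z = 3.44)
#' significance(0.13, 0.15) # FALSE
#' @export
significance <- function(estimate, se, alpha = 0.05) {
  stopifnot(all(se > 0, na.rm = TRUE))
  abs(estimate / se) > stats::qnorm(1 - alpha / 2)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("%s REML fit: %s\n", tools::toTitleCase(x$type),
              paste(x$traits, collapse = " x ")))
  cat(sprintf("  logLik %.4f after %d AI iterations (%s%s)\n", x$loglik,
              x$iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$boundary) ", at variance floor" else ""))
  cat("  variance components:\n")
  vc <- x$varcomp
  for (i in seq_len(nrow(vc))) {
    cat(sprintf("    %-14s %10.5g", vc$component[i], vc$estimate[i]))
    if (!is.null(vc$std.error) && !is.na(vc$std.error[i])) {
      cat(sprintf("  (%.3g)", vc$std.error[i]))
    }
    cat("\n")
  }
  cat("  derived:\n")
  r <- x$ratios[!is.na(x$ratios$estimate), ]
  for (i in seq_len(nrow(r))) {
    cat(sprintf("    %-14s %8.4f (%.4f)\n", r$quantity[i], r$estimate[i],
                r$std.error[i]))
  }
  invisible(x)
}

#' Tidy a REML fit
#'
#' @param x A `"reml_fit"` object.
#' @param ... Unused.
#' @return Tibble with columns `component`, `estimate`, `std.error` and
#'   `type` (`"variance"` or `"derived"`), covering the variance components
#'   and the derived ratios/correlations.
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) {
  vc <- x$varcomp
  if (is.null(vc$std.error)) vc$std.error <- NA_real_
  dplyr::bind_rows(
    dplyr::mutate(vc, type = "variance"),
    dplyr::mutate(dplyr::rename(x$ratios, component = "quantity"),
                  type = "derived")
  )
}

#' One-row summary of a REML fit
#'
#' @param x A `"reml_fit"` object.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `converged`, `iterations`, `boundary`,
#'   `n_records`, `n_fixed`.
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 iterations = x$iterations, boundary = x$boundary,
                 n_records = x$n, n_fixed = x$p)
}

#' Plot a REML fit
#'
#' Shows the derived quantities (heritability, repeatability, correlations)
#' with 95% Wald intervals, and the restricted-likelihood trace across AI
#' iterations.
#'
#' @param object A `"reml_fit"` object.
#' @param which `"estimates"` or `"trace"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reml_fit
#' @export
autoplot.reml_fit <- function(object, which = c("estimates", "trace"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    df <- tibble::tibble(iteration = seq_along(object$trace) - 1,
                         logLik = object$trace)
    return(ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$logLik)) +
             ggplot2::geom_line() + ggplot2::geom_point() +
             ggplot2::labs(title = "Restricted likelihood trace",
                           x = "AI iteration", y = "log restricted likelihood"))
  }
  df <- object$ratios[!is.na(object$ratios$estimate), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$quantity, .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$std.error,
      ymax = .data$estimate + 1.96 * .data$std.error), width = 0.15) +
    ggplot2::labs(title = paste("REML estimates:",
                                paste(object$traits, collapse = " x ")),
                  x = NULL, y = "estimate")
}
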