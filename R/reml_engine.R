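## Internal mixed-model-equations engine for (bi)variate REML under the
## repeatability animal model
##   y = Xb + Za + W_w pe_w + W_y pe_y + e,
## var(a) = A sigma2_a (Kronecker with the 2x2 genetic covariance in the
## bivariate case), var(pe) = I sigma2_pe, var(e) = I sigma2_e.
##
## The restricted log-likelihood is evaluated through the sparse Cholesky
## factorisation of the MME coefficient matrix
##   C = W' R^-1 W + blockdiag(0_p, Ginv_1, ..., Ginv_K),
## using  log|V| + log|X'V^-1 X| = log|R| + sum log|G_k| + log|C|  and
## y'Py = y'R^-1 y - rhs' sol.  The symbolic factorisation is cached and
## re-used across evaluations (the sparsity pattern is fixed).

new_mme_model <- function(designs, pedigree = NULL,
                          residual_cov = c("independent", "paired"),
                          pair_key = NULL) {
  residual_cov <- match.arg(residual_cov)
  Tn <- length(designs)
  stopifnot(Tn %in% 1:2)
  ns <- vapply(designs, function(d) d$n, 0L)
  n <- sum(ns)
  offset <- cumsum(c(0L, ns))[seq_len(Tn)]
  trait_of_row <- rep(seq_len(Tn), ns)
  y <- unlist(lapply(designs, `[[`, "y"), use.names = FALSE)

  Xs <- lapply(designs, function(d) methods::as(Matrix::Matrix(d$X, sparse = TRUE),
                                               "generalMatrix"))
  X <- if (Tn == 1) Xs[[1]] else Matrix::bdiag(Xs)
  p <- ncol(X)

  ## ---- random terms: union across traits, by name -------------------------
  term_names <- unique(unlist(lapply(designs, function(d) names(d$random))))
  Ainv <- NULL
  terms <- list()
  for (nm in term_names) {
    present <- which(vapply(designs, function(d) nm %in% names(d$random), TRUE))
    covk <- unique(vapply(present, function(t) designs[[t]]$random[[nm]]$covariance, ""))
    if (length(covk) != 1) stop("random term '", nm,
                                "' has conflicting covariance kinds across traits")
    nt <- length(present)
    if (covk == "pedigree") {
      if (is.null(Ainv)) {
        stopifnot(inherits(pedigree, "pedigree"))
        Ainv <- relationship_inverse(pedigree)
      }
      q <- nrow(Ainv)
      lv <- rownames(Ainv)
      jmaps <- lapply(present, function(t) {
        Zt <- designs[[t]]$random[[nm]]$Z
        stopifnot(ncol(Zt) == q)
        Matrix::mat2triplet(Zt)$j[order(Matrix::mat2triplet(Zt)$i)]
      })
    } else {
      lv <- sort(unique(unlist(lapply(present, function(t)
        designs[[t]]$random[[nm]]$levels))), method = "radix")
      q <- length(lv)
      jmaps <- lapply(present, function(t) {
        tr <- Matrix::mat2triplet(designs[[t]]$random[[nm]]$Z)
        match(designs[[t]]$random[[nm]]$levels, lv)[tr$j[order(tr$i)]]
      })
    }
    ii <- jj <- integer(0)
    for (s in seq_along(present)) {
      t <- present[s]
      ii <- c(ii, offset[t] + seq_len(ns[t]))
      jj <- c(jj, (s - 1L) * q + jmaps[[s]])
    }
    Z <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, nt * q))
    terms[[nm]] <- list(name = nm, Z = Z, q = q, nt = nt, traits = present,
                        covariance = covk, levels = lv)
  }

  ## identifiability: additive + PE separable only through pedigree covariance
  idmaps <- lapply(terms, function(tk) {
    if (tk$nt == 1) paste(Matrix::mat2triplet(tk$Z)$j[order(Matrix::mat2triplet(tk$Z)$i)])
    else NULL
  })
  idn <- names(terms)
  for (a in seq_along(terms)) {
    for (b in seq_len(a - 1L)) {
      if (!is.null(idmaps[[a]]) && !is.null(idmaps[[b]]) &&
          terms[[a]]$covariance == "identity" &&
          terms[[b]]$covariance == "identity" &&
          identical(idmaps[[a]], idmaps[[b]])) {
        stop("random terms '", idn[a], "' and '", idn[b],
             "' have identical incidence and identity covariance: ",
             "their variances are not separately identifiable. ",
             "Use pedigree covariance on the additive term or drop one.")
      }
    }
  }

  W <- if (length(terms)) do.call(cbind, c(list(X), lapply(terms, `[[`, "Z"))) else X
  cols <- p
  for (nm in names(terms)) {
    terms[[nm]]$idx <- cols + seq_len(terms[[nm]]$nt * terms[[nm]]$q)
    cols <- cols + terms[[nm]]$nt * terms[[nm]]$q
  }

  ## ---- residual structure -------------------------------------------------
  pairs <- NULL
  if (residual_cov == "paired") {
    if (Tn != 2) stop("paired residuals need two traits")
    key <- pair_key %||% "record"
    k1 <- designs[[1]]$data[[key]]
    k2 <- designs[[2]]$data[[key]]
    if (is.null(k1) || is.null(k2)) {
      stop("pair_key column '", key, "' not found in both designs")
    }
    m <- match(as.character(k1), as.character(k2))
    i1 <- which(!is.na(m))
    pairs <- cbind(i1, offset[2] + m[i1])
  }

  rows_t <- split(seq_len(n), trait_of_row)
  paired_rows <- if (!is.null(pairs)) c(pairs) else integer(0)
  unpaired_t <- lapply(rows_t, function(r) setdiff(r, paired_rows))

  ## precomputed cross-products so each likelihood evaluation is a scalar
  ## combination of fixed sparse matrices
  Wt <- Matrix::t(W)
  pre <- list()
  pre$U <- lapply(unpaired_t, function(r)
    list(WtW = Matrix::crossprod(W[r, , drop = FALSE]),
         Wty = as.numeric(Wt[, r, drop = FALSE] %*% y[r]),
         yy = sum(y[r]^2), n = length(r)))
  if (!is.null(pairs)) {
    W1 <- W[pairs[, 1], , drop = FALSE]; W2 <- W[pairs[, 2], , drop = FALSE]
    y1 <- y[pairs[, 1]]; y2 <- y[pairs[, 2]]
    pre$P <- list(
      W11 = Matrix::crossprod(W1), W22 = Matrix::crossprod(W2),
      W12 = Matrix::forceSymmetric(Matrix::crossprod(W1, W2) +
                                   Matrix::crossprod(W2, W1), "U"),
      Wty1 = as.numeric(Matrix::crossprod(W1, y1)),
      Wty2 = as.numeric(Matrix::crossprod(W2, y2)),
      Wty12 = as.numeric(Matrix::crossprod(W1, y2) + Matrix::crossprod(W2, y1)),
      y11 = sum(y1^2), y22 = sum(y2^2), y12 = sum(y1 * y2),
      n = nrow(pairs))
  }

  kin <- list()
  if (!is.null(Ainv)) {
    kin$Ainv <- Ainv
    kin$logdetA <- attr(Ainv, "logdet")
    kin$Afac <- Matrix::Cholesky(Ainv, LDL = TRUE, perm = TRUE)
  }

  ## ---- parameter map ------------------------------------------------------
  pmap <- list(); pos <- 0L
  for (nm in names(terms)) {
    np <- if (terms[[nm]]$nt == 2) 3L else 1L
    pmap[[nm]] <- list(kind = "term", term = nm,
                       type = if (np == 3) "cov2" else "var1",
                       idx = pos + seq_len(np))
    pos <- pos + np
  }
  if (residual_cov == "paired") {
    pmap[["residual"]] <- list(kind = "resid", type = "cov2", idx = pos + 1:3)
    pos <- pos + 3L
  } else {
    pmap[["residual"]] <- list(kind = "resid", type = "var_t",
                               idx = pos + seq_len(Tn))
    pos <- pos + Tn
  }

  env <- new.env(parent = emptyenv()) # caches the symbolic factorisation
  structure(list(
    designs = designs, ntraits = Tn, n = n, ns = ns, p = p,
    y = y, X = X, W = W, Wt = Wt, terms = terms, kin = kin,
    trait_of_row = trait_of_row, rows_t = rows_t, unpaired_t = unpaired_t,
    pairs = pairs, residual_cov = residual_cov, pre = pre,
    pmap = pmap, npar = pos, cache = env
  ), class = "mme_model")
}

## ---- parameterisation -----------------------------------------------------
## variances on the log scale; 2x2 covariance blocks via log-Cholesky
## L = [[exp(l11), 0], [l21, exp(l22)]], Sigma = L L'.

.chol2_to_sigma <- function(th3) {
  a <- exp(th3[1]); c <- th3[2]; b <- exp(th3[3])
  matrix(c(a^2, a * c, a * c, c^2 + b^2), 2, 2)
}

.sigma_to_chol2 <- function(S) {
  a <- sqrt(S[1, 1]); c <- S[1, 2] / a
  b2 <- S[2, 2] - c^2
  c(log(a), c, 0.5 * log(max(b2, 1e-12 * S[2, 2], 1e-300)))
}

.chol2_dsigma <- function(th3, m) {
  a <- exp(th3[1]); c <- th3[2]; b <- exp(th3[3])
  switch(m,
    matrix(c(2 * a^2, a * c, a * c, 0), 2, 2),
    matrix(c(0, a, a, 2 * c), 2, 2),
    matrix(c(0, 0, 0, 2 * b^2), 2, 2))
}

theta_to_comps <- function(model, theta) {
  out <- list(terms = list())
  for (nm in names(model$terms)) {
    pm <- model$pmap[[nm]]
    out$terms[[nm]] <- if (pm$type == "cov2") .chol2_to_sigma(theta[pm$idx])
                       else matrix(exp(theta[pm$idx]), 1, 1)
  }
  pmr <- model$pmap$residual
  out$resid <- if (pmr$type == "cov2") .chol2_to_sigma(theta[pmr$idx])
               else diag(exp(theta[pmr$idx]), nrow = model$ntraits)
  out
}

comps_to_theta <- function(model, comps) {
  theta <- numeric(model$npar)
  for (nm in names(model$terms)) {
    pm <- model$pmap[[nm]]
    S <- comps$terms[[nm]]
    theta[pm$idx] <- if (pm$type == "cov2") .sigma_to_chol2(S) else log(S[1, 1])
  }
  pmr <- model$pmap$residual
  theta[pmr$idx] <- if (pmr$type == "cov2") .sigma_to_chol2(comps$resid)
                    else log(diag(as.matrix(comps$resid)))
  theta
}

## ---- residual helpers -----------------------------------------------------

.resid_inv_coefs <- function(model, Se) {
  if (model$residual_cov == "paired") {
    Einv <- solve(Se)
    list(u = 1 / diag(Se), e11 = Einv[1, 1], e22 = Einv[2, 2],
         e12 = Einv[1, 2])
  } else {
    list(u = 1 / diag(as.matrix(Se)))
  }
}

.logdetR <- function(model, Se) {
  if (model$residual_cov == "paired") {
    npair <- model$pre$P$n
    npair * determinant(Se, logarithm = TRUE)$modulus +
      sum(vapply(1:2, function(t) length(model$unpaired_t[[t]]) *
                   log(Se[t, t]), 0))
  } else {
    sum(vapply(seq_len(model$ntraits), function(t)
      model$ns[t] * log(as.matrix(Se)[t, t]), 0))
  }
}

## apply R^-1 (or a symmetric 2x2-block matrix S on the residual structure)
## to a vector
.apply_resid <- function(model, coefs, v) {
  out <- numeric(model$n)
  for (t in seq_len(model$ntraits)) {
    r <- model$unpaired_t[[t]]
    out[r] <- coefs$u[t] * v[r]
  }
  if (!is.null(model$pairs)) {
    i1 <- model$pairs[, 1]; i2 <- model$pairs[, 2]
    out[i1] <- coefs$e11 * v[i1] + coefs$e12 * v[i2]
    out[i2] <- coefs$e12 * v[i1] + coefs$e22 * v[i2]
  }
  out
}

## ---- likelihood -----------------------------------------------------------

mme_eval <- function(model, theta, want_state = FALSE) {
  comps <- theta_to_comps(model, theta)
  rc <- .resid_inv_coefs(model, comps$resid)

  ## W' R^-1 W, W' R^-1 y, y' R^-1 y from precomputed pieces
  if (model$residual_cov == "paired") {
    P <- model$pre$P; U <- model$pre$U
    WtRW <- rc$e11 * P$W11 + rc$e22 * P$W22 + rc$e12 * P$W12
    rhs <- rc$e11 * P$Wty1 + rc$e22 * P$Wty2 + rc$e12 * P$Wty12
    ytRy <- rc$e11 * P$y11 + rc$e22 * P$y22 + 2 * rc$e12 * P$y12
    for (t in seq_along(U)) {
      if (U[[t]]$n) {
        WtRW <- WtRW + rc$u[t] * U[[t]]$WtW
        rhs <- rhs + rc$u[t] * U[[t]]$Wty
        ytRy <- ytRy + rc$u[t] * U[[t]]$yy
      }
    }
  } else {
    U <- model$pre$U
    WtRW <- rc$u[1] * U[[1]]$WtW
    rhs <- rc$u[1] * U[[1]]$Wty
    ytRy <- rc$u[1] * U[[1]]$yy
    if (model$ntraits == 2) {
      WtRW <- WtRW + rc$u[2] * U[[2]]$WtW
      rhs <- rhs + rc$u[2] * U[[2]]$Wty
      ytRy <- ytRy + rc$u[2] * U[[2]]$yy
    }
  }

  logdetG <- 0
  Gblocks <- list(Matrix::Matrix(0, model$p, model$p, sparse = TRUE))
  for (nm in names(model$terms)) {
    tk <- model$terms[[nm]]
    Sk <- comps$terms[[nm]]
    Sinv <- solve(Sk)
    Q <- if (tk$covariance == "pedigree") model$kin$Ainv
         else Matrix::Diagonal(tk$q)
    Gb <- if (tk$nt == 1) Sinv[1, 1] * Q else Matrix::kronecker(Sinv, Q)
    Gblocks[[length(Gblocks) + 1L]] <- Gb
    ldK <- if (tk$covariance == "pedigree") model$kin$logdetA else 0
    logdetG <- logdetG + tk$q * determinant(Sk, logarithm = TRUE)$modulus +
      tk$nt * ldK
  }
  C <- Matrix::forceSymmetric(WtRW + Matrix::bdiag(Gblocks), "U")
  C <- methods::as(C, "CsparseMatrix")

  ch <- model$cache$chol
  ok <- FALSE
  if (!is.null(ch)) {
    ch <- tryCatch({ r <- Matrix::update(ch, C); ok <- TRUE; r },
                   error = function(e) NULL)
  }
  if (!ok) {
    ch <- tryCatch(Matrix::Cholesky(C, LDL = TRUE, perm = TRUE),
                   error = function(e) stop(
                     "mixed-model coefficient matrix is not positive ",
                     "definite (singular V?): ", conditionMessage(e)))
    model$cache$chol <- ch
  }
  logdetC <- as.numeric(2 * Matrix::determinant(ch, sqrt = TRUE)$modulus)
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  yPy <- ytRy - sum(rhs * sol)
  ll <- -0.5 * ((model$n - model$p) * log(2 * pi) + .logdetR(model, comps$resid) +
                  as.numeric(logdetG) + logdetC + yPy)
  if (!want_state) return(ll)
  list(ll = ll, chol = ch, sol = sol, comps = comps, rc = rc)
}

## apply (Sigma_dot kron K) to the stacked effect vector of one term
.apply_term_cov <- function(model, tk, Sdot, v) {
  U <- matrix(v, tk$q, tk$nt)
  if (tk$covariance == "pedigree") {
    U <- as.matrix(Matrix::solve(model$kin$Afac, U, system = "A"))
  }
  as.numeric(U %*% Sdot)
}

## V_dot[m] %*% Py for every working parameter m
.ai_f_vectors <- function(model, theta, state, Py) {
  fs <- matrix(0, model$n, model$npar)
  for (nm in names(model$pmap)) {
    pm <- model$pmap[[nm]]
    if (pm$kind == "term") {
      tk <- model$terms[[nm]]
      ZtPy <- as.numeric(Matrix::crossprod(tk$Z, Py))
      for (s in seq_along(pm$idx)) {
        Sdot <- if (pm$type == "cov2") .chol2_dsigma(theta[pm$idx], s)
                else matrix(exp(theta[pm$idx]), 1, 1)
        fs[, pm$idx[s]] <- as.numeric(tk$Z %*%
                                        .apply_term_cov(model, tk, Sdot, ZtPy))
      }
    } else {
      if (pm$type == "cov2") {
        for (s in 1:3) {
          Sdot <- .chol2_dsigma(theta[pm$idx], s)
          co <- list(u = diag(Sdot), e11 = Sdot[1, 1], e22 = Sdot[2, 2],
                     e12 = Sdot[1, 2])
          fs[, pm$idx[s]] <- .apply_resid(model, co, Py)
        }
      } else {
        for (t in seq_len(model$ntraits)) {
          r <- model$rows_t[[t]]
          fs[r, pm$idx[t]] <- exp(theta[pm$idx[t]]) * Py[r]
        }
      }
    }
  }
  fs
}

## average-information matrix on the working-parameter scale
mme_ai_matrix <- function(model, theta, state) {
  e <- model$y - as.numeric(model$W %*% state$sol)
  Py <- .apply_resid(model, state$rc, e)
  fs <- .ai_f_vectors(model, theta, state, Py)
  gs <- matrix(0, model$n, model$npar)
  for (m in seq_len(model$npar)) {
    Rf <- .apply_resid(model, state$rc, fs[, m])
    s <- Matrix::solve(state$chol,
                       as.numeric(Matrix::crossprod(model$W, Rf)),
                       system = "A")
    gs[, m] <- Rf - .apply_resid(model, state$rc,
                                 as.numeric(model$W %*% s))
  }
  AI <- 0.5 * crossprod(fs, gs)
  (AI + t(AI)) / 2
}

mme_fd_grad <- function(model, theta, h = 1e-4) {
  g <- numeric(model$npar)
  for (m in seq_len(model$npar)) {
    tp <- theta; tp[m] <- tp[m] + h
    tm <- theta; tm[m] <- tm[m] - h
    g[m] <- (mme_eval(model, tp) - mme_eval(model, tm)) / (2 * h)
  }
  g
}

## ---- AI-REML driver -------------------------------------------------------

ai_reml <- function(model, theta0, control) {
  theta <- theta0
  vary <- stats::var(model$y)
  floor_log <- log(control$floor_frac * vary)
  var_idx <- unlist(lapply(model$pmap, function(pm) {
    if (pm$type == "cov2") pm$idx[c(1, 3)] else pm$idx
  }), use.names = FALSE)
  chol_floor <- 0.5 * floor_log # l11/l22 are log-sd-like
  clamp <- function(th) {
    for (nm in names(model$pmap)) {
      pm <- model$pmap[[nm]]
      if (pm$type == "cov2") {
        th[pm$idx[c(1, 3)]] <- pmax(th[pm$idx[c(1, 3)]], chol_floor)
        th[pm$idx[2]] <- pmin(pmax(th[pm$idx[2]], -1e6), 1e6)
      } else {
        th[pm$idx] <- pmax(th[pm$idx], floor_log)
      }
    }
    th
  }
  theta <- clamp(theta)
  state <- mme_eval(model, theta, want_state = TRUE)
  ll <- state$ll
  trace <- ll
  converged <- FALSE
  iter <- 0L
  grad <- rep(NA_real_, model$npar)
  AI <- diag(model$npar)
  ## the attainable precision scales with |logLik|: both the line-search
  ## acceptance and the gradient norm are limited by the rounding noise of
  ## the factorised likelihood (~ 1e-10 relative per evaluation)
  gtol <- function(ll) max(control$tol_grad, 1e-8 * (1 + abs(ll)))
  acc_tol <- function(ll) 1e-10 * (1 + abs(ll))
  while (iter < control$max_iter) {
    iter <- iter + 1L
    grad <- mme_fd_grad(model, theta, h = control$fd_step)
    AI <- mme_ai_matrix(model, theta, state)
    ## ascent direction: AI approximates the observed information
    dir <- tryCatch(solve(AI + diag(1e-8 * max(diag(AI), 1), model$npar), grad),
                    error = function(e) grad / max(abs(grad), 1))
    if (max(abs(dir)) > control$max_step) {
      dir <- dir * control$max_step / max(abs(dir))
    }
    step <- 1
    improved <- FALSE
    for (half in 1:25) {
      cand <- clamp(theta + step * dir)
      llc <- tryCatch(mme_eval(model, cand), error = function(e) -Inf)
      if (is.finite(llc) && llc >= ll - acc_tol(ll)) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    theta <- cand
    state <- mme_eval(model, theta, want_state = TRUE)
    dll <- state$ll - ll
    ll <- state$ll
    trace <- c(trace, ll)
    if (abs(dll) < control$tol_lik * (1 + abs(ll)) &&
        max(abs(grad)) < gtol(ll)) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iter >= 1) {
    ## final check: tiny gradient also counts even if last step was rejected
    grad <- mme_fd_grad(model, theta, h = control$fd_step)
    if (max(abs(grad)) < gtol(ll)) converged <- TRUE
  }
  at_floor <- any(theta[var_idx] <= pmax(floor_log, chol_floor) + 1e-8)
  AI <- mme_ai_matrix(model, theta, state)
  ## at a variance floor the AI matrix is singular; fall back to the
  ## Moore-Penrose inverse so the interior parameters still get SEs
  cov_theta <- tryCatch(solve(AI), error = function(e)
    tryCatch(MASS::ginv(AI), error = function(e2)
      matrix(NA_real_, model$npar, model$npar)))
  list(theta = theta, loglik = ll, converged = converged, iterations = iter,
       gradient = grad, ai = AI, cov_theta = cov_theta,
       boundary = at_floor, trace = trace, state = state)
}

#' REML fitting control parameters
#'
#' @param max_iter Maximum number of average-information iterations.
#' @param tol_lik Relative restricted-likelihood change declaring
#'   convergence.
#' @param tol_grad Infinity-norm tolerance on the score vector.
#' @param fd_step Central-difference step (working/log scale) for the score.
#' @param floor_frac Variance floor as a fraction of the phenotypic
#'   variance; components are not allowed below it.
#' @param max_step Cap on the infinity norm of one AI update (working
#'   scale).
#' @return A list of class `"reml_control"`.
#' @export
reml_control <- function(max_iter = 60L, tol_lik = 1e-8, tol_grad = 1e-4,
                         fd_step = 1e-4, floor_frac = 1e-10, max_step = 3) {
  structure(list(max_iter = max_iter, tol_lik = tol_lik, tol_grad = tol_grad,
                 fd_step = fd_step, floor_frac = floor_frac,
                 max_step = max_step), class = "reml_control")
}
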