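#' Run a panel of univariate repeatability-model fits
#'
#' For each trait in the panel: builds the design from its table and model
#' spec, fits the univariate animal model, and reports a summary row in the
#' style of a means/heritability/repeatability table: animal and record
#' counts, raw mean and SD, model-based phenotypic SD
#' `sigma_p = sqrt(sigma2_p)` (at most the raw SD when fixed effects explain
#' variance), and `h2` and repeatability with standard errors. A trait that
#' fails to converge is flagged and the run continues.
#'
#' @param tables Named list of phenotype tibbles (e.g. `chamber`,
#'   `maternal`, `egg`), or a single tibble used for every trait.
#' @param panel Named list, one entry per trait:
#'   `list(spec = model_spec(...), table = "chamber")` (`table` may be
#'   omitted when `tables` is a single tibble).
#' @param pedigree Pedigree object.
#' @param control A [reml_control()].
#' @return Tibble with one row per trait; the fitted `"reml_fit"` objects
#'   are attached as attribute `"fits"` (used to seed bivariate runs).
#' @export
run_univariate_panel <- function(tables, panel, pedigree,
                                 control = reml_control()) {
  single <- is.data.frame(tables)
  fits <- list()
  rows <- list()
  for (tr in names(panel)) {
    ent <- panel[[tr]]
    spec <- ent$spec
    dat <- if (single) tables else tables[[ent$table]]
    if (is.null(dat)) stop("panel trait '", tr, "' references unknown table '",
                           ent$table, "'")
    row <- tibble::tibble(trait = tr, n_animals = NA_integer_,
                          n_records = NA_integer_, mean = NA_real_,
                          sd = NA_real_, sigma_p = NA_real_,
                          h2 = NA_real_, h2_se = NA_real_,
                          repeatability = NA_real_,
                          repeatability_se = NA_real_, converged = FALSE)
    fit <- tryCatch({
      ds <- build_design(dat, spec, pedigree)
      fit_univariate(ds, pedigree, control = control)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      warning("trait '", tr, "' failed: ", conditionMessage(fit),
              call. = FALSE)
    } else {
      ds_y <- dat[[spec$response]]
      r <- fit$ratios
      row$n_animals <- fit$n_animals
      row$n_records <- fit$n
      row$mean <- mean(ds_y, na.rm = TRUE)
      row$sd <- stats::sd(ds_y, na.rm = TRUE)
      row$sigma_p <- fit$sigma_p
      row$h2 <- r$estimate[r$quantity == "h2"]
      row$h2_se <- r$std.error[r$quantity == "h2"]
      row$repeatability <- r$estimate[r$quantity == "repeatability"]
      row$repeatability_se <- r$std.error[r$quantity == "repeatability"]
      row$converged <- fit$converged
      fits[[tr]] <- fit
    }
    rows[[tr]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}

#' Run a panel of bivariate fits: correlation table
#'
#' Fits every requested trait pair bivariately and reports genetic and
#' phenotypic correlations with standard errors and a Wald significance
#' star at level `alpha`, mirroring the layout rows = non-methane traits,
#' columns = methane traits. Univariate fits (from
#' [run_univariate_panel()]) seed the starting values.
#'
#' @param tables,panel,pedigree,control As in [run_univariate_panel()].
#' @param pairs List of character pairs `c(trait1, trait2)` (or a 2-column
#'   data frame); trait names must exist in `panel`.
#' @param univariate Result of [run_univariate_panel()] (with its `"fits"`
#'   attribute); run internally when omitted.
#' @param alpha Significance level for stars.
#' @return Tibble: `trait1`, `trait2`, `r_g`, `r_g_se`, `r_g_sig`, `r_p`,
#'   `r_p_se`, `r_p_sig`, `converged`; fits attached as `"fits"`.
#' @export
run_bivariate_panel <- function(tables, panel, pairs, pedigree,
                                univariate = NULL, alpha = 0.05,
                                control = reml_control()) {
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) unlist(pairs[i, 1:2]))
  }
  pairs <- lapply(pairs, function(p) as.character(unlist(p)))
  for (pr in pairs) {
    if (!all(pr %in% names(panel))) {
      stop("pair ", paste(pr, collapse = " x "), " not covered by the panel")
    }
  }
  if (is.null(univariate)) {
    univariate <- run_univariate_panel(tables, panel, pedigree, control)
  }
  ufits <- attr(univariate, "fits")
  single <- is.data.frame(tables)
  get_design <- local({
    cache <- list()
    function(tr) {
      if (is.null(cache[[tr]])) {
        dat <- if (single) tables else tables[[panel[[tr]]$table]]
        cache[[tr]] <<- build_design(dat, panel[[tr]]$spec, pedigree)
      }
      cache[[tr]]
    }
  })
  rows <- list()
  fits <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = " x ")
    row <- tibble::tibble(trait1 = pr[1], trait2 = pr[2],
                          r_g = NA_real_, r_g_se = NA_real_, r_g_sig = NA,
                          r_p = NA_real_, r_p_se = NA_real_, r_p_sig = NA,
                          converged = FALSE)
    fit <- tryCatch({
      start <- if (!is.null(ufits[[pr[1]]]) && !is.null(ufits[[pr[2]]])) {
        list(ufits[[pr[1]]], ufits[[pr[2]]])
      } else NULL
      fit_bivariate(get_design(pr[1]), get_design(pr[2]), pedigree,
                    start = start, control = control)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      warning("pair ", key, " failed: ", conditionMessage(fit), call. = FALSE)
    } else {
      r <- fit$ratios
      gv <- function(q, col) r[[col]][r$quantity == q]
      row$r_g <- gv("r_g", "estimate"); row$r_g_se <- gv("r_g", "std.error")
      row$r_p <- gv("r_p", "estimate"); row$r_p_se <- gv("r_p", "std.error")
      row$r_g_sig <- significance(row$r_g, row$r_g_se, alpha)
      row$r_p_sig <- significance(row$r_p, row$r_p_se, alpha)
      row$converged <- fit$converged
      fits[[key]] <- fit
    }
    rows[[key]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}

#' Format "estimate (SE)" with a significance star
#'
#' @param estimate,se Numeric vectors.
#' @param sig Logical vector (starred when `TRUE`).
#' @param digits Decimal places.
#' @return Character vector like `"0.31 (0.09)*"`.
#' @export
format_estimate <- function(estimate, se, sig = FALSE, digits = 2) {
  out <- sprintf(paste0("%.", digits, "f (%.", digits, "f)"), estimate, se)
  out[is.na(estimate)] <- ""
  ifelse(!is.na(estimate) & !is.na(sig) & sig, paste0(out, "*"), out)
}

#' Serialize a REML fit to JSON
#'
#' Writes components, derived ratios, standard errors and convergence
#' metadata in a machine-readable form.
#'
#' @param fit A `"reml_fit"`.
#' @param path Output path.
#' @return Invisibly, the list that was serialized.
#' @export
write_fit_json <- function(fit, path) {
  x <- list(
    type = fit$type, traits = fit$traits,
    components = lapply(fit$components$terms, unclass),
    residual = unclass(fit$components$resid),
    ratios = fit$ratios, sigma_p = unname(fit$sigma_p),
    loglik = fit$loglik, converged = fit$converged,
    iterations = fit$iterations, boundary = fit$boundary
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' Run a full analysis from a declarative config
#'
#' Reads a YAML analysis configuration (pedigree path, phenotype CSVs,
#' per-trait model specs, trait pairs), runs the univariate and bivariate
#' panels, and writes `univariate.csv`, `bivariate.csv` and per-fit JSON
#' files to the output directory.
#'
#' Config layout:
#' ```yaml
#' pedigree: ped.txt
#' tables: {chamber: chamber.csv, maternal: maternal.csv}
#' alpha: 0.05
#' traits:
#'   ch4_gd:
#'     table: chamber
#'     response: ch4_gd
#'     fixed: [byr.flk.sex, ryr.lot.group.round]
#'     random:
#'       animal: {group_by: [animal], covariance: pedigree}
#' pairs: [[ch4_gd, lw_mate]]
#' out_dir: results
#' ```
#'
#' @param config Path to a YAML file, or the equivalent list.
#' @return List with `univariate` and `bivariate` tibbles (invisibly).
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ped <- read_pedigree(config$pedigree)
  tables <- lapply(config$tables, read_phenotypes)
  panel <- lapply(config$traits, function(ent) {
    list(table = ent$table,
         spec = model_spec(response = ent$response,
                           fixed = as.list(ent$fixed %||% list()),
                           covariates = unlist(ent$covariates) %||% character(),
                           random = ent$random %||% list()))
  })
  uni <- run_univariate_panel(tables, panel, ped)
  pairs <- config$pairs %||% list()
  biv <- if (length(pairs)) {
    run_bivariate_panel(tables, panel, pairs, ped, univariate = uni,
                        alpha = config$alpha %||% 0.05)
  } else NULL
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(uni, file.path(out_dir, "univariate.csv"))
    if (!is.null(biv)) readr::write_csv(biv, file.path(out_dir, "bivariate.csv"))
    for (tr in names(attr(uni, "fits"))) {
      write_fit_json(attr(uni, "fits")[[tr]],
                     file.path(out_dir, paste0("fit_", tr, ".json")))
    }
  }
  invisible(list(univariate = uni, bivariate = biv))
}
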