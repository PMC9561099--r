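#' Filter respiration-chamber records
#'
#' Applies the record-level quality rules for chamber methane data: a daily
#' record is kept only when the chamber seal held, at least
#' `eaten_threshold` of the offered feed was eaten on the day of measurement
#' (the boundary is kept: "less than" the threshold is discarded), and all
#' fields needed downstream are present.
#'
#' @param records Data frame of daily chamber records with at least
#'   `animal`, `ch4_g`, `co2_g`, `dmi_kg`, `offered_kg` and `seal_ok`
#'   columns.
#' @param eaten_threshold Minimum eaten fraction of offered feed, in (0, 1].
#'   Default 0.95.
#' @return The retained records as a tibble, with the rejected records (id,
#'   reason) attached as attribute `"rejections"`; see [rejection_log()].
#' @export
filter_chamber_records <- function(records, eaten_threshold = 0.95) {
  stopifnot(is.data.frame(records),
            eaten_threshold > 0, eaten_threshold <= 1)
  records <- tibble::as_tibble(records)
  need <- c("animal", "ch4_g", "co2_g", "dmi_kg", "offered_kg", "seal_ok")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("chamber records lack columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.na(records$offered_kg) & records$offered_kg <= 0)) {
    stop("offered_kg must be positive")
  }

  incomplete <- Reduce(`|`, lapply(records[need], is.na))
  seal_bad <- !incomplete & !records$seal_ok
  eaten <- records$dmi_kg / records$offered_kg
  refused <- !incomplete & records$seal_ok & eaten < eaten_threshold

  reason <- rep(NA_character_, nrow(records))
  reason[refused] <- "refusal"
  reason[seal_bad] <- "seal"
  reason[incomplete] <- "incomplete"
  keep <- is.na(reason)

  rejections <- tibble::tibble(
    row = which(!keep),
    animal = records$animal[!keep],
    reason = reason[!keep]
  )
  out <- records[keep, , drop = FALSE]
  attr(out, "rejections") <- rejections
  out
}

#' Rejection log of a chamber-record filter
#'
#' @param x The tibble returned by [filter_chamber_records()].
#' @return Tibble with `row` (input row number), `animal` and `reason`
#'   (`"seal"`, `"refusal"` or `"incomplete"`).
#' @export
rejection_log <- function(x) {
  attr(x, "rejections") %||% tibble::tibble(row = integer(), animal = character(),
                                            reason = character())
}

#' Derive the three methane traits from daily chamber records
#'
#' Adds, per record: gross emission `ch4_gd` (g CH4/day), methane yield
#' `ch4_dmi` (g CH4 per kg dry matter intake) and the molar fraction
#' `ch4_ratio` = (mol CH4)/(mol CH4 + mol CO2), a dimensionless yield proxy
#' that needs no intake measurement.
#'
#' @param records Filtered chamber records (see [filter_chamber_records()]).
#' @param molar_mass_ch4,molar_mass_co2 Molar masses in g/mol; defaults
#'   16.04 and 44.01.
#' @return The input tibble with `ch4_gd`, `ch4_dmi` and `ch4_ratio`
#'   columns appended. `ch4_dmi` is `NA` where intake is non-positive.
#' @examples
#' derive_methane_traits(tibble::tibble(
#'   animal = "x", ch4_g = 24, co2_g = 700, dmi_kg = 1.5,
#'   offered_kg = 1.6, seal_ok = TRUE))
#' @export
derive_methane_traits <- function(records, molar_mass_ch4 = 16.04,
                                  molar_mass_co2 = 44.01) {
  stopifnot(is.data.frame(records))
  records <- tibble::as_tibble(records)
  ch4_mol <- records$ch4_g / molar_mass_ch4
  co2_mol <- records$co2_g / molar_mass_co2
  dplyr::mutate(
    records,
    ch4_gd = records$ch4_g,
    ch4_dmi = ifelse(!is.na(records$dmi_kg) & records$dmi_kg > 0,
                     records$ch4_g / records$dmi_kg, NA_real_),
    ch4_ratio = ch4_mol / (ch4_mol + co2_mol)
  )
}

#' Log-transform faecal egg counts
#'
#' Egg counts (eggs/g) are analysed on the natural-log scale with an offset,
#' `log(x + offset)`, so zero counts remain defined.
#'
#' @param x Non-negative egg counts.
#' @param offset Additive offset before taking logs; default 50.
#' @return Transformed values, same length as `x`.
#' @examples
#' transform_egg_count(0)    # log(50)
#' transform_egg_count(382)  # log(432)
#' @export
transform_egg_count <- function(x, offset = 50) {
  if (any(x < 0, na.rm = TRUE)) stop("egg counts must be non-negative")
  log(x + offset)
}

#' Litter survival to weaning
#'
#' The fraction of lambs born that survived to weaning:
#' `n_weaned / nlb`. Undefined (returned as `NA`) for ewes that lambed no
#' lambs that year.
#'
#' @param nlb Number of lambs born, integer 0--3.
#' @param n_weaned Number of lambs weaned, integer 0--3, at most `nlb`.
#' @return Numeric vector in \[0, 1\], `NA` where `nlb == 0`.
#' @export
litter_survival <- function(nlb, n_weaned) {
  if (any(n_weaned > nlb, na.rm = TRUE)) {
    stop("more lambs weaned than born")
  }
  if (any(nlb < 0 | n_weaned < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  ifelse(!is.na(nlb) & nlb > 0, n_weaned / nlb, NA_real_)
}

#' Write a chamber-record rejection log to CSV
#'
#' @param x Tibble from [filter_chamber_records()].
#' @param path Output CSV path.
#' @return Invisibly, the log tibble.
#' @export
write_rejection_log <- function(x, path) {
  log <- rejection_log(x)
  readr::write_csv(log, path)
  invisible(log)
}
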