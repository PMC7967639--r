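#' The 16 USEPA priority PAH congeners
#'
#' Registry of the sixteen priority polycyclic aromatic hydrocarbon (PAH)
#' congeners measured on PM2.5 particles, with ring counts, the low/high
#' molecular-weight classification and the conventional probable-carcinogen
#' flag.
#'
#' `weight_class` is a pure function of the ring count: congeners with 2-3
#' rings are low molecular weight (`"LMW"`), those with 4-6 rings are high
#' molecular weight (`"HMW"`). The carcinogen flag marks the seven congeners
#' conventionally treated as probable human carcinogens (BaA, CYR, BbF, BkF,
#' BaP, IcP, DbA); callers that need a different grouping can subset the
#' registry themselves.
#'
#' @return A data.frame with one row per congener and columns `abbrev`,
#'   `name`, `ring_count`, `weight_class` and `carcinogen`.
#' @examples
#' congener_registry()
#' @export
congener_registry <- function() {
  reg <- data.frame(
    abbrev = c("NAP", "ACY", "ACP", "FLU", "PHE", "ANT",
               "FLA", "PYR", "BaA", "CYR", "BbF", "BkF",
               "BaP", "IcP", "DbA", "BgP"),
    name = c("naphthalene", "acenaphthylene", "acenaphthene", "fluorene",
             "phenanthrene", "anthracene", "fluoranthene", "pyrene",
             "benzo(a)anthracene", "chrysene", "benzo(b)fluoranthene",
             "benzo(k)fluoranthene", "benzo(a)pyrene",
             "indeno(1,2,3-cd)pyrene", "dibenzo(a,h)anthracene",
             "benzo(ghi)perylene"),
    ring_count = c(2L, 3L, 3L, 3L, 3L, 3L,
                   4L, 4L, 4L, 4L, 5L, 5L,
                   5L, 6L, 5L, 6L),
    stringsAsFactors = FALSE
  )
  reg$weight_class <- ifelse(reg$ring_count <= 3L, "LMW", "HMW")
  reg$carcinogen <- reg$abbrev %in%
    c("BaA", "CYR", "BbF", "BkF", "BaP", "IcP", "DbA")
  reg
}

#' Congener abbreviations in registry order
#'
#' @return Character vector of the 16 congener abbreviations.
#' @export
pah_congeners <- function() congener_registry()$abbrev

lmw_congeners <- function() {
  reg <- congener_registry()
  reg$abbrev[reg$weight_class == "LMW"]
}

hmw_congeners <- function() {
  reg <- congener_registry()
  reg$abbrev[reg$weight_class == "HMW"]
}

#' Abbreviations of the seven probable-carcinogen congeners
#'
#' @return Character vector of the congener abbreviations flagged as
#'   carcinogenic in [congener_registry()].
#' @export
carcinogenic_congeners <- function() {
  reg <- congener_registry()
  reg$abbrev[reg$carcinogen]
}

# Check that a data.frame carries the 16 congener columns; return their names.
congener_columns <- function(profiles) {
  missing <- setdiff(pah_congeners(), names(profiles))
  if (length(missing))
    stop("profile table is missing congener columns: ",
         paste(missing, collapse = ", "))
  pah_congeners()
}

stop_if_missing_values <- function(profiles, what) {
  cc <- congener_columns(profiles)
  mat <- as.matrix(profiles[, cc, drop = FALSE])
  if (anyNA(mat))
    stop(what, " requires an imputed profile with no missing values; ",
         "run impute_below_mdl() first")
  if (any(mat < 0))
    stop(what, ": negative congener concentrations are not allowed")
  invisible(mat)
}

#' Air concentration from a GC-MS extract measurement
#'
#' Converts a determined extract concentration (ng mL^-1) to an airborne
#' particulate concentration (ng m^-3) by scaling with the dilution factor
#' and dividing by the sampled air volume. The study design draws 7.2 m^3 of
#' air per 24 h sample, which is the default volume.
#'
#' @param c_determined Determined concentration in the extract, ng mL^-1.
#' @param dilution_factor Dimensionless dilution multiplier (>= 1 in normal
#'   use); absorbs the final extract volume.
#' @param air_volume Total sampled air volume in m^3; must be positive.
#' @return Concentration in ng m^-3 (vectorised over its arguments).
#' @examples
#' concentration_from_extract(7.2, 1, 7.2)  # 1 ng m^-3
#' @export
concentration_from_extract <- function(c_determined, dilution_factor = 1,
                                       air_volume = 7.2) {
  if (any(!is.finite(air_volume)) || any(air_volume <= 0))
    stop("air_volume must be positive")
  if (any(c_determined < 0, na.rm = TRUE))
    stop("c_determined must be nonnegative")
  if (any(dilution_factor <= 0, na.rm = TRUE))
    stop("dilution_factor must be positive")
  c_determined * dilution_factor / air_volume
}

#' Impute non-detects at half the method detection limit
#'
#' Missing or below-detection-limit congener concentrations are replaced by
#' MDL/2, the conventional substitution for left-censored air-quality data.
#' Detected values at or above their MDL are left untouched. The operation is
#' idempotent.
#'
#' @param profiles A data.frame with one row per sample and one column per
#'   congener abbreviation (`NA` = missing / non-detect), plus any metadata
#'   columns.
#' @param mdl Named numeric vector of method detection limits (ng m^-3), or a
#'   data.frame with columns `congener` and `mdl_ng_m3` as read from the
#'   companion MDL table.
#' @return `profiles` with every congener entry filled in.
#' @export
impute_below_mdl <- function(profiles, mdl) {
  if (is.data.frame(mdl)) {
    if (!all(c("congener", "mdl_ng_m3") %in% names(mdl)))
      stop("mdl data.frame needs columns 'congener' and 'mdl_ng_m3'")
    mdl <- stats::setNames(mdl$mdl_ng_m3, mdl$congener)
  }
  cc <- congener_columns(profiles)
  for (cg in cc) {
    x <- profiles[[cg]]
    if (any(x < 0, na.rm = TRUE))
      stop("negative concentration for ", cg)
    has_mdl <- cg %in% names(mdl) && is.finite(mdl[[cg]])
    below <- if (has_mdl) !is.na(x) & x < mdl[[cg]] else rep(FALSE, length(x))
    need <- is.na(x) | below
    if (any(need)) {
      if (!has_mdl)
        stop("missing value for ", cg, " but no MDL on record")
      x[need] <- mdl[[cg]] / 2
    }
    profiles[[cg]] <- x
  }
  profiles
}

#' Total PAH concentration per sample
#'
#' @param profiles Imputed profile table (see [impute_below_mdl()]).
#' @return Numeric vector: the sum over the 16 congeners, ng m^-3.
#' @export
total_pahs <- function(profiles) {
  mat <- stop_if_missing_values(profiles, "total_pahs")
  rowSums(mat)
}

#' Low vs high molecular-weight PAH totals
#'
#' Splits the per-sample total into the low molecular-weight (2-3 ring:
#' NAP, ACY, ACP, FLU, PHE, ANT) and high molecular-weight (4-6 ring)
#' fractions. The two parts always sum to [total_pahs()].
#'
#' @inheritParams total_pahs
#' @return data.frame with columns `lmw` and `hmw` (ng m^-3).
#' @export
lmw_hmw_split <- function(profiles) {
  mat <- stop_if_missing_values(profiles, "lmw_hmw_split")
  data.frame(
    lmw = rowSums(mat[, lmw_congeners(), drop = FALSE]),
    hmw = rowSums(mat[, hmw_congeners(), drop = FALSE])
  )
}

#' Read / write the sample and MDL tables
#'
#' `read_profiles_csv` reads the per-sample congener table (columns
#' `sample_id, school, zone, site` then the 16 congener abbreviations; empty
#' cells are missing). `read_mdl_csv` reads the companion detection-limit
#' table (`congener, mdl_ng_m3`). The writers emit the same layouts.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_profiles_csv <- function(path) {
  profiles <- utils::read.csv(path, stringsAsFactors = FALSE)
  congener_columns(profiles)
  profiles
}

#' @rdname read_profiles_csv
#' @param profiles Profile table to write.
#' @export
write_profiles_csv <- function(profiles, path) {
  congener_columns(profiles)
  utils::write.csv(profiles, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_profiles_csv
#' @export
read_mdl_csv <- function(path) {
  mdl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("congener", "mdl_ng_m3") %in% names(mdl)))
    stop("MDL table needs columns 'congener' and 'mdl_ng_m3'")
  mdl
}
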