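#' Define an experimental factor
#'
#' A factor is one controllable growth-condition variable screened at two
#' coded levels (low = -1, high = +1), optionally with a third center level
#' for quantitative factors. Each factor is mapped to one of the nine MIEO
#' reporting categories so that any design run can be re-expressed as a
#' minimum-information record.
#'
#' @param name Factor name (snake_case identifier, used as a design column).
#' @param mieo_category One of the nine MIEO categories, see
#'   [mieo_categories()].
#' @param kind `"quantitative"` or `"categorical"`.
#' @param low,high The two screening levels. Numeric for quantitative
#'   factors, character labels for categorical ones.
#' @param center Optional center level. Quantitative factors may omit it
#'   (no centerpoint defined); categorical factors may carry a character
#'   reference level (e.g. an ordered treatment whose middle setting acts
#'   as the centerpoint reference) but never a numeric midpoint.
#' @param units Unit string, free text; `""` for dimensionless or label
#'   levels.
#'
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("glycerol", "Media components", "quantitative",
#'             low = 3, high = 7, center = 5, units = "g/L")
#' @export
factor_spec <- function(name, mieo_category,
                        kind = c("quantitative", "categorical"),
                        low, high, center = NULL, units = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!mieo_category %in% mieo_categories()$category) {
    stop("unknown MIEO category: ", mieo_category, call. = FALSE)
  }
  if (identical(low, high)) {
    stop("factor '", name, "': low and high levels must differ", call. = FALSE)
  }
  if (kind == "quantitative") {
    stopifnot(is.numeric(low), is.numeric(high))
    if (!is.null(center)) stopifnot(is.numeric(center))
  } else {
    stopifnot(is.character(low), is.character(high))
    if (!is.null(center) && is.numeric(center)) {
      stop("factor '", name, "': categorical factors cannot have a numeric center",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, mieo_category = mieo_category, kind = kind,
         low = low, high = high, center = center, units = units),
    class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  lev <- if (is.null(x$center)) {
    paste(x$low, "/", x$high)
  } else {
    paste(x$low, "/", x$center, "/", x$high)
  }
  cat(sprintf("<factor_spec> %s [%s, %s]: %s %s\n",
              x$name, x$mieo_category, x$kind, lev, x$units))
  invisible(x)
}

#' Decode one coded level of a factor to its natural value
#'
#' @param spec A [factor_spec()].
#' @param code Coded level: -1, 0 (centerpoint) or +1.
#' @param center_policy Optional natural value to use at code 0 when the
#'   factor defines no center level (quantitative fallback, or the fixed
#'   level held for a categorical factor in centerpoint runs).
#' @return The natural level (numeric or character); `NA` if code is 0 and
#'   neither a center level nor a policy value exists.
#' @export
decode_level <- function(spec, code, center_policy = NULL) {
  stopifnot(inherits(spec, "factor_spec"))
  if (is.na(code)) {
    return(if (spec$kind == "quantitative") NA_real_ else NA_character_)
  }
  if (code == -1) return(spec$low)
  if (code == 1) return(spec$high)
  if (code == 0) {
    if (!is.null(center_policy)) return(center_policy)
    if (!is.null(spec$center)) return(spec$center)
    return(if (spec$kind == "quantitative") NA_real_ else NA_character_)
  }
  stop("coded level must be -1, 0 or +1, got ", code, call. = FALSE)
}

#' Factor catalogue for the lycopene screening campaign
#'
#' The 22 growth-condition factors screened for the lycopene-producing
#' *E. coli* strain, with their low/center/high levels and MIEO category
#' mapping: eight media factors, five microwell-container factors, four
#' shake-flask factors, and five further factors (time, environment,
#' inoculum, selective agent). Inoculum age is an ordered categorical
#' factor ("3", "16", "16+96" h, a storage treatment rather than a numeric
#' scale) with 16 h as the centerpoint reference.
#'
#' @return A named list of [factor_spec()] objects.
#' @export
lycopene_factor_catalogue <- function() {
  specs <- list(
    factor_spec("yeast_extract", "Media components", "quantitative",
                20, 28, 24, "g/L"),
    factor_spec("glycerol", "Media components", "quantitative",
                3, 7, 5, "g/L"),
    factor_spec("tryptone", "Media components", "quantitative",
                10, 14, 12, "g/L"),
    factor_spec("magnesium_sulfate", "Media components", "quantitative",
                0, 0.24, 0.12, "g/L"),
    factor_spec("yeast_extract_source", "Media components", "categorical",
                "Sigma", "Millipore"),
    factor_spec("ph", "Media properties", "quantitative",
                6.7, 7.5, 7.2, ""),
    factor_spec("buffer_capacity", "Media properties", "quantitative",
                70, 110, 90, "mmol/L"),
    factor_spec("osmolality", "Media properties", "quantitative",
                650, 850, 750, "mmol/kg"),
    factor_spec("well_volume", "Container geometry", "quantitative",
                2.5, 10, units = "mL"),
    factor_spec("well_fill_volume", "Container geometry", "quantitative",
                10, 30, units = "%"),
    factor_spec("well_cover", "Container geometry", "categorical",
                "AeraSeal", "Aluminum"),
    factor_spec("well_bottom", "Container geometry", "categorical",
                "Round", "Pyramidal"),
    factor_spec("flask_volume", "Container geometry", "quantitative",
                125, 250, units = "mL"),
    factor_spec("flask_fill_volume", "Container geometry", "quantitative",
                7.5, 15, units = "%"),
    factor_spec("flask_cover", "Container geometry", "categorical",
                "Foam", "Aluminum"),
    factor_spec("flask_baffles", "Container geometry", "categorical",
                "Unbaffled", "Baffled"),
    factor_spec("shake_speed", "Container shaking", "quantitative",
                230, 460, units = "rpm"),
    factor_spec("growth_time", "Time", "quantitative",
                24, 72, 48, "h"),
    factor_spec("temperature", "Environment", "quantitative",
                30, 37, units = "deg C"),
    factor_spec("inoculum_amount", "Inoculum", "quantitative",
                2e6, 3e7, 8e6, "cells/mL"),
    factor_spec("inoculum_age", "Inoculum", "categorical",
                "3", "16+96", center = "16", units = "h"),
    factor_spec("antibiotic_concentration", "Selective agents", "quantitative",
                6.25, 100, 25, "ug/mL")
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Factor catalogue for the RFP screening campaign
#'
#' The 18-factor variant used for the RFP-expressing strain: identical to
#' [lycopene_factor_catalogue()] minus the four shake-flask factors, which
#' were not screened for that strain. Provided so the same design and
#' analysis machinery accepts either factor list.
#'
#' @return A named list of [factor_spec()] objects.
#' @export
rfp_factor_catalogue <- function() {
  cat22 <- lycopene_factor_catalogue()
  cat22[setdiff(names(cat22),
                c("flask_volume", "flask_fill_volume",
                  "flask_cover", "flask_baffles"))]
}

#' Held levels for centerpoint (reference) runs
#'
#' Natural levels used at coded level 0 for factors that define no center
#' level, matching the published centerpoint growth condition: 2.5 mL
#' round-bottom wells filled to 10% under an AeraSeal cover, shaken at
#' 460 rpm, 30 deg C, Sigma yeast extract, 16 h inoculum. Factors with a
#' defined center level need no entry here.
#'
#' @return A named list mapping factor names to natural levels.
#' @export
centerpoint_policy <- function() {
  list(
    yeast_extract_source = "Sigma",
    well_volume = 2.5,
    well_fill_volume = 10,
    well_cover = "AeraSeal",
    well_bottom = "Round",
    shake_speed = 460,
    temperature = 30,
    inoculum_age = "16"
  )
}
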