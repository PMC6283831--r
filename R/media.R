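#' Osmolality contribution rules for common media components
#'
#' Defined chemicals contribute `mass / molar_mass * particles * 1000`
#' mmol/kg, assuming complete dissociation of ionic species (dilute aqueous
#' solutions, so mmol/L and mmol/kg are treated as numerically
#' interchangeable). Undefined mixtures (yeast extract, tryptone) use an
#' empirically determined coefficient of 6 mmol/kg per g/L.
#'
#' @return Data frame with columns `component`, `molar_mass` (g/mol),
#'   `particles` (ions per formula unit on complete dissociation) and
#'   `osmolal_coeff` (mmol/kg per g/L; `NA` for defined chemicals).
#' @export
media_component_table <- function() {
  data.frame(
    component = c("yeast_extract", "tryptone", "glycerol",
                  "magnesium_sulfate", "kh2po4", "k2hpo4", "nacl"),
    molar_mass = c(NA, NA, 92.094, 120.366, 136.086, 174.176, 58.44),
    particles = c(NA, NA, 1L, 2L, 2L, 3L, 2L),
    osmolal_coeff = c(6, 6, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Create a media recipe
#'
#' @param components Named numeric vector of mass concentrations in g/L
#'   (names must resolve against the component table), or a data frame with
#'   columns `component` and `mass_g_per_L`.
#' @param component_table Contribution rules, see [media_component_table()].
#' @return A `media_recipe` data frame.
#' @examples
#' media_recipe(c(yeast_extract = 24, glycerol = 5))
#' @export
media_recipe <- function(components, component_table = media_component_table()) {
  if (is.numeric(components)) {
    components <- data.frame(component = names(components) %||% character(0),
                             mass_g_per_L = unname(components),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("component", "mass_g_per_L") %in% names(components)))
  unknown <- setdiff(components$component, component_table$component)
  if (length(unknown)) {
    stop("no osmolality rule for component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(components[c("component", "mass_g_per_L")],
            component_table = component_table,
            class = c("media_recipe", "data.frame"))
}

#' Terrific Broth centerpoint recipe
#'
#' The baseline rich-medium composition used as the centerpoint condition:
#' 24 g/L yeast extract, 12 g/L tryptone, 5 g/L glycerol, 0.12 g/L
#' magnesium sulfate, phosphate buffer at 2.28 g/L KH2PO4 and 12.7 g/L
#' K2HPO4 (pH 7.5, 90 mM buffer capacity at pKa 6.86), and 6.63 g/L sodium
#' chloride bringing the osmolality to 750 mmol/kg. Note that the phosphate
#' mole amounts sometimes quoted for this medium (0.17 / 0.72 mol/L) are a
#' factor of 10 above these masses; the gram values here are the ones
#' consistent with the stated pH and 90 mM capacity.
#'
#' @param nacl Sodium chloride in g/L; set to 0 for the NaCl-free base
#'   recipe used when solving for an osmolality target.
#' @return A `media_recipe`.
#' @export
tb_centerpoint_recipe <- function(nacl = 6.63) {
  comps <- c(yeast_extract = 24, tryptone = 12, glycerol = 5,
             magnesium_sulfate = 0.12, kh2po4 = 2.28, k2hpo4 = 12.7)
  if (nacl > 0) comps <- c(comps, nacl = nacl)
  media_recipe(comps)
}

#' Osmolality of a media recipe
#'
#' Sums per-component contributions: defined chemicals contribute
#' `mass / molar_mass * particles * 1000` (complete dissociation);
#' undefined mixtures contribute `osmolal_coeff * mass`. Additive and
#' linear in each component's mass concentration.
#'
#' @param recipe A [media_recipe()].
#' @return Osmolality in mmol/kg.
#' @examples
#' osmolality(tb_centerpoint_recipe())  # about 750
#' @export
osmolality <- function(recipe) {
  stopifnot(inherits(recipe, "media_recipe"))
  if (nrow(recipe) == 0L) return(0)
  tab <- attr(recipe, "component_table")
  i <- match(recipe$component, tab$component)
  contrib <- ifelse(
    is.na(tab$osmolal_coeff[i]),
    recipe$mass_g_per_L / tab$molar_mass[i] * tab$particles[i] * 1000,
    tab$osmolal_coeff[i] * recipe$mass_g_per_L)
  sum(contrib)
}

#' Sodium chloride needed to reach a target osmolality
#'
#' NaCl dissociates into 2 particles per formula unit, so the required
#' mass is `(target - current) / 1000 * 58.44 / 2` g/L.
#'
#' @param recipe A [media_recipe()] (NaCl-free or partial).
#' @param target Target osmolality in mmol/kg; must not be below the
#'   recipe's current osmolality.
#' @return NaCl mass to add, g/L.
#' @examples
#' nacl_for_osmolality(tb_centerpoint_recipe(nacl = 0), 750)  # about 6.6
#' @export
nacl_for_osmolality <- function(recipe, target) {
  current <- osmolality(recipe)
  if (target < current) {
    stop(sprintf("target osmolality (%g) is below the recipe's current %g",
                 target, current), call. = FALSE)
  }
  tab <- attr(recipe, "component_table")
  nacl <- tab[tab$component == "nacl", ]
  (target - current) / 1000 * nacl$molar_mass / nacl$particles
}

#' Solve a phosphate buffer for a target pH and capacity
#'
#' Simultaneously solves the Henderson-Hasselbalch equation
#' `pH = pKa + log10([A-]/[HA])` and the buffer-capacity equation
#' `capacity = [A-] + [HA]` for the conjugate base (`[A-]`, dibasic
#' phosphate) and conjugate acid (`[HA]`, monobasic phosphate)
#' concentrations.
#'
#' @param target_ph Target pH.
#' @param target_capacity Total phosphate concentration; any concentration
#'   unit (conventionally mmol/L), returned concentrations share it.
#' @param pka Acid dissociation constant; 6.86 for the second phosphate
#'   proton.
#' @return A `buffer_spec` list with `acid` (`[HA]`), `base` (`[A-]`),
#'   `ph`, `capacity`, `pka`.
#' @examples
#' solve_buffer(7.5, 90)  # [HA] ~ 16.8, [A-] ~ 73.2 mM
#' @export
solve_buffer <- function(target_ph, target_capacity, pka = 6.86) {
  if (target_capacity <= 0) {
    stop("buffer capacity must be positive", call. = FALSE)
  }
  r <- 10^(target_ph - pka)       # [A-]/[HA]
  acid <- target_capacity / (1 + r)
  base <- target_capacity - acid
  structure(list(acid = acid, base = base, ph = target_ph,
                 capacity = target_capacity, pka = pka),
            class = "buffer_spec")
}

#' pH and capacity of a phosphate buffer composition
#'
#' Inverse of [solve_buffer()]: given conjugate acid and base
#' concentrations, returns the buffer pH (Henderson-Hasselbalch) and
#' capacity (their sum).
#'
#' @param acid_conc `[HA]` concentration (> 0).
#' @param base_conc `[A-]` concentration (> 0), same unit.
#' @param pka Acid dissociation constant.
#' @return A `buffer_spec` list.
#' @export
buffer_properties <- function(acid_conc, base_conc, pka = 6.86) {
  if (acid_conc <= 0 || base_conc <= 0) {
    stop("buffer concentrations must be positive", call. = FALSE)
  }
  structure(list(acid = acid_conc, base = base_conc,
                 ph = pka + log10(base_conc / acid_conc),
                 capacity = acid_conc + base_conc, pka = pka),
            class = "buffer_spec")
}

#' @export
print.buffer_spec <- function(x, ...) {
  cat(sprintf(
    "<buffer_spec> pH %.3f, capacity %.3g ([HA] %.4g + [A-] %.4g), pKa %.2f\n",
    x$ph, x$capacity, x$acid, x$base, x$pka))
  invisible(x)
}

#' Buffer properties from phosphate salt masses
#'
#' Converts KH2PO4 (conjugate acid) and K2HPO4 (conjugate base) mass
#' concentrations to mmol/L via their molar masses (136.086 and
#' 174.176 g/mol) and evaluates [buffer_properties()].
#'
#' @param kh2po4_g_per_L,k2hpo4_g_per_L Salt masses in g/L.
#' @param pka Acid dissociation constant.
#' @return A `buffer_spec` with concentrations in mmol/L.
#' @examples
#' buffer_from_masses(2.28, 12.7)  # pH ~ 7.5, capacity ~ 90 mM
#' @export
buffer_from_masses <- function(kh2po4_g_per_L, k2hpo4_g_per_L, pka = 6.86) {
  tab <- media_component_table()
  mm <- stats::setNames(tab$molar_mass, tab$component)
  buffer_properties(kh2po4_g_per_L / mm[["kh2po4"]] * 1000,
                    k2hpo4_g_per_L / mm[["k2hpo4"]] * 1000,
                    pka = pka)
}

#' Phosphate salt masses realizing a buffer composition
#'
#' Inverse of [buffer_from_masses()]: converts a `buffer_spec` with
#' concentrations in mmol/L back to g/L of the two salts.
#'
#' @param spec A `buffer_spec`.
#' @return Named numeric vector `c(kh2po4, k2hpo4)` in g/L.
#' @export
phosphate_masses <- function(spec) {
  stopifnot(inherits(spec, "buffer_spec"))
  tab <- media_component_table()
  mm <- stats::setNames(tab$molar_mass, tab$component)
  c(kh2po4 = spec$acid / 1000 * mm[["kh2po4"]],
    k2hpo4 = spec$base / 1000 * mm[["k2hpo4"]])
}
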