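#' Constants of the sweet-potato carrying-capacity model
#'
#' Two published constants drive the conversion from cultivated area to
#' people: one metric ton per year of sweet potato supplies 2809 kcal/day,
#' and one person requires at most 2785 kcal/day.
#'
#' @param kcal_per_ton_year kcal/day delivered by 1 t/yr of sweet potato.
#' @param kcal_per_person_day Daily per-capita caloric requirement.
#' @return A list of class `capacity_constants`.
#' @export
capacity_constants <- function(kcal_per_ton_year = 2809,
                               kcal_per_person_day = 2785) {
  stopifnot(kcal_per_ton_year > 0, kcal_per_person_day > 0)
  structure(list(kcal_per_ton_year = kcal_per_ton_year,
                 kcal_per_person_day = kcal_per_person_day),
            class = "capacity_constants")
}

#' Sweet-potato yield table
#'
#' Published yields (tons/ha/year) by cultivation frequency and soil
#' nitrogen availability: continuous cultivation 1.46 (low N) / 5.09
#' (high N); shifting 5 years off, 5 on 2.38 / 8.00; shifting 15 off,
#' 3 on 5.61 / 17.60.
#'
#' @return Data frame with columns `frequency`, `n_availability`, `yield`.
#' @export
sweet_potato_yields <- function() {
  data.frame(
    frequency = rep(c("continuous", "shifting_5_5", "shifting_15_3"),
                    each = 2),
    n_availability = rep(c("low", "high"), 3),
    yield = c(1.46, 5.09, 2.38, 8.00, 5.61, 17.60),
    stringsAsFactors = FALSE
  )
}

# duty-cycle land fraction per cultivation frequency. The 15-off/3-on
# regime uses years_on / (years_on + years_off) = 3/18 = 1/6; the published
# caption's "25%" does not reproduce the published land areas and is
# available as `fifteen_three = "quarter"`.
land_fraction <- function(frequency, fifteen_three = c("duty_cycle", "quarter")) {
  fifteen_three <- match.arg(fifteen_three)
  switch(frequency,
    continuous = 1,
    shifting_5_5 = 0.5,
    shifting_15_3 = if (fifteen_three == "duty_cycle") 1 / 6 else 0.25,
    stop("unknown cultivation frequency: ", frequency)
  )
}

#' Land simultaneously available for cultivation
#'
#' Under shifting cultivation only a duty-cycle fraction
#' `years_on / (years_on + years_off)` of the garden area is in production
#' at any time: 100% for continuous cultivation, 50% for 5-off/5-on, 1/6
#' for 15-off/3-on. `display = TRUE` rounds as the published table does
#' (1 decimal, 2 below 500 ha); full precision is kept otherwise.
#'
#' @param total_area_ha Total rock-garden area, hectares.
#' @param frequency `"continuous"`, `"shifting_5_5"` or `"shifting_15_3"`.
#' @param display Round for display (default `FALSE`).
#' @param fifteen_three `"duty_cycle"` (1/6, default) or `"quarter"` (the
#'   alternative 25% rule).
#' @return Hectares in production.
#' @export
#' @examples
#' land_available(760, "shifting_15_3", display = TRUE) # 126.67
land_available <- function(total_area_ha, frequency, display = FALSE,
                           fifteen_three = "duty_cycle") {
  stopifnot(total_area_ha >= 0)
  x <- total_area_ha * land_fraction(frequency, fifteen_three)
  if (display) x <- round_half_down(x, if (x < 500) 2L else 1L)
  x
}

# display rounding matching the published land-area column: ties round
# down (1566.95 -> 1566.9), everything else as usual; the small guard
# absorbs binary representation error
round_half_down <- function(x, digits) {
  f <- 10^digits
  ceiling(x * f - 0.5 - 1e-9) / f
}

#' Daily caloric yield of a cultivated area
#'
#' `energy = area_ha x yield (t/ha/yr) x kcal_per_ton_year`.
#'
#' @param area_ha Hectares in production.
#' @param yield_t_ha_yr Sweet-potato yield, tons/ha/year.
#' @param constants A [capacity_constants()].
#' @return kcal/day.
#' @export
energy_yield <- function(area_ha, yield_t_ha_yr,
                         constants = capacity_constants()) {
  stopifnot(area_ha >= 0, yield_t_ha_yr >= 0)
  area_ha * yield_t_ha_yr * constants$kcal_per_ton_year
}

#' Population supported by a daily caloric supply
#'
#' Whole individuals only: `floor(energy / kcal_per_person_day)`. Floor
#' (not rounding) is the published table's convention.
#'
#' @param energy_kcal_day kcal/day available.
#' @param constants A [capacity_constants()].
#' @return Integer count of individuals.
#' @export
supported_population <- function(energy_kcal_day,
                                 constants = capacity_constants()) {
  stopifnot(energy_kcal_day >= 0)
  as.integer(floor(energy_kcal_day / constants$kcal_per_person_day))
}

# published kcal/day column for the default 12-scenario table, used only to
# flag print discrepancies; order matches capacity_table() rows
PUBLISHED_KCAL_DAY <- c(
  12852562.6, 44807906.8, 10475384.6, 35211376.8, 8230659.3, 25821676.3,
  3116886.4, 10866335.6, 2540459.6, 8539360.0, 1996075.4, 6262384.6
)
PUBLISHED_INDIVIDUALS <- c(
  4614L, 16089L, 3761L, 12643L, 2955L, 9271L,
  1119L, 3901L, 912L, 3066L, 716L, 2248L
)

#' Carrying-capacity scenario table
#'
#' The cross-product of area sources x three cultivation frequencies x two
#' nitrogen levels, each row evaluated by [land_available()] (at display
#' rounding, as the published table was computed), [energy_yield()] and
#' [supported_population()]. When called with the default areas (the
#' 3,133.9 ha earlier island-wide estimate and this survey's 760 ha) the
#' result carries the published reference columns and a
#' `print_discrepancy` flag marking the three published kcal cells that
#' differ from the arithmetic by < 0.005% (print/rounding artifacts).
#'
#' @param total_areas_ha Named numeric vector of garden-area sources in
#'   hectares (default `c(comparison = 3133.9, this_study = 760)`).
#' @param yields Yield table from [sweet_potato_yields()].
#' @param constants A [capacity_constants()].
#' @param fifteen_three Land-fraction rule for the 15/3 regime.
#' @return A data frame of class `capacity_result` with one row per
#'   scenario: `source`, `frequency`, `n_availability`, `yield`, `land_ha`,
#'   `kcal_day`, `individuals` (and reference columns for the default
#'   areas).
#' @export
#' @examples
#' tab <- capacity_table()
#' subset(tab, source == "this_study")
capacity_table <- function(total_areas_ha = c(comparison = 3133.9,
                                              this_study = 760),
                           yields = sweet_potato_yields(),
                           constants = capacity_constants(),
                           fifteen_three = "duty_cycle") {
  rows <- list()
  for (src in names(total_areas_ha)) {
    for (i in seq_len(nrow(yields))) {
      land <- land_available(total_areas_ha[[src]], yields$frequency[i],
                             display = TRUE, fifteen_three = fifteen_three)
      energy <- energy_yield(land, yields$yield[i], constants)
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, frequency = yields$frequency[i],
        n_availability = yields$n_availability[i], yield = yields$yield[i],
        land_ha = land, kcal_day = energy,
        individuals = supported_population(energy, constants),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  default_areas <- identical(sort(names(total_areas_ha)),
                             c("comparison", "this_study")) &&
    isTRUE(all.equal(unname(total_areas_ha[c("comparison", "this_study")]),
                     c(3133.9, 760))) &&
    identical(fifteen_three, "duty_cycle")
  if (default_areas && nrow(out) == 12L) {
    ord <- order(match(out$source, c("comparison", "this_study")))
    out <- out[ord, , drop = FALSE]
    out$kcal_day_reference <- PUBLISHED_KCAL_DAY
    out$individuals_reference <- PUBLISHED_INDIVIDUALS
    out$print_discrepancy <- abs(out$kcal_day - out$kcal_day_reference) > 0.05
  }
  rownames(out) <- NULL
  class(out) <- c("capacity_result", "data.frame")
  out
}

#' Diet-adjusted carrying capacity
#'
#' Rock gardening fed only part of the diet; marine foods and crops grown
#' outside mulched plots add the rest. The base estimate is the unweighted
#' mean of the six scenario populations for one area source; adding a
#' supplement fraction (default 50%) scales it up. Both raw values and
#' nearest-thousand roundings are reported.
#'
#' @param tab A [capacity_table()] result.
#' @param source Area source to average over (default `"this_study"`).
#' @param supplement_fraction Extra food supply as a fraction of the
#'   rock-garden supply (default 0.5).
#' @return A list: `base` (mean individuals), `adjusted`, and their
#'   nearest-thousand roundings `base_rounded` / `adjusted_rounded`.
#' @export
#' @examples
#' diet_adjusted(capacity_table()) # base ~2000, adjusted ~3000
diet_adjusted <- function(tab, source = "this_study",
                          supplement_fraction = 0.5) {
  vals <- tab$individuals[tab$source == source]
  if (!length(vals)) stop("no rows for source ", source)
  base <- mean(vals)
  adjusted <- base * (1 + supplement_fraction)
  list(base = base, adjusted = adjusted,
       base_rounded = round(base / 1000) * 1000,
       adjusted_rounded = round(adjusted / 1000) * 1000)
}
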