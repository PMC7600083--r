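#' Default standards for the adapted Healthy Eating Index (75 points)
#'
#' The adapted index keeps ten of the thirteen HEI-2015 components; the
#' whole-grain, refined-grain and seafood-and-plant-protein components are
#' dropped (the food databases the index was adapted to carry neither the
#' whole/refined grain split nor seafood detail), which reduces the ceiling
#' from 100 to 75 points. Published HEI-2015 density cutpoints are retained.
#' Densities are per 1000 kcal; portion constants are 250 g per cup and
#' 28.25 g per ounce. Units:
#' \describe{
#'   \item{cup_eq / oz_eq}{portions per 1000 kcal, computed from grams.}
#'   \item{percent_energy}{percent of the day's energy from the component
#'     (the `energy_per_g` column converts grams to kcal).}
#'   \item{grams}{grams per 1000 kcal (sodium).}
#'   \item{ratio}{a unitless ratio passed through as-is (fatty acids,
#'     (MUFA+PUFA)/SFA).}
#' }
#' Adequacy components score linearly from `density_for_zero` (0 for all but
#' the fatty-acid ratio) up to `density_for_max`; moderation components are
#' reverse-scored between `density_for_max` (best) and `density_for_zero`
#' (worst).
#'
#' @return data.frame of component standards; `sum(max_points)` is 75.
#' @export
hei_standards <- function() {
  df <- data.frame(
    component = c("total_fruits", "whole_fruits", "total_vegetables",
                  "greens_beans", "dairy", "protein_foods", "fatty_acids",
                  "sodium", "added_sugars", "saturated_fats"),
    kind = c(rep("adequacy", 7), rep("moderation", 3)),
    unit = c("cup_eq", "cup_eq", "cup_eq", "cup_eq", "cup_eq", "oz_eq",
             "ratio", "grams", "percent_energy", "percent_energy"),
    max_points = c(5, 5, 5, 5, 10, 5, 10, 10, 10, 10),
    density_for_max = c(0.8, 0.4, 1.1, 0.2, 1.3, 2.5, 2.5, 1.1, 6.5, 8),
    density_for_zero = c(0, 0, 0, 0, 0, 0, 1.2, 2.0, 26, 16),
    grams_per_portion = c(250, 250, 250, 250, 250, 28.25, NA, NA, NA, NA),
    energy_per_g = c(NA, NA, NA, NA, NA, NA, NA, NA, 4, 9),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(df$max_points) == 75)
  df
}

#' Default standards for the Colombian dietary-guidelines (GABA) index
#'
#' Seven food-group components, 10 points each (70-point ceiling). For each
#' component the guideline recommends a number of daily portions for a
#' reference energy intake (2650 kcal for males, 2100 kcal for females);
#' consumption is scored linearly in portions per 1000 kcal up to the
#' implied recommended density and capped at the component maximum. The
#' grams-per-portion constants and the (sex, age-group) specific recommended
#' portions are editable; only the 70-point total is fixed.
#'
#' @return data.frame with one row per component x sex x age_group cell.
#' @export
gaba_standards <- function() {
  comp <- data.frame(
    component = c("fruits", "vegetables", "dairy", "cereals", "meats",
                  "beans", "tubers"),
    grams_per_portion = c(120, 80, 200, 50, 75, 60, 100),
    max_points = 10,
    stringsAsFactors = FALSE
  )
  # recommended daily portions by (sex, age_group); middle-aged targets are
  # slightly lower for energy-dense groups
  rec <- expand.grid(sex = c("male", "female"),
                     age_group = c("18-40", "41-62"),
                     stringsAsFactors = FALSE)
  base <- c(fruits = 3, vegetables = 2, dairy = 2, cereals = 6, meats = 2,
            beans = 1, tubers = 2)
  out <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    portions <- base
    if (rec$age_group[i] == "41-62")
      portions[c("cereals", "tubers")] <- portions[c("cereals", "tubers")] - 1
    data.frame(comp, sex = rec$sex[i], age_group = rec$age_group[i],
               recommended_portions = unname(portions[comp$component]),
               reference_kcal = if (rec$sex[i] == "male") 2650 else 2100,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read or write a standards table as CSV
#'
#' Standards are plain data.frames; these helpers exist so that the true
#' component tables can be dropped in from an editable file.
#' @param path CSV path.
#' @param standards a standards data.frame.
#' @return `read_standards` returns a data.frame.
#' @export
read_standards <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_standards
#' @export
write_standards <- function(standards, path) {
  write.csv(standards, path, row.names = FALSE)
  invisible(path)
}

#' Default micronutrient requirement ranges by sex
#'
#' Lower/upper daily-intake bounds used by [micronutrient_adequacy()].
#' Values follow adult reference intakes; zinc illustrates a sex-dependent
#' band (higher male requirement, lower female tolerable range), the pattern
#' under which one intake can be deficient in males yet excessive in
#' females.
#' @return data.frame `nutrient`, `sex`, `lower`, `upper`.
#' @export
default_requirements <- function() {
  rbind(
    data.frame(nutrient = "calcium_mg", sex = c("male", "female"),
               lower = 1000, upper = 2500),
    data.frame(nutrient = "zinc_mg", sex = c("male", "female"),
               lower = c(11, 3), upper = c(40, 8)),
    data.frame(nutrient = "vitc_mg", sex = c("male", "female"),
               lower = c(90, 75), upper = 2000),
    data.frame(nutrient = "sodium_mg", sex = c("male", "female"),
               lower = 500, upper = 2300),
    data.frame(nutrient = "fiber_g", sex = c("male", "female"),
               lower = c(38, 25), upper = c(80, 80))
  )
}
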