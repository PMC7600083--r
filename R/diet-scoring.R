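#' Per-1000-kcal component densities
#'
#' Converts raw component amounts for one recall day into the density scale
#' the index standards are expressed in. For portion-based components the
#' density is `(grams / grams_per_portion) / (kcal / 1000)`; for
#' percent-energy components it is `100 * grams * energy_per_g / kcal`; for
#' gram-based components, `grams / (kcal / 1000)`; `ratio` components pass
#' through unchanged.
#'
#' @param amounts named numeric vector of component amounts (grams, or the
#'   ratio value for ratio-unit components). Missing components count as 0.
#' @param kcal the day's total energy (> 0).
#' @param standards a standards table such as [hei_standards()].
#' @return named numeric vector of densities, one per standards row.
#' @export
#' @examples
#' component_density(c(total_fruits = 250), kcal = 1000, hei_standards())
component_density <- function(amounts, kcal, standards) {
  if (length(kcal) != 1L || is.na(kcal) || kcal <= 0)
    stop("kcal must be a single positive number: density is undefined")
  unknown <- setdiff(names(amounts), standards$component)
  if (length(unknown))
    stop("unknown component(s): ", paste(unknown, collapse = ", "))
  a <- setNames(rep(0, nrow(standards)), standards$component)
  a[names(amounts)] <- amounts
  dens <- numeric(nrow(standards))
  for (i in seq_len(nrow(standards))) {
    dens[i] <- switch(standards$unit[i],
      cup_eq = ,
      oz_eq = (a[i] / standards$grams_per_portion[i]) / (kcal / 1000),
      grams = a[i] / (kcal / 1000),
      percent_energy = 100 * a[i] * standards$energy_per_g[i] / kcal,
      ratio = a[i],
      stop("unknown unit: ", standards$unit[i]))
  }
  setNames(dens, standards$component)
}

# linear interpolation between the zero- and max-point densities, clamped
score_component <- function(density, kind, dmax, dzero, max_points) {
  if (kind == "adequacy") {
    frac <- (density - dzero) / (dmax - dzero)
  } else {  # moderation: best at/below dmax, worst at/beyond dzero
    frac <- (dzero - density) / (dzero - dmax)
  }
  max_points * min(1, max(0, frac))
}

#' Score the adapted Healthy Eating Index (75-point ceiling)
#'
#' Each component scores linearly between its zero-point and max-point
#' density (moderation components reverse-scored); the total is the sum of
#' partial scores and is bounded by 75 under the default standards.
#'
#' @param densities named densities from [component_density()].
#' @param standards standards table, default [hei_standards()].
#' @return list with `total` and named `partial` scores.
#' @export
score_adapted_hei <- function(densities, standards = hei_standards()) {
  unknown <- setdiff(names(densities), standards$component)
  if (length(unknown))
    stop("unknown component(s): ", paste(unknown, collapse = ", "))
  d <- setNames(rep(0, nrow(standards)), standards$component)
  # an absent moderation density means zero intake, which is the best case
  d[standards$component[standards$kind == "moderation"]] <- 0
  d[names(densities)] <- densities
  partial <- vapply(seq_len(nrow(standards)), function(i) {
    score_component(d[standards$component[i]], standards$kind[i],
                    standards$density_for_max[i],
                    standards$density_for_zero[i], standards$max_points[i])
  }, numeric(1))
  names(partial) <- standards$component
  list(total = sum(partial), partial = partial)
}

#' Score the Colombian dietary-guidelines (GABA) index (70-point ceiling)
#'
#' Portions consumed per 1000 kcal are scored linearly up to the recommended
#' density implied by the (sex, age-group) specific recommendation at the
#' reference energy intake, capped at each component's maximum. The total
#' sums over the seven components.
#'
#' @param group_grams named grams by food group for one day.
#' @param kcal the day's energy (> 0).
#' @param sex,age_group person strata matching the standards table.
#' @param standards standards from [gaba_standards()].
#' @return list with `total` and named `partial` scores.
#' @export
score_gaba <- function(group_grams, kcal, sex, age_group,
                       standards = gaba_standards()) {
  if (kcal <= 0) stop("kcal must be positive")
  std <- standards[standards$sex == sex & standards$age_group == age_group, ]
  if (nrow(std) == 0L)
    stop("no standards for sex=", sex, ", age_group=", age_group)
  partial <- vapply(seq_len(nrow(std)), function(i) {
    g <- group_grams[[std$component[i]]]
    if (is.null(g) || is.na(g)) g <- 0
    density <- (g / std$grams_per_portion[i]) / (kcal / 1000)
    rec_density <- std$recommended_portions[i] / (std$reference_kcal[i] / 1000)
    std$max_points[i] * min(1, density / rec_density)
  }, numeric(1))
  names(partial) <- std$component
  list(total = sum(partial), partial = partial)
}

#' Percentage of calories from ultraprocessed foods
#'
#' Sums item energy over a set of recall records and reports the share
#' contributed by items flagged ultraprocessed. Items whose classification
#' is ambiguous are counted according to `ambiguous_policy`; computing the
#' percentage under both policies is the package's sensitivity analysis.
#'
#' @param records data.frame with `item_id` and `grams` (one or more days of
#'   one person, or any record subset).
#' @param db food database with `item_id`, `upf_status`, `kcal` per 100 g.
#' @param ambiguous_policy `"as_upf"` (default) or `"as_not_upf"`.
#' @return percentage in `[0, 100]`.
#' @export
upf_percentage <- function(records, db, ambiguous_policy = c("as_upf", "as_not_upf")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  m <- match(records$item_id, db$item_id)
  if (anyNA(m))
    stop("items not in database: ",
         paste(unique(records$item_id[is.na(m)]), collapse = ", "))
  kcal <- records$grams * db$kcal[m] / 100
  total <- sum(kcal)
  if (total <= 0) stop("total energy is zero: percentage undefined")
  status <- db$upf_status[m]
  is_upf <- status == "ultraprocessed" |
    (status == "ambiguous" & ambiguous_policy == "as_upf")
  100 * sum(kcal[is_upf]) / total
}

#' Classify a macronutrient distribution against the acceptable range
#'
#' Energy shares use 4/4/9 kcal per gram; the acceptable ranges are
#' carbohydrate 50--65%, protein 14--20% and fat 20--35% of energy, with
#' inclusive endpoints.
#'
#' @param carb_g,protein_g,fat_g usual daily intakes in grams.
#' @param kcal total energy; defaults to the energy implied by the macros.
#' @return list with `acceptable` (logical), `shares` (named percentages)
#'   and `flags` (`"low"`, `"ok"` or `"high"` per macronutrient).
#' @export
amdr_classify <- function(carb_g, protein_g, fat_g,
                          kcal = 4 * carb_g + 4 * protein_g + 9 * fat_g) {
  if (any(c(carb_g, protein_g, fat_g) < 0)) stop("negative intake")
  if (kcal <= 0) stop("kcal must be positive")
  shares <- c(carb = 100 * 4 * carb_g / kcal,
              protein = 100 * 4 * protein_g / kcal,
              fat = 100 * 9 * fat_g / kcal)
  lims <- rbind(carb = c(50, 65), protein = c(14, 20), fat = c(20, 35))
  flags <- vapply(names(shares), function(m) {
    if (shares[m] < lims[m, 1]) "low"
    else if (shares[m] > lims[m, 2]) "high" else "ok"
  }, character(1))
  list(acceptable = all(flags == "ok"), shares = shares, flags = flags)
}

#' Derive adapted-HEI component amounts from food-group and nutrient intake
#'
#' The adapted index is computed from what the recall pipeline knows: the
#' eleven food groups and the nutrient vector. The default mapping sends
#' fruits to total fruits (and, lacking juice information, also to whole
#' fruits), vegetables to total vegetables, beans to greens-and-beans, dairy
#' to dairy, meats+eggs+beans+nuts to protein foods, and takes the
#' fatty-acid ratio, sodium, added sugars and saturated fat straight from
#' the nutrient columns.
#'
#' @param group_grams named grams by food group for one day.
#' @param nutrients named nutrient vector for the day (`sfa_g`, `mufa_g`,
#'   `pufa_g`, `sodium_mg`, `sugar_g` used).
#' @return named amounts suitable for [component_density()].
#' @export
hei_components_from_intake <- function(group_grams, nutrients) {
  g <- function(x) { v <- group_grams[[x]]; if (is.null(v) || is.na(v)) 0 else v }
  nv <- function(x) { v <- nutrients[[x]]; if (is.null(v) || is.na(v)) 0 else v }
  sfa <- nv("sfa_g")
  ratio <- if (sfa > 0) (nv("mufa_g") + nv("pufa_g")) / sfa else 0
  c(total_fruits = g("fruits"),
    whole_fruits = g("fruits"),
    total_vegetables = g("vegetables"),
    greens_beans = g("beans"),
    dairy = g("dairy"),
    protein_foods = g("meats") + g("eggs") + g("beans") + g("nuts"),
    fatty_acids = ratio,
    sodium = nv("sodium_mg") / 1000,
    added_sugars = nv("sugar_g"),
    saturated_fats = sfa)
}
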