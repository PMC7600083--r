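#' Generate a balanced synthetic covariate table
#'
#' Emulates a community-dwelling cohort recruited in approximately equal
#' proportions across five cities, two sexes, two age groups and three BMI
#' classes. Persons are dealt round-robin over a randomly ordered list of the
#' 60 design cells, so every cell count is balanced to within one.
#' Socioeconomic level (1--6) is sampled independently with levels 2--4
#' carrying most of the mass (>80%), as in the cohort the generator emulates.
#'
#' @param n number of persons (>= 1).
#' @param seed integer seed.
#' @param ses_probs sampling probabilities for socioeconomic levels 1--6.
#' @return a data.frame with columns `person_id`, `city`, `sex`,
#'   `age_group`, `bmi_class`, `ses`.
#' @export
#' @examples
#' head(generate_covariates(60, seed = 1))
generate_covariates <- function(n, seed = 1L,
                                ses_probs = c(0.04, 0.30, 0.33, 0.23, 0.06, 0.04)) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a single integer >= 1")
  n <- as.integer(n)
  stopifnot(length(ses_probs) == 6L, all(ses_probs >= 0))
  withr_seed(split_seed(seed, "covariates"))

  cities <- c("bogota", "medellin", "cali", "barranquilla", "bucaramanga")
  cells <- expand.grid(city = cities, sex = c("male", "female"),
                       age_group = c("18-40", "41-62"),
                       bmi_class = c("lean", "overweight", "obese"),
                       stringsAsFactors = FALSE)
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
  assign <- cells[rep_len(seq_len(nrow(cells)), n), , drop = FALSE]
  out <- data.frame(
    person_id = sprintf("P%04d", seq_len(n)),
    assign,
    ses = sample(1:6, n, replace = TRUE, prob = ses_probs / sum(ses_probs)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[sample.int(n), , drop = FALSE] -> out  # shuffle so id order is not the design order
  out$person_id <- sprintf("P%04d", seq_len(n))
  rownames(out) <- NULL
  out
}

# run code under a local RNG state restored on exit
withr_seed <- function(seed) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  set.seed(seed)
  invisible(seed)
}

#' Generate a synthetic food composition database
#'
#' Items are spread over the eleven food groups of the Colombian food-based
#' dietary guidelines (dairy, meats, eggs, beans, nuts, fruits, vegetables,
#' cereals, tubers, fats, sugars), each group receiving at least one item.
#' Macronutrient composition per 100 g is drawn around group-typical
#' profiles; energy obeys the 4/4/9 kcal-per-gram rule to within 10%.
#' A configurable fraction of items is flagged ultraprocessed and a small
#' fraction (default 7%) is flagged `ambiguous` (classifiable either way, the
#' basis of the package's sensitivity analysis).
#'
#' @param n_items number of items (>= 11).
#' @param seed integer seed.
#' @param upf_frac fraction of unambiguous items flagged ultraprocessed.
#' @param ambiguous_frac fraction flagged ambiguous (default 0.07).
#' @return data.frame with `item_id`, `food_group`, `upf_status`, the energy
#'   column `kcal`, and nutrient composition per 100 g (`carb_g`,
#'   `protein_g`, `fat_g`, `sfa_g`, `mufa_g`, `pufa_g`, `cholesterol_mg`,
#'   `fiber_g`, `sugar_g`, `sodium_mg`, `calcium_mg`, `zinc_mg`, `vitc_mg`).
#' @export
generate_food_database <- function(n_items, seed = 1L, upf_frac = 0.30,
                                   ambiguous_frac = 0.07) {
  if (length(n_items) != 1L || is.na(n_items) || n_items < 11)
    stop("n_items must be >= 11 (one per food group)")
  n_items <- as.integer(n_items)
  withr_seed(split_seed(seed, "fooddb"))

  groups <- food_groups()
  # group-typical macro profile per 100 g: carb, protein, fat, fiber, sugar
  prof <- rbind(
    dairy      = c(5,  3.5, 3.5, 0.0, 5),
    meats      = c(0, 22,  10,  0.0, 0),
    eggs       = c(1, 13,  10,  0.0, 1),
    beans      = c(20,  8,  1,  7.0, 1),
    nuts       = c(15, 18, 50,  8.0, 4),
    fruits     = c(13,  1,  0.3, 2.5, 10),
    vegetables = c(5,  2,  0.3, 2.5, 3),
    cereals    = c(60,  9,  2,  3.0, 2),
    tubers     = c(20,  2,  0.1, 2.0, 1),
    fats       = c(1,  0.5, 80, 0.0, 0),
    sugars     = c(70,  1,  8,  0.5, 55)
  )
  fg <- c(groups, sample(groups, n_items - length(groups), replace = TRUE))
  jitter <- function(x) pmax(0, x * exp(rnorm(length(x), 0, 0.25)))
  carb <- jitter(prof[fg, 1]); protein <- jitter(prof[fg, 2])
  fat <- jitter(prof[fg, 3]);  fiber <- jitter(prof[fg, 4])
  sugar <- pmin(jitter(prof[fg, 5]), carb)
  kcal <- (4 * carb + 4 * protein + 9 * fat) * runif(n_items, 0.95, 1.05)
  # fatty-acid split of total fat; animal-source groups are SFA-heavy
  sfa_share <- ifelse(fg %in% c("dairy", "meats", "eggs", "sugars"),
                      runif(n_items, 0.40, 0.55), runif(n_items, 0.10, 0.30))
  pufa_share <- pmin(1 - sfa_share, runif(n_items, 0.15, 0.45))
  sfa <- fat * sfa_share
  pufa <- fat * pufa_share
  mufa <- pmax(fat - sfa - pufa, 0)
  chol <- ifelse(fg %in% c("meats", "eggs", "dairy"),
                 runif(n_items, 20, 400), runif(n_items, 0, 5))

  n_amb <- round(ambiguous_frac * n_items)
  n_upf <- round(upf_frac * (n_items - n_amb))
  status <- rep("not_ultraprocessed", n_items)
  # ultraprocessed items concentrate in sugars/fats/cereals-like groups
  upf_weight <- ifelse(fg %in% c("sugars", "fats", "cereals", "dairy"), 3, 1)
  ord <- sample.int(n_items, prob = upf_weight)
  status[ord[seq_len(n_upf)]] <- "ultraprocessed"
  if (n_amb > 0)
    status[ord[n_upf + seq_len(n_amb)]] <- "ambiguous"

  data.frame(
    item_id = sprintf("F%03d", seq_len(n_items)),
    food_group = fg, upf_status = status,
    kcal = kcal, carb_g = carb, protein_g = protein, fat_g = fat,
    sfa_g = sfa, mufa_g = mufa, pufa_g = pufa, cholesterol_mg = chol,
    fiber_g = fiber, sugar_g = sugar,
    sodium_mg = pmax(0, rnorm(n_items, ifelse(status == "ultraprocessed", 400, 120), 60)),
    calcium_mg = pmax(0, rnorm(n_items, ifelse(fg == "dairy", 120, 25), 15)),
    zinc_mg = pmax(0, rnorm(n_items, ifelse(fg %in% c("meats", "beans"), 3, 0.5), 0.3)),
    vitc_mg = pmax(0, rnorm(n_items, ifelse(fg %in% c("fruits", "vegetables", "tubers"), 30, 1), 8)),
    stringsAsFactors = FALSE
  )
}

#' The eleven food groups of the Colombian dietary guidelines
#' @return character vector of the 11 group names.
#' @export
food_groups <- function() {
  c("dairy", "meats", "eggs", "beans", "nuts", "fruits", "vegetables",
    "cereals", "tubers", "fats", "sugars")
}

#' Generate synthetic 24-hour dietary recalls
#'
#' Every person receives a day-1 recall; `ceiling(repeat_fraction * n)`
#' persons (or exactly `n_repeat` when given) receive a second recall on
#' another day. Per-person caloric intake follows a one-way random-effects
#' model on the kcal scale: a latent person mean around the sex-specific
#' cohort mean (defaults 2135 kcal for males, 1750 kcal for females, the
#' population this generator emulates), plus within-person day-to-day noise
#' whose variance is `var_ratio` times the between-person variance. Items
#' are drawn from the food database with higher weight on staple groups, and
#' grams are rescaled so each day's total energy hits the drawn target.
#'
#' @param covariates covariate table from [generate_covariates()].
#' @param db food database from [generate_food_database()].
#' @param seed integer seed.
#' @param repeat_fraction fraction of persons with a second recall, in `[0,1]`.
#' @param n_repeat optional integer override for the number of repeats.
#' @param kcal_mean named vector `c(male=, female=)` of day-1 kcal means.
#' @param kcal_sd_between between-person SD of the latent mean (kcal).
#' @param var_ratio within- to between-person variance ratio (default 1.5).
#' @param items_per_day range (min, max) of distinct items per recall day.
#' @param age_kcal_shift kcal added for age group 18-40 and subtracted for
#'   41-62 (half-difference; younger people eat more in the emulated cohort).
#' @param preference_sd SD of the person-level log item-preference weights.
#'   People eat from a personal repertoire: both recall days of a person
#'   draw items with the same person-specific weights, which is what makes
#'   between-person nutrient variance identifiable from repeat recalls.
#' @return data.frame with columns `person_id`, `day`, `item_id`, `grams`.
#' @export
generate_recalls <- function(covariates, db, seed = 1L, repeat_fraction = 0.21,
                             n_repeat = NULL,
                             kcal_mean = c(male = 2135, female = 1750),
                             kcal_sd_between = 250, var_ratio = 1.5,
                             items_per_day = c(8L, 15L),
                             age_kcal_shift = 90, preference_sd = 1.2) {
  if (nrow(db) == 0L) stop("food database is empty")
  if (repeat_fraction < 0 || repeat_fraction > 1)
    stop("repeat_fraction must be in [0, 1]")
  withr_seed(split_seed(seed, "recalls"))

  n <- nrow(covariates)
  nrep <- if (is.null(n_repeat)) ceiling(repeat_fraction * n) else as.integer(n_repeat)
  nrep <- min(nrep, n)
  repeat_ids <- sample(covariates$person_id, nrep)

  mu <- unname(kcal_mean[covariates$sex]) +
    ifelse(covariates$age_group == "18-40", age_kcal_shift, -age_kcal_shift)
  person_mean <- rnorm(n, mu, kcal_sd_between)
  sd_within <- sqrt(var_ratio) * kcal_sd_between

  # staples dominate reported grams in the emulated cohort
  gw <- c(dairy = 2, meats = 1.5, eggs = 1, beans = 0.7, nuts = 0.2,
          fruits = 2, vegetables = 1.5, cereals = 3, tubers = 1.5,
          fats = 0.8, sugars = 2)
  item_w <- unname(gw[db$food_group])
  # person-specific repertoire: same weights on both recall days
  pref <- matrix(rexp(n * nrow(db)) * exp(rnorm(n * nrow(db), 0, preference_sd)),
                 n, nrow(db))
  pref <- sweep(pref, 2, item_w, `*`)

  one_day <- function(i, pid, day, target) {
    k <- sample(seq.int(items_per_day[1], items_per_day[2]), 1L)
    rows <- sample.int(nrow(db), k, prob = pref[i, ])
    g <- rexp(k, 1 / 120)  # raw grams before energy calibration
    e <- sum(g * db$kcal[rows] / 100)
    if (e <= 0) g <- rep(100, k) else g <- g * target / e
    data.frame(person_id = pid, day = day, item_id = db$item_id[rows],
               grams = g, stringsAsFactors = FALSE)
  }

  recs <- vector("list", n + nrep)
  for (i in seq_len(n)) {
    t1 <- max(300, person_mean[i] + rnorm(1, 0, sd_within))
    recs[[i]] <- one_day(i, covariates$person_id[i], 1L, t1)
  }
  for (j in seq_along(repeat_ids)) {
    i <- match(repeat_ids[j], covariates$person_id)
    t2 <- max(300, person_mean[i] + rnorm(1, 0, sd_within))
    recs[[n + j]] <- one_day(i, repeat_ids[j], 2L, t2)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
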