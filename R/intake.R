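#' Aggregate recall records into the eleven food groups
#'
#' @param recalls data.frame `person_id`, `day`, `item_id`, `grams`.
#' @param db food database with `item_id`, `food_group`.
#' @return data.frame with `person_id`, `day` and one grams column per food
#'   group (groups with no items report 0); total grams are conserved.
#' @export
aggregate_food_groups <- function(recalls, db) {
  m <- match(recalls$item_id, db$item_id)
  if (anyNA(m))
    stop("unresolvable item_id(s): ",
         paste(unique(recalls$item_id[is.na(m)]), collapse = ", "))
  groups <- food_groups()
  fg <- factor(db$food_group[m], levels = groups)
  key <- interaction(recalls$person_id, recalls$day, drop = TRUE,
                     lex.order = TRUE, sep = "\t")
  agg <- tapply(recalls$grams, list(key, fg), sum, default = 0)
  agg[is.na(agg)] <- 0
  ids <- do.call(rbind, strsplit(rownames(agg), "\t", fixed = TRUE))
  out <- data.frame(person_id = ids[, 1], day = as.integer(ids[, 2]),
                    agg, row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out[order(out$person_id, out$day), , drop = FALSE]
}

#' Compute daily nutrient intakes from recall records
#'
#' Each record contributes `grams / 100 * composition_per_100g`; nutrients
#' sum linearly over the items of a person-day. The day's `kcal` is the sum
#' of item energies.
#'
#' @param recalls data.frame `person_id`, `day`, `item_id`, `grams`.
#' @param db food database whose nutrient columns include `kcal`.
#' @param nutrients which composition columns to compute (default: every
#'   numeric composition column in `db`).
#' @return data.frame `person_id`, `day`, one column per nutrient.
#' @export
compute_nutrients <- function(recalls, db, nutrients = NULL) {
  if (is.null(nutrients))
    nutrients <- setdiff(names(db)[vapply(db, is.numeric, logical(1))],
                         c("item_id"))
  missing_cols <- setdiff(nutrients, names(db))
  if (length(missing_cols))
    stop("missing nutrient column(s) in database: ",
         paste(missing_cols, collapse = ", "))
  m <- match(recalls$item_id, db$item_id)
  if (anyNA(m))
    stop("unresolvable item_id(s): ",
         paste(unique(recalls$item_id[is.na(m)]), collapse = ", "))
  key <- interaction(recalls$person_id, recalls$day, drop = TRUE,
                     lex.order = TRUE, sep = "\t")
  vals <- vapply(nutrients, function(nc) {
    contrib <- recalls$grams / 100 * db[[nc]][m]
    as.numeric(tapply(contrib, key, sum, default = 0))
  }, numeric(nlevels(key)))
  vals <- matrix(vals, nrow = nlevels(key),
                 dimnames = list(NULL, nutrients))
  ids <- do.call(rbind, strsplit(levels(key), "\t", fixed = TRUE))
  out <- data.frame(person_id = ids[, 1], day = as.integer(ids[, 2]), vals,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$person_id, out$day), , drop = FALSE]
}

#' Usual-intake BLUP shrinkage for one nutrient
#'
#' Fits the one-way random-effects measurement-error model
#' `x_ij = mu + b_i + e_ij` on the (optionally log1p-transformed) daily
#' intakes, with unbalanced method-of-moments variance components (Searle's
#' `n0 = (N - sum(n_i^2)/N) / (a - 1)`), and shrinks each person's mean
#' toward the grand mean: `BLUP_i = mu + lambda_i (xbar_i - mu)` with
#' `lambda_i = sigma_b^2 / (sigma_b^2 + sigma_w^2 / n_i)`. A negative
#' between-person moment estimate is clamped to zero (all BLUPs collapse to
#' the grand mean). Persons with a single recall are shrunk using the
#' cohort-level components. The result is back-transformed to the intake
#' scale.
#'
#' @param person_id vector of person ids, one per daily observation.
#' @param x daily intake values aligned with `person_id`.
#' @param transform `"log1p"` (default) or `"none"`.
#' @return data.frame `person_id`, `n_days`, `person_mean`, `blup` (intake
#'   scale), `blup_t` and `person_mean_t` (transformed scale), plus
#'   attributes `mu`, `sigma2_b`, `sigma2_w`, `transform`.
#' @export
estimate_blup <- function(person_id, x, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  stopifnot(length(person_id) == length(x))
  keep <- !is.na(x)
  person_id <- as.character(person_id)[keep]
  xt <- if (transform == "log1p") log1p(x[keep]) else x[keep]

  ni <- table(person_id)
  a <- length(ni)
  N <- sum(ni)
  if (a < 2 || !any(ni >= 2))
    stop("variance components unidentifiable: need >= 2 persons and at ",
         "least one person with >= 2 recall days; use pass-through instead")
  mu <- mean(xt)
  xbar <- tapply(xt, person_id, mean)
  ss_within <- sum((xt - xbar[person_id])^2)
  ms_within <- ss_within / (N - a)
  ms_between <- sum(ni * (xbar - mu)^2) / (a - 1)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  s2w <- ms_within
  s2b <- max(0, (ms_between - ms_within) / n0)

  lambda <- s2b / (s2b + s2w / as.numeric(ni))
  blup_t <- mu + lambda * (xbar - mu)
  blup <- if (transform == "log1p") expm1(blup_t) else blup_t
  pm <- if (transform == "log1p") expm1(xbar) else xbar

  out <- data.frame(person_id = names(xbar), n_days = as.integer(ni),
                    person_mean = as.numeric(pm), blup = as.numeric(blup),
                    person_mean_t = as.numeric(xbar),
                    blup_t = as.numeric(blup_t),
                    stringsAsFactors = FALSE)
  attr(out, "mu") <- mu
  attr(out, "sigma2_b") <- s2b
  attr(out, "sigma2_w") <- s2w
  attr(out, "transform") <- transform
  out
}

#' BLUP-normalized usual intakes for a whole daily-intake table
#'
#' Applies [estimate_blup()] column-wise to every nutrient of a daily-intake
#' table (as produced by [compute_nutrients()]).
#'
#' @param daily data.frame with `person_id`, `day` and nutrient columns.
#' @param transform passed to [estimate_blup()].
#' @return data.frame `person_id` plus one usual-intake column per nutrient,
#'   with a `components` attribute recording the fitted variance components.
#' @export
usual_intakes <- function(daily, transform = "log1p") {
  nut_cols <- setdiff(names(daily), c("person_id", "day"))
  fits <- lapply(nut_cols, function(nc)
    estimate_blup(daily$person_id, daily[[nc]], transform = transform))
  ids <- fits[[1]]$person_id
  out <- data.frame(person_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(nut_cols)) out[[nut_cols[i]]] <- fits[[i]]$blup
  attr(out, "components") <- data.frame(
    nutrient = nut_cols,
    mu = vapply(fits, attr, numeric(1), "mu"),
    sigma2_b = vapply(fits, attr, numeric(1), "sigma2_b"),
    sigma2_w = vapply(fits, attr, numeric(1), "sigma2_w"))
  out
}

#' Classify usual micronutrient intakes against requirement bands
#'
#' @param usual data.frame `person_id` plus nutrient columns (usual intakes).
#' @param covariates covariate table supplying `sex` per person.
#' @param requirements data.frame `nutrient`, `sex`, `lower`, `upper`
#'   (default [default_requirements()]).
#' @return long data.frame `person_id`, `nutrient`, `intake`, `status` with
#'   status in deficient/adequate/excess.
#' @export
micronutrient_adequacy <- function(usual, covariates,
                                   requirements = default_requirements()) {
  sex <- covariates$sex[match(usual$person_id, covariates$person_id)]
  nuts <- intersect(unique(requirements$nutrient), names(usual))
  if (!length(nuts)) stop("no requirement rows match the intake columns")
  out <- do.call(rbind, lapply(nuts, function(nc) {
    req <- requirements[requirements$nutrient == nc, ]
    m <- match(sex, req$sex)
    if (anyNA(m)) stop("missing requirement row for nutrient ", nc)
    intake <- usual[[nc]]
    status <- ifelse(intake < req$lower[m], "deficient",
                     ifelse(intake > req$upper[m], "excess", "adequate"))
    data.frame(person_id = usual$person_id, nutrient = nc, intake = intake,
               status = status, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
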