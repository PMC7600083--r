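#' Generate a random rooted bifurcating phylogeny over OTUs
#'
#' A random-join (coalescent-style) topology with exponential branch lengths,
#' leaves labelled `OTU0001`, `OTU0002`, ... The returned object is an
#' [ape::read.tree()] compatible `phylo`; [ape::write.tree()] round-trips it
#' through standard Newick.
#'
#' @param n_leaves number of OTUs (>= 2).
#' @param seed integer seed.
#' @param mean_branch mean of the exponential branch-length distribution.
#' @return an `ape::phylo` object with `n_leaves` tips.
#' @export
generate_tree <- function(n_leaves, seed = 1L, mean_branch = 0.1) {
  if (length(n_leaves) != 1L || is.na(n_leaves) || n_leaves < 2)
    stop("n_leaves must be >= 2")
  n_leaves <- as.integer(n_leaves)
  withr_seed(split_seed(seed, "tree"))
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   tip.label = sprintf("OTU%04d", seq_len(n_leaves)))
  tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / mean_branch)
  tr
}

#' Planted diet effect specification
#'
#' Describes a ground-truth association to plant in a synthetic OTU table:
#' the log-abundance of each OTU in `target_otus` is shifted by
#' `effect_size` (with `direction`) per one standard deviation of the diet
#' `driver`. Used by [generate_microbiome()] and recovered by the
#' association layer in tests.
#'
#' @param target_otus character vector of OTU ids (must be tree leaves).
#' @param driver name of a column of the diet-driver table.
#' @param effect_size non-negative log-abundance shift per 1 SD of driver.
#' @param direction `"+"` or `"-"`.
#' @return an object of class `planted_effect`.
#' @export
planted_effect <- function(target_otus, driver, effect_size, direction = "+") {
  stopifnot(is.character(target_otus), length(target_otus) >= 1,
            effect_size >= 0, direction %in% c("+", "-"))
  structure(list(target_otus = target_otus, driver = driver,
                 effect_size = effect_size, direction = direction),
            class = "planted_effect")
}

#' Generate a synthetic OTU count table with planted diet effects
#'
#' Per-sample OTU counts follow a log-normal compositional model: a global
#' base log-abundance per OTU, plus covariate offsets (city > sex > BMI, in
#' decreasing magnitude, mirroring the covariate hierarchy of the emulated
#' cohort), plus the planted `effect_size * z(driver)` shifts, plus
#' person-level noise (overdispersion). Relative abundances are the softmax
#' of this log-abundance and counts are multinomial draws at a per-sample
#' depth uniform in `depth_range`. Taxonomy labels are assigned so that a
#' designated block of OTUs are Clostridia ("SCFA producers"), another block
#' Bacteroidia, a small block Gammaproteobacteria ("bile-tolerant/pathogen"
#' guild) and the remainder minor classes.
#'
#' @param covariates covariate table; `person_id` becomes the sample ids.
#' @param diet_drivers data.frame of per-person numeric diet variables, rows
#'   aligned with `covariates` (a `person_id` column, if present, is checked
#'   and dropped).
#' @param tree phylogeny from [generate_tree()]; its tips define the OTUs.
#' @param effects list of [planted_effect()] objects (may be empty).
#' @param seed integer seed.
#' @param depth_range integer vector `c(min, max)` of sequencing depths
#'   (default the 3667--102660 read range of the emulated dataset).
#' @param base_sd SD of the base log-abundance across OTUs (rank-abundance
#'   steepness).
#' @param noise_sd person-level log-abundance noise (overdispersion).
#' @param covariate_sd named vector of offset SDs for `city`, `sex`,
#'   `bmi_class`.
#' @return list with `counts` (samples x OTUs integer matrix, rownames =
#'   person ids), `taxonomy` (data.frame `otu_id`, `phylum`, `class`,
#'   `label`), `depths`, and `guilds` (the designated SCFA-producer /
#'   bile-tolerant OTU id sets, handy when choosing plant targets).
#' @export
generate_microbiome <- function(covariates, diet_drivers = NULL, tree,
                                effects = list(), seed = 1L,
                                depth_range = c(3667L, 102660L),
                                base_sd = 2.0, noise_sd = 0.6,
                                covariate_sd = c(city = 0.45, sex = 0.2,
                                                 bmi_class = 0.12)) {
  otus <- tree$tip.label
  n_otu <- length(otus)
  n <- nrow(covariates)
  if (!is.null(diet_drivers)) {
    if ("person_id" %in% names(diet_drivers)) {
      if (!identical(as.character(diet_drivers$person_id),
                     as.character(covariates$person_id)))
        stop("diet_drivers rows must align with covariates person_id")
      diet_drivers <- diet_drivers[setdiff(names(diet_drivers), "person_id")]
    }
    if (nrow(diet_drivers) != n)
      stop("diet_drivers rows must align with covariates")
  }
  for (e in effects) {
    bad <- setdiff(e$target_otus, otus)
    if (length(bad))
      stop("planted-effect target OTUs not in tree: ",
           paste(bad, collapse = ", "))
    if (!is.null(e$driver) &&
        (is.null(diet_drivers) || !e$driver %in% names(diet_drivers)))
      stop("unknown driver column: ", e$driver)
  }
  withr_seed(split_seed(seed, "microbiome"))

  # taxonomy guilds: first half Clostridia, next quarter Bacteroidia,
  # small Gammaproteobacteria block, remainder minor classes
  n_clos <- floor(0.50 * n_otu)
  n_bact <- floor(0.25 * n_otu)
  n_gam <- max(1, floor(0.05 * n_otu))
  cls <- rep("minor", n_otu)
  cls[seq_len(n_clos)] <- "Clostridia"
  cls[n_clos + seq_len(n_bact)] <- "Bacteroidia"
  cls[n_clos + n_bact + seq_len(n_gam)] <- "Gammaproteobacteria"
  minor_pool <- c("Actinobacteria", "Verrucomicrobiae", "Erysipelotrichi",
                  "Methanobacteria", "Deltaproteobacteria")
  cls[cls == "minor"] <- sample(minor_pool, sum(cls == "minor"), replace = TRUE)
  phyla <- c(Clostridia = "Firmicutes", Bacteroidia = "Bacteroidetes",
             Gammaproteobacteria = "Proteobacteria",
             Actinobacteria = "Actinobacteria",
             Verrucomicrobiae = "Verrucomicrobia",
             Erysipelotrichi = "Firmicutes",
             Methanobacteria = "Euryarchaeota",
             Deltaproteobacteria = "Proteobacteria")
  taxonomy <- data.frame(otu_id = otus, phylum = unname(phyla[cls]),
                         class = cls,
                         label = paste0(cls, "_sp_", seq_len(n_otu)),
                         stringsAsFactors = FALSE)

  base <- rnorm(n_otu, 0, base_sd)
  # Firmicutes/Bacteroidetes dominance: nudge the two major classes up
  base <- base + ifelse(cls %in% c("Clostridia", "Bacteroidia"), 0.8, 0)

  offset_for <- function(fac, sdev) {
    lev <- unique(fac)
    off <- matrix(rnorm(length(lev) * n_otu, 0, sdev), length(lev),
                  dimnames = list(lev, NULL))
    off[fac, , drop = FALSE]
  }
  L <- matrix(base, n, n_otu, byrow = TRUE) +
    offset_for(covariates$city, covariate_sd[["city"]]) +
    offset_for(covariates$sex, covariate_sd[["sex"]]) +
    offset_for(covariates$bmi_class, covariate_sd[["bmi_class"]])

  for (e in effects) {
    z <- scale(diet_drivers[[e$driver]])[, 1]
    sgn <- if (e$direction == "+") 1 else -1
    j <- match(e$target_otus, otus)
    L[, j] <- L[, j] + sgn * e$effect_size * z
  }
  L <- L + matrix(rnorm(n * n_otu, 0, noise_sd), n, n_otu)

  depths <- if (depth_range[1] == depth_range[2]) rep(depth_range[1], n) else
    sample(seq.int(depth_range[1], depth_range[2]), n, replace = TRUE)
  counts <- matrix(0L, n, n_otu,
                   dimnames = list(as.character(covariates$person_id), otus))
  for (i in seq_len(n)) {
    p <- exp(L[i, ] - max(L[i, ]))
    counts[i, ] <- as.integer(rmultinom(1, depths[i], p / sum(p)))
  }
  list(counts = counts, taxonomy = taxonomy, depths = depths,
       guilds = list(scfa_producers = otus[cls == "Clostridia"],
                     bile_tolerant = otus[cls %in% c("Bacteroidia",
                                                     "Gammaproteobacteria")]))
}
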