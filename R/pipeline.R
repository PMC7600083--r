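#' Score diet quality for a whole cohort of recalls
#'
#' Computes, per person: the adapted HEI (averaged over recall days), the
#' GABA index (averaged over days, using the person's sex and age group)
#' and the percentage of calories from ultraprocessed foods (over all the
#' person's records), under the requested ambiguous-item policy.
#'
#' @param recalls recall records (`person_id`, `day`, `item_id`, `grams`).
#' @param db food database.
#' @param covariates covariate table (sex, age group per person).
#' @param ambiguous_policy passed to [upf_percentage()].
#' @param hei_std,gaba_std standards tables.
#' @return data.frame `person_id`, `hei`, `gaba`, `upf_pct`.
#' @export
score_diet_cohort <- function(recalls, db, covariates,
                              ambiguous_policy = "as_upf",
                              hei_std = hei_standards(),
                              gaba_std = gaba_standards()) {
  fg <- aggregate_food_groups(recalls, db)
  nut <- compute_nutrients(recalls, db)
  stopifnot(identical(fg$person_id, nut$person_id),
            identical(fg$day, nut$day))
  groups <- food_groups()
  hei_day <- numeric(nrow(fg))
  gaba_day <- numeric(nrow(fg))
  cov_row <- match(fg$person_id, covariates$person_id)
  for (i in seq_len(nrow(fg))) {
    gg <- as.list(fg[i, groups])
    nv <- as.list(nut[i, setdiff(names(nut), c("person_id", "day"))])
    kcal <- nv$kcal
    dens <- component_density(hei_components_from_intake(gg, nv), kcal, hei_std)
    hei_day[i] <- score_adapted_hei(dens, hei_std)$total
    gaba_day[i] <- score_gaba(gg, kcal, covariates$sex[cov_row[i]],
                              covariates$age_group[cov_row[i]], gaba_std)$total
  }
  hei <- tapply(hei_day, fg$person_id, mean)
  gaba <- tapply(gaba_day, fg$person_id, mean)
  ids <- names(hei)
  upf <- vapply(ids, function(p)
    upf_percentage(recalls[recalls$person_id == p, , drop = FALSE], db,
                   ambiguous_policy), numeric(1))
  data.frame(person_id = ids, hei = as.numeric(hei),
             gaba = as.numeric(gaba), upf_pct = as.numeric(upf),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build and validate a pipeline run configuration
#'
#' Exactly one of `inputs` (paths to covariates/recalls/food-db/OTU
#' table/taxonomy/tree files) or `simulate` (parameters for the synthetic
#' generators) must be given. Defaults mirror the reference analysis:
#' rarefaction at the minimum sample depth, ambiguous ultraprocessed items
#' counted as ultraprocessed, 10000 Procrustes and 999 PERMANOVA
#' permutations, 50000 random-forest trees (use far fewer for smoke tests).
#'
#' @param inputs named list of file paths (`covariates`, `recalls`,
#'   `food_db`, `otu_table`, `taxonomy`, `tree`), or NULL.
#' @param simulate named list of generator settings (`n`, `n_items`,
#'   `n_otus`, `repeat_fraction`, `depth_range`, `effects`), or NULL.
#' @param seed master seed; every stage derives its stream via
#'   [split_seed()].
#' @param depth rarefaction depth policy: `"auto-min"` or a fixed integer.
#' @param ambiguous_policy `"as_upf"` or `"as_not_upf"`.
#' @param rf list with `n_trees`, `variables` (NULL = default panel),
#'   `min_otus`.
#' @param n_perm list with `permanova`, `procrustes` counts.
#' @return validated config list of class `dietbiome_config`.
#' @export
run_config <- function(inputs = NULL, simulate = NULL, seed = 1L,
                       depth = "auto-min", ambiguous_policy = "as_upf",
                       rf = list(), n_perm = list()) {
  if (is.null(inputs) == is.null(simulate))
    stop("exactly one of `inputs` or `simulate` must be provided")
  rf <- modifyList(list(n_trees = 50000, variables = NULL, min_otus = 3L), rf)
  n_perm <- modifyList(list(permanova = 999, procrustes = 10000), n_perm)
  if (rf$n_trees < 1 || n_perm$permanova < 1 || n_perm$procrustes < 1)
    stop("all counts must be positive")
  if (!is.null(simulate))
    simulate <- modifyList(list(n = 120, n_items = 100, n_otus = 150,
                                repeat_fraction = 0.21,
                                depth_range = c(3667, 20000),
                                effect_size = 1.0, n_target = 5), simulate)
  structure(list(inputs = inputs, simulate = simulate, seed = seed,
                 depth = depth, ambiguous_policy = ambiguous_policy,
                 rf = rf, n_perm = n_perm),
            class = "dietbiome_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with fields as in [run_config()].
#' @return a `dietbiome_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    seed <- config$seed
    covariates <- generate_covariates(sim$n, seed = seed)
    db <- generate_food_database(sim$n_items, seed = seed)
    recalls <- generate_recalls(covariates, db, seed = seed,
                                repeat_fraction = sim$repeat_fraction)
    tree <- generate_tree(sim$n_otus, seed = seed)
    # planted ground truth: fiber drives a Clostridia block up, saturated
    # fat drives a Bacteroidia/pathogen block up
    daily <- compute_nutrients(recalls, db)
    drivers <- data.frame(
      fiber = as.numeric(tapply(daily$fiber_g, daily$person_id, mean)[covariates$person_id]),
      sfa = as.numeric(tapply(daily$sfa_g, daily$person_id, mean)[covariates$person_id]))
    mb0 <- generate_microbiome(covariates, NULL, tree, list(), seed = seed,
                               depth_range = sim$depth_range)
    effects <- list(
      planted_effect(head(mb0$guilds$scfa_producers, sim$n_target),
                     "fiber", sim$effect_size, "+"),
      planted_effect(head(mb0$guilds$bile_tolerant, sim$n_target),
                     "sfa", sim$effect_size, "+"))
    mb <- generate_microbiome(covariates, drivers, tree, effects,
                              seed = seed, depth_range = sim$depth_range)
    list(covariates = covariates, db = db, recalls = recalls, tree = tree,
         counts = mb$counts, taxonomy = mb$taxonomy, effects = effects)
  } else {
    ip <- config$inputs
    list(covariates = read.csv(ip$covariates, stringsAsFactors = FALSE),
         db = read.csv(ip$food_db, stringsAsFactors = FALSE),
         recalls = read.csv(ip$recalls, stringsAsFactors = FALSE),
         tree = ape::read.tree(ip$tree),
         counts = read_otu_table(ip$otu_table),
         taxonomy = read.delim(ip$taxonomy, stringsAsFactors = FALSE),
         effects = list())
  }
}

#' Read/write an OTU table as TSV (rows = OTUs, columns = samples)
#' @param path TSV path.
#' @param counts samples x OTUs matrix (transposed on disk).
#' @return `read_otu_table` returns a samples x OTUs integer matrix.
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  t(as.matrix(df))
}

#' @rdname read_otu_table
#' @export
write_otu_table <- function(counts, path) {
  df <- as.data.frame(t(counts))
  write.table(cbind(otu_id = rownames(df), df), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_dist <- function(d, path) {
  df <- as.data.frame(as.matrix(d))
  write.table(cbind(sample_id = rownames(df), df), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full diet-microbiota pipeline
#'
#' Executes every stage in dependency order: input loading or simulation,
#' diet-quality scoring, food-group/nutrient/usual-intake estimation,
#' rarefaction and diversity, and the association layer (PCA, adjusted
#' alpha regressions, PERMANOVA, Procrustes, random-forest OTU selection).
#' All outputs are plain CSV/TSV under `out_dir`, plus a JSON manifest with
#' seeds, the rarefaction depth and the md5 checksum of every file, which
#' makes a completed run verifiable and re-runs no-ops (stages whose
#' outputs already match the manifest are skipped unless `force`).
#'
#' @param config a `dietbiome_config` from [run_config()].
#' @param out_dir output directory (created if needed).
#' @param force rerun stages whose outputs are already up to date.
#' @param quiet suppress per-stage messages.
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config, out_dir, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "dietbiome_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path) && !force)
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()
  manifest$seed <- config$seed
  manifest$package_version <- as.character(utils::packageVersion("dietbiome"))
  checksums <- as.list(manifest$checksums %||% list())

  up_to_date <- function(files) {
    all(vapply(files, function(f) {
      p <- file.path(out_dir, f)
      file.exists(p) && !is.null(checksums[[f]]) &&
        identical(unname(tools::md5sum(p)), checksums[[f]])
    }, logical(1)))
  }
  record <- function(files) {
    for (f in files)
      checksums[[f]] <<- unname(tools::md5sum(file.path(out_dir, f)))
  }
  stage <- function(name, files, fun) {
    if (!force && up_to_date(files)) {
      say("[%s] up to date, skipping", name)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    record(files)
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
  }
  pth <- function(f) file.path(out_dir, f)

  # ---- inputs -------------------------------------------------------------
  inp <- load_inputs(config)
  input_files <- c("covariates.csv", "fooddb.csv", "recalls.csv",
                   "otu_table.tsv", "taxonomy.tsv", "tree.nwk")
  stage("inputs", input_files, function() {
    write.csv(inp$covariates, pth("covariates.csv"), row.names = FALSE)
    write.csv(inp$db, pth("fooddb.csv"), row.names = FALSE)
    write.csv(inp$recalls, pth("recalls.csv"), row.names = FALSE)
    write_otu_table(inp$counts, pth("otu_table.tsv"))
    write.table(inp$taxonomy, pth("taxonomy.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    ape::write.tree(inp$tree, pth("tree.nwk"))
  })

  # ---- diet scoring -------------------------------------------------------
  stage("score-diet", "quality.csv", function() {
    q <- score_diet_cohort(inp$recalls, inp$db, inp$covariates,
                           ambiguous_policy = config$ambiguous_policy)
    write.csv(q, pth("quality.csv"), row.names = FALSE)
  })
  quality <- read.csv(pth("quality.csv"), stringsAsFactors = FALSE)

  # ---- intake estimation --------------------------------------------------
  stage("estimate-intake",
        c("foodgroups.csv", "intake_daily.csv", "intake_usual.csv"), function() {
    fg <- aggregate_food_groups(inp$recalls, inp$db)
    daily <- compute_nutrients(inp$recalls, inp$db)
    usual <- usual_intakes(daily)
    fgp <- aggregate(fg[food_groups()], by = list(person_id = fg$person_id), mean)
    write.csv(fgp, pth("foodgroups.csv"), row.names = FALSE)
    write.csv(daily, pth("intake_daily.csv"), row.names = FALSE)
    write.csv(usual, pth("intake_usual.csv"), row.names = FALSE)
  })
  foodgrp <- read.csv(pth("foodgroups.csv"), stringsAsFactors = FALSE)
  usual <- read.csv(pth("intake_usual.csv"), stringsAsFactors = FALSE)

  # ---- diversity ----------------------------------------------------------
  depth_used <- if (identical(config$depth, "auto-min"))
    min_depth(inp$counts) else as.integer(config$depth)
  manifest$rarefaction_depth <- depth_used
  rar <- rarefy_table(inp$counts, depth = depth_used, seed = config$seed)
  stage("diversity", c("alpha.csv", "unifrac_weighted.tsv",
                       "unifrac_unweighted.tsv", "class_profile.csv"), function() {
    write.csv(alpha_diversity(rar), pth("alpha.csv"), row.names = FALSE)
    write_dist(unifrac(rar, inp$tree, "weighted"), pth("unifrac_weighted.tsv"))
    write_dist(unifrac(rar, inp$tree, "unweighted"), pth("unifrac_unweighted.tsv"))
    cp <- class_profile(rar, inp$taxonomy)
    write.csv(cbind(sample_id = rownames(cp), as.data.frame(cp)),
              pth("class_profile.csv"), row.names = FALSE)
  })
  alpha <- read.csv(pth("alpha.csv"), stringsAsFactors = FALSE)
  dW <- as.matrix(read.delim(pth("unifrac_weighted.tsv"), row.names = 1,
                             check.names = FALSE))
  dU <- as.matrix(read.delim(pth("unifrac_unweighted.tsv"), row.names = 1,
                             check.names = FALSE))

  # ---- association layer --------------------------------------------------
  cov <- inp$covariates[match(alpha$sample_id, inp$covariates$person_id), ]
  quality <- quality[match(alpha$sample_id, quality$person_id), ]
  foodgrp <- foodgrp[match(alpha$sample_id, foodgrp$person_id), ]
  usual <- usual[match(alpha$sample_id, usual$person_id), ]

  pca_fg <- zscore_pca(foodgrp[food_groups()])
  nut_cols <- setdiff(names(usual), "person_id")
  pca_nut <- zscore_pca(usual[nut_cols])

  assoc_files <- c("pca_foodgroups.csv", "pca_nutrients.csv",
                   "alpha_regressions.csv", "permanova.csv",
                   "procrustes.csv", "rf_associations.csv",
                   "heatmap_long.csv")
  stage("associate", assoc_files, function() {
    for (nm in c("foodgroups", "nutrients")) {
      pc <- if (nm == "foodgroups") pca_fg else pca_nut
      k <- min(3, ncol(pc$scores))
      df <- data.frame(person_id = alpha$sample_id,
                       pc$scores[, seq_len(k), drop = FALSE])
      write.csv(df, pth(sprintf("pca_%s.csv", nm)), row.names = FALSE)
    }

    diet_tab <- data.frame(
      hei = quality$hei, gaba = quality$gaba, upf_pct = quality$upf_pct,
      setNames(as.data.frame(pca_fg$scores[, 1:min(3, ncol(pca_fg$scores))]),
               paste0("foodgroup_PC", 1:min(3, ncol(pca_fg$scores)))),
      setNames(as.data.frame(pca_nut$scores[, 1:min(3, ncol(pca_nut$scores))]),
               paste0("nutrient_PC", 1:min(3, ncol(pca_nut$scores)))),
      check.names = FALSE)
    if (!is.null(usual$fiber_g)) diet_tab$fiber <- usual$fiber_g
    constant <- vapply(diet_tab, function(v) sd(v) == 0, logical(1))
    if (any(constant)) {
      say("dropping zero-variance diet variable(s): %s",
          paste(names(diet_tab)[constant], collapse = ", "))
      diet_tab <- diet_tab[!constant]
    }

    areg <- do.call(rbind, lapply(names(diet_tab), function(v) {
      r <- alpha_regression(alpha$shannon, diet_tab[[v]], cov)
      data.frame(diet_variable = v, coefficient = r$coefficient, F = r$F,
                 p_value = r$p_value)
    }))
    write.csv(areg, pth("alpha_regressions.csv"), row.names = FALSE)

    perm <- do.call(rbind, lapply(c("city", "sex", "age_group", "bmi_class",
                                    "ses"), function(v) {
      do.call(rbind, lapply(c(weighted = "dW", unweighted = "dU"), function(dn) {
        d <- if (dn == "dW") dW else dU
        r <- permanova(d, cov[[v]], n_perm = config$n_perm$permanova,
                       seed = split_seed(config$seed, "permanova"))
        data.frame(factor = v,
                   metric = if (dn == "dW") "weighted_unifrac" else "unweighted_unifrac",
                   R2 = r$R2, F = r$F, p_value = r$p_value, n_perm = r$n_perm)
      }))
    }))
    write.csv(perm, pth("permanova.csv"), row.names = FALSE)

    cfgs <- list(quality = scale(as.matrix(quality[c("hei", "gaba", "upf_pct")])),
                 foodgroups = pca_fg$scores[, 1:min(3, ncol(pca_fg$scores))],
                 nutrients = pca_nut$scores[, 1:min(3, ncol(pca_nut$scores))])
    proc <- do.call(rbind, lapply(names(cfgs), function(nm) {
      do.call(rbind, lapply(c("weighted", "unweighted"), function(metric) {
        d <- if (metric == "weighted") dW else dU
        r <- procrustes_test(cfgs[[nm]], pcoa_axes(d, 3),
                             n_perm = config$n_perm$procrustes,
                             seed = split_seed(config$seed, "procrustes"))
        data.frame(diet_side = nm, metric = paste0(metric, "_unifrac"),
                   correlation = r$correlation, m2 = r$m2,
                   p_value = r$p_value, n_perm = r$n_perm)
      }))
    }))
    write.csv(proc, pth("procrustes.csv"), row.names = FALSE)

    top <- filter_top_otus(rar, n = 100, min_median_rel = 1e-4)
    rel <- rar / rowSums(rar)
    rel <- rel[, top, drop = FALSE]
    rf_vars <- config$rf$variables %||% names(diet_tab)
    rf_res <- lapply(rf_vars, function(v) {
      adj <- residualize(diet_tab[[v]], cov)
      rf_diet_association(rel, adj, diet_variable = v,
                          n_trees = config$rf$n_trees,
                          min_otus = config$rf$min_otus,
                          seed = split_seed(config$seed, "rf"))
    })
    rf_long <- do.call(rbind, lapply(rf_res, function(r)
      data.frame(diet_variable = r$diet_variable, otu_id = r$selected_otus,
                 importance = unname(r$importance),
                 spearman_rho = unname(r$spearman_rho),
                 explained_variance = r$explained_variance)))
    write.csv(rf_long, pth("rf_associations.csv"), row.names = FALSE)

    adj_tab <- as.data.frame(lapply(rf_vars, function(v)
      residualize(diet_tab[[v]], cov)))
    names(adj_tab) <- rf_vars
    hm <- association_heatmap_table(rf_res, rel, adj_tab, inp$taxonomy)
    write.csv(hm, pth("heatmap_long.csv"), row.names = FALSE)
  })

  manifest$checksums <- checksums
  manifest$outputs <- names(checksums)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
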