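#' Regression random forest with out-of-bag error and permutation importance
#'
#' A from-scratch regression forest: CART trees with variance-reduction
#' splits, each tree grown on a random two-thirds of the samples drawn
#' without replacement, the held-out third serving as that tree's
#' out-of-bag (OOB) set. OOB explained variance is `1 - MSE_oob / var(y)`;
#' variable importance is the mean increase in OOB mean squared error when
#' the variable is permuted within the OOB set.
#'
#' @param x samples x predictors numeric matrix.
#' @param y numeric response.
#' @param n_trees number of trees (default 1000; the pipeline's reference
#'   configuration uses 50000, which is statistically but not bit-wise
#'   equivalent).
#' @param mtry predictors tried per split (default `max(1, floor(p / 3))`,
#'   the regression-forest convention).
#' @param min_node minimum node size (default 5).
#' @param train_frac per-tree training fraction (default 2/3).
#' @param importance compute permutation importance (default TRUE).
#' @param seed integer seed.
#' @return list of class `dietbiome_rf` with `oob_pred`, `mse_oob`,
#'   `explained_variance`, `importance` (named, MSE-increase scale) and the
#'   call parameters.
#' @export
rf_regression <- function(x, y, n_trees = 1000,
                          mtry = max(1L, floor(ncol(x) / 3)),
                          min_node = 5L, train_frac = 2 / 3,
                          importance = TRUE, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y))
  if (sd(y) == 0) stop("response is constant")
  withr_seed(split_seed(seed, "rf"))
  fit <- .rf_fit_cpp(x, as.numeric(y), as.integer(n_trees),
                     as.integer(min(mtry, ncol(x))), as.integer(min_node),
                     train_frac, importance)
  ok <- fit$oob_count > 0
  mse <- mean((y[ok] - fit$oob_pred[ok])^2)
  imp <- setNames(fit$importance, colnames(x))
  structure(list(oob_pred = setNames(fit$oob_pred, rownames(x)),
                 mse_oob = mse,
                 explained_variance = 1 - mse / var(y),
                 importance = imp, n_trees = n_trees, mtry = mtry,
                 min_node = min_node, train_frac = train_frac),
            class = "dietbiome_rf")
}

#' Random-forest selection of an OTU community associated with a diet variable
#'
#' Regresses a (multivariable-adjusted) diet variable on the relative
#' abundances of the abundant-OTU panel, then performs recursive feature
#' elimination: the OTU set is repeatedly halved by permutation importance
#' and the forest refit, and the subset maximizing OOB explained variance is
#' selected. Selected OTUs are reported with their importance (sorted
#' non-increasing) and the Spearman correlation against the diet variable,
#' which gives each association its direction.
#'
#' @param otu_rel samples x OTUs relative-abundance matrix (the filtered
#'   abundant panel).
#' @param diet_adjusted residualized diet variable aligned with the rows.
#' @param diet_variable name used in the output (default
#'   `"diet"`).
#' @param n_trees trees per forest fit (default 1000).
#' @param min_otus stop halving below this panel size (default 3).
#' @param seed integer seed.
#' @param ... passed to [rf_regression()].
#' @return list of class `dietbiome_rf_association` with `diet_variable`,
#'   `selected_otus`, `importance`, `spearman_rho`, `explained_variance`,
#'   and `path` (the OOB explained variance at each elimination step).
#' @export
rf_diet_association <- function(otu_rel, diet_adjusted,
                                diet_variable = "diet", n_trees = 1000,
                                min_otus = 3L, seed = 1L, ...) {
  otu_rel <- as.matrix(otu_rel)
  if (is.null(colnames(otu_rel)))
    colnames(otu_rel) <- paste0("OTU", seq_len(ncol(otu_rel)))
  if (sd(diet_adjusted) == 0) stop("diet variable is constant")

  panel <- colnames(otu_rel)
  best <- NULL
  path <- data.frame(n_otus = integer(), explained_variance = numeric())
  step <- 0L
  while (TRUE) {
    step <- step + 1L
    fit <- rf_regression(otu_rel[, panel, drop = FALSE], diet_adjusted,
                         n_trees = n_trees,
                         seed = split_seed(seed, step), ...)
    path <- rbind(path, data.frame(n_otus = length(panel),
                                   explained_variance = fit$explained_variance))
    if (is.null(best) || fit$explained_variance > best$ev) {
      best <- list(panel = panel, ev = fit$explained_variance, fit = fit)
    }
    if (length(panel) <= min_otus) break
    ord <- order(-fit$importance, names(fit$importance))
    panel <- names(fit$importance)[ord][seq_len(max(min_otus,
                                                    floor(length(panel) / 2)))]
  }
  imp <- sort(best$fit$importance, decreasing = TRUE)
  rho <- vapply(names(imp), function(o)
    cor(otu_rel[, o], diet_adjusted, method = "spearman"), numeric(1))
  structure(list(diet_variable = diet_variable,
                 selected_otus = names(imp),
                 importance = imp, spearman_rho = rho,
                 explained_variance = best$ev, path = path),
            class = "dietbiome_rf_association")
}

#' Long-format association table for heatmap plotting
#'
#' Combines random-forest associations over several diet variables into the
#' long table behind the association heatmaps: the union of selected OTUs,
#' a Spearman correlation for every (OTU, variable) pair, a selection flag,
#' the taxonomic class, and Ward-linkage row/column leaf orders.
#'
#' @param rf_results list of `dietbiome_rf_association` objects.
#' @param otu_rel samples x OTUs relative abundances (the common universe).
#' @param diet_vars data.frame of the adjusted diet variables (columns named
#'   as in the rf results), aligned with `otu_rel` rows.
#' @param taxonomy optional data.frame `otu_id`, `class`.
#' @return data.frame `otu_id`, `diet_variable`, `rho`, `selected`,
#'   `class`; attributes `otu_order` and `variable_order` give the
#'   Ward-clustering leaf orders.
#' @export
association_heatmap_table <- function(rf_results, otu_rel, diet_vars,
                                      taxonomy = NULL) {
  sel_union <- sort(unique(unlist(lapply(rf_results,
                                         function(r) r$selected_otus))))
  if (!length(sel_union))
    return(data.frame(otu_id = character(), diet_variable = character(),
                      rho = numeric(), selected = logical(),
                      class = character()))
  vars <- vapply(rf_results, function(r) r$diet_variable, character(1))
  rho <- sapply(vars, function(v)
    vapply(sel_union, function(o)
      cor(otu_rel[, o], diet_vars[[v]], method = "spearman"), numeric(1)))
  rho <- matrix(rho, nrow = length(sel_union),
                dimnames = list(sel_union, vars))
  sel <- sapply(rf_results, function(r) sel_union %in% r$selected_otus)
  sel <- matrix(sel, nrow = length(sel_union),
                dimnames = list(sel_union, vars))
  cls <- if (is.null(taxonomy)) rep(NA_character_, length(sel_union)) else
    taxonomy$class[match(sel_union, taxonomy$otu_id)]

  out <- data.frame(
    otu_id = rep(sel_union, times = length(vars)),
    diet_variable = rep(vars, each = length(sel_union)),
    rho = as.vector(rho), selected = as.vector(sel),
    class = rep(cls, times = length(vars)), stringsAsFactors = FALSE)
  attr(out, "otu_order") <- if (length(sel_union) > 2)
    sel_union[hclust(dist(rho), method = "ward.D2")$order] else sel_union
  attr(out, "variable_order") <- if (length(vars) > 2)
    vars[hclust(dist(t(rho)), method = "ward.D2")$order] else vars
  out
}
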