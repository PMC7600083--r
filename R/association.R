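#' Principal component analysis on z-scored variables
#'
#' Column-standardizes the matrix (dropping constant columns with a
#' warning), performs PCA on the correlation structure, and fixes component
#' signs so that each loading column's largest-magnitude entry is positive.
#'
#' @param x persons x variables numeric matrix or data.frame.
#' @return list of class `dietbiome_pca` with `scores`, `loadings`,
#'   `variance_explained` (fractions over all components) and `dropped`
#'   (names of constant columns removed).
#' @export
zscore_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve, dropped = dropped),
            class = "dietbiome_pca")
}

# dummy-coded design matrix for the standard confounder set
covariate_design <- function(covariates) {
  df <- data.frame(
    city = factor(covariates$city),
    sex = factor(covariates$sex),
    age_group = factor(covariates$age_group),
    bmi_class = factor(covariates$bmi_class),
    ses = factor(covariates$ses)
  )
  keep <- vapply(df, function(f) nlevels(droplevels(f)) > 1, logical(1))
  model.matrix(~ ., data = droplevels(df[, keep, drop = FALSE]))
}

#' Residualize a variable on the standard confounder set
#'
#' Least-squares adjustment of `y` for city, sex, age group, BMI class and
#' socioeconomic level (all dummy-coded); aliased columns are dropped with a
#' warning. Residuals have mean zero and are orthogonal to the design.
#'
#' @param y numeric vector, one value per person.
#' @param covariates covariate table aligned with `y`.
#' @return numeric vector of residuals.
#' @export
residualize <- function(y, covariates) {
  stopifnot(length(y) == nrow(covariates))
  X <- covariate_design(covariates)
  fit <- lm.fit(X, y)
  if (any(is.na(fit$coefficients)))
    warning("rank-deficient design; aliased column(s) dropped: ",
            paste(names(fit$coefficients)[is.na(fit$coefficients)],
                  collapse = ", "))
  as.numeric(fit$residuals)
}

#' Multivariable-adjusted regression of alpha diversity on a diet variable
#'
#' Fits `alpha ~ city + sex + age_group + bmi_class + ses + diet` and
#' reports the diet term's coefficient, its 1-df partial F statistic and
#' p-value.
#'
#' @param alpha numeric alpha-diversity values, one per person.
#' @param diet numeric diet variable aligned with `alpha`.
#' @param covariates covariate table aligned with both.
#' @return list with `coefficient`, `F`, `p_value`, `df_residual`.
#' @export
alpha_regression <- function(alpha, diet, covariates) {
  if (sd(diet) == 0) stop("diet variable has zero variance")
  X <- covariate_design(covariates)
  dat <- data.frame(alpha = alpha, X[, -1, drop = FALSE], diet = diet,
                    check.names = FALSE)
  fit <- lm(alpha ~ ., data = dat)
  co <- summary(fit)$coefficients
  if (!"diet" %in% rownames(co))
    stop("diet variable aliased with the covariates")
  tval <- co["diet", "t value"]
  list(coefficient = co["diet", "Estimate"], F = tval^2,
       p_value = co["diet", "Pr(>|t|)"], df_residual = fit$df.residual)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Single-factor partition of squared inter-sample distances:
#' `SS_total = sum(d_ij^2)/N` over all pairs, `SS_within` from within-group
#' pairs, and a pseudo-F `(SS_b/(a-1)) / (SS_w/(N-a))` whose null
#' distribution is obtained by permuting group labels. The p-value uses the
#' `(1 + #{F* >= F}) / (1 + n_perm)` convention.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param group factor with >= 2 levels, aligned with the rows of `d`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list of class `dietbiome_permanova` with `R2`, `F`, `p_value`,
#'   `n_perm`, `df`.
#' @export
permanova <- function(d, group, n_perm = 999, seed = 1L) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) stop("factor needs >= 2 levels")
  group <- droplevels(group)
  N <- nrow(d)
  d2 <- d^2

  ss_total <- sum(d2[upper.tri(d2)]) / N
  if (ss_total <= 0)
    stop("all distances are zero; PERMANOVA undefined")
  fstat <- function(g) {
    ssw <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1)
        ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    a <- nlevels(g)
    ssb <- ss_total - ssw
    list(F = (ssb / (a - 1)) / (ssw / (N - a)), R2 = ssb / ss_total)
  }
  obs <- fstat(group)
  withr_seed(split_seed(seed, "permanova"))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    fp <- fstat(group[sample.int(N)])$F
    if (fp >= obs$F) exceed <- exceed + 1L
  }
  structure(list(R2 = obs$R2, F = obs$F,
                 p_value = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
                 df = c(between = nlevels(group) - 1L,
                        within = N - nlevels(group))),
            class = "dietbiome_permanova")
}

#' Principal-coordinate configuration of a distance matrix
#'
#' Classical metric multidimensional scaling, used to turn a UniFrac matrix
#' into the configuration handed to the Procrustes test.
#'
#' @param d symmetric distance matrix.
#' @param k number of axes (default 3).
#' @return samples x k matrix of coordinates.
#' @export
pcoa_axes <- function(d, k = 3) {
  d <- as.matrix(d)
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  pts
}

#' Symmetric Procrustes superimposition with a permutation test
#'
#' Both configurations are column-centered and scaled to unit sum of
#' squares; the optimal rotation comes from the singular value
#' decomposition of the cross-product. The residual `m2 = 1 - (sum
#' sigma)^2` and correlation `sqrt(1 - m2)` follow; significance is
#' assessed by re-running the superimposition under row permutations of the
#' second configuration, with the `+1` p-value convention.
#'
#' @param X,Y numeric matrices with aligned rows (persons).
#' @param n_perm number of permutations (default 10000, the pipeline's
#'   reference count).
#' @param seed integer seed.
#' @return list of class `dietbiome_procrustes` with `correlation`, `m2`,
#'   `p_value`, `n_perm`.
#' @export
procrustes_test <- function(X, Y, n_perm = 10000, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  norm_cfg <- function(M) {
    M <- scale(M, center = TRUE, scale = FALSE)
    M / sqrt(sum(M^2))
  }
  stat <- function(A, B) {
    s <- sum(svd(crossprod(A, B))$d)
    min(1, s)  # guard rounding above 1
  }
  Xn <- norm_cfg(X); Yn <- norm_cfg(Y)
  s_obs <- stat(Xn, Yn)
  m2 <- 1 - s_obs^2
  withr_seed(split_seed(seed, "procrustes"))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    s_perm <- stat(Xn, norm_cfg(Y[sample.int(nrow(Y)), , drop = FALSE]))
    if (s_perm >= s_obs) exceed <- exceed + 1L
  }
  structure(list(correlation = s_obs, m2 = m2,
                 p_value = (1 + exceed) / (1 + n_perm), n_perm = n_perm),
            class = "dietbiome_procrustes")
}
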