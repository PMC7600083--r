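#' Minimum sequencing depth of an OTU table
#'
#' @param counts samples x OTUs count matrix.
#' @return the minimum row sum, the depth rarefaction defaults to.
#' @export
min_depth <- function(counts) {
  if (is.null(dim(counts)) || nrow(counts) < 1)
    stop("empty OTU table")
  min(rowSums(counts))
}

#' Rarefy an OTU table to a common depth
#'
#' Draws `depth` reads per sample without replacement from that sample's
#' read multiset (multivariate hypergeometric), a single draw per sample.
#' Samples below the target depth raise an error naming them; nothing is
#' dropped silently.
#'
#' @param counts samples x OTUs integer matrix.
#' @param depth target depth (>= 1); default the minimum sample depth.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return integer matrix of the same shape with every row summing to
#'   `depth` and every cell bounded by the original count.
#' @export
rarefy_table <- function(counts, depth = min_depth(counts), seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  totals <- rowSums(counts)
  shallow <- rownames(counts)[totals < depth]
  if (is.null(rownames(counts))) shallow <- which(totals < depth)
  if (length(shallow))
    stop("samples below rarefaction depth ", depth, ": ",
         paste(shallow, collapse = ", "))
  withr_seed(split_seed(seed, "rarefy"))
  out <- counts
  for (i in seq_len(nrow(counts))) {
    reads <- rep.int(seq_len(ncol(counts)), counts[i, ])
    kept <- reads[sample.int(length(reads), depth)]
    out[i, ] <- tabulate(kept, nbins = ncol(counts))
  }
  storage.mode(out) <- "integer"
  attr(out, "depth") <- as.integer(depth)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Alpha diversity: Shannon index, observed OTUs and evenness
#'
#' Shannon entropy `H = -sum p log p` in natural-log units over the nonzero
#' proportions of each sample, richness as the number of detected OTUs, and
#' Shannon evenness `J = H / log(S)` (defined as 0 for single-OTU samples).
#'
#' @param counts rarefied samples x OTUs matrix with positive row sums.
#' @param base logarithm base (default `exp(1)`).
#' @return data.frame `sample_id`, `shannon`, `observed_otus`, `evenness`.
#' @export
alpha_diversity <- function(counts, base = exp(1)) {
  totals <- rowSums(counts)
  if (any(totals <= 0)) stop("all-zero sample(s) in table")
  H <- apply(counts, 1, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p, base = base))
  })
  S <- rowSums(counts > 0)
  J <- ifelse(S > 1, H / log(S, base = base), 0)
  data.frame(sample_id = rownames(counts) %||% as.character(seq_along(H)),
             shannon = as.numeric(H), observed_otus = as.integer(S),
             evenness = as.numeric(J), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the most abundant OTUs
#'
#' Ranks OTUs by mean relative abundance across samples, keeps the top `n`
#' (ties broken by OTU id for determinism), then drops any whose median
#' relative abundance across samples falls below `min_median_rel`.
#'
#' @param counts samples x OTUs matrix (counts or relative abundances).
#' @param n number of OTUs to keep before the median filter (default 100).
#' @param min_median_rel median relative-abundance floor (default 1e-4,
#'   i.e. 0.01%).
#' @return character vector of retained OTU ids, with attribute
#'   `retained_fraction`, the fraction of all reads they carry.
#' @export
filter_top_otus <- function(counts, n = 100, min_median_rel = 1e-4) {
  if (n < 1) stop("n must be >= 1")
  rel <- counts / rowSums(counts)
  mean_rel <- colMeans(rel)
  ids <- colnames(rel) %||% as.character(seq_len(ncol(rel)))
  ord <- order(-mean_rel, ids)
  top <- ord[seq_len(min(n, ncol(rel)))]
  med <- apply(rel[, top, drop = FALSE], 2, median)
  keep <- top[med >= min_median_rel]
  out <- ids[keep]
  attr(out, "retained_fraction") <-
    sum(counts[, keep, drop = FALSE]) / sum(counts)
  out
}

#' Per-sample taxonomic profile at the class level
#'
#' Pools OTU relative abundances by taxonomic class; classes whose
#' cohort-wide median relative abundance is zero are combined into
#' `"Other"`. OTUs without taxonomy are labelled `unclassified`.
#'
#' @param counts samples x OTUs matrix.
#' @param taxonomy data.frame with `otu_id` and `class`.
#' @return samples x classes matrix of relative abundances; rows sum to 1.
#' @export
class_profile <- function(counts, taxonomy) {
  ids <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  cls <- taxonomy$class[match(ids, taxonomy$otu_id)]
  cls[is.na(cls)] <- "unclassified"
  rel <- counts / rowSums(counts)
  agg <- t(rowsum(t(rel), group = cls))
  med <- apply(agg, 2, median)
  pooled <- colnames(agg)[med == 0]
  if (length(pooled)) {
    other <- rowSums(agg[, pooled, drop = FALSE])
    agg <- cbind(agg[, setdiff(colnames(agg), pooled), drop = FALSE],
                 Other = other)
  }
  agg[, order(-colMeans(agg)), drop = FALSE]
}
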