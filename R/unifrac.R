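#' Branch-wise descendant proportions for a sample set
#'
#' One post-order traversal accumulating, for every branch of the tree, the
#' proportion of each sample's reads carried by leaves descending from that
#' branch. This is the quantity both UniFrac variants are defined on.
#'
#' @param counts samples x OTUs matrix (counts or relative abundances);
#'   column names must be tree tip labels for every nonzero column.
#' @param tree an `ape::phylo` with branch lengths.
#' @return list with `P` (edges x samples proportion matrix) and `lengths`
#'   (branch lengths aligned with the rows of `P`).
#' @keywords internal
branch_proportions <- function(counts, tree) {
  ids <- colnames(counts) %||% stop("counts must have OTU column names")
  unknown <- setdiff(ids[colSums(counts != 0) > 0], tree$tip.label)
  if (length(unknown))
    stop("OTU(s) with reads absent from tree: ",
         paste(unknown, collapse = ", "))
  rel <- counts / rowSums(counts)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  n <- nrow(rel)

  mass <- matrix(0, nnode, n)
  tipcols <- match(tree$tip.label, ids)
  has <- !is.na(tipcols)
  mass[which(has), ] <- t(rel[, tipcols[has], drop = FALSE])

  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    mass[tr$edge[k, 1], ] <- mass[tr$edge[k, 1], ] + mass[tr$edge[k, 2], ]
  }
  list(P = mass[tr$edge[, 2], , drop = FALSE], lengths = tr$edge.length)
}

#' Tree-based UniFrac distances
#'
#' Unweighted UniFrac for a sample pair is the branch length unique to one
#' of the two samples divided by the branch length present in either;
#' weighted UniFrac (normalized variant, range `[0, 1]`) replaces presence
#' by read proportions: `sum(l |pA - pB|) / sum(l (pA + pB))`. Both are
#' computed from a single post-order traversal of the tree.
#'
#' @param counts samples x OTUs matrix (raw or rarefied counts, or relative
#'   abundances).
#' @param tree `ape::phylo` over the OTUs.
#' @param mode `"weighted"` or `"unweighted"`.
#' @param normalized for `weighted`: divide by `sum(l (pA + pB))` (default
#'   TRUE, bounding the distance by 1); the raw variant divides by nothing.
#' @return a symmetric `dist`-convertible matrix with zero diagonal and the
#'   metric recorded in attribute `metric`.
#' @export
unifrac <- function(counts, tree, mode = c("weighted", "unweighted"),
                    normalized = TRUE) {
  mode <- match.arg(mode)
  bp <- branch_proportions(counts, tree)
  P <- bp$P
  len <- bp$lengths
  n <- ncol(P)
  D <- matrix(0, n, n,
              dimnames = list(rownames(counts), rownames(counts)))
  if (mode == "unweighted") {
    pres <- P > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      xor_ <- pres[, i] != pres[, j]
      or_ <- pres[, i] | pres[, j]
      denom <- sum(len[or_])
      D[i, j] <- D[j, i] <- if (denom > 0) sum(len[xor_]) / denom else 0
    }
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(len * abs(P[, i] - P[, j]))
      D[i, j] <- D[j, i] <- if (normalized) {
        denom <- sum(len * (P[, i] + P[, j]))
        if (denom > 0) num / denom else 0
      } else num
    }
  }
  attr(D, "metric") <- paste0(if (mode == "weighted") "weighted" else
    "unweighted", "_unifrac")
  D
}
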