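# Independent oracles and tiny fixtures shared across test files.

# Explicit branch-enumeration UniFrac: for every edge, the descendant leaf
# set is found by climbing each tip's path to the root (a different
# algorithm than the package's single post-order accumulation).
unifrac_enum <- function(counts, tree, mode) {
  rel <- counts / rowSums(counts)
  ntip <- length(tree$tip.label)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  # leaves under each edge (edge indexed by its child node)
  leaves_under <- vector("list", ntip + tree$Nnode)
  for (tip in seq_len(ntip)) {
    node <- tip
    while (node != root) {
      leaves_under[[node]] <- c(leaves_under[[node]], tip)
      node <- parent_of[node]
    }
  }
  n <- nrow(rel)
  D <- matrix(0, n, n)
  tipcol <- match(tree$tip.label, colnames(rel))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- den <- 0
    for (k in seq_len(nrow(tree$edge))) {
      child <- tree$edge[k, 2]
      lv <- leaves_under[[child]]
      cols <- tipcol[lv]
      cols <- cols[!is.na(cols)]
      pa <- if (length(cols)) sum(rel[i, cols]) else 0
      pb <- if (length(cols)) sum(rel[j, cols]) else 0
      len <- tree$edge.length[k]
      if (mode == "unweighted") {
        num <- num + len * ((pa > 0) != (pb > 0))
        den <- den + len * ((pa > 0) | (pb > 0))
      } else {
        num <- num + len * abs(pa - pb)
        den <- den + len * (pa + pb)
      }
    }
    D[i, j] <- D[j, i] <- if (den > 0) num / den else 0
  }
  D
}

# three-leaf caterpillar used by the worked UniFrac examples
toy_tree <- function() ape::read.tree(text = "((L1:1,L2:1):1,L3:2);")

toy_counts <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- c("L1", "L2", "L3")
  rownames(m) <- paste0("S", seq_len(nrow(m)))
  m
}

# small simulated cohort reused by several association tests
small_cohort <- function(n = 60, n_otus = 60, seed = 7) {
  cov <- generate_covariates(n, seed = seed)
  tree <- generate_tree(n_otus, seed = seed)
  mb <- generate_microbiome(cov, NULL, tree, list(), seed = seed,
                            depth_range = c(3667, 8000))
  list(cov = cov, tree = tree, mb = mb)
}
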