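# Brute-force oracles, deliberately independent of the package's (and
# ape's) implementations of the same quantities: everything here works
# by walking parent pointers in the raw edge matrix.

# nodes on the path from `node` up to the root, inclusive
bf_ancestors <- function(tree, node) {
  out <- node
  repeat {
    row <- match(node, tree$edge[, 2])
    if (is.na(row)) break
    node <- tree$edge[row, 1]
    out <- c(out, node)
  }
  out
}

# path length from the root down to `node`
bf_depth <- function(tree, node) {
  d <- 0
  repeat {
    row <- match(node, tree$edge[, 2])
    if (is.na(row)) return(d)
    d <- d + tree$edge.length[row]
    node <- tree$edge[row, 1]
  }
}

# MRCA as the deepest node present in every tip's ancestor list
bf_mrca <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  common <- Reduce(intersect, lapply(idx, bf_ancestors, tree = tree))
  common[which.max(vapply(common, bf_depth, numeric(1), tree = tree))]
}

# patristic distance via d(i,j) = depth(i) + depth(j) - 2 depth(mrca)
bf_patristic <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (ia == ib) return(0)
  bf_depth(tree, ia) + bf_depth(tree, ib) -
    2 * bf_depth(tree, bf_mrca(tree, c(a, b)))
}

# site-by-site pair counts via an explicit loop over characters
bf_pair_counts <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  purine <- c("A", "G")
  n <- ts <- tv <- 0L
  for (i in seq_along(va)) {
    x <- va[i]; y <- vb[i]
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T")))
      next
    n <- n + 1L
    if (x != y) {
      if ((x %in% purine) == (y %in% purine)) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  c(n_compared = n, n_transitions = ts, n_transversions = tv)
}

# random support-annotated tree for property tests
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$node.label <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
  attr(tr, "support_kind") <- "bootstrap"
  tr
}

# random DNA string with optional gaps/ambiguity
random_seq <- function(L, p_missing = 0.1) {
  paste(sample(c("A", "C", "G", "T", "-", "N", "R"), L, replace = TRUE,
               prob = c(rep((1 - p_missing) / 4, 4),
                        rep(p_missing / 3, 3))),
        collapse = "")
}

ref_fixture <- function(name) {
  path <- system.file("extdata", name, package = "haplodelim")
  stopifnot(nzchar(path))
  utils::read.delim(path, check.names = FALSE)
}
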