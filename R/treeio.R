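# Tree input/output and tree-metric primitives.
#
# Trees are `ape::phylo` objects carrying two extra attributes:
#   - "support_kind": "bootstrap" or "posterior" (caller-declared, never
#     auto-detected; the two scales overlap numerically)
#   - numeric node supports live in `tree$node.label` (newick internal
#     labels), NA where absent.

SUPPORT_KINDS <- c("bootstrap", "posterior")

#' Parse a newick string into a support-annotated rooted tree
#'
#' Numeric internal-node labels are interpreted as nodal support values
#' (bootstrap percentages or posterior probabilities; declare which with
#' `support_kind`). The tree is used as rooted exactly as written: no
#' re-rooting is performed.
#'
#' @param text A newick string (single tree, terminated by `;`).
#' @param support_kind `"bootstrap"` or `"posterior"`; stored as an
#'   attribute consulted by [support_category()] and [delimit_table()].
#' @param default_brlen If `NULL` (default), edges without a branch length
#'   are a parse error. Set to `0` to accept them with zero length
#'   (lenient mode for cladograms).
#' @return An object of class `phylo` with a `support_kind` attribute.
#'   Branch lengths are non-negative; tip labels are unique.
#' @examples
#' tr <- parse_newick("((A:1,B:1)90:0.5,C:1.5);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text, support_kind = c("bootstrap", "posterior"),
                         default_brlen = NULL) {
  support_kind <- match.arg(support_kind)
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in newick input (", n_open, " '(' vs ",
         n_close, "')')", call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed newick input", call. = FALSE)
  }
  tree <- validate_tree(tree, default_brlen = default_brlen)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(default_brlen, nrow(tree$edge))
  }
  attr(tree, "support_kind") <- support_kind
  tree
}

#' Read a support-annotated rooted tree from a newick file
#'
#' @inheritParams parse_newick
#' @param path Path to a newick file containing a single tree.
#' @return A `phylo` object; see [parse_newick()].
#' @export
read_support_tree <- function(path, support_kind = c("bootstrap", "posterior"),
                              default_brlen = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt, support_kind = support_kind, default_brlen = default_brlen)
}

# Structural checks shared by the parsers. Fails loudly rather than
# repairing: downstream statistics silently change meaning on a bad tree.
validate_tree <- function(tree, default_brlen = NULL) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip label", call. = FALSE)
  if (is.null(tree$edge.length)) {
    if (is.null(default_brlen)) {
      stop("tree has no branch lengths; pass default_brlen = 0 to accept",
           call. = FALSE)
    }
  } else {
    if (anyNA(tree$edge.length)) {
      if (is.null(default_brlen)) {
        stop("missing branch length(s); pass default_brlen = 0 to accept",
             call. = FALSE)
      }
      tree$edge.length[is.na(tree$edge.length)] <- default_brlen
    }
    bad <- which(tree$edge.length < 0)
    if (length(bad)) {
      stop("negative branch length ", tree$edge.length[bad[1]],
           " on edge ", bad[1], call. = FALSE)
    }
  }
  invisible(tree)
}

#' Serialize a tree to newick, supports as internal-node labels
#'
#' Inverse of [parse_newick()] on the tree data model (topology, branch
#' lengths, support labels round-trip exactly).
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if given the string is also written there.
#' @return The newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Numeric nodal support values of a tree
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode`, NA where the internal
#'   label is absent or non-numeric.
#' @export
node_supports <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Matrix of pairwise patristic (tree) distances between tips
#'
#' The patristic distance between two tips is the sum of branch lengths
#' along the unique path joining them; it is the "tree distance" on which
#' Intra, Inter and Av(MRCA-tips) are based.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Symmetric numeric matrix with zero diagonal, dimnames =
#'   tip labels.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  n <- ape::Ntip(tree)
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n), drop = FALSE]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# Map tip labels to tip indices, erroring on unknown labels.
tip_index <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip label(s): ",
         paste(tips[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels (non-empty). For a single
#'   tip the MRCA is the tip itself.
#' @return Node number in `ape`'s numbering (tips `1..Ntip`, internals
#'   above).
#' @export
tree_mrca <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), length(tips) >= 1L)
  idx <- unique(tip_index(tree, tips))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

# Tip indices descending from `node` (the node itself if it is a tip).
clade_tip_indices <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  kids <- node
  tips <- integer(0)
  while (length(kids)) {
    ch <- tree$edge[tree$edge[, 1] %in% kids, 2]
    tips <- c(tips, ch[ch <= n])
    kids <- ch[ch > n]
  }
  sort(tips)
}

#' Test a set of tips for monophyly and report intruders
#'
#' A group is monophyletic when the clade subtended by its MRCA contains
#' exactly the group's tips; the intruders are any other tips found there.
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels; a singleton group is
#'   monophyletic by definition.
#' @return A list with `monophyletic` (logical) and `intruders`
#'   (character vector, empty when monophyletic).
#' @export
is_monophyletic <- function(tree, tips) {
  stopifnot(length(tips) >= 1L)
  tip_index(tree, tips)             # validates labels
  node <- tree_mrca(tree, tips)
  clade <- tree$tip.label[clade_tip_indices(tree, node)]
  intruders <- setdiff(clade, tips)
  list(monophyletic = length(intruders) == 0L, intruders = intruders)
}

#' Categorize nodal support values
#'
#' Bootstrap percentages: `>= 75` strong, `> 50` and `< 75` moderate,
#' `<= 50` negligible. Posterior probabilities: `>= 0.95` significant,
#' otherwise negligible. Vectorized; NA in, NA out.
#'
#' @param value Numeric support value(s); bootstrap in \[0, 100\] or
#'   posterior in \[0, 1\].
#' @param kind `"bootstrap"` or `"posterior"`.
#' @return Character vector of categories.
#' @examples
#' support_category(c(100, 75, 60, 50), "bootstrap")
#' support_category(0.92, "posterior")
#' @export
support_category <- function(value, kind = c("bootstrap", "posterior")) {
  kind <- match.arg(kind)
  value <- as.numeric(value)
  ok <- !is.na(value)
  if (kind == "bootstrap") {
    if (any(value[ok] < 0 | value[ok] > 100)) {
      stop("bootstrap support outside [0, 100]", call. = FALSE)
    }
    out <- ifelse(value >= 75, "strong",
                  ifelse(value > 50, "moderate", "negligible"))
  } else {
    if (any(value[ok] < 0 | value[ok] > 1)) {
      stop("posterior probability outside [0, 1]", call. = FALSE)
    }
    out <- ifelse(value >= 0.95, "significant", "negligible")
  }
  out[!ok] <- NA_character_
  out
}
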