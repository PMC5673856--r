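# Per-haplogroup species-delimitation statistics on a gene tree.
#
# A haplogroup assignment is a named character vector: names are tip
# labels, values are haplogroup (putative species) names. All statistics
# use patristic ("tree") distances in whatever units the input branch
# lengths carry.

#' Construct a haplogroup assignment
#'
#' @param x Named character vector (names = tip labels, values =
#'   haplogroup names) or a two-column data frame (tip, haplogroup).
#' @return A named character vector of class `haplo_assignment`.
#' @export
as_assignment <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("assignment table needs two columns", call. = FALSE)
    v <- as.character(x[[2L]])
    names(v) <- as.character(x[[1L]])
    x <- v
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("assignments must be named by tip label", call. = FALSE)
  }
  if (any(is.na(x) | !nzchar(x))) {
    stop("empty haplogroup name", call. = FALSE)
  }
  # duplicate tips: tolerated when consistent, an error when conflicting
  if (anyDuplicated(names(x))) {
    conflict <- tapply(unname(x), names(x), function(g) length(unique(g)) > 1L)
    if (any(conflict)) {
      stop("tip(s) assigned to more than one haplogroup: ",
           paste(names(conflict)[conflict], collapse = ", "), call. = FALSE)
    }
    x <- x[!duplicated(names(x))]
  }
  structure(x, class = "haplo_assignment")
}

#' Read a tip-to-haplogroup assignment table (TSV)
#'
#' Two tab-separated columns: tip label, haplogroup name. A header line
#' is detected (and skipped) when its first field is `tip`.
#'
#' @param path Path to the TSV file.
#' @return A `haplo_assignment` (named character vector).
#' @export
load_assignments <- function(path) {
  if (!file.exists(path)) stop("assignment file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          blank.lines.skip = TRUE)
  if (nrow(df) && tolower(df[1, 1]) %in% c("tip", "label", "tip_label")) {
    df <- df[-1, , drop = FALSE]
  }
  if (!nrow(df)) stop("empty assignment table: ", path, call. = FALSE)
  as_assignment(df)
}

#' @export
print.haplo_assignment <- function(x, ...) {
  cat("<haplo_assignment> ", length(x), " tips in ",
      length(unique(unname(x))), " haplogroups\n", sep = "")
  invisible(x)
}

# Restrict an assignment to tips present in the tree; message about tree
# tips with no assignment (excluded from all statistics).
check_assignment <- function(tree, assignment, quiet = FALSE) {
  assignment <- as_assignment(unclass(assignment))
  known <- names(assignment) %in% tree$tip.label
  if (any(!known)) {
    stop("assigned tip(s) absent from tree: ",
         paste(utils::head(names(assignment)[!known], 5L), collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(tree$tip.label, names(assignment))
  if (length(orphan) && !quiet) {
    message(length(orphan), " tree tip(s) have no haplogroup assignment ",
            "and are excluded: ", paste(utils::head(orphan, 5L),
                                        collapse = ", "))
  }
  assignment
}

group_members <- function(assignment, focal) {
  if (!focal %in% unname(assignment)) {
    stop("unknown haplogroup: ", focal, call. = FALSE)
  }
  # sorted so that seeded Monte-Carlo draws are invariant to the input
  # order of the assignment table
  sort(names(assignment)[unname(assignment) == focal])
}

#' Mean pairwise tree distance within a haplogroup (Intra)
#'
#' @param tree A `phylo` object.
#' @param assignment A `haplo_assignment` (see [as_assignment()]).
#' @param focal Haplogroup name.
#' @param dmat Optional precomputed [patristic_matrix()] (a cache for
#'   callers looping over groups).
#' @return Mean patristic distance over all unordered member pairs, or
#'   `NA` for a singleton haplogroup.
#' @export
intra_distance <- function(tree, assignment, focal, dmat = NULL) {
  assignment <- check_assignment(tree, assignment, quiet = TRUE)
  members <- group_members(assignment, focal)
  if (length(members) < 2L) return(NA_real_)
  if (is.null(dmat)) dmat <- patristic_matrix(tree)
  sub <- dmat[members, members, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Closest haplogroup and mean between-group tree distance (Inter)
#'
#' For every other haplogroup the mean patristic distance over all
#' focal-by-other tip pairs is computed; the minimizing group is the
#' "closest haplogroup". Exact ties are broken towards the
#' lexicographically smallest name, with a warning.
#'
#' @inheritParams intra_distance
#' @return List with `closest` (haplogroup name) and `inter` (mean
#'   cross-pair patristic distance to it).
#' @export
inter_and_closest <- function(tree, assignment, focal, dmat = NULL) {
  assignment <- check_assignment(tree, assignment, quiet = TRUE)
  groups <- sort(unique(unname(assignment)))
  if (length(groups) < 2L) stop("need at least 2 haplogroups", call. = FALSE)
  members <- group_members(assignment, focal)
  if (is.null(dmat)) dmat <- patristic_matrix(tree)
  others <- setdiff(groups, focal)
  inter <- vapply(others, function(g) {
    mean(dmat[members, group_members(assignment, g), drop = FALSE])
  }, numeric(1))
  best <- min(inter)
  hits <- others[abs(inter - best) < .Machine$double.eps * 64]
  if (length(hits) > 1L) {
    warning("closest-haplogroup tie for '", focal, "' between ",
            paste(hits, collapse = ", "), "; choosing '", min(hits), "'",
            call. = FALSE)
  }
  pick <- min(hits)
  list(closest = pick, inter = unname(inter[pick]))
}

#' Ratio of within- to between-haplogroup tree distance
#'
#' @param intra Intra distance (may be `NA` for singletons).
#' @param inter Inter distance; must be positive.
#' @return `intra / inter`, or `NA` when `intra` is `NA`.
#' @export
intra_inter_ratio <- function(intra, inter) {
  if (any(!is.na(inter) & inter <= 0)) {
    stop("inter distance must be positive", call. = FALSE)
  }
  ifelse(is.na(intra) | is.na(inter), NA_real_, intra / inter)
}

#' Mean distance from a haplogroup's MRCA to its member tips
#'
#' @inheritParams intra_distance
#' @return Mean patristic distance from the MRCA node of the focal
#'   members to each member tip; `NA` for a singleton (whose MRCA is the
#'   tip itself).
#' @export
av_mrca_tips <- function(tree, assignment, focal, dmat = NULL) {
  assignment <- check_assignment(tree, assignment, quiet = TRUE)
  members <- group_members(assignment, focal)
  if (length(members) < 2L) return(NA_real_)
  node <- tree_mrca(tree, members)
  nd <- ape::dist.nodes(tree)
  mean(nd[node, tip_index(tree, members)])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# restores the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Monte-Carlo estimate of the probability of correct identification (P ID)
#'
#' Estimates the probability that a new, unknown member of the focal
#' haplogroup would be placed within its clade (`mode = "strict"`: it
#' must fall within, but not sister to, the clade) or within-or-sister
#' to it (`mode = "liberal"`).
#'
#' Each replicate simulates the query's attachment point: a random focal
#' member `m` is chosen, a divergence `delta` is drawn as the patristic
#' distance from `m` to another randomly chosen member (for singletons:
#' to the nearest non-member tip), and the query lineage attaches at
#' height `h ~ Uniform(0, delta)` on the path from `m` towards the root.
#' The attachment falls *within* the clade while `h` is below `m`'s
#' distance to the group MRCA, is *sister* to the clade while it lies on
#' the MRCA's subtending branch, and is a misidentification beyond that.
#'
#' @inheritParams intra_distance
#' @param mode `"strict"` or `"liberal"`.
#' @param n_reps Number of Monte-Carlo replicates (default 1000).
#' @param seed Optional integer; fixing it makes the estimate
#'   bit-reproducible.
#' @param conf Confidence level for the percentile-bootstrap interval.
#' @return Named numeric vector `c(mean, low, high)`; all `NA` for
#'   `mode = "strict"` on a singleton haplogroup (a query cannot fall
#'   "within" a single tip).
#' @export
pid_estimate <- function(tree, assignment, focal,
                         mode = c("strict", "liberal"),
                         n_reps = 1000L, seed = NULL, conf = 0.95,
                         dmat = NULL) {
  mode <- match.arg(mode)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  assignment <- check_assignment(tree, assignment, quiet = TRUE)
  members <- group_members(assignment, focal)
  singleton <- length(members) < 2L
  if (singleton && mode == "strict") {
    return(c(mean = NA_real_, low = NA_real_, high = NA_real_))
  }
  if (is.null(dmat)) dmat <- patristic_matrix(tree)
  node <- tree_mrca(tree, members)
  nd <- ape::dist.nodes(tree)
  midx <- tip_index(tree, members)
  d_mrca <- nd[node, midx]                 # member -> clade MRCA
  names(d_mrca) <- members
  # length of the branch subtending the clade (0 when the MRCA is the root)
  root <- ape::Ntip(tree) + 1L
  sub_len <- if (node == root) 0 else {
    tree$edge.length[match(node, tree$edge[, 2])]
  }
  nonmembers <- setdiff(names(assignment), members)
  scores <- with_seed(seed, {
    s <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      m <- sample(members, 1L)
      delta <- if (singleton) {
        min(dmat[m, nonmembers])
      } else {
        dmat[m, sample(setdiff(members, m), 1L)]
      }
      h <- stats::runif(1L, 0, delta)
      s[r] <- if (mode == "strict") {
        h < d_mrca[[m]]
      } else {
        h <= d_mrca[[m]] + sub_len
      }
    }
    est <- mean(s)
    boots <- vapply(seq_len(1000L),
                    function(i) mean(s[sample.int(n_reps, replace = TRUE)]),
                    numeric(1))
    c(est, boots)
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(scores[-1L], c(alpha, 1 - alpha), names = FALSE)
  c(mean = scores[1L], low = ci[1L], high = ci[2L])
}

#' Per-haplogroup species-delimitation table
#'
#' One row per haplogroup with the six delimitation statistics: support
#' of the focal MRCA node, Intra, Inter (with the closest haplogroup),
#' Intra/Inter, P ID (strict) and P ID (liberal) with confidence
#' intervals, and Av(MRCA-tips). Singleton haplogroups get `NA` for
#' support, Intra, ratio, P ID (strict) and Av(MRCA-tips); P ID
#' (liberal) is still estimated.
#'
#' @inheritParams pid_estimate
#' @param pid_reps Monte-Carlo replicates per P ID estimate.
#' @param seed Integer seed driving all P ID estimates (each group gets
#'   a distinct stream derived from it).
#' @return A data frame of class `delimitation_table`, one row per
#'   haplogroup (alphabetical), with columns `focal, closest, support,
#'   intra, inter, ratio, pid_strict_mean/low/high,
#'   pid_liberal_mean/low/high, av_mrca_tips`.
#' @export
delimit_table <- function(tree, assignment, pid_reps = 1000L, seed = 1L) {
  assignment <- check_assignment(tree, assignment)
  groups <- sort(unique(unname(assignment)))
  if (length(groups) < 2L) stop("need at least 2 haplogroups", call. = FALSE)
  dmat <- patristic_matrix(tree)
  supports <- node_supports(tree)
  root <- ape::Ntip(tree) + 1L
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    members <- group_members(assignment, g)
    singleton <- length(members) < 2L
    supp <- NA_real_
    if (!singleton) {
      node <- tree_mrca(tree, members)
      if (node != root) supp <- supports[node - ape::Ntip(tree)]
    }
    ic <- inter_and_closest(tree, assignment, g, dmat = dmat)
    intra <- intra_distance(tree, assignment, g, dmat = dmat)
    gseed <- if (is.null(seed)) NULL else (seed + 7919L * gi) %% 2147483647L
    ps <- pid_estimate(tree, assignment, g, "strict", n_reps = pid_reps,
                       seed = gseed, dmat = dmat)
    pl <- pid_estimate(tree, assignment, g, "liberal", n_reps = pid_reps,
                       seed = gseed, dmat = dmat)
    data.frame(
      focal = g, closest = ic$closest, support = supp,
      intra = intra, inter = ic$inter,
      ratio = intra_inter_ratio(intra, ic$inter),
      pid_strict_mean = ps[["mean"]], pid_strict_low = ps[["low"]],
      pid_strict_high = ps[["high"]],
      pid_liberal_mean = pl[["mean"]], pid_liberal_low = pl[["low"]],
      pid_liberal_high = pl[["high"]],
      av_mrca_tips = av_mrca_tips(tree, assignment, g, dmat = dmat),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("delimitation_table", "data.frame")
  attr(out, "support_kind") <- attr(tree, "support_kind")
  out
}

#' Column means of a delimitation table
#'
#' Arithmetic means of the Intra, Inter, P ID and Av(MRCA-tips) columns,
#' excluding `NA` entries (singleton rows contribute only where defined;
#' nothing is imputed).
#'
#' @param records A `delimitation_table` (or any data frame with the
#'   same columns).
#' @return Named numeric vector: `mean_intra`, `mean_inter`,
#'   `mean_pid_strict`, `mean_pid_liberal`, `mean_av_mrca_tips`.
#' @export
summarize_table <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 1L) {
    stop("need at least one delimitation record", call. = FALSE)
  }
  m <- function(col) mean(records[[col]], na.rm = TRUE)
  c(mean_intra = m("intra"),
    mean_inter = m("inter"),
    mean_pid_strict = m("pid_strict_mean"),
    mean_pid_liberal = m("pid_liberal_mean"),
    mean_av_mrca_tips = m("av_mrca_tips"))
}

#' Round a delimitation table to report precision
#'
#' Distances to 3 decimals, Av(MRCA-tips) to 4, ratio and P ID columns
#' to 2 — the precisions used in published per-haplogroup tables.
#'
#' @param records A `delimitation_table`.
#' @param digits_dist,digits_av,digits_ratio Decimal places for the
#'   distance, Av(MRCA-tips) and ratio/P ID columns.
#' @return A data frame of the same shape with rounded numeric columns.
#' @export
format_delimit_table <- function(records, digits_dist = 3L, digits_av = 4L,
                                 digits_ratio = 2L) {
  out <- as.data.frame(records)
  for (col in c("intra", "inter")) out[[col]] <- round(out[[col]], digits_dist)
  out$av_mrca_tips <- round(out$av_mrca_tips, digits_av)
  for (col in grep("^(ratio|pid_)", names(out), value = TRUE)) {
    out[[col]] <- round(out[[col]], digits_ratio)
  }
  out
}
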