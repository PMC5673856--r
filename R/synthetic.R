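# Synthetic benchmark data: multispecies-coalescent gene trees and
# transition-biased sequence evolution with known truth.
#
# Time units: species-tree branch lengths and all coalescent times are
# in coalescent units of 2N_ref generations. Within a species of
# relative effective size N_rel (= N_species / N_ref), each pair of
# lineages coalesces at rate 1 / N_rel per coalescent unit. Conversion
# to expected substitutions/site is via `mu`, the substitution rate per
# coalescent unit: a gene-tree branch of t coalescent units has length
# mu * t substitutions/site in the output tree and alignment.

#' Specification of a species tree for coalescent simulation
#'
#' @param species_tree Ultrametric `phylo` whose tip labels are species
#'   (haplogroup) names and whose branch lengths are in coalescent
#'   units (2N generations).
#' @param n_tips Named integer vector: sampled gene copies per species.
#'   Unnamed vectors are matched to `species_tree$tip.label` in order;
#'   a scalar is recycled.
#' @param N Relative effective population sizes (scalar or named
#'   vector), 1 = the reference 2N.
#' @return A list of class `species_tree_spec`.
#' @export
species_tree_spec <- function(species_tree, n_tips, N = 1) {
  stopifnot(inherits(species_tree, "phylo"))
  sp <- species_tree$tip.label
  if (length(sp) < 2L) stop("need at least 2 species", call. = FALSE)
  if (length(n_tips) == 1L) n_tips <- rep(n_tips, length(sp))
  if (is.null(names(n_tips))) names(n_tips) <- sp
  if (!setequal(names(n_tips), sp)) {
    stop("n_tips names must match species tree tips", call. = FALSE)
  }
  n_tips <- n_tips[sp]
  if (any(n_tips < 1L)) stop("n_tips must be >= 1", call. = FALSE)
  if (length(N) == 1L) N <- stats::setNames(rep(N, length(sp)), sp)
  if (any(N <= 0)) stop("population sizes must be positive", call. = FALSE)
  structure(list(species_tree = species_tree,
                 n_tips = as.integer(n_tips), N = N[sp]),
            class = "species_tree_spec")
}

# node heights (time above the tips) of an ultrametric phylo
node_heights <- function(tree) {
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)   # root -> node path length
  max(depth) - depth
}

# Kingman coalescent within one species-tree branch: merges `lineages`
# (list of nodes: list(id, height)) from time `t0` up to `t1` at rate
# choose(k,2)/N_rel. Returns updated lineages and accumulated merges.
coalesce_branch <- function(lineages, t0, t1, N_rel, state) {
  t <- t0
  while (length(lineages) > 1L) {
    k <- length(lineages)
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2 / N_rel)
    if (t >= t1) break
    pair <- sample.int(k, 2L)
    state$node_id <- state$node_id + 1L
    parent <- list(id = state$node_id, height = t)
    state$children[[as.character(state$node_id)]] <-
      c(lineages[[pair[1L]]]$id, lineages[[pair[2L]]]$id)
    state$heights[as.character(state$node_id)] <- t
    lineages <- c(lineages[-pair], list(parent))
  }
  lineages
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Gene lineages coalesce within each species-tree branch at the
#' Kingman rate (1 per pair per `N_rel` coalescent units) and are pooled
#' at species divergences; remaining lineages coalesce above the root.
#' Gene-tree branch lengths are reported in expected substitutions/site
#' (`mu` times the coalescent-unit lengths).
#'
#' @param spec A [species_tree_spec()].
#' @param mu Substitution rate per coalescent unit (scales all branch
#'   lengths; default 1 leaves lengths in coalescent units).
#' @param seed Optional integer for reproducibility.
#' @return A `phylo` gene tree. Tip labels are
#'   `<species>_<i>`; attribute `tip_species` maps them back.
#' @export
simulate_gene_tree <- function(spec, mu = 1, seed = NULL) {
  stopifnot(inherits(spec, "species_tree_spec"), mu >= 0)
  with_seed(seed, {
    st <- spec$species_tree
    n_sp <- ape::Ntip(st)
    heights <- node_heights(st)
    state <- new.env(parent = emptyenv())
    state$children <- list()
    state$heights <- numeric(0)
    # gene tips are ids 1..n_total
    labels <- unlist(lapply(seq_len(n_sp), function(i) {
      sprintf("%s_%d", st$tip.label[i], seq_len(spec$n_tips[i]))
    }))
    state$node_id <- length(labels)
    tip_id <- split(seq_along(labels),
                    rep(st$tip.label, spec$n_tips))[st$tip.label]
    # active lineage sets per species-tree node
    active <- vector("list", n_sp + st$Nnode)
    for (i in seq_len(n_sp)) {
      active[[i]] <- lapply(tip_id[[i]], function(id)
        list(id = id, height = 0))
    }
    # process species-tree nodes from the tips upward
    ord <- order(heights[-seq_len(n_sp)])
    parent_of <- function(node) st$edge[match(node, st$edge[, 2]), 1]
    for (i in seq_len(n_sp)) {
      p <- parent_of(i)
      active[[i]] <- coalesce_branch(active[[i]], heights[i], heights[p],
                                     spec$N[st$tip.label[i]], state)
    }
    root <- n_sp + 1L
    for (node in (n_sp + ord)) {
      kids <- st$edge[st$edge[, 1] == node, 2]
      pool <- do.call(c, active[kids])
      t1 <- if (node == root) Inf else heights[parent_of(node)]
      active[[node]] <- coalesce_branch(pool, heights[node], t1, 1, state)
    }
    stopifnot(length(active[[root]]) == 1L)
    # assemble newick from the merge records
    to_newick <- function(id, parent_h) {
      h <- if (id <= length(labels)) 0 else state$heights[[as.character(id)]]
      bl <- mu * (parent_h - h)
      if (id <= length(labels)) {
        sprintf("%s:%.10f", labels[id], bl)
      } else {
        kids <- state$children[[as.character(id)]]
        sprintf("(%s,%s):%.10f", to_newick(kids[1L], h),
                to_newick(kids[2L], h), bl)
      }
    }
    root_id <- active[[root]][[1L]]$id
    root_h <- state$heights[[as.character(root_id)]]
    kids <- state$children[[as.character(root_id)]]
    txt <- sprintf("(%s,%s);", to_newick(kids[1L], root_h),
                   to_newick(kids[2L], root_h))
    gt <- parse_newick(txt)
    attr(gt, "tip_species") <- stats::setNames(
      rep(st$tip.label, spec$n_tips), labels)
    gt
  })
}

#' Haplogroup assignment implied by a simulated gene tree
#'
#' @param gene_tree Output of [simulate_gene_tree()].
#' @return A `haplo_assignment` mapping each tip to its true species.
#' @export
true_assignment <- function(gene_tree) {
  sp <- attr(gene_tree, "tip_species")
  if (is.null(sp)) stop("tree carries no tip_species attribute",
                        call. = FALSE)
  as_assignment(sp)
}

# K80 substitution probabilities for branch length d (expected
# subs/site) and transition/transversion rate ratio kappa. Returns
# list(ts, tv) where tv is the probability of EACH of the two
# transversion targets.
k80_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  list(ts = 0.25 + 0.25 * e1 - 0.5 * e2,
       tv = 0.25 - 0.25 * e1)
}

#' Simulate an alignment down a tree under K2P(+Gamma+I)
#'
#' Sites evolve independently along the tree under the Kimura
#' 2-parameter model with transition/transversion rate ratio `kappa`,
#' optional gamma-distributed rate heterogeneity and a proportion of
#' invariant sites. Site rates are normalized to mean 1, so branch
#' lengths stay calibrated in expected substitutions/site.
#'
#' @param tree A `phylo` with branch lengths in expected
#'   substitutions/site.
#' @param L Alignment length (sites).
#' @param rate Global rate multiplier applied to every branch.
#' @param kappa Transition/transversion *rate* ratio (kappa = 1 is
#'   Jukes-Cantor-like; CYTB-like data is strongly transition-biased,
#'   kappa >> 1).
#' @param gamma_alpha Shape of the gamma rate distribution; `NULL`
#'   (default) = equal rates.
#' @param p_invariant Proportion of invariant sites in \[0, 1).
#' @param seed Optional integer seed.
#' @return A `dna_alignment` with one row per tip.
#' @export
simulate_alignment <- function(tree, L, rate = 1, kappa = 2,
                               gamma_alpha = NULL, p_invariant = 0,
                               seed = NULL) {
  stopifnot(inherits(tree, "phylo"), L >= 1, rate >= 0, kappa > 0,
            p_invariant >= 0, p_invariant < 1)
  with_seed(seed, {
    # per-site rates, mean 1 across all sites (invariant included)
    r <- rep(1, L)
    if (p_invariant > 0) r[stats::runif(L) < p_invariant] <- 0
    variable <- r > 0
    if (!is.null(gamma_alpha) && any(variable)) {
      r[variable] <- stats::rgamma(sum(variable), shape = gamma_alpha,
                                   rate = gamma_alpha)
    }
    if (any(variable)) r[variable] <- r[variable] / mean(r)
    n <- ape::Ntip(tree)
    root <- n + 1L
    seqs <- matrix(NA_integer_, n + tree$Nnode, L)
    seqs[root, ] <- sample.int(4L, L, replace = TRUE)
    # transition partner of codes 1..4 (A<->G, C<->T)
    ts_to <- c(3L, 4L, 1L, 2L)
    ord <- rev(ape::postorder(tree))   # edges, root-to-tip order
    for (e in ord) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      d <- rate * tree$edge.length[e] * r
      pr <- k80_probs(d, kappa)
      u <- stats::runif(L)
      x <- seqs[par, ]
      out <- x
      is_ts <- u < pr$ts
      is_tv1 <- !is_ts & u < pr$ts + pr$tv
      is_tv2 <- !is_ts & !is_tv1 & u < pr$ts + 2 * pr$tv
      out[is_ts] <- ts_to[x[is_ts]]
      # the two transversion targets of base x are the two bases of the
      # other chemical class
      tv_targets <- rbind(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
      out[is_tv1] <- tv_targets[x[is_tv1], 1L]
      out[is_tv2] <- tv_targets[x[is_tv2], 2L]
      seqs[child, ] <- out
    }
    m <- matrix(BASES[seqs[seq_len(n), , drop = FALSE]], nrow = n)
    rownames(m) <- tree$tip.label
    as_alignment(m)
  })
}

#' Replace a fixed fraction of alignment cells with 'N'
#'
#' Exactly `round(fraction * cells)` cells, chosen uniformly at random,
#' are overwritten with `N` — emulating the missing data typical of
#' degraded-DNA alignments.
#'
#' @param aln A `dna_alignment`.
#' @param fraction Fraction of cells to blank, in \[0, 1).
#' @param seed Optional integer seed (same seed, same mask).
#' @return The masked `dna_alignment`.
#' @export
inject_missing <- function(aln, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  m <- unclass(as_alignment(aln))
  k <- round(fraction * length(m))
  if (k > 0) {
    idx <- with_seed(seed, sample.int(length(m), k))
    m[idx] <- "N"
  }
  as_alignment(m)
}

# ladder (caterpillar) species tree with divergence heights spaced
# evenly from `depth_min` to `depth_max`; deterministic topology
ladder_species_tree <- function(k, depth_min, depth_max) {
  stopifnot(k >= 2)
  hs <- if (k == 2) depth_min else seq(depth_min, depth_max,
                                       length.out = k - 1)
  txt <- sprintf("(sp1:%.6f,sp2:%.6f)", hs[1], hs[1])
  if (k > 2) {
    for (i in 3:k) {
      txt <- sprintf("(%s:%.6f,sp%d:%.6f)", txt, hs[i - 1] - hs[i - 2],
                     i, hs[i - 1])
    }
  }
  ape::read.tree(text = paste0(txt, ";"))
}

#' Built-in simulation presets
#'
#' `"deer-like"` emulates a multi-species mitochondrial CYTB study: 17
#' species-level haplogroups of 1-20 sampled sequences (three
#' singletons), a coalescent-shaped species tree rescaled to root depth
#' 6 coalescent units, mu = 0.01 substitutions/site per coalescent unit
#' (within-group p-distances of roughly 0-3%, between-group roughly
#' 2-13%), strong transition bias (kappa = 8), gamma rate heterogeneity,
#' 30% invariant sites, 1140 sites, and 11% missing data.
#' `"deep"` separates species by 25-33 coalescent units, so that the
#' *realized* between:within divergence exceeds 10:1 even through
#' coalescent variance in within-species depths — the regime for clean
#' parameter-recovery checks; `"shallow"` uses
#' divergences comparable to 2N so incomplete lineage sorting produces
#' non-monophyletic species.
#'
#' @param name One of `"deer-like"`, `"deep"`, `"shallow"`.
#' @param seed Integer seed used for the random species tree of the
#'   deer-like preset.
#' @return A list with `spec` (a `species_tree_spec`) and `seq_params`
#'   (L, mu, kappa, gamma_alpha, p_invariant, missing).
#' @export
simulation_preset <- function(name = c("deer-like", "deep", "shallow"),
                              seed = 1L) {
  name <- match.arg(name)
  if (name == "deer-like") {
    k <- 17
    n_tips <- c(4, 1, 3, 18, 12, 1, 8, 7, 3, 4, 6, 9, 20, 5, 1, 4, 6)
    st <- with_seed(seed, ape::rcoal(k, tip.label = sprintf("sp%d", 1:k)))
    st$edge.length <- st$edge.length * 6 / max(node_heights(st))
    spec <- species_tree_spec(st, stats::setNames(n_tips, st$tip.label))
    seq_params <- list(L = 1140L, mu = 0.01, kappa = 8,
                       gamma_alpha = 0.5, p_invariant = 0.3,
                       missing = 0.11)
  } else if (name == "deep") {
    st <- ladder_species_tree(8, 25, 33)
    spec <- species_tree_spec(st, n_tips = 6)
    seq_params <- list(L = 2000L, mu = 0.01, kappa = 8,
                       gamma_alpha = NULL, p_invariant = 0,
                       missing = 0)
  } else {
    st <- ladder_species_tree(8, 0.8, 1.6)
    spec <- species_tree_spec(st, n_tips = 6)
    seq_params <- list(L = 1140L, mu = 0.01, kappa = 8,
                       gamma_alpha = NULL, p_invariant = 0,
                       missing = 0)
  }
  list(spec = spec, seq_params = seq_params)
}

#' Generate a full synthetic dataset (tree, alignment, assignments)
#'
#' Simulates a gene tree under the multispecies coalescent, evolves an
#' alignment along it, optionally masks missing data, and (when `dir`
#' is given) writes `tree.nwk`, `alignment.fasta`, `assignments.tsv`
#' and a `truth.json` sidecar recording every simulation parameter.
#'
#' @param spec A [species_tree_spec()] (or the `$spec` of a
#'   [simulation_preset()]).
#' @param seq_params List with `L`, `mu`, `kappa`, and optionally
#'   `gamma_alpha`, `p_invariant`, `missing`.
#' @param dir Output directory (`NULL` = in-memory only).
#' @param seed Integer seed; all stochastic stages derive their streams
#'   from it.
#' @return A list of class `simulated_dataset`: `tree`, `alignment`,
#'   `assignment`, `truth`, and `files` (paths, when written).
#' @export
make_dataset <- function(spec, seq_params, dir = NULL, seed = 1L) {
  stopifnot(inherits(spec, "species_tree_spec"))
  sp <- utils::modifyList(list(gamma_alpha = NULL, p_invariant = 0,
                               missing = 0), seq_params)
  gt <- simulate_gene_tree(spec, mu = sp$mu, seed = seed)
  aln <- simulate_alignment(gt, L = sp$L, kappa = sp$kappa,
                            gamma_alpha = sp$gamma_alpha,
                            p_invariant = sp$p_invariant,
                            seed = seed + 1L)
  if (sp$missing > 0) aln <- inject_missing(aln, sp$missing, seed = seed + 2L)
  assignment <- true_assignment(gt)
  truth <- list(seed = seed, L = sp$L, mu = sp$mu, kappa = sp$kappa,
                gamma_alpha = sp$gamma_alpha, p_invariant = sp$p_invariant,
                missing = sp$missing,
                n_species = ape::Ntip(spec$species_tree),
                n_tips = as.list(stats::setNames(spec$n_tips,
                                                 spec$species_tree$tip.label)),
                species_divergences = node_heights(
                  spec$species_tree)[-seq_len(ape::Ntip(spec$species_tree))],
                species_tree = write_newick(spec$species_tree))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(tree = file.path(dir, "tree.nwk"),
                  alignment = file.path(dir, "alignment.fasta"),
                  assignments = file.path(dir, "assignments.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_newick(gt, files$tree)
    write_alignment(aln, files$alignment)
    utils::write.table(
      data.frame(tip = names(assignment), haplogroup = unname(assignment)),
      files$assignments, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  structure(list(tree = gt, alignment = aln, assignment = assignment,
                 truth = truth, files = files),
            class = "simulated_dataset")
}
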