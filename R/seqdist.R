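# Alignment-based distances: uncorrected p, Kimura 2-parameter, and
# GTR-corrected, all under pairwise deletion; grouped distance matrices;
# saturation profile; missing-data fraction.
#
# An alignment is a character matrix (rows = sequences, uppercase,
# rownames = unique labels) of class "dna_alignment". Sites where either
# sequence of a pair is a gap, 'N', '?' or an IUPAC ambiguity code are
# excluded from that pair's counts (pairwise deletion); ambiguity codes
# are treated as missing rather than fractionally matched, so all counts
# are integers.

BASES <- c("A", "C", "G", "T")
# symbols counted as missing/ambiguous data
MISSING_SET <- c("-", "N", "?", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", ".")

#' Build an alignment object from named sequences
#'
#' @param x Named character vector of equal-length DNA strings, or a
#'   character matrix (rows = sequences) with rownames.
#' @return A `dna_alignment`: uppercase character matrix, rownames =
#'   labels.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    stopifnot(is.character(x))
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      stop("sequences must carry unique names", call. = FALSE)
    }
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      bad <- names(x)[lens != lens[1L]][1L]
      stop("ragged alignment: '", bad, "' has length ",
           nchar(x[bad]), ", expected ", lens[1L], call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("alignment rows must carry unique labels", call. = FALSE)
  }
  if (ncol(m) < 1L) stop("alignment has zero length", call. = FALSE)
  structure(m, class = "dna_alignment")
}

#' Read a FASTA alignment
#'
#' All records must have equal length (it is an alignment, not a
#' sequence set); lowercase bases are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A `dna_alignment` matrix.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path,
                               call. = FALSE)
  seqs <- ape::read.FASTA(path)
  if (!length(seqs)) stop("empty FASTA file: ", path, call. = FALSE)
  chr <- vapply(as.character(seqs), paste, character(1), collapse = "")
  names(chr) <- names(seqs)
  as_alignment(chr)
}

#' Write an alignment to FASTA
#'
#' @param aln A `dna_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  m <- unclass(aln)
  txt <- character(2L * nrow(m))
  txt[c(TRUE, FALSE)] <- paste0(">", rownames(m))
  txt[c(FALSE, TRUE)] <- apply(m, 1L, paste, collapse = "")
  writeLines(txt, path)
  invisible(path)
}

# Integer encoding A=1 C=2 G=3 T=4, everything else NA. Accepts a
# dna_alignment (-> matrix) or a single string / character vector.
encode_seq <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) x <- strsplit(x, "")[[1L]]
  match(toupper(x), BASES)
}

#' Pairwise site counts for two aligned sequences
#'
#' Counts compared sites, transitions and transversions under pairwise
#' deletion: only sites where both sequences carry an unambiguous
#' A/C/G/T are compared. Transitions are purine-purine (A/G) or
#' pyrimidine-pyrimidine (C/T) differences; every other difference is a
#' transversion.
#'
#' @param a,b Equal-length DNA strings (or character vectors of single
#'   bases).
#' @return Named integer vector `c(n_compared, n_transitions,
#'   n_transversions)`.
#' @examples
#' pairwise_counts("ACGT", "GCGT")
#' @export
pairwise_counts <- function(a, b) {
  ea <- encode_seq(a)
  eb <- encode_seq(b)
  if (length(ea) != length(eb)) {
    stop("sequence length mismatch: ", length(ea), " vs ", length(eb),
         call. = FALSE)
  }
  ok <- !is.na(ea) & !is.na(eb)
  ea <- ea[ok]; eb <- eb[ok]
  diff <- ea != eb
  # transitions: {A,G} = codes {1,3}, {C,T} = codes {2,4}; code parity
  # distinguishes purines (odd) from pyrimidines (even)
  ts <- diff & (ea %% 2L == eb %% 2L)
  c(n_compared = sum(ok), n_transitions = sum(ts),
    n_transversions = sum(diff & !ts))
}

#' Uncorrected p-distance from pairwise counts
#'
#' @param counts Output of [pairwise_counts()].
#' @return Proportion of compared sites that differ; `NA` (with a
#'   warning) when no sites are comparable.
#' @export
p_distance <- function(counts) {
  n <- counts[["n_compared"]]
  if (n == 0) {
    warning("no comparable sites; p-distance undefined", call. = FALSE)
    return(NA_real_)
  }
  (counts[["n_transitions"]] + counts[["n_transversions"]]) / n
}

#' Kimura 2-parameter distance from pairwise counts
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions. Outside the domain of the
#' logarithms the pair is saturated and `NA` is returned with a warning.
#'
#' @inheritParams p_distance
#' @return K2P-corrected distance (substitutions/site), or `NA`.
#' @export
k2p_distance <- function(counts) {
  n <- counts[["n_compared"]]
  if (n == 0) {
    warning("no comparable sites; K2P distance undefined", call. = FALSE)
    return(NA_real_)
  }
  P <- counts[["n_transitions"]] / n
  Q <- counts[["n_transversions"]] / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    warning("saturated pair: K2P correction undefined (P=", round(P, 3),
            ", Q=", round(Q, 3), ")", call. = FALSE)
    return(NA_real_)
  }
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' GTR-corrected distance between two aligned sequences
#'
#' General time-reversible distance from the symmetrized joint base
#' frequency matrix `F`: `d = -trace(Pi log(Pi^-1 F))`, evaluated
#' through the eigendecomposition of the symmetric similarity transform.
#' Base frequencies default to the pooled frequencies of the pair.
#'
#' @param a,b Equal-length DNA strings.
#' @param frequencies Optional length-4 vector of base frequencies
#'   (A, C, G, T); normalized internally. Default: estimated from the
#'   pooled pair.
#' @return GTR distance (substitutions/site); `NA` with a warning when
#'   the matrix logarithm is undefined (saturation) or a base is absent.
#' @export
gtr_distance <- function(a, b, frequencies = NULL) {
  ea <- encode_seq(a)
  eb <- encode_seq(b)
  if (length(ea) != length(eb)) stop("sequence length mismatch", call. = FALSE)
  ok <- !is.na(ea) & !is.na(eb)
  if (!sum(ok)) {
    warning("no comparable sites; GTR distance undefined", call. = FALSE)
    return(NA_real_)
  }
  FF <- matrix(0, 4, 4)
  tab <- table(factor(ea[ok], levels = 1:4), factor(eb[ok], levels = 1:4))
  FF[] <- as.numeric(tab) / sum(ok)
  FF <- (FF + t(FF)) / 2
  pi_ <- if (is.null(frequencies)) rowSums(FF) else frequencies / sum(frequencies)
  # bases absent from both sequences carry no signal: restrict the state
  # space to the observed ones instead of failing
  keep <- pi_ > 0
  if (sum(keep) < 2L) return(0)
  FF <- FF[keep, keep, drop = FALSE]
  pi_ <- pi_[keep] / sum(pi_[keep])
  FF <- FF / sum(FF)
  # log(Pi^-1 F) via S = Pi^-1/2 F Pi^-1/2 (symmetric, real spectrum);
  # then trace(Pi log(Pi^-1 F)) = sum_i pi_i [log S]_ii
  s <- diag(1 / sqrt(pi_)) %*% FF %*% diag(1 / sqrt(pi_))
  eg <- eigen((s + t(s)) / 2, symmetric = TRUE)
  if (any(eg$values <= 0)) {
    warning("saturated pair: GTR matrix logarithm undefined", call. = FALSE)
    return(NA_real_)
  }
  logS <- eg$vectors %*% (log(eg$values) * t(eg$vectors))
  d <- -sum(pi_ * diag(logS))
  max(d, 0)
}

#' Fraction of missing/ambiguous cells in an alignment
#'
#' @param aln A `dna_alignment`.
#' @param missing_set Characters counted as missing; defaults to gaps,
#'   `N`, `?`, `.` and all IUPAC ambiguity codes.
#' @return Proportion of alignment cells in `missing_set`.
#' @export
missing_fraction <- function(aln, missing_set = MISSING_SET) {
  m <- unclass(as_alignment(aln))
  mean(m %in% missing_set)
}

# counts for every unordered pair; returns list of matrices n, ts, tv
pair_count_matrices <- function(aln) {
  m <- unclass(as_alignment(aln))
  enc <- matrix(match(m, BASES), nrow = nrow(m),
                dimnames = list(rownames(m), NULL))
  k <- nrow(enc)
  n <- ts <- tv <- matrix(0L, k, k, dimnames = list(rownames(enc),
                                                    rownames(enc)))
  for (i in seq_len(k - 1L)) {
    ei <- enc[i, ]
    for (j in (i + 1L):k) {
      ej <- enc[j, ]
      ok <- !is.na(ei) & !is.na(ej)
      a <- ei[ok]; b <- ej[ok]
      diff <- a != b
      tsij <- sum(diff & (a %% 2L == b %% 2L))
      n[i, j] <- n[j, i] <- sum(ok)
      ts[i, j] <- ts[j, i] <- tsij
      tv[i, j] <- tv[j, i] <- sum(diff) - tsij
    }
  }
  list(n = n, ts = ts, tv = tv)
}

k2p_from_PQ <- function(P, Q) {
  bad <- (1 - 2 * P - Q <= 0) | (1 - 2 * Q <= 0)
  d <- -0.5 * log(pmax(1 - 2 * P - Q, 0)) - 0.25 * log(pmax(1 - 2 * Q, 0))
  d[bad] <- NA_real_
  d
}

#' Within/between-haplogroup distance matrix
#'
#' Mean uncorrected p-distance within each group (the diagonal; `NA`
#' for singleton groups), and mean p (lower triangle) and K2P (upper
#' triangle) distances over all cross-group sequence pairs. Distances
#' are stored as proportions; [format_grouped_matrix()] renders the
#' percent layout.
#'
#' @param aln A `dna_alignment`.
#' @param assignment A `haplo_assignment`; every alignment label must be
#'   assigned.
#' @return A list of class `grouped_distmat` with elements `groups`,
#'   `within` (named vector), `between_p` and `between_k2p` (symmetric
#'   matrices).
#' @export
grouped_distance_matrix <- function(aln, assignment) {
  aln <- as_alignment(aln)
  assignment <- as_assignment(unclass(assignment))
  labs <- rownames(aln)
  if (!all(labs %in% names(assignment))) {
    stop("unassigned sequence(s): ",
         paste(utils::head(setdiff(labs, names(assignment)), 5L),
               collapse = ", "), call. = FALSE)
  }
  groups <- sort(unique(unname(assignment[labs])))
  cm <- pair_count_matrices(aln)
  # mean distance over a set of (row, col) index pairs
  pd <- with(cm, (ts + tv) / ifelse(n > 0, n, NA))
  kd <- with(cm, k2p_from_PQ(ts / ifelse(n > 0, n, NA),
                             tv / ifelse(n > 0, n, NA)))
  within <- stats::setNames(rep(NA_real_, length(groups)), groups)
  g_of <- unname(assignment[labs])
  for (g in groups) {
    idx <- which(g_of == g)
    if (length(idx) >= 2L) {
      sub <- pd[idx, idx, drop = FALSE]
      within[g] <- mean(sub[upper.tri(sub)])
    }
  }
  k <- length(groups)
  bp <- bk <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ri <- which(g_of == groups[i]); rj <- which(g_of == groups[j])
      bp[i, j] <- bp[j, i] <- mean(pd[ri, rj, drop = FALSE])
      bk[i, j] <- bk[j, i] <- mean(kd[ri, rj, drop = FALSE])
    }
  }
  structure(list(groups = groups, within = within,
                 between_p = bp, between_k2p = bk),
            class = "grouped_distmat")
}

#' Render a grouped distance matrix in the publication layout
#'
#' One square character matrix: within-group mean p along the diagonal,
#' between-group p below it, K2P above it — in percent at the requested
#' precision, with `NA` for singleton diagonals.
#'
#' @param gdm A `grouped_distmat`.
#' @param digits Decimal places on the percent scale (default 1).
#' @return Character matrix with group names as dimnames.
#' @export
format_grouped_matrix <- function(gdm, digits = 1L) {
  stopifnot(inherits(gdm, "grouped_distmat"))
  k <- length(gdm$groups)
  fmt <- function(x) ifelse(is.na(x), "NA",
                            formatC(100 * x, format = "f", digits = digits))
  out <- matrix("", k, k, dimnames = list(gdm$groups, gdm$groups))
  for (i in seq_len(k)) {
    out[i, i] <- fmt(gdm$within[i])
    for (j in seq_len(k)) {
      if (j > i) out[i, j] <- fmt(gdm$between_k2p[i, j])
      if (j < i) out[i, j] <- fmt(gdm$between_p[i, j])
    }
  }
  out
}

#' @export
print.grouped_distmat <- function(x, ...) {
  cat("<grouped_distmat> ", length(x$groups),
      " haplogroups (diagonal = within p%, lower = between p%, ",
      "upper = between K2P%)\n", sep = "")
  print(format_grouped_matrix(x), quote = FALSE)
  invisible(x)
}

#' Substitution-saturation profile of an alignment
#'
#' For every unordered sequence pair: the GTR-corrected distance and the
#' proportions of compared sites that are transitions (`s`) and
#' transversions (`v`). Plotting `s` and `v` against the corrected
#' distance is the standard saturation diagnostic — a plateau in `s`
#' with `v` overtaking it indicates saturation.
#'
#' @param aln A `dna_alignment` with at least 2 sequences.
#' @return Data frame with columns `seq1, seq2, gtr, s, v`; attribute
#'   `n_v_exceeds_s` counts pairs where transversions exceed
#'   transitions.
#' @export
saturation_profile <- function(aln) {
  aln <- as_alignment(aln)
  labs <- rownames(aln)
  if (length(labs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  cm <- pair_count_matrices(aln)
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  rows <- list()
  for (i in seq_len(length(labs) - 1L)) {
    for (j in (i + 1L):length(labs)) {
      n <- cm$n[i, j]
      rows[[length(rows) + 1L]] <- data.frame(
        seq1 = labs[i], seq2 = labs[j],
        gtr = suppressWarnings(gtr_distance(seqs[i], seqs[j])),
        s = if (n > 0) cm$ts[i, j] / n else NA_real_,
        v = if (n > 0) cm$tv[i, j] / n else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_v_exceeds_s") <- sum(out$v > out$s, na.rm = TRUE)
  out
}
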