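test_that("alignment construction and FASTA round trip", {
  a <- as_alignment(c(s1 = "acgtACGTnn", s2 = "ACGTACGT-N"))
  expect_s3_class(a, "dna_alignment")
  expect_equal(dim(unclass(a)), c(2, 10))
  expect_true(all(unclass(a) %in% c("A", "C", "G", "T", "N", "-")))
  expect_error(as_alignment(c(s1 = "ACGT", s2 = "ACG")), "ragged")
  expect_error(as_alignment(c("ACGT", "ACGT")), "unique names")
  f <- tempfile(fileext = ".fasta")
  on.exit(unlink(f))
  write_alignment(a, f)
  b <- read_alignment(f)
  expect_equal(unclass(b), unclass(a), ignore_attr = TRUE)
  expect_identical(rownames(b), c("s1", "s2"))
  expect_error(read_alignment("/nonexistent.fa"), "not found")
})

test_that("pairwise_counts classifies sites like the brute-force loop", {
  expect_equal(pairwise_counts("ACGT", "ACGT"),
               c(n_compared = 4L, n_transitions = 0L, n_transversions = 0L))
  expect_equal(pairwise_counts("ACGT", "GCGT"),
               c(n_compared = 4L, n_transitions = 1L, n_transversions = 0L))
  expect_equal(pairwise_counts("AC-T", "ACGT")[["n_compared"]], 3L)
  expect_equal(pairwise_counts("ACGT", "ACGA")[["n_transversions"]], 1L)
  expect_error(pairwise_counts("ACGT", "ACG"), "length mismatch")
  set.seed(31)
  for (rep in 1:30) {
    a <- random_seq(60); b <- random_seq(60)
    expect_identical(pairwise_counts(a, b), bf_pair_counts(a, b))
  }
})

test_that("p_distance and k2p_distance evaluate their closed forms", {
  expect_equal(p_distance(c(n_compared = 4, n_transitions = 0,
                            n_transversions = 0)), 0)
  expect_equal(p_distance(pairwise_counts("ACGT", "ACGA")), 0.25)
  expect_equal(k2p_distance(c(n_compared = 10, n_transitions = 0,
                              n_transversions = 0)), 0)
  # P = 0.1, Q = 0.05 under the Kimura closed form
  expect_equal(k2p_distance(c(n_compared = 100, n_transitions = 10,
                              n_transversions = 5)), 0.17018, tolerance = 1e-4)
  # saturation: log domain violated
  expect_warning(
    d <- k2p_distance(c(n_compared = 10, n_transitions = 5,
                        n_transversions = 0)), "saturated")
  expect_true(is.na(d))
  expect_warning(p_distance(c(n_compared = 0, n_transitions = 0,
                              n_transversions = 0)), "no comparable")
  # K2P >= p on random valid pairs; K2P -> p at low divergence
  set.seed(5)
  for (rep in 1:20) {
    n <- 1000L
    ts <- sample(0:150, 1); tv <- sample(0:100, 1)
    cts <- c(n_compared = n, n_transitions = ts, n_transversions = tv)
    k <- suppressWarnings(k2p_distance(cts))
    if (!is.na(k)) expect_gte(k + 1e-12, p_distance(cts))
  }
  low <- c(n_compared = 10000, n_transitions = 70, n_transversions = 30)
  expect_lt(abs(k2p_distance(low) - p_distance(low)) / p_distance(low), 0.02)
})

test_that("p-distance behaves as a metric on gap-free sequences", {
  set.seed(8)
  pdist <- function(a, b) p_distance(pairwise_counts(a, b))
  for (rep in 1:15) {
    s <- replicate(3, paste(sample(c("A", "C", "G", "T"), 80, TRUE),
                            collapse = ""))
    expect_equal(pdist(s[1], s[2]), pdist(s[2], s[1]))
    expect_equal(pdist(s[1], s[1]), 0)
    expect_lte(pdist(s[1], s[3]),
               pdist(s[1], s[2]) + pdist(s[2], s[3]) + 1e-12)
  }
})

test_that("gtr_distance: identity, JC agreement, simulation recovery", {
  s <- paste(rep("ACGT", 50), collapse = "")
  expect_equal(gtr_distance(s, s), 0)
  # on JC-like data (kappa = 1) GTR matches the JC closed form
  tr2 <- parse_newick("(x:0.075,y:0.075);")
  aln <- simulate_alignment(tr2, L = 10000, kappa = 1, seed = 21)
  sq <- apply(unclass(aln), 1, paste, collapse = "")
  p <- p_distance(pairwise_counts(sq[1], sq[2]))
  jc <- -0.75 * log(1 - 4 * p / 3)
  g <- gtr_distance(sq[1], sq[2])
  expect_lt(abs(g - jc) / jc, 0.02)
  # recovers the simulated branch length within 10% at d_true = 0.1
  expect_lt(abs(g - 0.15) / 0.15, 0.1)
  aln2 <- simulate_alignment(parse_newick("(x:0.05,y:0.05);"),
                             L = 10000, kappa = 6, seed = 22)
  sq2 <- apply(unclass(aln2), 1, paste, collapse = "")
  g2 <- gtr_distance(sq2[1], sq2[2])
  expect_lt(abs(g2 - 0.1) / 0.1, 0.1)
})

test_that("grouped_distance_matrix: singletons, closed form, invariances", {
  # 2 groups x 2 identical sequences, 10% cross difference, all
  # transversions: between_p = 10%, between_k2p = -.5 ln .9 - .25 ln .8
  base <- paste(rep(c("A", "G"), 50), collapse = "")
  swapped <- strsplit(base, "")[[1]]
  swapped[seq_len(10)] <- c("C", "T")[match(swapped[seq_len(10)],
                                            c("A", "G"))]
  other <- paste(swapped, collapse = "")
  aln <- as_alignment(c(p1 = base, p2 = base, q1 = other, q2 = other))
  asn <- as_assignment(c(p1 = "P", p2 = "P", q1 = "Q", q2 = "Q"))
  gdm <- grouped_distance_matrix(aln, asn)
  expect_equal(unname(gdm$within), c(0, 0))
  expect_equal(gdm$between_p["P", "Q"], 0.10)
  expect_equal(gdm$between_k2p["P", "Q"],
               -0.5 * log(0.9) - 0.25 * log(0.8), tolerance = 1e-12)
  # singleton group: within NA, between still computed
  asn2 <- as_assignment(c(p1 = "P", p2 = "P", q1 = "Q", q2 = "R"))
  gdm2 <- grouped_distance_matrix(aln, asn2)
  expect_true(is.na(gdm2$within["Q"]))
  expect_false(is.na(gdm2$between_p["P", "Q"]))
  expect_error(grouped_distance_matrix(aln, asn2[1:3]), "unassigned")
  # K2P >= p everywhere, permutation invariance, on simulated data
  ds <- make_dataset(simulation_preset("deep")$spec,
                     list(L = 400, mu = 0.01, kappa = 8), seed = 14)
  g3 <- grouped_distance_matrix(ds$alignment, ds$assignment)
  expect_true(all(g3$between_k2p >= g3$between_p - 1e-12, na.rm = TRUE))
  perm <- sample(nrow(unclass(ds$alignment)))
  alnp <- as_alignment(unclass(ds$alignment)[perm, , drop = FALSE])
  g4 <- grouped_distance_matrix(alnp, ds$assignment)
  expect_equal(g3$between_p, g4$between_p)
  expect_equal(g3$within, g4$within)
  # percent layout: diagonal within, lower p, upper K2P
  fm <- format_grouped_matrix(gdm)
  expect_identical(fm["P", "P"], "0.0")
  expect_identical(fm["Q", "P"], "10.0")   # lower = p
  expect_identical(fm["P", "Q"], "10.8")   # upper = K2P
})

test_that("saturation_profile reports per-pair s, v and GTR distance", {
  s0 <- paste(rep("ACGT", 30), collapse = "")
  aln <- as_alignment(c(a = s0, b = s0))
  prof <- saturation_profile(aln)
  expect_equal(prof[1, c("gtr", "s", "v")],
               data.frame(gtr = 0, s = 0, v = 0), ignore_attr = TRUE)
  # strong transition bias: s > v for every pair
  ds <- make_dataset(simulation_preset("shallow")$spec,
                     list(L = 1500, mu = 0.01, kappa = 10), seed = 4)
  prof2 <- saturation_profile(ds$alignment)
  expect_equal(nrow(prof2), choose(nrow(unclass(ds$alignment)), 2))
  # transition bias: every pair with a non-trivial number of observed
  # differences has more transitions than transversions (near-identical
  # pairs carry too few substitutions to compare proportions)
  diffs <- (prof2$s + prof2$v) * 1500
  expect_true(all(prof2$s[diffs >= 10] > prof2$v[diffs >= 10]))
  expect_gt(sum(prof2$s), sum(prof2$v))
  expect_identical(attr(prof2, "n_v_exceeds_s"),
                   sum(prof2$v > prof2$s, na.rm = TRUE))
  # proportions equal brute-force site classification
  m <- unclass(ds$alignment)
  for (k in 1:5) {
    i <- sample(nrow(m), 2)
    cts <- bf_pair_counts(paste(m[i[1], ], collapse = ""),
                          paste(m[i[2], ], collapse = ""))
    row <- prof2[(prof2$seq1 == rownames(m)[i[1]] &
                    prof2$seq2 == rownames(m)[i[2]]) |
                   (prof2$seq1 == rownames(m)[i[2]] &
                      prof2$seq2 == rownames(m)[i[1]]), ]
    expect_equal(row$s, cts[["n_transitions"]] / cts[["n_compared"]])
    expect_equal(row$v, cts[["n_transversions"]] / cts[["n_compared"]])
  }
})

test_that("missing_fraction counts the configured missing set", {
  expect_equal(missing_fraction(as_alignment(c(a = "ACGT", b = "TGCA"))), 0)
  expect_equal(missing_fraction(as_alignment(c(a = "ACGT", b = "----"))), 0.5)
  # 33 missing cells of 300
  m <- matrix("A", 3, 100, dimnames = list(c("x", "y", "z"), NULL))
  m[sample(300, 33)] <- sample(c("-", "N", "R"), 33, replace = TRUE)
  expect_equal(missing_fraction(as_alignment(m)), 0.11)
  # ambiguity codes count as missing for pair counts too
  expect_equal(pairwise_counts("ARGT", "AYGT")[["n_compared"]], 3L)
})
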