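# Reference fixtures

Small plain-text fixtures transcribed from a published single-locus
(mitochondrial CYTB) delimitation analysis of American deer
haplogroups. They are used to exercise the aggregation/reporting path
(ratio and column-mean computation, Table-style layouts); the raw
sequences and trees behind them are not shipped.

- `ref_delimitation_ml.tsv` — per-haplogroup delimitation statistics
  computed on a maximum-likelihood tree (support = bootstrap %;
  `<50` means "below 50"). Distances ("tree distance") are in the
  units of that tree's branch lengths.
- `ref_delimitation_bi.tsv` — the same statistics computed on a
  Bayesian tree (support = posterior probability). Two cells in the
  published ratio column are typesetting artifacts (a spurious `NA`
  for one defined row, a `0.00` for a singleton) and are kept as
  printed.
- `ref_grouped_distances.tsv` — grouped distance matrix in percent:
  within-group mean p-distance on the diagonal (`NA` for singleton
  groups), between-group p below the diagonal, K2P above.
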