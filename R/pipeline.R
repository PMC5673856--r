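# Command-line orchestration: configuration, report generation, and the
# subcommand dispatcher behind the `haplodelim` executable script.
#
# Reports are plain TSV with the literal "NA" for undefined cells; the
# cause of every NA (singleton group, saturated pair, ...) is logged to
# stderr.

#' Assemble a pipeline configuration
#'
#' @param tree,aln,groups,out Paths: newick tree, FASTA alignment,
#'   assignments TSV, output directory.
#' @param support_kind `"bootstrap"` or `"posterior"`.
#' @param pid_reps Monte-Carlo replicates for P ID (>= 1000 for report
#'   runs; smaller values are allowed but warned about).
#' @param seed Integer seed for all stochastic steps.
#' @param digits_dist,digits_ratio,digits_percent Report precisions.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tree = NULL, aln = NULL, groups = NULL,
                            out = ".", support_kind = "bootstrap",
                            pid_reps = 1000L, seed = 1L,
                            digits_dist = 3L, digits_ratio = 2L,
                            digits_percent = 1L) {
  if (pid_reps < 1L) stop("pid_reps must be >= 1", call. = FALSE)
  if (pid_reps < 1000L) {
    warning("pid_reps < 1000 gives wide Monte-Carlo intervals",
            call. = FALSE)
  }
  structure(list(tree = tree, aln = aln, groups = groups, out = out,
                 support_kind = match.arg(support_kind,
                                          c("bootstrap", "posterior")),
                 pid_reps = as.integer(pid_reps), seed = as.integer(seed),
                 digits_dist = digits_dist, digits_ratio = digits_ratio,
                 digits_percent = digits_percent),
            class = "pipeline_config")
}

require_path <- function(path, what) {
  if (is.null(path)) stop("no ", what, " path configured", call. = FALSE)
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  path
}

log_na_cells <- function(tab) {
  singles <- tab$focal[is.na(tab$intra)]
  if (length(singles)) {
    message("NA intra/ratio/av_mrca_tips/pid_strict for singleton ",
            "haplogroup(s): ", paste(singles, collapse = ", "))
  }
}

#' Run the delimitation stage and write its reports
#'
#' Writes `delimitation.tsv` (one row per haplogroup, rounded to report
#' precision) and `delimitation_summary.tsv` (the NA-excluding column
#' means) under `config$out`.
#'
#' @param config A [pipeline_config()] with `tree` and `groups` set.
#' @return Invisibly, a list with the full-precision `table`, the
#'   `summary` vector, and output `files`.
#' @export
run_delimit <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tree <- read_support_tree(require_path(config$tree, "tree"),
                            support_kind = config$support_kind)
  assignment <- load_assignments(require_path(config$groups, "assignments"))
  tab <- delimit_table(tree, assignment, pid_reps = config$pid_reps,
                       seed = config$seed)
  log_na_cells(tab)
  summ <- summarize_table(tab)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  f_tab <- file.path(config$out, "delimitation.tsv")
  f_sum <- file.path(config$out, "delimitation_summary.tsv")
  utils::write.table(format_delimit_table(tab,
                                          digits_dist = config$digits_dist,
                                          digits_ratio = config$digits_ratio),
                     f_tab, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(statistic = names(summ),
                                mean = round(unname(summ), 4L)),
                     f_sum, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(table = tab, summary = summ,
                 files = c(f_tab, f_sum)))
}

#' Run the distance stage and write its reports
#'
#' Writes `grouped_distances.tsv` (within-group p on the diagonal,
#' between-group p below, K2P above, in percent) and `saturation.tsv`
#' (per-pair GTR distance with transition and transversion proportions)
#' under `config$out`.
#'
#' @param config A [pipeline_config()] with `aln` and `groups` set.
#' @return Invisibly, a list with the `grouped` matrix object, the
#'   `saturation` data frame, and output `files`.
#' @export
run_distances <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  aln <- read_alignment(require_path(config$aln, "alignment"))
  assignment <- load_assignments(require_path(config$groups, "assignments"))
  gdm <- grouped_distance_matrix(aln, assignment)
  singles <- gdm$groups[is.na(gdm$within)]
  if (length(singles)) {
    message("NA within-group distance for singleton haplogroup(s): ",
            paste(singles, collapse = ", "))
  }
  sat <- saturation_profile(aln)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  f_mat <- file.path(config$out, "grouped_distances.tsv")
  f_sat <- file.path(config$out, "saturation.tsv")
  fm <- format_grouped_matrix(gdm, digits = config$digits_percent)
  utils::write.table(cbind(haplogroup = rownames(fm), as.data.frame(fm)),
                     f_mat, sep = "\t", quote = FALSE, row.names = FALSE)
  sat_out <- sat
  sat_out$gtr <- round(sat_out$gtr, 6L)
  sat_out$s <- round(sat_out$s, 6L)
  sat_out$v <- round(sat_out$v, 6L)
  utils::write.table(sat_out, f_sat, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(grouped = gdm, saturation = sat, files = c(f_mat, f_sat)))
}

#' Simulate a benchmark dataset from a named preset
#'
#' @param preset Preset name (see [simulation_preset()]).
#' @param out Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the `simulated_dataset`.
#' @export
run_simulate <- function(preset = "deer-like", out = ".", seed = 1L) {
  ps <- tryCatch(simulation_preset(preset, seed = seed), error = function(e) {
    stop("unknown preset '", preset, "'; available: deer-like, deep, ",
         "shallow", call. = FALSE)
  })
  invisible(make_dataset(ps$spec, ps$seq_params, dir = out, seed = seed))
}

cli_usage <- function() {
  paste(
    "usage: haplodelim <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate   --preset NAME --out DIR [--seed N]",
    "  delimit    --tree F --groups F --out DIR [--support-kind K]",
    "             [--pid-reps N] [--seed N]",
    "  distances  --aln F --groups F --out DIR",
    "  report     --tree F --aln F --groups F --out DIR [...]",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      stop("flag ", a, " needs a value", call. = FALSE)
    }
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `delimit`, `distances` and `report`
#' subcommands (the installed `exec/haplodelim` script calls this and
#' exits with the returned status). Errors are printed to stderr;
#' missing input files yield status 2, usage errors status 1.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
haplodelim_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message(cli_usage())
    return(invisible(1L))
  }
  sub <- args[1L]
  res <- tryCatch({
    flags <- parse_cli_flags(args[-1L])
    num <- function(x, d) if (is.null(x)) d else as.integer(x)
    if (sub == "simulate") {
      run_simulate(preset = flags$preset %||% "deer-like",
                   out = flags$out %||% ".",
                   seed = num(flags$seed, 1L))
    } else if (sub %in% c("delimit", "distances", "report")) {
      cfg <- pipeline_config(tree = flags$tree, aln = flags$aln,
                             groups = flags$groups,
                             out = flags$out %||% ".",
                             support_kind = flags$support_kind %||%
                               "bootstrap",
                             pid_reps = num(flags$pid_reps, 1000L),
                             seed = num(flags$seed, 1L))
      if (sub %in% c("delimit", "report")) run_delimit(cfg)
      if (sub %in% c("distances", "report")) run_distances(cfg)
    } else {
      message("unknown subcommand: ", sub, "\n", cli_usage())
      return(invisible(1L))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("not found", conditionMessage(e))) 2L else 1L
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
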