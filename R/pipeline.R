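#' End-to-end divergence-point simulation
#'
#' Generates (or accepts) a lexicon, design and segment features, builds the
#' evidence matrix at the requested temperature, runs the condition-level
#' divergence-point simulation and the uncertainty sweep, and optionally
#' writes the result tables plus a provenance record to a directory.
#'
#' @param params A [design_params()] object (ignored when `lexicon`,
#'   `design` and `features` are all supplied).
#' @param temperature Softmax temperature for the headline simulation.
#' @param t_grid Temperature grid for the sweep (`NULL` to skip it).
#' @param lexicon,design,features Optional pre-built inputs.
#' @param out_dir Optional output directory for tidy delimited tables
#'   (`items.tsv`, `condition_means.tsv`, `sweep_flags.tsv`), the inputs
#'   that generated them (`lexicon.tsv`, `inventory.txt`, `features.tsv`,
#'   `design.tsv` -- valid inputs for [read_lexicon()] and
#'   [read_segment_features()], so a run can be rebuilt from its artifact)
#'   and `provenance.json`.
#' @return List of class `simulation_pipeline` with `lexicon`, `design`,
#'   `features`, `evidence`, `simulation` (a `dp_simulation`) and `sweep`
#'   (an `uncertainty_sweep` or `NULL`).
#' @export
run_divergence_simulation <- function(params = design_params(),
                                      temperature = default_temperature(),
                                      t_grid = default_temperature_grid(),
                                      lexicon = NULL, design = NULL,
                                      features = NULL, out_dir = NULL) {
  if (is.null(lexicon) || is.null(design)) {
    gen <- generate_lexicon(params)
    lexicon <- gen$lexicon
    design <- gen$design
  }
  if (is.null(features)) features <- generate_segment_features(params)
  d <- segment_distance_matrix(features, boundary = boundary_token(lexicon))
  evidence <- softmax_evidence(d, temperature)
  simulation <- run_condition_simulation(lexicon, evidence, design)
  sweep <- if (!is.null(t_grid)) {
    uncertainty_sweep(lexicon, features, design, t_grid)
  }
  out <- structure(list(lexicon = lexicon, design = design,
                        features = features, evidence = evidence,
                        simulation = simulation, sweep = sweep,
                        params = params, temperature = temperature,
                        t_grid = t_grid),
                   class = "simulation_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(simulation$items, file.path(out_dir, "items.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(simulation$condition_means,
                       file.path(out_dir, "condition_means.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sweep)) {
      utils::write.table(sweep$flags, file.path(out_dir, "sweep_flags.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_lexicon(lexicon, file.path(out_dir, "lexicon.tsv"))
    writeLines(segment_inventory(lexicon), file.path(out_dir, "inventory.txt"))
    write_segment_features(features, file.path(out_dir, "features.tsv"))
    utils::write.table(design, file.path(out_dir, "design.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(out_dir, list(
      temperature = temperature, t_grid = t_grid,
      params = unclass(params)))
  }
  out
}

#' @export
print.simulation_pipeline <- function(x, ...) {
  cat(sprintf("<simulation_pipeline: %d items, T = %g>\n",
              nrow(x$design), x$temperature))
  print(x$simulation$crossover[, c("kind", "crossover")], ...)
  invisible(x)
}

# per-subject item-by-sensor patterns, averaged over repetitions and the
# response-window timepoints (rejected epochs skipped)
window_patterns <- function(dataset, window) {
  sel_t <- which(dataset$times >= window[1] & dataset$times <= window[2])
  d <- dim(dataset$data)
  lapply(seq_len(d[1]), function(s) {
    apply(dataset$data[s, , , , sel_t, drop = FALSE], c(2, 4), mean,
          na.rm = TRUE)
  })
}

# subjects x timepoints matrix of the pattern-distance interaction contrast
# (Strong - Weak | Mismatch) - (Strong - Weak | Match)
interaction_timecourse <- function(dataset, mask) {
  d <- dim(dataset$data)
  design <- dataset$design
  out <- matrix(NA_real_, d[1], d[5])
  for (s in seq_len(d[1])) {
    for (tp in seq_len(d[5])) {
      pat <- apply(dataset$data[s, , , , tp, drop = FALSE], c(2, 4), mean,
                   na.rm = TRUE)
      cm <- condition_mean_distance(euclidean_rdm(pat), design, mask)
      v <- setNames(cm$mean_distance, cm$condition)
      out[s, tp] <- (v["Strong+Mismatch"] - v["Weak+Mismatch"]) -
        (v["Strong+Match"] - v["Weak+Match"])
    }
  }
  out
}

#' Mechanism-recovery experiment on synthetic neural data
#'
#' For each run, generates a synthetic sensor dataset embedding one of the
#' two candidate mechanisms, applies pattern-mode outlier rejection, builds
#' per-subject Euclidean RDMs from window-averaged patterns, and identifies
#' the generating mechanism as the model RDM (prediction error vs sharpened
#' signal, at the generating temperature) with the larger mean
#' Fisher-transformed Spearman correlation across subjects. Optionally also
#' runs the cluster permutation test on each dataset's pattern-distance
#' interaction timecourse.
#'
#' @param n_runs Number of datasets (mechanisms alternate run by run).
#' @param snr Signal-to-noise amplitude passed to the generator.
#' @param params A [design_params()] for the lexicon/design (built once).
#' @param temperature Softmax temperature of the generating/analysing model.
#' @param gen Base [neural_gen_params()] settings (mechanism, snr and seed
#'   fields are overridden per run).
#' @param cluster_test Also run the interaction cluster permutation test per
#'   dataset (slower).
#' @param n_perm Permutations for the cluster test.
#' @param seed Master seed; run `r` uses `seed + r` for its dataset.
#' @return Tibble of class `recovery_report`: one row per run with the mean
#'   subject-level RDM correlations (`z_pe`, `z_sharpened`), the decoded
#'   `winner`, `correct`, and `interaction_p` when requested. `glance()`
#'   gives the overall accuracy.
#' @export
run_mechanism_recovery <- function(n_runs = 50, snr = 0.5,
                                   params = design_params(),
                                   temperature = default_temperature(),
                                   gen = neural_gen_params(snr = snr),
                                   cluster_test = FALSE, n_perm = 500,
                                   seed = 0) {
  gen$snr <- snr
  gsetup <- generate_lexicon(params)
  features <- generate_segment_features(params)
  d <- segment_distance_matrix(features, boundary = boundary_token(gsetup$lexicon))
  evidence <- softmax_evidence(d, temperature)
  sim <- run_condition_simulation(gsetup$lexicon, evidence, gsetup$design)
  mask <- sim$mask
  model_rdms <- sim$rdms
  mechanisms <- rep(c("prediction_error", "sharpened"), length.out = n_runs)

  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    gp <- gen
    gp$mechanism <- mechanisms[r]
    gp$seed <- seed + r
    ds <- generate_neural_dataset(gsetup$lexicon, evidence, gsetup$design, gp)
    ds <- reject_outlier_epochs(ds, "pattern")$dataset
    pats <- window_patterns(ds, gp$window)
    zs <- vapply(pats, function(p) {
      nr <- euclidean_rdm(p)
      c(pe = rdm_correlation(nr, model_rdms$prediction_error, mask),
        sharpened = rdm_correlation(nr, model_rdms$sharpened, mask))
    }, numeric(2))
    z_pe <- mean(zs["pe", ])
    z_sh <- mean(zs["sharpened", ])
    winner <- if (z_pe >= z_sh) "prediction_error" else "sharpened"
    row <- tibble::tibble(run = r, mechanism = mechanisms[r],
                          seed = gp$seed, snr = snr,
                          z_pe = z_pe, z_sharpened = z_sh,
                          winner = winner, correct = winner == mechanisms[r])
    if (cluster_test) {
      ic <- interaction_timecourse(ds, mask)
      ct <- cluster_permutation_test(ic, n_perm = n_perm, seed = gp$seed,
                                     times = ds$times)
      row$interaction_p <- if (nrow(ct$clusters)) min(ct$clusters$p_value) else NA_real_
    }
    rows[[r]] <- row
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recovery_report", class(out))
  out
}

#' Cluster test on a supplied contrast table
#'
#' @param contrast_table Data frame with numeric `subject`, `time` and
#'   `value` columns (one row per subject x timepoint), or a path to such a
#'   tab-separated file.
#' @param n_perm,alpha_height,seed Passed to [cluster_permutation_test()].
#' @param out_file Optional path for the structured text report.
#' @return A `cluster_test`.
#' @export
run_cluster_stats <- function(contrast_table, n_perm = 5000,
                              alpha_height = 0.05, seed = 0,
                              out_file = NULL) {
  if (is.character(contrast_table)) {
    contrast_table <- utils::read.delim(contrast_table)
  }
  needed <- c("subject", "time", "value")
  if (!all(needed %in% names(contrast_table))) {
    abort("contrast table needs subject, time and value columns",
          class = "cohortpe_bad_contrast")
  }
  bad <- which(!is.finite(contrast_table$value))
  if (length(bad) > 0) {
    abort(paste0("non-numeric or missing contrast value in row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "cohortpe_bad_contrast")
  }
  wide <- tidyr::pivot_wider(contrast_table, id_cols = "subject",
                             names_from = "time", values_from = "value")
  times <- as.numeric(names(wide)[-1])
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(m)) {
    abort("contrast table is not complete over subjects x timepoints",
          class = "cohortpe_bad_contrast")
  }
  ct <- cluster_permutation_test(m, n_perm = n_perm,
                                 alpha_height = alpha_height, seed = seed,
                                 times = times)
  if (!is.null(out_file)) write_cluster_report(ct, out_file)
  ct
}

#' Write a machine-readable provenance record
#'
#' Records the configuration, seeds, package version and R version needed to
#' re-run an analysis bit-identically.
#'
#' @param dir Output directory.
#' @param config Named list of run configuration (seeds included).
#' @return The file path, invisibly.
#' @export
write_provenance <- function(dir, config) {
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(list(
    package = "cohortpe",
    version = as.character(utils::packageVersion("cohortpe")),
    r_version = R.version.string,
    config = config
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
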