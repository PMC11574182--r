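#' Bundle an epoched sensor dataset with its metadata
#'
#' @param data 5-d numeric array: subjects x items x repetitions x sensors x
#'   timepoints. `NA` marks rejected epochs.
#' @param times Strictly increasing sample times in ms (relative to the
#'   second-syllable onset), length matching the last dimension.
#' @param design Item design table covering every item (rows parallel to the
#'   item dimension).
#' @return Object of class `neural_dataset`.
#' @export
neural_dataset <- function(data, times, design) {
  stopifnot(length(dim(data)) == 5)
  if (any(!is.finite(data) & !is.na(data))) {
    abort("data must be finite (or NA for rejected epochs)",
          class = "cohortpe_bad_neural")
  }
  if (length(times) != dim(data)[5] || any(diff(times) <= 0)) {
    abort("times must be strictly increasing and match the time dimension",
          class = "cohortpe_bad_neural")
  }
  if (nrow(design) != dim(data)[2]) {
    abort("design must cover every item", class = "cohortpe_bad_neural")
  }
  structure(list(data = data, times = times,
                 design = tibble::as_tibble(design)),
            class = "neural_dataset")
}

#' @export
print.neural_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<neural_dataset: %d subjects x %d items x %d reps x %d sensors x %d timepoints (%g..%g ms)>\n",
    d[1], d[2], d[3], d[4], d[5], min(x$times), max(x$times)))
  invisible(x)
}

# per-epoch power: time- and channel-averaged squared signal
epoch_power <- function(data) {
  apply(data, c(1, 2, 3), function(v) mean(v^2))
}

#' Reject high-power outlier epochs
#'
#' Epochs (one subject x item x repetition recording) are dropped when their
#' time- and channel-averaged power exceeds the reference mean by more than
#' a threshold number of standard deviations, computed per subject:
#' condition-specific mean and 2 SD in `"magnitude"` mode, pooled mean and
#' 3 SD in `"pattern"` mode.
#'
#' @param dataset A [neural_dataset()].
#' @param mode `"magnitude"` or `"pattern"`.
#' @return List with `dataset` (rejected epochs set to `NA`) and `report`
#'   (tibble of dropped `subject`, `item`, `rep`, `power`).
#' @export
reject_outlier_epochs <- function(dataset, mode = c("magnitude", "pattern")) {
  mode <- match.arg(mode)
  k <- if (mode == "magnitude") 2 else 3
  pw <- epoch_power(dataset$data)
  cond <- as.character(design_conditions(dataset$design))
  d <- dim(pw)
  drop <- array(FALSE, d)
  for (s in seq_len(d[1])) {
    groups <- if (mode == "magnitude") cond else rep("all", d[2])
    for (g in unique(groups)) {
      sel <- which(groups == g)
      v <- pw[s, sel, ]
      mu <- mean(v, na.rm = TRUE)
      sg <- sd(v, na.rm = TRUE)
      if (!is.finite(sg) || sg == 0) next
      drop[s, sel, ] <- drop[s, sel, ] | (pw[s, sel, ] > mu + k * sg)
    }
  }
  idx <- which(drop, arr.ind = TRUE)
  report <- tibble::tibble(subject = idx[, 1],
                           item = dataset$design$item_id[idx[, 2]],
                           rep = idx[, 3],
                           power = pw[idx])
  data <- dataset$data
  for (r in seq_len(nrow(idx))) {
    data[idx[r, 1], idx[r, 2], idx[r, 3], , ] <- NA_real_
  }
  # every subject x condition must keep at least one epoch
  kept <- !apply(is.na(data[, , , 1, 1, drop = FALSE]), c(1, 2), all)
  for (g in unique(cond)) {
    if (any(rowSums(kept[, cond == g, drop = FALSE]) == 0)) {
      abort(paste0("outlier rejection left a subject with no epochs in ", g),
            class = "cohortpe_empty_condition")
    }
  }
  list(dataset = neural_dataset(data, dataset$times, dataset$design),
       report = report)
}

#' Select the sensors with the largest evoked response
#'
#' @param evoked Sensors-by-timepoints matrix of condition-averaged signal
#'   (one participant / hemisphere at a time).
#' @param n Number of sensors to keep (default 20).
#' @return Sorted integer indices of the `n` sensors with the largest
#'   time-averaged signal power; ties break deterministically toward the
#'   lower sensor index.
#' @export
select_sensors <- function(evoked, n = 20) {
  evoked <- as.matrix(evoked)
  if (n > nrow(evoked)) {
    abort("n exceeds the sensor count", class = "cohortpe_bad_neural")
  }
  power <- rowMeans(evoked^2)
  sort(order(-power, seq_along(power))[seq_len(n)])
}

# subject x condition x sensor x time condition-averaged signal
condition_average <- function(dataset) {
  cond <- as.character(design_conditions(dataset$design))
  lev <- intersect(condition_levels(), unique(cond))
  d <- dim(dataset$data)
  out <- array(NA_real_, c(d[1], length(lev), d[4], d[5]),
               dimnames = list(NULL, lev, NULL, NULL))
  for (g in seq_along(lev)) {
    sel <- which(cond == lev[g])
    # average over items and repetitions, ignoring rejected epochs
    out[, g, , ] <- apply(dataset$data[, sel, , , , drop = FALSE],
                          c(1, 4, 5), mean, na.rm = TRUE)
  }
  out
}

#' RMS summary time course over selected sensors
#'
#' Condition-averages the signal per subject (over items and repetitions,
#' skipping rejected epochs), then takes the root mean square over the
#' selected sensors at each timepoint.
#'
#' @param dataset A [neural_dataset()].
#' @param sensors Integer sensor indices; when `NULL` the `n_sensors`
#'   strongest sensors are selected per subject with [select_sensors()].
#' @param n_sensors Used when `sensors` is `NULL`.
#' @return Array subjects x conditions x timepoints with condition dimnames
#'   and attribute `times`.
#' @export
rms_timecourse <- function(dataset, sensors = NULL, n_sensors = 20) {
  avg <- condition_average(dataset)
  d <- dim(avg)
  out <- array(NA_real_, c(d[1], d[2], d[4]),
               dimnames = list(NULL, dimnames(avg)[[2]], NULL))
  for (s in seq_len(d[1])) {
    sel <- sensors
    if (is.null(sel)) {
      evoked <- apply(avg[s, , , , drop = FALSE], c(3, 4), mean)
      sel <- select_sensors(evoked, n = n_sensors)
    }
    if (length(sel) == 0) abort("sensor set must be non-empty",
                                class = "cohortpe_bad_neural")
    for (g in seq_len(d[2])) {
      m <- matrix(avg[s, g, sel, ], nrow = length(sel))
      out[s, g, ] <- sqrt(colMeans(m^2))
    }
  }
  attr(out, "times") <- dataset$times
  out
}

#' Cluster-based sign-flip permutation test
#'
#' One-sample t-test at every timepoint; contiguous runs of same-signed
#' supra-threshold t-values form clusters scored by their summed t. The null
#' distribution is the maximum absolute cluster t-sum over random
#' whole-subject sign flips, giving family-wise error control across
#' timepoints; tests are two-sided via sign-specific clusters against the
#' max-|t-sum| null. Clusters touching the epoch edges are retained.
#'
#' @param contrast_values Subjects-by-timepoints matrix of per-subject
#'   contrast values.
#' @param n_perm Number of sign-flip permutations (>= 100; 5000 for
#'   publication-grade inference).
#' @param alpha_height Two-sided pointwise p threshold defining cluster
#'   membership (default 0.05).
#' @param seed Integer seed; the test is bit-reproducible given a seed.
#' @param times Optional timepoint labels (ms) attached to the cluster
#'   bounds.
#' @return Object of class `cluster_test` with a `clusters` tibble
#'   (`start`, `end`, `sign`, `t_sum`, `p_value`, plus `start_ms`/`end_ms`
#'   when `times` given), the pointwise `t` series, `threshold`, `n_perm`,
#'   `seed` and the permutation `null_max` distribution.
#' @export
cluster_permutation_test <- function(contrast_values, n_perm = 5000,
                                     alpha_height = 0.05, seed = 0,
                                     times = NULL) {
  x <- as.matrix(contrast_values)
  dimnames(x) <- NULL
  n <- nrow(x)
  if (n < 3) abort("need at least 3 subjects", class = "cohortpe_bad_neural")
  if (n_perm < 100) abort("n_perm must be >= 100", class = "cohortpe_bad_neural")
  tcrit <- qt(1 - alpha_height / 2, df = n - 1)

  msq <- colMeans(x^2)
  t_of_means <- function(means) {
    # sign flips leave sum(x^2) unchanged, so the flipped-sample t statistic
    # is a function of the flipped mean alone
    v <- (n * msq - n * means^2) / (n - 1)
    tt <- means / sqrt(v / n)
    tt[is.nan(tt)] <- 0
    tt
  }
  t_obs <- t_of_means(colMeans(x))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  perm_means <- (signs %*% x) / n
  # all permutation t series at once: v/n = (msq - mean^2) / (n - 1)
  perm_t <- perm_means /
    sqrt((matrix(msq, n_perm, ncol(x), byrow = TRUE) - perm_means^2) / (n - 1))
  perm_t[is.nan(perm_t)] <- 0
  null_max <- vapply(seq_len(n_perm), function(p) {
    max_abs_cluster_sum(perm_t[p, ], tcrit)
  }, numeric(1))

  clusters <- find_clusters(t_obs, tcrit)
  clusters$p_value <- vapply(clusters$t_sum, function(ts) {
    (1 + sum(null_max >= abs(ts))) / (1 + n_perm)
  }, numeric(1))
  if (!is.null(times)) {
    clusters$start_ms <- times[clusters$start]
    clusters$end_ms <- times[clusters$end]
  }
  structure(list(clusters = clusters, t = t_obs, threshold = tcrit,
                 alpha_height = alpha_height, n_perm = n_perm, seed = seed,
                 null_max = null_max, times = times),
            class = "cluster_test")
}

# allocation-free variant of find_clusters for the permutation loop
max_abs_cluster_sum <- function(t_series, tcrit) {
  lab <- (t_series > tcrit) - (t_series < -tcrit)
  if (all(lab == 0L)) return(0)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cs <- c(0, cumsum(t_series))
  max(abs(cs[ends + 1L] - cs[starts])[r$values != 0L])
}

find_clusters <- function(t_series, tcrit) {
  lab <- ifelse(t_series > tcrit, 1L, ifelse(t_series < -tcrit, -1L, 0L))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  tibble::tibble(
    start = starts[keep], end = ends[keep], sign = r$values[keep],
    t_sum = vapply(which(keep), function(i) {
      sum(t_series[starts[i]:ends[i]])
    }, numeric(1))
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test: %d permutations, |t| > %.3f>\n",
              x$n_perm, x$threshold))
  if (nrow(x$clusters) == 0) cat("no supra-threshold clusters\n")
  else print(x$clusters, ...)
  invisible(x)
}

#' Serialise a cluster test as a structured text report
#'
#' @param x A `cluster_test`.
#' @param file Path.
#' @export
write_cluster_report <- function(x, file) {
  lines <- c(
    sprintf("cluster permutation test (n_perm=%d, height alpha=%g, seed=%d)",
            x$n_perm, x$alpha_height, x$seed),
    sprintf("cluster-defining |t| threshold: %.4f", x$threshold))
  if (nrow(x$clusters) == 0) {
    lines <- c(lines, "no supra-threshold clusters")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      span <- if (!is.null(cl$start_ms)) {
        sprintf("%g..%g ms", cl$start_ms, cl$end_ms)
      } else sprintf("samples %d..%d", cl$start, cl$end)
      lines <- c(lines, sprintf("cluster %d: %s sign=%+d t-sum=%.3f p=%.5f",
                                i, span, cl$sign, cl$t_sum, cl$p_value))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' Within-subject (Cousineau-Morey) standard errors
#'
#' Removes between-subject offsets (subtract each subject's mean, add the
#' grand mean) before computing per-condition standard errors, then applies
#' the Morey bias correction `sqrt(C / (C - 1))`.
#'
#' @param values Subjects-by-conditions numeric matrix (condition names as
#'   column names), or a data frame with `subject`, `condition`, `value`
#'   columns; every subject must have every condition.
#' @return Tibble with `condition`, `mean`, `se`.
#' @export
within_subject_se <- function(values) {
  if (is.data.frame(values)) {
    wide <- tidyr::pivot_wider(values[, c("subject", "condition", "value")],
                               names_from = "condition",
                               values_from = "value")
    values <- as.matrix(wide[, -1, drop = FALSE])
  }
  if (anyNA(values)) {
    abort("values must be complete (every subject x condition cell)",
          class = "cohortpe_bad_neural")
  }
  n <- nrow(values); k <- ncol(values)
  centred <- values - rowMeans(values) + mean(values)
  se <- apply(centred, 2, sd) / sqrt(n) * sqrt(k / (k - 1))
  tibble::tibble(condition = colnames(values) %||% as.character(seq_len(k)),
                 mean = colMeans(values), se = se)
}
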