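#' Normalised Levenshtein dissimilarity between phonetic transcriptions
#'
#' Unit-cost edit distance (insert / delete / substitute over whole segment
#' labels) divided by the longer of the two syllable lengths, giving a value
#' in `[0, 1]`: 0 for identical syllables, 1 for fully disjoint syllables of
#' equal length.
#'
#' @param syl_a,syl_b Non-empty segment sequences (character vectors or
#'   space-separated strings).
#' @return Dissimilarity in `[0, 1]`.
#' @export
levenshtein_phonetic_dissimilarity <- function(syl_a, syl_b) {
  a <- parse_segments(syl_a)
  b <- parse_segments(syl_b)
  if (length(a) == 0 || length(b) == 0) {
    abort("syllables must be non-empty", class = "cohortpe_bad_syllable")
  }
  segment_edit_distance(a, b) / max(length(a), length(b))
}

# classic two-row dynamic programme over label vectors
segment_edit_distance <- function(a, b) {
  na <- length(a); nb <- length(b)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cur[j + 1] <- min(prev[j + 1] + 1,             # delete
                        cur[j] + 1,                  # insert
                        prev[j] + (a[i] != b[j]))    # substitute
    }
    prev <- cur
  }
  prev[nb + 1]
}

#' Phonetic dissimilarity matrix over items
#'
#' Builds the normalised-Levenshtein RDM between the chosen syllable of all
#' item pairs in a design.
#'
#' @param design Item design table.
#' @param syllables Character vector (parallel to the design rows) of
#'   space-separated syllable transcriptions to compare; typically the Syl2
#'   portion of each item.
#' @return An `rdm` matrix (metric `"levenshtein"`), item ids as dimnames.
#' @export
phonetic_rdm <- function(design, syllables) {
  stopifnot(length(syllables) == nrow(design))
  segs <- lapply(syllables, parse_segments)
  n <- length(segs)
  m <- matrix(0, n, n, dimnames = list(design$item_id, design$item_id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <-
        levenshtein_phonetic_dissimilarity(segs[[i]], segs[[j]])
    }
  }
  new_rdm(m, "levenshtein")
}

new_rdm <- function(m, metric) {
  structure(m, class = c("rdm", class(m)), metric = metric)
}

#' Euclidean pattern-distance matrix
#'
#' @param patterns Numeric matrix, one row per item (item ids as row names),
#'   equal-length pattern vectors as columns.
#' @return An `rdm`: symmetric, zero diagonal, metric `"euclidean"`.
#' @export
euclidean_rdm <- function(patterns) {
  if (!is.matrix(patterns)) patterns <- as.matrix(patterns)
  if (!all(is.finite(patterns))) {
    abort("patterns must be finite", class = "cohortpe_bad_patterns")
  }
  new_rdm(as.matrix(dist(patterns, method = "euclidean")), "euclidean")
}

#' Cross-validated Mahalanobis (crossnobis) pattern distances
#'
#' For each item pair (i, j) the distance is the average over ordered fold
#' pairs (a != b) of `(x_i^a - x_j^a)' Sigma^-1 (x_i^b - x_j^b)`, where
#' `Sigma` is the noise covariance. Cross-validation makes the estimate
#' unbiased: its expectation is zero when two patterns do not differ, so
#' individual values can be negative and are deliberately not floored.
#'
#' @param patterns_by_fold List (length >= 2) of item-by-feature matrices,
#'   one per independent data fold, identical row order.
#' @param noise_covariance Symmetric positive-definite feature covariance;
#'   identity by default. See [shrinkage_covariance()] for a regularised
#'   estimate from residuals.
#' @return An `rdm` with metric `"crossnobis"` (entries may be negative).
#' @export
crossnobis_rdm <- function(patterns_by_fold, noise_covariance = NULL) {
  if (!is.list(patterns_by_fold) || length(patterns_by_fold) < 2) {
    abort("need at least two folds of patterns", class = "cohortpe_bad_patterns")
  }
  folds <- lapply(patterns_by_fold, as.matrix)
  dims <- vapply(folds, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    abort("all folds must have identical dimensions",
          class = "cohortpe_bad_patterns")
  }
  n_items <- dims[1, 1]; n_feat <- dims[2, 1]
  if (is.null(noise_covariance)) noise_covariance <- diag(n_feat)
  prec <- tryCatch(solve(noise_covariance), error = function(e) {
    abort("noise covariance is singular", class = "cohortpe_singular_covariance")
  })
  n_folds <- length(folds)
  acc <- matrix(0, n_items, n_items)
  n_pairs <- 0L
  for (a in seq_len(n_folds)) {
    for (b in seq_len(n_folds)) {
      if (a == b) next
      # g[i,j] = x_i^a' P x_j^b; then
      # (x_i^a - x_j^a)' P (x_i^b - x_j^b) = g_ii + g_jj - g_ij - g_ji
      g <- folds[[a]] %*% prec %*% t(folds[[b]])
      dg <- diag(g)
      acc <- acc + (matrix(dg, n_items, n_items) +
                      matrix(dg, n_items, n_items, byrow = TRUE) - g - t(g))
      n_pairs <- n_pairs + 1L
    }
  }
  m <- acc / n_pairs
  m <- (m + t(m)) / 2
  rownames(m) <- colnames(m) <- rownames(folds[[1]])
  new_rdm(m, "crossnobis")
}

#' Shrinkage-regularised noise covariance
#'
#' Sample covariance of residuals shrunk toward its diagonal,
#' `(1 - lambda) * S + lambda * diag(diag(S))`, with a Ledoit-Wolf-style
#' data-driven shrinkage intensity when `lambda` is `NULL`.
#'
#' @param residuals Observations-by-features residual matrix.
#' @param lambda Shrinkage intensity in `[0, 1]`, or `NULL` to estimate it.
#' @return Symmetric positive-definite covariance matrix.
#' @export
shrinkage_covariance <- function(residuals, lambda = NULL) {
  x <- scale(as.matrix(residuals), center = TRUE, scale = FALSE)
  n <- nrow(x)
  s <- crossprod(x) / (n - 1)
  if (is.null(lambda)) {
    # variance of the off-diagonal sample covariances vs their magnitude
    xc2 <- x^2
    phi <- (crossprod(xc2) / n - (crossprod(x) / n)^2) * n / (n - 1)^2
    target <- diag(diag(s))
    num <- sum(phi[upper.tri(phi)])
    den <- sum((s - target)[upper.tri(s)]^2)
    lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  }
  out <- (1 - lambda) * s + lambda * diag(diag(s))
  attr(out, "lambda") <- lambda
  out
}

#' Reciprocal-pair exclusion mask
#'
#' Within each item set and congruency class, pairs whose second syllables
#' differ are excluded from pattern statistics: with two Syl2 types per set,
#' these are exactly the pairs in which one item's prediction is the other
#' item's input, evoking similar but opposite prediction errors whose
#' neural encoding polarity is unknown.
#'
#' @param design Item design table with `item_id`, `set_id`, `congruency`
#'   and `syl2_label` columns.
#' @return Logical item-by-item matrix, `TRUE` for excluded pairs (diagonal
#'   `FALSE`); dimnames are the item ids.
#' @export
reciprocal_pair_mask <- function(design) {
  needed <- c("item_id", "set_id", "congruency", "syl2_label")
  if (!all(needed %in% names(design))) {
    abort("design needs item_id, set_id, congruency and syl2_label columns",
          class = "cohortpe_bad_design")
  }
  labels_per_set <- tapply(design$syl2_label, design$set_id,
                           function(x) length(unique(x)))
  if (any(labels_per_set != 2)) {
    abort("every set must contain exactly two Syl2 labels",
          class = "cohortpe_bad_design")
  }
  same_set <- outer(design$set_id, design$set_id, "==")
  same_congr <- outer(design$congruency, design$congruency, "==")
  diff_syl2 <- outer(design$syl2_label, design$syl2_label, "!=")
  mask <- same_set & same_congr & diff_syl2
  diag(mask) <- FALSE
  dimnames(mask) <- list(design$item_id, design$item_id)
  mask
}

#' Fisher-transformed Spearman correlation between two RDMs
#'
#' Spearman's rho over the unmasked upper-triangle pairs of the two
#' matrices, clipped to +/-(1 - 1e-10) and arc-tangent transformed.
#'
#' @param rdm_a,rdm_b Square matrices over the same items.
#' @param mask Optional logical matrix, `TRUE` for pairs to exclude.
#' @return Fisher-z value.
#' @export
rdm_correlation <- function(rdm_a, rdm_b, mask = NULL) {
  stopifnot(all(dim(rdm_a) == dim(rdm_b)))
  keep <- upper.tri(rdm_a)
  if (!is.null(mask)) keep <- keep & !mask
  a <- rdm_a[keep]; b <- rdm_b[keep]
  if (length(a) < 3) {
    abort("need at least 3 unmasked pairs", class = "cohortpe_too_few_pairs")
  }
  rho <- cor(a, b, method = "spearman")
  rho <- max(min(rho, 1 - 1e-10), -(1 - 1e-10))
  atanh(rho)
}

#' Mean pattern distance per condition
#'
#' Averages the unmasked distances over item pairs in which both items
#' belong to the same condition.
#'
#' @param rdm Square distance matrix over the design's items (same order).
#' @param design Item design table.
#' @param mask Optional exclusion mask (`TRUE` = excluded).
#' @return Tibble with `condition`, `mean_distance`, `n_pairs`.
#' @export
condition_mean_distance <- function(rdm, design, mask = NULL) {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(rdm), ncol(rdm))
  pairs <- rdm_pairs(rdm, design, mask, within_condition = TRUE)
  out <- pairs |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_distance = mean(.data$distance),
                     n_pairs = dplyr::n(), .groups = "drop")
  present <- unique(as.character(design_conditions(design)))
  empty <- setdiff(present, out$condition)
  if (length(empty) > 0) {
    abort(paste0("condition(s) with no unmasked within-condition pair: ",
                 paste(empty, collapse = ", ")),
          class = "cohortpe_empty_condition")
  }
  out
}

#' Pair-level predictor from item values
#'
#' For analyses relating pattern distances to item predictability: the pair
#' value is the mean of the log-transformed item values,
#' `(log v_i + log v_j) / 2`, computed for unmasked pairs only.
#'
#' @param design Item design table (defines the pair order).
#' @param item_values Strictly positive numeric vector parallel to the
#'   design rows (e.g. conditional syllable probabilities).
#' @param mask Optional exclusion mask.
#' @return Tibble with `item_a`, `item_b`, `value`.
#' @export
predictor_pair_values <- function(design, item_values, mask = NULL) {
  stopifnot(length(item_values) == nrow(design))
  if (any(!is.finite(item_values)) || any(item_values <= 0)) {
    abort("item_values must be strictly positive and finite",
          class = "cohortpe_bad_predictor")
  }
  n <- nrow(design)
  if (is.null(mask)) mask <- matrix(FALSE, n, n)
  lv <- log(item_values)
  ut <- which(upper.tri(mask) & !mask, arr.ind = TRUE)
  tibble::tibble(item_a = design$item_id[ut[, 1]],
                 item_b = design$item_id[ut[, 2]],
                 value = (lv[ut[, 1]] + lv[ut[, 2]]) / 2)
}

#' Read / write an RDM as delimited text
#'
#' Square tab-separated matrix with an item-id header row and column.
#'
#' @param rdm Square matrix with item dimnames.
#' @param file Path.
#' @param metric Metric tag to attach on read.
#' @export
write_rdm <- function(rdm, file) {
  df <- data.frame(item_id = rownames(rdm), rdm, row.names = NULL,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(file, metric = "euclidean") {
  x <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  new_rdm(m, metric)
}
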