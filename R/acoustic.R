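#' Pairwise Euclidean distances between segment feature vectors
#'
#' Each segment is summarised by one fixed-length acoustic feature vector
#' (in the real stimuli, vectorised spectrotemporal-modulation energy
#' averaged over productions; here usually the synthetic stand-in from
#' [generate_segment_features()]). The boundary token has no acoustics of its
#' own: it is treated as perceptually unambiguous, with zero self-distance
#' and a distance to every phoneme equal to the largest phoneme-to-phoneme
#' distance observed.
#'
#' @param features Numeric matrix (segments x features) with segment labels
#'   as row names, or a data frame with a `segment` column followed by
#'   numeric feature columns.
#' @param boundary Optional boundary label to append as described above; use
#'   `NULL` if `features` already covers every segment you need.
#' @return Symmetric non-negative distance matrix with zero diagonal and
#'   segment labels as dimnames.
#' @export
segment_distance_matrix <- function(features, boundary = NULL) {
  features <- features_as_matrix(features)
  if (nrow(features) < 2) {
    abort("need at least two segments", class = "cohortpe_bad_features")
  }
  if (!all(is.finite(features))) {
    abort("features must be finite", class = "cohortpe_bad_features")
  }
  d <- as.matrix(dist(features, method = "euclidean"))
  if (!is.null(boundary)) {
    if (boundary %in% rownames(d)) {
      abort("boundary label already present in features",
            class = "cohortpe_bad_features")
    }
    dmax <- max(d)
    d <- rbind(cbind(d, rep(dmax, nrow(d))), rep(dmax, nrow(d) + 1))
    d[nrow(d), ncol(d)] <- 0
    rownames(d)[nrow(d)] <- boundary
    colnames(d)[ncol(d)] <- boundary
  }
  d
}

features_as_matrix <- function(features) {
  if (is.data.frame(features)) {
    if (!"segment" %in% names(features)) {
      abort("feature data frame needs a 'segment' column",
            class = "cohortpe_bad_features")
    }
    m <- as.matrix(features[, setdiff(names(features), "segment"), drop = FALSE])
    rownames(m) <- features$segment
    features <- m
  }
  if (!is.matrix(features) || !is.numeric(features)) {
    abort("features must be a numeric matrix or data frame",
          class = "cohortpe_bad_features")
  }
  if (is.null(rownames(features))) {
    abort("feature rows must be named by segment label",
          class = "cohortpe_bad_features")
  }
  features
}

#' Temperature-controlled softmax over acoustic distances
#'
#' Converts a segment distance matrix into row-wise segment probabilities:
#' `p(segment_j | heard i) = exp(-d_ij * T) / sum_j exp(-d_ij * T)`.
#' Rows index the heard segment; each row is a probability distribution over
#' the inventory. Large `T` approaches one-hot rows (minimal sensory
#' uncertainty); `T -> 0` approaches uniform rows (maximal uncertainty).
#'
#' @param distances Symmetric distance matrix from
#'   [segment_distance_matrix()].
#' @param temperature Positive scalar `T`.
#' @return Row-stochastic matrix of class `evidence_matrix` with attribute
#'   `temperature`.
#' @export
softmax_evidence <- function(distances, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0) {
    abort("temperature must be a single positive number",
          class = "cohortpe_bad_temperature")
  }
  z <- exp(-distances * temperature)
  p <- z / rowSums(z)
  structure(p, class = c("evidence_matrix", class(p)),
            temperature = temperature)
}

#' Read / write segment feature files
#'
#' Tab-separated text: one row per segment label followed by its feature
#' values (header `segment f1 f2 ...`).
#'
#' @param file Path.
#' @return `read_segment_features()` returns a numeric matrix with segment
#'   row names.
#' @export
read_segment_features <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  features_as_matrix(x)
}

#' @rdname read_segment_features
#' @param features Matrix or data frame of features.
#' @export
write_segment_features <- function(features, file) {
  m <- features_as_matrix(features)
  df <- data.frame(segment = rownames(m), m, row.names = NULL,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write an evidence (or distance) matrix as delimited text
#'
#' @param m Square matrix with segment labels as dimnames.
#' @param file Path.
#' @export
write_square_matrix <- function(m, file) {
  df <- data.frame(segment = rownames(m), m, row.names = NULL,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Product-rule sensory evidence for a word given heard segments
#'
#' Multiplies, over heard positions, the probability that the heard segment
#' would be produced when the word's segment at that position was intended:
#' `prod_k evidence[heard_k, word_k]`. Hearing more segments than the word
#' has falsifies it (likelihood 0).
#'
#' @param evidence An `evidence_matrix` (rows: heard segment, columns:
#'   intended segment).
#' @param segments The word's segment sequence (boundary tokens included).
#' @param heard_segments Heard segment sequence; empty gives likelihood 1.
#' @return Likelihood in `[0, 1]`.
#' @export
word_evidence <- function(evidence, segments, heard_segments) {
  segments <- parse_segments(segments)
  heard <- parse_segments(heard_segments)
  n <- length(heard)
  if (n == 0) return(1)
  if (length(segments) < n) return(0)
  prod(evidence[cbind(heard, segments[seq_len(n)])])
}
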