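# Archive search (Hamming / XOR), leave-one-out MV@k evaluation, macro
# metrics and dissimilarity summaries.

as_bits64 <- function(code) {
  if (is.character(code)) {
    b <- hex_to_bits(code)
    if (nrow(b) != 1L) stop("expected a single code")
    return(as.integer(b[1L, ]))
  }
  b <- as.integer(code)
  if (length(b) != 64L) stop("codes must have exactly 64 bits")
  if (!all(b %in% c(0L, 1L))) stop("codes must be 0/1")
  b
}

#' Hamming distance between two 64-bit monogram codes
#'
#' Count of differing bit positions; the archive search metric.
#'
#' @param code_a,code_b codes as 16-hex-digit strings, length-64 0/1
#'   vectors, or 8x8 binary matrices.
#' @return Integer in \[0, 64\].
#' @examples
#' hamming("0000000000000000", "ffffffffffffffff")
#' @export
hamming <- function(code_a, code_b) {
  a <- as_bits64(code_a)
  b <- as_bits64(code_b)
  sum(a != b)
}

#' Signed XOR map between two binary monograms
#'
#' Per-cell signed difference `m_b - m_a`: +1 marks a 0-to-1 change, -1 a
#' 1-to-0 change, 0 agreement. The count of nonzero cells equals the
#' Hamming distance, and the map shows \emph{which} monogram features
#' differ between two cases or subtypes.
#'
#' @param m_a,m_b 8x8 binary matrices.
#' @return 8x8 integer matrix with entries in \{-1, 0, 1\}.
#' @export
xor_map <- function(m_a, m_b) {
  stopifnot(identical(dim(m_a), c(8L, 8L)), identical(dim(m_b), c(8L, 8L)))
  out <- matrix(as.integer(m_b) - as.integer(m_a), 8L, 8L)
  out
}

#' Search a monogram archive by Hamming distance
#'
#' Ranks archive records by ascending Hamming distance to the query code;
#' ties break by ascending patient id (a fixed, reproducible rule). For
#' leave-one-out querying, `exclude_id` removes the query's own record
#' before ranking.
#'
#' @param archive a [monogram_archive()].
#' @param query_code query as hex string, 64-bit 0/1 vector or 8x8 matrix.
#' @param k number of neighbors (>= 1). If fewer records remain after
#'   exclusion, all are returned with a warning.
#' @param exclude_id optional patient id to drop before ranking.
#' @return data.frame with columns `patient_id`, `label`, `distance`,
#'   ordered by rank.
#' @export
search_archive <- function(archive, query_code, k = 10L, exclude_id = NULL) {
  stopifnot(inherits(archive, "monogram_archive"), k >= 1L)
  q <- as_bits64(query_code)
  keep <- rep(TRUE, archive_size(archive))
  if (!is.null(exclude_id)) keep <- archive$patient_id != exclude_id
  if (!any(keep)) stop("archive empty after exclusion")
  ids <- archive$patient_id[keep]
  labs <- archive$label[keep]
  d <- rowSums(archive$bits[keep, , drop = FALSE] !=
                 rep(q, each = sum(keep)))
  if (k > length(ids)) {
    warning("k = ", k, " exceeds archive size ", length(ids),
            " after exclusion; returning all records")
    k <- length(ids)
  }
  ord <- order(d, ids, method = "radix")[seq_len(k)]
  data.frame(patient_id = ids[ord], label = labs[ord],
             distance = as.integer(d[ord]))
}

#' Majority vote over ranked neighbor labels
#'
#' Predicts the most frequent label among the retrieved neighbors; on a
#' tie, the tied label whose first occurrence ranks best (earliest in the
#' list) wins.
#'
#' @param neighbor_labels character vector of labels ordered by rank.
#' @return The predicted label.
#' @examples
#' majority_vote(c("A", "B", "B"))
#' majority_vote(c("A", "B"))  # tie -> rank-1 label "A"
#' @export
majority_vote <- function(neighbor_labels) {
  labs <- as.character(neighbor_labels)
  if (length(labs) == 0L) stop("empty neighbor list")
  counts <- table(labs)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  first_pos <- vapply(top, function(l) which(labs == l)[1L], integer(1L))
  top[which.min(first_pos)]
}

#' Macro-averaged retrieval metrics
#'
#' Per-class precision, recall and F1 averaged with equal class weight
#' over the classes present in the ground truth, plus plain accuracy.
#' Macro averaging keeps rare subtypes from being swamped by common ones.
#' A class that is never predicted contributes precision 0; a class with
#' zero precision and recall contributes F1 0.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return Named numeric vector `c(macro_f1, macro_precision,
#'   macro_recall, accuracy)`, all in \[0, 1\].
#' @export
macro_metrics <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  classes <- sort(unique(y_true))
  prec <- rec <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) {
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    } else 0
  }
  c(macro_f1 = mean(f1), macro_precision = mean(prec),
    macro_recall = mean(rec), accuracy = mean(y_true == y_pred))
}

# Core leave-one-out evaluation on a precomputed distance matrix.
# Ties break by ascending patient id; the query's own record is excluded.
loo_eval_dist <- function(ids, labels, D, ks) {
  n <- length(ids)
  stopifnot(nrow(D) == n, ncol(D) == n, length(labels) == n)
  if (n < 2L) stop("need at least 2 records")
  if (length(unique(labels)) < 2L) {
    stop("leave-one-out evaluation needs at least 2 classes")
  }
  ks <- sort(unique(as.integer(ks)))
  preds <- matrix(NA_character_, n, length(ks),
                  dimnames = list(ids, paste0("k", ks)))
  for (q in seq_len(n)) {
    others <- setdiff(seq_len(n), q)
    ord <- others[order(D[q, others], ids[others], method = "radix")]
    for (j in seq_along(ks)) {
      kk <- min(ks[j], length(ord))
      preds[q, j] <- majority_vote(labels[ord[seq_len(kk)]])
    }
  }
  metrics <- t(vapply(seq_along(ks),
                      function(j) macro_metrics(labels, preds[, j]),
                      numeric(4L)))
  metrics <- data.frame(k = ks, metrics)
  structure(
    list(ks = ks, metrics = metrics, predictions = preds,
         labels = stats::setNames(labels, ids)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> leave-one-out, n = ",
      length(x$labels), "\n", sep = "")
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Leave-one-out MV@k evaluation of a monogram archive
#'
#' Every record queries the archive with itself removed; the label is
#' predicted by majority vote over the top-k neighbors (MV@k) and scored
#' against the record's true label with [macro_metrics()].
#'
#' @param archive a [monogram_archive()] with >= 2 records and >= 2
#'   classes.
#' @param ks vote sizes, default `c(1, 3, 5, 10)` (top-1 plus MV@3/5/10).
#' @param representation `"binary"` ranks by Hamming distance on the
#'   64-bit codes; `"real"` ranks by Euclidean distance on the 64
#'   real-valued (tanh) monogram entries, which the archive must retain.
#' @return An `"evaluation_report"`: per-k metrics data.frame plus the
#'   per-record predictions.
#' @export
leave_one_out_eval <- function(archive, ks = c(1L, 3L, 5L, 10L),
                               representation = c("binary", "real")) {
  stopifnot(inherits(archive, "monogram_archive"))
  representation <- match.arg(representation)
  if (representation == "binary") {
    B <- archive$bits
    D <- B %*% t(1L - B) + (1L - B) %*% t(B) # pairwise Hamming
  } else {
    if (is.null(archive$real)) {
      stop("archive does not retain real-valued monograms")
    }
    D <- as.matrix(stats::dist(archive$real))
  }
  loo_eval_dist(archive$patient_id, archive$label, D, ks)
}

#' Leave-one-out MV@k evaluation of raw feature vectors
#'
#' The same protocol as [leave_one_out_eval()] but ranking by Euclidean
#' distance on arbitrary per-patient feature rows -- used for the
#' unimodal image-only and sequence-only retrieval baselines.
#'
#' @param ids,labels per-row patient ids and true labels.
#' @param features n x d numeric matrix.
#' @param ks vote sizes.
#' @return An `"evaluation_report"`.
#' @export
loo_feature_eval <- function(ids, labels, features, ks = c(1L, 3L, 5L, 10L)) {
  D <- as.matrix(stats::dist(as.matrix(features)))
  loo_eval_dist(as.character(ids), as.character(labels), D, ks)
}

#' Mean normalized Hamming dissimilarity between label groups
#'
#' Samples `n_per_group` records per label (seeded; groups with fewer
#' members contribute all of them with a warning) and reports the mean
#' pairwise Hamming distance / 64 between groups. Diagonal entries use
#' distinct within-group pairs only. Low diagonal and high off-diagonal
#' values indicate subtype-coherent monograms.
#'
#' @param archive a [monogram_archive()].
#' @param n_per_group records sampled per label group.
#' @param seed sampling seed.
#' @return Symmetric g x g matrix in \[0, 1\] with label dimnames.
#' @export
dissimilarity_heatmap <- function(archive, n_per_group = 19L, seed = 1L) {
  stopifnot(inherits(archive, "monogram_archive"))
  groups <- sort(unique(archive$label))
  sel <- with_seed(seed, {
    lapply(groups, function(g) {
      idx <- which(archive$label == g)
      if (length(idx) < n_per_group) {
        warning("group '", g, "' has only ", length(idx),
                " member(s); using all")
        idx
      } else {
        idx[sample.int(length(idx), n_per_group)]
      }
    })
  })
  H <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (a in seq_along(groups)) {
    for (b in seq.int(a, length(groups))) {
      Ba <- archive$bits[sel[[a]], , drop = FALSE]
      Bb <- archive$bits[sel[[b]], , drop = FALSE]
      Dab <- Ba %*% t(1L - Bb) + (1L - Ba) %*% t(Bb)
      if (a == b) {
        m <- nrow(Dab)
        if (m < 2L) {
          H[a, b] <- 0
        } else {
          H[a, b] <- sum(Dab[upper.tri(Dab)]) / (m * (m - 1) / 2) / 64
        }
      } else {
        H[a, b] <- H[b, a] <- mean(Dab) / 64
      }
    }
  }
  H
}

#' Mean intra- vs inter-class code distances
#'
#' Summarizes how tightly an archive's codes cluster by diagnosis: the
#' mean normalized Hamming distance over all same-label pairs versus all
#' different-label pairs (and the same on real monogram Euclidean
#' distances when retained).
#'
#' @param archive a [monogram_archive()].
#' @return List with `hamming = c(intra, inter)` (normalized to \[0, 1\])
#'   and, if real monograms are present, `euclidean = c(intra, inter)`.
#' @export
class_distance_summary <- function(archive) {
  n <- archive_size(archive)
  same <- outer(archive$label, archive$label, "==")
  ut <- upper.tri(same)
  B <- archive$bits
  Dh <- (B %*% t(1L - B) + (1L - B) %*% t(B)) / 64
  out <- list(hamming = c(intra = mean(Dh[ut & same]),
                          inter = mean(Dh[ut & !same])))
  if (!is.null(archive$real)) {
    De <- as.matrix(stats::dist(archive$real))
    out$euclidean <- c(intra = mean(De[ut & same]),
                       inter = mean(De[ut & !same]))
  }
  out
}
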