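# Neighbor recommender method (NRM): a candidate pair (i, j) is scored by
# the similarity-weighted average of j's known combination partners over
# i's neighbors,
#
#   Y_ij = sum_{k != j} S_ik a_kj / sum_{k != j} S_ik ,
#
# symmetrized as score_ij = Y_ij + Y_ji and mapped to a probability as
# score/2 so a 0.5 decision threshold is well defined.
#
# By default k = i is excluded from both sums as well: with S_ii = 1 the
# literal sum would feed a_ij -- the very label being predicted -- into its
# own score, which invalidates cross-validation. exclude_self = FALSE
# restores the literal sum for replication.

mask_adjacency <- function(A, masked) {
  if (is.null(masked) || !NROW(masked)) return(A)
  masked <- as.data.frame(masked, stringsAsFactors = FALSE)
  ia <- match(as.character(masked[[1]]), rownames(A))
  ib <- match(as.character(masked[[2]]), rownames(A))
  if (anyNA(ia) || anyNA(ib)) {
    stop("masked pair mentions a drug outside the universe", call. = FALSE)
  }
  A[cbind(ia, ib)] <- 0L
  A[cbind(ib, ia)] <- 0L
  A
}

# All n x n Y values at once: Y[i, j] = sum_{k} S_ik A_kj over admissible k,
# divided by the matching similarity mass. a_jj = 0 removes k = j from the
# numerator automatically; the denominator drops S_ij; exclude_self
# additionally removes S_ii * a_ij = a_ij and S_ii = 1.
nrm_y_matrix <- function(S, A, exclude_self = TRUE) {
  S <- unclass(S)
  num <- S %*% A
  den <- matrix(rowSums(S), nrow(S), ncol(S)) - S
  if (exclude_self) {
    num <- num - A
    den <- den - 1
  }
  degenerate <- den <= 1e-12
  Y <- ifelse(degenerate, 0, num / ifelse(degenerate, 1, den))
  list(Y = Y, degenerate = degenerate)
}

#' Neighbor-recommender Y value for one ordered pair
#'
#' @param S A [similarity_matrix()].
#' @param A A [combination_network()] (or its 0/1 adjacency matrix).
#' @param i,j Drug ids, `i != j`.
#' @param exclude_self Drop `k = i` from both sums (default), so the queried
#'   pair's own label never contributes; `FALSE` is the literal textbook sum.
#' @return List with `y` (in [0,1]) and `degenerate` (`TRUE` when the
#'   similarity mass over admissible neighbors is zero, in which case
#'   `y = 0`).
#' @export
nrm_y <- function(S, A, i, j, exclude_self = TRUE) {
  if (inherits(A, "combination_network")) A <- A$adjacency
  ids <- rownames(S)
  if (!(i %in% ids)) stop("unknown drug: ", i, call. = FALSE)
  if (!(j %in% ids)) stop("unknown drug: ", j, call. = FALSE)
  if (identical(i, j)) stop("i == j: self-pairs are not scored", call. = FALSE)
  if (!identical(rownames(A), ids)) {
    stop("similarity matrix and network index different drug sets",
         call. = FALSE)
  }
  ii <- match(i, ids); jj <- match(j, ids)
  keep <- setdiff(seq_along(ids), if (exclude_self) c(ii, jj) else jj)
  w <- unclass(S)[ii, keep]
  den <- sum(w)
  if (den <= 1e-12) return(list(y = 0, degenerate = TRUE))
  list(y = sum(w * A[keep, jj]) / den, degenerate = FALSE)
}

#' Score candidate drug pairs with the neighbor recommender
#'
#' For every candidate pair, `score = Y_ij + Y_ji` and
#' `probability = score / 2`. Masked pairs (e.g. the test fold of a
#' cross-validation round) are removed from the adjacency before any Y is
#' computed, so a masked edge contributes to no pair's score -- including
#' pairs other than itself.
#'
#' @param S A [similarity_matrix()].
#' @param A A [combination_network()].
#' @param pairs Two-column data frame of candidate pairs, or `NULL` for all
#'   unordered pairs in the universe.
#' @param masked Optional two-column data frame of pairs whose edges must be
#'   hidden from the network.
#' @param exclude_self See [nrm_y()].
#' @return Data frame with columns `drug_a, drug_b, y_ij, y_ji, score,
#'   probability, degenerate`; symmetric in the pair order.
#' @export
score_pairs <- function(S, A, pairs = NULL, masked = NULL,
                        exclude_self = TRUE) {
  adj <- if (inherits(A, "combination_network")) A$adjacency else A
  ids <- rownames(S)
  if (!identical(rownames(adj), ids)) {
    stop("similarity matrix and network index different drug sets",
         call. = FALSE)
  }
  adj <- mask_adjacency(adj, masked)
  if (is.null(pairs)) {
    idx <- which(upper.tri(adj), arr.ind = TRUE)
    pairs <- data.frame(drug_a = ids[idx[, 1]], drug_b = ids[idx[, 2]],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("drug_a", "drug_b")
  }
  ia <- match(pairs$drug_a, ids); ib <- match(pairs$drug_b, ids)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- c(pairs$drug_a[is.na(ia)], pairs$drug_b[is.na(ib)])
    stop("unknown drug: ", bad[1], call. = FALSE)
  }
  if (any(ia == ib)) stop("i == j: self-pairs are not scored", call. = FALSE)
  ym <- nrm_y_matrix(S, adj, exclude_self = exclude_self)
  y_ij <- ym$Y[cbind(ia, ib)]
  y_ji <- ym$Y[cbind(ib, ia)]
  data.frame(drug_a = pairs$drug_a, drug_b = pairs$drug_b,
             y_ij = y_ij, y_ji = y_ji, score = y_ij + y_ji,
             probability = (y_ij + y_ji) / 2,
             degenerate = ym$degenerate[cbind(ia, ib)] |
               ym$degenerate[cbind(ib, ia)],
             stringsAsFactors = FALSE)
}

#' Threshold NRM probabilities into predicted labels
#'
#' A pair is called positive when its probability is greater than *or equal
#' to* the threshold (the conventional `>= 0.5` rule).
#'
#' @param scores Output of [score_pairs()].
#' @param threshold Decision threshold in (0, 1), applied to `probability`.
#' @return `scores` with an added integer `label` column.
#' @export
classify <- function(scores, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must be in (0,1)", call. = FALSE)
  }
  scores$label <- as.integer(scores$probability >= threshold)
  scores
}
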