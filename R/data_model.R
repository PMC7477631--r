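# Core domain types: the drug universe, set-valued feature profiles,
# per-channel similarity matrices, the known-combination network, labeled
# pair datasets and the run configuration shared by the CLI and the
# evaluation harness.

#' Construct the ordered drug universe
#'
#' The drug set fixes the row/column order of every similarity matrix and
#' adjacency matrix downstream. Identifiers must be unique and at least two
#' drugs are required (a single drug admits no pairs).
#'
#' @param ids Character vector of drug identifiers.
#' @return A `drug_set` object (a character vector with a class attribute).
#' @export
#' @examples
#' drug_set(c("paclitaxel", "doxorubicin", "monobenzone"))
drug_set <- function(ids) {
  ids <- as.character(ids)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("drug identifiers must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate drug identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (length(ids) < 2) stop("a drug set needs at least 2 drugs", call. = FALSE)
  structure(ids, class = "drug_set")
}

#' @export
print.drug_set <- function(x, ...) {
  cat("<drug_set> ", length(x), " drugs: ",
      paste(utils::head(unclass(x), 5), collapse = ", "),
      if (length(x) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Set-valued feature profile for one channel
#'
#' One channel (targets, indications, expression-signature genes, modules,
#' ...) maps every drug to a finite token set. Empty sets are kept: a drug
#' with no recorded annotation is data, not an error. Tokens are compared by
#' exact string equality after whitespace trimming.
#'
#' @param members Named list: drug id -> character vector of tokens.
#' @param channel Channel name (e.g. `"target"`).
#' @param drugs Optional [drug_set()]; every profiled drug must belong to it.
#' @return A `feature_profile` object.
#' @export
feature_profile <- function(members, channel, drugs = NULL) {
  if (!is.list(members) || is.null(names(members)) ||
      any(!nzchar(names(members)))) {
    stop("'members' must be a named list of token vectors", call. = FALSE)
  }
  if (anyDuplicated(names(members))) {
    nm <- names(members)
    merged <- lapply(unique(nm), function(d) {
      unlist(members[nm == d], use.names = FALSE)
    })
    names(merged) <- unique(nm)
    members <- merged
    warning("duplicate drug entries merged by set union", call. = FALSE)
  }
  members <- lapply(members, function(tok) {
    tok <- trimws(as.character(tok))
    sort(unique(tok[nzchar(tok)]))
  })
  if (!is.null(drugs)) {
    unknown <- setdiff(names(members), drugs)
    if (length(unknown)) {
      stop("profiled drugs not in the drug set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(channel = as.character(channel)[1], members = members),
            class = "feature_profile")
}

#' @export
print.feature_profile <- function(x, ...) {
  sizes <- lengths(x$members)
  cat("<feature_profile> channel '", x$channel, "': ", length(x$members),
      " drugs, token set sizes ", min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Per-channel drug-by-drug similarity matrix
#'
#' Validates (and lightly repairs) a square similarity matrix: entries in
#' [0, 1], symmetric up to `tol` (then symmetrized by averaging), unit
#' diagonal (forced, with a warning, if the input diagonal differs).
#'
#' @param values Square numeric matrix with drug ids as dimnames.
#' @param channel Channel name.
#' @param tol Maximum tolerated asymmetry `|v_ij - v_ji|`; larger
#'   discrepancies are treated as data errors.
#' @return A `similarity_matrix`: the validated matrix with `channel`
#'   attribute.
#' @export
similarity_matrix <- function(values, channel = "similarity", tol = 1e-6) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("similarity matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("similarity matrix needs drug ids as row and column names",
         call. = FALSE)
  }
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column drug ids differ", call. = FALSE)
  }
  if (anyNA(values)) stop("similarity matrix contains NA", call. = FALSE)
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol),
         call. = FALSE)
  }
  values <- (values + t(values)) / 2
  bad <- which(values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("similarity out of [0,1] at (%s, %s): %g",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  if (any(abs(diag(values) - 1) > tol)) {
    warning("diagonal forced to 1", call. = FALSE)
  }
  diag(values) <- 1
  structure(values, channel = as.character(channel)[1],
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> channel '", attr(x, "channel"), "', ",
      nrow(x), " x ", ncol(x), ", off-diagonal range [",
      sprintf("%.3f", min(x[upper.tri(x)])), ", ",
      sprintf("%.3f", max(x[upper.tri(x)])), "]\n", sep = "")
  invisible(x)
}

canonical_pairs <- function(pairs) {
  # lexicographically smaller id first; unordered uniqueness
  a <- as.character(pairs[[1]])
  b <- as.character(pairs[[2]])
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  out <- data.frame(drug_a = lo, drug_b = hi, stringsAsFactors = FALSE)
  out[!duplicated(paste(out$drug_a, out$drug_b, sep = "\r")), , drop = FALSE]
}

#' Known drug-combination network
#'
#' Symmetric binary adjacency over the drug universe: entry 1 iff the
#' unordered pair is a known (positive) combination. Self-pairs are
#' rejected; reversed duplicates collapse to one edge.
#'
#' @param pairs Two-column data frame / matrix of positive drug pairs.
#' @param drugs A [drug_set()], or `NULL` to infer the sorted union of
#'   mentioned ids.
#' @return A `combination_network` with fields `drugs`, `adjacency`
#'   (0/1 matrix) and `positive_pairs` (canonical two-column data frame).
#' @export
combination_network <- function(pairs, drugs = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2) stop("need two columns of drug ids", call. = FALSE)
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  self <- which(a == b)
  if (length(self)) {
    stop("self-pair not allowed (row ", self[1], ": '", a[self[1]], "')",
         call. = FALSE)
  }
  if (is.null(drugs)) {
    drugs <- drug_set(sort(unique(c(a, b))))
  } else {
    if (!inherits(drugs, "drug_set")) drugs <- drug_set(drugs)
    unknown <- setdiff(unique(c(a, b)), drugs)
    if (length(unknown)) {
      stop("pair list mentions drugs outside the drug set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  pp <- canonical_pairs(data.frame(a, b, stringsAsFactors = FALSE))
  n <- length(drugs)
  adj <- matrix(0L, n, n, dimnames = list(as.character(drugs),
                                          as.character(drugs)))
  if (nrow(pp)) {
    ia <- match(pp$drug_a, drugs); ib <- match(pp$drug_b, drugs)
    adj[cbind(ia, ib)] <- 1L
    adj[cbind(ib, ia)] <- 1L
  }
  structure(list(drugs = drugs, adjacency = adj, positive_pairs = pp),
            class = "combination_network")
}

#' @export
print.combination_network <- function(x, ...) {
  cat("<combination_network> ", length(x$drugs), " drugs, ",
      nrow(x$positive_pairs), " known combinations\n", sep = "")
  invisible(x)
}

#' Enumerate the negative pool (all unordered non-edges)
#'
#' @param network A [combination_network()].
#' @return Two-column data frame of all unordered drug pairs that are not
#'   known combinations (the candidate negatives for downsampling).
#' @export
non_edges <- function(network) {
  adj <- network$adjacency
  ut <- upper.tri(adj)
  idx <- which(ut & adj == 0L, arr.ind = TRUE)
  data.frame(drug_a = rownames(adj)[idx[, 1]],
             drug_b = colnames(adj)[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Labeled drug-pair dataset with per-channel similarity features
#'
#' @param pairs Data frame with columns `drug_a`, `drug_b`, `label` (0/1).
#' @param features Numeric matrix, one column per channel (declared order),
#'   values in [0, 1] or `NA` for flagged-missing.
#' @param channels Character vector of channel names, matching `features`
#'   columns.
#' @return A `pair_dataset` (data frame with feature columns and attributes
#'   `channels`).
#' @export
pair_dataset <- function(pairs, features, channels) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_a", "drug_b", "label") %in% names(pairs)))
  if (any(pairs$drug_a == pairs$drug_b)) {
    stop("self-pairs not allowed in a pair dataset", call. = FALSE)
  }
  key <- paste(pmin(pairs$drug_a, pairs$drug_b),
               pmax(pairs$drug_a, pairs$drug_b), sep = "\r")
  if (anyDuplicated(key)) stop("duplicate unordered pairs", call. = FALSE)
  if (!all(pairs$label %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  features <- as.matrix(features)
  if (ncol(features) != length(channels)) {
    stop("feature columns must match declared channels", call. = FALSE)
  }
  if (nrow(features) != nrow(pairs)) {
    stop("one feature vector per pair required", call. = FALSE)
  }
  rng <- range(features, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("similarity features must lie in [0,1] (or be NA)", call. = FALSE)
  }
  colnames(features) <- channels
  out <- cbind(pairs[c("drug_a", "drug_b", "label")],
               as.data.frame(features))
  structure(out, channels = as.character(channels),
            class = c("pair_dataset", "data.frame"))
}

#' @export
`[.pair_dataset` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "channels") <- attr(x, "channels")
    class(out) <- c("pair_dataset", "data.frame")
  }
  out
}

#' Feature matrix of a pair dataset
#' @param dataset A [pair_dataset()].
#' @return Numeric matrix of per-channel similarities, in declared order.
#' @export
pair_features <- function(dataset) {
  as.matrix(dataset[, attr(dataset, "channels"), drop = FALSE])
}

#' Run configuration
#'
#' Captures the experiment settings shared by the evaluation harness and the
#' CLI: which channels enter the model, the number of cross-validation folds
#' (3, 5 and 10 in typical use, any k >= 2 accepted), the negative:positive
#' downsampling ratio, the number of sampling repeats, the decision
#' threshold on predicted probabilities, the master seed, and the policy for
#' similarities missing from a channel.
#'
#' @param channels Character vector of channel names to use.
#' @param k Number of cross-validation folds (>= 2).
#' @param ratio Negative:positive downsampling ratio (>= 1).
#' @param repeats Number of repeated sampling rounds; each repeat redraws
#'   negatives and folds from a seed derived from `seed`.
#' @param threshold Decision threshold in (0, 1) applied to probabilities.
#' @param seed Master random seed (recorded in all outputs).
#' @param missing_policy `"zero"` (missing similarity scored 0 and flagged)
#'   or `"complete"` (drop pairs lacking any channel).
#' @return A `run_config` list.
#' @export
run_config <- function(channels = NULL, k = 5L, ratio = 1L, repeats = 20L,
                       threshold = 0.5, seed = 1L,
                       missing_policy = c("zero", "complete")) {
  k <- as.integer(k); ratio <- as.integer(ratio); repeats <- as.integer(repeats)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (ratio < 1) stop("ratio must be >= 1", call. = FALSE)
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must be in (0,1)", call. = FALSE)
  }
  structure(list(channels = channels, k = k, ratio = ratio, repeats = repeats,
                 threshold = threshold, seed = as.integer(seed),
                 missing_policy = match.arg(missing_policy)),
            class = "run_config")
}

# Deterministic 32-bit FNV-1a hash of the configuration; embedded in output
# file headers together with the seed so any result file names the settings
# that produced it.
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Seeds for repeat r, fold f, ... are derived from the master seed with a
# fixed affine map, kept strictly below 2^31 so they remain valid R integers.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (i in idx) h <- (h * 69069 + as.double(i) * 1000003 + 1) %% 2147483647
  as.integer(h)
}
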