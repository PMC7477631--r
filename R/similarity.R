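# Tanimoto (Jaccard) similarity between set-valued drug annotations:
# |A n B| / (|A| + |B| - |A n B|), the field's standard overlap coefficient
# for binary fingerprints and annotation sets.

#' Tanimoto coefficient between two token sets
#'
#' Computes `|A n B| / (|A| + |B| - |A n B|)`. When both sets are empty the
#' coefficient is 0/0: the result is flagged undefined rather than raising
#' an error, and carries no similarity value.
#'
#' @param set_a,set_b Character vectors (treated as sets after whitespace
#'   trimming and deduplication).
#' @return A list with `value` (in [0,1], `NA` when undefined) and `defined`
#'   (FALSE only for the empty-empty case).
#' @export
#' @examples
#' tanimoto(c("t1", "t2"), c("t2", "t3"))  # 1/3
tanimoto <- function(set_a, set_b) {
  a <- unique(trimws(as.character(set_a)))
  b <- unique(trimws(as.character(set_b)))
  a <- a[nzchar(a)]; b <- b[nzchar(b)]
  na <- length(a); nb <- length(b)
  if (na + nb == 0L) {
    return(list(value = NA_real_, defined = FALSE))
  }
  nab <- length(intersect(a, b))
  list(value = nab / (na + nb - nab), defined = TRUE)
}

#' Pairwise Tanimoto similarity matrix for one feature channel
#'
#' Builds the full drug-by-drug similarity matrix of a channel from its
#' set-valued profile. Internally uses a drugs-by-tokens incidence matrix so
#' that all pairwise intersections are one cross-product; results agree with
#' element-wise [tanimoto()] calls exactly.
#'
#' Pairs where both drugs have empty token sets are undefined; the policy
#' decides whether they become similarity 0 (recorded in the `undefined`
#' attribute) or an error. The diagonal is 1 by convention, including for
#' annotation-free drugs.
#'
#' @param profile A [feature_profile()].
#' @param drugs A [drug_set()]; drugs absent from the profile get empty sets.
#' @param undefined_policy `"zero"` or `"error"`.
#' @return A [similarity_matrix()] with attribute `undefined` (logical
#'   matrix marking resolved 0/0 pairs) when any pair was undefined.
#' @export
profile_to_matrix <- function(profile, drugs,
                              undefined_policy = c("zero", "error")) {
  undefined_policy <- match.arg(undefined_policy)
  if (!inherits(drugs, "drug_set")) drugs <- drug_set(drugs)
  ids <- as.character(drugs)
  members <- lapply(ids, function(d) {
    m <- profile$members[[d]]
    if (is.null(m)) character(0) else m
  })
  names(members) <- ids
  sizes <- lengths(members)
  tokens <- unique(unlist(members, use.names = FALSE))
  n <- length(ids)
  if (length(tokens)) {
    inc <- matrix(0, n, length(tokens), dimnames = list(ids, tokens))
    for (i in seq_len(n)) inc[i, members[[i]]] <- 1
    nab <- inc %*% t(inc)
  } else {
    nab <- matrix(0, n, n)
  }
  denom <- outer(sizes, sizes, `+`) - nab
  undef <- denom == 0
  vals <- ifelse(undef, 0, nab / ifelse(undef, 1, denom))
  if (any(undef[upper.tri(undef)])) {
    if (undefined_policy == "error") {
      ij <- which(undef & upper.tri(undef), arr.ind = TRUE)[1, ]
      stop("Tanimoto undefined (both sets empty) for pair (",
           ids[ij[1]], ", ", ids[ij[2]], ")", call. = FALSE)
    }
  }
  dimnames(vals) <- list(ids, ids)
  diag(vals) <- 1
  out <- similarity_matrix(vals, channel = profile$channel)
  if (any(undef[upper.tri(undef)])) attr(out, "undefined") <- undef
  out
}
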