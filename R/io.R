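# Readers and writers for the external plain-text formats: 2-column pair
# lists, GMT-like or long-format profiles, square similarity matrices, and
# the evaluation report table. All writers emit a '# seed=.. config=..'
# comment header when a run_config is supplied; all readers skip '#' lines.

header_aliases <- c("drug1", "drug2", "drug_1", "drug_2", "drug_a", "drug_b",
                    "druga", "drugb", "drug_i", "drug_j", "source", "target",
                    "id1", "id2")

#' Read a two-column list of known drug combinations
#'
#' One positive pair per line, tab- or whitespace-delimited; an optional
#' header row (recognised by conventional column names such as
#' `drug1 drug2`) is skipped. Duplicate and reversed-duplicate rows collapse
#' to a single edge; self-pair rows are rejected with their line number.
#'
#' @param path File path.
#' @param drugs A [drug_set()] fixing the universe, or `"infer"` to use the
#'   sorted union of all mentioned ids.
#' @return A [combination_network()].
#' @export
read_pair_list <- function(path, drugs = "infer") {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty pair list: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[\t ,;]+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("line ", lineno[which(nf < 2)[1]], ": expected two drug ids",
         call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1)
  b <- vapply(fields, `[[`, "", 2)
  if (tolower(a[1]) %in% header_aliases && tolower(b[1]) %in% header_aliases &&
      tolower(a[1]) != tolower(b[1])) {
    a <- a[-1]; b <- b[-1]; lineno <- lineno[-1]
  }
  self <- which(a == b)
  if (length(self)) {
    stop("self-pair at line ", lineno[self[1]], ": '", a[self[1]], "'",
         call. = FALSE)
  }
  if (identical(drugs, "infer")) drugs <- NULL
  combination_network(data.frame(a, b, stringsAsFactors = FALSE), drugs)
}

#' Write a combination network as a two-column pair list
#' @param network A [combination_network()].
#' @param path Output path.
#' @param config Optional [run_config()] recorded in the comment header.
#' @export
write_pair_list <- function(network, path, config = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  write_provenance(con, config)
  writeLines("drug1\tdrug2", con)
  if (nrow(network$positive_pairs)) {
    writeLines(paste(network$positive_pairs$drug_a,
                     network$positive_pairs$drug_b, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a set-valued feature profile
#'
#' Two layouts are auto-detected: *long* (two columns, `drug token`, one
#' token per row) and *GMT-like* (one row per drug: the drug id followed by
#' all of its tokens). A file in which every row has exactly two fields is
#' read as long format; the detected layout is reported via `message()`.
#' A GMT-like row holding only a drug id yields an (intentional) empty set.
#'
#' @param path File path.
#' @param channel Channel name to attach.
#' @return A [feature_profile()].
#' @export
read_profile <- function(path, channel) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty profile file: ", path, call. = FALSE)
  fields <- strsplit(sub("\\s+$", "", lines), "\t| +")
  nf <- lengths(fields)
  long <- all(nf == 2)
  message("read_profile: '", path, "' parsed as ",
          if (long) "long (drug, token)" else "GMT-like", " format")
  if (long) {
    drug <- vapply(fields, `[[`, "", 1)
    token <- vapply(fields, `[[`, "", 2)
    if (anyDuplicated(paste(drug, token, sep = "\r"))) {
      warning("duplicate (drug, token) rows collapsed (set semantics)",
              call. = FALSE)
    }
    members <- split(token, drug)
  } else {
    drug <- vapply(fields, `[[`, "", 1)
    members <- lapply(fields, function(f) f[-1])
    names(members) <- drug
  }
  if (anyDuplicated(names(members))) {
    warning("duplicate drug rows merged by set union", call. = FALSE)
    nm <- names(members)
    members <- lapply(split(seq_along(members), nm),
                      function(i) unlist(members[i], use.names = FALSE))
  }
  feature_profile(members, channel)
}

#' Write a feature profile (GMT-like layout)
#' @param profile A [feature_profile()].
#' @param path Output path.
#' @param config Optional [run_config()] recorded in the comment header.
#' @export
write_profile <- function(profile, path, config = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  write_provenance(con, config)
  rows <- vapply(names(profile$members), function(d) {
    paste(c(d, profile$members[[d]]), collapse = "\t")
  }, "")
  writeLines(rows, con)
  invisible(path)
}

#' Read a square similarity matrix
#'
#' Expects a delimited square matrix whose first row and first column carry
#' the drug ids. `scale = "percent"` divides entries by 100 (e.g. 2D
#' structural similarity scores reported on a 0-100 scale). The matrix is
#' symmetrized by averaging; asymmetry beyond 1e-6, out-of-range entries and
#' non-square input are errors; a non-unit diagonal is forced to 1 with a
#' warning.
#'
#' @param path File path.
#' @param scale `"unit"` (entries already in [0,1]) or `"percent"`.
#' @param channel Channel name to attach (defaults to the file name).
#' @return A [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path, scale = c("unit", "percent"),
                                   channel = NULL) {
  scale <- match.arg(scale)
  m <- as.matrix(read.table(path, header = TRUE, row.names = 1, sep = "\t",
                            check.names = FALSE, comment.char = "#"))
  if (nrow(m) != ncol(m)) {
    stop("similarity matrix must be square: ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  }
  if (scale == "percent") m <- m / 100
  if (is.null(channel)) {
    channel <- sub("\\.[^.]*$", "", basename(path))
  }
  similarity_matrix(m, channel = channel)
}

#' Write a similarity matrix as TSV (full double precision)
#' @param matrix A [similarity_matrix()].
#' @param path Output path.
#' @param config Optional [run_config()] recorded in the comment header.
#' @export
write_similarity_matrix <- function(matrix, path, config = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  write_provenance(con, config)
  writeLines(paste(c("drug", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 1, function(r) {
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = "\t")
  })
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

write_provenance <- function(con, config = NULL) {
  if (!is.null(config)) {
    writeLines(sprintf("# seed=%d config=%s", config$seed,
                       config_hash(config)), con)
  }
}

#' Write an evaluation report
#'
#' Emits a delimited table with one row per (model, k, metric): the mean and
#' standard deviation over repeats, plus a display cell in the conventional
#' `mean +/- sd` layout (e.g. `0.795 ± 0.006`).
#'
#' @param report An `evaluation_report` (see [run_experiment()]), or any
#'   data frame with columns `model, k, metric, mean, sd`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  summ <- if (inherits(report, "evaluation_report")) report$summary else
    as.data.frame(report)
  config <- if (inherits(report, "evaluation_report")) report$config else NULL
  con <- file(path, "w"); on.exit(close(con))
  write_provenance(con, config)
  writeLines("model\tk\tmetric\tmean\tsd\tcell", con)
  if (nrow(summ)) {
    cell <- sprintf("%.3f ± %.3f", summ$mean, summ$sd)
    writeLines(paste(summ$model, summ$k, summ$metric,
                     format(summ$mean, digits = 17, trim = TRUE),
                     format(summ$sd, digits = 17, trim = TRUE),
                     cell, sep = "\t"), con)
  }
  invisible(path)
}

#' Read back a written evaluation report summary
#' @param path Path written by [write_report()].
#' @return Data frame with columns `model, k, metric, mean, sd, cell`.
#' @export
read_report <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}
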