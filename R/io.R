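#' Read a long-format clonal tracking dataset
#'
#' Canonical format: delimited text with a header containing (at least) the
#' four columns `clone_id, time, lineage, count`, one row per detected
#' (clone, time, lineage) cell count. Absence of a row means the entry is
#' unobserved — a false negative or an unmeasured lineage — never an
#' observed zero. Consistently, rows with `count == 0` are dropped to
#' missing by default (with an informative message); set the dialect flag
#' `zeros_are_observations = TRUE` to keep them as measurements of zero.
#'
#' @param path delimited text file.
#' @param dialect list of reader options: `sep` (default `","`), `col_map`
#'   (named character vector mapping canonical names to file column names),
#'   `zeros_are_observations` (default `FALSE`).
#' @return Validated data.frame with columns `clone_id`, `time`, `lineage`,
#'   `count`, ordered by clone, time, lineage.
#' @export
read_dataset <- function(path, dialect = list()) {
  dialect <- utils::modifyList(
    list(sep = ",", col_map = NULL, zeros_are_observations = FALSE), dialect)
  raw <- read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  cols <- c(clone_id = "clone_id", time = "time", lineage = "lineage",
            count = "count")
  if (!is.null(dialect$col_map)) cols[names(dialect$col_map)] <- dialect$col_map
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols)) {
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ds <- data.frame(clone_id = as.character(raw[[cols["clone_id"]]]),
                   time = as.numeric(raw[[cols["time"]]]),
                   lineage = as.character(raw[[cols["lineage"]]]),
                   count = as.numeric(raw[[cols["count"]]]),
                   stringsAsFactors = FALSE)
  bad <- which(!is.finite(ds$time) | !is.finite(ds$count) | ds$count < 0)
  if (length(bad)) {
    stop("malformed rows (non-finite time/count or negative count): rows ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!dialect$zeros_are_observations) {
    nz <- ds$count == 0
    if (any(nz)) {
      message(sum(nz), " zero-count row(s) dropped to missing ",
              "(zeros_are_observations = FALSE)")
      ds <- ds[!nz, , drop = FALSE]
    }
  }
  validate_dataset(ds)
}

#' Write a clonal tracking dataset
#'
#' Inverse of [read_dataset()] for the canonical CSV layout.
#'
#' @param dataset validated long data.frame.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path) {
  dataset <- validate_dataset(dataset)
  write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a long clonal tracking data.frame
#'
#' Checks the four canonical columns, finiteness and nonnegativity of
#' counts, uniqueness of (clone, time, lineage) triples and — when a node
#' set is supplied — that every lineage belongs to the network. Rows come
#' back sorted by clone, time, lineage.
#'
#' @param dataset data.frame with columns `clone_id`, `time`, `lineage`,
#'   `count`.
#' @param nodes optional character vector of admissible lineage names.
#' @return The validated, sorted data.frame.
#' @export
validate_dataset <- function(dataset, nodes = NULL) {
  req <- c("clone_id", "time", "lineage", "count")
  miss <- setdiff(req, names(dataset))
  if (length(miss)) stop("dataset is missing column(s): ",
                         paste(miss, collapse = ", "))
  dataset <- dataset[req]
  dataset$clone_id <- as.character(dataset$clone_id)
  dataset$lineage <- as.character(dataset$lineage)
  if (any(!is.finite(dataset$count)) || any(dataset$count < 0)) {
    stop("counts must be finite and >= 0")
  }
  key <- paste(dataset$clone_id, dataset$time, dataset$lineage, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicated (clone, time, lineage) triple: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }
  if (!is.null(nodes)) {
    bad <- setdiff(unique(dataset$lineage), nodes)
    if (length(bad)) stop("lineage name(s) not in the network: ",
                          paste(bad, collapse = ", "))
  }
  dataset <- dataset[order(dataset$clone_id, dataset$time, dataset$lineage), ,
                     drop = FALSE]
  rownames(dataset) <- NULL
  dataset
}

#' Keep the most recaptured clones
#'
#' Recapture score of a clone = number of (time, lineage) cells with a
#' present record. Keeps the `n` highest-scoring clones; ties at the cutoff
#' are broken in favour of the lexicographically smaller `clone_id`. The
#' operation is idempotent and independent of input row order.
#'
#' @param dataset validated long data.frame.
#' @param n number of clones to keep (>= 1).
#' @return The filtered dataset.
#' @export
top_recaptured_clones <- function(dataset, n) {
  stopifnot(n >= 1)
  dataset <- validate_dataset(dataset)
  score <- table(dataset$clone_id)
  ids <- names(score)
  ord <- order(-as.integer(score), ids)
  keep <- ids[ord][seq_len(min(n, length(ids)))]
  validate_dataset(dataset[dataset$clone_id %in% keep, , drop = FALSE])
}

#' Rescale counts by per-sample factors
#'
#' Generic normalisation hook: multiplies counts by positive factors keyed
#' by `time` or by `(time, lineage)`. Typical use is library-size
#' normalisation across sampling time points; study-specific normalisations
#' should be expressed through this interface by the caller. The applied
#' factor table is recorded in `attr(, "scaling")`.
#'
#' @param dataset validated long data.frame.
#' @param factors data.frame with columns `time`, optionally `lineage`, and
#'   `factor` (> 0).
#' @return The rescaled dataset with the factor table attached.
#' @export
rescale_by_sample <- function(dataset, factors) {
  dataset <- validate_dataset(dataset)
  stopifnot(is.data.frame(factors), all(c("time", "factor") %in% names(factors)),
            all(factors$factor > 0))
  by_lineage <- "lineage" %in% names(factors)
  key_f <- if (by_lineage) paste(factors$time, factors$lineage) else
    as.character(factors$time)
  if (anyDuplicated(key_f)) stop("duplicated keys in factor table")
  key_d <- if (by_lineage) paste(dataset$time, dataset$lineage) else
    as.character(dataset$time)
  idx <- match(key_d, key_f)
  if (anyNA(idx)) {
    stop("no factor for sample(s): ",
         paste(utils::head(unique(key_d[is.na(idx)]), 5), collapse = ", "))
  }
  dataset$count <- dataset$count * factors$factor[idx]
  attr(dataset, "scaling") <- factors
  dataset
}
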