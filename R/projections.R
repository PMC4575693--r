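#' Construct a directed projection table
#'
#' Holds one record per *examined* ordered area pair; ordered pairs of
#' distinct areas without a record are treated as status `unknown`
#' throughout the package. The unknown/absent distinction is first-class:
#' `absent` means a tracing experiment looked and found no projection,
#' `unknown` means nobody looked.
#'
#' @param records data.frame with columns `source`, `target`, `status`
#'   (one of `r toString(STATUS_LEVELS)`, or `present` for binarized
#'   tables). Rows with status `unknown` are dropped (absence of a record
#'   encodes unknown).
#' @param areas character vector of all area names in the universe
#'   (sources and targets must be drawn from it)
#' @return object of class `projection_table` (a data.frame with an
#'   `areas` attribute)
#' @export
projection_table <- function(records, areas) {
  stopifnot(is.data.frame(records),
            all(c("source", "target", "status") %in% names(records)))
  areas <- as.character(areas)
  if (anyDuplicated(areas))
    stop("duplicate area names in universe")
  records <- records[records$status != "unknown", , drop = FALSE]
  records$source <- as.character(records$source)
  records$target <- as.character(records$target)
  records$status <- as.character(records$status)
  ok <- records$status %in% c(STATUS_LEVELS, "present")
  if (any(!ok))
    stop("invalid status token(s): ", toString(unique(records$status[!ok])))
  missing <- setdiff(c(records$source, records$target), areas)
  if (length(missing))
    stop("record references area(s) outside the universe: ", toString(missing))
  if (any(records$source == records$target))
    stop("self-projections are not part of the data model")
  key <- paste(records$source, records$target, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate records for ordered pair(s): ",
         toString(sub("\r", "->", unique(key[duplicated(key)]))))
  rownames(records) <- NULL
  structure(records[c("source", "target", "status")],
            areas = areas, class = c("projection_table", "data.frame"))
}

#' @export
print.projection_table <- function(x, ...) {
  cat("projection_table:", nrow(x), "known records over",
      length(attr(x, "areas")), "areas\n")
  print(status_counts(x))
  invisible(x)
}

#' Count projection records by status
#'
#' @param table a [projection_table()]
#' @return named integer vector including the implicit `unknown` count
#'   (ordered pairs of distinct areas without a record)
#' @export
status_counts <- function(table) {
  n_areas <- length(attr(table, "areas"))
  lev <- if (any(table$status == "present")) BINARY_LEVELS else STATUS_LEVELS
  counts <- table(factor(table$status, levels = lev))
  c(unknown = n_areas * (n_areas - 1L) - nrow(table), counts)
}

#' Collapse ordinal projection strengths to binary existence
#'
#' Maps sparse/intermediate/dense to a single `present` code; `absent`
#' and the implicit `unknown` are preserved.
#'
#' @param table a [projection_table()]
#' @return binarized [projection_table()]
#' @export
binarize <- function(table) {
  table$status[table$status %in% c("sparse", "intermediate", "dense")] <- "present"
  table
}

#' Read a connectivity matrix from TSV
#'
#' The file is a square matrix with a header row and a first column of
#' area names; rows are projection sources, columns targets. Cells must be
#' `NA` (unknown), or the ordinal codes 0 (absent), 1 (sparse),
#' 2 (intermediate), 3 (dense). The diagonal is ignored.
#'
#' @param path TSV file
#' @param areas optional character vector of valid area names; when given,
#'   the file's names are validated against it
#' @return a [projection_table()]
#' @export
load_connectivity <- function(path, areas = NULL) {
  m <- read.delim(path, row.names = 1, check.names = FALSE,
                  colClasses = "character", na.strings = "NA")
  if (!identical(rownames(m), colnames(m)))
    stop("connectivity matrix must have identical row and column names")
  if (anyDuplicated(rownames(m)))
    stop("duplicate area name in connectivity matrix: ",
         toString(rownames(m)[duplicated(rownames(m))]))
  if (!is.null(areas)) {
    extra <- setdiff(rownames(m), areas)
    if (length(extra))
      stop("connectivity matrix names not in the area list: ", toString(extra))
  }
  m <- as.matrix(m)
  bad <- which(!is.na(m) & !m %in% c("0", "1", "2", "3"), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unparseable cell '%s' at row %s, column %s",
                 m[bad[1, , drop = FALSE]],
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  diag(m) <- NA
  idx <- which(!is.na(m), arr.ind = TRUE)
  records <- data.frame(
    source = rownames(m)[idx[, 1]],
    target = colnames(m)[idx[, 2]],
    status = STATUS_LEVELS[as.integer(m[idx]) + 1L]
  )
  projection_table(records, rownames(m))
}

#' Write a projection table as a TSV connectivity matrix
#'
#' Inverse of [load_connectivity()]: unknown pairs and the diagonal are
#' written as `NA`, known statuses as their ordinal codes.
#'
#' @param table a [projection_table()] (unbinarized)
#' @param path output TSV
#' @export
write_connectivity <- function(table, path) {
  areas <- attr(table, "areas")
  m <- matrix(NA_integer_, length(areas), length(areas),
              dimnames = list(areas, areas))
  if (any(table$status == "present"))
    stop("cannot write a binarized table as an ordinal matrix")
  m[cbind(table$source, table$target)] <- STATUS_CODES[table$status]
  write_matrix_tsv(m, path)
}

#' Read a symmetric 0/1 adjacency matrix from TSV
#' @param path TSV file (header row + first column of area names)
#' @return logical matrix
#' @export
read_adjacency <- function(path) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  mode(m) <- "logical"
  m
}

# shared TSV matrix writer (first column = area names, header row)
write_matrix_tsv <- function(m, path) {
  df <- data.frame(name = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach projection statuses to a pair-variables table
#'
#' Left-joins the known statuses onto every ordered pair; pairs without a
#' record get status `unknown`. With `binary = TRUE` the three ordinal
#' strengths collapse to `present`.
#'
#' @param pairs output of [pair_variables()]
#' @param table a [projection_table()]
#' @param binary collapse strengths to present? (default TRUE)
#' @return `pairs` with a `status` column
#' @export
join_status <- function(pairs, table, binary = TRUE) {
  if (binary) table <- binarize(table)
  key <- paste(pairs$source, pairs$target, sep = "\r")
  tkey <- paste(table$source, table$target, sep = "\r")
  status <- table$status[match(key, tkey)]
  status[is.na(status)] <- "unknown"
  pairs$status <- status
  pairs
}
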