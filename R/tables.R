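#' Construct a validated abundance table
#'
#' A `count_table` is the package's universal currency: a numeric matrix of
#' samples (rows) by taxa (columns) holding either raw sequencing read counts
#' or relative abundances (proportions). All downstream operations
#' ([relative_abundance()], [scaled_abundance()], the simulator) consume and
#' produce this class.
#'
#' @param values numeric matrix, samples in rows, taxa in columns, with
#'   dimnames giving sample and taxon identifiers.
#' @param mode `"counts"` or `"proportions"`. In proportions mode every
#'   sample row must sum to 1 within `1e-9`.
#' @return a `count_table` object (a classed numeric matrix with an
#'   `abund_mode` attribute).
#' @details Invariants enforced: no negative or non-finite values, no
#'   duplicate sample or taxon ids, at least one sample and two taxa, and the
#'   proportions row-sum condition. Violations raise a validation error
#'   naming the offending cell or identifier.
#' @examples
#' m <- matrix(c(30, 70, 50, 50), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB")))
#' count_table(m, mode = "counts")
#' @export
count_table <- function(values, mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  values <- bare_matrix(as.matrix(values))
  x <- structure(values, abund_mode = mode,
                 class = c("count_table", "matrix", "array"))
  validate_count_table(x)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d taxa, mode = %s\n",
              nrow(x), ncol(x), abund_mode(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE]),
        ...)
  if (ncol(x) > 8L) cat(sprintf("... %d more taxa\n", ncol(x) - 8L))
  invisible(x)
}

#' Abundance mode of a table
#'
#' @param x a `count_table` or `relabund_table`.
#' @return `"counts"` or `"proportions"`.
#' @export
abund_mode <- function(x) attr(x, "abund_mode", exact = TRUE) %||% "counts"

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain double matrix with only dim/dimnames (drops class, stray attrs)
bare_matrix <- function(m) {
  matrix(as.numeric(m), nrow = nrow(m), ncol = ncol(m),
         dimnames = dimnames(m))
}

validate_count_table <- function(x) {
  v <- unclass(x)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    sa_validation_error("count table must have sample and taxon identifiers")
  if (nrow(v) < 1L) sa_validation_error("count table needs at least one sample")
  if (ncol(v) < 2L) sa_validation_error("count table needs at least two taxa")
  if (anyDuplicated(rownames(v)))
    sa_validation_error(sprintf(
      "duplicate sample ids: %s",
      paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
  if (anyDuplicated(colnames(v)))
    sa_validation_error(sprintf(
      "duplicate taxon ids: %s",
      paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
  bad <- which(!is.finite(v) | v < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    sa_validation_error(sprintf(
      "negative or non-finite value %g at sample '%s', taxon '%s'",
      v[bad[1L, , drop = FALSE]],
      rownames(v)[bad[1L, 1L]], colnames(v)[bad[1L, 2L]]))
  if (identical(abund_mode(x), "proportions")) {
    rs <- rowSums(v)
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off) > 0L)
      sa_validation_error(sprintf(
        "proportions row for sample '%s' sums to %.12g, not 1",
        rownames(v)[off[1L]], rs[off[1L]]))
  }
  x
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an abundance table from a delimited file
#'
#' Reads a TSV/CSV table with a header row of taxon ids and a leading
#' sample-id column (or the transpose), validates it, and auto-detects
#' whether it holds counts or proportions.
#'
#' @param path file path; delimiter inferred from the extension (`.csv` is
#'   comma, anything else tab) unless `delim` is given.
#' @param mode_hint `"auto"` (default), `"counts"` or `"proportions"`.
#'   In auto mode the table is declared proportions when every row sum lies
#'   in `[1 - 1e-6, 1 + 1e-6]`; a proportions table inside that band is
#'   renormalized to row sums of exactly 1.
#' @param orientation `"auto"`, `"samples_rows"` or `"taxa_rows"`. Auto
#'   assumes samples in rows unless only the transposed reading has row sums
#'   of 1 (a proportions table stored taxa-in-rows).
#' @param delim optional field separator overriding the extension rule.
#' @return a validated [count_table()].
#' @seealso [write_table()]
#' @export
read_count_table <- function(path,
                             mode_hint = c("auto", "counts", "proportions"),
                             orientation = c("auto", "samples_rows",
                                             "taxa_rows"),
                             delim = NULL) {
  mode_hint <- match.arg(mode_hint)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) sa_io_error(sprintf("file not found: %s", path))
  sep <- infer_delim(path, delim)

  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L)
    sa_parse_error(sprintf("'%s' has fewer than two non-empty lines", path))
  if (length(unique(nf)) != 1L) {
    bad_line <- which(nf != nf[1L])[1L]
    sa_parse_error(sprintf(
      "ragged table in '%s': line %d has %d fields, expected %d",
      path, bad_line, nf[bad_line], nf[1L]))
  }

  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  # data.frame subsetting deduplicates column names; keep the raw header
  # so duplicate taxon ids are caught by validation
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  names(body) <- header[-1L]
  for (j in seq_along(body)) {
    col <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(col) && !anyNA(suppressWarnings(body[[j]]))) {
      i <- which(is.na(col))[1L]
      sa_parse_error(sprintf(
        "non-numeric value '%s' at row '%s', column '%s' in '%s'",
        as.character(body[[j]][i]), ids[i], names(body)[j], path))
    }
    body[[j]] <- col
  }
  m <- as.matrix(body)
  rownames(m) <- ids

  near_one <- function(v) all(abs(rowSums(v) - 1) <= 1e-6)
  if (orientation == "taxa_rows") {
    m <- t(m)
  } else if (orientation == "auto" && !near_one(m) && near_one(t(m))) {
    m <- t(m)
  }

  mode <- if (mode_hint == "auto") {
    if (near_one(m)) "proportions" else "counts"
  } else mode_hint
  if (mode == "proportions") {
    if (!near_one(m))
      sa_validation_error(sprintf(
        "table '%s' forced to proportions but row sums deviate from 1 by more than 1e-6",
        path))
    m <- m / rowSums(m)
  }
  count_table(m, mode = mode)
}

format_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[x == round(x) & abs(x) < 1e15] <- sprintf("%.0f", x[x == round(x) &
                                                            abs(x) < 1e15])
  out
}

#' Write a table to a delimited file
#'
#' Writes abundance matrices (and the package's tabular results) as TSV or
#' CSV with full floating-point fidelity: reading a written table back
#' reproduces its values to better than 1e-12 relative.
#'
#' @param x a `count_table`, `relabund_table`, `scaled_abundance` matrix, or
#'   plain data frame.
#' @param path destination file; parent directory must exist and be
#'   writable.
#' @param delim optional separator overriding the extension rule.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, delim = NULL) {
  UseMethod("write_table")
}

write_delim_df <- function(df, path, sep) {
  ok <- tryCatch({
    con <- file(path, open = "wt")
    on.exit(close(con))
    utils::write.table(df, con, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    sa_io_error(sprintf("cannot write '%s': %s", path,
                        conditionMessage(ok)))
  invisible(path)
}

#' @export
write_table.default <- function(x, path, delim = NULL) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], format_num)
  write_delim_df(df, path, infer_delim(path, delim))
}

write_matrix_table <- function(m, path, delim) {
  df <- data.frame(sample_id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- apply(unclass(m), 2L, format_num)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(m))
  colnames(vals) <- colnames(m)
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  write_delim_df(df, path, infer_delim(path, delim))
}

#' @export
write_table.count_table <- function(x, path, delim = NULL) {
  write_matrix_table(x, path, delim)
}

#' @export
write_table.relabund_table <- function(x, path, delim = NULL) {
  write_matrix_table(x, path, delim)
}

#' @export
write_table.scaled_abundance <- function(x, path, delim = NULL) {
  write_matrix_table(x, path, delim)
}
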