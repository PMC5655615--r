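## CSV and MDL SD (V2000) input/output for descriptor/activity tables.
## SD records are kept as verbatim lines so that writing an unmodified
## table reproduces the input file byte for byte (CRLF dialects included);
## only value lines of fields that actually changed are rewritten.

#' Read a descriptor/activity table from CSV
#'
#' All columns other than the id column and the named activity columns
#' become descriptors.  The dialect is fixed: comma separator,
#' double-quote quoting, mandatory header, `.` decimal point.
#'
#' @param path path to a CSV file with a header row.
#' @param idColumn name of the identifier column, or `NULL` to
#'   synthesize ids `rec1`, `rec2`, ...
#' @param activityColumns character vector naming the activity columns.
#' @return a [DescriptorTable-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,d1,d2,act", "a,1,2,0.5", "b,3,4,0.7"), f)
#' readDescriptorCsv(f, idColumn = "id", activityColumns = "act")
#' @export
readDescriptorCsv <- function(path, idColumn = NULL,
                              activityColumns = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        stringsAsFactors = FALSE)
  nm <- names(df)
  if (anyDuplicated(nm))
    stop("format error: duplicate column header(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (col in c(idColumn, activityColumns))
    if (!col %in% nm)
      stop("configuration error: column '", col, "' not present in ", path)
  if (!is.null(idColumn)) {
    ids <- df[[idColumn]]
  } else {
    ids <- paste0("rec", seq_len(nrow(df)))
  }
  valueCols <- setdiff(nm, idColumn)
  parsed <- lapply(valueCols, function(col) .parseNumericColumn(df[[col]], col))
  mat <- do.call(cbind, c(parsed, list(deparse.level = 0)))
  if (is.null(mat)) mat <- matrix(numeric(0), nrow(df), 0)
  colnames(mat) <- valueCols
  descCols <- setdiff(valueCols, activityColumns)
  DescriptorTable(ids,
                  mat[, descCols, drop = FALSE],
                  mat[, activityColumns, drop = FALSE],
                  metadata = list(idColumn = idColumn %||% "id",
                                  source = "csv"))
}

.parseNumericColumn <- function(raw, col) {
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(x) & !(trimws(raw) %in% c("NA")))
  if (length(bad))
    stop("parse error: non-numeric value '", raw[bad[1]], "' in column '",
         col, "', row ", bad[1])
  x
}

#' Write a DescriptorTable to CSV
#'
#' Emits the id column, then descriptors, then activities, with
#' shortest-round-trip float formatting (a value written and re-read
#' compares equal bit for bit), comma separation and LF line endings.
#'
#' @param table a [DescriptorTable-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDescriptorCsv <- function(table, path) {
  stopifnot(is(table, "DescriptorTable"))
  idName <- table@metadata$idColumn %||% "id"
  mat <- cbind(table@descriptors, table@activities)
  header <- paste(c(idName, colnames(mat)), collapse = ",")
  body <- vapply(seq_len(nCompounds(table)), function(i) {
    paste(c(table@recordIds[i], formatShortest(mat[i, ])), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Shortest decimal representation that round-trips a double
#'
#' @param x numeric vector.
#' @return character vector; `as.numeric(formatShortest(x))` equals `x`
#'   exactly (NA/NaN/Inf pass through as their standard spellings).
#' @export
formatShortest <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    if (v == trunc(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

## ---- SD files -------------------------------------------------------

## Internal record representation ("SdfRecord"): a list with
##   lines  - character vector of the record's physical lines, each
##            carrying its own terminator (so CRLF files survive)
##   title  - molblock title line (line 1, terminator stripped)
##   items  - named list of data items: list(name, valueRange (line
##            indices), value (string), numeric (double or NA))
## Serializing an unmodified record is paste0(lines, collapse = "").

.splitKeepEOL <- function(txt) {
  ## physical lines including their terminators
  regmatches(txt, gregexpr("[^\n]*\n|[^\n]+$", txt))[[1]]
}

.lineContent <- function(line) sub("\r?\n?$", "", line)

.parseSdfRecord <- function(lines, index) {
  contents <- vapply(lines, .lineContent, character(1), USE.NAMES = FALSE)
  mend <- which(contents == "M  END")
  if (length(mend) == 0)
    stop("SDF record ", index, ": no 'M  END' line (V2000 required)")
  mend <- mend[1]
  items <- list()
  i <- mend + 1
  nl <- length(lines)
  while (i <= nl) {
    if (startsWith(contents[i], ">")) {
      name <- regmatches(contents[i], regexpr("<[^>]*>", contents[i]))
      name <- substr(name, 2, nchar(name) - 1)
      j <- i + 1
      while (j <= nl && nzchar(contents[j]) && contents[j] != "$$$$") j <- j + 1
      valueLines <- if (j > i + 1) contents[(i + 1):(j - 1)] else character(0)
      value <- paste(valueLines, collapse = "\n")
      num <- if (length(valueLines) == 1)
        suppressWarnings(as.numeric(trimws(value))) else NA_real_
      items[[name]] <- list(name = name, valueRange = c(i + 1, j - 1),
                            value = value, numeric = num)
      i <- j
    } else {
      i <- i + 1
    }
  }
  list(lines = lines, title = contents[1], items = items)
}

#' Read a descriptor/activity table from an MDL SD file
#'
#' Each record's single-line numeric data items become columns of the
#' table (the named `activityFields` as activities, the rest as
#' descriptors); non-numeric items are carried through verbatim and
#' written back untouched.  Molblocks are opaque: no chemistry is
#' perceived, and an unmodified table written with
#' [writeDescriptorSdf()] is byte-identical to the input.
#'
#' @param path path to a V2000 SD file (records terminated by `$$$$`).
#' @param activityFields data-item names to treat as activities.
#' @param skipMissing if `FALSE` (default) a record lacking a requested
#'   activity field is a hard error naming the record; if `TRUE` such
#'   records are dropped with a warning.
#' @return a [DescriptorTable-class] carrying verbatim SD records.
#' @export
readDescriptorSdf <- function(path, activityFields = character(),
                              skipMissing = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readChar(path, file.info(path)$size, useBytes = TRUE)
  lines <- .splitKeepEOL(txt)
  contents <- vapply(lines, .lineContent, character(1), USE.NAMES = FALSE)
  ends <- which(contents == "$$$$")
  if (length(ends) == 0) stop("no '$$$$' record terminator found in ", path)
  starts <- c(1, head(ends, -1) + 1)
  records <- mapply(function(s, e) .parseSdfRecord(lines[s:e], which(ends == e)),
                    starts, ends, SIMPLIFY = FALSE)
  keep <- rep(TRUE, length(records))
  for (k in seq_along(records)) {
    missing <- setdiff(activityFields, names(records[[k]]$items))
    if (length(missing)) {
      if (skipMissing) {
        warning("dropping record ", k, " (missing field(s): ",
                paste(missing, collapse = ", "), ")")
        keep[k] <- FALSE
      } else {
        stop("record ", k, " is missing requested activity field(s): ",
             paste(missing, collapse = ", "))
      }
    }
  }
  records <- records[keep]
  if (length(records) == 0) stop("no usable records in ", path)
  ## a field becomes a numeric column iff present and numeric in every record
  allFields <- unique(unlist(lapply(records, function(r) names(r$items))))
  numericField <- vapply(allFields, function(f) {
    all(vapply(records, function(r)
      f %in% names(r$items) && !is.na(r$items[[f]]$numeric), logical(1)))
  }, logical(1))
  cols <- allFields[numericField]
  missingAct <- setdiff(activityFields, cols)
  if (length(missingAct))
    stop("activity field(s) not numeric in every record: ",
         paste(missingAct, collapse = ", "))
  mat <- vapply(cols, function(f)
    vapply(records, function(r) r$items[[f]]$numeric, numeric(1)),
    numeric(length(records)))
  mat <- matrix(mat, nrow = length(records),
                dimnames = list(NULL, cols))
  ids <- vapply(seq_along(records), function(k) {
    t <- trimws(records[[k]]$title)
    if (nzchar(t)) t else paste0("rec", k)
  }, character(1))
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_dup")
  descCols <- setdiff(cols, activityFields)
  DescriptorTable(ids,
                  mat[, descCols, drop = FALSE],
                  mat[, activityFields, drop = FALSE],
                  sdfRecords = records,
                  metadata = list(source = "sdf"))
}

#' Write a DescriptorTable back to an MDL SD file
#'
#' Requires a table that originated from [readDescriptorSdf()] (SDF
#' output requires SDF input).  Molblocks and non-numeric data items are
#' emitted verbatim; a data item's value line is rewritten only when the
#' table now holds a different number for it, so files differ from the
#' source only inside randomized fields.
#'
#' @param table a [DescriptorTable-class] with SD payloads.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDescriptorSdf <- function(table, path) {
  stopifnot(is(table, "DescriptorTable"))
  if (!hasPayloads(table))
    stop("SDF output requires SDF input: table has no molecule payloads")
  mat <- cbind(table@descriptors, table@activities)
  cols <- colnames(mat)
  out <- vapply(seq_along(table@sdfRecords), function(k) {
    rec <- table@sdfRecords[[k]]
    lines <- rec$lines
    for (f in cols) {
      item <- rec$items[[f]]
      if (is.null(item)) next
      cur <- mat[k, f]
      if (isTRUE(item$numeric == cur)) next   # untouched: keep bytes
      rng <- item$valueRange
      eol <- if (rng[1] <= length(lines) && grepl("\r\n$", lines[rng[1]]))
        "\r\n" else "\n"
      newLine <- paste0(formatShortest(cur), eol)
      lines <- append(lines[-(rng[1]:rng[2])], newLine, after = rng[1] - 1)
      ## ranges of later items shift if the value spanned several lines
      shift <- 1 - (rng[2] - rng[1] + 1)
      if (shift != 0) {
        for (g in names(rec$items)) {
          r2 <- rec$items[[g]]$valueRange
          if (r2[1] > rng[2]) rec$items[[g]]$valueRange <- r2 + shift
        }
      }
      rec$items[[f]]$numeric <- cur
      rec$lines <- lines
    }
    paste0(rec$lines, collapse = "")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(out, collapse = ""), con, eos = NULL, useBytes = TRUE)
  invisible(path)
}
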