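#' Construct a source table
#'
#' A source table is the package's "named matrix" data model: a titled,
#' tab-delimited table with one (list) or two (network) identifier columns
#' plus zero or more attribute columns. Attributes are typed as either
#' \code{"value"} (numeric, filterable with comparison operators) or
#' \code{"label"} (tags, filterable by set membership). Blank attribute
#' cells are permitted and are stored as \code{NA} (value) or \code{""}
#' (label).
#'
#' @param name Source name; must be unique within one integration run.
#' @param kind \code{"list"} (one key column) or \code{"network"} (two).
#' @param key_columns Character vector of key column names (length 1 or 2).
#' @param schema Data frame with columns \code{name}, \code{kind}
#'   (\code{"value"} or \code{"label"}) describing the attribute columns,
#'   in order. May have zero rows.
#' @param records Data frame holding the rows: key columns as character,
#'   value attributes as numeric, label attributes as character.
#' @return An object of class \code{source_table}.
#' @export
source_table <- function(name, kind = c("list", "network"), key_columns,
                         schema = empty_schema(), records) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_keys <- if (kind == "list") 1L else 2L
  if (length(key_columns) != n_keys) {
    stop(sprintf("a %s source needs exactly %d key column(s), got %d",
                 kind, n_keys, length(key_columns)), call. = FALSE)
  }
  stopifnot(is.data.frame(schema), all(c("name", "kind") %in% names(schema)))
  if (anyDuplicated(c(key_columns, schema$name))) {
    stop("column names must be unique within a source table", call. = FALSE)
  }
  if (nrow(schema) && !all(schema$kind %in% c("value", "label"))) {
    stop("attribute kind must be 'value' or 'label'", call. = FALSE)
  }
  expected <- c(key_columns, schema$name)
  if (!identical(names(records), expected)) {
    stop("record columns must be exactly the key columns followed by the declared attributes",
         call. = FALSE)
  }
  for (k in key_columns) {
    records[[k]] <- trimws(records[[k]])
    if (any(!nzchar(records[[k]]))) stop("blank key identifiers are not allowed", call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, key_columns = key_columns,
         schema = schema, records = records),
    class = "source_table"
  )
}

empty_schema <- function() {
  data.frame(name = character(), kind = character(), stringsAsFactors = FALSE)
}

#' @export
print.source_table <- function(x, ...) {
  cat(sprintf("<source_table> %s (%s): %d record(s), %d attribute(s)\n",
              x$name, x$kind, nrow(x$records), nrow(x$schema)))
  if (nrow(x$schema)) {
    cat(paste0("  ", x$schema$name, " <", x$schema$kind, ">", collapse = "\n"), "\n")
  }
  invisible(x)
}

# Numeric cells accept plain decimal and scientific notation only; no
# locale-dependent separators. NA/NaN/Inf text does not qualify.
is_numeric_text <- function(x) {
  grepl("^[+-]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$", x)
}

#' Infer attribute schema from data
#'
#' A non-key column is typed \code{"value"} iff it has at least one
#' non-blank cell and every non-blank cell parses as a finite decimal
#' number; otherwise (mixed content or entirely blank) it is
#' \code{"label"}. Inference is total and independent of row order.
#'
#' @param header Character vector of all column names.
#' @param rows Character matrix or data frame of cells (columns follow
#'   \code{header}).
#' @param key_columns Names of the key column(s) to skip.
#' @return A schema data frame (\code{name}, \code{kind}) for the non-key
#'   columns, in header order.
#' @export
infer_schema <- function(header, rows, key_columns) {
  attrs <- setdiff(header, key_columns)
  if (!length(attrs)) return(empty_schema())
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(rows) <- header
  kind <- vapply(attrs, function(a) {
    cells <- trimws(as.character(rows[[a]]))
    nb <- cells[nzchar(cells)]
    if (length(nb) && all(is_numeric_text(nb)) &&
        all(is.finite(suppressWarnings(as.numeric(nb))))) "value" else "label"
  }, character(1))
  data.frame(name = attrs, kind = unname(kind), stringsAsFactors = FALSE)
}

#' Read a tab-delimited source file
#'
#' Reads one list or network source in the node-pair / element-list format:
#' UTF-8, tab-separated, mandatory header row naming all columns, blank
#' attribute fields allowed. Column roles and attribute kinds come from the
#' declaration when given, otherwise the first one (list) or two (network)
#' columns are keys and attribute kinds are inferred with
#' \code{\link{infer_schema}}.
#'
#' @param path Path to the file.
#' @param name Source name; defaults to the file's base name without
#'   extension.
#' @param kind \code{"list"} or \code{"network"}.
#' @param key_columns Optional key column names (default: leading columns).
#' @param attr_kinds Optional named character vector mapping attribute name
#'   to \code{"value"} or \code{"label"}; unnamed attributes are inferred.
#' @return A \code{\link{source_table}}.
#' @export
read_source_table <- function(path, name = NULL, kind = c("list", "network"),
                              key_columns = NULL, attr_kinds = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (!length(lines)) stop(sprintf("%s: empty file (header row required)", path), call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (any(!nzchar(header))) stop(sprintf("%s: blank column name in header", path), call. = FALSE)
  ncol <- length(header)
  n_keys <- if (kind == "list") 1L else 2L
  if (ncol < n_keys) {
    stop(sprintf("%s: %s source needs at least %d column(s)", path, kind, n_keys),
         call. = FALSE)
  }
  if (is.null(key_columns)) key_columns <- header[seq_len(n_keys)]
  if (!all(key_columns %in% header)) {
    stop(sprintf("%s: declared key column(s) %s not in header", path,
                 paste(setdiff(key_columns, header), collapse = ", ")), call. = FALSE)
  }

  body <- lines[-1L]
  # strsplit drops trailing empty fields, so field counts come from tab counts
  nf <- lengths(gregexpr("\t", body, fixed = TRUE))
  nf[!grepl("\t", body, fixed = TRUE)] <- 0L
  nf <- nf + 1L
  bad <- which(nf != ncol)
  if (length(bad)) {
    stop(sprintf("%s: row %d has %d field(s), header has %d",
                 path, bad[1] + 1L, nf[bad[1]], ncol), call. = FALSE)
  }
  cells <- matrix("", nrow = length(body), ncol = ncol,
                  dimnames = list(NULL, header))
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      length(p) <- ncol           # pad dropped trailing blanks
      p[is.na(p)] <- ""
      cells[i, ] <- p
    }
  }

  for (k in key_columns) {
    keys <- trimws(cells[, k])
    blank <- which(!nzchar(keys))
    if (length(blank)) {
      stop(sprintf("%s: blank key in column '%s' at row %d", path, k, blank[1] + 1L),
           call. = FALSE)
    }
    cells[, k] <- keys
  }

  attr_names <- setdiff(header, key_columns)
  inferred <- infer_schema(header, cells, key_columns)
  kinds <- stats::setNames(inferred$kind, inferred$name)
  if (!is.null(attr_kinds)) {
    unknown <- setdiff(names(attr_kinds), attr_names)
    if (length(unknown)) {
      stop(sprintf("%s: declared attribute(s) %s not in header", path,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    kinds[names(attr_kinds)] <- attr_kinds
  }

  records <- data.frame(matrix(nrow = nrow(cells), ncol = 0), stringsAsFactors = FALSE)
  for (k in key_columns) records[[k]] <- cells[, k]
  for (a in attr_names) {
    col <- trimws(cells[, a])
    if (kinds[[a]] == "value") {
      nb <- nzchar(col)
      ok <- is_numeric_text(col[nb])
      if (!all(ok)) {
        row <- which(nb)[which(!ok)[1]]
        stop(sprintf("%s: value column '%s' has non-numeric cell '%s' at row %d",
                     path, a, col[nb][which(!ok)[1]], row + 1L), call. = FALSE)
      }
      v <- rep(NA_real_, length(col))
      v[nb] <- as.numeric(col[nb])
      records[[a]] <- v
    } else {
      records[[a]] <- col
    }
  }

  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  schema <- data.frame(name = attr_names,
                       kind = unname(kinds[attr_names]),
                       stringsAsFactors = FALSE)
  source_table(name, kind, key_columns, schema, records)
}

#' Write a source table back to TSV
#'
#' Inverse of \code{\link{read_source_table}}: writing and re-reading a
#' table (with the same declaration) yields an identical source table,
#' blanks included. Numeric cells are written with full double precision.
#'
#' @param table A \code{source_table}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_source_table <- function(table, path) {
  stopifnot(inherits(table, "source_table"))
  cols <- lapply(names(table$records), function(cn) {
    col <- table$records[[cn]]
    if (is.numeric(col)) {
      out <- ifelse(is.na(col), "", sprintf("%.17g", col))
    } else {
      out <- as.character(col)
    }
    out
  })
  lines <- c(paste(names(table$records), collapse = "\t"),
             if (nrow(table$records)) do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Validate a source table
#'
#' Non-mutating checks: duplicate key rows within the source (for networks,
#' duplicates under the unordered node pair), self-loop edges, and value
#' cells violating the declared schema. All findings are warnings — reads
#' already reject structural errors — so duplicates collapse later at
#' integration and self-loops are retained.
#'
#' @param table A \code{source_table}.
#' @return A data frame of diagnostics with columns \code{type},
#'   \code{row}, \code{message}; zero rows for a clean table.
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "source_table"))
  diags <- list()
  add <- function(type, row, message) {
    diags[[length(diags) + 1L]] <<- data.frame(
      type = type, row = row, message = message, stringsAsFactors = FALSE)
  }
  rec <- table$records
  if (nrow(rec)) {
    if (table$kind == "list") {
      key <- rec[[table$key_columns[1]]]
    } else {
      a <- rec[[table$key_columns[1]]]
      b <- rec[[table$key_columns[2]]]
      key <- edge_label(pmin_chr(a, b), pmax_chr(a, b))
      for (i in which(a == b)) add("self_loop", i, sprintf("self-loop edge (%s, %s)", a[i], b[i]))
    }
    for (i in which(duplicated(key))) {
      add("duplicate_key", i, sprintf("duplicate key row '%s'", key[i]))
    }
    for (k in table$key_columns) {
      for (i in which(!nzchar(trimws(rec[[k]])))) add("blank_key", i, sprintf("blank key in '%s'", k))
    }
    for (j in seq_len(nrow(table$schema))) {
      a <- table$schema$name[j]
      if (table$schema$kind[j] == "value" && !is.numeric(rec[[a]])) {
        add("type_violation", NA_integer_,
            sprintf("value attribute '%s' is not stored numerically", a))
      }
    }
  }
  if (!length(diags)) {
    return(data.frame(type = character(), row = integer(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, diags)
}
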