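#' Filter criteria
#'
#' A criterion is a single attribute predicate. Value (numeric) attributes
#' take one of the comparison operators \code{<, <=, >, >=, ==}; label
#' attributes take a non-empty tag set with OR semantics (the cell matches
#' if its tag is any member). A blank cell fails every criterion.
#'
#' @param attribute Attribute name the criterion targets.
#' @param operator Comparison operator (comparison form only).
#' @param value Numeric operand (comparison form only).
#' @param tags Character vector of tags (tag-set form only).
#' @return An object of class \code{criterion}.
#' @export
criterion <- function(attribute, operator = NULL, value = NULL, tags = NULL) {
  stopifnot(is.character(attribute), length(attribute) == 1L, nzchar(attribute))
  if (!is.null(tags)) {
    if (!is.null(operator) || !is.null(value)) {
      stop("a criterion is either a comparison or a tag set, not both", call. = FALSE)
    }
    tags <- trimws(as.character(tags))
    tags <- tags[nzchar(tags)]
    if (!length(tags)) stop("tag set must be non-empty", call. = FALSE)
    out <- list(attribute = attribute, form = "tag_set", tags = unique(tags))
  } else {
    if (!operator %in% c("<", "<=", ">", ">=", "==")) {
      stop(sprintf("unknown operator '%s'", operator), call. = FALSE)
    }
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
      stop("comparison operand must be a single finite number", call. = FALSE)
    }
    out <- list(attribute = attribute, form = "comparison",
                operator = operator, value = as.numeric(value))
  }
  structure(out, class = "criterion")
}

#' @export
format.criterion <- function(x, ...) {
  if (x$form == "comparison") {
    paste(x$attribute, x$operator, format(x$value, digits = 15))
  } else {
    paste(x$attribute, "==", paste(x$tags, collapse = " | "))
  }
}

#' @export
print.criterion <- function(x, ...) {
  cat("<criterion>", format(x), "\n")
  invisible(x)
}

#' Parse a criterion expression
#'
#' Grammar: \code{attr OP number} for value attributes
#' (OP one of \code{< <= > >= ==}) or \code{attr == tag1 | tag2 | ...} for
#' label attributes. The attribute must be declared in \code{schema} and
#' the expression form must match its kind.
#'
#' @param text Criterion expression, e.g. \code{"corr > 0.9"} or
#'   \code{"age == P6 | P10"}.
#' @param schema Schema data frame (\code{name}, \code{kind}) of the
#'   source's attributes.
#' @return A \code{\link{criterion}}.
#' @export
parse_criterion <- function(text, schema) {
  m <- regmatches(text, regexec("^\\s*(\\S+)\\s*(<=|>=|==|<|>)\\s*(.*?)\\s*$", text))[[1]]
  if (!length(m)) stop(sprintf("cannot parse criterion '%s'", text), call. = FALSE)
  attr <- m[2]; op <- m[3]; rhs <- m[4]
  i <- match(attr, schema$name)
  if (is.na(i)) stop(sprintf("unknown attribute '%s' in criterion '%s'", attr, text),
                     call. = FALSE)
  kind <- schema$kind[i]
  if (kind == "value") {
    if (!nzchar(rhs) || !is_numeric_text(rhs)) {
      stop(sprintf("non-numeric operand '%s' for value attribute '%s'", rhs, attr),
           call. = FALSE)
    }
    criterion(attr, operator = op, value = as.numeric(rhs))
  } else {
    if (op != "==") {
      stop(sprintf("operator '%s' cannot apply to label attribute '%s'; use '=='",
                   op, attr), call. = FALSE)
    }
    tags <- trimws(strsplit(rhs, "|", fixed = TRUE)[[1]])
    tags <- tags[nzchar(tags)]
    if (!length(tags)) stop(sprintf("empty tag list in criterion '%s'", text), call. = FALSE)
    criterion(attr, tags = tags)
  }
}

# numeric == on value attributes uses a fixed absolute tolerance
EQ_TOL <- 1e-9

# Vectorized truth of one criterion over a whole attribute column.
# Blank cells (NA numeric / "" label) are always FALSE.
criterion_mask <- function(col, cr) {
  if (cr$form == "comparison") {
    x <- col
    out <- switch(cr$operator,
      "<"  = x <  cr$value,
      "<=" = x <= cr$value,
      ">"  = x >  cr$value,
      ">=" = x >= cr$value,
      "==" = abs(x - cr$value) <= EQ_TOL)
    out[is.na(out)] <- FALSE
    out
  } else {
    !is.na(col) & nzchar(col) & col %in% cr$tags
  }
}

#' Evaluate one criterion against one record
#'
#' @param record A one-row data frame or named list holding the record's
#'   attribute values.
#' @param criterion A \code{\link{criterion}}.
#' @return \code{TRUE} iff the cell is non-blank and satisfies the
#'   predicate.
#' @export
evaluate_criterion <- function(record, criterion) {
  cell <- record[[criterion$attribute]]
  if (is.null(cell)) {
    stop(sprintf("record has no attribute '%s'", criterion$attribute), call. = FALSE)
  }
  as.logical(criterion_mask(cell[[1]], criterion))
}

#' Construct a filter set
#'
#' A filter set is the per-source conjunction of attribute groups. Each
#' group holds the criteria targeting one attribute plus that group's
#' combination logic: \code{"all"} (AND — e.g. a cutoff range
#' \code{>= 0.4} and \code{<= 0.6}) or \code{"any"} (OR — e.g. the
#' absolute-value cutoff \code{> 0.9} or \code{< -0.9}, or a tag
#' disjunction). Groups for different attributes always combine with AND.
#' An empty filter set retains every record.
#'
#' @param source Name of the source the filters apply to.
#' @param groups Named list (by attribute) of lists with elements
#'   \code{criteria} (list of \code{\link{criterion}}) and \code{logic}
#'   (\code{"all"} or \code{"any"}, default \code{"all"}).
#' @return An object of class \code{filter_set}.
#' @export
filter_set <- function(source, groups = list()) {
  stopifnot(is.character(source), length(source) == 1L)
  if (length(groups)) {
    stopifnot(!is.null(names(groups)), all(nzchar(names(groups))))
    groups <- lapply(stats::setNames(names(groups), names(groups)), function(a) {
      g <- groups[[a]]
      if (inherits(g, "criterion")) g <- list(criteria = list(g))
      if (is.null(g$logic)) g$logic <- "all"
      stopifnot(g$logic %in% c("all", "any"), length(g$criteria) >= 1L)
      for (cr in g$criteria) {
        stopifnot(inherits(cr, "criterion"))
        if (cr$attribute != a) {
          stop(sprintf("criterion on '%s' placed in group '%s'", cr$attribute, a),
               call. = FALSE)
        }
      }
      g[c("criteria", "logic")]
    })
  }
  structure(list(source = source, groups = groups), class = "filter_set")
}

#' @export
format.filter_set <- function(x, ...) {
  if (!length(x$groups)) return("(no filters)")
  paste(vapply(names(x$groups), function(a) {
    g <- x$groups[[a]]
    sep <- if (g$logic == "any") " | " else " & "
    body <- paste(vapply(g$criteria, format, character(1)), collapse = sep)
    if (length(g$criteria) > 1L) sprintf("%s(%s)", g$logic, body) else body
  }, character(1)), collapse = " AND ")
}

#' @export
print.filter_set <- function(x, ...) {
  cat(sprintf("<filter_set> %s: %s\n", x$source, format(x)))
  invisible(x)
}

#' Evaluate a filter set against one record
#'
#' @param record One-row data frame or named list.
#' @param filters A \code{\link{filter_set}}.
#' @return \code{TRUE} iff every attribute group is satisfied under its
#'   logic; \code{TRUE} for an empty filter set.
#' @export
evaluate_filter_set <- function(record, filters) {
  stopifnot(inherits(filters, "filter_set"))
  for (a in names(filters$groups)) {
    g <- filters$groups[[a]]
    hits <- vapply(g$criteria, function(cr) evaluate_criterion(record, cr), logical(1))
    ok <- if (g$logic == "any") any(hits) else all(hits)
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Apply a filter set to a source table
#'
#' Returns a new table containing exactly the records satisfying
#' \code{\link{evaluate_filter_set}}; the input table, its schema and name
#' are untouched. Evaluation is column-vectorized; applying the same filter
#' set twice equals applying it once.
#'
#' @param table A \code{\link{source_table}}.
#' @param filters A \code{\link{filter_set}} with
#'   \code{filters$source == table$name}.
#' @return The filtered \code{source_table}.
#' @export
apply_filter_set <- function(table, filters) {
  stopifnot(inherits(table, "source_table"), inherits(filters, "filter_set"))
  if (filters$source != table$name) {
    stop(sprintf("filter set targets source '%s', table is '%s'",
                 filters$source, table$name), call. = FALSE)
  }
  missing <- setdiff(names(filters$groups), table$schema$name)
  if (length(missing)) {
    stop(sprintf("filter references attribute(s) absent from '%s': %s",
                 table$name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(table$records))
  for (a in names(filters$groups)) {
    g <- filters$groups[[a]]
    masks <- lapply(g$criteria, function(cr) criterion_mask(table$records[[a]], cr))
    gm <- Reduce(if (g$logic == "any") `|` else `&`, masks)
    keep <- keep & gm
  }
  out <- table
  out$records <- table$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  if (nrow(table$records) && !nrow(out$records)) {
    warning(sprintf("all %d record(s) of '%s' were filtered out",
                    nrow(table$records), table$name), call. = FALSE)
  }
  out
}
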