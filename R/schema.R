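#' Column schema
#'
#' Describes one attribute of a mixed-type table: its name, whether it is
#' numerical or categorical, the category labels (categorical) or the
#' observed value range (numerical).
#'
#' @param name Column name (non-empty string).
#' @param kind Either `"numerical"` or `"categorical"`.
#' @param categories Character vector of category labels; required for
#'   categorical columns, must be `NULL` for numerical ones.
#' @param observed_range Length-2 numeric `(min, max)` for numerical columns;
#'   optional (recorded at load/inference time).
#' @return An object of class `sde_column`.
#' @export
column_schema <- function(name, kind = c("numerical", "categorical"),
                          categories = NULL, observed_range = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) == 0L)
      stop("categorical column '", name, "' needs a non-empty category list")
    categories <- as.character(categories)
    if (anyDuplicated(categories))
      stop("duplicate categories in column '", name, "'")
    observed_range <- NULL
  } else {
    categories <- NULL
    if (!is.null(observed_range)) {
      observed_range <- as.numeric(observed_range)
      stopifnot(length(observed_range) == 2L, observed_range[1] <= observed_range[2])
    }
  }
  structure(list(name = name, kind = kind, categories = categories,
                 observed_range = observed_range),
            class = "sde_column")
}

#' Table schema
#'
#' @param columns List of [column_schema()] objects with unique names.
#' @return An object of class `sde_schema`.
#' @export
table_schema <- function(columns) {
  if (length(columns) < 1L) stop("a schema needs at least one column")
  stopifnot(all(vapply(columns, inherits, logical(1), "sde_column")))
  nms <- vapply(columns, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("column names must be unique")
  structure(list(columns = columns), class = "sde_schema")
}

#' @export
print.sde_schema <- function(x, ...) {
  cat("<sde_schema> ", length(x$columns), " columns\n", sep = "")
  for (cs in x$columns) {
    extra <- if (cs$kind == "categorical")
      paste0(" {", paste(cs$categories, collapse = ","), "}")
    else if (!is.null(cs$observed_range))
      sprintf(" [%g, %g]", cs$observed_range[1], cs$observed_range[2])
    else ""
    cat("  ", cs$name, ": ", cs$kind, extra, "\n", sep = "")
  }
  invisible(x)
}

schema_names <- function(schema) vapply(schema$columns, `[[`, character(1), "name")
schema_kinds <- function(schema) vapply(schema$columns, `[[`, character(1), "kind")

schema_column <- function(schema, name) {
  i <- match(name, schema_names(schema))
  if (is.na(i)) stop("no column named '", name, "' in schema")
  schema$columns[[i]]
}

#' Infer a schema from a raw table
#'
#' A column is classed categorical if any value is non-numeric or if it has
#' at most `category_threshold` distinct values (small integer codes such as
#' risk factors or disease stages are treated as categories); otherwise it is
#' numerical and its observed range is recorded.
#'
#' @param table A data frame with at least one row and column.
#' @param category_threshold Maximum distinct-value count for a numeric
#'   column to be treated as categorical. Default 20.
#' @return An `sde_schema`.
#' @export
infer_schema <- function(table, category_threshold = 20L) {
  if (!is.data.frame(table) || nrow(table) == 0L || ncol(table) == 0L)
    stop("cannot infer a schema from an empty table")
  cols <- lapply(names(table), function(nm) {
    v <- table[[nm]]
    v <- v[!is.na(v)]
    num <- suppressWarnings(as.numeric(as.character(v)))
    if (anyNA(num) || length(unique(v)) <= category_threshold) {
      column_schema(nm, "categorical",
                    categories = unique(as.character(v)))
    } else {
      column_schema(nm, "numerical", observed_range = range(num))
    }
  })
  table_schema(cols)
}

#' Read / write a schema descriptor
#'
#' JSON layout: `{"columns":[{"name":..., "kind":"numerical"|"categorical",
#' "categories":[...], "observed_range":[min,max]}]}`.
#'
#' @param path File path.
#' @return [read_schema()] returns an `sde_schema`; [write_schema()] returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$columns)) stop("schema JSON lacks a 'columns' array")
  table_schema(lapply(obj$columns, function(co) {
    column_schema(co$name, co$kind,
                  categories = if (!is.null(co$categories)) unlist(co$categories),
                  observed_range = if (!is.null(co$observed_range)) unlist(co$observed_range))
  }))
}

#' @rdname read_schema
#' @param schema An `sde_schema`.
#' @export
write_schema <- function(schema, path) {
  obj <- list(columns = lapply(schema$columns, function(cs) {
    out <- list(name = cs$name, kind = cs$kind)
    if (!is.null(cs$categories)) out$categories <- as.list(cs$categories)
    if (!is.null(cs$observed_range)) out$observed_range <- cs$observed_range
    out
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
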