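#' Gower distance between mixed-type records
#'
#' Mean over attributes of the per-attribute dissimilarity: range-normalized
#' absolute difference `|a - b| / range` for numerical columns and the 0/1
#' mismatch indicator for categorical ones. Bounded in `[0, 1]`, symmetric,
#' and 0 iff the records agree attribute-wise (constant numerical columns,
#' whose range is degenerate, contribute 0).
#'
#' Ranges default to the schema's `observed_range` fields; in the privacy
#' attacks they are taken from the real training data so that real and
#' synthetic records live on one scale.
#'
#' @param a,b Records: one-row data frames or named lists conforming to
#'   `schema`.
#' @param schema An `sde_schema`.
#' @param ranges Optional named list of `(min, max)` numeric ranges
#'   overriding the schema's, e.g. from [observed_ranges()].
#' @return A number in `[0, 1]`.
#' @export
gower_distance <- function(a, b, schema, ranges = NULL) {
  nms <- schema_names(schema)
  if (!all(nms %in% names(a)) || !all(nms %in% names(b)))
    stop("records do not conform to schema")
  d <- 0
  for (cs in schema$columns) {
    av <- a[[cs$name]]; bv <- b[[cs$name]]
    if (cs$kind == "numerical") {
      r <- column_range(cs, ranges)
      w <- r[2] - r[1]
      d <- d + if (w > 0) min(abs(av - bv) / w, 1) else 0
    } else {
      d <- d + as.numeric(as.character(av) != as.character(bv))
    }
  }
  d / length(schema$columns)
}

#' Observed numeric ranges of a dataset
#'
#' @param data An `sde_dataset`.
#' @return Named list of `(min, max)` for each numerical column.
#' @export
observed_ranges <- function(data) {
  schema <- dataset_schema(data)
  out <- list()
  for (cs in schema$columns)
    if (cs$kind == "numerical") out[[cs$name]] <- range(data[[cs$name]])
  out
}

column_range <- function(cs, ranges) {
  if (!is.null(ranges) && !is.null(ranges[[cs$name]])) return(ranges[[cs$name]])
  if (!is.null(cs$observed_range)) return(cs$observed_range)
  stop("no range available for numerical column '", cs$name, "'")
}

#' Pairwise Gower distances between two datasets
#'
#' Vectorized over records; used by the linkability, membership- and
#' attribute-inference attacks.
#'
#' @param x,y `sde_dataset`s sharing a schema.
#' @param schema The shared `sde_schema`.
#' @param ranges Named list of numeric ranges (see [gower_distance()]).
#' @param columns Optional subset of column names to use.
#' @return A `nrow(x)` by `nrow(y)` matrix of distances in `[0, 1]`.
#' @export
gower_matrix <- function(x, y, schema, ranges = NULL, columns = NULL) {
  cols <- schema$columns
  if (!is.null(columns)) {
    cols <- cols[schema_names(schema) %in% columns]
    if (length(cols) == 0L) stop("no schema columns selected")
  }
  acc <- matrix(0, nrow(x), nrow(y))
  for (cs in cols) {
    xv <- x[[cs$name]]; yv <- y[[cs$name]]
    if (cs$kind == "numerical") {
      r <- column_range(cs, ranges)
      w <- r[2] - r[1]
      if (w > 0) {
        d <- abs(outer(xv, yv, `-`)) / w
        d[d > 1] <- 1
        acc <- acc + d
      }
    } else {
      acc <- acc + outer(as.character(xv), as.character(yv), `!=`)
    }
  }
  acc / length(cols)
}
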