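#' Schema-typed dataset
#'
#' An `sde_dataset` is a plain data frame carrying an `sde_schema` attribute.
#' Numerical columns are stored as doubles, categorical columns as character
#' vectors whose values are drawn from the schema's category list. No missing
#' values are permitted (preprocessing removes them at load time).
#'
#' @param df A data frame.
#' @param schema An `sde_schema`; inferred with [infer_schema()] when absent.
#' @param extend_categories If `TRUE` (default), categorical values absent
#'   from the schema's category list are appended to it; otherwise they are
#'   an error.
#' @return An object of classes `sde_dataset`, `data.frame`.
#' @export
as_dataset <- function(df, schema = NULL, extend_categories = TRUE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(schema)) schema <- infer_schema(df)
  nms <- schema_names(schema)
  if (!all(nms %in% names(df)))
    stop("table is missing schema columns: ",
         paste(setdiff(nms, names(df)), collapse = ", "))
  df <- df[, nms, drop = FALSE]
  cols <- schema$columns
  for (i in seq_along(cols)) {
    cs <- cols[[i]]
    v <- df[[i]]
    if (cs$kind == "numerical") {
      if (is.factor(v)) v <- as.character(v)
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num) & !(v %in% c("", "NA")))
      if (length(bad))
        stop("non-numeric value '", v[bad[1]], "' in declared-numerical column '",
             cs$name, "'")
      df[[i]] <- num
    } else {
      v <- as.character(v)
      v[v == ""] <- NA_character_
      new <- setdiff(unique(v[!is.na(v)]), cs$categories)
      if (length(new)) {
        if (!extend_categories)
          stop("values outside category list in column '", cs$name, "': ",
               paste(new, collapse = ", "))
        cols[[i]]$categories <- c(cs$categories, new)
      }
      df[[i]] <- v
    }
  }
  schema <- table_schema(cols)
  if (anyNA(df)) stop("dataset contains missing values; use load_table() to drop them")
  rownames(df) <- NULL
  structure(df, schema = schema, class = c("sde_dataset", "data.frame"))
}

#' @rdname as_dataset
#' @param data An `sde_dataset`.
#' @export
dataset_schema <- function(data) {
  s <- attr(data, "schema", exact = TRUE)
  if (is.null(s)) stop("not an sde_dataset: no schema attribute")
  s
}

#' @export
print.sde_dataset <- function(x, ...) {
  cat("<sde_dataset> ", nrow(x), " rows x ", ncol(x), " columns\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Load a delimited table as a dataset
#'
#' Reads a CSV with a header row, drops every row containing a missing cell
#' (the framework performs no imputation), and types each column from the
#' schema (inferred when not supplied). The number of dropped rows is stored
#' in the `n_removed` attribute and reported.
#'
#' @param path Path to a CSV file (header row, UTF-8).
#' @inheritParams as_dataset
#' @param category_threshold Passed to [infer_schema()] when `schema` is `NULL`.
#' @param quiet Suppress the removed-row message.
#' @return An `sde_dataset` with attribute `n_removed`.
#' @export
load_table <- function(path, schema = NULL, category_threshold = 20L, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""), colClasses = "character")
  if (nrow(raw) == 0L) stop("empty table in '", path, "'")
  if (!is.null(schema)) {
    nms <- schema_names(schema)
    if (!all(nms %in% names(raw)))
      stop("header does not match schema; missing: ",
           paste(setdiff(nms, names(raw)), collapse = ", "))
  }
  keep <- stats::complete.cases(raw)
  n_removed <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no complete rows left after removing missing values")
  if (is.null(schema)) {
    # re-type numeric-looking columns before inference
    for (nm in names(raw)) {
      num <- suppressWarnings(as.numeric(raw[[nm]]))
      if (!anyNA(num)) raw[[nm]] <- num
    }
    schema <- infer_schema(raw, category_threshold)
  }
  out <- as_dataset(raw, schema)
  attr(out, "n_removed") <- n_removed
  if (!quiet && n_removed > 0L)
    message("removed ", n_removed, " row(s) with missing values")
  out
}

#' Write a dataset to CSV
#'
#' Numerics are written with 15 significant digits so a load/write/load
#' round trip preserves them to at least 12 significant digits.
#'
#' @param data An `sde_dataset`.
#' @param path Output path.
#' @export
write_table <- function(data, path) {
  schema <- dataset_schema(data)
  df <- as.data.frame(data)
  for (cs in schema$columns)
    if (cs$kind == "numerical")
      df[[cs$name]] <- formatC(df[[cs$name]], digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Split a dataset into train and test parts
#'
#' One uniformly random permutation is drawn under `seed`; the first
#' `floor(train_frac * n)` permuted rows form the training set and the rest
#' the test set. The same seed always yields the identical split.
#'
#' @param data An `sde_dataset` with at least 2 rows.
#' @param train_frac Training fraction, strictly between 0 and 1. Default 0.8.
#' @param seed Integer seed.
#' @return A list of class `sde_split` with elements `train`, `test`,
#'   `seed`, `train_frac`.
#' @export
split_train_test <- function(data, train_frac = 0.8, seed) {
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 rows to split")
  if (!(train_frac > 0 && train_frac < 1)) stop("train_frac must be in (0, 1)")
  n_train <- floor(train_frac * n)
  if (n_train < 1L || n_train >= n) stop("degenerate split: train size ", n_train)
  perm <- local_seed_eval(seed, sample.int(n))
  schema <- dataset_schema(data)
  take <- function(idx) as_dataset(as.data.frame(data)[idx, , drop = FALSE], schema)
  structure(list(train = take(perm[seq_len(n_train)]),
                 test  = take(perm[(n_train + 1L):n]),
                 seed = as.integer(seed), train_frac = train_frac),
            class = "sde_split")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
local_seed_eval <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Encode a dataset as a numeric matrix
#'
#' Categorical columns are one-hot expanded over the schema's category list;
#' numerical columns are standardized to zero mean and unit variance. The
#' standardization (and one-hot layout) statistics come from `reference` when
#' supplied — so real and synthetic data can share one embedding — and from
#' `data` itself otherwise. Constant numerical columns encode to all zeros.
#'
#' @param data An `sde_dataset`.
#' @param reference Optional `sde_dataset` providing the encoding statistics.
#' @return A list with `matrix` (numeric, one row per record) and `map`
#'   (data frame mapping encoded columns back to source columns).
#' @export
encode_numeric <- function(data, reference = NULL) {
  schema <- dataset_schema(data)
  ref <- if (is.null(reference)) data else reference
  ref_schema <- dataset_schema(ref)
  if (!identical(schema_names(ref_schema), schema_names(schema)))
    stop("reference schema does not match data schema")
  blocks <- list(); map <- list()
  for (cs in ref_schema$columns) {
    v <- data[[cs$name]]
    if (cs$kind == "numerical") {
      mu <- mean(ref[[cs$name]]); sdv <- stats::sd(ref[[cs$name]])
      enc <- if (!is.finite(sdv) || sdv == 0) rep(0, length(v)) else (v - mu) / sdv
      blocks[[length(blocks) + 1L]] <- matrix(enc, ncol = 1,
        dimnames = list(NULL, cs$name))
      map[[length(map) + 1L]] <- data.frame(source = cs$name, level = NA_character_)
    } else {
      cats <- cs$categories
      enc <- matrix(0, nrow = length(v), ncol = length(cats),
                    dimnames = list(NULL, paste0(cs$name, "=", cats)))
      hit <- match(v, cats)
      ok <- which(!is.na(hit))
      enc[cbind(ok, hit[ok])] <- 1
      blocks[[length(blocks) + 1L]] <- enc
      map[[length(map) + 1L]] <- data.frame(source = cs$name, level = cats)
    }
  }
  list(matrix = do.call(cbind, blocks), map = do.call(rbind, map))
}
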