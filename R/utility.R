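#' The five predictive model families of the utility protocol
#'
#' @return Character vector of family names.
#' @export
model_families <- function()
  c("random_forest", "k_nearest_neighbors", "decision_tree",
    "support_vector_machine", "multilayer_perceptron")

#' Build one prediction task per attribute
#'
#' Every column becomes a target once: categorical targets yield
#' classification tasks, numerical targets regression tasks, with all other
#' columns as features.
#'
#' @param schema An `sde_schema` with at least 2 columns.
#' @return List of tasks (`target`, `kind`, `features`).
#' @export
build_tasks <- function(schema) {
  nms <- schema_names(schema)
  if (length(nms) < 2L) stop("utility tasks need at least 2 columns")
  kinds <- schema_kinds(schema)
  lapply(seq_along(nms), function(i) {
    list(target = nms[i],
         kind = if (kinds[i] == "categorical") "classification" else "regression",
         features = nms[-i])
  })
}

subset_dataset <- function(data, cols) {
  schema <- dataset_schema(data)
  keep <- schema$columns[schema_names(schema) %in% cols]
  as_dataset(as.data.frame(data)[, cols, drop = FALSE], table_schema(keep))
}

#' Fit one model family on one task and score it on the test set
#'
#' Features are one-hot encoded and standardized with the training
#' statistics. Regression targets are min-max normalized to `[0, 1]` with
#' the training min/max (test values and predictions clipped to `[0, 1]`)
#' so every regression error metric is bounded. Classification metrics use
#' support-weighted multiclass averaging, under which weighted recall equals
#' accuracy; test-only class levels count as errors rather than raising.
#'
#' @param train,test `sde_dataset`s sharing a schema.
#' @param task One element of [build_tasks()].
#' @param family One of [model_families()].
#' @param seed Integer seed set before the fit, making it reproducible.
#' @return Named numeric: `acc`, `precision`, `recall`, `f1`
#'   (classification) or `mae`, `mse`, `rmse`, `r2` (regression), all in
#'   `[0, 1]`.
#' @export
fit_and_score <- function(train, test, task, family, seed = 0L) {
  family <- match.arg(family, model_families())
  feat_train <- subset_dataset(train, task$features)
  x_train <- encode_numeric(feat_train)$matrix
  x_test <- encode_numeric(subset_dataset(test, task$features),
                           reference = feat_train)$matrix
  colnames(x_train) <- colnames(x_test) <- paste0("v", seq_len(ncol(x_train)))
  if (task$kind == "classification") {
    lev <- unique(as.character(train[[task$target]]))
    if (length(lev) < 2L)
      stop("classification target '", task$target, "' has fewer than 2 levels in train")
    y_train <- factor(as.character(train[[task$target]]), levels = lev)
    truth <- as.character(test[[task$target]])
    pred <- local_seed_eval(seed,
      predict_family(family, x_train, y_train, x_test))
    classification_metrics(truth, as.character(pred))
  } else {
    lo <- min(train[[task$target]]); hi <- max(train[[task$target]])
    norm <- function(v) if (hi > lo) pmin(pmax((v - lo) / (hi - lo), 0), 1) else rep(0, length(v))
    y_train <- norm(train[[task$target]])
    truth <- norm(test[[task$target]])
    pred <- local_seed_eval(seed,
      predict_family(family, x_train, y_train, x_test))
    regression_metrics(truth, pmin(pmax(as.numeric(pred), 0), 1),
                       constant_train = hi == lo)
  }
}

# Dispatch one family; y factor => classification, numeric => regression.
predict_family <- function(family, x, y, newx) {
  cls <- is.factor(y)
  switch(family,
    random_forest = {
      fit <- randomForest::randomForest(x = x, y = y, ntree = 100L)
      predict(fit, newx)
    },
    k_nearest_neighbors = knn_predict(x, y, newx, k = 5L),
    decision_tree = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df,
                          method = if (cls) "class" else "anova")
      predict(fit, data.frame(newx, check.names = FALSE),
              type = if (cls) "class" else "vector")
    },
    support_vector_machine = {
      fit <- e1071::svm(x = x, y = y, kernel = "radial", scale = FALSE)
      predict(fit, newx)
    },
    multilayer_perceptron = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      fit <- nnet::nnet(.y ~ ., data = df, size = 100L, maxit = 500L,
                        linout = !cls, trace = FALSE, MaxNWts = 100000L)
      if (cls) {
        p <- predict(fit, data.frame(newx, check.names = FALSE))
        if (ncol(p) == 1L)   # binary: single logistic output for level 2
          factor(levels(y)[1L + (p[, 1L] > 0.5)], levels = levels(y))
        else
          factor(colnames(p)[max.col(p, ties.method = "first")], levels = levels(y))
      } else {
        predict(fit, data.frame(newx, check.names = FALSE))[, 1L]
      }
    })
}

# k-nearest-neighbour prediction with deterministic tie-breaks: neighbour
# ties resolve by row order, classification vote ties by training level order.
knn_predict <- function(x, y, newx, k = 5L) {
  k <- min(k, nrow(x))
  d2 <- outer(rowSums(newx^2), rep(1, nrow(x))) +
        outer(rep(1, nrow(newx)), rowSums(x^2)) - 2 * newx %*% t(x)
  idx <- apply(d2, 1L, function(r) order(r)[seq_len(k)])
  idx <- matrix(idx, nrow = k)
  if (is.factor(y)) {
    out <- apply(idx, 2L, function(i) {
      votes <- tabulate(as.integer(y[i]), nbins = nlevels(y))
      levels(y)[which.max(votes)]
    })
    factor(out, levels = levels(y))
  } else {
    apply(idx, 2L, function(i) mean(y[i]))
  }
}

classification_metrics <- function(truth, pred) {
  lev <- unique(c(truth, pred))
  n <- length(truth)
  per <- vapply(lev, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    support <- sum(truth == cl)
    predicted <- sum(pred == cl)
    prec <- if (predicted > 0) tp / predicted else 0
    rec <- if (support > 0) tp / support else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(support = support, prec = prec, rec = rec, f1 = f1)
  }, numeric(4))
  w <- per["support", ] / n
  c(acc = mean(truth == pred),
    precision = sum(w * per["prec", ]),
    recall = sum(w * per["rec", ]),
    f1 = sum(w * per["f1", ]))
}

regression_metrics <- function(truth, pred, constant_train = FALSE) {
  err <- truth - pred
  mse <- mean(err^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (constant_train || ss_tot == 0) 0
        else min(max(1 - sum(err^2) / ss_tot, 0), 1)
  c(mae = mean(abs(err)), mse = mse, rmse = sqrt(mse), r2 = r2)
}

#' Run one full training-testing scenario
#'
#' Fits all five model families on every per-attribute prediction task and
#' scores them on the test set — called once with the real training set
#' (TRTR: train on real, test on real) and once with the synthetic dataset
#' as training data (TSTR: train on synthetic, test on real).
#'
#' @param train,test `sde_dataset`s sharing a schema.
#' @param schema Optional shared `sde_schema` (defaults to the train's).
#' @param seed Integer base seed; each (task, family) fit gets a derived
#'   seed so the table is bit-reproducible.
#' @return A long-format data frame (`target`, `kind`, `family`, `metric`,
#'   `value`) of class `sde_metric_table`.
#' @export
run_scenario <- function(train, test, schema = NULL, seed = 0L) {
  if (is.null(schema)) schema <- check_shared_schema(train, test)
  tasks <- build_tasks(schema)
  fams <- model_families()
  rows <- list()
  for (ti in seq_along(tasks)) for (fi in seq_along(fams)) {
    sc <- fit_and_score(train, test, tasks[[ti]], fams[fi],
                        seed = seed + 97L * ti + fi)
    rows[[length(rows) + 1L]] <- data.frame(
      target = tasks[[ti]]$target, kind = tasks[[ti]]$kind,
      family = fams[fi], metric = names(sc), value = unname(sc),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sde_metric_table", "data.frame")
  out
}

#' Utility differences between the TRTR and TSTR scenarios
#'
#' For each of the eight metrics, the mean over all (task, family) pairs of
#' the absolute TSTR-TRTR difference, with a paired two-sided t-test over
#' the same pairs (p defined as 1 when every paired difference is zero). A
#' p-value above the significance level means the synthetic training data
#' gave statistically indistinguishable downstream performance.
#'
#' @param trtr,tstr `sde_metric_table`s from [run_scenario()] sharing keys.
#' @return A list of class `sde_utility` with `differences` (named numeric),
#'   `pvalues`, and the two tables (`trtr`, `tstr`).
#' @export
utility_differences <- function(trtr, tstr) {
  key <- function(tb) paste(tb$target, tb$family, tb$metric)
  if (!identical(sort(key(trtr)), sort(key(tstr))))
    stop("TRTR and TSTR tables do not share (task, family, metric) keys")
  tstr <- tstr[match(key(trtr), key(tstr)), ]
  mets <- unique(trtr$metric)
  diffs <- pv <- stats::setNames(numeric(length(mets)), mets)
  for (m in mets) {
    i <- trtr$metric == m
    diffs[m] <- mean(abs(tstr$value[i] - trtr$value[i]))
    pv[m] <- paired_pvalue(tstr$value[i], trtr$value[i])
  }
  structure(list(differences = diffs, pvalues = pv, trtr = trtr, tstr = tstr),
            class = "sde_utility")
}
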