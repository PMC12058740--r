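#' Configuration for a full evaluation run
#'
#' @param n_folds Number of generation+evaluation repetitions on the one
#'   fixed train/test split. Default 10.
#' @param base_seed Integer seed; fold `i` uses `base_seed + i`.
#' @param train_frac Training fraction of the single split. Default 0.8.
#' @param significance_level Threshold for the paired model-comparison
#'   t-tests. Default 0.05.
#' @param binning A [binning_spec()].
#' @param attack_cfg An [attack_config()] (its seed is overridden per fold).
#' @return An object of class `sde_eval_config`.
#' @export
evaluation_config <- function(n_folds = 10L, base_seed = 0L, train_frac = 0.8,
                              significance_level = 0.05,
                              binning = binning_spec(),
                              attack_cfg = attack_config()) {
  stopifnot(n_folds >= 1L, significance_level > 0, significance_level < 1)
  structure(list(n_folds = as.integer(n_folds), base_seed = as.integer(base_seed),
                 train_frac = train_frac, significance_level = significance_level,
                 binning = binning, attack_cfg = attack_cfg),
            class = "sde_eval_config")
}

#' Fidelity-utility tradeoff score G
#'
#' Equal weighting of the fidelity side (the pairwise correlation
#' difference) and the utility side (the mean of the per-metric mean
#' absolute TSTR-TRTR differences):
#' `G = 0.5 * PCD + 0.5 * mean(utility differences)`. Lower is better; 0
#' means the synthetic data preserves both the pairwise association
#' structure and downstream model performance exactly. Computed on the
#' output of a differentially private generator at budget epsilon, the same
#' quantity is the G_epsilon score.
#'
#' @param pcd The pairwise correlation difference in `[0, 1]`.
#' @param utility An `sde_utility` report (or a numeric vector of
#'   per-metric mean absolute differences).
#' @return A number in `[0, 1]`.
#' @export
g_tradeoff <- function(pcd, utility) {
  diffs <- if (inherits(utility, "sde_utility")) utility$differences else utility
  stopifnot(pcd >= 0, pcd <= 1, all(diffs >= -1e-12 & diffs <= 1 + 1e-12))
  0.5 * pcd + 0.5 * mean(diffs)
}

#' Evaluate one synthetic dataset against one real split
#'
#' Runs the complete framework once: the four fidelity metrics (real train
#' versus synthetic), the TRTR/TSTR utility protocol (testing on the real
#' test set), the five privacy attacks (control = the real test set), and
#' the G tradeoff score. The fold seed is `base_seed + fold_index`.
#'
#' @param train,test,synth `sde_dataset`s sharing a schema.
#' @param cfg An [evaluation_config()].
#' @param fold_index Integer fold label.
#' @return A list of class `sde_fold` with `fold_index`, `fidelity`,
#'   `utility`, `privacy`, `tradeoff_g`.
#' @export
evaluate_once <- function(train, test, synth, cfg = evaluation_config(),
                          fold_index = 0L) {
  check_shared_schema(train, synth)
  check_shared_schema(train, test)
  if (nrow(synth) != nrow(train))
    warning("synthetic dataset size (", nrow(synth),
            ") differs from training size (", nrow(train), ")")
  seed <- cfg$base_seed + as.integer(fold_index)
  fid <- fidelity_report(train, synth, cfg$binning, seed = seed)
  trtr <- run_scenario(train, test, seed = seed)
  tstr <- run_scenario(synth, test, schema = dataset_schema(train), seed = seed)
  util <- utility_differences(trtr, tstr)
  acfg <- cfg$attack_cfg; acfg$seed <- seed
  priv <- privacy_report(synth, train, test, acfg)
  structure(list(fold_index = as.integer(fold_index), fidelity = fid,
                 utility = util, privacy = priv,
                 tradeoff_g = g_tradeoff(fid$pcd, util)),
            class = "sde_fold")
}

#' Flatten a fold result into a named metric vector
#'
#' @param fold An `sde_fold`.
#' @return Named numeric vector covering all fidelity metrics, the eight
#'   utility differences, the five privacy adjusted risks, and G.
#' @export
fold_metrics <- function(fold) {
  u <- fold$utility$differences
  names(u) <- paste0("utility_", names(u), "_diff")
  p <- vapply(fold$privacy, `[[`, numeric(1), "adjusted_risk")
  c(hellinger_mean = fold$fidelity$hellinger_mean,
    pcd = fold$fidelity$pcd,
    ddplot_r2 = fold$fidelity$ddplot_r2,
    auc_roc = fold$fidelity$auc_roc,
    u, p, g = fold$tradeoff_g)
}

# Ideal value of each metric; "best" across folds is the value nearest it.
metric_ideal <- function(metric)
  switch(metric, ddplot_r2 = 1, auc_roc = 0.5, 0)

#' Aggregate fold results into best/worst/mean values
#'
#' The mean is the arithmetic average over folds; "best" is the fold value
#' closest to the metric's ideal (0 for distances, differences, risks and
#' G; 1 for the DD-plot R-squared; 0.5 for the distinguishability AUC-ROC)
#' and "worst" the value farthest from it.
#'
#' @param folds List of `sde_fold` results.
#' @return A data frame with columns `metric`, `best`, `worst`, `mean`.
#' @export
aggregate_folds <- function(folds) {
  stopifnot(length(folds) >= 1L)
  mat <- vapply(folds, fold_metrics, fold_metrics(folds[[1L]]))
  mat <- matrix(mat, nrow = length(fold_metrics(folds[[1L]])),
                dimnames = list(names(fold_metrics(folds[[1L]])), NULL))
  out <- lapply(rownames(mat), function(m) {
    v <- mat[m, ]
    dist <- abs(v - metric_ideal(m))
    data.frame(metric = m, best = v[which.min(dist)],
               worst = v[which.max(dist)], mean = mean(v))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full fold-based evaluation procedure
#'
#' Splits the real dataset once (80/20 by default) under `base_seed`, runs
#' the TRTR baseline implicitly inside each fold, fits the requested
#' baseline generator on the training set once, then for each fold draws a
#' fresh synthetic dataset of the training size under the fold seed (or
#' consumes one pre-generated external dataset per fold) and evaluates it.
#' Fold results are aggregated into best/worst/mean values per metric.
#'
#' @param real An `sde_dataset`.
#' @param generator `"gaussian_copula"`, `"npc"`, an already fitted
#'   `sde_generator`, or a list of external synthetic `sde_dataset`s (one
#'   per fold).
#' @param cfg An [evaluation_config()].
#' @return A list of class `sde_run` with `split`, `folds`, `aggregate`,
#'   `config`.
#' @export
run_folds <- function(real, generator = "gaussian_copula",
                      cfg = evaluation_config()) {
  split <- split_train_test(real, cfg$train_frac, seed = cfg$base_seed)
  external <- is.list(generator) && !inherits(generator, "sde_generator")
  if (external) {
    if (length(generator) < cfg$n_folds)
      stop("need at least ", cfg$n_folds, " external synthetic datasets")
  } else if (is.character(generator)) {
    generator <- switch(match.arg(generator, c("gaussian_copula", "npc")),
      gaussian_copula = fit_gaussian_copula(split$train, seed = cfg$base_seed),
      npc = fit_npc(split$train, seed = cfg$base_seed))
  }
  folds <- lapply(seq_len(cfg$n_folds), function(i) {
    synth <- if (external) generator[[i]]
             else generate_synthetic(generator, nrow(split$train),
                                     seed = cfg$base_seed + i)
    evaluate_once(split$train, split$test, synth, cfg, fold_index = i)
  })
  structure(list(split = split, folds = folds,
                 aggregate = aggregate_folds(folds), config = cfg),
            class = "sde_run")
}

#' Compare two models' fold results metric by metric
#'
#' For each metric a paired two-sided t-test across fold indices between
#' the two models' values (p defined as 1 when every paired difference is
#' zero); a metric differs significantly when p falls below the configured
#' significance level.
#'
#' @param folds_a,folds_b Lists of `sde_fold` results of equal length (or
#'   `sde_run` objects).
#' @param cfg An [evaluation_config()].
#' @return Data frame with `metric`, `mean_a`, `mean_b`, `p_value`,
#'   `significant`.
#' @export
compare_models <- function(folds_a, folds_b, cfg = evaluation_config()) {
  if (inherits(folds_a, "sde_run")) folds_a <- folds_a$folds
  if (inherits(folds_b, "sde_run")) folds_b <- folds_b$folds
  if (length(folds_a) != length(folds_b)) stop("fold counts differ")
  ma <- vapply(folds_a, fold_metrics, fold_metrics(folds_a[[1L]]))
  mb <- vapply(folds_b, fold_metrics, fold_metrics(folds_b[[1L]]))
  ma <- matrix(ma, nrow = length(fold_metrics(folds_a[[1L]])),
               dimnames = list(names(fold_metrics(folds_a[[1L]])), NULL))
  mb <- matrix(mb, nrow = nrow(ma), dimnames = dimnames(ma))
  if (!identical(rownames(ma), rownames(mb))) stop("metric sets differ")
  out <- do.call(rbind, lapply(rownames(ma), function(m) {
    p <- paired_pvalue(ma[m, ], mb[m, ])
    data.frame(metric = m, mean_a = mean(ma[m, ]), mean_b = mean(mb[m, ]),
               p_value = p, significant = p < cfg$significance_level)
  }))
  rownames(out) <- NULL
  out
}

report_version <- "1.0"

#' Write an evaluation report to JSON
#'
#' Produces a single schema-versioned JSON document carrying the config
#' echo (seeds included), the per-fold metric values, the best/worst/mean
#' aggregate, and optional model comparisons — everything needed to
#' reproduce the run.
#'
#' @param run An `sde_run`.
#' @param path Output path.
#' @param comparisons Optional [compare_models()] data frame.
#' @return `path`, invisibly.
#' @export
write_report <- function(run, path, comparisons = NULL) {
  cfg <- run$config
  doc <- list(
    schema_version = report_version,
    config = list(n_folds = cfg$n_folds, base_seed = cfg$base_seed,
                  train_frac = cfg$train_frac,
                  significance_level = cfg$significance_level,
                  hellinger_bins = cfg$binning$hellinger_bins,
                  association_bins = cfg$binning$association_bins,
                  n_attacks = cfg$attack_cfg$n_attacks,
                  link_neighbors = cfg$attack_cfg$link_neighbors,
                  membership_quantile = cfg$attack_cfg$membership_quantile,
                  numeric_tolerance = cfg$attack_cfg$numeric_tolerance),
    folds = lapply(run$folds, function(f) {
      m <- fold_metrics(f)
      c(list(fold_index = f$fold_index), as.list(m),
        list(pcd_pvalue = f$fidelity$pcd_pvalue,
             hellinger_per_attribute = as.list(f$fidelity$hellinger_per_attribute),
             utility_pvalues = as.list(f$utility$pvalues),
             privacy = lapply(f$privacy, function(a)
               a[c("attack_name", "attack_rate", "control_rate",
                   "adjusted_risk", "n_attacks")])))
    }),
    aggregate = run$aggregate)
  if (!is.null(comparisons)) doc$comparisons <- comparisons
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
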