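#' Binning specification for marginal and association discretization
#'
#' @param hellinger_bins Equal-width bins for numeric marginals in the
#'   Hellinger distance (over the combined real/synthetic range). Default 20.
#' @param association_bins Quantile bins for numeric columns in the
#'   mixed-type association coefficient. Default 10.
#' @return An object of class `sde_binning`.
#' @export
binning_spec <- function(hellinger_bins = 20L, association_bins = 10L) {
  stopifnot(hellinger_bins >= 2L, association_bins >= 2L)
  structure(list(hellinger_bins = as.integer(hellinger_bins),
                 association_bins = as.integer(association_bins),
                 edge_policy = "combined_range"),
            class = "sde_binning")
}

#' Discrete distribution on an explicit support
#'
#' @param support Bin labels or category labels.
#' @param probs Probabilities, non-negative and summing to 1.
#' @return An object of class `sde_distribution`.
#' @export
discrete_distribution <- function(support, probs) {
  probs <- as.numeric(probs)
  stopifnot(length(support) >= 1L, length(support) == length(probs), all(probs >= 0))
  if (abs(sum(probs) - 1) > 1e-9) stop("probabilities must sum to 1")
  structure(list(support = support, probs = probs), class = "sde_distribution")
}

#' Discretize a real/synthetic column pair onto a shared support
#'
#' Categorical columns use the union of observed categories as support, with
#' relative frequencies as probabilities (a category absent from one side
#' gets probability 0 there). Numerical columns are cut into
#' `spec$hellinger_bins` equal-width bins spanning the combined
#' real-union-synthetic range.
#'
#' @param real_col,synth_col Value vectors of one attribute.
#' @param schema A [column_schema()] for the attribute.
#' @param spec A [binning_spec()].
#' @return A list of two [discrete_distribution()]s `(P, Q)` on one support.
#' @export
discretize_pair <- function(real_col, synth_col, schema, spec = binning_spec()) {
  if (length(real_col) == 0L || length(synth_col) == 0L)
    stop("cannot discretize an empty column")
  if (schema$kind == "categorical") {
    support <- unique(c(schema$categories,
                        as.character(real_col), as.character(synth_col)))
    p <- tabulate(match(as.character(real_col), support), length(support))
    q <- tabulate(match(as.character(synth_col), support), length(support))
  } else {
    lo <- min(real_col, synth_col); hi <- max(real_col, synth_col)
    k <- spec$hellinger_bins
    if (hi == lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
    breaks <- seq(lo, hi, length.out = k + 1L)
    support <- sprintf("[%g,%g)", breaks[-(k + 1L)], breaks[-1L])
    bin <- function(v) {
      i <- findInterval(v, breaks, rightmost.closed = TRUE)
      i[i < 1L] <- 1L; i[i > k] <- k
      tabulate(i, k)
    }
    p <- bin(real_col); q <- bin(synth_col)
  }
  list(P = discrete_distribution(support, p / sum(p)),
       Q = discrete_distribution(support, q / sum(q)))
}

#' Hellinger distance between two discrete distributions
#'
#' `H(P, Q) = sqrt(0.5 * sum_i (sqrt(p_i) - sqrt(q_i))^2)` — half the squared
#' Euclidean norm of the difference of the square-root probability vectors,
#' under a square root. 0 means identical distributions; 1 means disjoint
#' support.
#'
#' @param P,Q [discrete_distribution()]s on the same support.
#' @return A number in `[0, 1]`.
#' @export
hellinger <- function(P, Q) {
  if (!identical(P$support, Q$support)) stop("distributions must share a support")
  h2 <- 0.5 * sum((sqrt(P$probs) - sqrt(Q$probs))^2)
  min(sqrt(max(h2, 0)), 1)
}

#' Mean per-attribute Hellinger distance between two datasets
#'
#' Each attribute's real and synthetic marginals are discretized onto a
#' shared support ([discretize_pair()]) and compared with [hellinger()]; the
#' unweighted mean over attributes is the summary fidelity value.
#'
#' @param real,synth `sde_dataset`s sharing a schema.
#' @param spec A [binning_spec()].
#' @return A list with `per_attribute` (named numeric) and `mean`.
#' @export
mean_hellinger <- function(real, synth, spec = binning_spec()) {
  schema <- check_shared_schema(real, synth)
  per <- vapply(schema$columns, function(cs) {
    dd <- discretize_pair(real[[cs$name]], synth[[cs$name]], cs, spec)
    hellinger(dd$P, dd$Q)
  }, numeric(1))
  names(per) <- schema_names(schema)
  list(per_attribute = per, mean = mean(per))
}

check_shared_schema <- function(real, synth) {
  sr <- dataset_schema(real); ss <- dataset_schema(synth)
  if (!identical(schema_names(sr), schema_names(ss)) ||
      !identical(schema_kinds(sr), schema_kinds(ss)))
    stop("real and synthetic datasets must share a schema")
  sr
}

#' Mahalanobis data depth
#'
#' `D(x) = 1 / (1 + (x - mu)' S^-1 (x - mu))` with `mu` and `S` the mean and
#' covariance of the reference sample. The covariance is ridge-regularized
#' (`1e-6 * trace(S)/d` on the diagonal) so the one-hot block structure of
#' encoded categorical columns cannot make it singular. Depth is 1 at the
#' reference mean and decreases monotonically along any ray from it.
#'
#' @param points Numeric matrix of points to evaluate (rows).
#' @param reference Numeric matrix defining the depth ordering; needs at
#'   least `ncol + 2` rows.
#' @return Numeric vector of depths in `(0, 1]`.
#' @export
depth_values <- function(points, reference) {
  points <- as.matrix(points); reference <- as.matrix(reference)
  if (ncol(points) != ncol(reference)) stop("dimension mismatch")
  d <- ncol(reference)
  if (nrow(reference) < d + 2L)
    stop("reference needs at least ", d + 2L, " rows for a stable covariance")
  mu <- colMeans(reference)
  S <- stats::cov(reference)
  ridge <- 1e-6 * sum(diag(S)) / d
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-6
  S <- S + diag(ridge, d)
  md <- stats::mahalanobis(points, mu, S)
  1 / (1 + md)
}

#' DD-plot agreement between real and synthetic datasets
#'
#' Every record of the combined sample is assigned two depths: one with
#' respect to the real dataset and one with respect to the synthetic dataset
#' (both in the shared real-referenced encoding). When the two multivariate
#' distributions agree, the depth pairs fall on the identity line `y = x`;
#' the returned R-squared measures the variance of the synthetic depths
#' explained by that identity line, `1 - SS_res/SS_tot` with residuals taken
#' about `y = x`, clamped into `[0, 1]`.
#'
#' @param real,synth `sde_dataset`s sharing a schema.
#' @return A list with `r2` and `depth_pairs` (data frame with columns
#'   `real_depth`, `synth_depth`).
#' @export
ddplot_r2 <- function(real, synth) {
  check_shared_schema(real, synth)
  enc_real <- encode_numeric(real)$matrix
  enc_synth <- encode_numeric(synth, reference = real)$matrix
  combined <- rbind(enc_real, enc_synth)
  dx <- depth_values(combined, enc_real)
  dy <- depth_values(combined, enc_synth)
  ss_res <- sum((dy - dx)^2)
  ss_tot <- sum((dy - mean(dy))^2)
  r2 <- if (ss_tot == 0) as.numeric(ss_res == 0) else 1 - ss_res / ss_tot
  list(r2 = min(max(r2, 0), 1),
       depth_pairs = data.frame(real_depth = dx, synth_depth = dy))
}

#' Distinguishability of synthetic from real records (OOB AUC-ROC)
#'
#' Pools real (label 0) and synthetic (label 1) records in the shared
#' real-referenced encoding and trains a random forest of 1,000 trees with
#' maximum depth 3 (8 terminal nodes). Each record's synthetic-class
#' probability is the average vote over the trees for which the record was
#' out-of-bag; the AUC-ROC of these out-of-bag probabilities against the
#' true labels is returned. 0.5 means the classifier cannot tell real from
#' synthetic (high fidelity); values near 1 mean the two are easily
#' separated.
#'
#' @param real,synth `sde_dataset`s sharing a schema.
#' @param seed Integer seed controlling the bootstrap resampling.
#' @return AUC-ROC in `[0, 1]`.
#' @export
distinguishability_auc <- function(real, synth, seed) {
  check_shared_schema(real, synth)
  x <- rbind(encode_numeric(real)$matrix,
             encode_numeric(synth, reference = real)$matrix)
  y <- factor(c(rep(0L, nrow(real)), rep(1L, nrow(synth))), levels = c(0L, 1L))
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  rf <- local_seed_eval(seed,
    randomForest::randomForest(x = x, y = y, ntree = 1000L, maxnodes = 8L))
  oob_p <- rf$votes[, "1"]
  seen <- rf$oob.times > 0L   # P(never OOB) < 1e-434 at 1,000 trees
  as.numeric(pROC::auc(pROC::roc(response = y[seen], predictor = oob_p[seen],
                                 levels = c("0", "1"), direction = "<",
                                 quiet = TRUE)))
}

#' Full fidelity report
#'
#' Runs the four fidelity metrics — mean Hellinger distance, pairwise
#' correlation difference, DD-plot R-squared, and out-of-bag AUC-ROC — for
#' one real/synthetic pair.
#'
#' @param real,synth `sde_dataset`s sharing a schema.
#' @param spec A [binning_spec()].
#' @param seed Integer seed for the distinguishability classifier.
#' @return A list of class `sde_fidelity` with elements
#'   `hellinger_per_attribute`, `hellinger_mean`, `pcd`, `pcd_pvalue`,
#'   `ddplot_r2`, `depth_pairs`, `auc_roc`.
#' @export
fidelity_report <- function(real, synth, spec = binning_spec(), seed = 0L) {
  h <- mean_hellinger(real, synth, spec)
  pc <- pcd(real, synth, spec)
  dd <- ddplot_r2(real, synth)
  auc <- distinguishability_auc(real, synth, seed)
  structure(list(hellinger_per_attribute = h$per_attribute,
                 hellinger_mean = h$mean,
                 pcd = pc$pcd, pcd_pvalue = pc$pvalue,
                 ddplot_r2 = dd$r2, depth_pairs = dd$depth_pairs,
                 auc_roc = auc),
            class = "sde_fidelity")
}
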