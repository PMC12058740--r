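#' Mixed-type association coefficient (phi-k style)
#'
#' Association in `[0, 1]` between two columns of arbitrary kinds, built the
#' way the phi-k coefficient of Baak et al. is: each column is binned
#' (categoricals by category, numerics into `spec$association_bins` quantile
#' bins), the Pearson chi-squared statistic of the contingency table is
#' computed, the expected chance ("pedestal") contribution — the
#' independence expectation of the statistic, equal to the table's degrees
#' of freedom — is subtracted with a floor at zero, and the result is mapped
#' to a correlation by inverting the chi-squared curve of a binned bivariate
#' normal with the same marginal bin probabilities and sample size. The
#' coefficient is 0 under independence, 1 under perfect dependence, and for
#' bivariate-normal input recovers the absolute Pearson correlation.
#'
#' @param col_a,col_b Equal-length value vectors (numeric or character).
#' @param spec A [binning_spec()].
#' @return A number in `[0, 1]`. A column with a single distinct value gives
#'   0 with a warning.
#' @export
mixed_association <- function(col_a, col_b, spec = binning_spec()) {
  if (length(col_a) != length(col_b)) stop("columns must have equal length")
  a <- assoc_bin(col_a, spec$association_bins)
  b <- assoc_bin(col_b, spec$association_bins)
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    warning("column with a single distinct value: association defined as 0")
    return(0)
  }
  tab <- table(a, b)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("degenerate contingency table: association defined as 0")
    return(0)
  }
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  expected <- n * outer(px, py)
  chi2 <- sum((tab - expected)^2 / expected)
  pedestal <- (nrow(tab) - 1) * (ncol(tab) - 1)
  chi2_corr <- max(0, chi2 - pedestal)
  invert_bvn_chi2(chi2_corr, n, px, py)
}

# Bin one column: categoricals by value, numerics into quantile bins.
assoc_bin <- function(v, bins) {
  if (is.numeric(v)) {
    qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                                 type = 7, names = FALSE))
    if (length(qs) < 3L) return(factor(v))
    cut(v, breaks = qs, include.lowest = TRUE)
  } else {
    factor(as.character(v))
  }
}

# Standard bivariate normal CDF at (x, y) with correlation rho;
# infinite limits resolved through the marginals.
pbvn <- function(x, y, rho) {
  if (x == -Inf || y == -Inf) return(0)
  if (x == Inf && y == Inf) return(1)
  if (x == Inf) return(stats::pnorm(y))
  if (y == Inf) return(stats::pnorm(x))
  mvtnorm::pmvnorm(upper = c(x, y),
                   corr = matrix(c(1, rho, rho, 1), 2),
                   algorithm = mvtnorm::Miwa())[1]
}

# Expected Pearson chi-squared of a bivariate normal with correlation rho,
# discretized so its marginal bin probabilities are px and py, at size n.
bvn_chi2 <- function(rho, n, px, py) {
  xe <- stats::qnorm(c(0, cumsum(px)))
  ye <- stats::qnorm(c(0, cumsum(py)))
  xe[length(xe)] <- Inf; ye[length(ye)] <- Inf
  Fg <- outer(xe, ye, Vectorize(function(x, y) pbvn(x, y, rho)))
  r <- length(px); s <- length(py)
  P <- Fg[-1, -1, drop = FALSE] - Fg[-(r + 1), -1, drop = FALSE] -
       Fg[-1, -(s + 1), drop = FALSE] + Fg[-(r + 1), -(s + 1), drop = FALSE]
  P[P < 0] <- 0
  E <- outer(px, py)
  n * sum((P - E)^2 / E)
}

# Solve bvn_chi2(rho) = chi2_corr for rho in [0, 1].
invert_bvn_chi2 <- function(chi2_corr, n, px, py) {
  if (chi2_corr <= 0) return(0)
  rho_hi <- 0.999
  top <- bvn_chi2(rho_hi, n, px, py)
  if (chi2_corr >= top) return(1)
  stats::uniroot(function(r) bvn_chi2(r, n, px, py) - chi2_corr,
                 lower = 0, upper = rho_hi, tol = 1e-4)$root
}

#' Pairwise mixed-type association matrix
#'
#' [mixed_association()] for every unordered column pair; symmetric with
#' unit diagonal.
#'
#' @param data An `sde_dataset` with at least 2 columns.
#' @param spec A [binning_spec()].
#' @return An object of class `sde_association`: list with `labels` and
#'   `values` (symmetric matrix in `[0, 1]`).
#' @export
association_matrix <- function(data, spec = binning_spec()) {
  schema <- dataset_schema(data)
  nms <- schema_names(schema)
  d <- length(nms)
  if (d < 2L) stop("association matrix needs at least 2 columns")
  m <- diag(1, d)
  dimnames(m) <- list(nms, nms)
  for (i in seq_len(d - 1L))
    for (j in (i + 1L):d)
      m[i, j] <- m[j, i] <- mixed_association(data[[nms[i]]], data[[nms[j]]], spec)
  structure(list(labels = nms, values = m), class = "sde_association")
}

#' Pairwise correlation difference between real and synthetic data
#'
#' `PCD = mean_i |Corr(X_real)_i - Corr(X_synth)_i|` over the n unique
#' upper-triangular entries of the two mixed-type association matrices. The
#' accompanying p-value is a paired two-sided t-test on the two vectors of n
#' association values (defined as 1 when every paired difference is zero,
#' and 0 when the differences are constant but nonzero).
#'
#' @param real,synth `sde_dataset`s sharing a schema with >= 2 columns.
#' @param spec A [binning_spec()].
#' @return A list with `pcd`, `pvalue`, and the two association matrices
#'   (`real_assoc`, `synth_assoc`).
#' @export
pcd <- function(real, synth, spec = binning_spec()) {
  check_shared_schema(real, synth)
  ar <- association_matrix(real, spec)
  as_ <- association_matrix(synth, spec)
  vr <- ar$values[upper.tri(ar$values)]
  vs <- as_$values[upper.tri(as_$values)]
  list(pcd = mean(abs(vr - vs)),
       pvalue = paired_pvalue(vr, vs),
       real_assoc = ar, synth_assoc = as_)
}

# Paired two-sided t-test p-value with defined degenerate cases.
paired_pvalue <- function(x, y) {
  d <- x - y
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0 || length(d) < 2L) return(0)
  stats::t.test(x, y, paired = TRUE)$p.value
}
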