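#' Marginal definitions for fixture columns
#'
#' Constructors for the per-column marginals a [fixture_spec()] accepts:
#' normal, lognormal and uniform numericals, and categoricals with given
#' label probabilities.
#'
#' @param mean,sd,meanlog,sdlog,min,max Distribution parameters.
#' @param labels Character vector of category labels.
#' @param probs Category probabilities (sum to 1).
#' @return A marginal definition list.
#' @name fixture_marginals
NULL

#' @rdname fixture_marginals
#' @export
marg_normal <- function(mean = 0, sd = 1)
  list(kind = "numerical", quantile = function(u) stats::qnorm(u, mean, sd))

#' @rdname fixture_marginals
#' @export
marg_lognormal <- function(meanlog = 0, sdlog = 1)
  list(kind = "numerical", quantile = function(u) stats::qlnorm(u, meanlog, sdlog))

#' @rdname fixture_marginals
#' @export
marg_uniform <- function(min = 0, max = 1)
  list(kind = "numerical", quantile = function(u) stats::qunif(u, min, max))

#' @rdname fixture_marginals
#' @export
marg_categorical <- function(labels, probs) {
  probs <- as.numeric(probs)
  stopifnot(length(labels) == length(probs), all(probs > 0))
  if (abs(sum(probs) - 1) > 1e-9) stop("category probabilities must sum to 1")
  list(kind = "categorical", labels = as.character(labels), probs = probs)
}

#' Fixture specification: a mixed-type table with known structure
#'
#' Defines the ground truth the fixture generator draws from: per-column
#' marginals tied together by a Gaussian copula with the given latent
#' correlation matrix (categorical columns are realized by thresholding
#' their latent coordinate at probability-matched cutpoints). Because the
#' latent structure is known exactly, every evaluator can be tested for
#' parameter recovery offline.
#'
#' @param marginals Named list of marginal definitions
#'   (see [fixture_marginals]).
#' @param latent_correlation Correlation matrix over the columns (symmetric,
#'   unit diagonal, positive semi-definite). Default: identity.
#' @param n_rows Number of records to draw.
#' @param seed Integer seed.
#' @return An object of class `sde_fixture_spec`.
#' @export
fixture_spec <- function(marginals, latent_correlation = NULL, n_rows, seed) {
  d <- length(marginals)
  stopifnot(d >= 1L, !is.null(names(marginals)), all(nzchar(names(marginals))))
  if (is.null(latent_correlation)) latent_correlation <- diag(d)
  latent_correlation <- as.matrix(latent_correlation)
  stopifnot(nrow(latent_correlation) == d, ncol(latent_correlation) == d)
  if (max(abs(latent_correlation - t(latent_correlation))) > 1e-12)
    stop("latent correlation must be symmetric")
  if (max(abs(diag(latent_correlation) - 1)) > 1e-12)
    stop("latent correlation must have a unit diagonal")
  if (min(eigen(latent_correlation, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("latent correlation must be positive semi-definite")
  structure(list(marginals = marginals, latent_correlation = latent_correlation,
                 n_rows = as.integer(n_rows), seed = as.integer(seed)),
            class = "sde_fixture_spec")
}

fixture_schema <- function(spec) {
  table_schema(lapply(names(spec$marginals), function(nm) {
    m <- spec$marginals[[nm]]
    if (m$kind == "categorical") column_schema(nm, "categorical", categories = m$labels)
    else column_schema(nm, "numerical")
  }))
}

#' Generate a fixture dataset
#'
#' Draws latent multivariate-normal rows under the spec's seed, then maps
#' each latent coordinate through its marginal's inverse CDF (categoricals
#' through cumulative-probability cutpoints). Deterministic under seed.
#'
#' @param spec An [fixture_spec()].
#' @return An `sde_dataset` of `spec$n_rows` records.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "sde_fixture_spec"))
  d <- length(spec$marginals)
  L <- chol_psd(spec$latent_correlation)
  z <- local_seed_eval(spec$seed,
                       matrix(stats::rnorm(spec$n_rows * d), ncol = d) %*% L)
  u <- stats::pnorm(z)
  out <- as.data.frame(lapply(seq_len(d), function(j) {
    m <- spec$marginals[[j]]
    if (m$kind == "categorical") {
      cut_u <- c(0, cumsum(m$probs)); cut_u[length(cut_u)] <- 1
      m$labels[findInterval(u[, j], cut_u, rightmost.closed = TRUE)]
    } else m$quantile(u[, j])
  }), optional = TRUE)
  names(out) <- names(spec$marginals)
  as_dataset(out, fixture_schema(spec))
}

# Upper Cholesky factor tolerant of a PSD (rank-deficient) correlation.
chol_psd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(v), length(v)))
}

#' Default mixed-type fixture specification
#'
#' A compact stand-in for a typical clinical table: five bounded numeric
#' attributes (two normals, a lognormal biomarker, a uniform score, a wider
#' normal) and three multi-level categoricals, linked by moderate latent
#' correlations (0.6 between the first two numerics, 0.4 between the first
#' numeric and the first categorical's latent coordinate, 0.3 between the
#' last two numerics).
#'
#' @param n_rows Number of records.
#' @param seed Integer seed.
#' @return An [fixture_spec()].
#' @export
default_fixture_spec <- function(n_rows, seed) {
  marginals <- list(
    age      = marg_normal(60, 12),
    biomarker = marg_lognormal(0, 0.5),
    bmi      = marg_normal(27, 4),
    score    = marg_uniform(0, 100),
    pressure = marg_normal(130, 18),
    sex      = marg_categorical(c("F", "M"), c(0.55, 0.45)),
    stage    = marg_categorical(c("I", "II", "III", "IV"), c(0.4, 0.3, 0.2, 0.1)),
    smoker   = marg_categorical(c("never", "former", "current"), c(0.5, 0.3, 0.2))
  )
  R <- diag(8)
  dimnames(R) <- list(names(marginals), names(marginals))
  R["age", "biomarker"] <- R["biomarker", "age"] <- 0.6
  R["age", "sex"] <- R["sex", "age"] <- 0.4
  R["score", "pressure"] <- R["pressure", "score"] <- 0.3
  fixture_spec(marginals, R, n_rows = n_rows, seed = seed)
}

#' Fit the Gaussian-copula baseline generator
#'
#' Stores each column's empirical marginal (sorted value table for numerics,
#' category frequencies for categoricals), transforms every column to normal
#' scores — numerics by rank, categoricals by a uniform jitter of the rank
#' inside each category's cumulative-probability block so the transform is
#' well defined for discrete marginals — and estimates the latent
#' correlation as the Pearson correlation of those scores, projected to the
#' nearest positive semi-definite matrix if needed. Constant columns get
#' zero correlation with everything.
#'
#' @param train An `sde_dataset` with at least 10 rows.
#' @param seed Integer seed for the categorical rank jitter. Default 0.
#' @param epsilon Optional privacy budget, recorded for interface parity
#'   with differentially private generators; this baseline does not use it.
#' @return An object of class `sde_generator` with `kind = "gaussian_copula"`.
#' @export
fit_gaussian_copula <- function(train, seed = 0L, epsilon = NULL) {
  schema <- dataset_schema(train)
  n <- nrow(train)
  if (n < 10L) stop("need at least 10 rows to fit")
  marginals <- fit_marginals(train, schema)
  z <- local_seed_eval(seed, {
    vapply(schema$columns, function(cs) {
      v <- train[[cs$name]]
      if (cs$kind == "numerical") {
        if (length(unique(v)) == 1L) return(rep(NA_real_, n))
        stats::qnorm(rank(v, ties.method = "average") / (n + 1))
      } else {
        freq <- marginals[[cs$name]]$probs
        cum <- c(0, cumsum(freq))
        idx <- match(v, marginals[[cs$name]]$labels)
        stats::qnorm(cum[idx] + stats::runif(n) * freq[idx])
      }
    }, numeric(n))
  })
  d <- ncol(z)
  R <- diag(d)
  ok <- !vapply(seq_len(d), function(j) anyNA(z[, j]), logical(1))
  if (sum(ok) >= 2L) R[ok, ok] <- stats::cor(z[, ok, drop = FALSE])
  R <- nearest_psd_correlation(R)
  structure(list(kind = "gaussian_copula", schema = schema,
                 marginals = marginals, latent_correlation = R,
                 epsilon = epsilon),
            class = "sde_generator")
}

fit_marginals <- function(train, schema) {
  out <- lapply(schema$columns, function(cs) {
    v <- train[[cs$name]]
    if (cs$kind == "numerical") list(kind = "numerical", values = sort(v))
    else {
      tab <- table(factor(v, levels = cs$categories))
      list(kind = "categorical", labels = cs$categories,
           probs = as.numeric(tab) / sum(tab))
    }
  })
  names(out) <- schema_names(schema)
  out
}

nearest_psd_correlation <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(R)
  v <- pmax(e$values, 1e-8)
  S <- e$vectors %*% diag(v) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(S)))
  R2 <- D %*% S %*% D
  dimnames(R2) <- dimnames(R)
  (R2 + t(R2)) / 2
}

#' Fit the nonparametric (empirical) copula baseline generator
#'
#' Stores the training table's pseudo-observations — each column's ranks
#' scaled to `rank/(n+1)` — together with the empirical marginal quantile
#' tables. Sampling resamples whole pseudo-observation rows (preserving all
#' cross-column rank dependence), perturbs each uniform by a small jitter of
#' half a rank width `1/(2n)`, and inverts through the empirical marginals.
#'
#' @inheritParams fit_gaussian_copula
#' @return An `sde_generator` with `kind = "npc"`.
#' @export
fit_npc <- function(train, seed = 0L, epsilon = NULL) {
  schema <- dataset_schema(train)
  n <- nrow(train)
  if (n < 10L) stop("need at least 10 rows to fit")
  marginals <- fit_marginals(train, schema)
  pseudo <- vapply(schema$columns, function(cs) {
    v <- train[[cs$name]]
    if (cs$kind == "numerical") rank(v, ties.method = "average") / (n + 1)
    else {
      freq <- marginals[[cs$name]]$probs
      cum <- c(0, cumsum(freq))
      idx <- match(v, marginals[[cs$name]]$labels)
      # category block midpoint; jitter happens at sampling time
      cum[idx] + freq[idx] / 2
    }
  }, numeric(n))
  structure(list(kind = "npc", schema = schema, marginals = marginals,
                 pseudo = pseudo, epsilon = epsilon),
            class = "sde_generator")
}

#' Sample synthetic records from a fitted baseline generator
#'
#' Gaussian copula: draws latent multivariate-normal rows under the fitted
#' correlation and inverts each coordinate through its empirical marginal.
#' NPC: resamples stored pseudo-observation rows with jitter `+/- 1/(2n)`
#' and inverts the same way. Output conforms to the training schema;
#' categorical values come only from the observed categories.
#'
#' @param model An `sde_generator` from [fit_gaussian_copula()] or
#'   [fit_npc()].
#' @param n Number of records to draw.
#' @param seed Integer seed.
#' @return An `sde_dataset`.
#' @export
generate_synthetic <- function(model, n, seed) {
  stopifnot(inherits(model, "sde_generator"), n >= 1L)
  schema <- model$schema
  d <- length(schema$columns)
  u <- if (model$kind == "gaussian_copula") {
    L <- chol_psd(model$latent_correlation)
    stats::pnorm(local_seed_eval(seed,
      matrix(stats::rnorm(n * d), ncol = d) %*% L))
  } else {
    n_train <- nrow(model$pseudo)
    local_seed_eval(seed, {
      rows <- sample.int(n_train, n, replace = TRUE)
      uu <- model$pseudo[rows, , drop = FALSE] +
        matrix(stats::runif(n * d, -1, 1) / (2 * n_train), ncol = d)
      pmin(pmax(uu, 1e-12), 1 - 1e-12)
    })
  }
  out <- as.data.frame(lapply(seq_len(d), function(j) {
    cs <- schema$columns[[j]]
    m <- model$marginals[[cs$name]]
    if (m$kind == "categorical") {
      cum <- c(0, cumsum(m$probs)); cum[length(cum)] <- 1
      m$labels[findInterval(u[, j], cum, rightmost.closed = TRUE)]
    } else {
      stats::quantile(m$values, probs = u[, j], type = 7, names = FALSE)
    }
  }), optional = TRUE)
  names(out) <- schema_names(schema)
  as_dataset(out, schema)
}
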