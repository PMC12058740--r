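#' Configuration for the privacy attack simulations
#'
#' @param n_attacks Number of attack attempts (predicates or target
#'   records); capped by the available data. Default 500, which keeps the
#'   binomial error on a success rate near +/- 0.02.
#' @param link_neighbors `k`, the neighbour-set size of the linkability
#'   attack. Default 1.
#' @param aux_split Optional list with character vectors `A` and `B`
#'   partitioning the columns into the two auxiliary-knowledge sets of the
#'   linkability attack; default alternating halves of the schema.
#' @param membership_quantile Quantile of the control nearest-synthetic
#'   distance distribution used as the membership threshold. Default 0.05.
#' @param numeric_tolerance Fraction of the real-train numeric range within
#'   which a numeric guess/interval counts as a hit. Default 0.05.
#' @param seed Integer seed; every attack is deterministic under it.
#' @return An object of class `sde_attack_config`.
#' @export
attack_config <- function(n_attacks = 500L, link_neighbors = 1L,
                          aux_split = NULL, membership_quantile = 0.05,
                          numeric_tolerance = 0.05, seed = 0L) {
  stopifnot(n_attacks >= 1L, link_neighbors >= 1L,
            membership_quantile > 0, membership_quantile < 1,
            numeric_tolerance > 0, numeric_tolerance < 1)
  structure(list(n_attacks = as.integer(n_attacks),
                 link_neighbors = as.integer(link_neighbors),
                 aux_split = aux_split,
                 membership_quantile = membership_quantile,
                 numeric_tolerance = numeric_tolerance,
                 seed = as.integer(seed)),
            class = "sde_attack_config")
}

#' Baseline-adjusted privacy risk
#'
#' The excess of the attack's success rate over the control baseline,
#' normalized by the attainable headroom:
#' `max(0, (attack_rate - control_rate) / (1 - control_rate))`, defined as 0
#' when the control rate is 1. The control baseline — the same attack run
#' against held-out real records — measures what an adversary gains from
#' population-level structure alone, so the adjusted risk isolates leakage
#' attributable to the synthetic data itself.
#'
#' @param attack_rate,control_rate Success fractions in `[0, 1]`.
#' @return A number in `[0, 1]`.
#' @export
adjusted_risk <- function(attack_rate, control_rate) {
  stopifnot(attack_rate >= 0, attack_rate <= 1,
            control_rate >= 0, control_rate <= 1)
  if (control_rate >= 1) return(0)
  max(0, (attack_rate - control_rate) / (1 - control_rate))
}

attack_result <- function(name, attack_rate, control_rate, n_attacks) {
  structure(list(attack_name = name,
                 attack_rate = attack_rate,
                 control_rate = control_rate,
                 adjusted_risk = adjusted_risk(attack_rate, control_rate),
                 n_attacks = as.integer(n_attacks)),
            class = "sde_attack_result")
}

#' @export
print.sde_attack_result <- function(x, ...) {
  cat(sprintf("<%s> attack %.3f | control %.3f | adjusted risk %.3f (n=%d)\n",
              x$attack_name, x$attack_rate, x$control_rate,
              x$adjusted_risk, x$n_attacks))
  invisible(x)
}

default_aux_split <- function(schema) {
  nms <- schema_names(schema)
  if (length(nms) < 2L) stop("linkability needs at least 2 columns")
  odd <- seq_along(nms) %% 2L == 1L
  list(A = nms[odd], B = nms[!odd])
}

# Evaluate predicates on a dataset; a predicate singles out when it matches
# exactly one record.
singles_out <- function(preds, data) {
  vapply(preds, function(p) {
    hits <- switch(p$op,
      "<=" = sum(data[[p$column]] <= p$value),
      ">=" = sum(data[[p$column]] >= p$value),
      "==" = sum(as.character(data[[p$column]]) == p$value),
      "in" = {
        m <- rep(TRUE, nrow(data))
        for (j in seq_along(p$columns)) {
          vj <- data[[p$columns[j]]]
          m <- m & if (p$kinds[j] == "numerical")
            vj >= p$lo[j] & vj <= p$hi[j]
          else as.character(vj) == p$cat[j]
        }
        sum(m)
      })
    hits == 1L
  }, logical(1))
}

#' Univariate singling-out attack
#'
#' Generates single-attribute predicates from the synthetic data — extreme
#' values (at or beyond the synthetic minimum/maximum and the 1%/99%
#' quantiles) for numeric attributes and the rarest synthetic categories
#' for categorical ones — and counts a predicate as a success when it
#' matches exactly one record of the attacked table. The attack rate is the
#' success fraction on the real training data, the control rate the success
#' fraction of the same predicates on the held-out control data.
#'
#' @param synth,train,control `sde_dataset`s sharing a schema; `control`
#'   must be disjoint from `train`.
#' @param cfg An [attack_config()].
#' @return An `sde_attack_result`.
#' @export
singling_out_univariate <- function(synth, train, control, cfg = attack_config()) {
  schema <- check_shared_schema(train, synth)
  preds <- list()
  for (cs in schema$columns) {
    v <- synth[[cs$name]]
    if (cs$kind == "numerical") {
      qs <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
      cand <- list(list(column = cs$name, op = "<=", value = min(v)),
                   list(column = cs$name, op = ">=", value = max(v)),
                   list(column = cs$name, op = "<=", value = qs[1]),
                   list(column = cs$name, op = ">=", value = qs[2]))
    } else {
      counts <- sort(table(factor(v, levels = cs$categories)))
      rare <- names(counts)[seq_len(min(4L, sum(counts > 0)))]
      cand <- lapply(rare, function(cat)
        list(column = cs$name, op = "==", value = cat))
    }
    preds <- c(preds, cand)
  }
  sig <- vapply(preds, function(p) paste(p$column, p$op, p$value), character(1))
  preds <- preds[!duplicated(sig)]
  if (length(preds) > cfg$n_attacks)
    preds <- local_seed_eval(cfg$seed,
                             preds[sample.int(length(preds), cfg$n_attacks)])
  attack_result("singling_out_univariate",
                mean(singles_out(preds, train)),
                mean(singles_out(preds, control)),
                length(preds))
}

#' Multivariate singling-out attack
#'
#' Samples synthetic records and turns each into a conjunction over all
#' attributes: closed intervals of `+/- numeric_tolerance * range` around
#' numeric values (ranges from the real training data) and equality for
#' categoricals. Success, evaluation and baseline adjustment as in the
#' univariate attack.
#'
#' @inheritParams singling_out_univariate
#' @return An `sde_attack_result`.
#' @export
singling_out_multivariate <- function(synth, train, control, cfg = attack_config()) {
  schema <- check_shared_schema(train, synth)
  ranges <- observed_ranges(train)
  n_pred <- min(cfg$n_attacks, nrow(synth))
  rows <- local_seed_eval(cfg$seed + 1L, sample.int(nrow(synth), n_pred))
  kinds <- schema_kinds(schema)
  nms <- schema_names(schema)
  preds <- lapply(rows, function(r) {
    lo <- hi <- numeric(length(nms)); cat <- character(length(nms))
    for (j in seq_along(nms)) {
      if (kinds[j] == "numerical") {
        w <- cfg$numeric_tolerance * diff(ranges[[nms[j]]])
        lo[j] <- synth[[nms[j]]][r] - w; hi[j] <- synth[[nms[j]]][r] + w
      } else cat[j] <- as.character(synth[[nms[j]]][r])
    }
    list(op = "in", columns = nms, kinds = kinds, lo = lo, hi = hi, cat = cat)
  })
  attack_result("singling_out_multivariate",
                mean(singles_out(preds, train)),
                mean(singles_out(preds, control)),
                n_pred)
}

k_nearest <- function(dmat, k) {
  # row-wise indices of the k smallest distances, ties by column order
  idx <- apply(dmat, 1L, function(r) order(r)[seq_len(k)])
  t(matrix(idx, nrow = k))
}

#' Linkability attack
#'
#' Models an adversary holding two disjoint attribute subsets (A and B) of
#' some real records. For each target record the k nearest synthetic
#' records are found using only the A columns and, independently, only the
#' B columns (Gower distance on the real-train ranges); the attack succeeds
#' when the two neighbour sets intersect — the synthetic data then links
#' the two halves of the record. Targets are drawn from the training data
#' for the attack rate and from the control data for the baseline.
#'
#' @inheritParams singling_out_univariate
#' @return An `sde_attack_result`.
#' @export
linkability <- function(synth, train, control, cfg = attack_config()) {
  schema <- check_shared_schema(train, synth)
  if (cfg$link_neighbors > nrow(synth))
    stop("link_neighbors exceeds the synthetic dataset size")
  aux <- if (is.null(cfg$aux_split)) default_aux_split(schema) else cfg$aux_split
  stopifnot(length(aux$A) >= 1L, length(aux$B) >= 1L)
  ranges <- observed_ranges(train)
  rate <- function(targets, off) {
    n_t <- min(cfg$n_attacks, nrow(targets))
    idx <- local_seed_eval(cfg$seed + off, sample.int(nrow(targets), n_t))
    tg <- subset_rows(targets, idx)
    nnA <- k_nearest(gower_matrix(tg, synth, schema, ranges, aux$A),
                     cfg$link_neighbors)
    nnB <- k_nearest(gower_matrix(tg, synth, schema, ranges, aux$B),
                     cfg$link_neighbors)
    hits <- vapply(seq_len(n_t), function(i)
      length(intersect(nnA[i, ], nnB[i, ])) > 0L, logical(1))
    c(mean(hits), n_t)
  }
  a <- rate(train, 2L); c0 <- rate(control, 3L)
  attack_result("linkability", a[1], c0[1], min(a[2], c0[2]))
}

#' Select rows of a dataset by index
#'
#' @param data An `sde_dataset`.
#' @param idx Integer row indices.
#' @return An `sde_dataset` with the selected rows, schema preserved.
#' @export
subset_rows <- function(data, idx)
  as_dataset(as.data.frame(data)[idx, , drop = FALSE], dataset_schema(data))

#' Membership-inference attack
#'
#' For each target record the Gower distance to its nearest synthetic
#' record is computed; the record is declared a training member when that
#' distance falls at or below a threshold, set as the `membership_quantile`
#' quantile of the control records' nearest-synthetic distances. The attack
#' rate is the true-positive rate on training records, the control rate the
#' false-positive rate on control records (approximately the quantile by
#' construction).
#'
#' @inheritParams singling_out_univariate
#' @return An `sde_attack_result`.
#' @export
membership_inference <- function(synth, train, control, cfg = attack_config()) {
  schema <- check_shared_schema(train, synth)
  if (nrow(synth) == 0L) stop("empty synthetic dataset")
  ranges <- observed_ranges(train)
  n_t <- min(cfg$n_attacks, nrow(train), nrow(control))
  it <- local_seed_eval(cfg$seed + 4L, sample.int(nrow(train), n_t))
  ic <- local_seed_eval(cfg$seed + 5L, sample.int(nrow(control), n_t))
  d_train <- apply(gower_matrix(subset_rows(train, it), synth, schema, ranges), 1L, min)
  d_ctrl <- apply(gower_matrix(subset_rows(control, ic), synth, schema, ranges), 1L, min)
  tau <- stats::quantile(d_ctrl, cfg$membership_quantile, names = FALSE, type = 7)
  attack_result("membership_inference",
                mean(d_train <= tau), mean(d_ctrl <= tau), n_t)
}

#' Attribute-inference attack
#'
#' The adversary knows every attribute of a target record except `secret`,
#' finds the nearest synthetic record on the known columns (Gower), and
#' guesses its secret value. A guess is correct when categorical values
#' match exactly or a numeric guess lies within
#' `numeric_tolerance * range` of the truth. [attribute_inference_all()]
#' runs the attack with every column as the secret and averages the
#' adjusted risks into a dataset-level summary.
#'
#' @inheritParams singling_out_univariate
#' @param secret Name of the attacked column.
#' @return An `sde_attack_result`; for [attribute_inference_all()] a list
#'   with `per_column` results and `mean_adjusted_risk`.
#' @export
attribute_inference <- function(synth, train, control, secret, cfg = attack_config()) {
  schema <- check_shared_schema(train, synth)
  if (!secret %in% schema_names(schema)) stop("secret column not in schema")
  known <- setdiff(schema_names(schema), secret)
  if (length(known) < 1L) stop("attribute inference needs at least 1 known column")
  ranges <- observed_ranges(train)
  cs <- schema_column(schema, secret)
  tol <- if (cs$kind == "numerical")
    cfg$numeric_tolerance * diff(ranges[[secret]]) else NA_real_
  rate <- function(targets, off) {
    n_t <- min(cfg$n_attacks, nrow(targets))
    idx <- local_seed_eval(cfg$seed + off, sample.int(nrow(targets), n_t))
    tg <- subset_rows(targets, idx)
    nn <- k_nearest(gower_matrix(tg, synth, schema, ranges, known), 1L)[, 1L]
    guess <- synth[[secret]][nn]
    truth <- tg[[secret]]
    ok <- if (cs$kind == "numerical") abs(guess - truth) <= tol
          else as.character(guess) == as.character(truth)
    c(mean(ok), n_t)
  }
  a <- rate(train, 6L); c0 <- rate(control, 7L)
  attack_result(paste0("attribute_inference:", secret), a[1], c0[1], min(a[2], c0[2]))
}

#' @rdname attribute_inference
#' @export
attribute_inference_all <- function(synth, train, control, cfg = attack_config()) {
  schema <- check_shared_schema(train, synth)
  per <- lapply(schema_names(schema), function(nm)
    attribute_inference(synth, train, control, nm, cfg))
  names(per) <- schema_names(schema)
  list(per_column = per,
       mean_adjusted_risk = mean(vapply(per, `[[`, numeric(1), "adjusted_risk")))
}

#' Run all five privacy attacks
#'
#' @inheritParams singling_out_univariate
#' @return Named list of `sde_attack_result`s: `singling_out_univariate`,
#'   `singling_out_multivariate`, `linkability`, `membership_inference`,
#'   `attribute_inference` (the dataset-level average over secrets).
#' @export
privacy_report <- function(synth, train, control, cfg = attack_config()) {
  ai <- attribute_inference_all(synth, train, control, cfg)
  ai_mean <- attack_result("attribute_inference",
    mean(vapply(ai$per_column, `[[`, numeric(1), "attack_rate")),
    mean(vapply(ai$per_column, `[[`, numeric(1), "control_rate")),
    min(vapply(ai$per_column, `[[`, integer(1), "n_attacks")))
  ai_mean$adjusted_risk <- ai$mean_adjusted_risk
  list(singling_out_univariate = singling_out_univariate(synth, train, control, cfg),
       singling_out_multivariate = singling_out_multivariate(synth, train, control, cfg),
       linkability = linkability(synth, train, control, cfg),
       membership_inference = membership_inference(synth, train, control, cfg),
       attribute_inference = ai_mean)
}
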