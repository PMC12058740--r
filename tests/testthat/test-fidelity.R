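test_that("hellinger distance has its fixed points and matches hand-evaluated values", {
  P <- discrete_distribution(c("a", "b"), c(0.5, 0.5))
  expect_equal(hellinger(P, P), 0)
  expect_equal(hellinger(discrete_distribution(1:2, c(1, 0)),
                         discrete_distribution(1:2, c(0, 1))), 1)
  Q <- discrete_distribution(c("a", "b"), c(0.98, 0.02))
  expect_equal(hellinger(P, Q), 0.4472, tolerance = 1e-4)
  expect_equal(hellinger(P, Q), hellinger(Q, P))
  expect_error(hellinger(P, discrete_distribution(c("a", "c"), c(0.5, 0.5))),
               "support")
})

test_that("hellinger agrees with a direct-summation oracle on random distribution pairs", {
  # oracle: Euclidean norm of the square-root vector difference over sqrt(2)
  oracle <- function(p, q) sqrt(sum((sqrt(p) - sqrt(q))^2)) / sqrt(2)
  set.seed(11)
  for (i in 1:200) {
    k <- sample(2:10, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    q <- rgamma(k, 1); q <- q / sum(q)
    h <- hellinger(discrete_distribution(seq_len(k), p),
                   discrete_distribution(seq_len(k), q))
    expect_equal(h, oracle(p, q), tolerance = 1e-12)
    expect_gte(h, 0); expect_lte(h, 1)
  }
})

test_that("discretization builds shared supports with union categories and equal-width bins", {
  cs <- column_schema("g", "categorical", categories = c("A", "B"))
  dd <- discretize_pair(c("A", "A", "A", "B"), c("A", "B"), cs)
  expect_equal(dd$P$probs, c(0.75, 0.25))
  expect_equal(dd$Q$probs, c(0.5, 0.5))

  # synthetic-only category joins the support with real probability 0
  dd2 <- discretize_pair(c("A", "B"), c("A", "B", "C", "C"), cs)
  expect_equal(dd2$P$support, c("A", "B", "C"))
  expect_equal(dd2$P$probs[3], 0)
  expect_equal(dd2$Q$probs[3], 0.5)

  # 20 equal-width bins over the combined range [0, 10]
  csn <- column_schema("v", "numerical")
  ddn <- discretize_pair(c(0, 2, 5), c(7, 10), csn, binning_spec(20))
  expect_length(ddn$P$support, 20L)
  expect_match(ddn$P$support[1], "\\[0,0\\.5\\)")
  expect_equal(sum(ddn$P$probs), 1)
  expect_error(discretize_pair(numeric(0), c(1), csn), "empty")
})

test_that("mean hellinger is zero for a copy and averages per-attribute distances", {
  d <- small_fixture(300, seed = 4)
  h <- mean_hellinger(d, d)
  expect_equal(unname(h$per_attribute), rep(0, 5))
  expect_equal(h$mean, 0)
  expect_equal(h$mean, mean(h$per_attribute))
  # independent draws from one spec stay close in distribution
  h2 <- mean_hellinger(small_fixture(5000, seed = 1), small_fixture(5000, seed = 2))
  expect_lt(h2$mean, 0.1)
})

test_that("mahalanobis depth peaks at the reference mean and decays along rays", {
  # reference with exactly zero mean and identity sample covariance
  ref <- sqrt(3 / 2) * rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(depth_values(rbind(c(0, 0)), ref), 1, tolerance = 1e-5)
  # squared distance 4 from the mean under identity covariance
  expect_equal(depth_values(rbind(c(2, 0)), ref), 0.2, tolerance = 1e-5)
  along <- depth_values(cbind(seq(0, 3, by = 0.5), 0), ref)
  expect_true(all(diff(along) < 0))
  expect_true(all(along > 0 & along <= 1))
  expect_error(depth_values(rbind(c(0, 0, 0)), ref), "dimension")
  expect_error(depth_values(rbind(c(0, 0)), ref[1:3, ]), "at least")
})

test_that("DD-plot R2 is 1 for identical datasets, permutation invariant, and clamps under mismatch", {
  d <- small_fixture(200, seed = 8)
  expect_equal(ddplot_r2(d, d)$r2, 1)

  perm <- subset_rows(d, rev(seq_len(nrow(d))))
  expect_equal(ddplot_r2(d, perm)$r2, 1)

  # heavy multivariate mismatch drives the identity-line R2 to the 0 clamp
  far <- as.data.frame(d)
  far$x1 <- far$x1 + 100
  far$x2 <- far$x2 * 50
  expect_equal(ddplot_r2(d, as_dataset(far, dataset_schema(d)))$r2, 0)

  # close distributions score high
  a <- small_fixture(2000, seed = 5)
  b <- small_fixture(2000, seed = 6)
  expect_gt(ddplot_r2(a, b)$r2, 0.9)
})

test_that("distinguishability AUC is seed-reproducible and detects a shifted column", {
  d <- small_fixture(400, seed = 13)
  half1 <- subset_rows(d, 1:200)
  half2 <- subset_rows(d, 201:400)
  a1 <- distinguishability_auc(half1, half2, seed = 99)
  a2 <- distinguishability_auc(half1, half2, seed = 99)
  expect_identical(a1, a2)
  expect_gt(a1, 0.3); expect_lt(a1, 0.7)

  shifted <- as.data.frame(half2)
  shifted$x1 <- shifted$x1 + 3 * sd(half1$x1)
  a3 <- distinguishability_auc(half1, as_dataset(shifted, dataset_schema(d)),
                               seed = 99)
  expect_gt(a3, 0.9)

  # swapping which dataset is called real leaves distinguishability unchanged
  a4 <- distinguishability_auc(half2, half1, seed = 99)
  expect_equal(abs(a4 - 0.5), abs(a1 - 0.5), tolerance = 0.06)
})

test_that("fidelity report collects all four metrics with their fixed points on a copy", {
  d <- small_fixture(250, seed = 17)
  rep <- fidelity_report(d, d, seed = 3)
  expect_equal(rep$hellinger_mean, 0)
  expect_equal(rep$pcd, 0)
  expect_equal(rep$pcd_pvalue, 1)
  expect_equal(rep$ddplot_r2, 1)
  expect_true(rep$auc_roc >= 0 && rep$auc_roc <= 1)
  expect_equal(nrow(rep$depth_pairs), 2L * nrow(d))
})
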