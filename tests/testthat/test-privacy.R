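test_that("baseline adjustment measures excess success over the control", {
  expect_equal(adjusted_risk(0.3, 0.3), 0)
  expect_equal(adjusted_risk(1, 0.4), 1)
  expect_equal(adjusted_risk(0.6, 0.2), 0.5)
  expect_equal(adjusted_risk(0.1, 0.5), 0)    # floored at zero
  expect_equal(adjusted_risk(1, 1), 0)        # defined 0 at saturated control
  expect_error(adjusted_risk(1.2, 0), "attack_rate")
})

test_that("univariate singling out cannot isolate records in a fully duplicated table", {
  dup <- toy_dataset(rep(c(1, 5, 9), each = 2), rep(c("A", "B", "A"), each = 2))
  ctrl <- toy_dataset(c(2, 6), c("B", "A"))
  synth <- toy_dataset(c(1, 5, 9, 2), c("A", "B", "A", "B"))
  res <- singling_out_univariate(synth, dup, ctrl, attack_config(seed = 1))
  expect_equal(res$attack_rate, 0)
  expect_equal(res$adjusted_risk, 0)
  expect_lte(res$n_attacks, 500L)
})

test_that("a synthetic extreme value unique to train singles it out there but not in control", {
  train <- toy_dataset(c(1, 2, 3, 99), c("A", "A", "B", "B"))
  ctrl <- toy_dataset(c(1.5, 2.5, 3.5), c("A", "B", "A"))
  synth <- toy_dataset(c(99, 2, 1), c("B", "A", "A"))
  res <- singling_out_univariate(synth, train, ctrl, attack_config(seed = 2))
  # the ">= 99" predicate matches exactly the one extreme train record
  expect_gt(res$attack_rate, 0)
  expect_gt(res$attack_rate, res$control_rate)
  expect_gt(res$adjusted_risk, 0)
})

test_that("multivariate singling out isolates a cloned unique record and weakens with tolerance", {
  train <- toy_dataset(c(1, 2, 50), c("A", "A", "B"))
  ctrl <- toy_dataset(c(1.2, 2.2), c("A", "A"))
  synth <- toy_dataset(c(50), c("B"))   # exact clone of the unique train record
  r1 <- singling_out_multivariate(synth, train, ctrl, attack_config(seed = 3))
  expect_equal(r1$attack_rate, 1)
  expect_equal(r1$adjusted_risk, 1)

  # widening the numeric tolerance can only weaken isolation
  rates <- vapply(c(0.01, 0.2, 0.8), function(tol) {
    singling_out_multivariate(synth, train, ctrl,
      attack_config(numeric_tolerance = tol, seed = 3))$attack_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))

  dup <- toy_dataset(rep(5, 6), rep("A", 6))
  r0 <- singling_out_multivariate(dup, dup, ctrl, attack_config(seed = 3))
  expect_equal(r0$adjusted_risk, 0)
})

test_that("linkability saturates for a leaked copy and degenerates when k covers all of synth", {
  d <- small_fixture(200, seed = 91)
  sp <- split_train_test(d, 0.8, seed = 1)
  cfg <- attack_config(n_attacks = 100, seed = 5)
  leaked <- linkability(sp$train, sp$train, sp$test, cfg)
  expect_gt(leaked$adjusted_risk, 0.9)

  cfg_all <- attack_config(n_attacks = 50, link_neighbors = nrow(sp$train), seed = 5)
  sat <- linkability(sp$train, sp$train, sp$test, cfg_all)
  expect_equal(sat$attack_rate, 1)
  expect_equal(sat$control_rate, 1)
  expect_equal(sat$adjusted_risk, 0)

  cfg_big <- attack_config(link_neighbors = nrow(sp$train) + 1L)
  expect_error(linkability(sp$train, sp$train, sp$test, cfg_big), "exceeds")
})

test_that("membership inference flags a leaked copy and calibrates its control rate", {
  d <- small_fixture(1200, seed = 101)
  sp <- split_train_test(d, 0.8, seed = 2)
  cfg <- attack_config(n_attacks = 200, membership_quantile = 0.05, seed = 7)
  leaked <- membership_inference(sp$train, sp$train, sp$test, cfg)
  expect_equal(leaked$attack_rate, 1)
  expect_gt(leaked$adjusted_risk, 0.9)
  # threshold set at the 5% control quantile keeps the false-positive rate near it
  expect_lte(leaked$control_rate, 0.1)

  indep <- small_fixture(960, seed = 555)
  free <- membership_inference(indep, sp$train, sp$test, cfg)
  expect_lt(free$adjusted_risk, 0.15)
})

test_that("attribute inference separates relationship knowledge from data leakage", {
  # secret deterministically equal to a known column everywhere: the
  # relationship predicts, so control matches attack and risk is ~0
  mk <- function(x) as_dataset(
    data.frame(known = x, secret = x, stringsAsFactors = FALSE),
    table_schema(list(
      column_schema("known", "categorical", categories = c("A", "B", "C")),
      column_schema("secret", "categorical", categories = c("A", "B", "C")))))
  set.seed(3)
  tr <- mk(sample(c("A", "B", "C"), 60, TRUE))
  ct <- mk(sample(c("A", "B", "C"), 30, TRUE))
  sy <- mk(sample(c("A", "B", "C"), 60, TRUE))
  rel <- attribute_inference(sy, tr, ct, "secret", attack_config(seed = 11))
  expect_equal(rel$attack_rate, 1)
  expect_equal(rel$control_rate, 1)
  expect_equal(rel$adjusted_risk, 0)

  # leaked copy with a pure-noise secret: only the copy can predict it
  d <- small_fixture(400, seed = 111)
  noise <- as.data.frame(d)
  set.seed(4); noise$secret <- runif(nrow(noise), 0, 100)
  schema2 <- table_schema(c(dataset_schema(d)$columns,
                            list(column_schema("secret", "numerical"))))
  full <- as_dataset(noise, schema2)
  sp <- split_train_test(full, 0.8, seed = 5)
  leak <- attribute_inference(sp$train, sp$train, sp$test, "secret",
                              attack_config(n_attacks = 150, seed = 12))
  expect_equal(leak$attack_rate, 1)
  expect_gt(leak$adjusted_risk, 0.8)

  # constant secret: trivially predictable everywhere, zero adjusted risk
  const <- as.data.frame(sp$train); const$secret <- 1
  constd <- as_dataset(const, schema2)
  ctl <- as.data.frame(sp$test); ctl$secret <- 1
  r0 <- attribute_inference(constd, constd, as_dataset(ctl, schema2), "secret",
                            attack_config(n_attacks = 50, seed = 13))
  expect_equal(r0$attack_rate, 1)
  expect_equal(r0$adjusted_risk, 0)

  expect_error(attribute_inference(sp$train, sp$train, sp$test, "nope",
                                   attack_config()), "not in schema")
})

test_that("attacks are deterministic under a fixed seed and rates stay in [0,1]", {
  d <- small_fixture(300, seed = 121)
  sp <- split_train_test(d, 0.8, seed = 6)
  synth <- small_fixture(240, seed = 122)
  cfg <- attack_config(n_attacks = 80, seed = 17)
  r1 <- privacy_report(synth, sp$train, sp$test, cfg)
  r2 <- privacy_report(synth, sp$train, sp$test, cfg)
  expect_identical(r1, r2)
  for (a in r1) {
    expect_gte(a$attack_rate, 0); expect_lte(a$attack_rate, 1)
    expect_gte(a$control_rate, 0); expect_lte(a$control_rate, 1)
    expect_gte(a$adjusted_risk, 0); expect_lte(a$adjusted_risk, 1)
  }
})

test_that("leak monotonicity: risks do not decrease as synth copies more of train", {
  d <- small_fixture(600, seed = 131)
  sp <- split_train_test(d, 0.8, seed = 7)
  n <- nrow(sp$train)
  risks <- function(f) {
    vals <- sapply(1:3, function(s) {
      indep <- generate_fixture(small_fixture_spec(n, seed = 1000 + s))
      n_copy <- round(f * n)
      synth <- if (n_copy == 0) indep
      else if (n_copy == n) sp$train
      else as_dataset(rbind(as.data.frame(sp$train)[seq_len(n_copy), ],
                            as.data.frame(indep)[seq_len(n - n_copy), ]),
                      dataset_schema(d))
      cfg <- attack_config(n_attacks = 100, seed = s)
      c(membership_inference(synth, sp$train, sp$test, cfg)$adjusted_risk,
        linkability(synth, sp$train, sp$test, cfg)$adjusted_risk)
    })
    rowMeans(vals)
  }
  r0 <- risks(0); r5 <- risks(0.5); r1 <- risks(1)
  expect_true(all(r5 >= r0 - 0.02))
  expect_true(all(r1 >= r5 - 0.02))
  expect_gt(r1[1], 0.9)
})
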