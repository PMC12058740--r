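test_that("load_table keeps complete rows, drops rows with missing cells, rejects bad numerics", {
  schema <- toy_schema()

  p1 <- write_temp_csv(c("num,cat", "1,A", "2,B", "3,A", "4,B", "5,A"))
  d1 <- load_table(p1, schema, quiet = TRUE)
  expect_equal(nrow(d1), 5L)
  expect_equal(attr(d1, "n_removed"), 0L)

  p2 <- write_temp_csv(c("num,cat", "1,A", ",B", "3,A", "4,", "5,A"))
  d2 <- load_table(p2, schema, quiet = TRUE)
  expect_equal(nrow(d2), 3L)
  expect_equal(attr(d2, "n_removed"), 2L)
  expect_equal(d2$num, c(1, 3, 5))

  p3 <- write_temp_csv(c("num,cat", "1,A", "abc,B"))
  expect_error(load_table(p3, schema, quiet = TRUE), "non-numeric")

  expect_error(load_table(file.path(tempdir(), "nope.csv"), schema), "cannot read")
  p4 <- write_temp_csv(c("other,cat", "1,A"))
  expect_error(load_table(p4, schema, quiet = TRUE), "header")
})

test_that("schema inference separates categoricals from numericals by type and cardinality", {
  df <- data.frame(sex = c("M", "F", "M", "F"),
                   code = c(0L, 1L, 2L, 1L),
                   val = as.numeric(1:4))
  sc <- infer_schema(df, category_threshold = 20L)
  kinds <- setNames(vapply(sc$columns, `[[`, character(1), "kind"),
                    vapply(sc$columns, `[[`, character(1), "name"))
  expect_equal(kinds[["sex"]], "categorical")
  expect_equal(sort(sc$columns[[1]]$categories), c("F", "M"))
  # 3 distinct integer values fall at or below the threshold
  expect_equal(kinds[["code"]], "categorical")

  many <- data.frame(v = seq(0, 1, length.out = 1000) + 0.0001)
  sc2 <- infer_schema(many)
  expect_equal(sc2$columns[[1]]$kind, "numerical")
  expect_equal(sc2$columns[[1]]$observed_range, range(many$v))

  expect_error(infer_schema(data.frame()), "empty")
})

test_that("train/test split is a seeded partition with floor-sized train set", {
  d <- small_fixture(10, seed = 3)
  sp <- split_train_test(d, 0.8, seed = 7)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$test), 2L)

  sp2 <- split_train_test(d, 0.8, seed = 7)
  expect_identical(as.data.frame(sp$train), as.data.frame(sp2$train))

  # partition property across a spread of sizes
  for (n in c(2L, 3L, 17L, 1540L, 38962L)) {
    base <- as_dataset(data.frame(id = as.numeric(seq_len(n)) + 0.5),
                       table_schema(list(column_schema("id", "numerical"))))
    s <- split_train_test(base, 0.8, seed = n)
    expect_equal(nrow(s$train), floor(0.8 * n))
    expect_equal(nrow(s$test), n - floor(0.8 * n))
    expect_setequal(c(s$train$id, s$test$id), base$id)
  }

  expect_error(split_train_test(small_fixture(2, 1), 1.0, seed = 1), "train_frac")
  one <- as_dataset(data.frame(id = 1.5),
                    table_schema(list(column_schema("id", "numerical"))))
  expect_error(split_train_test(one, 0.8, seed = 1), "at least 2 rows")
})

test_that("numeric encoding one-hot expands categoricals and standardizes with reference stats", {
  d <- as_dataset(
    data.frame(a = c(1, 2, 3, 4), b = c(10, 10, 10, 10),
               g = c("x", "y", "z", "x"), stringsAsFactors = FALSE),
    table_schema(list(column_schema("a", "numerical"),
                      column_schema("b", "numerical"),
                      column_schema("g", "categorical", categories = c("x", "y", "z")))))
  enc <- encode_numeric(d)
  expect_equal(ncol(enc$matrix), 2L + 3L)
  expect_equal(mean(enc$matrix[, "a"]), 0)
  expect_equal(sd(enc$matrix[, "a"]), 1)
  # constant numeric column encodes to all zeros
  expect_true(all(enc$matrix[, "b"] == 0))
  expect_equal(enc$matrix[, "g=x"], c(1, 0, 0, 1))

  # shared reference statistics give one common embedding
  other <- as_dataset(
    data.frame(a = c(2, 3), b = c(5, 6), g = c("y", "y"),
               stringsAsFactors = FALSE), dataset_schema(d))
  enc2 <- encode_numeric(other, reference = d)
  expect_identical(enc2$map, enc$map)
  expect_equal(enc2$matrix[, "a"], (c(2, 3) - mean(d$a)) / sd(d$a))
})

test_that("gower distance matches its defining formula and is a bounded symmetric dissimilarity", {
  schema <- toy_schema()
  a <- list(num = 2, cat = "A")
  b <- list(num = 7, cat = "A")
  # (|2-7|/10 + 0)/2 = 0.25
  expect_equal(gower_distance(a, b, schema), 0.25)
  expect_equal(gower_distance(a, a, schema), 0)
  expect_equal(gower_distance(list(num = 0, cat = "A"),
                              list(num = 10, cat = "B"), schema), 1)

  # property: symmetry and bounds over random record pairs
  set.seed(42)
  for (i in 1:50) {
    r1 <- list(num = runif(1, 0, 10), cat = sample(c("A", "B"), 1))
    r2 <- list(num = runif(1, 0, 10), cat = sample(c("A", "B"), 1))
    d12 <- gower_distance(r1, r2, schema)
    expect_equal(d12, gower_distance(r2, r1, schema))
    expect_gte(d12, 0); expect_lte(d12, 1)
    if (!identical(r1, r2)) expect_gt(gower_distance(r1, r2, schema), 0)
  }

  # matrix form agrees with the scalar form
  d <- toy_dataset(c(0, 5, 10), c("A", "B", "A"))
  m <- gower_matrix(d, d, schema)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m, t(m))
  expect_equal(m[1, 2],
               gower_distance(list(num = 0, cat = "A"),
                              list(num = 5, cat = "B"), schema))
})

test_that("a dataset survives a write/load round trip", {
  d <- small_fixture(50, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(d, path)
  d2 <- load_table(path, dataset_schema(d), quiet = TRUE)
  expect_identical(d2$c1, d$c1)
  expect_identical(d2$c2, d$c2)
  for (nm in c("x1", "x2", "x3"))
    expect_equal(d2[[nm]], d[[nm]], tolerance = 1e-12)
})
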