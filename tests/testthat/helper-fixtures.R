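# Small fixture specs shared across test files. All generation is seeded,
# so every test is deterministic.

# Compact 5-column spec with one strong latent pair (rho between x1 and x2).
small_fixture_spec <- function(n_rows, seed, rho = 0.8) {
  marg <- list(
    x1 = marg_normal(0, 1),
    x2 = marg_normal(5, 2),
    x3 = marg_lognormal(0, 0.4),
    c1 = marg_categorical(c("a", "b", "c"), c(0.5, 0.3, 0.2)),
    c2 = marg_categorical(c("u", "v"), c(0.6, 0.4))
  )
  R <- diag(5)
  R[1, 2] <- R[2, 1] <- rho
  fixture_spec(marg, R, n_rows = n_rows, seed = seed)
}

small_fixture <- function(n_rows, seed, rho = 0.8)
  generate_fixture(small_fixture_spec(n_rows, seed, rho))

# A tiny hand-written mixed table with a known schema.
toy_schema <- function() {
  table_schema(list(
    column_schema("num", "numerical", observed_range = c(0, 10)),
    column_schema("cat", "categorical", categories = c("A", "B"))
  ))
}

toy_dataset <- function(num, cat) {
  as_dataset(data.frame(num = num, cat = cat, stringsAsFactors = FALSE),
             toy_schema())
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
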