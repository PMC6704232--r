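test_that("clock constructs randomize the requested number of positions", {
  base <- random_rna(500, seed = 50)
  c0 <- generate_clock_construct(base, 0, seed = 1)
  expect_equal(c0$sequence, base)
  expect_length(c0$altered_positions, 0)

  c2 <- generate_clock_construct(base, 2, seed = 1)
  expect_length(c2$altered_positions, 10L)
  expect_false(anyDuplicated(c2$altered_positions) > 0)
  chars_b <- strsplit(base, "", fixed = TRUE)[[1]]
  chars_c <- strsplit(c2$sequence, "", fixed = TRUE)[[1]]
  untouched <- setdiff(seq_len(500), c2$altered_positions)
  expect_equal(chars_c[untouched], chars_b[untouched])

  expect_error(generate_clock_construct(base, 101), "percent")
  expect_equal(generate_clock_construct(base, 10, seed = 2)$name, "5MY")
})

test_that("Monte-Carlo identity of clock constructs matches the
           100 - 0.75 p expectation", {
  base <- random_rna(500, seed = 51)
  n_seeds <- 500
  for (p in c(10, 50, 100)) {
    ids <- vapply(seq_len(n_seeds), function(s) {
      cc <- generate_clock_construct(base, p, seed = 7000L + s)
      percent_identity(cc$sequence, base)
    }, numeric(1))
    expected <- 100 - 0.75 * p
    n_alt <- round(p * 500 / 100)
    se_mean <- 100 * sqrt(n_alt * 0.25 * 0.75) / 500 / sqrt(n_seeds)
    expect_lt(abs(mean(ids) - expected), 2.576 * se_mean)
  }
})

test_that("perfect-match hit counts decay monotonically with divergence", {
  base <- random_rna(500, seed = 52)
  db <- transcript_db(c(target = base))
  percents <- c(0, 2, 4, 6, 8, 10, 20, 40, 100)
  n_seeds <- 100
  means <- vapply(percents, function(p) {
    counts <- vapply(seq_len(n_seeds), function(s) {
      cc <- generate_clock_construct(base, p, seed = 9000L + 17L * s)
      h <- find_hits(enumerate_sirnas(c(x = cc$sequence)), db, 0)
      sum(h$orientation == "sense-match")
    }, numeric(1))
    mean(counts)
  }, numeric(1))
  expect_equal(means[1], 480)
  expect_equal(means[length(means)], 0)
  expect_true(all(diff(means) < 0))
})

test_that("window constructs copy the base only inside the window", {
  base <- random_rna(500, seed = 53)
  backbone <- random_rna(500, seed = 54)
  expect_equal(generate_window_construct(base, 1, 500, backbone), base)
  expect_equal(generate_window_construct(base, 1, 0, backbone), backbone)
  w <- generate_window_construct(base, 101, 100, backbone)
  expect_equal(substr(w, 101, 200), substr(base, 101, 200))
  expect_equal(substr(w, 1, 100), substr(backbone, 1, 100))
  expect_equal(substr(w, 201, 500), substr(backbone, 201, 500))
  expect_error(generate_window_construct(base, 1, 100, "ACGU"),
               "equal length")

  series <- window_series(base, backbone, 100)
  expect_equal(names(series),
               c("1-100W", "101-200W", "201-300W", "301-400W", "401-500W"))
})

test_that("percent identity is positional and behaves as expected", {
  a <- random_rna(100, seed = 55)
  expect_equal(percent_identity(a, a), 100)
  flipped <- paste0(if (substr(a, 1, 1) == "A") "C" else "A",
                    substr(a, 2, 100))
  expect_equal(percent_identity(a, flipped), 99)
  # identity to the reverse complement is ~25% in expectation
  ids <- vapply(1:200, function(s) {
    x <- random_rna(200, seed = 600 + s)
    percent_identity(x, reverse_complement(x))
  }, numeric(1))
  expect_lt(abs(mean(ids) - 25), 1.5)
})

test_that("pearson_r reproduces the published count/silencing correlations", {
  tab <- construct_evaluation()
  expect_equal(nrow(tab), 12L)
  r <- evaluate_counts(tab)
  expect_equal(round(unname(r), 2), c(-0.31, -0.37, -0.61))
  x <- c(1, 3, 2, 5)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 4)), "constant")
  expect_error(pearson_r(x, 1:3), "equal length")
})

test_that("construct series export writes FASTA plus manifest", {
  base <- random_rna(200, seed = 57)
  series <- clock_series(base, percents = c(0, 10, 100), seed = 3)
  out <- withr::local_tempdir()
  paths <- write_construct_series(series, base, out, prefix = "clock")
  db <- read_fasta(paths[["fasta"]])
  expect_equal(db$entries$id, names(series))
  expect_equal(db$entries$seq[1], base)
  manifest <- read.delim(paths[["manifest"]])
  expect_equal(manifest$percent_randomized, c(0, 10, 100))
  expect_equal(manifest$n_altered, c(0, 20, 200))
})
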