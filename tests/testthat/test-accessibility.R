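test_that("parameter validation enforces u <= span <= window and the
           threshold range", {
  expect_error(accessibility_params(u = 50, span_l = 40), "u <= span_l")
  expect_error(accessibility_params(span_l = 100, window_w = 80),
               "span_l <= window_w")
  expect_error(accessibility_params(threshold = 1.5), "threshold")
  p <- accessibility_params()
  expect_equal(c(p$u, p$span_l, p$window_w, p$threshold), c(8, 40, 80, 0.1))
})

test_that("a sequence without complementary pairs is fully accessible", {
  p <- partition_unpaired(strrep("A", 100))
  expect_true(all(is.na(p$lap[1:7])))
  expect_equal(p$lap[8:100], rep(1, 93))
  # ambiguous bases cannot pair either
  pn <- partition_unpaired(strrep("N", 40), accessibility_params(u = 4))
  expect_equal(pn$lap[4:40], rep(1, 37))
})

test_that("partition function equals exhaustive structure enumeration", {
  model <- fold_energy_model()
  cases <- list(
    list(seq = "AAAGGGGAAAACCCCAAA", u = 4, span = 18),   # strong hairpin
    list(seq = "GCGCGCGCGCGC", u = 3, span = 12),
    list(seq = random_rna(15, seed = 21), u = 4, span = 12),
    list(seq = random_rna(18, seed = 22), u = 8, span = 18),
    list(seq = random_rna(18, seed = 23), u = 4, span = 10),
    list(seq = random_rna(16, seed = 24), u = 5, span = 16))
  for (cs in cases) {
    params <- accessibility_params(u = cs$u, span_l = cs$span,
                                   window_w = max(cs$span, nchar(cs$seq)))
    got <- partition_unpaired(cs$seq, params, model)$lap
    want <- oracle_lap(cs$seq, cs$u, cs$span, model)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("stem stretches are less accessible than loop stretches", {
  hp <- "AAAGGGGAAAACCCCAAA" # 4-bp GC stem (pos 4-7/12-15), 4-nt loop
  params <- accessibility_params(u = 4, span_l = 18, window_w = 18)
  lap <- partition_unpaired(hp, params)$lap
  stem <- lap[7]   # stretch 4-7: entirely in the stem
  loop <- lap[11]  # stretch 8-11: the hairpin loop
  expect_lt(stem, 0.1)
  expect_gt(loop, 0.9)
  expect_lt(stem, loop)
})

test_that("with u equal to the sequence length the LAP is the open-chain
           probability 1/Z", {
  model <- fold_energy_model()
  s <- random_rna(14, seed = 31)
  params <- accessibility_params(u = 14, span_l = 14, window_w = 14)
  lap <- partition_unpaired(s, params, model)$lap
  expect_equal(sum(!is.na(lap)), 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  structs <- oracle_structures(chars, 14)
  z <- sum(vapply(structs, function(p) {
    exp(-oracle_energy(chars, p, model) / model$rt)
  }, numeric(1)))
  expect_equal(lap[14], 1 / z, tolerance = 1e-9)
})

test_that("longer stretches are never more accessible than contained
           sub-stretches", {
  # single folding window, so both stretch lengths share one ensemble
  s <- random_rna(70, seed = 33)
  p8 <- partition_unpaired(s, accessibility_params(u = 8))$lap
  p4 <- partition_unpaired(s, accessibility_params(u = 4))$lap
  for (i in 8:70) {
    subs <- p4[(i - 4):i]           # all 4-stretches inside the 8-stretch
    expect_true(all(p8[i] <= subs[!is.na(subs)] + 1e-12))
  }
})

test_that("profiles average per-window unpaired probabilities over all
           covering windows", {
  s <- random_rna(90, seed = 35)
  params <- accessibility_params(u = 8, span_l = 40, window_w = 80)
  lap <- partition_unpaired(s, params)$lap
  # recompute by folding each 80-nt window independently
  wins <- lapply(1:11, function(ws) {
    partition_unpaired(substr(s, ws, ws + 79), params)$lap
  })
  for (pos in c(8, 20, 45, 60, 83, 90)) {
    vals <- c()
    for (ws in 1:11) {
      local_pos <- pos - ws + 1L
      if (local_pos >= 8 && local_pos <= 80) {
        vals <- c(vals, wins[[ws]][local_pos])
      }
    }
    expect_equal(lap[pos], mean(vals), tolerance = 1e-12)
  }
})

test_that("raising the loop penalty shifts the ensemble toward the open
           chain", {
  # Pointwise monotonicity does not hold: suppressing multi-loop
  # structures can concentrate probability on one dominant stem, making
  # stem positions *less* accessible. The ensemble-level effects below do
  # hold: mean accessibility rises, and a prohibitive penalty leaves only
  # the open chain.
  s <- random_rna(60, seed = 36)
  params <- accessibility_params(u = 6, span_l = 40, window_w = 60)
  lo <- partition_unpaired(s, params, fold_energy_model(loop_penalty = 3))
  hi <- partition_unpaired(s, params, fold_energy_model(loop_penalty = 6))
  open <- partition_unpaired(s, params, fold_energy_model(loop_penalty = 80))
  ok <- !is.na(lo$lap)
  expect_true(all(lo$lap[ok] >= 0 & lo$lap[ok] <= 1))
  expect_gt(mean(hi$lap[ok]), mean(lo$lap[ok]))
  expect_equal(open$lap[ok], rep(1, sum(ok)), tolerance = 1e-6)
})

test_that("site accessibility is the maximum LAP over the site", {
  s <- random_rna(100, seed = 37)
  prof <- partition_unpaired(s)
  v <- site_accessibility(prof, 10, 21)
  expect_equal(v, max(prof$lap[10:30], na.rm = TRUE))
  expect_error(site_accessibility(prof, 85, 21), "outside profile bounds")
  expect_error(partition_unpaired("ACG"), "shorter than")
})
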