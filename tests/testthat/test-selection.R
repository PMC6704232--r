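fake_profile <- function(lap, id = "t") {
  structure(list(transcript_id = id, lap = lap,
                 params = accessibility_params()),
            class = "accessibility_profile")
}

test_that("HS passes when either strand-selection rule favors the
           antisense strand", {
  model <- nn_model()
  # antisense 5' = A: the sequence rule favors the antisense strand
  d1 <- enumerate_sirnas(c(x = paste0("GCG", random_rna(15, seed = 1), "CGU")))
  v1 <- strand_selection(d1, model)
  expect_equal(substr(d1$antisense, 1, 1), "A")
  expect_true(classify_hs(v1))

  # antisense 5' = G, sense 5' = U, delta < 0: both rules favor sense
  d2 <- data.frame(trigger_id = "x", start = 1L,
                   sense = paste0("UUA", random_rna(15, seed = 2), "GCC"),
                   stringsAsFactors = FALSE)
  d2$antisense <- reverse_complement(d2$sense)
  v2 <- strand_selection(d2, model)
  expect_equal(substr(d2$antisense, 1, 1), "G")
  expect_true(v2$delta_mfe < 0)
  expect_false(classify_hs(v2))
  expect_equal(v2$predicted_guide, "sense")
})

test_that("HE is the strict conjunction of strand rules and accessibility", {
  model <- nn_model()
  params <- accessibility_params()
  # strongly asymmetric duplex: antisense 5'-UA (weak), sense 5'-GC (strong)
  d <- data.frame(trigger_id = "x", start = 1L,
                  sense = paste0("GCG", random_rna(15, seed = 3), "CUA"),
                  stringsAsFactors = FALSE)
  d$antisense <- reverse_complement(d$sense)
  v <- strand_selection(d, model)
  expect_true(v$sequence_rule_pass && v$strict_thermo_pass)
  hit <- list(position = 5L, orientation = "sense-match",
              transcript_id = "t")

  open <- fake_profile(c(rep(NA, 7), rep(1, 93)))
  closed <- fake_profile(c(rep(NA, 7), rep(0.05, 93)))

  ev <- classify_he(v, hit, open, params, k = 21)
  expect_true(ev$he_pass && ev$hs_pass)
  expect_length(ev$reasons, 0)

  ev2 <- classify_he(v, hit, closed, params, k = 21)
  expect_false(ev2$he_pass)
  expect_true(ev2$hs_pass)
  expect_equal(ev2$reasons, "accessibility")
  expect_lt(ev2$accessibility_value, 0.1)

  # antisense-match hits can never be HE on that transcript
  ev3 <- classify_he(v, list(position = 5L, orientation = "antisense-match"),
                     open, params, k = 21)
  expect_false(ev3$he_pass)
  expect_equal(ev3$reasons, "orientation")
})

test_that("sub-threshold end asymmetry fails HE but not HS", {
  model <- nn_model()
  set.seed(6)
  found <- FALSE
  for (i in 1:200) {
    d <- enumerate_sirnas(c(x = random_rna(21)))
    v <- strand_selection(d, model)
    if (v$sequence_rule_pass && v$delta_mfe > 0 && v$delta_mfe <= 1) {
      found <- TRUE
      ev <- classify_he(v, list(position = 1L, orientation = "sense-match",
                                transcript_id = "t"),
                        fake_profile(c(rep(NA, 7), rep(1, 50))),
                        accessibility_params(), k = 21)
      expect_true(ev$hs_pass)
      expect_false(ev$he_pass)
      expect_true("strict_thermo" %in% ev$reasons)
      break
    }
  }
  expect_true(found)
})

test_that("HE implies HS over random duplex/profile combinations", {
  model <- nn_model()
  params <- accessibility_params()
  set.seed(7)
  d <- enumerate_sirnas(c(x = random_rna(120)))
  v <- strand_selection(d, model)
  lap <- c(rep(NA, 7), runif(113))
  prof <- fake_profile(lap)
  for (i in seq_len(nrow(d))) {
    ev <- classify_he(v[i, ], list(position = i, orientation = "sense-match",
                                   transcript_id = "t"),
                      prof, params, k = 21)
    if (ev$he_pass) expect_true(ev$hs_pass)
  }
})
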