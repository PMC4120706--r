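test_that("condition tables reproduce the three experiment designs", {
  e1 <- build_condition_table("exp1")
  expect_equal(nrow(e1), 11)
  expect_equal(e1$target_scale_x, seq(1, 0, by = -0.1))
  expect_true(all(e1$left == "F1,F2,F3" & e1$right == "F1,F2,F3"))
  expect_true(all(is.na(e1$f2c_kind)))

  e2 <- build_condition_table("exp2")
  expect_equal(nrow(e2), 7)
  c4 <- e2[e2$id == "C4", ]
  expect_equal(c4$left, "F1,F2C")
  expect_equal(c4$right, "F2,F3")
  expect_equal(c4$f2c_kind, "inverted")
  expect_equal(c4$f2c_scale_x, 0.5)
  expect_equal(e2[e2$id == "C1", ]$right, "F3")
  expect_true(is.na(e2[e2$id == "C7", ]$f2c_kind))
  expect_equal(e2[e2$id == "C7", ]$left, "F1")
  expect_equal(e2$f2c_scale_x[2:6], seq(0, 1, by = 0.25))
  expect_true(all(e2$target_scale_x == 0.5))

  e3 <- build_condition_table("exp3")
  expect_equal(nrow(e3), 8)
  expect_equal(e3[e3$id == "C1", ]$left, "")
  expect_equal(e3[e3$id == "C1", ]$right, "F2,F3")
  expect_equal(e3$f2c_kind[2:6], rep("triangle", 5))
  expect_equal(e3$f2c_scale_x[2:6], seq(0, 1, by = 0.25))
  c7 <- e3[e3$id == "C7", ]
  expect_equal(c7$f2c_kind, "inverted")
  expect_equal(c7$f2c_scale_x, 1)
  expect_equal(e3[e3$id == "C8", ]$left, "F1")
  expect_error(build_condition_table("exp4"))
})

test_that("sentence allocation rotates cyclically and exhausts all conditions", {
  ids <- sprintf("s%02d", 1:42)
  a0 <- allocate_sentences(ids, 7, rotation = 0)
  expect_true(all(lengths(a0) == 6))
  expect_setequal(unlist(a0), ids)

  # rotation by the condition count reproduces rotation 0
  expect_identical(allocate_sentences(ids, 7, 7), a0)

  # rotation 1 moves each block to the next condition index
  a1 <- allocate_sentences(ids, 7, 1)
  expect_identical(a1[[2]], a0[[1]])
  expect_identical(a1[[1]], a0[[7]])

  # across a full rotation cycle every sentence meets every condition once
  seen <- matrix(0L, nrow = 42, ncol = 7, dimnames = list(ids, NULL))
  for (rot in 0:6) {
    a <- allocate_sentences(ids, 7, rot)
    for (cond in 1:7) seen[a[[cond]], cond] <- seen[a[[cond]], cond] + 1L
  }
  expect_true(all(seen == 1L))

  expect_error(allocate_sentences(ids[1:40], 7), "divisible")
})

test_that("competitor kinds match their defining constructions", {
  n <- 1000
  fp <- 0.001
  f1 <- formant_track(rep(450, n), frame_period = fp, label = "F1")
  f2 <- log_sinusoid_track(1500, n_cycles = 2, duration = 1, depth = 0.25)
  f2$amps <- c(rep(3, n / 2), rep(4, n / 2))
  g <- geometric_mean(f2)

  const <- make_competitor(f2, f1, competitor_spec("constant"))
  expect_equal(const$freqs, rep(g, n), tolerance = 1e-9)
  expect_equal(const$amps, rep(sqrt(12.5), n))

  inv <- make_competitor(f2, f1, competitor_spec("inverted", 1))
  expect_equal(inv$freqs, g^2 / f2$freqs, tolerance = 1e-9)

  # triangle on a noiseless 2-cycle log-sinusoid: matched period and range
  tri <- make_competitor(f2, f1, competitor_spec("triangle", 1,
                                                 rng_seed = 5))
  expect_equal(max(log(tri$freqs)) - min(log(tri$freqs)),
               max(log(f2$freqs)) - min(log(f2$freqs)),
               tolerance = 1e-3)   # peak sampled within frame quantization
  sm <- block_smooth(f2$freqs, 40)
  expect_equal(estimate_cycles(sm, g, 1)$period_T, 0.5)

  # scale 0: inverted, triangle and constant all collapse to g
  inv0 <- make_competitor(f2, f1, competitor_spec("inverted", 0))
  tri0 <- make_competitor(f2, f1, competitor_spec("triangle", 0,
                                                  rng_seed = 5))
  expect_equal(inv0$freqs, rep(g, n), tolerance = 1e-9)
  expect_equal(tri0$freqs, rep(g, n), tolerance = 1e-9)

  # inversion and depth scaling commute about the shared pivot
  a <- scale_depth(invert_about_gmean(f2), 0.6)
  b <- invert_about_gmean(scale_depth(f2, 0.6))
  expect_equal(a$freqs, b$freqs, tolerance = 1e-9)
})

test_that("separation violations raise a structured error naming the worst frame", {
  n <- 500
  f2 <- formant_track(rep(1000, n), frame_period = 0.001, label = "F2")
  f1_close <- formant_track(rep(980, n), frame_period = 0.001,
                            label = "F1")
  expect_error(make_competitor(f2, f1_close, competitor_spec("constant")),
               class = "f2c_separation_error")
  # triangle redraw cannot rescue an always-violating geometry
  expect_error(
    make_competitor(f2, f1_close,
                    competitor_spec("triangle", 0.1, rng_seed = 1,
                                    max_phase_redraws = 5)),
    class = "f2c_separation_error")
})

test_that("triangle competitors keep 80 Hz from F1, redrawing the phase when needed", {
  # F1 placed so some triangle phases violate the constraint but others pass
  n <- 1000
  f2 <- log_sinusoid_track(1200, 3, 1, depth = 0.4)
  f1 <- formant_track(1200 * exp(-0.4) - 80 + 40 *
                        sin(2 * pi * 3 * (1:n) / n),
                      frame_period = 0.001, label = "F1")
  hits <- 0
  for (seed in 1:20) {
    comp <- tryCatch(
      make_competitor(f2, f1, competitor_spec("triangle", 1,
                                              rng_seed = seed)),
      f2c_separation_error = function(e) NULL)
    if (!is.null(comp)) {
      hits <- hits + 1
      expect_length(check_min_separation(comp, f1, 80), 0)
    }
  }
  expect_gt(hits, 0)
})

test_that("stimulus assembly routes formants per condition and is deterministic", {
  sen <- make_tracks(synthetic_sentence_spec(duration = 0.7, rng_seed = 31),
                     id = "s1")
  e2 <- build_condition_table("exp2")
  ref <- build_stimulus(sen, e2[e2$id == "C7", ], rng_seed = 9)
  expect_equal(ref$meta$left_formants, "F1")
  expect_equal(ref$meta$right_formants, c("F2", "F3"))

  e3 <- build_condition_table("exp3")
  ctrl <- build_stimulus(sen, e3[e3$id == "C1", ], rng_seed = 9)
  expect_equal(max(abs(ctrl$left)), 0)
  expect_gt(max(abs(ctrl$right)), 0)

  a <- build_stimulus(sen, e3[e3$id == "C4", ], rng_seed = 9)
  b <- build_stimulus(sen, e3[e3$id == "C4", ], rng_seed = 9)
  expect_identical(a$left, b$left)
  expect_identical(a$right, b$right)
})

test_that("corpus-wide separation audit reports per-competitor minima", {
  corpus <- make_corpus(4, base_seed = 3,
                        spec = synthetic_sentence_spec(duration = 0.8))
  audit <- competitor_separation_audit(corpus, base_seed = 3)
  expect_equal(nrow(audit), 4 * 3 * 5)
  expect_true(all(audit$min_gap_hz >= 80))
  expect_true(all(audit$n_redraws >= 0))
})
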