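small_optics <- function(...) {
  optics_config(sensor = c(96L, 72L), ring_scale = 108,
                frames_per_transit = 10, ...)
}

test_that("first-ring radius decreases strictly with particle diameter", {
  opt <- small_optics()
  radii <- pattern_radius(c(9, 12, 16, 20), opt)
  expect_true(all(diff(radii) < 0))
  expect_error(pattern_radius(0, opt), "positive")
  # explicit pattern_scale table overrides and must be decreasing
  opt2 <- optics_config(sensor = c(96L, 72L),
                        pattern_scale = c("9" = 12, "20" = 5))
  expect_equal(pattern_radius(9, opt2), 12)
  expect_error(optics_config(pattern_scale = c("9" = 5, "20" = 12)),
               "decreasing")
})

test_that("rendered patterns place the first dark ring at the nominal radius", {
  opt <- small_optics(travel_fraction = 0, breathing = 0,
                      sample_jitter_sd = 0, amp_jitter_sd = 0)
  for (diam in c(9, 20)) {
    fr <- render_transit(diam, opt, seed = 1)$frames[[5]] # near peak
    cy <- (72 - 1) / 2; cx <- (96 - 1) / 2
    r <- sqrt(outer(((seq_len(72) - 1) - cy)^2,
                    ((seq_len(96) - 1) - cx)^2, "+"))
    prof <- tapply(as.vector(fr), round(as.vector(r)), mean)
    radii <- as.numeric(names(prof))
    inner <- radii <= 1.6 * pattern_radius(diam, opt)
    first_min <- radii[inner][which.min(prof[inner])]
    expect_lt(abs(first_min - pattern_radius(diam, opt)), 1.5)
  }
  # size ordering of the dark-ring radius: 9 um wider than 20 um
  expect_gt(pattern_radius(9, opt), pattern_radius(20, opt))
})

test_that("centred drift-free frames are left-right symmetric", {
  opt <- small_optics(travel_fraction = 0, breathing = 0,
                      sample_jitter_sd = 0, amp_jitter_sd = 0)
  fr <- render_transit(12, opt, seed = 1)$frames[[5]]
  expect_equal(fr, fr[, ncol(fr):1], tolerance = 1e-10)
})

test_that("transit rendering is deterministic in its seed and drift sample", {
  opt <- small_optics()
  drift <- draw_drift(drift_config(), seed = 3)
  a <- render_transit(16, opt, drift, seed = 7)
  b <- render_transit(16, opt, drift, seed = 7)
  expect_identical(a, b)
  c_ <- render_transit(16, opt, drift, seed = 8)
  expect_false(identical(a$frames[[5]], c_$frames[[5]]))
  # drift gain scales the pattern above background
  up <- draw_drift(drift_config(gain_sd = 0), seed = 1)
  up$gain <- 2
  hi <- render_transit(16, opt, up, seed = 7)$frames[[5]]
  lo <- render_transit(16, opt, seed = 7)$frames[[5]]
  expect_gt(max(hi), max(lo))
})

test_that("the diffuser redistributes energy and widens with coarser grit", {
  opt <- small_optics()
  tr <- render_transit(9, opt, seed = 2)
  expect_identical(apply_diffuser(tr, diffuser_config("none"))$frames,
                   tr$frames)
  widths <- sapply(c("120", "600", "1500"), function(g) {
    out <- apply_diffuser(tr, diffuser_config(g, seed = 5))
    # energy redistribution, not absorption
    expect_equal(sum(out$frames[[5]]), sum(tr$frames[[5]]),
                 tolerance = 0.01)
    pattern_second_moment(out$frames[[5]])
  })
  expect_true(widths["120"] > widths["600"])
  expect_true(widths["600"] > widths["1500"])
  # config invariant: envelope width decreases with grit number
  expect_true(diffuser_config("120")$envelope_sigma >
                diffuser_config("600")$envelope_sigma)
  expect_true(diffuser_config("600")$envelope_sigma >
                diffuser_config("1500")$envelope_sigma)
})

test_that("constant intensity with no noise produces no events", {
  frames <- replicate(4, matrix(0.3, 10, 12), simplify = FALSE)
  ev <- simulate_dvs(frames, c(0, 100, 200, 300),
                     sensor_config(noise_rate = 0), seed = 1)
  expect_equal(nrow(ev), 0)
  expect_error(simulate_dvs(frames, c(0, 100, 100, 300),
                            sensor_config()), "strictly increasing")
  expect_error(simulate_dvs(frames[1], c(0), sensor_config()), "2 frames")
})

test_that("a 2.5-threshold step emits exactly two positive events", {
  sen <- sensor_config(contrast_threshold = 0.15, noise_rate = 0,
                       refractory_us = 0)
  i0 <- 0.2
  i1 <- exp(log(i0 + sen$log_eps) + 2.5 * 0.15) - sen$log_eps
  frames <- list(matrix(i0, 4, 4),
                 `[<-`(matrix(i0, 4, 4), 2, 3, i1))
  ev <- simulate_dvs(frames, c(0, 100), sen, seed = 1)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$p == 1))
  expect_true(all(ev$x == 2 & ev$y == 1)) # 0-based (x=2, y=1)
  expect_true(all(diff(ev$t) >= 0))
})

test_that("symmetric brighten-then-dim emits equal counts of each polarity", {
  sen <- sensor_config(noise_rate = 0, refractory_us = 0)
  up <- matrix(0.1, 5, 5); up[3, 3] <- 1.9
  frames <- list(matrix(0.1, 5, 5), up, matrix(0.1, 5, 5))
  ev <- simulate_dvs(frames, c(0, 100, 200), sen, seed = 1)
  expect_gt(nrow(ev), 0)
  expect_equal(sum(ev$p == 1), sum(ev$p == -1))
})

test_that("signed crossing counts on monotone ramps follow the closed form", {
  sen <- sensor_config(contrast_threshold = 0.15, noise_rate = 0,
                       refractory_us = 0)
  for (seed in 1:100) {
    r <- withr::with_seed(seed, {
      list(i0 = runif(1, 0.05, 0.5), span = runif(1, 0.1, 3),
           n = sample(3:8, 1), up = runif(1) < 0.5)
    })
    l0 <- log(r$i0 + sen$log_eps)
    l1 <- l0 + if (r$up) r$span else -r$span
    levels <- seq(l0, l1, length.out = r$n)
    frames <- lapply(levels, function(l) {
      matrix(exp(l) - sen$log_eps, 2, 2)
    })
    ev <- simulate_dvs(frames, seq(0, by = 50, length.out = r$n), sen,
                       seed = seed)
    per_pixel <- floor(r$span / 0.15 + 1e-9)
    signed <- sum(ev$p)
    expect_equal(abs(signed), 4 * per_pixel) # 4 pixels
    expect_equal(sign(signed), if (per_pixel == 0) 0
                 else if (r$up) 1 else -1)
    expect_equal(nrow(ev), 4 * per_pixel) # monotone: single polarity
  }
})

test_that("the refractory period suppresses same-pixel event pile-up", {
  sen0 <- sensor_config(noise_rate = 0, refractory_us = 0)
  sen <- sensor_config(noise_rate = 0, refractory_us = 200)
  lvl <- exp(log(0.1 + sen$log_eps) + c(0, 1, 2, 3) * 0.15) - sen$log_eps
  frames <- lapply(lvl, function(v) matrix(v, 2, 2))
  free <- simulate_dvs(frames, c(0, 100, 200, 300), sen0, seed = 1)
  damped <- simulate_dvs(frames, c(0, 100, 200, 300), sen, seed = 1)
  expect_lt(nrow(damped), nrow(free))
  for (pix in split(damped$t, paste(damped$x, damped$y))) {
    if (length(pix) > 1) expect_true(all(diff(sort(pix)) >= 200))
  }
})

test_that("dataset generation writes the documented layout reproducibly", {
  cfg <- demo_config(master_seed = 3L, n_sessions = 2L,
                     samples_per_class_session = 2L)
  d1 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, d1)
  expect_equal(nrow(m1), 4 * 2 * 2)
  expect_true(all(file.exists(file.path(d1, m1$file))))
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  expect_true(file.exists(file.path(d1, "config.yml")))
  # reproducibility: same master seed, byte-identical outputs
  d2 <- withr::local_tempdir()
  m2 <- generate_dataset(cfg, d2)
  expect_equal(m1$file, m2$file)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(readLines(file.path(d1, m1$file[5])),
                   readLines(file.path(d2, m2$file[5])))
  # manifest loads back with sensor dims recovered from the config
  lm <- load_manifest(d1)
  expect_equal(attr(lm, "sensor_dims"), cfg$optics$sensor)
  expect_equal(nrow(lm), nrow(m1))
})

test_that("class-correlated and shared drift differ as documented", {
  dc <- drift_config(class_correlated = TRUE)
  a <- draw_drift(dc, derive_seed(1, "drift", "A", 1))
  b <- draw_drift(dc, derive_seed(1, "drift", "B", 1))
  expect_false(identical(a, b)) # per (class, session)
  expect_identical(draw_drift(dc, derive_seed(1, "drift", "A", 1)), a)
})

test_that("simulation configs round-trip through the YAML file", {
  cfg <- demo_config(master_seed = 9L, n_sessions = 3L,
                     samples_per_class_session = 4L,
                     diffuser = diffuser_config("600", seed = 2))
  path <- withr::local_tempfile(fileext = ".yml")
  write_simulation_config(cfg, path)
  back <- read_simulation_config(path)
  expect_equal(back$classes, cfg$classes)
  expect_equal(back$optics$sensor, cfg$optics$sensor)
  expect_equal(back$diffuser$grit, "600")
  expect_equal(back$drift$gain_sd, cfg$drift$gain_sd)
  expect_equal(back$master_seed, 9L)
})

test_that("derived seeds are deterministic, distinct and 32-bit safe", {
  s1 <- derive_seed(1, "a", 1)
  expect_identical(s1, derive_seed(1, "a", 1))
  expect_false(s1 == derive_seed(1, "a", 2))
  expect_false(s1 == derive_seed(2, "a", 1))
  many <- vapply(1:500, function(i) derive_seed(7, "x", i), integer(1))
  expect_lt(max(many), 2^31)
  expect_gt(length(unique(many)), 495) # collisions essentially absent
})
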