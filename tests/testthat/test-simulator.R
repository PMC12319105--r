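test_that("empty scene gives an all-zero stack", {
  plan <- scene_plan(list(), background_model(0), tiny_cfg(16L, 10L),
                     rng_seed = 1, warm_pixel_fraction = 0, base_dark_rate = 0)
  st <- simulate_stack(plan)
  expect_true(all(st$frames == 0L))
  expect_equal(dim(st$frames), c(16, 16, 20))
  expect_equal(st$gate_index, rep(c(0L, 1L), 10))
})

test_that("simulated gate ratio matches exp(-T/tau)", {
  plan <- one_emitter_plan(tau = 2.1, S = 1000, seed = 2, side = 32L,
                           n_pairs = 500L, T_ns = 2.5)
  st <- simulate_stack(plan)
  q <- st$cfg$bit_depth
  # box-summed, pile-up-corrected counts around the emitter
  rows <- 14:18; cols <- 14:18
  g0 <- which(st$gate_index == 0L); g1 <- which(st$gate_index == 1L)
  sum_box <- function(fs) vapply(fs, function(f)
    sum(pileup_correct(st$frames[rows, cols, f], q, "censor"), na.rm = TRUE),
    numeric(1))
  ratio <- mean(sum_box(g1)) / mean(sum_box(g0))
  expect_equal(ratio, exp(-2.5 / 2.1), tolerance = 0.01 / exp(-2.5 / 2.1))
})

test_that("per-pixel counts follow the binomial saturation law", {
  cfg <- tiny_cfg(100L, 5L, q = 8L)
  nmax <- 255
  for (lam in c(1, 10, 25, 100)) {
    plan <- scene_plan(list(), background_model(25 * lam, 25 * lam,
                                                spatial_density = lam),
                       cfg, rng_seed = lam, warm_pixel_fraction = 0,
                       base_dark_rate = 0)
    st <- suppressWarnings(simulate_stack(plan))
    expect_equal(mean(st$frames), nmax * (1 - exp(-lam / nmax)),
                 tolerance = 0.01)
  }
})

test_that("pile-up correction recovers the simulated uniform rate", {
  cfg <- tiny_cfg(100L, 5L)
  plan <- scene_plan(list(), background_model(625, 625, spatial_density = 25),
                     cfg, rng_seed = 9, warm_pixel_fraction = 0,
                     base_dark_rate = 0)
  st <- simulate_stack(plan)
  corrected <- pileup_correct(as.numeric(st$frames), 8, "censor")
  expect_equal(mean(corrected, na.rm = TRUE), 25, tolerance = 0.1 / 25)
})

test_that("box sums conserve photons in expectation", {
  # sigma = 0.8 px: > 99.8% of the PSF mass inside the 5x5 box
  plan <- one_emitter_plan(tau = 2.5, S = 400, B_box = 50, seed = 4,
                           side = 32L, n_pairs = 300L, psf_sigma = 0.8)
  st <- simulate_stack(plan)
  rows <- 14:18; cols <- 14:18
  g0 <- which(st$gate_index == 0L)
  sums <- vapply(g0, function(f)
    sum(pileup_correct(st$frames[rows, cols, f], 8, "censor"), na.rm = TRUE),
    numeric(1))
  expect_equal(mean(sums), 450, tolerance = 0.01)
})

test_that("simulation warns when the expected rate strains the dynamic range", {
  plan <- one_emitter_plan(tau = 2.5, S = 5000, seed = 5, side = 24L,
                           n_pairs = 2L)
  expect_warning(simulate_stack(plan), "pile-up")
})

test_that("dark stacks show warm pixels at their rate and are reproducible", {
  cfg <- tiny_cfg(64L, 10L)
  quiet <- scene_plan(list(), background_model(0), cfg, rng_seed = 6,
                      warm_pixel_fraction = 0)
  d0 <- simulate_dark_stack(quiet, 50)
  expect_lt(mean(d0$frames), 0.01)  # base dark rate only

  warm <- scene_plan(list(), background_model(0), cfg, rng_seed = 6,
                     warm_pixel_fraction = 0.01, warm_pixel_rate = 5)
  d1 <- simulate_dark_stack(warm, 200)
  rates <- apply(d1$frames, c(1, 2), mean)
  hot <- rates > 1
  expect_equal(sum(hot) / length(hot), 0.01, tolerance = 0.3)
  expect_equal(mean(rates[hot]), 5, tolerance = 0.05)

  d2 <- simulate_dark_stack(warm, 200)
  expect_identical(d1$frames, d2$frames)  # same seed, same bits
  expect_error(simulate_dark_stack(warm, 5), ">= 10")
})

test_that("stacks are bit-identical under a fixed seed", {
  plan <- one_emitter_plan(seed = 12, side = 24L, n_pairs = 20L)
  expect_identical(simulate_stack(plan)$frames, simulate_stack(plan)$frames)
})

test_that("scene_plan validates bounds and warm-pixel fraction", {
  cfg <- tiny_cfg(16L, 5L)
  out <- emitter_truth(20, 5, 2.5, 100)
  expect_error(scene_plan(list(out), background_model(0), cfg, rng_seed = 1),
               "outside")
  expect_error(scene_plan(list(), background_model(0), cfg, rng_seed = 1,
                          warm_pixel_fraction = 0.2), "0.05")
  expect_error(scene_plan(list(), background_model(0), cfg), "rng_seed")
})

test_that("fret_scene builds the acceptor-bleach world", {
  expect_equal(length(fret_scene(0, seed = 1, cfg = tiny_cfg())$emitters), 0)

  cfg <- tiny_cfg(96L, 50L, T_ns = 3)
  plan <- fret_scene(20, tau_DA = 2.1, tau_D = 3.4, brightness = 500,
                     seed = 3, cfg = cfg)
  bg <- background_model(0)
  for (em in plan$emitters) {
    if (!is.null(em$t_acceptor_bleach)) {
      pre <- expected_counts(em, cfg, bg, em$t_acceptor_bleach - 1, 0)
      post <- expected_counts(em, cfg, bg, em$t_acceptor_bleach, 0)
      expect_equal(post / pre, 3.4 / 2.1, tolerance = 1e-12)
      expect_lt(em$t_acceptor_bleach, em$t_off)
    } else {
      # donor-only molecules carry the unquenched brightness
      expect_equal(em$brightness, 500 * 3.4 / 2.1)
      expect_equal(em$lifetime_ns, 3.4)
    }
  }
  # minimum separation honoured
  gt <- ground_truth_table(plan)
  dmin <- min(dist(gt[, c("x", "y")]))
  expect_gte(dmin, 6)
  expect_error(fret_scene(2.1, 3.4, n_molecules = 500, seed = 1,
                          cfg = tiny_cfg(32L)), "density|separation|sensor")
  expect_error(fret_scene(5, tau_DA = 3.4, tau_D = 2.1, seed = 1), "tau_DA")
})

test_that("geometric bleach times have the exponential median", {
  set.seed(8)
  t_off <- rgeom(1000, 1 / 50) + 1
  expect_equal(median(t_off), 50 * log(2), tolerance = 0.2)
  # the same draw the generator uses
  plan <- fret_scene(60, seed = 21, cfg = tiny_cfg(200L, 10L),
                     bleach_time_scale = 50, fraction_da = 0)
  gt <- ground_truth_table(plan)
  expect_gt(min(gt$t_off), 0)
})
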