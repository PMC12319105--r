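test_that("static lifetime recovers the truth at high photon budget", {
  set.seed(19)
  tau <- 2.5; T_ns <- 2.5
  tr <- poisson_trace(S = 2000, tau = tau, T_ns = T_ns, B = 100,
                      n_pairs = 250, t_off = 180)
  # plant the (known) step so this test isolates the estimator; detection
  # and classification under shot noise are covered in test-traces.R
  seg <- classify_trace(tr, data.frame(time = 180L, sign = -1L,
                                       amplitude = -2000))
  expect_equal(seg$class, "single_step")
  est <- static_lifetime(tr, seg, T_ns)
  expect_equal(est$tau_ns, tau, tolerance = 0.05 / tau)
  expect_gt(est$n_photons, 2 * 150 * 2000)
  expect_false(est$low_n)
})

test_that("degenerate and misclassified traces are handled", {
  # one-frame ON segment, segmentation supplied by hand
  tr <- make_trace(c(500, rep(10, 60)), c(200, rep(10, 60)))
  seg <- classify_trace(tr, data.frame(time = 1L, sign = -1L,
                                       amplitude = -490))
  if (seg$class == "single_step") {
    est <- static_lifetime(tr, seg, 2.5)
    expect_true(est$low_n)
  }
  # background-only trace forced through the static path: censored
  set.seed(20)
  bgtr <- make_trace(rpois(100, 50), rpois(100, 50))
  fake <- classify_trace(bgtr, data.frame(time = 50L, sign = -1L,
                                          amplitude = -100))
  est2 <- static_lifetime(make_trace(rpois(100, 50), rpois(100, 50)),
                          structure(list(class = "single_step", t_off = 50L,
                                         B_o = 50, B_1 = 50, guard = 2L),
                                    class = "trace_segmentation"), 2.5)
  expect_true(est2$censored)
  expect_error(static_lifetime(bgtr, fake, 2.5), class = NULL)
})

test_that("noiseless streams give identical lifetimes at every rate", {
  T_ns <- 2.5; tau <- 2.1
  n <- 100
  tr <- make_trace(rep(1000, n), rep(1000 * exp(-T_ns / tau), n))
  seg <- classify_trace(tr, data.frame(time = integer(), sign = integer(),
                                       amplitude = numeric()))
  lt <- dynamic_lifetime(tr, seg, T_ns)
  # background estimate comes from the trailing frames of a never-bleaching
  # trace here, so subtract nothing by construction
  expect_error(regexp = NA, {
    lt2 <- dynamic_lifetime(tr, structure(list(t_off = NA_integer_, B_o = 0,
                                               B_1 = 0, guard = 2L,
                                               segments = data.frame(
                                                 start = 0L, end = n,
                                                 mean_No = 1000,
                                                 mean_N1 = 1000 * exp(-T_ns / tau))),
                                          class = "trace_segmentation"), T_ns)
  })
  expect_true(all(abs(lt2$tau_native - tau) < 1e-10))
  expect_true(all(abs(lt2$binned$bin2$tau_ns - tau) < 1e-10))
  expect_true(all(abs(lt2$binned$bin10$tau_ns - tau) < 1e-10))
  expect_equal(lt2$segments$tau_ns[1], tau, tolerance = 1e-10)
})

test_that("binned lifetimes come from binned counts, not averaged lifetimes", {
  T_ns <- 2
  N_o <- rep(c(1000, 400), 10)
  N_1 <- rep(c(500, 100), 10)
  tr <- make_trace(N_o, N_1)
  seg <- structure(list(t_off = NA_integer_, B_o = 0, B_1 = 0, guard = 2L,
                        segments = data.frame(start = 0L, end = 20L,
                                              mean_No = mean(N_o),
                                              mean_N1 = mean(N_1))),
                   class = "trace_segmentation")
  lt <- dynamic_lifetime(tr, seg, T_ns, bin_factors = 2L)
  oracle <- T_ns / log(mean(c(1000, 400)) / mean(c(500, 100)))  # Eq on means
  wrong <- mean(T_ns / log(c(1000 / 500, 400 / 100)))           # mean of taus
  expect_equal(lt$binned$bin2$tau_ns, rep(oracle, 10), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(oracle, wrong)))
})

test_that("time averaging trades rate for precision like sqrt(bin size)", {
  set.seed(22)
  tau <- 2.5; T_ns <- 2.5
  tr <- poisson_trace(S = 500, tau = tau, T_ns = T_ns, B = 50,
                      n_pairs = 4000, t_off = Inf)
  seg <- structure(list(t_off = NA_integer_, B_o = 50, B_1 = 50, guard = 2L,
                        segments = data.frame(start = 0L, end = 4000L,
                                              mean_No = mean(tr$N_o),
                                              mean_N1 = mean(tr$N_1))),
                   class = "trace_segmentation")
  lt <- dynamic_lifetime(tr, seg, T_ns, bin_factors = c(2L, 10L))
  ratio <- sd(lt$binned$bin2$tau_ns, na.rm = TRUE) /
    sd(lt$binned$bin10$tau_ns, na.rm = TRUE)
  expect_equal(ratio, sqrt(5), tolerance = 0.2)
})

test_that("per-molecule F lands in the observed 2-6 range near the optimum", {
  set.seed(23)
  f_vals <- replicate(60, {
    sbr <- runif(1, 3, 10)
    tau <- 2.5
    u <- optimal_gate_delay(1 / sbr)$u_star
    tr <- poisson_trace(S = 500, tau = tau, T_ns = u * tau, B = 500 / sbr,
                        n_pairs = 300, t_off = Inf)
    seg <- structure(list(t_off = NA_integer_, B_o = 500 / sbr,
                          B_1 = 500 / sbr, guard = 2L,
                          segments = data.frame(start = 0L, end = 300L,
                                                mean_No = mean(tr$N_o),
                                                mean_N1 = mean(tr$N_1))),
                     class = "trace_segmentation")
    dynamic_lifetime(tr, seg, u * tau)$f_empirical$F
  })
  expect_gt(mean(f_vals >= 2 & f_vals <= 6), 0.95)
})

test_that("FRET readout recovers E from an acceptor-donor trace", {
  set.seed(24)
  tau_DA <- 2.1; tau_D <- 3.4; T_ns <- 3
  E_true <- 1 - tau_DA / tau_D  # 0.382
  tr <- poisson_trace(S = 800, tau = tau_DA, T_ns = T_ns, B = 80,
                      n_pairs = 300, t_off = 220, t_acc = 120,
                      tau_post = tau_D)
  planted <- data.frame(time = c(120L, 220L), sign = c(1L, -1L),
                        amplitude = c(495, -1375))
  seg <- classify_trace(tr, planted)
  expect_equal(seg$class, "acceptor_donor")
  lt <- dynamic_lifetime(tr, seg, T_ns)
  fe <- fret_from_segmentation(lt, seg)
  expect_equal(fe$E_lifetime, E_true, tolerance = 0.05 / E_true)
  expect_lt(abs(fe$E_intensity - fe$E_lifetime), 0.05)

  # an intensity-only step (no lifetime change) is flagged by E_lifetime ~ 0
  tr2 <- poisson_trace(S = 500, tau = 3.4, T_ns = T_ns, B = 80,
                       n_pairs = 300, t_off = 220, t_acc = 120,
                       tau_post = 3.4)  # brightness step only via tau ratio = 1
  tr2$N_o[121:220] <- rpois(100, 800 + 80)  # plant a pure intensity step
  tr2$N_1[121:220] <- rpois(100, 800 * exp(-T_ns / 3.4) + 80)
  seg2 <- classify_trace(tr2, planted)
  expect_equal(seg2$class, "acceptor_donor")
  fe2 <- fret_from_segmentation(dynamic_lifetime(tr2, seg2, T_ns), seg2)
  expect_lt(abs(fe2$E_lifetime), 0.1)
  expect_gt(fe2$E_intensity, 0.2)

  # segmentation whose boundaries do not match the lifetime trace:
  # the tau_DA segment cannot be located
  seg_bad <- seg2
  seg_bad$t_up <- 110L
  expect_error(fret_from_segmentation(dynamic_lifetime(tr2, seg2, T_ns),
                                      seg_bad), "tau_DA")
})

test_that("lifetime histograms summarise and resolve mixtures", {
  set.seed(25)
  taus <- rnorm(1000, 2.5, 0.08)
  h <- lifetime_histogram(taus)
  expect_equal(h$mode, 2.5, tolerance = 0.1 / 2.5)
  expect_equal(h$n, 1000)

  # bimodal 2.1 / 3.4 at high budget: two maxima with a valley between
  mix <- c(rnorm(700, 2.1, 0.12), rnorm(700, 3.4, 0.12))
  hm <- lifetime_histogram(mix)
  in_band <- function(x, lo, hi) hm$counts[hm$mids >= lo & hm$mids <= hi]
  peak1 <- max(in_band(hm, 1.8, 2.4)); peak2 <- max(in_band(hm, 3.1, 3.7))
  valley <- min(in_band(hm, 2.5, 3.0))
  expect_gt(peak1, 2 * valley)
  expect_gt(peak2, 2 * valley)

  single <- lifetime_histogram(2.2)
  expect_equal(single$n, 1)
  expect_error(lifetime_histogram(c(NA_real_, NA_real_)), "censored")
  expect_equal(lifetime_histogram(c(2.5, NA))$censored_fraction, 0.5)
})

test_that("wide-field parallelisation arithmetic", {
  expect_equal(throughput_speedup(3000, 1, 10), 300)
  expect_error(throughput_speedup(10, 1, 0), "> 0")
})
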