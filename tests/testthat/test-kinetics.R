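test_that("dwell extraction converts runs to durations with censoring", {
  labels <- c(rep("unbound", 5), rep("site1", 30), rep("unbound", 10),
              rep("site1", 2), rep("nonspecific", 3), rep("site1", 4))
  ss <- as_state_seq(labels, dt = 0.1)
  dw <- extract_dwells(ss, "site1")
  expect_equal(nrow(dw), 3L)
  expect_equal(dw$duration_s, c(3.0, 0.2, 0.4))
  expect_equal(dw$censored, c(FALSE, FALSE, TRUE))   # last run touches the end
  # min_frames drops short runs
  expect_equal(nrow(extract_dwells(ss, "site1", min_frames = 3L)), 2L)
  # collapse treats all bound states as one run
  dwb <- extract_dwells(ss, c("site1", "nonspecific", "site2"), collapse = TRUE)
  expect_equal(dwb$duration_s, c(3.0, 0.9))
})

test_that("dwell extraction reproduces a hand-annotated fixture", {
  # 12 planted events with known frame counts
  lens <- c(3, 7, 1, 12, 5, 2, 9, 4, 6, 2, 8, 10)
  labels <- unlist(lapply(lens, function(l) c(rep("site1", l), "unbound")))
  labels <- c("unbound", labels)
  ss <- as_state_seq(labels, dt = 0.035)
  dw <- extract_dwells(ss, "site1")
  expect_equal(nrow(dw), 12L)
  expect_equal(dw$duration_s, lens * 0.035)
  expect_false(any(dw$censored))
})

test_that("survival fit recovers exponential dwell scales", {
  set.seed(2)
  for (tau in c(0.5, 3.1)) {
    d <- rexp(1500, 1 / tau)
    f <- fit_survival(d, n_boot = 60)
    se <- f$se["tau"]
    expect_lt(abs(f$tau - tau), 3 * se)
    expect_true(f$ci["tau", 1] < f$tau && f$tau < f$ci["tau", 2])
    # scale equivariance
    f2 <- fit_survival(2 * d)
    expect_equal(f2$tau / f$tau, 2, tolerance = 0.02)
    expect_lt(abs(f2$y0 - f$y0), 0.02)
  }
  expect_error(fit_survival(rep(1, 50)), "degenerate")
  expect_warning(fit_survival(rexp(10, 1)), "fewer than 20")
})

test_that("survival-fit bias shrinks with sample size", {
  tau <- 1.7
  err <- vapply(c(100, 1000, 10000), function(n) {
    est <- vapply(1:8, function(i) {
      set.seed(1000 * n + i)
      fit_survival(rexp(n, 1 / tau))$tau
    }, numeric(1L))
    abs(mean(est) - tau)
  }, numeric(1L))
  expect_lt(err[3], err[1])
  expect_lt(err[3] / tau, 0.02)
})

test_that("a two-population mixture yields an intermediate tau and worse fit", {
  set.seed(5)
  pure <- fit_survival(rexp(2000, 1 / 1))
  mix <- fit_survival(c(rexp(1000, 1 / 0.2), rexp(1000, 1 / 5)))
  expect_gt(mix$tau, 0.2)
  expect_lt(mix$tau, 5)
  expect_gt(mix$residual, pure$residual)
})

test_that("censored dwells are excluded by default but usable via Kaplan-Meier", {
  set.seed(6)
  d <- rexp(500, 1 / 2)
  dw <- structure(data.frame(id = "t", state = "site1", start_s = 0,
                             duration_s = d,
                             censored = seq_along(d) <= 100),
                  class = c("dwell_table", "data.frame"))
  f <- fit_survival(dw)
  expect_equal(f$n, 400L)
  fkm <- fit_survival(dw, include_censored = TRUE)
  expect_equal(fkm$n, 500L)
  expect_lt(abs(fkm$tau - 2) / 2, 0.25)
})

test_that("binding frequency and waiting times match the counting definition", {
  expect_equal(binding_frequency(10, 100, 10), 0.01)
  expect_equal(waiting_time(0.0018), 560)
  expect_equal(waiting_time(0.028), 36)
  expect_error(binding_frequency(1, 0, 1), "video_length")
})

test_that("kinetic K_D composes k_on and k_off correctly", {
  ks <- kinetic_kd(c(1, 2, 4), c(0.1, 0.2, 0.4), k_off = 1)
  expect_equal(ks$k_on, 0.1)
  expect_equal(ks$K_D, 10)
  # doubling concentrations and frequencies leaves K_D unchanged
  ks2 <- kinetic_kd(2 * c(1, 2, 4), 2 * c(0.1, 0.2, 0.4), k_off = 1)
  expect_equal(ks2$K_D, ks$K_D)
  # recovery from simulated counts
  set.seed(7)
  k_on <- 0.05; k_off <- 2; Tvid <- 200; Ntr <- 25
  conc <- c(0.5, 1, 2, 5)
  freq <- vapply(conc, function(c0) {
    n <- rpois(1L, k_on * c0 * Tvid * Ntr)
    binding_frequency(n, Tvid, Ntr)
  }, numeric(1L))
  ks3 <- kinetic_kd(conc, freq, k_off)
  expect_lt(abs(ks3$K_D - k_off / k_on) / (k_off / k_on), 0.10)
})

test_that("event categorization follows the three published schemes", {
  lk <- "site_linker"; nc <- "site_nuc"
  # scheme i: composition of visited site classes
  expect_equal(categorize_event(c(lk, nc, lk, nc), "composition", lk, nc),
               "nucleosome_and_linker")
  expect_equal(categorize_event(c("nonspecific", lk, lk), "composition", lk, nc),
               "linker_only")
  expect_equal(categorize_event(c(nc, nc), "composition", lk, nc),
               "nucleosome_only")
  expect_equal(categorize_event(c("nonspecific"), "composition", lk, nc),
               "nonspecific_only")
  # scheme ii: landing-site classes
  expect_equal(categorize_event(c(lk, nc), "landing", lk, nc),
               "linker_to_nucleosome")
  expect_equal(categorize_event(c(nc, "nonspecific", lk), "landing", lk, nc),
               "nucleosome_to_linker")
  expect_equal(categorize_event(c(lk, lk), "landing", lk, nc), "linker_only")
  expect_equal(categorize_event(c(nc), "landing", lk, nc), "nucleosome_only")
  expect_equal(categorize_event(c("nonspecific", lk), "landing", lk, nc),
               "nonspecific_to_linker")
  expect_equal(categorize_event(c("nonspecific", nc), "landing", lk, nc),
               "nonspecific_to_nucleosome")
  # scheme iii: nucleosomal-motif access
  expect_equal(categorize_event(c(lk, lk), "nucleosome_access", lk, nc),
               "linker_motif_only")
  expect_equal(categorize_event(c(nc, nc), "nucleosome_access", lk, nc),
               "nucleosomal_motif_only")
  expect_equal(categorize_event(c(nc, "nonspecific", nc), "nucleosome_access",
                                lk, nc), "scanning")
  expect_equal(categorize_event(c("nonspecific"), "nucleosome_access", lk, nc),
               "other")
})

test_that("category counts partition the events under every scheme", {
  tpl <- template_601(7)
  pars <- search_params(k_assoc = 2, D1 = 2000, k_off_ns = 2)
  sched <- schedule_three_color(0.035)
  em <- emission_params(noise_sd = 20,
                        bleach_rates = c(cy3 = 0, cy5 = 0, cy7 = 0))
  p <- simulate_path(tpl, pars, duration = 34.65, seed = 31)
  tr <- render_trace(p, sched, em, seed = 32)
  truth <- true_states(p, sched)
  ev <- detect_events(tr, 3 * em$background, sqrt(3) * em$noise_sd)
  for (scheme in c("composition", "landing", "nucleosome_access")) {
    cats <- vapply(seq_len(nrow(ev)), function(i) {
      categorize_event(truth$state[ev$start_frame[i]:ev$end_frame[i]], scheme,
                       linker_sites = "linker_site",
                       nucleosome_sites = "nuc_site")
    }, character(1L))
    expect_equal(length(cats), nrow(ev))
    expect_true(all(nchar(cats) > 0))
  }
})

test_that("rebinding matrix estimates next-event site preferences", {
  # all events at one site: identity row
  M <- rebinding_matrix(rep("m1", 4), rep("A", 4))
  expect_equal(unname(M["A", "A"]), 1)
  # planted first-order Markov chain is recovered
  P <- matrix(c(0.88, 0.12, 0.3, 0.7), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  set.seed(12)
  s <- character(10000); s[1] <- "A"
  for (i in 2:10000) s[i] <- sample(c("A", "B"), 1L, prob = P[s[i - 1], ])
  Mhat <- rebinding_matrix(rep("m1", 10000), s)
  expect_lt(max(abs(Mhat - P)), 0.02)
  # molecule boundaries contribute no pairs
  m2 <- rebinding_matrix(c("m1", "m1", "m2", "m2"), c("A", "A", "B", "B"))
  expect_equal(unname(m2["A", "B"]), 0)
  expect_equal(unname(m2["A", "A"]), 1)
  expect_equal(unname(m2["B", "B"]), 1)
})

test_that("donor-delay fraction counts events starting nonspecifically", {
  ev1 <- list(c("site1", "site1"), c("site2"))
  expect_equal(donor_delay_fraction(ev1), 0)
  expect_equal(donor_delay_fraction(list(c("nonspecific", "site1"))), 1)
  expect_equal(donor_delay_fraction(list(c("nonspecific", "nonspecific"))), 0)
  # simulation with a planted delay fraction
  set.seed(13)
  f <- 0.3
  evs <- lapply(1:2000, function(i) {
    if (runif(1) < f) c("nonspecific", "site1") else c("site1", "site1")
  })
  expect_lt(abs(donor_delay_fraction(evs) - f), 3 * sqrt(f * (1 - f) / 2000))
})

test_that("sub-frame dwells escape detection and bias observed lifetimes up", {
  tpl <- template_cognate_dna()
  sched <- schedule_two_color(0.1)
  em <- emission_params(noise_sd = 20,
                        bleach_rates = c(cy3 = 0, cy5 = 0, cy7 = 0))
  # fast nonspecific kinetics: most dwells shorter than one 100-ms frame
  pars <- search_params(k_assoc = 3, D1 = 0, k_off_ns = 20, k_escape = 20)
  n_events_true <- 0L; n_events_det <- 0L
  true_d <- det_d <- numeric(0)
  for (i in 1:12) {
    p <- simulate_path(tpl, pars, duration = 100, seed = 500 + i)
    ev <- attr(p, "events")
    n_events_true <- n_events_true + nrow(ev)
    true_d <- c(true_d, ev$t_end - ev$t_land)
    tr <- render_trace(p, sched, em, seed = 600 + i)
    det <- detect_events(tr, 3 * em$background, sqrt(3) * em$noise_sd)
    n_events_det <- n_events_det + nrow(det)
    det_d <- c(det_d, det$n_frames * 0.1)
  }
  expect_gt(sum(true_d < 0.1), 0)
  expect_lt(n_events_det, n_events_true)
  # observed mean dwell is biased upward relative to ground truth
  expect_gt(mean(det_d), mean(true_d))
})
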