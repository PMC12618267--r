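test_that("event detection thresholds donor-excitation intensity runs", {
  bg <- 100; sdv <- 10
  set.seed(1)
  flat <- as_trace(rnorm(200, bg / 3, sdv / 2), rnorm(200, bg / 3, sdv / 2),
                   rnorm(200, bg / 3, sdv / 2))
  expect_equal(nrow(detect_events(flat, bg, sdv, k_sigma = 5)), 0L)
  # one 5-frame plateau at 10 sigma above background
  cy3 <- rep(bg, 100); cy3[41:45] <- bg + 10 * sdv * 3
  tr <- as_trace(cy3, rep(0, 100), rep(0, 100))
  ev <- detect_events(tr, bg, sdv, k_sigma = 3)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start_frame, ev$end_frame), c(41L, 45L))
  # two runs separated by one below-threshold frame are distinct
  cy3[48:50] <- bg + 10 * sdv * 3
  ev2 <- detect_events(as_trace(cy3, rep(0, 100), rep(0, 100)), bg, sdv)
  expect_equal(nrow(ev2), 2L)
})

test_that("Viterbi equals brute-force path enumeration on short traces", {
  set.seed(99)
  for (i in 1:60) {
    S <- sample(2:4, 1L)
    T_ <- sample(2:8, 1L)
    hp <- random_hmm(S)
    X <- matrix(runif(T_ * 3, 0, 1000), T_, 3L)
    tr <- as_trace(X[, 1L], X[, 2L], X[, 3L])
    got <- viterbi_assign(tr, hp)
    want <- bf_viterbi(tfsearch:::emission_loglik(X, hp), hp$init, hp$trans)
    expect_equal(got$state, hp$states[want])
  }
})

test_that("Viterbi with the rendering HMM recovers planted states exactly at low noise", {
  tpl <- simple_template()
  em <- emission_params(noise_sd = 1e-3,
                        bleach_rates = c(cy3 = 0, cy5 = 0, cy7 = 0))
  sched <- schedule_three_color(0.1)
  seg <- data.frame(time = c(0, 10, 12, 13.5, 20, 40, 41.2),
                    position = c(NA, 38, 50, 72, NA, 72, NA),
                    state = c("unbound", "site1", "nonspecific", "site2",
                              "unbound", "site2", "unbound"))
  p <- trajectory_path(seg, tpl, duration = 100)
  tr <- render_trace(p, sched, em, seed = 2)
  hp <- hmm_from_template(tpl, em)
  ss <- viterbi_assign(tr, hp)
  truth <- true_states(p, sched)
  don <- !is.na(truth$state)
  expect_equal(ss$state[don], truth$state[don])
  expect_true(all(is.na(ss$state[!don])))
})

test_that("Baum-Welch fitting recovers well-separated emission means", {
  tpl <- simple_template()
  em <- emission_params(noise_sd = 25,
                        bleach_rates = c(cy3 = 0, cy5 = 0, cy7 = 0))
  sched <- schedule_three_color(0.1)
  pars <- search_params(k_assoc = 0.4, D1 = 10, k_off_ns = 0.3, k_escape = 0.8)
  traces <- lapply(1:6, function(i) {
    p <- simulate_path(tpl, pars, duration = 100, seed = 100 + i)
    render_trace(p, sched, em, seed = 200 + i)
  })
  fit <- fit_hmm(traces, n_sites = 2, seed = 5, max_iter = 60)
  # EM log-likelihood is monotone non-decreasing
  ll <- attr(fit, "loglik_trace")
  expect_true(all(diff(ll) > -1e-6))
  expect_true(all(abs(rowSums(fit$trans) - 1) < 1e-9))
  expect_true(abs(sum(fit$init) - 1) < 1e-9)
  # recovered state means within 5% of the rendering truth
  truth <- hmm_from_template(tpl, em)
  scale <- em$donor_total
  for (st in c("unbound", "nonspecific")) {
    i <- match(st, fit$states); j <- match(st, truth$states)
    expect_lt(max(abs(fit$means[i, ] - truth$means[j, ])) / scale, 0.05)
  }
  i5 <- grep("site_Cy5", fit$states)[1L]
  expect_lt(max(abs(fit$means[i5, ] - truth$means[match("site2", truth$states), ])) /
              scale, 0.05)
  i7 <- grep("site_Cy7", fit$states)[1L]
  expect_lt(max(abs(fit$means[i7, ] - truth$means[match("site1", truth$states), ])) /
              scale, 0.05)
})

test_that("relative-intensity rule assigns sites, nonspecific and ties", {
  # frames: Cy5-FRET, donor-only, Cy7-FRET, exact tie (carries previous label)
  cy3 <- c(150, 800, 150, 150)
  cy5 <- c(700, 105, 110, 600)
  cy7 <- c(110, 100, 650, 600)
  tr <- as_trace(cy3, cy5, cy7)
  ev <- data.frame(start_frame = 1L, end_frame = 4L)
  ss <- relative_intensity_assign(tr, ev, bg_mean = 100, bg_sd = 10,
                                  site_names = c(Cy5 = "site2", Cy7 = "site1"))
  expect_equal(ss$state, c("site2", "nonspecific", "site1", "site1"))
  # tie at the start of an event resolves to nonspecific
  tr2 <- as_trace(c(150), c(600), c(600))
  ss2 <- relative_intensity_assign(tr2, data.frame(start_frame = 1L, end_frame = 1L),
                                   bg_mean = 100, bg_sd = 10,
                                   site_names = c(Cy5 = "site2", Cy7 = "site1"))
  expect_equal(ss2$state, "nonspecific")
  # outside events is unbound
  tr3 <- as_trace(rep(100, 5), rep(100, 5), rep(100, 5))
  ss3 <- relative_intensity_assign(tr3, ev[0, ], bg_mean = 100, bg_sd = 10)
  expect_true(all(ss3$state == "unbound"))
})

test_that("assignments are invariant under uniform intensity scaling", {
  set.seed(4)
  cy3 <- runif(30, 100, 900); cy5 <- runif(30, 100, 900); cy7 <- runif(30, 100, 900)
  tr <- as_trace(cy3, cy5, cy7)
  ev <- data.frame(start_frame = 1L, end_frame = 30L)
  a <- relative_intensity_assign(tr, ev, fret_threshold = 300)
  tr2 <- as_trace(2 * cy3, 2 * cy5, 2 * cy7)
  b <- relative_intensity_assign(tr2, ev, fret_threshold = 600)
  expect_equal(a$state, b$state)
})

test_that("HMM and relative-intensity assignments agree at high SNR", {
  tpl <- simple_template()
  em <- emission_params(noise_sd = 20,
                        bleach_rates = c(cy3 = 0, cy5 = 0, cy7 = 0))
  sched <- schedule_three_color(0.1)
  pars <- search_params(k_assoc = 0.6, D1 = 3000, k_off_ns = 1, k_escape = 2)
  agree <- vapply(1:5, function(i) {
    p <- simulate_path(tpl, pars, duration = 100, seed = 300 + i)
    tr <- render_trace(p, sched, em, seed = 400 + i)
    hp <- hmm_from_template(tpl, em)
    v <- viterbi_assign(tr, hp)
    ev <- detect_events(tr, 3 * em$background, sqrt(3) * em$noise_sd)
    ri <- relative_intensity_assign(tr, ev, bg_mean = em$background,
                                    bg_sd = em$noise_sd,
                                    site_names = c(Cy5 = "site2", Cy7 = "site1"))
    don <- tr$excitation == "Cy3"
    # compare bound-state calls; relative intensity cannot see unbound inside
    # its own event windows, so restrict to frames both call bound
    both <- don & v$state != "unbound" & ri$state != "unbound"
    mean(v$state[both] == ri$state[both])
  }, numeric(1L))
  expect_true(all(agree >= 0.9))
})

test_that("direct transitions are counted by intervening nonspecific frames", {
  expect_equal(direct_transitions(c("site1", "site2"))[c("n_direct", "n_total")],
               list(n_direct = 1L, n_total = 1L))
  expect_equal(direct_transitions(c("site1", "nonspecific", "site2"))$n_direct, 0L)
  expect_equal(direct_transitions(c("site1", "nonspecific", "site2"))$n_total, 1L)
  # unbound gaps split events: no transition across them
  expect_equal(direct_transitions(c("site1", "unbound", "site2"))$n_total, 0L)
  # revisits through nonspecific count as indirect transitions
  r <- direct_transitions(c("site1", "nonspecific", "site1", "site2"))
  expect_equal(r$n_direct, 1L)
  expect_equal(r$n_total, 2L)
})

test_that("direct-transition fraction matches the transit-time distribution", {
  # plant site1 -> site2 switches with exponential transit gaps; a switch is
  # direct when its gap is shorter than one frame
  set.seed(8)
  dt <- 0.035
  rate <- 20          # mean transit 50 ms
  n <- 4000
  gaps <- rexp(n, rate)
  labels <- character(0)
  for (i in seq_len(n)) {
    labels <- c(labels, "site1",
                rep("nonspecific", floor(gaps[i] / dt)), "site2", "unbound")
  }
  got <- direct_transitions(labels)
  p_direct <- 1 - exp(-rate * dt)   # P(transit < frame interval)
  expect_equal(got$n_total, n)
  expect_lt(abs(got$fraction - p_direct), 3 * sqrt(p_direct * (1 - p_direct) / n))
})
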