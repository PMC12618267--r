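# Synthetic-data generator: continuous-time simulation of target search on a
# template, rendered into multicolor smFRET traces and confocal kymographs.
#
# The search model: a molecule in solution associates with the template at a
# fixed rate (proportional to concentration).  It lands uniformly on
# slidable DNA (linker plus the nucleosome edge) or, with a small probability,
# directly on a solvent-exposed core site.  While bound nonspecifically it
# performs a nearest-neighbour continuous-time random walk (hop rate D1 per
# direction, so MSD = 2*D1*t in bp^2) and dissociates at a constant rate.
# Entering a cognate motif footprint traps it; it escapes at the site's escape
# rate.  With occlusion enabled, sliding cannot carry it past the nucleosome
# edge (|SHL| >= 7) into the core.

#' Search-model parameters
#'
#' @param k_assoc association rate per trace in s^-1 (proportional to
#'   protein concentration; default 0.028 s^-1, the cognate-DNA binding
#'   frequency at 0.2 nM).
#' @param D1 1D diffusion coefficient in bp^2 s^-1 (default 160; with per-bp
#'   hopping competing against motif traps this makes the overall dwell on a
#'   two-site cognate fragment roughly tenfold the 0.33-s nonspecific event
#'   dwell, the observed cognate/noncognate dwell ratio).
#' @param k_escape motif escape rate(s) in s^-1, recycled over sites
#'   (default 4 s^-1, i.e. a 0.25-s cognate dwell).
#' @param k_off_ns dissociation rate from nonspecific positions in s^-1
#'   (default 3 s^-1, a 0.33-s nonspecific dwell).
#' @param occlusion_enabled block sliding past the nucleosome edge
#'   (default `TRUE`).
#' @param direct_3d_fraction fraction of landings that go directly to a
#'   solvent-exposed core site when one exists (default 0.2).
#' @param fret_radius bp distance from a labeled site within which FRET is
#'   rendered (default 2).
#' @return A list of class `search_params`.
#' @export
search_params <- function(k_assoc = 0.028, D1 = 160, k_escape = 4,
                          k_off_ns = 3, occlusion_enabled = TRUE,
                          direct_3d_fraction = 0.2, fret_radius = 2) {
  stopifnot(k_assoc >= 0, D1 >= 0, all(k_escape >= 0), k_off_ns >= 0,
            direct_3d_fraction >= 0, direct_3d_fraction <= 1, fret_radius >= 0)
  structure(list(k_assoc = k_assoc, D1 = D1, k_escape = k_escape,
                 k_off_ns = k_off_ns, occlusion_enabled = occlusion_enabled,
                 direct_3d_fraction = direct_3d_fraction,
                 fret_radius = fret_radius),
            class = "search_params")
}

# per-bp maps driving the walk kernel
template_maps <- function(tpl, params) {
  L <- nchar(tpl$sequence)
  enterable <- rep(TRUE, L)
  if (!is.na(tpl$dyad) && params$occlusion_enabled) {
    p <- 0:(L - 1L)
    enterable[abs(p - tpl$dyad) <= CORE_HALF - 1L] <- FALSE
  }
  n <- nrow(tpl$sites)
  trap_id <- integer(L)
  label <- integer(L)
  classes <- character(n)
  if (n) {
    for (k in seq_len(n)) {
      s <- tpl$sites[k, ]
      classes[k] <- site_accessibility(s, tpl)
      fp <- (s$start + 1L):s$end            # 1-based indices
      trap_id[fp] <- k
      if (classes[k] %in% c("linker_slidable", "edge_slidable")) {
        enterable[fp] <- TRUE
      }
      lo <- max(1L, s$start + 1L - params$fret_radius)
      hi <- min(L, s$end + params$fret_radius)
      label[lo:hi] <- k
    }
  }
  k_escape <- rep_len(params$k_escape, max(1L, n))
  list(L = L, enterable = enterable, trap_id = trap_id, label = label,
       trap_start = if (n) tpl$sites$start else integer(),
       trap_end = if (n) tpl$sites$end else integer(),
       k_escape = k_escape, classes = classes,
       slidable_bp = which(enterable) - 1L,
       exposed_sites = which(classes == "core_3d_exposed"))
}

#' Simulate a target-search trajectory
#'
#' Exact continuous-time (Gillespie) simulation of repeated rounds of
#' association, 1D sliding, motif trapping and dissociation on a template.
#' Sub-frame events exist in the ground truth; frame-rate effects enter only
#' at rendering ([render_trace()]).
#'
#' @param tpl a `tf_template`.
#' @param params a [search_params()] object.
#' @param duration trace duration in s.
#' @param seed integer seed; identical seeds give identical paths.
#' @return A `trajectory_path`: `data.frame` with columns `time` (s),
#'   `position` (bp, `NA` when unbound) and `state` (`"unbound"`,
#'   `"nonspecific"`, or a site name), each row opening a constant-state
#'   segment.  Attributes: `events` (per binding event: landing time/position,
#'   direct-3D flag, end time, min/max position visited, whether it ended by
#'   dissociation), `occupancy` (bound time per bp), `template`, `params`,
#'   `duration`, `seed`.
#' @export
simulate_path <- function(tpl, params = search_params(), duration, seed = 1L) {
  stopifnot(inherits(tpl, "tf_template"), duration > 0)
  maps <- template_maps(tpl, params)
  site_names <- tpl$sites$name
  lab_name <- function(l) {
    ifelse(l == 0L, "nonspecific", site_names[pmax(l, 1L)])
  }
  rows <- list(data.frame(time = 0, position = NA_integer_, state = "unbound",
                          stringsAsFactors = FALSE))
  evs <- list()
  occupancy <- numeric(maps$L)
  exposed_bp_of <- lapply(maps$exposed_sites, function(k) {
    as.integer(round((tpl$sites$start[k] + tpl$sites$end[k]) / 2))
  })
  with_seed(seed, {
    t <- 0
    while (params$k_assoc > 0) {
      t_land <- t + rexp(1L, params$k_assoc)
      if (t_land >= duration) break
      direct <- length(maps$exposed_sites) > 0L &&
        runif(1L) < params$direct_3d_fraction
      if (direct) {
        k <- maps$exposed_sites[sample.int(length(maps$exposed_sites), 1L)]
        p0 <- exposed_bp_of[[match(k, maps$exposed_sites)]]
      } else {
        if (length(maps$slidable_bp) == 0L) break
        p0 <- maps$slidable_bp[sample.int(length(maps$slidable_bp), 1L)]
      }
      w <- walk_cpp(p0, t_land, duration, params$D1, params$k_off_ns,
                    maps$enterable, maps$trap_id, maps$trap_start,
                    maps$trap_end, maps$k_escape, maps$label)
      rows[[length(rows) + 1L]] <-
        data.frame(time = w$t, position = w$pos, state = lab_name(w$label),
                   stringsAsFactors = FALSE)
      occupancy <- occupancy + w$occupancy
      if (w$dissociated) {
        rows[[length(rows) + 1L]] <-
          data.frame(time = w$t_end, position = NA_integer_, state = "unbound",
                     stringsAsFactors = FALSE)
      }
      evs[[length(evs) + 1L]] <-
        data.frame(t_land = t_land, landed_pos = p0, direct_3d = direct,
                   t_end = w$t_end, pos_min = w$pmin, pos_max = w$pmax,
                   dissociated = w$dissociated)
      t <- w$t_end
      if (t >= duration) break
    }
  })
  path <- do.call(rbind, rows)
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(t_land = numeric(), landed_pos = integer(), direct_3d = logical(),
               t_end = numeric(), pos_min = integer(), pos_max = integer(),
               dissociated = logical())
  structure(path, events = events, occupancy = occupancy, template = tpl,
            params = params, duration = duration, seed = seed,
            class = c("trajectory_path", "data.frame"))
}

#' Laser excitation schedule
#'
#' Alternating-excitation program as repeating blocks of frames per channel.
#' `schedule_three_color()` is the standard three-color program (10 frames
#' Cy7, 10 Cy5, 960 Cy3, 10 Cy7, 10 Cy5); `schedule_two_color()` is the
#' two-color program (10 frames Cy5 then 990 Cy3).
#'
#' @param blocks `data.frame` with columns `frames` (>= 1) and `channel`
#'   (`"Cy3"`, `"Cy5"`, `"Cy7"`).
#' @param frame_interval frame interval in s (> 0).
#' @return A list of class `excitation_schedule` with per-frame `excitation`
#'   expanded.
#' @export
excitation_schedule <- function(blocks, frame_interval = 0.1) {
  stopifnot(frame_interval > 0, all(blocks$frames >= 1L),
            all(blocks$channel %in% c("Cy3", "Cy5", "Cy7")))
  structure(list(blocks = blocks, frame_interval = frame_interval,
                 excitation = rep(blocks$channel, blocks$frames)),
            class = "excitation_schedule")
}

#' @rdname excitation_schedule
#' @export
schedule_three_color <- function(frame_interval = 0.1) {
  excitation_schedule(data.frame(frames = c(10L, 10L, 960L, 10L, 10L),
                                 channel = c("Cy7", "Cy5", "Cy3", "Cy7", "Cy5")),
                      frame_interval)
}

#' @rdname excitation_schedule
#' @export
schedule_two_color <- function(frame_interval = 0.1) {
  excitation_schedule(data.frame(frames = c(10L, 990L), channel = c("Cy5", "Cy3")),
                      frame_interval)
}

#' Fluorescence emission parameters
#'
#' Mean per-state channel intensities (arbitrary camera units above
#' background) under donor (Cy3) excitation, plus direct-excitation acceptor
#' level, background, per-channel Gaussian noise and per-fluorophore
#' photobleaching rates.
#'
#' @param donor_total total emission of a bound molecule under Cy3
#'   excitation.
#' @param fret_leak residual donor emission during FRET.
#' @param direct_acceptor acceptor signal during its own excitation block.
#' @param background background level per channel.
#' @param noise_sd Gaussian noise sd per channel.
#' @param bleach_rates named rates (s^-1) for `cy3`, `cy5`, `cy7`.
#' @return A list of class `emission_params`.
#' @export
emission_params <- function(donor_total = 800, fret_leak = 150,
                            direct_acceptor = 700, background = 100,
                            noise_sd = 40,
                            bleach_rates = c(cy3 = 0, cy5 = 0.002, cy7 = 0.002)) {
  stopifnot(donor_total >= 0, fret_leak >= 0, direct_acceptor >= 0,
            background >= 0, noise_sd >= 0, all(bleach_rates >= 0))
  structure(list(donor_total = donor_total, fret_leak = fret_leak,
                 direct_acceptor = direct_acceptor, background = background,
                 noise_sd = noise_sd, bleach_rates = bleach_rates),
            class = "emission_params")
}

#' Render a trajectory into a multicolor intensity trace
#'
#' Bins the continuous-time path into camera frames: each frame's channel
#' means are the time-weighted mixture of the emissions of the states visited
#' during the frame, plus background and Gaussian noise.  Binding within the
#' FRET radius of a Cy5-labeled site gives Cy5-high/Cy3-low emission during
#' Cy3 excitation (Cy7 analogously); binding elsewhere gives Cy3-only.
#' Acceptor-excitation frames report direct acceptor fluorescence (a
#' fluorophore-presence check).  Acceptor photobleaching times are drawn per
#' fluorophore; a bleached acceptor renders as nonspecific (donor-only).
#'
#' @param path a `trajectory_path`.
#' @param schedule an [excitation_schedule()].
#' @param emission an [emission_params()].
#' @param seed integer seed for noise and bleach times.
#' @param id trace identifier.
#' @return An `intensity_trace`: `data.frame` with columns `frame`, `time_s`,
#'   `cy3`, `cy5`, `cy7`, `excitation`; attributes `frame_interval`, `id`,
#'   `template`.
#' @export
render_trace <- function(path, schedule, emission = emission_params(),
                         seed = 1L, id = "trace1") {
  stopifnot(inherits(path, "trajectory_path"),
            inherits(schedule, "excitation_schedule"))
  tpl <- attr(path, "template")
  dt <- schedule$frame_interval
  nf <- length(schedule$excitation)
  duration <- attr(path, "duration")
  site_acceptor <- setNames(tpl$sites$acceptor, tpl$sites$name)

  # piecewise-constant state segments
  seg_t0 <- path$time
  seg_t1 <- c(path$time[-1L], max(duration, nf * dt))
  seg_state <- path$state
  keep <- seg_t1 > seg_t0
  seg_t0 <- seg_t0[keep]; seg_t1 <- seg_t1[keep]; seg_state <- seg_state[keep]

  states <- c("unbound", "nonspecific", tpl$sites$name)
  occ <- matrix(0, nrow = nf, ncol = length(states),
                dimnames = list(NULL, states))
  for (i in seq_along(seg_t0)) {
    f0 <- max(1L, floor(seg_t0[i] / dt) + 1L)
    f1 <- min(nf, ceiling(seg_t1[i] / dt))
    if (f0 > f1) next
    for (f in f0:f1) {
      ov <- min(seg_t1[i], f * dt) - max(seg_t0[i], (f - 1) * dt)
      if (ov > 0) occ[f, seg_state[i]] <- occ[f, seg_state[i]] + ov / dt
    }
  }
  # time not covered by the path (past its end) counts as unbound
  occ[, "unbound"] <- occ[, "unbound"] + pmax(0, 1 - rowSums(occ))

  with_seed(seed, {
    bleach_t <- vapply(c("cy3", "cy5", "cy7"), function(ch) {
      r <- emission$bleach_rates[[ch]]
      if (is.null(r) || r <= 0) Inf else rexp(1L, r)
    }, numeric(1L))
    mid <- (seq_len(nf) - 0.5) * dt
    cy3 <- cy5 <- cy7 <- numeric(nf)
    donor_on <- mid < bleach_t["cy3"]
    for (f in seq_len(nf)) {
      exc <- schedule$excitation[f]
      if (exc == "Cy3") {
        if (donor_on[f]) {
          ns_frac <- occ[f, "nonspecific"]
          for (s in tpl$sites$name) {
            acc <- site_acceptor[[s]]
            fr <- occ[f, s]
            if (fr <= 0) next
            ch <- tolower(acc)
            if (acc != "none" && mid[f] < bleach_t[ch]) {
              cy3[f] <- cy3[f] + fr * emission$fret_leak
              if (acc == "Cy5") cy5[f] <- cy5[f] + fr * (emission$donor_total - emission$fret_leak)
              else cy7[f] <- cy7[f] + fr * (emission$donor_total - emission$fret_leak)
            } else {
              ns_frac <- ns_frac + fr
            }
          }
          cy3[f] <- cy3[f] + ns_frac * emission$donor_total
        }
      } else {
        ch <- tolower(exc)
        present <- any(site_acceptor == exc) && mid[f] < bleach_t[ch]
        if (present) {
          if (exc == "Cy5") cy5[f] <- emission$direct_acceptor
          else cy7[f] <- emission$direct_acceptor
        }
      }
    }
    bg <- emission$background
    sdv <- emission$noise_sd
    out <- data.frame(frame = seq_len(nf), time_s = (seq_len(nf) - 1L) * dt,
                      cy3 = cy3 + bg + rnorm(nf, 0, sdv),
                      cy5 = cy5 + bg + rnorm(nf, 0, sdv),
                      cy7 = cy7 + bg + rnorm(nf, 0, sdv),
                      excitation = schedule$excitation,
                      stringsAsFactors = FALSE)
  })
  structure(out, frame_interval = dt, id = id, template = tpl,
            class = c("intensity_trace", "data.frame"))
}

#' Simulate a confocal kymograph of molecules diffusing on a DNA tether
#'
#' Each molecule performs reflected 1D Brownian motion on `[0, tether_length]`
#' sampled at the line time; on reaching within one pixel of a target it
#' immobilizes at rate `immobilization_rate`.  Each scan line renders every
#' molecule as a Gaussian point-spread profile (sd ~ 1.3 pixels) with Poisson
#' photon statistics over background.  Multimeric molecules carry `n_fluors`
#' independent fluorophores, each photobleaching exponentially, giving
#' gradual intensity loss.
#'
#' @param n_molecules number of molecules.
#' @param D diffusion coefficient in um^2 s^-1.
#' @param targets target positions in um (may be empty).
#' @param immobilization_rate rate (s^-1) of locking when within one pixel of
#'   a target.
#' @param n_lines number of scan lines.
#' @param line_time line (frame) time in s, 0.07-0.2 s typical.
#' @param pixel_size pixel size in um (default 0.1).
#' @param tether_length tether length in um.
#' @param photobleach_rate per-fluorophore bleach rate in s^-1.
#' @param n_fluors fluorophores per molecule (1 = monomer).
#' @param amplitude mean photons per fluorophore per line.
#' @param background mean background photons per pixel per line.
#' @param seed integer seed.
#' @return A list of class `kymograph`: `counts` (pixels x lines photon
#'   matrix), `pixel_size`, `line_time`, and ground-truth `tracks`
#'   (`data.frame` line, molecule, position_um, immobile, n_active_fluors).
#' @export
simulate_kymo <- function(n_molecules = 10, D = 0.15, targets = numeric(),
                          immobilization_rate = 0, n_lines = 200,
                          line_time = 0.1, pixel_size = 0.1,
                          tether_length = 10, photobleach_rate = 0,
                          n_fluors = 1L, amplitude = 50, background = 1,
                          seed = 1L) {
  stopifnot(pixel_size > 0, line_time > 0, tether_length > 0, D >= 0,
            n_lines >= 1, n_molecules >= 1)
  n_px <- as.integer(ceiling(tether_length / pixel_size))
  px_centers <- (seq_len(n_px) - 0.5) * pixel_size
  psf_sd <- 1.3 * pixel_size
  with_seed(seed, {
    truth <- vector("list", n_molecules)
    counts <- matrix(0L, nrow = n_px, ncol = n_lines)
    for (m in seq_len(n_molecules)) {
      x <- numeric(n_lines)
      x[1L] <- runif(1L, 0, tether_length)
      immobile <- logical(n_lines)
      bleach_t <- if (photobleach_rate > 0) rexp(n_fluors, photobleach_rate)
                  else rep(Inf, n_fluors)
      for (l in 2:n_lines) {
        if (immobile[l - 1L]) {
          x[l] <- x[l - 1L]; immobile[l] <- TRUE
        } else {
          step <- rnorm(1L, 0, sqrt(2 * D * line_time))
          xx <- x[l - 1L] + step
          # reflect at tether ends
          while (xx < 0 || xx > tether_length) {
            if (xx < 0) xx <- -xx
            if (xx > tether_length) xx <- 2 * tether_length - xx
          }
          x[l] <- xx
          immobile[l] <- length(targets) > 0L &&
            min(abs(xx - targets)) <= pixel_size &&
            runif(1L) < 1 - exp(-immobilization_rate * line_time)
        }
      }
      t_line <- (seq_len(n_lines) - 0.5) * line_time
      active <- vapply(t_line, function(tt) sum(bleach_t > tt), integer(1L))
      for (l in seq_len(n_lines)) {
        if (active[l] == 0L) next
        lam <- amplitude * active[l] *
          exp(-(px_centers - x[l])^2 / (2 * psf_sd^2))
        counts[, l] <- counts[, l] + rpois(n_px, lam)
      }
      truth[[m]] <- data.frame(line = seq_len(n_lines), molecule = m,
                               position_um = x, immobile = immobile,
                               n_active_fluors = active)
    }
    counts <- counts + matrix(rpois(n_px * n_lines, background), n_px, n_lines)
  })
  structure(list(counts = counts, pixel_size = pixel_size,
                 line_time = line_time,
                 tracks = do.call(rbind, truth)),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d px x %d lines, pixel %.3g um, line time %.3g s\n",
              nrow(x$counts), ncol(x$counts), x$pixel_size, x$line_time))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  image(x = (seq_len(ncol(x$counts)) - 0.5) * x$line_time,
        y = (seq_len(nrow(x$counts)) - 0.5) * x$pixel_size,
        z = t(x$counts), xlab = "time (s)", ylab = "position (um)",
        col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Construct a trajectory path by hand
#'
#' Builds a `trajectory_path` from explicit state segments, e.g. to plant
#' dwells of known duration for rendering and detection benchmarks.
#'
#' @param segments `data.frame` with columns `time` (segment start, s;
#'   strictly increasing, first row at 0), `position` (bp or `NA`) and
#'   `state` (`"unbound"`, `"nonspecific"`, or a site name of `tpl`).
#' @param tpl a `tf_template`.
#' @param duration total duration in s (>= last segment start).
#' @return A `trajectory_path`.
#' @export
trajectory_path <- function(segments, tpl, duration) {
  stopifnot(all(diff(segments$time) > 0), segments$time[1L] == 0,
            duration >= max(segments$time))
  ok <- segments$state %in% c("unbound", "nonspecific", tpl$sites$name)
  if (!all(ok)) stop("unknown state label: ", segments$state[!ok][1L])
  structure(as.data.frame(segments),
            events = NULL, occupancy = NULL, template = tpl,
            params = NULL, duration = duration, seed = NA_integer_,
            class = c("trajectory_path", "data.frame"))
}

#' Ground-truth per-frame state labels
#'
#' Bins a trajectory into the frames of an excitation schedule and labels
#' each donor-excitation frame with the state occupying the largest share of
#' the frame (acceptor-excitation frames get `NA`), for benchmarking
#' assignment methods against simulation truth.
#'
#' @param path a `trajectory_path`.
#' @param schedule an [excitation_schedule()].
#' @return A `state_seq` with `provenance = "ground_truth"`.
#' @export
true_states <- function(path, schedule) {
  tpl <- attr(path, "template")
  dt <- schedule$frame_interval
  nf <- length(schedule$excitation)
  states <- c("unbound", "nonspecific", tpl$sites$name)
  seg_t0 <- path$time
  seg_t1 <- c(path$time[-1L], max(attr(path, "duration"), nf * dt))
  occ <- matrix(0, nf, length(states), dimnames = list(NULL, states))
  for (i in seq_along(seg_t0)) {
    if (seg_t1[i] <= seg_t0[i]) next
    f0 <- max(1L, floor(seg_t0[i] / dt) + 1L)
    f1 <- min(nf, ceiling(seg_t1[i] / dt))
    if (f0 > f1) next
    for (f in f0:f1) {
      ov <- min(seg_t1[i], f * dt) - max(seg_t0[i], (f - 1) * dt)
      if (ov > 0) occ[f, path$state[i]] <- occ[f, path$state[i]] + ov / dt
    }
  }
  occ[, "unbound"] <- occ[, "unbound"] + pmax(0, 1 - rowSums(occ))
  lab <- states[max.col(occ, ties.method = "first")]
  lab[schedule$excitation != "Cy3"] <- NA_character_
  fake <- data.frame(frame = seq_len(nf), time_s = (seq_len(nf) - 1L) * dt)
  structure(data.frame(frame = fake$frame, time_s = fake$time_s, state = lab,
                       stringsAsFactors = FALSE),
            provenance = "ground_truth", states = states,
            frame_interval = dt, id = "truth",
            class = c("state_seq", "data.frame"))
}
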