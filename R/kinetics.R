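# Dwell-time kinetics: dwell extraction, survival (1-CDF) exponential fits,
# binding frequency, equilibrium constants, event categorization and
# rebinding statistics.

#' Extract dwell times from a state sequence
#'
#' Maximal runs of frames in the requested states become dwell records;
#' duration is run length times the frame interval.  Runs touching the start
#' or end of the (decoded) trace are flagged censored; runs shorter than
#' `min_frames` are dropped.
#'
#' @param stateseq a `state_seq` (frames with `NA` labels, e.g.
#'   acceptor-excitation checks, are skipped).
#' @param states state labels of interest; a run may not mix labels.  Use
#'   e.g. `c("site1")` for motif dwells or all bound states for overall
#'   dwells via `collapse = TRUE`.
#' @param min_frames minimum run length in frames (default 1).
#' @param collapse treat all requested states as one (runs may mix labels;
#'   the record keeps the first label) - used for overall DNA-bound dwells.
#' @return A `dwell_table`: `data.frame` with `id`, `state`, `start_s`,
#'   `duration_s`, `censored`.
#' @export
extract_dwells <- function(stateseq, states, min_frames = 1L,
                           collapse = FALSE) {
  dt <- attr(stateseq, "frame_interval")
  id <- attr(stateseq, "id")
  if (is.null(id)) id <- "trace"
  lab <- stateseq$state
  keep <- !is.na(lab)
  lab <- lab[keep]
  tt <- stateseq$time_s[keep]
  n <- length(lab)
  if (n == 0L) {
    return(structure(data.frame(id = character(), state = character(),
                                start_s = numeric(), duration_s = numeric(),
                                censored = logical()),
                     class = c("dwell_table", "data.frame")))
  }
  key <- if (collapse) ifelse(lab %in% states, "IN", lab) else lab
  r <- rle(key)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- if (collapse) r$values == "IN" else r$values %in% states
  out <- data.frame(id = rep(id, sum(sel)),
                    state = lab[starts[sel]],
                    start_s = tt[starts[sel]],
                    duration_s = r$lengths[sel] * dt,
                    censored = starts[sel] == 1L | ends[sel] == n)
  out <- out[r$lengths[sel] >= min_frames, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("dwell_table", "data.frame"))
}

#' Fit a single-exponential to the dwell-time survival curve
#'
#' Computes the empirical survival function (1-CDF) at the sorted dwell
#' times and fits `y = y0 + A * exp(-x / tau)` by nonlinear least squares.
#' Censored dwells are excluded by default; `include_censored = TRUE` instead
#' derives the survival curve from a Kaplan-Meier estimate
#' ([survival::survfit()]) as a sensitivity check.
#'
#' Least-squares parameter covariances understate the sampling error of
#' `tau` because neighbouring survival points are strongly correlated; with
#' `n_boot > 0` the `tau` standard error and CI are instead taken from a
#' nonparametric bootstrap over dwells.
#'
#' @param dwells a `dwell_table` or numeric vector of durations (s).
#' @param include_censored use Kaplan-Meier survival including censored
#'   dwells (default `FALSE`).
#' @param n_boot bootstrap replicates for the `tau` standard error
#'   (default 0 = use the least-squares covariance).
#' @param boot_seed seed for the bootstrap resampling.
#' @return An `exp_fit` with components `tau`, `y0`, `A`, `ci` (95% per
#'   parameter), `n`, `residual` (RMS), and the fitted curve data; methods
#'   `print`, `coef`, `predict`, `plot`.
#' @export
fit_survival <- function(dwells, include_censored = FALSE, n_boot = 0L,
                         boot_seed = 1L) {
  if (inherits(dwells, "dwell_table") || is.data.frame(dwells)) {
    if (include_censored) {
      fitkm <- survival::survfit(
        survival::Surv(dwells$duration_s, !dwells$censored) ~ 1)
      x <- fitkm$time
      y <- fitkm$surv
      n <- nrow(dwells)
    } else {
      d <- dwells$duration_s[!dwells$censored]
      return(fit_survival(d, n_boot = n_boot, boot_seed = boot_seed))
    }
  } else {
    d <- as.numeric(dwells)
    n <- length(d)
    if (n < 20L) warning("fewer than 20 uncensored dwells; fit may be unstable")
    if (n < 3L) stop("need at least 3 dwells")
    if (max(d) - min(d) < .Machine$double.eps * max(d)) {
      stop("degenerate fit: all dwell durations identical")
    }
    x <- sort(d)
    y <- (n - seq_len(n)) / n   # empirical 1 - CDF at each sorted dwell
    x <- c(0, x); y <- c(1, y)
  }
  start <- list(y0 = 0, A = 1, tau = max(mean(x), 1e-9))
  fit <- minpack.lm::nlsLM(y ~ y0 + A * exp(-x / tau), start = start,
                           data = data.frame(x = x, y = y),
                           lower = c(-Inf, -Inf, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (n_boot > 0L && exists("d", inherits = FALSE)) {
    taus <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        db <- sample(d, replace = TRUE)
        tryCatch(suppressWarnings(fit_survival(db)$tau),
                 error = function(e) NA_real_)
      }, numeric(1L))
    })
    se["tau"] <- stats::sd(taus, na.rm = TRUE)
  }
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  structure(list(tau = unname(est["tau"]), y0 = unname(est["y0"]),
                 A = unname(est["A"]), se = se, ci = ci, n = n,
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 curve = data.frame(x = x, y = y), fit = fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> tau = %.4g s (95%% CI %.4g-%.4g), y0 = %.3g, A = %.3g, n = %d\n",
              x$tau, x$ci["tau", 1L], x$ci["tau", 2L], x$y0, x$A, x$n))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  c(tau = object$tau, y0 = object$y0, A = object$A)
}

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$curve$x else newdata$x
  object$y0 + object$A * exp(-x / object$tau)
}

#' @export
plot.exp_fit <- function(x, ...) {
  plot(x$curve$x, x$curve$y, xlab = "dwell time (s)", ylab = "1 - CDF",
       pch = 16, cex = 0.6, ...)
  xs <- seq(0, max(x$curve$x), length.out = 200L)
  lines(xs, x$y0 + x$A * exp(-xs / x$tau), col = "red3", lwd = 2)
  invisible(x)
}

#' Binding frequency and mean waiting time
#'
#' Frequency is the total number of events divided by the product of video
#' length and number of trajectories examined; the waiting time is its
#' reciprocal (reported to 2 significant figures by `waiting_time()` for
#' printed-style values).
#'
#' @param n_events total number of binding events.
#' @param video_length_s video length in s (> 0).
#' @param n_trajectories number of trajectories examined (>= 1).
#' @return Frequency in s^-1.
#' @export
binding_frequency <- function(n_events, video_length_s, n_trajectories) {
  stopifnot(video_length_s > 0, n_trajectories >= 1)
  n_events / (video_length_s * n_trajectories)
}

#' @rdname binding_frequency
#' @param frequency binding frequency in s^-1.
#' @param digits significant figures for reporting (default 2).
#' @export
waiting_time <- function(frequency, digits = 2) {
  stopifnot(frequency > 0)
  signif_half_up(1 / frequency, digits)
}

#' Kinetic equilibrium constant from single-molecule rates
#'
#' `k_on` is the slope (through the origin) of binding frequency versus
#' protein concentration; `K_D = k_off / k_on`.
#'
#' @param concentration_nM protein concentrations (nM).
#' @param frequency_s binding frequencies (s^-1), same length.
#' @param k_off dissociation rate (s^-1, > 0).
#' @return A `kinetics_summary` list with `k_on` (nM^-1 s^-1), `k_off`
#'   (s^-1), `K_D` (nM) and the inputs.
#' @export
kinetic_kd <- function(concentration_nM, frequency_s, k_off) {
  stopifnot(length(concentration_nM) == length(frequency_s),
            length(concentration_nM) >= 1L, k_off > 0,
            all(concentration_nM > 0))
  k_on <- sum(concentration_nM * frequency_s) / sum(concentration_nM^2)
  structure(list(k_on = k_on, k_off = k_off, K_D = k_off / k_on,
                 concentration_nM = concentration_nM,
                 frequency_s = frequency_s),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf("<kinetics_summary> k_on = %.4g nM^-1 s^-1, k_off = %.4g s^-1, K_D = %.4g nM\n",
              x$k_on, x$k_off, x$K_D))
  invisible(x)
}

#' Categorize a binding event
#'
#' Deterministic classification of one detected binding event from its
#' per-frame state labels, under one of three schemes:
#'
#' * `"composition"`: which site classes the event visits -
#'   `nucleosome_and_linker` (FRET alternates between the linker and
#'   nucleosomal site within the event), `linker_only`, `nucleosome_only`,
#'   or `nonspecific_only`.
#' * `"landing"`: six classes by where the event starts and where it goes -
#'   `linker_to_nucleosome`, `nucleosome_to_linker`, `linker_only`,
#'   `nucleosome_only`, `nonspecific_to_linker`, `nonspecific_to_nucleosome`
#'   (plus `other` for events never reaching a site).
#' * `"nucleosome_access"`: `linker_motif_only` (constant linker-site FRET
#'   throughout), `nucleosomal_motif_only`, `scanning` (dynamic transitions
#'   between the nucleosomal site and nonspecific or linker-site binding),
#'   or `other`.
#'
#' @param states character vector of per-frame labels for one event
#'   (`NA` frames ignored).
#' @param scheme one of `"composition"`, `"landing"`,
#'   `"nucleosome_access"`.
#' @param linker_sites,nucleosome_sites site labels counting as linker /
#'   nucleosomal.
#' @return A single category label.
#' @export
categorize_event <- function(states,
                             scheme = c("composition", "landing",
                                        "nucleosome_access"),
                             linker_sites, nucleosome_sites) {
  scheme <- match.arg(scheme)
  s <- states[!is.na(states) & states != "unbound"]
  if (length(s) == 0L) return("other")
  has_l <- any(s %in% linker_sites)
  has_n <- any(s %in% nucleosome_sites)
  has_ns <- any(s == "nonspecific")
  if (scheme == "composition") {
    if (has_l && has_n) return("nucleosome_and_linker")
    if (has_l) return("linker_only")
    if (has_n) return("nucleosome_only")
    return("nonspecific_only")
  }
  if (scheme == "landing") {
    first <- s[1L]
    if (first %in% linker_sites) {
      return(if (has_n) "linker_to_nucleosome" else "linker_only")
    }
    if (first %in% nucleosome_sites) {
      return(if (has_l) "nucleosome_to_linker" else "nucleosome_only")
    }
    # nonspecific landing: classify by first specific visit
    spec <- s[s %in% c(linker_sites, nucleosome_sites)]
    if (length(spec) == 0L) return("other")
    return(if (spec[1L] %in% linker_sites) "nonspecific_to_linker"
           else "nonspecific_to_nucleosome")
  }
  # nucleosome_access
  if (all(s %in% linker_sites)) return("linker_motif_only")
  if (all(s %in% nucleosome_sites)) return("nucleosomal_motif_only")
  if (has_n && (has_ns || has_l)) return("scanning")
  "other"
}

#' Rebinding preference matrix
#'
#' For ordered binding events per molecule, entry (i, j) is the fraction of
#' events at site i whose next event on the same molecule is at site j.
#' Event pairs never cross molecules.
#'
#' @param molecule molecule identifiers, one per event, in temporal order
#'   within each molecule.
#' @param site site label per event.
#' @return Row-stochastic matrix (rows with no successor events are `NaN`).
#' @export
rebinding_matrix <- function(molecule, site) {
  stopifnot(length(molecule) == length(site))
  sites <- sort(unique(site))
  M <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  for (m in unique(molecule)) {
    s <- site[molecule == m]
    if (length(s) < 2L) next
    for (i in seq_len(length(s) - 1L)) {
      M[s[i], s[i + 1L]] <- M[s[i], s[i + 1L]] + 1
    }
  }
  rs <- rowSums(M)
  sweep(M, 1L, ifelse(rs > 0, rs, NA_real_), "/")
}

#' Fraction of events with a donor-only delay before site binding
#'
#' An event counts when its first decoded frame is nonspecific (donor-only)
#' and a specific-site frame appears later in the same event; the delay
#' threshold is one frame.
#'
#' @param event_states list of character vectors, per-frame labels per event.
#' @param site_states labels that count as specific sites; default: all
#'   labels other than `unbound`/`nonspecific`.
#' @return Fraction in `[0, 1]`.
#' @export
donor_delay_fraction <- function(event_states, site_states = NULL) {
  stopifnot(length(event_states) >= 1L)
  delayed <- vapply(event_states, function(s) {
    s <- s[!is.na(s) & s != "unbound"]
    if (length(s) == 0L) return(FALSE)
    sites <- if (is.null(site_states))
      setdiff(unique(s), "nonspecific") else site_states
    s[1L] == "nonspecific" && any(s %in% sites)
  }, logical(1L))
  mean(delayed)
}
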