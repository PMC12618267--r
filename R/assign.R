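# Binding-site assignment from multicolor intensity traces: event detection,
# Gaussian-emission HMM (Baum-Welch + Viterbi) and the relative-intensity
# rule.  Acceptor-excitation check frames are excluded from decoding and the
# corresponding state labels are NA.

CHANNELS <- c("cy3", "cy5", "cy7")

donor_frames <- function(trace) which(trace$excitation == "Cy3")

#' Detect binding events by intensity thresholding
#'
#' Maximal runs of donor-excitation frames whose total intensity
#' (cy3 + cy5 + cy7) exceeds `bg_mean + k_sigma * bg_sd`.  Runs separated by
#' at least one below-threshold (or acceptor-excitation) frame are distinct
#' events.
#'
#' @param trace an `intensity_trace`.
#' @param bg_mean,bg_sd background mean and sd of the total intensity
#'   (`bg_sd > 0`).
#' @param k_sigma threshold multiplier (default 3).
#' @return `data.frame` with `start_frame`, `end_frame` (inclusive, original
#'   frame numbers) and `n_frames`.
#' @export
detect_events <- function(trace, bg_mean, bg_sd, k_sigma = 3) {
  stopifnot(bg_sd > 0)
  df <- donor_frames(trace)
  total <- trace$cy3 + trace$cy5 + trace$cy7
  above <- logical(nrow(trace))
  above[df] <- total[df] > bg_mean + k_sigma * bg_sd
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_frame = starts[keep], end_frame = ends[keep],
             n_frames = r$lengths[keep])
}

#' Construct HMM parameters
#'
#' @param states state labels; the first is conventionally `"unbound"`.
#' @param init initial state probabilities (sum to 1).
#' @param trans per-frame transition matrix (rows sum to 1).
#' @param means,sds state x channel (cy3, cy5, cy7) Gaussian emission means
#'   and standard deviations.
#' @param loglik optional final log-likelihood (set by [fit_hmm()]).
#' @return An object of class `trace_hmm`.
#' @export
hmm_params <- function(states, init, trans, means, sds, loglik = NA_real_) {
  S <- length(states)
  stopifnot(length(init) == S, all(dim(trans) == c(S, S)),
            all(dim(means) == c(S, 3L)), all(dim(sds) == c(S, 3L)),
            all(sds > 0))
  if (abs(sum(init) - 1) > 1e-9) stop("initial probabilities must sum to 1")
  if (any(abs(rowSums(trans) - 1) > 1e-9)) stop("transition rows must sum to 1")
  dimnames(means) <- dimnames(sds) <- list(states, CHANNELS)
  structure(list(states = states, init = init, trans = trans,
                 means = means, sds = sds, loglik = loglik),
            class = "trace_hmm")
}

#' @export
print.trace_hmm <- function(x, ...) {
  cat(sprintf("<trace_hmm> %d states: %s\n", length(x$states),
              paste(x$states, collapse = ", ")))
  if (!is.na(x$loglik)) cat(sprintf("  log-likelihood %.3f\n", x$loglik))
  cat("  emission means:\n")
  print(round(x$means, 1))
  invisible(x)
}

#' HMM parameters implied by a template and emission model
#'
#' Builds decoding parameters directly from the rendering model: one state
#' per labeled site plus `unbound` and `nonspecific`, emission means equal to
#' the rendered state means, and a sticky transition matrix.
#'
#' @param tpl a `tf_template`.
#' @param emission an [emission_params()].
#' @param stay_prob per-frame self-transition probability (default 0.95).
#' @return A `trace_hmm`.
#' @export
hmm_from_template <- function(tpl, emission = emission_params(),
                              stay_prob = 0.95) {
  states <- c("unbound", "nonspecific", tpl$sites$name)
  S <- length(states)
  bg <- emission$background
  means <- matrix(bg, S, 3L)
  means[2L, 1L] <- bg + emission$donor_total
  if (nrow(tpl$sites)) {
    for (k in seq_len(nrow(tpl$sites))) {
      acc <- tpl$sites$acceptor[k]
      means[2L + k, 1L] <- bg + emission$fret_leak
      if (acc == "Cy5") means[2L + k, 2L] <- bg + emission$donor_total - emission$fret_leak
      if (acc == "Cy7") means[2L + k, 3L] <- bg + emission$donor_total - emission$fret_leak
    }
  }
  sds <- matrix(max(emission$noise_sd, 1e-3), S, 3L)
  trans <- matrix((1 - stay_prob) / (S - 1), S, S)
  diag(trans) <- stay_prob
  hmm_params(states, rep(1 / S, S), trans, means, sds)
}

# per-frame emission log-densities, frames x states (diagonal Gaussian)
emission_loglik <- function(X, params) {
  S <- length(params$states)
  ll <- matrix(0, nrow(X), S)
  for (s in seq_len(S)) {
    for (c in 1:3) {
      ll[, s] <- ll[, s] +
        stats::dnorm(X[, c], params$means[s, c], params$sds[s, c], log = TRUE)
    }
  }
  ll
}

# scaled forward-backward; returns gamma, xi sums, loglik
forward_backward <- function(ll, init, trans) {
  T_ <- nrow(ll); S <- ncol(ll)
  B <- exp(ll - apply(ll, 1L, max))
  a <- matrix(0, T_, S); cscale <- numeric(T_)
  a[1L, ] <- init * B[1L, ]
  cscale[1L] <- sum(a[1L, ]); a[1L, ] <- a[1L, ] / cscale[1L]
  if (T_ >= 2L) {
    for (t in 2:T_) {
      a[t, ] <- (a[t - 1L, ] %*% trans) * B[t, ]
      cscale[t] <- sum(a[t, ])
      a[t, ] <- a[t, ] / cscale[t]
    }
  }
  b <- matrix(0, T_, S); b[T_, ] <- 1
  if (T_ >= 2L) {
    for (t in (T_ - 1L):1L) {
      b[t, ] <- trans %*% (B[t + 1L, ] * b[t + 1L, ]) / cscale[t + 1L]
    }
  }
  g <- a * b
  g <- g / rowSums(g)
  xi <- matrix(0, S, S)
  if (T_ >= 2L) {
    for (t in 1:(T_ - 1L)) {
      m <- (a[t, ] %o% (B[t + 1L, ] * b[t + 1L, ])) * trans / cscale[t + 1L]
      xi <- xi + m
    }
  }
  loglik <- sum(log(cscale)) + sum(apply(ll, 1L, max))
  list(gamma = g, xi = xi, loglik = loglik)
}

#' Fit a Gaussian-emission HMM to intensity traces
#'
#' Baum-Welch estimation over the donor-excitation frames of one or more
#' traces, with seeded k-means initialization of the emission means.  States
#' are `unbound` and `nonspecific` plus one per site; after fitting, states
#' are labeled by their emission signature (lowest total mean is `unbound`;
#' among the rest, acceptor-dominant states become `site_Cy5`/`site_Cy7` and
#' donor-dominant states `nonspecific`).
#'
#' @param traces an `intensity_trace` or list of them.
#' @param n_sites number of labeled sites (>= 1).
#' @param seed integer seed for initialization.
#' @param max_iter,tol EM stopping controls.
#' @param sd_floor lower bound applied to emission sds (regularization; a
#'   zero-variance channel triggers a warning and is floored).
#' @return A `trace_hmm` with `loglik` (final) and attribute
#'   `loglik_trace` (per-iteration, non-decreasing).
#' @export
fit_hmm <- function(traces, n_sites, seed = 1L, max_iter = 100L, tol = 1e-4,
                    sd_floor = NULL) {
  if (inherits(traces, "intensity_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L, n_sites >= 1L)
  Xs <- lapply(traces, function(tr) {
    as.matrix(tr[donor_frames(tr), CHANNELS])
  })
  X <- do.call(rbind, Xs)
  S <- n_sites + 2L
  if (is.null(sd_floor)) sd_floor <- max(1e-6, 1e-3 * max(stats::sd(X), 1e-6))
  km <- with_seed(seed, kmeans(X, centers = S, nstart = 10L, iter.max = 50L))
  means <- km$centers
  sds <- matrix(0, S, 3L)
  for (s in seq_len(S)) {
    xs <- X[km$cluster == s, , drop = FALSE]
    sds[s, ] <- apply(xs, 2L, stats::sd)
  }
  if (any(!is.finite(sds)) || any(sds < sd_floor, na.rm = TRUE)) {
    warning("degenerate emission variance; applying covariance regularization")
  }
  sds[!is.finite(sds) | sds < sd_floor] <- sd_floor
  init <- rep(1 / S, S)
  trans <- matrix(0.1 / (S - 1), S, S); diag(trans) <- 0.9

  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    p <- hmm_params(paste0("s", seq_len(S)), init, trans, means, sds)
    tot_ll <- 0
    xi_sum <- matrix(0, S, S)
    init_new <- numeric(S)
    sum_x <- matrix(0, S, 3L); sum_x2 <- matrix(0, S, 3L); den <- numeric(S)
    for (Xi in Xs) {
      fb <- forward_backward(emission_loglik(Xi, p), init, trans)
      tot_ll <- tot_ll + fb$loglik
      init_new <- init_new + fb$gamma[1L, ]
      xi_sum <- xi_sum + fb$xi
      den <- den + colSums(fb$gamma)
      sum_x <- sum_x + t(fb$gamma) %*% Xi
      sum_x2 <- sum_x2 + t(fb$gamma) %*% (Xi^2)
    }
    ll_trace <- c(ll_trace, tot_ll)
    if (it > 1L && tot_ll - ll_trace[it - 1L] < tol) break
    init <- init_new / sum(init_new)
    trans <- xi_sum / pmax(rowSums(xi_sum), 1e-300)
    means <- sum_x / den
    sds <- sqrt(pmax(sum_x2 / den - means^2, 0))
    sds[!is.finite(sds) | sds < sd_floor] <- sd_floor
  }
  states <- label_states(means)
  out <- hmm_params(states, init, trans, means, sds, loglik = ll_trace[length(ll_trace)])
  attr(out, "loglik_trace") <- ll_trace
  out
}

# name states by emission signature
label_states <- function(means) {
  S <- nrow(means)
  tot <- rowSums(means)
  states <- rep(NA_character_, S)
  iu <- which.min(tot)
  states[iu] <- "unbound"
  rest <- setdiff(seq_len(S), iu)
  base <- means[iu, ]
  for (s in rest) {
    d <- means[s, ] - base
    ch <- which.max(d)
    states[s] <- c("nonspecific", "site_Cy5", "site_Cy7")[ch]
  }
  # disambiguate duplicates
  for (nm in unique(states[duplicated(states)])) {
    idx <- which(states == nm)
    if (length(idx) > 1L) states[idx] <- paste0(nm, "_", seq_along(idx))
  }
  states
}

#' Viterbi binding-site assignment
#'
#' Maximum a posteriori state path over the donor-excitation frames of a
#' trace under a fitted (or constructed) HMM.  Deterministic; ties are broken
#' toward the lower-indexed state.  Acceptor-excitation check frames get an
#' `NA` label.
#'
#' @param trace an `intensity_trace`.
#' @param params a `trace_hmm`.
#' @return A `state_seq`: `data.frame` with `frame`, `time_s`, `state`;
#'   attributes `provenance = "hmm"`, `frame_interval`, `states`.
#' @export
viterbi_assign <- function(trace, params) {
  df <- donor_frames(trace)
  X <- as.matrix(trace[df, CHANNELS])
  ll <- emission_loglik(X, params)
  T_ <- nrow(ll); S <- ncol(ll)
  logtrans <- log(params$trans)
  delta <- matrix(-Inf, T_, S)
  psi <- matrix(0L, T_, S)
  delta[1L, ] <- log(params$init) + ll[1L, ]
  if (T_ >= 2L) for (t in 2:T_) {
    for (s in seq_len(S)) {
      v <- delta[t - 1L, ] + logtrans[, s]
      psi[t, s] <- which.max(v)
      delta[t, s] <- v[psi[t, s]] + ll[t, s]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  if (T_ >= 2L) for (t in (T_ - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  state <- rep(NA_character_, nrow(trace))
  state[df] <- params$states[path]
  new_state_seq(trace, state, "hmm", params$states)
}

new_state_seq <- function(trace, state, provenance, states) {
  structure(data.frame(frame = trace$frame, time_s = trace$time_s,
                       state = state, stringsAsFactors = FALSE),
            provenance = provenance, states = states,
            frame_interval = attr(trace, "frame_interval"),
            id = attr(trace, "id"),
            class = c("state_seq", "data.frame"))
}

#' Relative-intensity binding-site assignment
#'
#' Within detected events, assigns each donor-excitation frame to the
#' Cy5-labeled site if Cy5 fluorescence is stronger than Cy7 (and above the
#' FRET threshold), to the Cy7-labeled site if Cy7 is stronger, and to
#' nonspecific binding if only Cy3 fluorescence is present.  An exact
#' above-threshold tie carries the previous frame's label (nonspecific at the
#' start of an event).  Frames outside events are unbound.
#'
#' @param trace an `intensity_trace`.
#' @param events event table from [detect_events()].
#' @param fret_threshold intensity above which an acceptor channel counts as
#'   FRET (default `bg_mean + 3 * bg_sd`).
#' @param bg_mean,bg_sd per-channel background mean and sd used for the
#'   default threshold.
#' @param site_names named character vector mapping acceptor channels to site
#'   labels, e.g. `c(Cy5 = "site2", Cy7 = "site1")`; defaults come from the
#'   trace's template when present.
#' @return A `state_seq` with `provenance = "relative_intensity"`.
#' @export
relative_intensity_assign <- function(trace, events, fret_threshold = NULL,
                                      bg_mean = NULL, bg_sd = NULL,
                                      site_names = NULL) {
  if (is.null(site_names)) {
    tpl <- attr(trace, "template")
    if (!is.null(tpl) && nrow(tpl$sites)) {
      site_names <- setNames(tpl$sites$name, tpl$sites$acceptor)
    } else {
      site_names <- c(Cy5 = "site_Cy5", Cy7 = "site_Cy7")
    }
  }
  if (is.null(fret_threshold)) {
    if (is.null(bg_mean) || is.null(bg_sd)) {
      stop("supply fret_threshold or bg_mean and bg_sd")
    }
    fret_threshold <- bg_mean + 3 * bg_sd
  }
  state <- rep(NA_character_, nrow(trace))
  df <- donor_frames(trace)
  state[df] <- "unbound"
  for (i in seq_len(nrow(events))) {
    prev <- "nonspecific"
    for (f in events$start_frame[i]:events$end_frame[i]) {
      if (trace$excitation[f] != "Cy3") next
      c5 <- trace$cy5[f]; c7 <- trace$cy7[f]
      lab <- if (c5 > fret_threshold && c5 > c7) unname(site_names["Cy5"])
        else if (c7 > fret_threshold && c7 > c5) unname(site_names["Cy7"])
        else if (c5 > fret_threshold && c5 == c7) prev
        else "nonspecific"
      state[f] <- lab
      prev <- lab
    }
  }
  new_state_seq(trace, state, "relative_intensity",
                c("unbound", "nonspecific", unname(site_names)))
}

#' Count direct site-to-site transitions
#'
#' Within each binding event (maximal run of bound frames), successive visits
#' to specific sites form site-to-site transitions; a transition is *direct*
#' when no nonspecific frame intervenes (transit faster than one camera
#' exposure).
#'
#' @param stateseq a `state_seq` (or character vector of per-frame labels;
#'   `NA`/`"unbound"` frames delimit events).
#' @param site_states labels that count as specific sites (default: all
#'   labels other than `unbound`/`nonspecific`).
#' @return List with `n_direct`, `n_total` and `fraction`.
#' @export
direct_transitions <- function(stateseq, site_states = NULL) {
  labels <- if (is.data.frame(stateseq)) stateseq$state else stateseq
  labels <- labels[!is.na(labels)]
  if (is.null(site_states)) {
    site_states <- setdiff(unique(labels), c("unbound", "nonspecific"))
  }
  bound <- labels != "unbound"
  r <- rle(bound)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  n_direct <- 0L; n_total <- 0L
  for (i in which(r$values)) {
    seg <- labels[starts[i]:ends[i]]
    rr <- rle(seg)
    is_site <- rr$values %in% site_states
    site_idx <- which(is_site)
    if (length(site_idx) < 2L) next
    for (j in seq_len(length(site_idx) - 1L)) {
      n_total <- n_total + 1L
      if (site_idx[j + 1L] == site_idx[j] + 1L) n_direct <- n_direct + 1L
    }
  }
  list(n_direct = n_direct, n_total = n_total,
       fraction = if (n_total > 0L) n_direct / n_total else NA_real_)
}
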