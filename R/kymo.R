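# Kymograph analysis: single-particle tracking with centroid refinement,
# time-averaged MSD, OLS diffusion-coefficient estimation, mobility
# classification, and group comparison.

#' Construct a kymograph container
#'
#' @param counts photon-count matrix, position pixels x scan lines
#'   (non-negative).
#' @param pixel_size pixel size in um (default 0.1).
#' @param line_time line time in s.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(counts, pixel_size = 0.1, line_time = 0.1) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), pixel_size > 0, line_time > 0)
  structure(list(counts = counts, pixel_size = pixel_size,
                 line_time = line_time, tracks = NULL),
            class = "kymograph")
}

#' Track molecules in a kymograph
#'
#' Per scan line, local intensity maxima above `min_photons` seed detections;
#' each position is refined as the intensity centroid within half a track
#' width.  Detections are linked across consecutive lines by greedy
#' nearest-neighbour association with maximum jump equal to the track width;
#' unmatched detections start new tracks.  Tracks shorter than 3 lines are
#' discarded.  Crossing tracks are split, not swapped.
#'
#' @param kymo a `kymograph`.
#' @param track_width association/refinement width in um (must be at least
#'   2 pixels; default 0.5).
#' @param min_photons minimum summed photon count for a detection.
#' @return List of tracks, each a `data.frame` with `line`, `position_um`,
#'   `photons`; attribute `track_id`.
#' @export
track_kymo <- function(kymo, track_width = 0.5, min_photons = 10) {
  px <- kymo$pixel_size
  if (track_width < 2 * px) stop("track_width must be at least 2 pixels")
  C <- kymo$counts
  n_px <- nrow(C); n_lines <- ncol(C)
  if (n_px == 0L || n_lines == 0L) return(list())
  half <- max(1L, round(track_width / 2 / px))
  centers <- (seq_len(n_px) - 0.5) * px
  detect_line <- function(l) {
    v <- C[, l]
    is_max <- v >= c(-Inf, v[-n_px]) & v >= c(v[-1L], -Inf) & v > 0
    peaks <- which(is_max)
    # suppress plateau duplicates / shoulders within the refinement window
    peaks <- peaks[order(v[peaks], decreasing = TRUE)]
    kept <- integer(0)
    for (p in peaks) {
      if (!length(kept) || min(abs(kept - p)) > half) kept <- c(kept, p)
    }
    # background-subtracted centroid, iteratively re-centred so that the
    # finite window does not shrink displacements
    vb <- pmax(v - stats::median(v), 0)
    out <- NULL
    for (p in sort(kept)) {
      ctr <- p
      pos <- centers[p]
      for (it in 1:3) {
        w <- max(1L, ctr - half):min(n_px, ctr + half)
        tot <- sum(vb[w])
        if (tot <= 0) break
        pos <- sum(centers[w] * vb[w]) / tot
        ctr <- max(1L, min(n_px, round(pos / px + 0.5)))
      }
      w <- max(1L, ctr - half):min(n_px, ctr + half)
      tot <- sum(v[w])
      if (tot < min_photons) next
      out <- rbind(out, c(pos = pos, photons = tot, peak = p))
    }
    out
  }
  active <- list()   # each: list(rows = data.frame, last_pos, last_line)
  done <- list()
  for (l in seq_len(n_lines)) {
    det <- detect_line(l)
    used <- logical(if (is.null(det)) 0L else nrow(det))
    if (length(active)) {
      for (ai in seq_along(active)) {
        a <- active[[ai]]
        if (is.null(det) || all(used)) { next }
        dists <- abs(det[, "pos"] - a$last_pos)
        dists[used] <- Inf
        j <- which.min(dists)
        if (dists[j] <= track_width) {
          used[j] <- TRUE
          a$rows <- rbind(a$rows,
                          data.frame(line = l, position_um = det[j, "pos"],
                                     photons = det[j, "photons"]))
          a$last_pos <- det[j, "pos"]; a$last_line <- l
          active[[ai]] <- a
        }
      }
    }
    # close tracks not extended this line
    keep <- vapply(active, function(a) a$last_line == l, logical(1L))
    done <- c(done, lapply(active[!keep], function(a) a$rows))
    active <- active[keep]
    # new tracks from unmatched detections
    if (!is.null(det)) {
      for (j in which(!used)) {
        active[[length(active) + 1L]] <-
          list(rows = data.frame(line = l, position_um = det[j, "pos"],
                                 photons = det[j, "photons"]),
               last_pos = det[j, "pos"], last_line = l)
      }
    }
  }
  done <- c(done, lapply(active, function(a) a$rows))
  done <- Filter(function(d) nrow(d) >= 3L, done)
  for (i in seq_along(done)) attr(done[[i]], "track_id") <- i
  done
}

#' Time-averaged mean squared displacement
#'
#' `MSD(k) = mean over i of (x[i+k] - x[i])^2` using all overlapping pairs,
#' for lags `k = 1..max_lag`.
#'
#' @param track a track `data.frame` (column `position_um`) or numeric
#'   position vector, equally spaced in time.
#' @param max_lag maximum lag (default 5); track must be longer than this.
#' @param overlapping use overlapping displacement pairs (default `TRUE`);
#'   `FALSE` uses disjoint pairs.
#' @return Numeric vector of MSD values (um^2), names `1..max_lag`.
#' @export
msd <- function(track, max_lag = 5L, overlapping = TRUE) {
  x <- if (is.data.frame(track)) track$position_um else as.numeric(track)
  n <- length(x)
  if (n <= max_lag) stop("track length must exceed max_lag")
  v <- vapply(seq_len(max_lag), function(k) {
    if (overlapping) {
      mean((x[(1L + k):n] - x[1:(n - k)])^2)
    } else {
      i <- seq(1L, n - k, by = k)
      mean((x[i + k] - x[i])^2)
    }
  }, numeric(1L))
  names(v) <- seq_len(max_lag)
  v
}

#' Estimate a diffusion coefficient from MSD values
#'
#' Ordinary least squares fit of `MSD = 2 D tau + b` over lags, with a free
#' intercept absorbing localization error; `D = slope / 2`.
#'
#' @param msd_values MSD values at lags `1..length(msd_values)` (um^2); at
#'   least 2 lags.
#' @param line_time time per lag step in s.
#' @return A `diffusion_estimate` with `D` (um^2 s^-1), `intercept`, `msd`,
#'   `lags_s`.
#' @export
estimate_D <- function(msd_values, line_time) {
  stopifnot(length(msd_values) >= 2L, line_time > 0)
  tau <- seq_along(msd_values) * line_time
  fit <- lm(msd_values ~ tau)
  structure(list(D = unname(coef(fit)[2L] / 2),
                 intercept = unname(coef(fit)[1L]),
                 msd = msd_values, lags_s = tau),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.4g um^2/s (intercept %.3g um^2, %d lags)\n",
              x$D, x$intercept, length(x$msd)))
  invisible(x)
}

#' @export
coef.diffusion_estimate <- function(object, ...) {
  c(D = object$D, intercept = object$intercept)
}

#' Per-track diffusion estimation over a kymograph
#'
#' Convenience chain: [track_kymo()] on a kymograph (or a supplied track
#' list), [msd()] per track, [estimate_D()] per track, then the across-track
#' mean D with its standard error.
#'
#' @param tracks list of tracks (from [track_kymo()] or ground truth).
#' @param line_time line time in s.
#' @param max_lag maximum MSD lag (default 5).
#' @return List with `D_mean`, `D_sem`, `D` (per track), `n`.
#' @export
diffusion_by_track <- function(tracks, line_time, max_lag = 5L) {
  tracks <- Filter(function(d) nrow(d) > max_lag, tracks)
  D <- vapply(tracks, function(tr) {
    estimate_D(msd(tr, max_lag), line_time)$D
  }, numeric(1L))
  list(D_mean = mean(D), D_sem = stats::sd(D) / sqrt(length(D)), D = D,
       n = length(D))
}

#' Classify mobility of a bound molecule
#'
#' Nondiffusive binding is defined by `D < threshold` (strict), with the
#' threshold at 0.01 um^2 s^-1 by default.
#'
#' @param D diffusion coefficient(s) in um^2 s^-1 (>= 0).
#' @param threshold mobility threshold (default 0.01).
#' @return Character vector, `"diffusive"` or `"nondiffusive"`.
#' @export
classify_mobility <- function(D, threshold = 0.01) {
  stopifnot(all(D >= 0))
  ifelse(D < threshold, "nondiffusive", "diffusive")
}

#' Compare diffusion coefficients between two conditions
#'
#' Two-tailed unpaired t-test with Welch's correction
#' (Welch-Satterthwaite degrees of freedom).
#'
#' @param a,b numeric vectors of per-track D values, each with `n >= 2` and
#'   nonzero variance.
#' @return List with `t`, `p`, `df`.
#' @export
compare_groups <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    stop("both groups have zero variance")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Convert between um and bp on stretched or wrapped DNA
#'
#' Two conventions exist and must be chosen explicitly: `"tether"` uses
#' 3.3 kbp per um (one plasmid length spans ~1 um on a stretched tether);
#' `"contour"` uses 0.34 nm per bp (B-DNA contour length).
#'
#' @param x value(s) to convert.
#' @param from,to `"um"` or `"bp"`.
#' @param context `"tether"` or `"contour"`.
#' @return Converted value(s).
#' @export
convert_dna_length <- function(x, from = c("um", "bp"), to = c("bp", "um"),
                               context = c("tether", "contour")) {
  from <- match.arg(from); to <- match.arg(to)
  context <- match.arg(context)
  if (from == to) return(x)
  bp_per_um <- switch(context, tether = 3300, contour = 1000 / 0.34)
  if (from == "um") x * bp_per_um else x / bp_per_um
}
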