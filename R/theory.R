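# Closed-form facilitated-diffusion calculators.
#
# One-dimensional Brownian length scale: <x^2> = 2 D t, so the distance a
# slider covers in time t is sqrt(2 D t) and covering L within t requires
# D >= L^2 / (2 t).

#' Characteristic 1D sliding length
#'
#' Distance a 1D Brownian slider covers in time `t`: `sqrt(2 D t)`.
#'
#' @param D diffusion coefficient in um^2 s^-1 (>= 0).
#' @param t time in s (>= 0).
#' @return Length in um.
#' @examples
#' sliding_length(0.149, 0.2)  # ~0.25 um
#' @export
sliding_length <- function(D, t) {
  stopifnot(all(D >= 0), all(t >= 0))
  sqrt(2 * D * t)
}

#' Diffusion coefficient required to cover a distance
#'
#' Inverse of [sliding_length()]: `L^2 / (2 t)`.
#'
#' @param L distance in um (>= 0).
#' @param t time in s (> 0).
#' @return D in um^2 s^-1.
#' @examples
#' required_D(1, 0.2)  # 2.5 um^2/s
#' @export
required_D <- function(L, t) {
  stopifnot(all(L >= 0), all(t > 0))
  L^2 / (2 * t)
}

#' Probability of landing within a segment
#'
#' Probability that a uniform landing on an interval of length `L` falls
#' within a segment of length `l`: `min(1, l / L)`.
#'
#' @param l segment length (>= 0), same units as `L`.
#' @param L interval length (> 0).
#' @return Probability in `[0, 1]`.
#' @export
interval_hit_probability <- function(l, L) {
  stopifnot(all(l >= 0), all(L > 0))
  pmin(1, l / L)
}

#' Probability of falsely calling short-range 1D sliding a 3D event
#'
#' A molecule landing within one sliding length of the target reaches it
#' within a single exposure and looks like direct 3D binding:
#' `interval_hit_probability(sliding_length(D, t_exposure), spacing)`.
#'
#' @param D 1D diffusion coefficient in um^2 s^-1.
#' @param t_exposure exposure time in s.
#' @param spacing distance between targets in um (> 0).
#' @return Probability in `[0, 1]`.
#' @export
false_3d_fraction <- function(D, t_exposure, spacing) {
  interval_hit_probability(sliding_length(D, t_exposure), spacing)
}

#' Fold ratio with reporting-style rounding
#'
#' `a / b` rounded half-up to the nearest integer (`mode = "integer"`) or to
#' one significant figure (`mode = "one_sig_fig"`, for "~N-fold" claims).
#'
#' @param a,b numerator and denominator (`b != 0`).
#' @param mode rounding mode.
#' @return Rounded fold change.
#' @examples
#' fold_ratio(3.1, 0.33)                      # 9
#' fold_ratio(0.222, 0.007, "one_sig_fig")    # 30
#' @export
fold_ratio <- function(a, b, mode = c("integer", "one_sig_fig")) {
  if (any(b == 0)) stop("denominator must be nonzero")
  mode <- match.arg(mode)
  r <- a / b
  switch(mode,
         integer = round_half_up(r, 0),
         one_sig_fig = signif_half_up(r, 1))
}
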