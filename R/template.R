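# DNA / nucleosome template model: motif sites, SHL coordinates, accessibility.
#
# Coordinates are 0-based, half-open throughout.  A nucleosome core occupies the
# 147 bp centred on the dyad (positions dyad-73 .. dyad+73 inclusive); one
# superhelical location (SHL) spans 73/7 ~ 10.43 bp so that SHL +/-7 falls on
# the outermost core base pairs.

BP_PER_SHL <- 73 / 7
CORE_HALF <- 73L

#' Construct a labeled motif site
#'
#' A motif site is a genomic-style interval on a template: 0-based, half-open,
#' at least 3 bp wide, optionally carrying the acceptor fluorophore attached
#' near it (`"Cy5"`, `"Cy7"`, or `"none"` for unlabeled).
#'
#' @param name site label, e.g. `"site1"`.
#' @param start,end 0-based half-open interval on the template.
#' @param strand `"+"` or `"-"`.
#' @param acceptor `"Cy5"`, `"Cy7"` or `"none"`.
#' @return A one-row `data.frame` with columns `name`, `start`, `end`,
#'   `strand`, `acceptor`.
#' @export
motif_site <- function(name, start, end, strand = "+", acceptor = "none") {
  stopifnot(is.character(name), length(name) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 0L && start < end)) {
    stop("motif site must satisfy 0 <= start < end")
  }
  if (end - start < 3L) stop("motif site must span at least 3 bp")
  strand <- match.arg(strand, c("+", "-"))
  acceptor <- match.arg(acceptor, c("none", "Cy5", "Cy7"))
  data.frame(name = name, start = start, end = end, strand = strand,
             acceptor = acceptor, stringsAsFactors = FALSE)
}

#' Construct a DNA / nucleosome template
#'
#' Bundles a DNA sequence with labeled motif-site annotations and, for
#' nucleosomal templates, the dyad position of a 147-bp core particle.
#'
#' @param sequence DNA string over `A`,`C`,`G`,`T`.
#' @param sites `data.frame` of motif sites (rows as built by [motif_site()]);
#'   may be empty.
#' @param dyad 0-based position of the nucleosome dyad, or `NA` for bare DNA.
#'   When present the 147-bp core `[dyad - 73, dyad + 73]` must lie inside the
#'   sequence.
#' @param phase_offset rotational phase offset in bp, in `[0, 10)`; shifts the
#'   solvent-facing window used by [site_accessibility()].
#' @param name template name (used as the chromosome field in BED-like output).
#' @return An object of class `tf_template`.
#' @seealso [scan_motifs()], [shl_of()], [site_accessibility()]
#' @export
template <- function(sequence, sites = NULL, dyad = NA, phase_offset = 0,
                     name = "template") {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("empty template sequence")
  if (grepl("[^ACGT]", sequence)) stop("template sequence has non-ACGT characters")
  L <- nchar(sequence)
  if (is.null(sites)) {
    sites <- motif_site("x", 0, 3)[0L, ]
  }
  stopifnot(all(c("name", "start", "end", "strand", "acceptor") %in% names(sites)))
  if (nrow(sites)) {
    if (any(sites$start < 0L | sites$end > L)) stop("site outside template bounds")
    if (any(sites$end - sites$start < 3L)) stop("site shorter than 3 bp")
    for (s in unique(sites$strand)) {
      ss <- sites[sites$strand == s, , drop = FALSE]
      ss <- ss[order(ss$start), , drop = FALSE]
      if (nrow(ss) > 1L && any(ss$start[-1L] < ss$end[-nrow(ss)])) {
        stop("overlapping sites on the same strand")
      }
    }
  }
  dyad <- if (is.na(dyad)) NA_integer_ else as.integer(dyad)
  if (!is.na(dyad) && (dyad - CORE_HALF < 0L || dyad + CORE_HALF > L - 1L)) {
    stop("147-bp nucleosome core does not fit inside the sequence")
  }
  if (phase_offset < 0 || phase_offset >= 10) stop("phase_offset must be in [0, 10)")
  structure(list(name = name, sequence = sequence, sites = sites,
                 dyad = dyad, phase_offset = phase_offset),
            class = "tf_template")
}

#' @export
print.tf_template <- function(x, ...) {
  L <- nchar(x$sequence)
  cat(sprintf("<tf_template> %s: %d bp, %d site(s), %s\n", x$name, L,
              nrow(x$sites),
              if (is.na(x$dyad)) "bare DNA" else sprintf("dyad at bp %d", x$dyad)))
  if (nrow(x$sites)) print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Linker spans of a template
#'
#' @param tpl a `tf_template`.
#' @return A `data.frame` with 0-based half-open `start`,`end` of each linker
#'   span (the whole sequence for bare DNA).
#' @export
linker_spans <- function(tpl) {
  L <- nchar(tpl$sequence)
  if (is.na(tpl$dyad)) {
    return(data.frame(start = 0L, end = L))
  }
  out <- data.frame(start = integer(), end = integer())
  if (tpl$dyad - CORE_HALF > 0L) {
    out <- rbind(out, data.frame(start = 0L, end = tpl$dyad - CORE_HALF))
  }
  if (tpl$dyad + CORE_HALF + 1L < L) {
    out <- rbind(out, data.frame(start = tpl$dyad + CORE_HALF + 1L, end = L))
  }
  out
}

#' Exact motif scan
#'
#' Finds all exact (overlap-allowed) occurrences of a motif in a DNA sequence,
#' optionally on both strands.  Minus-strand hits are matches of the motif's
#' reverse complement, reported in plus-strand coordinates with `strand = "-"`.
#'
#' @param sequence DNA string (`A/C/G/T`).
#' @param motif non-empty DNA string.
#' @param both_strands scan the minus strand as well (default `FALSE`).
#' @return `data.frame` of sites (columns as [motif_site()]); zero rows if no
#'   match.
#' @examples
#' scan_motifs("GAGAGAG", "GAGAG")   # two overlapping hits
#' @export
scan_motifs <- function(sequence, motif, both_strands = FALSE) {
  sequence <- toupper(as.character(sequence))
  motif <- toupper(as.character(motif))
  if (nchar(motif) == 0L) stop("empty motif")
  if (grepl("[^ACGT]", motif)) stop("motif has non-ACGT characters")
  if (nchar(sequence) > 0L && grepl("[^ACGT]", sequence)) {
    stop("sequence has non-ACGT characters")
  }
  empty <- motif_site("x", 0, 3)[0L, ]
  if (nchar(sequence) < nchar(motif)) return(empty)
  subj <- Biostrings::DNAString(sequence)
  one_strand <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj)
    if (length(m) == 0L) return(empty)
    st <- Biostrings::start(m) - 1L
    data.frame(name = sprintf("%s_%s%d", motif, ifelse(strand == "+", "p", "m"), st),
               start = st, end = st + nchar(pat), strand = strand,
               acceptor = "none", stringsAsFactors = FALSE)
  }
  out <- one_strand(motif, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    out <- rbind(out, one_strand(rc, "-"))
  }
  out[order(out$start), , drop = FALSE]
}

#' Probability of hitting a cognate motif by a random collision
#'
#' Number of exact cognate k-mer occurrences divided by the number of k-bp
#' windows (`L - k + 1`).  By default only plus-strand windows are counted.
#'
#' @param tpl a `tf_template` (or plain DNA string).
#' @param motif cognate motif (default `"GAGAG"`); `k = nchar(motif)`.
#' @param both_strands also count minus-strand occurrences (default `FALSE`).
#' @return Fraction in `[0, 1]`.
#' @seealso [round_percent()] for nearest-percent reporting.
#' @export
random_hit_probability <- function(tpl, motif = "GAGAG", both_strands = FALSE) {
  seq <- if (inherits(tpl, "tf_template")) tpl$sequence else toupper(as.character(tpl))
  k <- nchar(motif)
  L <- nchar(seq)
  if (k > L) stop("motif longer than template")
  hits <- scan_motifs(seq, motif, both_strands = both_strands)
  nrow(hits) / (L - k + 1)
}

#' Superhelical location of a base-pair position
#'
#' Maps a position to its SHL coordinate, `(position - dyad) / (73/7)`,
#' reported to the nearest 0.5.  Positions outside the 147-bp core (and every
#' position on a bare-DNA template) are linker and return `NA`.
#'
#' @param position_bp 0-based position(s) on the template.
#' @param tpl a `tf_template`.
#' @return Numeric vector of SHL values (half-integer resolution); `NA` for
#'   linker positions.
#' @export
shl_of <- function(position_bp, tpl) {
  L <- nchar(tpl$sequence)
  if (any(position_bp < 0 | position_bp >= L)) stop("position outside template")
  if (is.na(tpl$dyad)) return(rep(NA_real_, length(position_bp)))
  d <- position_bp - tpl$dyad
  shl <- round(d / BP_PER_SHL / 0.5) * 0.5
  shl[abs(d) > CORE_HALF] <- NA_real_
  shl
}

#' Accessibility class of a motif site
#'
#' Classifies a site by where it sits relative to the nucleosome:
#' `linker_slidable` (on linker DNA, reachable by 1D sliding),
#' `edge_slidable` (at SHL +/-7, the outermost reach of sliding),
#' `core_3d_exposed` (inside the core but solvent-facing, reachable only by
#' direct 3D binding), or `core_occluded` (histone-facing, inaccessible).
#'
#' A core site is solvent-facing when
#' `((site_center - dyad) + phase_offset) mod 10` falls inside
#' `solvent_window`, a half-period (5 bp) window, so that shifting a site by
#' 5 bp flips its exposure.
#'
#' @param site one-row site `data.frame` (or index into `tpl$sites`).
#' @param tpl a `tf_template`.
#' @param solvent_window length-2 numeric, half-open `[lo, hi)` window of the
#'   10-bp helical period that faces the solvent (default `c(3, 8)`).
#' @return One of `"linker_slidable"`, `"edge_slidable"`, `"core_3d_exposed"`,
#'   `"core_occluded"`.
#' @export
site_accessibility <- function(site, tpl, solvent_window = c(3, 8)) {
  if (is.numeric(site) && length(site) == 1L) site <- tpl$sites[site, , drop = FALSE]
  stopifnot(nrow(site) == 1L)
  if (site$end > nchar(tpl$sequence)) stop("site outside template")
  if (is.na(tpl$dyad)) return("linker_slidable")
  center <- (site$start + site$end) / 2
  d <- center - tpl$dyad
  if (abs(d) > CORE_HALF) return("linker_slidable")
  shl <- round(d / BP_PER_SHL / 0.5) * 0.5   # half-integer SHL, as reported
  if (abs(shl) >= 7) return("edge_slidable")
  w <- (d + tpl$phase_offset) %% 10
  if (w >= solvent_window[1L] && w < solvent_window[2L]) "core_3d_exposed" else "core_occluded"
}

# ---- rounding conventions used when reporting printed-style figures --------

#' Half-up rounding helpers
#'
#' `round_half_up()` rounds to `digits` decimals with ties away from zero
#' (unlike base [round()], which rounds half to even).  `signif_half_up()`
#' does the same to a number of significant figures.  `round_percent()`
#' converts a fraction to the nearest whole percent.
#'
#' @param x numeric.
#' @param digits decimal places (`round_half_up`) or significant figures
#'   (`signif_half_up`).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @rdname round_half_up
#' @export
signif_half_up <- function(x, digits = 1) {
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - digits + 1
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / 10^e + 0.5) * 10^e
  out
}

#' @rdname round_half_up
#' @param p fraction in `[0, 1]`.
#' @export
round_percent <- function(p) round_half_up(100 * p, 0)
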