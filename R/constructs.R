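# Standard experimental constructs, generated deterministically in code.
#
# Background sequences are synthetic (seeded random DNA scrubbed of the cognate
# motif); only the planted motif elements, lengths, label positions and
# nucleosome geometry reproduce the experimental designs.  Nucleosome
# positioning is declared by the dyad annotation, not encoded in sequence.

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# random DNA of length L containing no occurrence of any `avoid` motif on
# either strand; deterministic given seed
dna_without <- function(L, avoid = "GAGAG", seed = 1L) {
  avoid <- unique(c(avoid, vapply(avoid, function(m) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
  }, character(1L))))
  with_seed(seed, {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    repeat {
      seqc <- paste(s, collapse = "")
      hit <- FALSE
      for (m in avoid) {
        h <- scan_motifs(seqc, m)
        if (nrow(h)) {
          hit <- TRUE
          for (i in seq_len(nrow(h))) {
            idx <- (h$start[i] + 1L):h$end[i]
            s[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
          }
        }
      }
      if (!hit) return(seqc)
    }
  })
}

# plant `insert` at 0-based offset `at`, then verify the expected plus-strand
# GAGAG count (junctions can create spurious motifs; bump the background seed
# until clean)
plant <- function(L, inserts, expected_gagag, seed = 1L) {
  for (s in seed + 0:50) {
    bg <- dna_without(L, seed = s)
    v <- strsplit(bg, "")[[1L]]
    for (i in seq_len(nrow(inserts))) {
      at <- inserts$at[i]
      piece <- strsplit(inserts$what[i], "")[[1L]]
      v[(at + 1L):(at + length(piece))] <- piece
    }
    out <- paste(v, collapse = "")
    if (nrow(scan_motifs(out, "GAGAG")) == expected_gagag) return(out)
  }
  stop("could not assemble construct without spurious motifs")
}

#' Standard two-color cognate DNA construct
#'
#' A 90-bp surface-tethered DNA carrying a single `GAGAGAG` element (two
#' overlapping `GAGAG` cognate motifs) with a Cy5 acceptor at the element.
#'
#' @return A `tf_template` with one 7-bp Cy5-labeled cognate site.
#' @export
template_cognate_dna <- function() {
  seqc <- plant(90L, data.frame(at = 41L, what = "GAGAGAG"), expected_gagag = 2L,
                seed = 11L)
  template(seqc,
           sites = motif_site("cognate", 41L, 48L, acceptor = "Cy5"),
           name = "cognate90")
}

#' Standard two-color noncognate control DNA
#'
#' Same 90-bp design with the cognate element replaced by the non-target
#' sequence `TATACAG`; the construct carries no specific site.
#'
#' @return A `tf_template` with no motif sites.
#' @export
template_noncognate_dna <- function() {
  seqc <- plant(90L, data.frame(at = 41L, what = "TATACAG"), expected_gagag = 0L,
                seed = 11L)
  template(seqc, name = "noncognate90")
}

#' Three-color hsp70-promoter-like construct
#'
#' A 187-bp fragment with two cognate elements ~40 bp apart: site 1, a longer
#' 12-bp GAGAG-repeat element labeled with Cy7, and site 2, a 7-bp `GAGAGAG`
#' element labeled with Cy5.  With `nucleosome = TRUE` the fragment is a
#' 40-N-0 nucleosome (dyad at bp 113) placing both sites on nucleosomal DNA.
#'
#' @param nucleosome position a nucleosome core on the fragment
#'   (default `FALSE`, bare DNA).
#' @return A `tf_template` with two labeled sites.
#' @export
template_hsp70 <- function(nucleosome = FALSE) {
  seqc <- plant(187L,
                data.frame(at = c(55L, 97L),
                           what = c("GAGAGAGAGAGA", "GAGAGAG")),
                expected_gagag = 6L, seed = 21L)
  template(seqc,
           sites = rbind(motif_site("site1", 55L, 67L, acceptor = "Cy7"),
                         motif_site("site2", 97L, 104L, acceptor = "Cy5")),
           dyad = if (nucleosome) 113L else NA,
           name = if (nucleosome) "hsp70p_nuc" else "hsp70p")
}

#' Positioned-nucleosome (40-N-40) construct with an internal cognate site
#'
#' A 227-bp template with a 147-bp nucleosome core (dyad at bp 113) flanked by
#' 40-bp linkers.  A Cy5-labeled `GAGAGAG` cognate site sits on the left
#' linker; a Cy7-labeled 5-bp `GAGAG` site is placed at the requested
#' superhelical location on nucleosomal DNA.  `shift_bp` moves the nucleosomal
#' site toward the dyad (a 5-bp shift flips its rotational phase from
#' histone-facing to solvent-facing).
#'
#' @param shl superhelical location of the nucleosomal site (7, 5 or 3 in the
#'   standard designs; any value in `(0, 7]` accepted).
#' @param shift_bp shift of the nucleosomal site toward the dyad, in bp
#'   (default 0; 5 gives the SHL4.5 / SHL2.5 solvent-facing variants).
#' @return A `tf_template`.
#' @export
template_601 <- function(shl = 7, shift_bp = 0) {
  dyad <- 113L
  center <- dyad + shl * BP_PER_SHL - shift_bp
  start <- as.integer(round(center)) - 3L
  seqc <- plant(227L,
                data.frame(at = c(10L, start), what = c("GAGAGAG", "GAGAG")),
                expected_gagag = 3L, seed = 31L)
  template(seqc,
           sites = rbind(motif_site("linker_site", 10L, 17L, acceptor = "Cy5"),
                         motif_site("nuc_site", start, start + 5L, acceptor = "Cy7")),
           dyad = dyad,
           name = sprintf("601_SHL%g", round((shl - shift_bp / BP_PER_SHL) / 0.5) * 0.5))
}
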