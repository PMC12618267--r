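# Shared fixtures and independent oracles, all built in code.

# small bare-DNA template with two labeled sites, for fast trace tests
simple_template <- function() {
  template(paste0("ACGTTGCACCGTTACGGATTACGCCGTATACCGGAT",   # 36 bp
                  "GAGAG",
                  "TTACCGGTTAACCGGTTAACCGGTTAACC",           # 29 bp
                  "GAGAG",
                  "ACCGGTTAACCGGTTAAGGCCAATTGGCC"),
           sites = rbind(motif_site("site1", 36L, 41L, acceptor = "Cy7"),
                         motif_site("site2", 70L, 75L, acceptor = "Cy5")),
           name = "simple")
}

# brute-force motif scan: sliding window
bf_scan <- function(sequence, motif) {
  k <- nchar(motif)
  L <- nchar(sequence)
  if (L < k) return(integer())
  which(vapply(0:(L - k), function(i) {
    substr(sequence, i + 1L, i + k) == motif
  }, logical(1L))) - 1L
}

# brute-force Viterbi by exhaustive path enumeration (log scores); ties are
# broken toward the lexicographically smallest path over lower state indices,
# matching per-step argmax tie-breaking when scores are distinct
bf_viterbi <- function(ll, init, trans) {
  T_ <- nrow(ll); S <- ncol(ll)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_))[, T_:1, drop = FALSE])
  score <- log(init[paths[, 1L]]) + ll[cbind(1L, paths[, 1L])]
  if (T_ >= 2L) {
    for (t in 2:T_) {
      score <- score + log(trans)[cbind(paths[, t - 1L], paths[, t])] +
        ll[cbind(t, paths[, t])]
    }
  }
  paths[which.max(score), ]
}

# random HMM parameters for oracle batteries
random_hmm <- function(S) {
  trans <- matrix(runif(S * S, 0.05, 1), S, S)
  trans <- trans / rowSums(trans)
  init <- runif(S, 0.05, 1); init <- init / sum(init)
  means <- matrix(runif(S * 3, 0, 1000), S, 3L)
  sds <- matrix(runif(S * 3, 20, 120), S, 3L)
  hmm_params(paste0("s", seq_len(S)), init, trans, means, sds)
}

# wrap raw channel values into an intensity_trace (all donor excitation)
as_trace <- function(cy3, cy5, cy7, dt = 0.1, excitation = "Cy3") {
  n <- length(cy3)
  structure(data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1L) * dt,
                       cy3 = cy3, cy5 = cy5, cy7 = cy7,
                       excitation = rep_len(excitation, n),
                       stringsAsFactors = FALSE),
            frame_interval = dt, id = "fixture",
            class = c("intensity_trace", "data.frame"))
}

# state_seq from a plain label vector
as_state_seq <- function(labels, dt = 0.1, id = "fixture") {
  n <- length(labels)
  structure(data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1L) * dt,
                       state = labels, stringsAsFactors = FALSE),
            provenance = "ground_truth", states = unique(labels),
            frame_interval = dt, id = id,
            class = c("state_seq", "data.frame"))
}
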