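# Plain-text I/O: TSV traces, FASTA + BED-like templates, kymograph
# containers, rastergrams and dwell tables.  All writers accept an optional
# header of key=value comment lines (seed, config hash) and all readers skip
# comment lines.

TRACE_COLS <- c("frame", "time_s", "cy3", "cy5", "cy7", "excitation")

#' Write / read an intensity trace as TSV
#'
#' Columns `frame`, `time_s`, `cy3`, `cy5`, `cy7`, `excitation`; `#`-prefixed
#' header comment lines carry metadata.  `read_trace()` validates the header,
#' reports malformed rows with their line number, and infers the frame
#' interval from the time column (which must be constant within 1%).
#'
#' @param trace an `intensity_trace`.
#' @param path file path.
#' @param meta named character vector written as `# key=value` lines.
#' @return `read_trace()` returns an `intensity_trace`.
#' @export
write_trace <- function(trace, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s=%s", names(meta), meta), con)
  }
  writeLines(sprintf("# id=%s", attr(trace, "id") %||% "trace"), con)
  out <- as.data.frame(trace)[, TRACE_COLS]
  out[, 2:5] <- signif(out[, 2:5], 7)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  id <- sub("^# id=", "", grep("^# id=", lines, value = TRUE))
  body <- lines[!hdr]
  if (length(body) < 2L) stop("trace file has no data rows")
  cols <- strsplit(body[1L], "\t")[[1L]]
  missing_cols <- setdiff(TRACE_COLS, cols)
  if (length(missing_cols)) {
    stop("trace file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  num <- c("frame", "time_s", "cy3", "cy5", "cy7")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad)) {
      line_no <- which(!hdr)[1L + bad[1L]]
      stop(sprintf("malformed value in column '%s' at line %d", cn, line_no))
    }
    df[[cn]] <- v
  }
  dts <- diff(df$time_s)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 0.01 * dt)) {
    stop("frame interval inferred from time column is not constant within 1%")
  }
  structure(df[, TRACE_COLS], frame_interval = dt,
            id = if (length(id)) id[1L] else "trace",
            class = c("intensity_trace", "data.frame"))
}

#' Read / write a template as FASTA plus BED-like annotations
#'
#' The FASTA file holds a single record.  The annotation file is a BED-like
#' TSV with columns `chrom`, `start`, `end`, `name`, `strand`, `attribute`
#' (0-based half-open coordinates).  Site rows carry `acceptor=Cy5`,
#' `acceptor=Cy7` or `acceptor=none` in the attribute column; an optional
#' `dyad` row marks the nucleosome dyad at its `start` coordinate.
#'
#' @param fasta_path path to the FASTA file.
#' @param annot_path path to the BED-like TSV.
#' @return `read_template()` returns a `tf_template`.
#' @export
read_template <- function(fasta_path, annot_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) stop("template FASTA must contain a single record")
  sequence <- as.character(seqs[[1L]])
  nm <- names(seqs)[1L]
  ann <- utils::read.delim(annot_path, comment.char = "#", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "strand", "attribute"))
  if (any(ann$end > nchar(sequence) | ann$start < 0)) {
    stop("annotation outside sequence bounds")
  }
  is_dyad <- ann$attribute == "dyad" | ann$name == "dyad"
  dyad <- if (any(is_dyad)) ann$start[which(is_dyad)[1L]] else NA
  sit <- ann[!is_dyad, , drop = FALSE]
  sites <- NULL
  if (nrow(sit)) {
    acc <- sub("^acceptor=", "", sit$attribute)
    acc[!acc %in% c("Cy5", "Cy7")] <- "none"
    sites <- do.call(rbind, lapply(seq_len(nrow(sit)), function(i) {
      motif_site(sit$name[i], sit$start[i], sit$end[i],
                 strand = sit$strand[i], acceptor = acc[i])
    }))
  }
  template(sequence, sites = sites, dyad = dyad, name = nm)
}

#' @rdname read_template
#' @param tpl a `tf_template`.
#' @export
write_template <- function(tpl, fasta_path, annot_path) {
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(tpl$sequence), tpl$name), fasta_path)
  rows <- NULL
  if (nrow(tpl$sites)) {
    rows <- data.frame(chrom = tpl$name, start = tpl$sites$start,
                       end = tpl$sites$end, name = tpl$sites$name,
                       strand = tpl$sites$strand,
                       attribute = paste0("acceptor=", tpl$sites$acceptor))
  }
  if (!is.na(tpl$dyad)) {
    rows <- rbind(rows, data.frame(chrom = tpl$name, start = tpl$dyad,
                                   end = tpl$dyad + 1L, name = "dyad",
                                   strand = "+", attribute = "dyad"))
  }
  write.table(rows, annot_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(annot_path)
}

#' Write / read a kymograph as a delimited-text container
#'
#' Header comment lines carry `pixel_size_um` and `line_time_s`; the body is
#' the photon-count matrix (pixels x lines) as TSV.
#'
#' @param kymo a `kymograph`.
#' @param path file path.
#' @return `read_kymograph()` returns a `kymograph` (without ground-truth
#'   tracks).
#' @export
write_kymograph <- function(kymo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pixel_size_um=%.6g", kymo$pixel_size),
               sprintf("# line_time_s=%.6g", kymo$line_time)), con)
  write.table(kymo$counts, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) stop("kymograph file missing header key ", key)
    as.numeric(sub(".*=", "", m[1L]))
  }
  counts <- as.matrix(utils::read.delim(text = paste(lines[!grepl("^#", lines)],
                                                     collapse = "\n"),
                                        header = FALSE))
  dimnames(counts) <- NULL
  kymograph(counts, pixel_size = getv("pixel_size_um"),
            line_time = getv("line_time_s"))
}

#' Write a state sequence (rastergram) as TSV
#'
#' Columns `frame`, `time_s`, `state`; metadata as `#` comment lines.
#'
#' @param stateseq a `state_seq`.
#' @param path file path.
#' @param meta named character vector written as `# key=value` lines.
#' @export
write_rastergram <- function(stateseq, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(sprintf("# %s=%s", names(meta), meta), con)
  writeLines(sprintf("# provenance=%s", attr(stateseq, "provenance") %||% "unknown"),
             con)
  write.table(as.data.frame(stateseq), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Plot an intensity trace
#'
#' Donor-excitation channel intensities against time, one line per channel
#' (Cy3 green, Cy5 red, Cy7 dark red).
#'
#' @param x an `intensity_trace`.
#' @param ... passed to [plot()].
#' @export
plot.intensity_trace <- function(x, ...) {
  df <- x[x$excitation == "Cy3", ]
  plot(df$time_s, df$cy3, type = "l", col = "forestgreen",
       xlab = "time (s)", ylab = "intensity (a.u.)",
       ylim = range(df[, c("cy3", "cy5", "cy7")]), ...)
  lines(df$time_s, df$cy5, col = "red3")
  lines(df$time_s, df$cy7, col = "darkred")
  legend("topright", legend = c("Cy3", "Cy5", "Cy7"), lty = 1,
         col = c("forestgreen", "red3", "darkred"), bty = "n")
  invisible(x)
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %s: %d frames at %.3g s\n",
              attr(x, "id") %||% "trace", nrow(x), attr(x, "frame_interval")))
  print(head(as.data.frame(x)))
  invisible(x)
}
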