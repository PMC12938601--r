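#' Read a recording from an EDF/EDF+ file
#'
#' Minimal native reader for 16-bit European Data Format with an EDF+
#' annotations channel for events. Signals are rescaled to physical units
#' (assumed microvolts) from the per-signal digital/physical ranges.
#'
#' @param path EDF file path.
#' @param montage_subset Optional character vector: channels to keep, in
#'   the requested order. Missing labels raise an error naming them.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, montage_subset = NULL) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_chr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr_num <- function(n) as.numeric(hdr_chr(n))
  hdr_chr(8); hdr_chr(80); hdr_chr(80); hdr_chr(8); hdr_chr(8)
  hdr_num(8)                       # header length (recomputed below)
  hdr_chr(44)
  n_rec <- hdr_num(8)
  rec_dur <- hdr_num(8)
  ns <- as.integer(hdr_num(4))
  field <- function(n) vapply(seq_len(ns), function(i) hdr_chr(n), character(1))
  labels <- field(16); field(80); field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8)); field(32)

  is_annot <- labels == "EDF Annotations"
  raw_bytes <- vector("list", n_rec)
  sig <- lapply(seq_len(ns), function(i) vector("list", n_rec))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_annot[i]) {
        raw_bytes[[r]] <- readBin(con, "raw", 2L * spr[i])
      } else {
        sig[[i]][[r]] <- readBin(con, "integer", spr[i], size = 2L,
                                 signed = TRUE, endian = "little")
      }
    }
  }
  fs <- spr[!is_annot][1] / rec_dur
  keep <- which(!is_annot)
  samples <- do.call(rbind, lapply(keep, function(i) {
    d <- unlist(sig[[i]])
    scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    (d - dmin[i]) * scale + pmin[i]
  }))
  events <- .parse_annotations(raw_bytes, fs)
  rec <- raw_recording(samples, labels[keep], fs, events)
  if (!is.null(montage_subset)) rec <- select_channels(rec, montage_subset)
  rec
}

.parse_annotations <- function(raw_bytes, fs) {
  onset <- numeric(0); label <- character(0)
  for (b in raw_bytes) {
    if (is.null(b)) next
    zero <- b == as.raw(0)
    seg_id <- cumsum(zero)            # NUL separates TALs
    tals <- vapply(split(b[!zero], seg_id[!zero]), rawToChar, character(1))
    for (tal in tals) {
      if (!nzchar(tal)) next
      parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      if (length(parts) < 2 || !nzchar(parts[2])) next  # timestamp-only TAL
      od <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
      onset <- c(onset, as.numeric(od[1]))
      label <- c(label, parts[2])
    }
  }
  ord <- order(onset)
  tibble::tibble(onset_sample = as.integer(round(onset[ord] * fs)) + 1L,
                 label = label[ord])
}

#' Write a recording to an EDF+ file
#'
#' 16-bit EDF+C with one-second data records and an annotations channel
#' carrying the task events. Data whose length is not a whole number of
#' seconds are zero-padded to the next record boundary. Samples
#' round-trip through [read_recording()] within one quantization step of
#' the per-channel physical range.
#'
#' @param raw A [raw_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(raw, path) {
  x <- raw$samples
  fs <- raw$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  nch <- nrow(x)
  n_rec <- ceiling(ncol(x) / fs)
  if (ncol(x) < n_rec * fs)
    x <- cbind(x, matrix(0, nch, n_rec * fs - ncol(x)))
  prange <- pmax(apply(abs(x), 1, max), 1)
  prange <- ceiling(prange)
  annot_bytes <- 2L * .annot_spr(raw, n_rec)

  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) {
    s <- substr(s, 1, n)
    writeChar(formatC(s, width = -n), con, n, eos = NULL)
  }
  ns <- nch + 1L
  pad("0", 8); pad("X X X X", 80); pad("Startdate X X X X", 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(as.character(256 * (ns + 1L)), 8)
  pad("EDF+C", 44)
  pad(as.character(n_rec), 8); pad("1", 8); pad(as.character(ns), 4)
  fld <- function(vals, n) for (v in vals) pad(as.character(v), n)
  fld(c(raw$channel_names, "EDF Annotations"), 16)
  fld(rep("", ns), 80)
  fld(c(rep("uV", nch), ""), 8)
  fld(c(-prange, -1), 8)
  fld(c(prange, 1), 8)
  fld(rep(-32768, ns), 8)
  fld(rep(32767, ns), 8)
  fld(rep("", ns), 80)
  fld(c(rep(fs, nch), annot_bytes / 2L), 8)
  fld(rep("", ns), 32)

  scale <- 2 * prange / 65535            # same affine map the reader applies
  annots <- .annot_records(raw, n_rec, annot_bytes)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(nch)) {
      d <- as.integer(round((x[i, cols] + prange[i]) / scale[i])) - 32768L
      d <- pmin(32767L, pmax(-32768L, d))
      writeBin(d, con, size = 2L, endian = "little")
    }
    writeBin(annots[[r]], con)
  }
  invisible(path)
}

# bytes needed per record for the annotations signal (even, >= 24)
.annot_spr <- function(raw, n_rec) {
  ev <- raw$events
  per_rec <- rep(24L, n_rec)   # room for the timestamp TAL
  if (nrow(ev)) {
    t0 <- (ev$onset_sample - 1L) / raw$fs
    rec <- pmin(n_rec, floor(t0) + 1L)
    for (k in seq_len(nrow(ev)))
      per_rec[rec[k]] <- per_rec[rec[k]] +
        nchar(sprintf("+%.4f\x14%s\x14", t0[k], ev$label[k])) + 1L
  }
  m <- max(per_rec)
  as.integer(ceiling(m / 2) * 2)
}

.annot_records <- function(raw, n_rec, nbytes) {
  ev <- raw$events
  t0 <- if (nrow(ev)) (ev$onset_sample - 1L) / raw$fs else numeric(0)
  rec_of <- if (nrow(ev)) pmin(n_rec, floor(t0) + 1L) else integer(0)
  lapply(seq_len(n_rec), function(r) {
    b <- charToRaw(sprintf("+%d\x14\x14", r - 1L))
    for (k in which(rec_of == r))
      b <- c(b, as.raw(0),
             charToRaw(sprintf("+%.4f\x14%s\x14", t0[k], ev$label[k])))
    b <- c(b, as.raw(0))
    if (length(b) > nbytes) stop("annotation overflow")   # guarded by .annot_spr
    c(b, rep(as.raw(0), nbytes - length(b)))
  })
}
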