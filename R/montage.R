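#' The 30-channel sensorimotor montage
#'
#' Channel labels of the symmetric 30-channel subset covering frontal,
#' central-parietal and posterior-parietal scalp used throughout the
#' pipeline, in their canonical order.
#'
#' @return Character vector of 30 channel labels.
#' @export
motor_montage <- function() {
  c("F3", "Fz", "F4", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
    "FC6", "FT8", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "CP3",
    "CP1", "CP2", "CP4", "P5", "P3", "Pz", "P4", "P6", "PO7", "PO8")
}

# Decompose a 10-10 label into (row, lateral step, side).
# Rows index anterior(+)/posterior(-) offsets from the central coronal line
# in 10%-of-arc (18 degree) steps; lateral steps likewise from the midline.
.montage_grid <- function(labels) {
  row_of <- c(Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, C = 0, CP = -1,
              TP = -1, P = -2, PO = -3, O = -4)
  out <- lapply(labels, function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+)([z0-9]+)$", lab))[[1]]
    if (length(m) != 3) stop("unrecognized channel label: ", lab)
    prefix <- m[2]; suffix <- m[3]
    row <- row_of[[sub("z$", "", prefix)]]
    if (identical(suffix, "z")) {
      list(row = row, lat = 0, side = 0)
    } else {
      d <- as.integer(suffix)
      side <- if (d %% 2 == 1) -1 else 1     # odd digits left, even right
      lat <- ceiling(d / 2)
      # temporal/edge variants (FT7, T7, PO7 ...) sit one step further out
      if (prefix %in% c("FT", "TP", "T")) lat <- lat + 2
      list(row = row, lat = lat, side = side)
    }
  })
  do.call(rbind, lapply(out, as.data.frame))
}

#' Idealized spherical electrode positions
#'
#' Places 10-10 labels on a sphere of given radius: latitude/longitude
#' offsets from the vertex in 18-degree (10% of arc) steps along the
#' sagittal and coronal directions. This is an idealized montage intended
#' for the analytic concentric-sphere head model, not digitized positions.
#'
#' @param labels Character vector of channel labels (default the
#'   30-channel sensorimotor montage).
#' @param radius Scalp sphere radius in mm.
#' @return Numeric matrix (channels x 3) of x/y/z positions in mm with
#'   x right, y anterior, z superior; rownames are the labels.
#' @export
electrode_positions <- function(labels = motor_montage(), radius = 85) {
  g <- .montage_grid(labels)
  step <- pi / 10   # 18 degrees
  ant <- g$row * step          # rotation about x-axis (anterior +)
  lat <- g$lat * g$side * step # rotation about y-axis (right +)
  # start at vertex (0,0,1); apply lateral then anterior rotation
  pos <- t(vapply(seq_along(labels), function(i) {
    v <- c(0, 0, 1)
    a <- lat[i]
    v <- c(v[1] * cos(a) + v[3] * sin(a), v[2], -v[1] * sin(a) + v[3] * cos(a))
    b <- ant[i]
    v <- c(v[1], v[2] * cos(b) + v[3] * sin(b), -v[2] * sin(b) + v[3] * cos(b))
    v
  }, numeric(3)))
  pos <- pos * radius
  rownames(pos) <- labels
  colnames(pos) <- c("x", "y", "z")
  pos
}
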