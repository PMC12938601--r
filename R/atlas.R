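#' Default motor-imagery region atlas
#'
#' Axis-aligned bounding boxes (mm, x right / y anterior / z superior)
#' approximating the Brodmann-area groups implicated in hand motor
#' imagery: somatosensory (BA1-3), primary motor (BA4), superior parietal
#' (BA5/7), premotor and supplementary motor (BA6), anterior cingulate
#' (BA24/32), fusiform body area (BA37), inferior parietal (BA40),
#' opercular (BA44/45) and middle frontal (BA9/46) regions. Boxes are
#' deliberately coarse: the selection rules only require hemisphere and
#' broad region membership. Midline regions carry hemisphere `"both"` and
#' match either required hemisphere. Users needing template-accurate
#' membership should supply their own table via [read_atlas()].
#'
#' @return Tibble with columns `region`, `ba`, `hemisphere`, `xmin`,
#'   `xmax`, `ymin`, `ymax`, `zmin`, `zmax`.
#' @export
default_motor_atlas <- function() {
  box <- function(region, ba, xr, yr, zr, midline = FALSE) {
    if (midline) {
      tibble::tibble(region = region, ba = ba, hemisphere = "both",
                     xmin = -xr[2], xmax = xr[2],
                     ymin = yr[1], ymax = yr[2], zmin = zr[1], zmax = zr[2])
    } else {
      tibble::tibble(region = rep(region, 2), ba = rep(ba, 2),
                     hemisphere = c("left", "right"),
                     xmin = c(-xr[2], xr[1]), xmax = c(-xr[1], xr[2]),
                     ymin = yr[1], ymax = yr[2], zmin = zr[1], zmax = zr[2])
    }
  }
  dplyr::bind_rows(
    box("somatosensory",      "BA1-3",  c(10, 62), c(-50, 0),   c(20, 72)),
    box("primary motor",      "BA4",    c(10, 62), c(-40, 5),   c(25, 75)),
    box("superior parietal",  "BA5-7",  c(5, 45),  c(-75, -38), c(38, 75)),
    box("lateral premotor",   "BA6",    c(15, 60), c(-20, 25),  c(35, 78)),
    box("SMA (medial BA6)",   "BA6",    c(0, 15),  c(-20, 25),  c(40, 78),
        midline = TRUE),
    box("anterior cingulate", "BA24-32", c(0, 15), c(-10, 45),  c(0, 45),
        midline = TRUE),
    box("fusiform body area", "BA37",   c(25, 55), c(-68, -35), c(-25, 0)),
    box("inferior parietal",  "BA40",   c(35, 65), c(-62, -22), c(22, 55)),
    box("opercular",          "BA44-45", c(38, 62), c(2, 35),   c(2, 35)),
    box("middle frontal",     "BA9-46", c(25, 55), c(22, 58),   c(12, 48))
  )
}

#' Read a region atlas from CSV
#'
#' The file must provide columns `region`, `ba`, `hemisphere` (one of
#' `"left"`, `"right"`, `"both"`) and the box bounds `xmin`, `xmax`,
#' `ymin`, `ymax`, `zmin`, `zmax` in mm.
#'
#' @param path CSV file path.
#' @return Tibble in the format of [default_motor_atlas()].
#' @export
read_atlas <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "ba", "hemisphere",
            "xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("atlas is missing columns: ", paste(miss, collapse = ", "))
  bad <- with(a, xmin >= xmax | ymin >= ymax | zmin >= zmax)
  if (any(bad)) stop("atlas rows with empty boxes: ", paste(which(bad), collapse = ", "))
  tibble::as_tibble(a[, need])
}

#' Test whether a fitted dipole lies in an atlas region
#'
#' Membership requires the position to fall inside at least one box whose
#' hemisphere matches `required_hemisphere`; boxes tagged `"both"`
#' (midline regions) match either hemisphere.
#'
#' @param fit A `dipole_fit` (see [fit_dipole()]) or length-3 position.
#' @param atlas Atlas tibble, see [default_motor_atlas()].
#' @param required_hemisphere `"left"` or `"right"`.
#' @return Logical scalar.
#' @export
in_region <- function(fit, atlas = default_motor_atlas(),
                      required_hemisphere = c("left", "right")) {
  required_hemisphere <- match.arg(required_hemisphere)
  if (!nrow(atlas)) stop("empty atlas")
  p <- if (inherits(fit, "dipole_fit")) fit$position else as.numeric(fit)
  ok <- atlas$hemisphere %in% c(required_hemisphere, "both")
  a <- atlas[ok, ]
  any(p[1] >= a$xmin & p[1] <= a$xmax &
      p[2] >= a$ymin & p[2] <= a$ymax &
      p[3] >= a$zmin & p[3] <= a$zmax)
}
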