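#' AHA 17-segment angular conventions
#'
#' One angular convention is fixed globally for the whole package. On a
#' standard short-axis display (anterior wall up, septum left, inferior wall
#' down, lateral wall right) the anatomical angle theta increases
#' counterclockwise with the anterior wall at 90 degrees, septum at 180,
#' inferior at 270 and lateral at 0/360. Basal and mid rings are split into
#' six 60-degree sectors, the apical ring into four 90-degree sectors:
#'
#' * basal:  #1 anterior `[60,120)`, #2 anteroseptal `[120,180)`,
#'   #3 inferoseptal `[180,240)`, #4 inferior `[240,300)`,
#'   #5 inferolateral `[300,360)`, #6 anterolateral `[0,60)`
#' * mid:    #7-#12, same sectors
#' * apical: #13 anterior `[45,135)`, #14 septal `[135,225)`,
#'   #15 inferior `[225,315)`, #16 lateral `[315,45)`
#' * apex:   #17 (whole disc)
#'
#' @param theta_deg angles in degrees (any real; reduced mod 360).
#' @param ring one of `"basal"`, `"mid"`, `"apical"`, `"apex"`.
#' @return integer AHA segment numbers.
#' @export
aha_segment_of <- function(theta_deg, ring) {
  th <- theta_deg %% 360
  switch(ring,
    basal = c(6L, 1L, 2L, 3L, 4L, 5L)[floor(th / 60) + 1L],
    mid   = c(6L, 1L, 2L, 3L, 4L, 5L)[floor(th / 60) + 1L] + 6L,
    apical = 13L + floor(((th - 45) %% 360) / 90),
    apex  = rep(17L, length(th)),
    stop("unknown ring: ", ring))
}

#' Anatomical angle of pixels relative to a center
#'
#' Rows increase downwards on screen, so the anatomical angle (counter-
#' clockwise, anterior = 90 = up) is `atan2(-(row - cr), col - cc)`.
#'
#' @param row,col pixel coordinates (1-based, may be vectors).
#' @param center `c(row, col)` of the LV long axis on this slice.
#' @return angles in `[0, 360)` degrees.
#' @export
pixel_angle <- function(row, col, center) {
  (atan2(-(row - center[1]), col - center[2]) * 180 / pi) %% 360
}

#' Unit step vector (row, col) pointing along anatomical angle theta
#' @noRd
angle_step <- function(theta_deg) {
  rad <- theta_deg * pi / 180
  list(row = -sin(rad), col = cos(rad))
}

#' Default coronary-territory assignment of the 17 AHA segments
#'
#' The standard mapping: LAD `{1,2,7,8,13,14,17}`, RCA `{3,4,9,10,15}`,
#' LCX `{5,6,11,12,16}`. Override by passing a named list of integer vectors
#' covering all 17 segments exactly once.
#'
#' @return named list with elements `LAD`, `RCA`, `LCX`.
#' @export
territory_map_default <- function() {
  list(LAD = c(1L, 2L, 7L, 8L, 13L, 14L, 17L),
       RCA = c(3L, 4L, 9L, 10L, 15L),
       LCX = c(5L, 6L, 11L, 12L, 16L))
}

#' Angular interval(s) of an AHA segment within its ring
#' @noRd
aha_sector_interval <- function(seg) {
  if (seg == 17L) return(c(0, 360))
  if (seg <= 12L) {
    s <- if (seg <= 6L) seg else seg - 6L
    lo <- c(60, 120, 180, 240, 300, 0)[s]
    return(c(lo, lo + 60))
  }
  lo <- c(45, 135, 225, 315)[seg - 12L]
  c(lo, lo + 90)
}

# Circular angular distance (degrees) from angles th to interval [lo, hi)
ang_dist_interval <- function(th, lo, hi) {
  width <- hi - lo
  if (width >= 360) return(rep(0, length(th)))
  mid <- lo + width / 2
  d <- abs((th - mid + 180) %% 360 - 180)
  pmax(d - width / 2, 0)
}

check_territory_map <- function(map) {
  segs <- sort(unlist(map, use.names = FALSE))
  if (!identical(as.integer(segs), 1:17))
    stop("territory map must assign all 17 segments exactly once")
  map
}
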