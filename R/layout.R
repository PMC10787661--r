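#' Polar-map layout
#'
#' Builds the pixel layout of a left-ventricular polar map: `n_rings`
#' apex-to-base rings times `n_sectors` angular sectors, each pixel assigned
#' to one coronary artery territory. The default 21 x 64 layout yields the
#' 1344 radial pixels used throughout the package. Territories are contiguous
#' sector arcs (LAD anterior/septal, LCx lateral, RCA inferior) and can be
#' overridden with any partition of the sector indices.
#'
#' @param n_rings Number of rings (apex to base).
#' @param n_sectors Number of angular sectors per ring.
#' @param territory_sectors Named list mapping territory name to the 0-based
#'   sector indices it owns. Must partition `0:(n_sectors-1)`.
#' @return A tibble with one row per pixel: `pixel` (0-based index), `ring`,
#'   `sector` (both 0-based) and `territory`.
#' @examples
#' layout <- polar_layout()
#' nrow(layout) # 1344
#' @export
polar_layout <- function(n_rings = 21, n_sectors = 64,
                         territory_sectors = default_territories(n_sectors)) {
  stopifnot(n_rings >= 1, n_sectors >= 1)
  sec_all <- sort(unlist(territory_sectors, use.names = FALSE))
  if (!identical(as.integer(sec_all), 0:(n_sectors - 1L))) {
    stop("territory_sectors must partition the sector indices 0:(n_sectors-1)",
         call. = FALSE)
  }
  sec2terr <- character(n_sectors)
  for (terr in names(territory_sectors)) {
    sec2terr[territory_sectors[[terr]] + 1L] <- terr
  }
  ring <- rep(0:(n_rings - 1L), each = n_sectors)
  sector <- rep(0:(n_sectors - 1L), times = n_rings)
  tibble::tibble(
    pixel = seq_len(n_rings * n_sectors) - 1L,
    ring = ring,
    sector = sector,
    territory = sec2terr[sector + 1L]
  )
}

#' Default artery-territory sector arcs
#'
#' Contiguous arcs covering all sectors: LAD gets the largest share
#' (anterior + septal walls), LCx and RCA split the remainder.
#'
#' @param n_sectors Number of angular sectors.
#' @return Named list of 0-based sector index vectors.
#' @export
default_territories <- function(n_sectors = 64) {
  n_lad <- round(n_sectors * 0.40)
  n_lcx <- round(n_sectors * 0.30)
  list(
    LAD = 0:(n_lad - 1L),
    LCx = n_lad:(n_lad + n_lcx - 1L),
    RCA = (n_lad + n_lcx):(n_sectors - 1L)
  )
}
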