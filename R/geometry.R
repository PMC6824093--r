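#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km. All arguments are
#' recycled to a common length, so the function works on whole columns of
#' station or detection tables.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in km.
#' @examples
#' great_circle_km(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  k <- vctrs::vec_recycle_common(lat1, lon1, lat2, lon2)
  if (length(k[[1]]) == 0) return(numeric(0))
  geosphere::distHaversine(
    cbind(k[[2]], k[[1]]), cbind(k[[4]], k[[3]]), r = 6371
  )
}

#' Parameterised coastline geometry
#'
#' The synthetic study region is a concave coastal arc around an open bight:
#' a circular arc of radius `radius_km` about an offshore centre, spanning
#' `arc_deg` (degrees measured anticlockwise from east). The northern end of
#' the arc plays the role of the tagging coast; the western end is the far
#' coast reached by both route types. Offshore islands sit inside the arc.
#'
#' @param center_lat,center_lon Arc centre (decimal degrees), placed in open
#'   water.
#' @param radius_km Arc radius in km.
#' @param arc_deg Length-2 numeric, start and end angle of the coastline in
#'   degrees (0 = east of centre, anticlockwise positive).
#' @param deploy_deg Length-2 numeric, the sub-range of angles where birds are
#'   tagged (the "northern" coast).
#' @param alongshore_end_deg Arc angle where alongshore flights terminate:
#'   the "corner" of the bight, after which coastal network coverage ends.
#'   Offshore crossings instead head straight for the far (western) end of
#'   the arc.
#' @return A list of class `coast_geometry`.
#' @export
coast_geometry <- function(center_lat = 54.75, center_lon = 7.3,
                           radius_km = 130,
                           arc_deg = c(-90, 30),
                           deploy_deg = c(5, 28),
                           alongshore_end_deg = -55) {
  if (!is.numeric(arc_deg) || length(arc_deg) != 2 || arc_deg[1] >= arc_deg[2])
    abort("`arc_deg` must be two increasing angles.", class = "coastflight_config_error")
  if (radius_km <= 0)
    abort("`radius_km` must be positive.", class = "coastflight_config_error")
  structure(
    list(center_lat = center_lat, center_lon = center_lon,
         radius_km = radius_km, arc_deg = arc_deg, deploy_deg = deploy_deg,
         alongshore_end_deg = alongshore_end_deg),
    class = "coast_geometry"
  )
}

# point on the coast arc at angle phi (deg); radius_frac < 1 moves towards the
# (offshore) centre. Small-area equirectangular placement is fine at bight scale.
coast_point <- function(geometry, phi_deg, radius_frac = 1) {
  km_per_deg_lat <- 111.19
  r <- geometry$radius_km * radius_frac
  lat <- geometry$center_lat + (r / km_per_deg_lat) * sin(phi_deg * pi / 180)
  km_per_deg_lon <- km_per_deg_lat * cos(geometry$center_lat * pi / 180)
  lon <- geometry$center_lon + (r / km_per_deg_lon) * cos(phi_deg * pi / 180)
  tibble(lat = lat, lon = lon)
}
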