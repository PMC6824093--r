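#' Sunset time (UTC) at a location
#'
#' Standard solar-geometry sunset (solar altitude -0.833 deg, i.e. refraction
#' plus solar radius) from the usual sunrise-equation approximation; accurate
#' to a couple of minutes away from polar latitudes. Vectorised over all
#' arguments.
#'
#' @param date `Date` (or coercible) — the civil UTC date of the evening.
#' @param lat,lon Decimal degrees; `abs(lat)` must be below 66.5 (no polar
#'   day/night handling).
#' @return `POSIXct` (UTC) sunset times.
#' @examples
#' sunset_utc(as.Date("2017-10-20"), 54.2, 8.5)
#' @export
sunset_utc <- function(date, lat, lon) {
  date <- as.Date(date)
  k <- vctrs::vec_recycle_common(as.numeric(date), lat, lon)
  dnum <- k[[1]]; lat <- k[[2]]; lon <- k[[3]]
  if (any(abs(lat) >= 66.5))
    abort("sunset_utc() does not support polar latitudes (|lat| >= 66.5).",
          class = "coastflight_polar_error")
  deg2rad <- pi / 180
  # Julian day at 00:00 UTC of `date`; Unix epoch is JD 2440587.5
  jd <- dnum + 2440587.5
  n <- ceiling(jd - 2451545.0 - 0.0009 + lon / 360)
  jstar <- n + 0.0009 - lon / 360                    # mean solar noon
  M <- (357.5291 + 0.98560028 * jstar) %% 360        # solar mean anomaly
  C <- 1.9148 * sin(M * deg2rad) + 0.02 * sin(2 * M * deg2rad) +
    0.0003 * sin(3 * M * deg2rad)
  lambda <- (M + C + 180 + 102.9372) %% 360          # ecliptic longitude
  jtransit <- 2451545.0 + jstar + 0.0053 * sin(M * deg2rad) -
    0.0069 * sin(2 * lambda * deg2rad)
  sindec <- sin(lambda * deg2rad) * sin(23.4397 * deg2rad)
  cosdec <- cos(asin(sindec))
  cosw <- (sin(-0.833 * deg2rad) - sin(lat * deg2rad) * sindec) /
    (cos(lat * deg2rad) * cosdec)
  if (any(abs(cosw) > 1))
    abort("Sun does not set/rise at this latitude and date.",
          class = "coastflight_polar_error")
  w0 <- acos(cosw) / deg2rad
  jset <- jtransit + w0 / 360
  out <- as.POSIXct((jset - 2440587.5) * 86400,
                    origin = "1970-01-01", tz = "UTC")
  # the transit chosen by the rounding above can land a day off the civil
  # date requested; shift by whole solar days until the evening matches
  off <- round(dnum - as.numeric(as.Date(out)))
  out + off * 86400
}
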