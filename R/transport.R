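#' Transport parameters
#'
#' Describes how samples travel between a clinic and a testing site: a
#' transport mode with an average speed, and multiplicative road- and
#' weather-condition coefficients (0.8 good, 1.0 average, 1.2 bad by
#' default; any positive value is accepted).
#'
#' @param mode One of `"walk"`, `"bike"`, `"motorbike"`, `"car"`.
#' @param speed_kmh Average speed in km/h; defaults to 5/20/40/50 by mode.
#' @param road_coeff Road-condition multiplier (default 1, average).
#' @param weather_coeff Weather-condition multiplier (default 1, average).
#' @return A list of class `transport_params`.
#' @examples
#' transport_params("motorbike")
#' transport_params("walk", road_coeff = 1.2, weather_coeff = 1.2)
#' @export
transport_params <- function(mode = "motorbike", speed_kmh = NULL,
                             road_coeff = 1, weather_coeff = 1) {
  speeds <- c(walk = 5, bike = 20, motorbike = 40, car = 50)
  if (length(mode) != 1 || !mode %in% names(speeds)) {
    stop("unknown transport mode: ", paste(mode, collapse = ","), call. = FALSE)
  }
  if (is.null(speed_kmh)) speed_kmh <- unname(speeds[mode])
  if (speed_kmh <= 0) stop("speed must be positive", call. = FALSE)
  if (road_coeff <= 0 || weather_coeff <= 0) {
    stop("road and weather coefficients must be positive", call. = FALSE)
  }
  structure(
    list(mode = mode, speed_kmh = speed_kmh,
         road_coeff = road_coeff, weather_coeff = weather_coeff),
    class = "transport_params"
  )
}

#' Travel time for a sample shipment
#'
#' `minutes = distance / speed * road_coeff * weather_coeff * 60`. Linear in
#' distance and multiplicative in both condition coefficients, so improving
#' the road coefficient from 1.0 to 0.8 scales the time by exactly 0.8.
#'
#' @param distance_km Distance in km (vectorized, non-negative).
#' @param transport A [transport_params()] object.
#' @return Travel time in minutes.
#' @examples
#' transport_time(40, transport_params("motorbike")) # 60
#' @export
transport_time <- function(distance_km, transport = transport_params()) {
  stopifnot(inherits(transport, "transport_params"))
  if (any(distance_km < 0)) stop("distance must be non-negative", call. = FALSE)
  distance_km / transport$speed_kmh *
    transport$road_coeff * transport$weather_coeff * 60
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf("Transport: %s at %g km/h (road %g, weather %g)\n",
              x$mode, x$speed_kmh, x$road_coeff, x$weather_coeff))
  invisible(x)
}

# facility-by-site transport-time matrix in minutes; a travel-time matrix
# supplied with the instance overrides the computed one
transport_minutes <- function(instance, transport = instance$transport) {
  if (!is.null(instance$time_min)) return(instance$time_min)
  tm <- transport_time(instance$distance_km, transport)
  dimnames(tm) <- dimnames(instance$distance_km)
  tm
}
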