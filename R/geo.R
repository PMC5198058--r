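# Great-circle distance between zip-code centroids and facility proximity
# filtering (United States only).

EARTH_RADIUS <- c(miles = 3959, km = 6371)

#' Great-circle distance between two points (haversine)
#'
#' Computes the spherical great-circle distance
#' \deqn{d = 2 r \arcsin\sqrt{\sin^2\frac{\theta_2-\theta_1}{2} +
#'   \cos\theta_1 \cos\theta_2 \sin^2\frac{\lambda_2-\lambda_1}{2}}}
#' where \eqn{\theta} is latitude and \eqn{\lambda} longitude in radians,
#' and \eqn{r} is the Earth radius: 3959 miles or 6371 km.
#' Inputs are in degrees and converted internally. Vectorized.
#'
#' @param lat1,lon1 coordinates of the first point, decimal degrees.
#' @param lat2,lon2 coordinates of the second point, decimal degrees.
#' @param unit \code{"miles"} or \code{"km"}; fixes the Earth radius.
#' @return non-negative distance(s) in the requested unit.
#' @examples
#' haversine_distance(40.68, -75.22, 39.95, -75.16)  # about 50 miles
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2,
                               unit = c("miles", "km")) {
  unit <- match.arg(unit)
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  r <- EARTH_RADIUS[[unit]]
  t1 <- lat1 * pi / 180
  t2 <- lat2 * pi / 180
  dlon <- (lon2 - lon1) * pi / 180
  a <- sin((t2 - t1) / 2)^2 + cos(t1) * cos(t2) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Read a zip-code coordinate table
#'
#' Headered CSV with columns \code{zip}, \code{latitude}, \code{longitude}
#' (Census-gazetteer-like). Zip codes are normalized: non-digits removed,
#' ZIP+4 truncated to the first five digits, zero-padded to five characters.
#'
#' @param file CSV path.
#' @return a data.frame (class \code{zip_table}) with normalized \code{zip},
#'   \code{latitude}, \code{longitude}; rownames are the zip codes.
#' @export
read_zip_table <- function(file) {
  if (!file.exists(file)) stop("zip table not found: ", file, call. = FALSE)
  tab <- utils::read.csv(file, colClasses = c(zip = "character"),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("zip", "latitude", "longitude") %in% names(tab)))
  tab$zip <- normalize_zip(tab$zip)
  tab <- tab[!duplicated(tab$zip), , drop = FALSE]
  rownames(tab) <- tab$zip
  class(tab) <- c("zip_table", class(tab))
  tab
}

# Keep digits, truncate ZIP+4 to 5, zero-pad to 5. Empty stays empty.
normalize_zip <- function(zip) {
  zip <- substr(gsub("[^0-9]", "", as.character(zip)), 1, 5)
  out <- ifelse(nzchar(zip),
                paste0(strrep("0", pmax(0, 5 - nchar(zip))), zip), "")
  unname(out)
}

zip_point <- function(zip, table) {
  zip <- normalize_zip(zip)
  i <- match(zip, table$zip)
  if (is.na(i)) return(NULL)
  c(latitude = table$latitude[i], longitude = table$longitude[i])
}

#' Filter trial facilities by distance from a zip code
#'
#' Keeps a facility when (a) its country is not the United States (proximity
#' checking applies to US facilities only), or (b) its zip code is empty or
#' absent from the coordinate table (unknown-zip rule: included without
#' filtering), or (c) its great-circle distance from the origin zip is at
#' most \code{max_distance}. \code{max_distance = 0} is the sentinel for "no
#' proximity filtering": all facilities are kept.
#'
#' @param locations a locations data.frame (as in a trial record).
#' @param origin_zip the user's 5-digit zip code; must be in \code{table}.
#' @param max_distance non-negative; 0 disables filtering.
#' @param unit \code{"miles"} or \code{"km"}.
#' @param table a \code{zip_table}.
#' @return the subset of \code{locations} retained (row order preserved).
#' @export
facilities_within <- function(locations, origin_zip, max_distance,
                              unit = c("miles", "km"), table) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(max_distance), max_distance >= 0)
  if (max_distance == 0 || nrow(locations) == 0) return(locations)
  origin <- zip_point(origin_zip, table)
  if (is.null(origin)) {
    stop("origin zip code not found in the coordinate table: ", origin_zip,
         call. = FALSE)
  }
  keep <- vapply(seq_len(nrow(locations)), function(i) {
    if (tolower(locations$country[i]) != "united states") return(TRUE)
    pt <- zip_point(locations$zip[i], table)
    if (is.null(pt)) return(TRUE)  # unknown zip: include unfiltered
    haversine_distance(origin[["latitude"]], origin[["longitude"]],
                       pt[["latitude"]], pt[["longitude"]],
                       unit = unit) <= max_distance
  }, logical(1))
  locations[keep, , drop = FALSE]
}
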