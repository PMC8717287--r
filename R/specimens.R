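#' @keywords internal
"_PACKAGE"

# IUGG mean Earth radius, metres; fixed so transect distances are
# bit-reproducible across machines.
EARTH_RADIUS_M <- 6371008.8

SPECIMEN_COLUMNS <- c(
  "id", "caste", "latitude", "longitude", "color_phenotype",
  "color_genotype", "mt_haplogroup", "period", "locality"
)

#' Project a latitude onto the north-south transect
#'
#' Great-circle (Haversine) distance along a meridian between a specimen's
#' latitude and a reference latitude, in kilometres.  Positive values lie
#' north of the reference, negative south.  With
#' `projection = "great_circle"` the full 2D great-circle distance between
#' the two coordinate pairs is used instead (still signed by latitude).
#'
#' @param latitude numeric vector of latitudes, degrees in \[-90, 90\].
#' @param reference_latitude single reference latitude (the southernmost
#'   specimen in a [specimen_table()]).
#' @param longitude,reference_longitude longitudes, only used for
#'   `projection = "great_circle"`.
#' @param projection `"latitudinal"` (default; distance computed along a
#'   meridian, longitude ignored) or `"great_circle"`.
#' @return distances in km, same length as `latitude`.
#' @export
project_to_transect <- function(latitude, reference_latitude,
                                longitude = 0, reference_longitude = 0,
                                projection = c("latitudinal", "great_circle")) {
  projection <- match.arg(projection)
  if (any(!is.finite(latitude)) || any(abs(latitude) > 90) ||
      !is.finite(reference_latitude) || abs(reference_latitude) > 90) {
    stop("latitudes must be finite and within [-90, 90]")
  }
  if (projection == "latitudinal") {
    lon1 <- rep(0, length(latitude))
    lon2 <- 0
  } else {
    lon1 <- rep_len(longitude, length(latitude))
    lon2 <- reference_longitude
  }
  d <- geosphere::distHaversine(
    cbind(lon1, latitude), c(lon2, reference_latitude),
    r = EARTH_RADIUS_M
  ) / 1000
  sign(latitude - reference_latitude) * d
}

#' Construct and validate a specimen table
#'
#' A `specimen_table` is a data.frame of one row per bee with a derived
#' `ploidy` column (drones are haploid, queens and workers diploid) and a
#' `transect_km` column measuring signed Haversine distance north of the
#' southernmost specimen.
#'
#' Validated invariants: latitudes in range; haploid genotypes in
#' \{f, b, unknown\}; a diploid `fb` genotype implies the ferruginous
#' phenotype (ferruginous is dominant); `bb` or `b` implies black.
#'
#' @param records data.frame with columns `id`, `caste`, `latitude`,
#'   `longitude`, `color_phenotype`, `color_genotype`, `mt_haplogroup`,
#'   `period`, `locality`.  Unknowns are the string `"unknown"` (or NA).
#' @param projection passed to [project_to_transect()].
#' @return the validated data.frame with `ploidy` and `transect_km` added,
#'   class `specimen_table`; the reference latitude is stored in
#'   `attr(, "reference_latitude")`.
#' @export
specimen_table <- function(records, projection = "latitudinal") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SPECIMEN_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("specimen table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("color_phenotype", "color_genotype", "mt_haplogroup")) {
    records[[col]][is.na(records[[col]])] <- "unknown"
  }
  if (anyDuplicated(records$id)) stop("specimen ids must be unique")

  ok_caste <- records$caste %in% c("queen", "worker", "drone")
  if (!all(ok_caste)) {
    stop("unknown caste for id(s): ",
         paste(records$id[!ok_caste], collapse = ", "))
  }
  records$ploidy <- ifelse(records$caste == "drone", "haploid", "diploid")

  if (any(!is.finite(records$latitude)) || any(abs(records$latitude) > 90)) {
    stop("latitude out of [-90, 90] for id(s): ",
         paste(records$id[!is.finite(records$latitude) |
                            abs(records$latitude) > 90], collapse = ", "))
  }

  ok_phen <- records$color_phenotype %in% c("ferruginous", "black", "unknown")
  if (!all(ok_phen)) {
    stop("invalid color_phenotype for id(s): ",
         paste(records$id[!ok_phen], collapse = ", "))
  }
  hap <- records$ploidy == "haploid"
  ok_gt <- ifelse(hap,
                  records$color_genotype %in% c("f", "b", "unknown"),
                  records$color_genotype %in% c("ff", "fb", "bb", "unknown"))
  if (!all(ok_gt)) {
    stop("genotype incompatible with ploidy for id(s): ",
         paste(records$id[!ok_gt], collapse = ", "))
  }
  # dominance: fb and ff (and haploid f) are ferruginous; bb and b are black
  expected <- rep(NA_character_, nrow(records))
  expected[records$color_genotype %in% c("ff", "fb", "f")] <- "ferruginous"
  expected[records$color_genotype %in% c("bb", "b")] <- "black"
  bad <- !is.na(expected) & records$color_phenotype != "unknown" &
    records$color_phenotype != expected
  if (any(bad)) {
    stop("genotype/phenotype dominance violation for id(s): ",
         paste(records$id[bad], collapse = ", "))
  }
  ok_mt <- records$mt_haplogroup %in% c("northern", "southern", "unknown")
  if (!all(ok_mt)) {
    stop("invalid mt_haplogroup for id(s): ",
         paste(records$id[!ok_mt], collapse = ", "))
  }

  ref_idx <- which.min(records$latitude)
  ref_lat <- records$latitude[ref_idx]
  records$transect_km <- project_to_transect(
    records$latitude, ref_lat,
    longitude = records$longitude,
    reference_longitude = records$longitude[ref_idx],
    projection = projection
  )
  attr(records, "reference_latitude") <- ref_lat
  attr(records, "projection") <- projection
  class(records) <- c("specimen_table", "data.frame")
  records
}

#' Read a specimen TSV
#'
#' Tab-separated file with the columns of [specimen_table()]; `NA` encodes
#' unknown categorical fields.
#'
#' @param path file path.
#' @param projection passed to [specimen_table()].
#' @return a `specimen_table`.
#' @export
load_specimens <- function(path, projection = "latitudinal") {
  records <- utils::read.delim(path, sep = "\t", header = TRUE,
                               colClasses = "character",
                               na.strings = "NA")
  records$latitude <- as.numeric(records$latitude)
  records$longitude <- as.numeric(records$longitude)
  specimen_table(records, projection = projection)
}

#' Write a specimen table as TSV
#'
#' Drops the derived `ploidy`/`transect_km` columns so that a load/write
#' round trip reproduces the original records exactly.
#'
#' @param table a `specimen_table`.
#' @param path output path.
#' @param keep_derived keep `ploidy` and `transect_km` columns.
#' @export
write_specimens <- function(table, path, keep_derived = FALSE) {
  out <- as.data.frame(table)
  if (!keep_derived) out <- out[, SPECIMEN_COLUMNS]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
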