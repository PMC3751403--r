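## Assignment of species to biogeographic zones from occurrence records.
##
## Zones are named polygons in lon/lat (a "region_map").  Species are
## first classified as inside or outside the hotspot super-region (the
## union of the zone polygons, optionally buffered: a few species sit
## slightly outside the formal boundary but clearly belong), then
## hotspot species are assigned to a single zone if >90% of their
## records fall there, otherwise to "both".

#' Construct a region map from named polygons
#'
#' @param zones Named list of polygons; each polygon is a two-column
#'   matrix of (lon, lat) vertices, or a list of such matrices for a
#'   multipolygon.  Rings need not repeat the first vertex.
#' @return An object of class `region_map`.
#' @export
region_map <- function(zones) {
  stopifnot(is.list(zones), length(zones) > 0,
            !is.null(names(zones)), !anyDuplicated(names(zones)))
  zones <- lapply(zones, function(z) {
    if (is.matrix(z)) z <- list(z)
    lapply(z, function(r) {
      r <- as.matrix(r)
      stopifnot(ncol(r) == 2, nrow(r) >= 3)
      storage.mode(r) <- "double"
      r
    })
  })
  structure(list(zones = zones), class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("region map with", length(x$zones), "zone(s):",
      paste(names(x$zones), collapse = ", "), "\n")
  invisible(x)
}

#' Read zones from a GeoJSON FeatureCollection
#'
#' Each feature must be a Polygon or MultiPolygon with a property
#' `name` giving the zone name.
#'
#' @param path Path to a GeoJSON file.
#' @return A `region_map`.
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  zones <- list()
  for (ft in gj$features) {
    nm <- ft$properties$name
    if (is.null(nm)) stop("feature without a 'name' property")
    geom <- ft$geometry
    ring2mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(geom$type,
      Polygon = list(ring2mat(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates,
                            function(poly) ring2mat(poly[[1]])),
      stop("unsupported geometry type: ", geom$type))
    zones[[nm]] <- rings
  }
  region_map(zones)
}

#' Write a region map as GeoJSON
#' @param map A `region_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(map, path) {
  feats <- lapply(names(map$zones), function(nm) {
    rings <- map$zones[[nm]]
    coords <- lapply(rings, function(r) {
      r <- close_ring(r)
      list(lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    })
    list(type = "Feature", properties = list(name = nm),
         geometry = if (length(coords) == 1L)
           list(type = "Polygon", coordinates = coords[[1]])
         else list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

close_ring <- function(r) {
  if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
  r
}

#' Read occurrence records from CSV
#'
#' Expects columns `species,lon,lat` and optionally `source_id`.
#' Coordinates outside valid lon/lat ranges are rejected.
#'
#' @param path CSV file path.
#' @return A data frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  occ <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(occ)))
    stop("occurrence CSV must have columns: ", paste(need, collapse = ","))
  validate_occurrences(occ)
  occ
}

validate_occurrences <- function(occ) {
  if (any(!is.finite(occ$lon)) || any(occ$lon < -180 | occ$lon > 180))
    stop("longitudes must be finite and in [-180, 180]")
  if (any(!is.finite(occ$lat)) || any(occ$lat < -90 | occ$lat > 90))
    stop("latitudes must be finite and in [-90, 90]")
  invisible(occ)
}

## point-in-polygon for a zone (possibly multiple rings); boundary
## points count as inside (herbarium coordinates are coarse)
points_in_zone <- function(lon, lat, rings) {
  inside <- rep(FALSE, length(lon))
  for (r in rings) {
    r <- close_ring(r)
    code <- sp::point.in.polygon(lon, lat, r[, 1], r[, 2])
    inside <- inside | code > 0  # 1 interior, 2 edge, 3 vertex
  }
  inside
}

#' Filter occurrence records by an exclusion rule set
#'
#' Removes records judged to lie outside a species' natural
#' distribution, e.g. cultivated specimens from botanic gardens.  Rules
#' are per-species bounding boxes and/or a blacklist of `source_id`s;
#' a removal log records each removed record with the rule that fired.
#'
#' @param records Occurrence data frame (`species,lon,lat[,source_id]`).
#' @param exclusion List with optional elements `bbox` (data frame
#'   `species,lon_min,lon_max,lat_min,lat_max`) and `blacklist`
#'   (character vector of `source_id`s to drop).
#' @return List with `records` (retained) and `removed` (log data frame
#'   with a `rule` column).  `filtered + removed = input`.
#' @export
filter_records <- function(records, exclusion = list()) {
  validate_occurrences(records)
  rule <- rep(NA_character_, nrow(records))
  bl <- exclusion$blacklist
  if (length(bl) && "source_id" %in% names(records)) {
    hit <- records$source_id %in% bl
    rule[hit & is.na(rule)] <- "blacklist"
  }
  bb <- exclusion$bbox
  if (!is.null(bb)) {
    unknown <- setdiff(bb$species, records$species)
    if (length(unknown))
      warning("bounding-box rules for species absent from records: ",
              paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(bb))) {
      sel <- records$species == bb$species[i] &
        (records$lon < bb$lon_min[i] | records$lon > bb$lon_max[i] |
         records$lat < bb$lat_min[i] | records$lat > bb$lat_max[i])
      rule[sel & is.na(rule)] <- paste0("bbox:", bb$species[i])
    }
  }
  keep <- is.na(rule)
  removed <- records[!keep, , drop = FALSE]
  removed$rule <- rule[!keep]
  list(records = records[keep, , drop = FALSE], removed = removed)
}

#' Count records per zone
#'
#' Assigns each record to at most one zone by point-in-polygon
#' (boundary points count as inside) and tallies per-zone and outside
#' counts; `in-zone + outside = total`.  A point on the shared
#' boundary of two adjacent zones is assigned to the first zone in map
#' order (a deterministic tie-break for coarse herbarium coordinates);
#' a point in the *interior* of two zones means the polygons genuinely
#' overlap, which is an error naming the zones.
#'
#' @param records Occurrence data frame.
#' @param map A `region_map`.
#' @return Named integer vector of per-zone counts plus `outside`.
#' @export
count_in_zones <- function(records, map) {
  stopifnot(inherits(map, "region_map"))
  validate_occurrences(records)
  zn <- names(map$zones)
  code <- vapply(zn, function(nm)
    zone_membership(records$lon, records$lat, map$zones[[nm]]),
    integer(nrow(records)))
  code <- matrix(code, nrow = nrow(records), dimnames = list(NULL, zn))
  interior <- rowSums(code == 1L)
  if (any(interior > 1)) {
    bad <- which(interior > 1)[1]
    stop("point (", records$lon[bad], ", ", records$lat[bad],
         ") claimed by overlapping zones: ",
         paste(zn[code[bad, ] == 1L], collapse = ", "))
  }
  assigned <- apply(code > 0L, 1, function(x)
    if (any(x)) which(x)[1] else NA_integer_)
  counts <- vapply(seq_along(zn), function(i)
    sum(assigned == i, na.rm = TRUE), 0L)
  names(counts) <- zn
  c(counts, outside = sum(is.na(assigned)))
}

## 0 = outside, 1 = interior, 2 = boundary (edge or vertex)
zone_membership <- function(lon, lat, rings) {
  out <- integer(length(lon))
  for (r in rings) {
    r <- close_ring(r)
    code <- sp::point.in.polygon(lon, lat, r[, 1], r[, 2])
    out[code == 1 & out == 0L] <- 1L
    out[code >= 2] <- 2L
  }
  out
}

#' Assign a species to a zone by the >90% rule
#'
#' A species is assigned to the single zone holding strictly more than
#' `threshold` of its in-zone records; otherwise its zone is `"both"`.
#'
#' @param counts Named per-zone record counts (an `outside` element, if
#'   present, is ignored).
#' @param threshold Share required for single-zone assignment
#'   (default 0.90; comparison is strict).
#' @return Zone name or `"both"`.
#' @examples
#' assign_zone(c(HRZ = 95, TRZ_SCP = 5))   # "HRZ"
#' assign_zone(c(HRZ = 90, TRZ_SCP = 10))  # "both": 0.90 is not > 0.90
#' @export
assign_zone <- function(counts, threshold = 0.90) {
  counts <- counts[setdiff(names(counts), "outside")]
  total <- sum(counts)
  if (total <= 0) stop("no in-zone records: species cannot be classified")
  share <- counts / total
  if (max(share) > threshold) names(which.max(share)) else "both"
}

#' Classify a species as hotspot (SWBP) or not
#'
#' A species belongs to the hotspot super-region if the majority of its
#' records fall inside the union of the zone polygons or within
#' `buffer_km` of it; the buffer accommodates species slightly outside
#' the formal boundary but clearly disjunct from the rest of the
#' continent.  Distances to the boundary are great-circle distances.
#'
#' @param records Occurrence data frame for one species.
#' @param map A `region_map` whose zones jointly delimit the hotspot.
#' @param buffer_km Buffer width in km (default 50).
#' @return `"SWBP"` or `"nonSWBP"`.
#' @export
assign_swbp <- function(records, map, buffer_km = 50) {
  stopifnot(inherits(map, "region_map"))
  if (nrow(records) == 0) stop("no records: species cannot be classified")
  validate_occurrences(records)
  inside <- rep(FALSE, nrow(records))
  for (nm in names(map$zones))
    inside <- inside | points_in_zone(records$lon, records$lat,
                                      map$zones[[nm]])
  if (buffer_km > 0 && any(!inside)) {
    pts <- cbind(records$lon, records$lat)[!inside, , drop = FALSE]
    near <- rep(FALSE, nrow(pts))
    for (rings in map$zones) {
      for (r in rings) {
        d <- geosphere::dist2Line(pts, close_ring(r))[, "distance"]
        near <- near | d <= buffer_km * 1000
      }
    }
    inside[!inside] <- near
  }
  if (mean(inside) > 0.5) "SWBP" else "nonSWBP"
}

#' Assign all species to geographic states
#'
#' Runs the full assignment: optional record filtering, hotspot
#' classification per species, and zone assignment (>`threshold` rule)
#' for hotspot species.  Zone state is `NA` for non-hotspot species.
#'
#' @param records Occurrence data frame for all species.
#' @param map `region_map` of the within-hotspot zones.
#' @param exclusion Optional exclusion rule set (see [filter_records()]).
#' @param threshold Single-zone share threshold (default 0.90).
#' @param buffer_km Hotspot boundary buffer in km (default 50).
#' @return Data frame `species, swbp_state, zone_state`, one per-zone
#'   count column (`n_<zone>`), and `n_outside`.
#' @export
assign_regions <- function(records, map, exclusion = list(),
                           threshold = 0.90, buffer_km = 50) {
  filt <- filter_records(records, exclusion)
  recs <- filt$records
  zn <- names(map$zones)
  res <- lapply(split(recs, recs$species), function(r) {
    swbp <- assign_swbp(r, map, buffer_km)
    counts <- count_in_zones(r, map)
    zone <- if (swbp == "SWBP" && sum(counts[zn]) > 0)
      assign_zone(counts, threshold) else NA_character_
    c(list(species = r$species[1], swbp_state = swbp, zone_state = zone),
      as.list(counts[zn]), list(n_outside = unname(counts["outside"])))
  })
  out <- do.call(rbind, lapply(res, as.data.frame))
  names(out) <- c("species", "swbp_state", "zone_state",
                  paste0("n_", tolower(zn)), "n_outside")
  rownames(out) <- NULL
  out
}

#' Sampling fractions from present / absent species counts
#'
#' SSE likelihoods correct for incomplete sampling through the
#' proportion of extant species of each state present in the tree.
#' Given per-state counts of species present in and absent from the
#' phylogeny, returns `present / (present + absent)` per state.
#'
#' @param present Named integer vector of species in the tree per state.
#' @param absent Named integer vector (same names) of species not in
#'   the tree.
#' @return Named numeric vector of sampling fractions in (0, 1].
#' @examples
#' sampling_fractions(c(nonSWBP = 15, SWBP = 143), c(nonSWBP = 1, SWBP = 12))
#' @export
sampling_fractions <- function(present, absent) {
  stopifnot(identical(names(present), names(absent)),
            all(present >= 1), all(absent >= 0))
  present / (present + absent)
}
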