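#' Assemble the modelling feature table from occurrences and traits
#'
#' Computes the geographical predictors from per-species occupied grid
#' cells and joins them to the ecological traits: `range` is the number
#' of occupied cells, the centroid is the mean of the cell-centre
#' coordinates, `abs_lat` is the absolute centroid latitude, and
#' `dist_iaa` is the great-circle distance (6371-km sphere) from the
#' centroid to a reference point in the Indo-Australian Archipelago
#' (latitude 0, longitude +121). By convention the
#' distance is measured from the *absolute*-latitude centroid (i.e. the
#' centroid folded onto the northern hemisphere) combined with the
#' longitudinal centroid. Mean SST and primary productivity are looked
#' up at the nearest cell of `env` when given, otherwise taken from
#' `traits`.
#'
#' @param occurrences Data frame with `species`, `lat`, `lon` (cell
#'   centres, one row per occupied cell).
#' @param traits Data frame with `species`, `trophic`, `size`,
#'   `activity`, `position` and (if `env` is `NULL`) `basin`, `sst`,
#'   `prprod`.
#' @param env Optional data frame of cell-level environmental values:
#'   `lat`, `lon`, `sst`, `prprod`, and optionally `basin`.
#' @return A feature table (data frame) with the ten predictor columns;
#'   species with no occupied cells are dropped and listed in attribute
#'   `"dropped"`.
#' @export
assemble_features <- function(occurrences, traits, env = NULL) {
  stopifnot(all(c("species", "lat", "lon") %in% names(occurrences)))
  if (any(abs(occurrences$lat) > 90) || any(abs(occurrences$lon) > 180))
    stop_reefdiv("occurrence coordinates out of range")
  agg <- aggregate(cbind(lat, lon) ~ species, data = occurrences, FUN = mean)
  cnt <- aggregate(lat ~ species, data = occurrences, FUN = length)
  names(cnt)[2] <- "range"
  geo <- merge(agg, cnt, by = "species")
  geo$abs_lat <- abs(geo$lat)
  geo$dist_iaa <- geosphere::distCosine(
    cbind(geo$lon, geo$abs_lat), c(121, 0), r = 6371000) / 1000
  dropped <- setdiff(traits$species, geo$species)
  if (length(dropped))
    message(sprintf("dropping %d species with no occupied cells", length(dropped)))
  out <- merge(traits, geo[, c("species", "range", "abs_lat", "dist_iaa",
                               "lat", "lon")], by = "species")
  if (!is.null(env)) {
    nearest <- vapply(seq_len(nrow(out)), function(i) {
      which.min((env$lat - out$lat[i])^2 + (env$lon - out$lon[i])^2)
    }, 0L)
    out$sst <- env$sst[nearest]
    out$prprod <- env$prprod[nearest]
    if ("basin" %in% names(env)) out$basin <- env$basin[nearest]
  }
  need <- c("species", "trophic", "size", "activity", "position", "range",
            "basin", "abs_lat", "dist_iaa", "sst", "prprod")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop_reefdiv("feature table is missing column(s): %s",
                 paste(miss, collapse = ", "))
  out <- out[, need]
  attr(out, "dropped") <- dropped
  out
}

PREDICTORS <- c("trophic", "size", "activity", "position", "range",
                "basin", "abs_lat", "dist_iaa", "sst", "prprod")
CATEGORICAL <- c("trophic", "activity", "position", "basin")

## One-hot encode the predictor columns; returns the design matrix and a
## map from encoded column to source variable (importance is aggregated
## back through it, so attribution is per variable, not per dummy).
encode_features <- function(table, predictors = PREDICTORS) {
  miss <- setdiff(predictors, names(table))
  if (length(miss))
    stop_reefdiv("missing predictor column(s): %s", paste(miss, collapse = ", "))
  cols <- list(); groups <- character(0)
  for (v in predictors) {
    x <- table[[v]]
    if (v %in% CATEGORICAL || is.factor(x) || is.character(x)) {
      f <- if (is.factor(x)) x else factor(x)
      for (lv in levels(f)) {
        cols[[paste0(v, ".", lv)]] <- as.numeric(f == lv)
        groups <- c(groups, setNames(v, paste0(v, ".", lv)))
      }
    } else {
      cols[[v]] <- as.numeric(x)
      groups <- c(groups, setNames(v, v))
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  list(X = X, groups = groups, predictors = predictors)
}
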