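#' Labelled distance matrix
#'
#' @param d Symmetric non-negative numeric matrix with zero diagonal; dimnames
#'   give the population labels.
#' @param kind One of `"nei_genetic"`, `"geographic_km"`,
#'   `"mds_configuration"`.
#' @return A `ystr_dist` object.
#' @export
dist_matrix <- function(d, kind = c("nei_genetic", "geographic_km",
                                    "mds_configuration")) {
  kind <- match.arg(kind)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("P", seq_len(nrow(d)))
  }
  fin <- is.finite(d)
  if (!isTRUE(all.equal(d[fin & t(fin)], t(d)[fin & t(fin)], tolerance = 1e-9)) ||
      any(diag(d) != 0) || any(d[fin] < 0)) {
    ystr_abort("distance matrix must be symmetric, non-negative, zero-diagonal",
               "ystr_validation_error")
  }
  structure(list(labels = rownames(d), d = d, kind = kind),
            class = "ystr_dist")
}

#' @export
print.ystr_dist <- function(x, ...) {
  cat(sprintf("<ystr_dist (%s): %d populations>\n", x$kind, length(x$labels)))
  print(round(x$d, 4))
  invisible(x)
}

#' Nei's standard genetic distance between two frequency vectors
#'
#' `D = -ln( Jxy / sqrt(Jx Jy) )` with `Jxy = sum(x y)`, `Jx = sum(x^2)`,
#' `Jy = sum(y^2)`. Zero for identical vectors; infinite (returned as `Inf`
#' with a warning) when the two populations share no haplogroup. Nei distance
#' does not satisfy the triangle inequality.
#'
#' @param x,y Frequency vectors over the same ordered haplogroup list, each
#'   summing to 1.
#' @return Non-negative distance (possibly `Inf`).
#' @examples
#' nei_distance(c(0.5, 0.5, 0), c(0.5, 0.25, 0.25)) # 0.1438
#' @export
nei_distance <- function(x, y) {
  if (length(x) != length(y)) {
    ystr_abort("frequency vectors must cover the same haplogroup list",
               "ystr_validation_error")
  }
  if (abs(sum(x) - 1) > 1e-6 || abs(sum(y) - 1) > 1e-6) {
    ystr_abort("frequency vectors must each sum to 1", "ystr_validation_error")
  }
  jxy <- sum(x * y)
  if (jxy == 0) {
    ystr_warn("no shared haplogroups: Nei distance is infinite",
              "ystr_infinite_distance")
    return(Inf)
  }
  max(0, -log(jxy / sqrt(sum(x^2) * sum(y^2))))
}

#' Nei distance matrix from a frequency table
#'
#' @param ft A [frequency_table()].
#' @return A `ystr_dist` of kind `nei_genetic`.
#' @export
nei_distance_matrix <- function(ft) {
  p <- ft$p
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(ft$populations, ft$populations))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) d[i, j] <- d[j, i] <- nei_distance(p[i, ], p[j, ])
    }
  }
  dist_matrix(d, "nei_genetic")
}

#' Great-circle distances between populations
#'
#' Haversine distances (Earth radius 6371 km) from metadata coordinates.
#'
#' @param meta A [read_population_meta()] table (columns `population`,
#'   `latitude`, `longitude`).
#' @return A `ystr_dist` of kind `geographic_km`.
#' @export
geographic_distance <- function(meta) {
  bad <- is.na(meta$latitude) | is.na(meta$longitude)
  if (any(bad)) {
    ystr_abort(sprintf("missing coordinates for population(s): %s",
                       paste(meta$population[bad], collapse = ", ")),
               "ystr_validation_error")
  }
  R <- 6371
  lat <- meta$latitude * pi / 180
  lon <- meta$longitude * pi / 180
  n <- nrow(meta)
  d <- matrix(0, n, n, dimnames = list(meta$population, meta$population))
  for (i in seq_len(n)) {
    dlat <- lat - lat[i]
    dlon <- lon - lon[i]
    a <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat) * sin(dlon / 2)^2
    d[i, ] <- 2 * R * asin(pmin(1, sqrt(a)))
  }
  d <- (d + t(d)) / 2 # enforce exact symmetry against fp noise
  diag(d) <- 0
  dist_matrix(d, "geographic_km")
}
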