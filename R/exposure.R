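#' Aggregate use records to section totals
#'
#' Sums pounds of active ingredient per section centroid, either over the
#' whole study period (`period_total`, the default) or as a per-year mean
#' (`annual_mean`). Records with nonpositive pounds are rejected with a
#' warning before aggregation.
#'
#' @param records use-record data frame (`section_id`, `x_km`, `y_km`,
#'   `year`, `pounds`).
#' @param mode `"period_total"` or `"annual_mean"`.
#' @param n_years number of study years for `annual_mean`; defaults to the
#'   number of distinct years present.
#' @return data frame of section totals: `section_id`, `x_km`, `y_km`, `q_u`
#'   (strictly positive, one row per section).
#' @export
aggregate_sections <- function(records, mode = c("period_total", "annual_mean"),
                               n_years = NULL) {
  mode <- match.arg(mode)
  bad <- records$pounds <= 0
  if (any(bad)) {
    warning(sprintf("aggregate_sections: dropping %d record(s) with nonpositive pounds", sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  if (!nrow(records)) stop("aggregate_sections: no valid use records")
  n_years <- n_years %||% length(unique(records$year))
  q <- tapply(records$pounds, records$section_id, sum)
  first <- records[!duplicated(records$section_id), c("section_id", "x_km", "y_km")]
  first <- first[order(first$section_id), ]
  q <- q[first$section_id]
  if (mode == "annual_mean") q <- q / n_years
  data.frame(section_id = first$section_id, x_km = first$x_km,
             y_km = first$y_km, q_u = as.numeric(q),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exponential decay coefficient for a characteristic travel distance
#'
#' The characteristic travel distance (CTD) is the distance at which 63% of
#' a volatilized chemical's mass has been degraded or deposited, so the
#' per-km decay-rate constant is `0.37^(1/CTD)` and the weight applied to a
#' source at distance `d` is
#' \deqn{\beta^d = 0.37^{d / CTD}.}
#'
#' @param d_km nonnegative distance(s) in km.
#' @param ctd_km positive characteristic travel distance in km.
#' @return decay weight(s) in (0, 1]; exactly 1 at `d_km = 0`.
#' @examples
#' decay_coefficient(0, 60)              # 1
#' decay_coefficient(60, 60)             # 0.37: 63% of mass lost at d = CTD
#' round(decay_coefficient(1, 10), 3)    # per-km constant for CTD 10 km
#' @export
decay_coefficient <- function(d_km, ctd_km) {
  if (any(d_km < 0)) stop("decay_coefficient: negative distance")
  if (any(ctd_km <= 0)) stop("decay_coefficient: CTD must be positive")
  0.37^(d_km / ctd_km)
}

# Even-odd ray cast with inclusive boundary: points on a polygon edge count
# as inside (deterministic for section centroids sitting on unit borders).
point_in_polygon <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring) - 1L  # closed ring: last vertex repeats the first
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  for (e in seq_len(n)) {
    x1 <- ring[e, 1]; y1 <- ring[e, 2]; x2 <- ring[e + 1, 1]; y2 <- ring[e + 1, 2]
    # boundary test: projection onto the segment within eps
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) clamp(((px - x1) * dx + (py - y1) * dy) / len2, 0, 1) else 0
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    on_edge <- on_edge | d2 <= eps^2
    # ray cast to the right
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * dx / ifelse(dy == 0, Inf, dy))
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Distance-weighted local use around one unit
#'
#' Implements \eqn{q_i = \sum_u q_u \, 0.37^{d_{iu}/CTD}} where \eqn{d_{iu}}
#' is the Euclidean distance from the unit's population-weighted centroid to
#' the section centroid, with the override that the decay coefficient is set
#' to 1 whenever the section centroid lies within the unit polygon
#' (boundary inclusive), regardless of distance. No cutoff radius is
#' applied; weights below 1e-300 underflow to 0.
#'
#' @param centroid numeric `c(x_km, y_km)` population-weighted centroid.
#' @param ring closed polygon vertex matrix of the unit.
#' @param sections section totals from [aggregate_sections()].
#' @param ctd_km positive CTD in km.
#' @return nonnegative scalar `q_i` (pounds).
#' @export
local_use <- function(centroid, ring, sections, ctd_km) {
  if (!nrow(sections)) stop("local_use: no sections")
  if (is.null(centroid) || any(!is.finite(centroid)))
    stop("local_use: unit has no weighted centroid")
  d <- sqrt((sections$x_km - centroid[1])^2 + (sections$y_km - centroid[2])^2)
  w <- decay_coefficient(d, ctd_km)
  w[w < 1e-300] <- 0
  inside <- point_in_polygon(sections$x_km, sections$y_km, ring)
  w[inside] <- 1
  sum(sections$q_u * w)
}

#' Exposure vectors for a set of units and CTDs
#'
#' Computes `q_i` and the dependent variable `log10(q_i)` for every unit and
#' each requested CTD. Units with `q_i = 0` for a CTD get `log_q_i = NA` and
#' are flagged for exclusion from that CTD's regression.
#'
#' @param units units data frame with `unit_id` and `ring` list column.
#' @param centroids weighted-centroid data frame (`unit_id`, `x_km`, `y_km`).
#' @param sections section totals.
#' @param ctd_km numeric vector of CTDs in km (default the study set
#'   1, 10, 30, 60, 90).
#' @return data frame: `unit_id`, `ctd_km`, `q_i`, `log_q_i`.
#' @export
exposure_vectors <- function(units, centroids, sections,
                             ctd_km = c(1, 10, 30, 60, 90)) {
  ord <- match(centroids$unit_id, units$unit_id)
  if (anyNA(ord)) stop("exposure_vectors: centroids for unknown unit(s)")
  out <- do.call(rbind, lapply(ctd_km, function(ctd) {
    q <- vapply(seq_len(nrow(centroids)), function(i)
      local_use(c(centroids$x_km[i], centroids$y_km[i]),
                units$ring[[ord[i]]], sections, ctd), numeric(1))
    data.frame(unit_id = centroids$unit_id, ctd_km = ctd, q_i = q,
               log_q_i = ifelse(q > 0, log10(q), NA_real_),
               stringsAsFactors = FALSE)
  }))
  n_zero <- sum(out$q_i == 0)
  if (n_zero > 0)
    message(sprintf("exposure_vectors: %d unit-CTD cell(s) with zero local use flagged (log DV undefined)", n_zero))
  rownames(out) <- NULL
  out
}
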