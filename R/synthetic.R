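#' Spatial Durbin data-generating-process configuration
#'
#' Bundles the parameters of the synthetic outcome model
#' \deqn{y = (I - \rho W)^{-1} (X\beta + WX\theta + \varepsilon),\qquad
#'       \varepsilon \sim N(0, \sigma^2 I)}
#' together with the measurement-error scale used when demographics are
#' reported with survey noise (reported = truth + Normal(0, moe_scale)).
#'
#' @param rho spatial autoregressive coefficient, strictly inside (-1, 1).
#' @param beta named numeric vector of covariate coefficients; the names
#'   define the independent variables the generator emits.
#' @param theta numeric vector of spatial-lag coefficients, same length as
#'   `beta`.
#' @param sigma nonnegative residual standard deviation.
#' @param moe_scale nonnegative scalar or per-IV vector: the standard
#'   deviation of reported-minus-true proportions, which also becomes the
#'   margin of error attached to the reported estimate.
#' @return an object of class `dgp_config`.
#' @export
dgp_config <- function(rho = 0.4,
                       beta = c(hispanic = 0.8, poverty = 0.3, ag_employment = 0.5),
                       theta = rep(0.2, length(beta)),
                       sigma = 0.3,
                       moe_scale = 0.03) {
  stopifnot(is.numeric(rho), length(rho) == 1L, abs(rho) < 1,
            is.numeric(beta), !is.null(names(beta)),
            length(theta) == length(beta),
            is.numeric(sigma), sigma >= 0, all(moe_scale >= 0))
  if (length(moe_scale) == 1L) moe_scale <- stats::setNames(rep(moe_scale, length(beta)), names(beta))
  if (is.null(names(moe_scale))) names(moe_scale) <- names(beta)
  structure(list(rho = rho, beta = beta,
                 theta = stats::setNames(theta, names(beta)),
                 sigma = sigma, moe_scale = moe_scale),
            class = "dgp_config")
}

# typical study-area base proportions used when the generator has to invent
# a latent demographic composition (roughly Central-Valley-like magnitudes)
.base_props <- c(hispanic = 0.42, black = 0.05, indigenous = 0.01, asian = 0.08,
                 children = 0.07, poverty = 0.22, noncitizens = 0.10,
                 women = 0.50, ag_employment = 0.10)

#' Generate a synthetic planar landscape
#'
#' Builds an abstract study area on a planar km grid: rectangular "tract"
#' polygons tiling the extent, smaller "place" polygons inside a seeded
#' subset of cells, block points with populations inside every unit, and
#' point-source section centroids on a regular 1.6 km lattice (one-mile
#' sections).
#'
#' If `n_units` does not factor into a near-square grid it is adjusted to
#' the nearest rectangle `nr x nc` and the adjustment is reported via a
#' message and the returned `$adjusted` flag.
#'
#' @param n_units requested number of tract units (>= 4).
#' @param grid_extent_km side length of the square study area in km.
#' @param k_blocks_per_unit block points generated per unit (>= 1).
#' @param seed integer seed; the same seed reproduces the landscape exactly.
#' @param make_places also generate a second geography class of "place"
#'   units (inner rectangles of roughly half the cells).
#' @param place_fraction fraction of cells that receive a place.
#' @param n_counties number of county bands (columns of the grid).
#' @param section_spacing_km lattice spacing for section centroids (1.6 km,
#'   the side of a one-mile section).
#' @return an object of class `landscape`: list with `units` (data frame with
#'   `unit_id`, `geography_class`, `county_id`, `area_km2`, and a `ring` list
#'   column of closed polygon vertex matrices), `blocks`, `sections`,
#'   `extent_km`, `dims`, `adjusted`.
#' @export
gen_landscape <- function(n_units, grid_extent_km, k_blocks_per_unit = 4L,
                          seed = 1L, make_places = TRUE, place_fraction = 0.5,
                          n_counties = 3L, section_spacing_km = 1.6) {
  stopifnot(n_units >= 4, grid_extent_km > 0, k_blocks_per_unit >= 1)
  nr <- max(2L, round(sqrt(n_units)))
  nc <- max(2L, round(n_units / nr))
  adjusted <- (nr * nc != n_units)
  if (adjusted) {
    message(sprintf("n_units = %d is not a grid; using %d x %d = %d units",
                    n_units, nr, nc, nr * nc))
  }
  n <- nr * nc
  dx <- grid_extent_km / nc
  dy <- grid_extent_km / nr
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  xmin <- (col - 1) * dx; ymin <- (row - 1) * dy

  rect_ring <- function(x0, y0, x1, y1) {
    cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
  }
  county <- paste0("C", pmin(n_counties, ceiling(col / (nc / n_counties))))

  units <- data.frame(
    unit_id = sprintf("T%04d", seq_len(n)),
    geography_class = "tract",
    county_id = county,
    area_km2 = dx * dy,
    stringsAsFactors = FALSE
  )
  units$ring <- lapply(seq_len(n), function(i)
    rect_ring(xmin[i], ymin[i], xmin[i] + dx, ymin[i] + dy))

  set.seed(derive_seed(seed, "landscape"))
  if (isTRUE(make_places)) {
    n_pl <- max(2L, round(place_fraction * n))
    pick <- sort(sample.int(n, n_pl))
    px0 <- xmin[pick] + dx / 4; py0 <- ymin[pick] + dy / 4
    places <- data.frame(
      unit_id = sprintf("P%04d", seq_along(pick)),
      geography_class = "place",
      county_id = county[pick],
      area_km2 = (dx / 2) * (dy / 2),
      stringsAsFactors = FALSE
    )
    places$ring <- lapply(seq_along(pick), function(i)
      rect_ring(px0[i], py0[i], px0[i] + dx / 2, py0[i] + dy / 2))
    units <- rbind(units, places)
  }

  # block points: uniform inside each unit's rectangle, Poisson-ish pops
  blocks <- do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
    r <- units$ring[[i]]
    x0 <- min(r[, 1]); x1 <- max(r[, 1]); y0 <- min(r[, 2]); y1 <- max(r[, 2])
    k <- k_blocks_per_unit
    data.frame(unit_id = units$unit_id[i],
               x_km = stats::runif(k, x0, x1),
               y_km = stats::runif(k, y0, y1),
               pop = stats::rpois(k, 60) + 1L,
               stringsAsFactors = FALSE)
  }))

  ax <- seq(section_spacing_km / 2, grid_extent_km,
            by = section_spacing_km)
  ax <- ax[ax <= grid_extent_km]
  sections <- expand.grid(x_km = ax, y_km = ax, KEEP.OUT.ATTRS = FALSE)
  sections <- data.frame(section_id = sprintf("S%05d", seq_len(nrow(sections))),
                         sections, stringsAsFactors = FALSE)

  structure(list(units = units, blocks = blocks, sections = sections,
                 extent_km = grid_extent_km, dims = c(nr = nr, nc = nc),
                 adjusted = adjusted, seed = seed),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %g km x %g km; %d units (%d tracts, %d places), %d blocks, %d sections\n",
              x$extent_km, x$extent_km, nrow(x$units),
              sum(x$units$geography_class == "tract"),
              sum(x$units$geography_class == "place"),
              nrow(x$blocks), nrow(x$sections)))
  invisible(x)
}

#' Generate synthetic point-source use records
#'
#' Emulates geocoded pesticide-use reports aggregated to section centroids:
#' for each section and year, pounds of active ingredient are drawn
#' log-uniformly inside `bounds`, with the position in the (log) range scaled
#' by a nonnegative intensity surface evaluated at the section centroid.
#' Sections where the intensity is zero emit no records.
#'
#' @param sections data frame with `section_id`, `x_km`, `y_km`.
#' @param intensity_surface vectorised function of (x, y) returning
#'   nonnegative relative intensities.
#' @param seed integer seed.
#' @param bounds length-2 positive vector: lower/upper pounds per record.
#' @param years integer vector of study years.
#' @return data frame of use records: `section_id`, `x_km`, `y_km`, `year`,
#'   `pounds` (all strictly positive).
#' @export
gen_use_records <- function(sections, intensity_surface = function(x, y) rep(1, length(x)),
                            seed = 1L, bounds = c(1e-2, 1e4), years = 2011:2015) {
  stopifnot(length(bounds) == 2L, all(bounds > 0), bounds[1] <= bounds[2])
  s <- intensity_surface(sections$x_km, sections$y_km)
  if (any(s < 0)) stop("intensity_surface must be nonnegative")
  keep <- which(s > 0)
  if (!length(keep)) return(data.frame(section_id = character(), x_km = numeric(),
                                       y_km = numeric(), year = integer(),
                                       pounds = numeric(), stringsAsFactors = FALSE))
  srel <- s[keep] / max(s[keep])
  set.seed(derive_seed(seed, "use_records"))
  out <- do.call(rbind, lapply(years, function(yr) {
    u <- stats::runif(length(keep))
    data.frame(section_id = sections$section_id[keep],
               x_km = sections$x_km[keep], y_km = sections$y_km[keep],
               year = yr,
               pounds = bounds[1] * (bounds[2] / bounds[1])^(u * srel),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate synthetic demographics with margins of error
#'
#' Draws a latent true proportion for each independent variable named in the
#' DGP configuration (plus a women/children/etc. base when requested through
#' the names), then reports it with survey-style measurement error:
#' `reported = truth + Normal(0, moe_scale)`, clamped to `[0, 1]`. Reported
#' values are emitted as count pairs (`<var>_est`, `<var>_moe`) against the
#' unit's total population, so that deriving proportions downstream returns
#' exactly the reported proportion and its margin of error.
#'
#' The latent truth is retained in `attr(, "truth")` for recovery tests.
#'
#' @param landscape a `landscape` object (or any list with a `units` data
#'   frame carrying `unit_id`, `geography_class`, `county_id`, `area_km2`).
#' @param dgp a [dgp_config()]; its `beta` names define the IVs.
#' @param seed integer seed.
#' @param employment_rate fraction of the population employed (drives the
#'   total-employment column used by the exclusion filter and county ag
#'   control).
#' @param zero_pop_fraction fraction of units reported with zero population
#'   (to exercise the exclusion filter); 0 by default.
#' @return data frame with one row per unit: identifiers, `area_km2`,
#'   `total_pop_est`/`_moe`, `total_employment_est`/`_moe`,
#'   `ag_employment_est`/`_moe` and per-IV count pairs. Attribute `truth`
#'   holds the latent proportions; attribute `clamped_fraction` the share of
#'   reported values that hit the [0,1] bounds.
#' @export
gen_demographics <- function(landscape, dgp = dgp_config(), seed = 1L,
                             employment_rate = 0.45, zero_pop_fraction = 0) {
  units <- landscape$units
  n <- nrow(units)
  ivs <- names(dgp$beta)
  set.seed(derive_seed(seed, "demographics"))

  # population spans orders of magnitude: log10 density ~ N(2.4, 0.8)
  log_dens <- stats::rnorm(n, mean = 2.4, sd = 0.8)
  total_pop <- pmax(1, round(units$area_km2 * 10^log_dens))
  if (zero_pop_fraction > 0) {
    nz <- max(1L, round(zero_pop_fraction * n))
    total_pop[sample.int(n, nz)] <- 0
  }

  out <- data.frame(unit_id = units$unit_id,
                    geography_class = units$geography_class,
                    county_id = units$county_id,
                    area_km2 = units$area_km2,
                    total_pop_est = total_pop, total_pop_moe = 0,
                    stringsAsFactors = FALSE)
  truth <- data.frame(unit_id = units$unit_id, stringsAsFactors = FALSE)

  n_clamped <- 0L; n_vals <- 0L
  for (v in ivs) {
    base <- .base_props[[v]] %||% 0.2
    p_true <- stats::plogis(stats::rnorm(n, stats::qlogis(base), 0.8))
    mscale <- unname(dgp$moe_scale[[v]])
    p_rep <- p_true + stats::rnorm(n, 0, mscale)
    n_clamped <- n_clamped + sum(p_rep < 0 | p_rep > 1)
    n_vals <- n_vals + n
    p_rep <- clamp(p_rep)
    truth[[v]] <- p_true
    out[[paste0(v, "_est")]] <- p_rep * total_pop
    out[[paste0(v, "_moe")]] <- mscale * total_pop
  }

  emp <- round(employment_rate * total_pop)
  out$total_employment_est <- emp
  out$total_employment_moe <- 0
  if (!"ag_employment" %in% ivs) {
    p_ag <- stats::plogis(stats::rnorm(n, stats::qlogis(.base_props[["ag_employment"]]), 0.8))
    out$ag_employment_est <- p_ag * total_pop
    out$ag_employment_moe <- 0
    truth$ag_employment <- p_ag
  }
  truth$log_density <- ifelse(total_pop > 0, log10(total_pop / units$area_km2), NA_real_)

  if (n_clamped > 0)
    message(sprintf("gen_demographics: clamped %d of %d reported proportions to [0,1]",
                    n_clamped, n_vals))
  attr(out, "truth") <- truth
  attr(out, "clamped_fraction") <- if (n_vals) n_clamped / n_vals else 0
  out
}

#' Generate an outcome from the spatial Durbin process
#'
#' Solves \eqn{(I - \rho W) y = X\beta + WX\theta + \varepsilon} densely,
#' with \eqn{\varepsilon \sim N(0, \sigma^2 I)}.
#'
#' @param X numeric matrix of covariates (columns ordered as `dgp$beta`).
#' @param w a [knn_weights()] object (row-standardized).
#' @param dgp a [dgp_config()].
#' @param seed integer seed for the noise draw.
#' @return numeric outcome vector of length `nrow(X)`.
#' @export
gen_outcome <- function(X, w, dgp, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(inherits(w, "knn_weights"), w$n == n,
            ncol(X) == length(dgp$beta))
  Wd <- as.matrix(w$W)
  A <- diag(n) - dgp$rho * Wd
  if (rcond(A) < 1e-12)
    stop("(I - rho W) is numerically singular; check rho against the feasible interval")
  set.seed(derive_seed(seed, "outcome"))
  eps <- stats::rnorm(n, 0, dgp$sigma)
  rhs <- X %*% dgp$beta + Wd %*% X %*% dgp$theta + eps
  drop(solve(A, rhs))
}

#' Write the four synthetic pipeline input files
#'
#' Emits exactly the formats the ingestion side reads: a use-record CSV, a
#' geography GeoJSON, a block-point CSV, and a demographics CSV, plus a JSON
#' manifest recording the seed and configuration.
#'
#' @param landscape a [gen_landscape()] result.
#' @param demographics a [gen_demographics()] result.
#' @param records a [gen_use_records()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, a named list of the five file paths.
#' @export
write_synthetic_inputs <- function(landscape, demographics, records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    use_records = file.path(dir, "use_records.csv"),
    geography = file.path(dir, "geography.geojson"),
    blocks = file.path(dir, "blocks.csv"),
    demographics = file.path(dir, "demographics.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  utils::write.csv(records, paths$use_records, row.names = FALSE)
  write_geography(landscape$units, paths$geography)
  utils::write.csv(landscape$blocks, paths$blocks, row.names = FALSE)
  demo <- demographics
  attr(demo, "truth") <- NULL; attr(demo, "clamped_fraction") <- NULL
  utils::write.csv(demo, paths$demographics, row.names = FALSE)
  manifest <- list(seed = landscape$seed, extent_km = landscape$extent_km,
                   dims = as.list(landscape$dims),
                   n_units = nrow(landscape$units),
                   n_sections = nrow(landscape$sections),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
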