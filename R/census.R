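#' Population-weighted centroid of block points
#'
#' @param blocks data frame with `x_km`, `y_km`, `pop` (one unit's blocks).
#' @return named numeric vector `c(x_km, y_km)`.
#' @details The centroid is \eqn{\sum p_b c_b / \sum p_b}; a unit whose
#'   blocks all have zero population has no centroid and should have been
#'   excluded upstream, so that case is an error.
#' @export
weighted_centroid <- function(blocks) {
  stopifnot(all(c("x_km", "y_km", "pop") %in% names(blocks)))
  tot <- sum(blocks$pop)
  if (nrow(blocks) == 0 || tot <= 0)
    stop("weighted_centroid: no block population; unit should have been excluded")
  c(x_km = sum(blocks$pop * blocks$x_km) / tot,
    y_km = sum(blocks$pop * blocks$y_km) / tot)
}

#' Weighted centroids for every unit
#'
#' @param blocks data frame with `unit_id`, `x_km`, `y_km`, `pop`.
#' @param unit_ids character vector of units to compute (defaults to all in
#'   `blocks`).
#' @return data frame `unit_id`, `x_km`, `y_km` in the order of `unit_ids`.
#' @export
weighted_centroids <- function(blocks, unit_ids = unique(blocks$unit_id)) {
  idx <- split(seq_len(nrow(blocks)), blocks$unit_id)
  miss <- setdiff(unit_ids, names(idx))
  if (length(miss))
    stop("no blocks for unit(s): ", paste(miss, collapse = ", "))
  cc <- t(vapply(unit_ids, function(u) weighted_centroid(blocks[idx[[u]], ]),
                 numeric(2)))
  data.frame(unit_id = unit_ids, x_km = cc[, 1], y_km = cc[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Derived proportion with propagated margin of error
#'
#' Computes `p = num/den` and propagates survey margins of error with the
#' census-recommended formula for derived proportions,
#' \deqn{MOE_p = \sqrt{MOE_{num}^2 - p^2 MOE_{den}^2} / den,}
#' falling back to the derived-ratio formula
#' \deqn{MOE_p = \sqrt{MOE_{num}^2 + p^2 MOE_{den}^2} / den}
#' whenever the radicand is negative, so the returned MOE is always real and
#' nonnegative.
#'
#' @param num_est,num_moe numerator estimate and MOE (vectors allowed).
#' @param den_est,den_moe denominator estimate and MOE.
#' @return data frame with columns `est` and `moe`.
#' @export
derive_proportion <- function(num_est, num_moe, den_est, den_moe) {
  if (any(den_est <= 0))
    stop("derive_proportion: denominator estimate <= 0; filter units first")
  stopifnot(all(num_moe >= 0), all(den_moe >= 0))
  p <- num_est / den_est
  rad <- num_moe^2 - p^2 * den_moe^2
  fallback <- rad < 0
  rad[fallback] <- (num_moe^2 + p^2 * den_moe^2)[fallback]
  data.frame(est = p, moe = sqrt(rad) / den_est)
}

#' Log population density
#'
#' @param total_pop positive resident count.
#' @param area_km2 positive area.
#' @return `log10(total_pop / area_km2)` (base 10, matching the dependent
#'   variable's convention).
#' @export
derive_density <- function(total_pop, area_km2) {
  if (any(total_pop <= 0))
    stop("derive_density: zero population; unit should have been excluded")
  stopifnot(all(area_km2 > 0))
  log10(total_pop / area_km2)
}

#' Exclusion filter for zero-population / zero-employment units
#'
#' Drops units whose reported total population or total employment is zero
#' (their proportions and density are undefined). Idempotent.
#'
#' @param table demographics data frame with `total_pop_est` and
#'   `total_employment_est`.
#' @return list with `retained` (filtered table) and `excluded` (data frame
#'   `unit_id`, `reason`).
#' @export
filter_units <- function(table) {
  bad_pop <- table$total_pop_est <= 0
  bad_emp <- table$total_employment_est <= 0
  reason <- ifelse(bad_pop & bad_emp, "zero population and employment",
                   ifelse(bad_pop, "zero population",
                          ifelse(bad_emp, "zero employment", NA_character_)))
  drop <- bad_pop | bad_emp
  excluded <- data.frame(unit_id = table$unit_id[drop],
                         reason = reason[drop], stringsAsFactors = FALSE)
  list(retained = table[!drop, , drop = FALSE], excluded = excluded)
}

#' County-level control variables
#'
#' Aggregates retained units within each county as a county-level ACS pull
#' would: county log density is `log10(sum(pop) / sum(area))`; county
#' agricultural employment is `sum(ag workers) / sum(total employment)`.
#' Values are broadcast back to the member units.
#'
#' @param table retained demographics data frame (after [filter_units()]).
#' @return data frame `unit_id`, `county_log_density`, `county_ag_employment`
#'   in the row order of `table`.
#' @export
county_controls <- function(table) {
  sp <- split(seq_len(nrow(table)), table$county_id)
  out <- data.frame(unit_id = table$unit_id,
                    county_log_density = NA_real_,
                    county_ag_employment = NA_real_,
                    stringsAsFactors = FALSE)
  for (idx in sp) {
    pop <- sum(table$total_pop_est[idx]); area <- sum(table$area_km2[idx])
    emp <- sum(table$total_employment_est[idx])
    ag <- sum(table$ag_employment_est[idx])
    out$county_log_density[idx] <- log10(pop / area)
    out$county_ag_employment[idx] <- ag / emp
  }
  out
}

#' Prepare analysis-ready independent variables
#'
#' Full census-preparation stage for one geography class: applies the
#' exclusion filter, derives each subgroup proportion with propagated MOE
#' (counts exceeding the population are clamped so proportions stay in
#' [0, 1], with a warning), computes log population density, county-level
#' controls, and population-weighted centroids.
#'
#' @param demographics demographics data frame (count pairs `<var>_est`,
#'   `<var>_moe` against `total_pop_est`/`_moe`).
#' @param blocks block-point data frame (`unit_id`, `x_km`, `y_km`, `pop`).
#' @param iv_names character vector of subgroup count variables to derive as
#'   proportions; defaults to every `<var>_est` column other than totals.
#' @return list of class `derived_ivs`: `ivs` (data frame of `unit_id`,
#'   `geography_class`, `county_id`, per-IV `<v>_est`/`<v>_moe` proportion
#'   columns, `log_density_est` (+ `_moe = NA`), county controls),
#'   `centroids`, `excluded`, and `proportion_vars`.
#' @export
prepare_units <- function(demographics, blocks, iv_names = NULL) {
  est_cols <- grep("_est$", names(demographics), value = TRUE)
  auto <- setdiff(sub("_est$", "", est_cols),
                  c("total_pop", "total_employment"))
  iv_names <- iv_names %||% auto
  flt <- filter_units(demographics)
  d <- flt$retained
  if (!nrow(d)) stop("prepare_units: no units retained after filtering")

  ivs <- data.frame(unit_id = d$unit_id,
                    geography_class = d$geography_class,
                    county_id = d$county_id, stringsAsFactors = FALSE)
  clamped <- 0L
  for (v in iv_names) {
    num <- d[[paste0(v, "_est")]]
    over <- num > d$total_pop_est
    if (any(over)) { clamped <- clamped + sum(over); num[over] <- d$total_pop_est[over] }
    pr <- derive_proportion(num, d[[paste0(v, "_moe")]],
                            d$total_pop_est, d$total_pop_moe)
    ivs[[paste0(v, "_est")]] <- pr$est
    ivs[[paste0(v, "_moe")]] <- pr$moe
  }
  if (clamped > 0)
    warning(sprintf("prepare_units: clamped %d subgroup counts exceeding total population", clamped))
  ivs$log_density_est <- derive_density(d$total_pop_est, d$area_km2)
  ivs$log_density_moe <- NA_real_
  cc <- county_controls(d)
  ivs$county_log_density_est <- cc$county_log_density
  ivs$county_log_density_moe <- NA_real_
  ivs$county_ag_employment_est <- cc$county_ag_employment
  ivs$county_ag_employment_moe <- NA_real_

  centroids <- weighted_centroids(blocks, unit_ids = d$unit_id)
  structure(list(ivs = ivs, centroids = centroids, excluded = flt$excluded,
                 proportion_vars = iv_names),
            class = "derived_ivs")
}

#' Extract the design matrix of IV point estimates
#'
#' @param ivs the `ivs` data frame from [prepare_units()] (or any data frame
#'   with `<v>_est` columns).
#' @param vars variable names (without the `_est` suffix).
#' @return numeric matrix, one column per variable.
#' @export
iv_matrix <- function(ivs, vars) {
  cols <- paste0(vars, "_est")
  miss <- setdiff(cols, names(ivs))
  if (length(miss)) stop("missing IV columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(ivs[, cols, drop = FALSE])
  colnames(m) <- vars
  m
}
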