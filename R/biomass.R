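# Converts reconstructed volumes and measured masses into wet-mass density
# (g/mL) and percent-water reports, the downstream biomass summary of the
# reconstruction pipeline.

#' Wet-mass density of a root system
#'
#' `wet_mass / volume` in g/mL. Reconstructions occasionally fail (no
#' volume estimate); for those records the density is undefined and `NA`
#' is returned rather than an error, so whole tables can be processed.
#'
#' @param wet_mass Wet mass, g (vectorized).
#' @param volume Estimated volume, mL; must be positive where a density is
#'   to be computed, `NA` marks a failed reconstruction.
#' @return Density in g/mL at full precision (see [format_density()] for
#'   the 3-decimal display rule); `NA` where volume is missing or
#'   non-positive.
#' @examples
#' density_gml(1.772, 116.740)  # 0.0152 -> displayed 0.015
#' @export
density_gml <- function(wet_mass, volume) {
  stopifnot(all(wet_mass >= 0, na.rm = TRUE))
  bad <- is.na(volume) | volume <= 0
  out <- wet_mass / volume
  out[bad] <- NA_real_
  out
}

#' Display rounding for densities
#'
#' Densities are displayed at 3 decimals (half away from zero), the
#' convention that best matches tabulated density reports computed from
#' full-precision values; internal computation always keeps full precision.
#'
#' @param x Densities, g/mL.
#' @export
format_density <- function(x) round(x + 1e-12, 3)

#' Percent water of a root sample
#'
#' `100 (wet - dry) / wet` from wet and oven-dry masses.
#'
#' @param wet,dry Masses, g; requires `0 <= dry <= wet`, `wet > 0`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_water <- function(wet, dry) {
  if (any(wet <= 0)) stop_rootcarve("wet mass must be positive",
                                    "rootcarve_invalid_measurement")
  if (any(dry < 0 | dry > wet))
    stop_rootcarve("dry mass must satisfy 0 <= dry <= wet",
                   "rootcarve_invalid_measurement")
  100 * (wet - dry) / wet
}

#' Build validated plant records
#'
#' @param df Data frame with columns `root` (id), `days_elapsed`,
#'   `volume_ml` (`NA` = failed reconstruction), `wet_mass_g`, and
#'   optionally `dry_mass_g` and/or `pct_water`.
#' @return The data frame with a derived `density_g_ml` column, class
#'   `plant_records`.
#' @export
plant_records <- function(df) {
  need <- c("root", "days_elapsed", "volume_ml", "wet_mass_g")
  if (!all(need %in% names(df)))
    stop_rootcarve(paste("plant records need columns:",
                         paste(need, collapse = ", ")),
                   "rootcarve_bad_records")
  if (any(df$wet_mass_g < 0, na.rm = TRUE))
    stop_rootcarve("negative mass", "rootcarve_invalid_measurement")
  df$density_g_ml <- density_gml(df$wet_mass_g, df$volume_ml)
  if (!"pct_water" %in% names(df) && "dry_mass_g" %in% names(df))
    df$pct_water <- percent_water(df$wet_mass_g, df$dry_mass_g)
  class(df) <- c("plant_records", "data.frame")
  df
}

#' Bundled hydroponic growth-study measurements
#'
#' Example measurements from an 18-plant, 30-day hydroponic growth study:
#' per plant, days elapsed, reconstructed root volume (mL; `NA` for the two
#' plants whose 3D reconstruction failed), measured wet mass (g) and the
#' reported percent water. Used by the worked examples and the report
#' command.
#'
#' @return A [plant_records()] data frame.
#' @export
root_measurements <- function() {
  path <- system.file("extdata", "root_measurements.csv",
                      package = "rootcarve")
  plant_records(read.csv(path))
}

#' Summarize density and volume across plant records
#'
#' Overall mean density (unweighted across plants with a successful
#' reconstruction; optionally mass-weighted), per-timepoint means, and the
#' count of failed reconstructions.
#'
#' @param records A [plant_records()] data frame.
#' @param weighted Mass-weight the mean density (default unweighted).
#' @return Object of class `biomass_summary`: list with `mean_density`,
#'   `by_day` (per-timepoint data frame), `n`, `n_failed`.
#' @export
summarize_records <- function(records, weighted = FALSE) {
  d <- records$density_g_ml
  ok <- !is.na(d)
  if (!any(ok))
    stop_rootcarve("no records with a defined density", "rootcarve_empty_report")
  mean_density <- if (weighted)
    sum(records$wet_mass_g[ok] * d[ok]) / sum(records$wet_mass_g[ok])
  else mean(d[ok])
  sub <- records[ok, , drop = FALSE]
  by_day <- aggregate(cbind(density_g_ml = sub$density_g_ml,
                            volume_ml = sub$volume_ml,
                            wet_mass_g = sub$wet_mass_g),
                      by = list(days_elapsed = sub$days_elapsed), FUN = mean)
  counts <- aggregate(list(n = sub$root), by = list(days_elapsed =
                                                      sub$days_elapsed),
                      FUN = length)
  by_day <- merge(by_day, counts, by = "days_elapsed")
  structure(list(mean_density = mean_density, by_day = by_day,
                 n = nrow(records), n_failed = sum(!ok),
                 weighted = weighted),
            class = "biomass_summary")
}

#' @export
print.biomass_summary <- function(x, ...) {
  cat(sprintf("Biomass density summary (%d plants, %d failed reconstructions)\n",
              x$n, x$n_failed))
  cat(sprintf("Mean %sdensity: %.3f g/mL\n",
              if (x$weighted) "mass-weighted " else "", x$mean_density))
  df <- x$by_day
  df$density_g_ml <- format_density(df$density_g_ml)
  df$volume_ml <- round(df$volume_ml, 3)
  df$wet_mass_g <- round(df$wet_mass_g, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
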