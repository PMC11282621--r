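#' Dispersal origin
#'
#' A named geographic point. The default is Ganj Dareh (central Zagros
#' Mountains, western Iran; 34.27 N, 47.47 E), the Neolithic settlement used
#' as the reference location of early goat management.
#'
#' @param name label for the point.
#' @param lat,lon coordinates in decimal degrees, N/E positive.
#' @return A list of class `origin` with `name`, `lat`, `lon`.
#' @export
origin_point <- function(name = "Ganj Dareh", lat = 34.27, lon = 47.47) {
  if (!is.finite(lat) || !is.finite(lon) || abs(lat) > 90 || abs(lon) > 180)
    stop("invalid coordinates: lat ", lat, ", lon ", lon)
  structure(list(name = name, lat = lat, lon = lon), class = "origin")
}

#' @rdname origin_point
#' @export
ganj_dareh <- function() origin_point()

#' Vincenty ellipsoid distance
#'
#' Inverse geodesic distance on the WGS84 ellipsoid (a = 6378137 m,
#' f = 1/298.257223563), in kilometres, via the iterative Vincenty solution
#' of `geosphere::distVincentyEllipsoid` -- the same method used for the
#' published breed-to-origin distances. Vectorized over the first point.
#'
#' @param lat1,lon1 first point(s), decimal degrees.
#' @param lat2,lon2 second point, decimal degrees.
#' @return Distance(s) in kilometres.
#' @export
vincenty_km <- function(lat1, lon1, lat2, lon2) {
  ok <- function(lat, lon) all(is.finite(lat) & is.finite(lon) &
                                 abs(lat) <= 90 & abs(lon) <= 180)
  if (!ok(lat1, lon1) || !ok(lat2, lon2)) stop("invalid coordinates")
  d <- geosphere::distVincentyEllipsoid(cbind(lon1, lat1), cbind(lon2, lat2))
  if (any(!is.finite(d)))
    stop("Vincenty iteration failed to converge (near-antipodal points); ",
         "use a spherical fallback for such pairs")
  d / 1000
}

#' Distances of breed sampling sites to an origin
#'
#' @param breeds data frame with `breed_id`, `lon`, `lat`.
#' @param origin an [origin_point()] (default Ganj Dareh).
#' @return `breeds` with a `distance_km` column appended (replacing any
#'   existing one; the computation is idempotent).
#' @export
distances_to_origin <- function(breeds, origin = ganj_dareh()) {
  stopifnot(all(c("breed_id", "lon", "lat") %in% names(breeds)))
  d <- tryCatch(
    vincenty_km(breeds$lat, breeds$lon, origin$lat, origin$lon),
    error = function(e) {
      i <- which(!is.finite(breeds$lat) | !is.finite(breeds$lon) |
                   abs(breeds$lat) > 90 | abs(breeds$lon) > 180)
      ctx <- if (length(i)) paste0(" (breed ", breeds$breed_id[i[1]], ")") else ""
      stop(conditionMessage(e), ctx, call. = FALSE)
    })
  breeds$distance_km <- d
  breeds
}

# Breed sets behind the named subset presets. The three South African
# commercial breeds (part-Asian ancestry) are always excluded from African
# cline analyses; island populations are excluded in the "no islands"
# variants because their reduced diversity reflects insularity rather than
# dispersal history.
.africa_commercial <- c("BOE", "SAV", "KHAR")
.africa_islands <- c("MEN", "SOF", "PAL")
.europe_british_irish <- c("ENG", "IRL")
.europe_med_islands <- c("CRS", "SAR", "MAL", "MLT", "GGT")

#' Subset a breed table for a cline analysis
#'
#' @param tab data frame with `breed_id` and (for presets) `continent`.
#' @param subset either a preset name -- `"europe_all"`,
#'   `"europe_no_british_irish"`, `"europe_no_all_islands"`,
#'   `"africa_with_islands"`, `"africa_no_islands"`, `"asia_all"` -- or a
#'   list with optional `include` / `exclude` character vectors of breed ids.
#' @return The filtered data frame.
#' @export
subset_breeds <- function(tab, subset) {
  stopifnot("breed_id" %in% names(tab))
  if (is.character(subset) && length(subset) == 1) {
    has_cont <- "continent" %in% names(tab)
    pick <- function(cont, exclude = character()) {
      out <- if (has_cont) tab[tab$continent == cont, ] else tab
      out[!out$breed_id %in% exclude, ]
    }
    out <- switch(subset,
      europe_all = pick("Europe"),
      europe_no_british_irish = pick("Europe", .europe_british_irish),
      europe_no_all_islands =
        pick("Europe", c(.europe_british_irish, .europe_med_islands)),
      africa_with_islands = pick("Africa", .africa_commercial),
      africa_no_islands =
        pick("Africa", c(.africa_commercial, .africa_islands)),
      asia_all = pick("Asia"),
      stop("unknown subset preset: ", subset))
  } else if (is.list(subset)) {
    known <- tab$breed_id
    ids <- c(subset$include, subset$exclude)
    if (length(bad <- setdiff(ids, known)))
      stop("unknown breed_id: ", paste(bad, collapse = ", "))
    out <- tab
    if (!is.null(subset$include)) out <- out[out$breed_id %in% subset$include, ]
    if (!is.null(subset$exclude)) out <- out[!out$breed_id %in% subset$exclude, ]
  } else stop("subset must be a preset name or a list(include=, exclude=)")
  rownames(out) <- NULL
  out
}

stat_column <- function(statistic) {
  switch(statistic, ho = "ho", he = "he", fst = "fst_vs_ref",
         f_roh = "f_roh", fis = "fis",
         stop("unknown statistic: ", statistic))
}

#' Correlation of a diversity statistic with distance to the origin
#'
#' Pearson product-moment correlation of a per-breed statistic against the
#' breed's distance to the origin, with the two-sided p-value from the exact
#' t transform on n - 2 degrees of freedom (appropriate at the small
#' per-continent sample sizes), plus the ordinary least-squares slope and
#' intercept for plotting. Rows with an absent statistic or distance are
#' dropped pairwise and counted.
#'
#' @param tab data frame with the statistic column and `distance_km`.
#' @param statistic one of `"ho"`, `"he"`, `"fst"`, `"f_roh"`.
#' @param subset_label label carried into the result.
#' @return A one-row data frame: `statistic`, `subset_label`, `n_breeds`,
#'   `n_dropped`, `r`, `p`, `slope`, `intercept`.
#' @export
pearson_cline <- function(tab, statistic = c("ho", "he", "fst", "f_roh"),
                          subset_label = "") {
  statistic <- match.arg(statistic)
  col <- stat_column(statistic)
  if (!col %in% names(tab)) stop("column not present: ", col)
  x <- tab[[col]]
  d <- tab$distance_km
  ok <- is.finite(x) & is.finite(d)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 breeds with both ", statistic,
                  " and distance present (have ", n, ")")
  x <- x[ok]; d <- d[ok]
  if (stats::sd(x) == 0 || stats::sd(d) == 0)
    stop("degenerate: zero variance in ", if (stats::sd(x) == 0) statistic
         else "distance")
  ct <- stats::cor.test(x, d, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(x ~ d)
  data.frame(statistic = statistic, subset_label = subset_label,
             n_breeds = n, n_dropped = sum(!ok),
             r = unname(ct$estimate), p = ct$p.value,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             stringsAsFactors = FALSE)
}

#' All diversity-versus-distance clines on a breed table
#'
#' Runs [pearson_cline()] for every continental subset preset and every
#' statistic with at least three present values, reproducing the full set of
#' published correlation analyses in one table.
#'
#' @param tab joined breed/diversity table (see [load_goat_tables()]`$table`)
#'   with `continent`, `distance_km` and statistic columns.
#' @param presets subset presets to evaluate.
#' @param statistics statistics to evaluate where present.
#' @return Data frame of cline results, one row per preset x statistic.
#' @export
cline_report <- function(tab,
                         presets = c("europe_all", "europe_no_british_irish",
                                     "africa_with_islands",
                                     "africa_no_islands", "asia_all"),
                         statistics = c("ho", "he", "fst", "f_roh")) {
  rows <- list()
  for (ps in presets) {
    sub <- subset_breeds(tab, ps)
    for (st in statistics) {
      col <- stat_column(st)
      if (!col %in% names(sub)) next
      if (sum(is.finite(sub[[col]]) & is.finite(sub$distance_km)) < 3) next
      rows[[length(rows) + 1]] <- pearson_cline(sub, st, subset_label = ps)
    }
  }
  do.call(rbind, rows)
}
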