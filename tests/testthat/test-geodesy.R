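test_that("Vincenty distance handles trivial and closed-form cases", {
  expect_equal(vincenty_km(34.27, 47.47, 34.27, 47.47), 0)
  # one degree along the equator is an exact arc of the ellipsoid:
  # a * pi / 180 = 111.3195 km
  expect_equal(vincenty_km(0, 0, 0, 1), 6378.137 * pi / 180,
               tolerance = 1e-9)
  expect_error(vincenty_km(95, 0, 0, 0), "invalid coordinates")
})

test_that("published breed-to-origin distances are matched to the
           coordinate-rounding limit", {
  # Printed distances derive from unrounded sampling coordinates; printed
  # coordinates are rounded to 0.01 degrees (~0.55 km), which bounds the
  # achievable agreement below 1 km.
  ft <- load_goat_tables()
  tab <- ft$table[!is.na(ft$table$distance_km), ]
  calc <- vincenty_km(tab$lat, tab$lon, 34.27, 47.47)
  expect_lt(max(abs(calc - tab$distance_km)), 1)
  # spot rows named in the published tables
  expect_equal(calc[tab$breed_id == "LNR_DK"], 3631.118, tolerance = 2e-4)
  expect_equal(calc[tab$breed_id == "IRA_KUR"], 124.337, tolerance = 5e-3)
  expect_equal(calc[tab$breed_id == "CRP"], 2255.681, tolerance = 2e-4)
})

test_that("geodesic distance is symmetric and metric-like", {
  set.seed(17)
  pts <- cbind(lat = runif(20, -60, 70), lon = runif(20, -170, 170))
  for (i in 1:10) {
    a <- pts[i, ]; b <- pts[i + 10, ]
    expect_equal(vincenty_km(a[1], a[2], b[1], b[2]),
                 vincenty_km(b[1], b[2], a[1], a[2]))
  }
  # triangle inequality over all ordered triples of a 6-point subset
  sub <- pts[1:6, ]
  d <- outer(1:6, 1:6, function(i, j)
    vincenty_km(sub[i, 1], sub[i, 2], sub[j, 1], sub[j, 2]))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
})

test_that("ellipsoid and sphere agree within the known 0.56% bound", {
  set.seed(23)
  lat1 <- runif(50, -80, 80); lon1 <- runif(50, -180, 180)
  lat2 <- runif(50, -80, 80); lon2 <- runif(50, -180, 180)
  dv <- vincenty_km(lat1, lon1, lat2, lon2)
  ds <- sphere_km(lat1, lon1, lat2, lon2)
  keep <- ds > 1  # relative bound is meaningless at tiny separations
  expect_true(all(abs(dv - ds)[keep] / ds[keep] < 0.0056))
})

test_that("distances_to_origin appends and is idempotent", {
  ft <- load_goat_tables("Asia")
  b <- distances_to_origin(ft$breeds)
  expect_true("distance_km" %in% names(b))
  expect_equal(b$distance_km[b$breed_id == "IRA_KUR"], 124.337,
               tolerance = 5e-3)
  expect_equal(distances_to_origin(b), b)
  # the origin itself as a pseudo-breed is at distance zero
  self <- data.frame(breed_id = "GD", lon = 47.47, lat = 34.27)
  expect_equal(distances_to_origin(self)$distance_km, 0)
  bad <- data.frame(breed_id = "BAD", lon = 500, lat = 0)
  expect_error(distances_to_origin(bad), "BAD")
})

test_that("subset presets select the documented breed sets", {
  tab <- load_goat_tables()$table
  expect_identical(nrow(subset_breeds(tab, "europe_all")), 40L)
  expect_identical(nrow(subset_breeds(tab, "europe_no_british_irish")), 38L)
  expect_identical(nrow(subset_breeds(tab, "africa_with_islands")), 40L)
  expect_identical(nrow(subset_breeds(tab, "africa_no_islands")), 37L)
  expect_identical(nrow(subset_breeds(tab, "asia_all")), 22L)
  af <- subset_breeds(tab, "africa_with_islands")
  expect_false(any(c("BOE", "SAV", "KHAR") %in% af$breed_id))
  expect_true(all(c("MEN", "SOF", "PAL") %in% af$breed_id))
  expect_identical(subset_breeds(tab, list(exclude = character()))$breed_id,
                   tab$breed_id)
  expect_error(subset_breeds(tab, list(exclude = "ZZZ")), "unknown breed_id")
  expect_error(subset_breeds(tab, "nope"), "unknown subset preset")
})

test_that("a perfect negative linear relation gives r = -1", {
  tab <- data.frame(breed_id = letters[1:6], ho = 0.5 - (1:6) * 0.02,
                    distance_km = (1:6) * 100)
  res <- pearson_cline(tab, "ho", subset_label = "toy")
  expect_equal(res$r, -1)
  expect_equal(res$slope, -0.0002)
  expect_identical(res$n_breeds, 6L)
})

test_that("degenerate and undersized cline inputs error", {
  tab <- data.frame(breed_id = letters[1:5], ho = rep(0.4, 5),
                    distance_km = 1:5 * 100)
  expect_error(pearson_cline(tab, "ho"), "degenerate")
  expect_error(pearson_cline(tab[1:2, ], "ho"), "at least 3 breeds")
})

test_that("absent values are dropped pairwise and counted", {
  tab <- data.frame(breed_id = letters[1:6],
                    fst_vs_ref = c(0.1, 0.2, NA, 0.3, 0.25, 0.15),
                    distance_km = c(100, 200, 300, NA, 500, 600))
  res <- pearson_cline(tab, "fst")
  expect_identical(res$n_breeds, 4L)
  expect_identical(res$n_dropped, 2L)
})

test_that("t-based p-values are calibrated against a permutation null", {
  for (n in c(10, 38)) {
    set.seed(n)
    x <- runif(n); y <- 0.3 * x + rnorm(n, sd = 0.4)
    r_obs <- cor(x, y)
    p_t <- cor.test(x, y)$p.value
    perm <- replicate(1000, abs(cor(x, sample(y))))
    p_perm <- (sum(perm >= abs(r_obs)) + 1) / 1001
    mc_err <- 3 * sqrt(p_t * (1 - p_t) / 1000) + 2 / 1000
    expect_lt(abs(p_t - p_perm), mc_err + 0.02)
  }
})

test_that("the full cline report reproduces the published correlations", {
  rep <- cline_report(load_goat_tables()$table)
  get_r <- function(lbl, st) rep$r[rep$subset_label == lbl & rep$statistic == st]
  expect_equal(get_r("europe_all", "ho"), -0.47, tolerance = 0.01)
  expect_equal(get_r("africa_no_islands", "fst"), 0.62, tolerance = 0.01)
  expect_equal(get_r("asia_all", "ho"), -0.32, tolerance = 0.01)
  # f_roh has no published per-breed values packaged, so no f_roh rows
  expect_false("f_roh" %in% rep$statistic)
})
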