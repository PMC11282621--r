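#' Serial-founder dispersal configuration
#'
#' Parameters of the synthetic dispersal model: populations are founded in
#' sequence along a geographic route away from an origin, each founding
#' event resampling 2 * `bottleneck_size` allele copies from its source, so
#' heterozygosity erodes by a factor `(1 - 1/(2 Nb))` per step while
#' distance to the origin grows -- the statistical structure a
#' post-domestication dispersal is expected to leave in breed data.
#'
#' Defaults emulate a continental transect: 12 populations spaced 500 km
#' along an eastward route, 0..11 founder steps, bottlenecks of 25 diploids,
#' 30 sampled individuals and 2000 unlinked loci per population, origin
#' allele frequencies Uniform(0.05, 0.95) (array-like common variants), and
#' 1% missing calls.
#'
#' @param origin an [origin_point()]; default Ganj Dareh.
#' @param n_populations number of populations.
#' @param founder_steps integer vector (one per population, non-decreasing
#'   along the route) of successive founding events behind each population.
#' @param bottleneck_size diploid size Nb of each founding bottleneck.
#' @param sample_n individuals sampled (genotyped) per population.
#' @param n_loci number of biallelic loci.
#' @param origin_freq `c(low, high)` of the uniform law for origin allele
#'   frequencies.
#' @param missing_rate independent probability that a call is missing.
#' @param step_km route spacing between consecutive populations, km.
#' @param bearing initial route bearing, degrees clockwise from north.
#' @param route optional matrix/data frame of (lon, lat) waypoints, one per
#'   population, overriding the auto-generated route.
#' @param migration_rate fraction of each population's allele frequencies
#'   replaced by its upstream neighbour's after drift (0 = pure serial
#'   founder model; positive values blur the cline, mimicking post-dispersal
#'   gene flow).
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return A list of class `dispersal_config`.
#' @export
dispersal_config <- function(origin = ganj_dareh(), n_populations = 12,
                             founder_steps = seq_len(n_populations) - 1L,
                             bottleneck_size = 25, sample_n = 30,
                             n_loci = 2000, origin_freq = c(0.05, 0.95),
                             missing_rate = 0.01, step_km = 500,
                             bearing = 90, route = NULL,
                             migration_rate = 0, seed = 1L) {
  stopifnot(bottleneck_size >= 1, missing_rate >= 0, missing_rate < 1,
            length(founder_steps) == n_populations,
            all(founder_steps >= 0), !is.unsorted(founder_steps),
            sample_n >= 1, n_loci >= 1,
            migration_rate >= 0, migration_rate <= 1)
  if (!(length(origin_freq) == 2 && origin_freq[1] >= 0 &&
        origin_freq[2] <= 1 && origin_freq[1] <= origin_freq[2]))
    stop("invalid origin frequency law: need 0 <= low <= high <= 1")
  if (!is.null(route)) {
    route <- as.matrix(route)
    stopifnot(nrow(route) == n_populations, ncol(route) == 2)
  }
  structure(list(origin = origin, n_populations = as.integer(n_populations),
                 founder_steps = as.integer(founder_steps),
                 bottleneck_size = as.integer(bottleneck_size),
                 sample_n = as.integer(sample_n), n_loci = as.integer(n_loci),
                 origin_freq = origin_freq, missing_rate = missing_rate,
                 step_km = step_km, bearing = bearing, route = route,
                 migration_rate = migration_rate, seed = as.integer(seed)),
            class = "dispersal_config")
}

#' Simulate genotypes along a dispersal route
#'
#' Origin allele frequencies are drawn i.i.d. from the configured uniform
#' law; population k's frequencies are obtained by `founder_steps[k]`
#' successive binomial resamplings of `2 * bottleneck_size` allele copies
#' (pure drift); individuals are then drawn as Binomial(2, p) per locus
#' (Hardy-Weinberg proportions within each population) and calls are masked
#' missing independently. Populations are placed along the route so that
#' geodesic distance to the origin increases with route position.
#'
#' @param config a [dispersal_config()].
#' @return A list with `genotypes` (a [genotypes] object), `breeds` (breed
#'   table with coordinates) and `freqs` (loci x populations matrix of true
#'   post-drift allele frequencies).
#' @export
simulate_dispersal <- function(config) {
  stopifnot(inherits(config, "dispersal_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_pop <- config$n_populations
  n_loci <- config$n_loci
  two_nb <- 2L * config$bottleneck_size
  p0 <- stats::runif(n_loci, config$origin_freq[1], config$origin_freq[2])

  freqs <- matrix(NA_real_, n_loci, n_pop)
  prev <- p0
  prev_steps <- 0L
  for (k in seq_len(n_pop)) {
    p <- prev
    for (s in seq_len(config$founder_steps[k] - prev_steps))
      p <- stats::rbinom(n_loci, two_nb, p) / two_nb
    if (config$migration_rate > 0 && k > 1)
      p <- (1 - config$migration_rate) * p +
        config$migration_rate * freqs[, k - 1]
    freqs[, k] <- p
    prev <- p
    prev_steps <- config$founder_steps[k]
  }

  pop_id <- sprintf("POP%02d", seq_len(n_pop))
  calls <- matrix(NA_integer_, n_pop * config$sample_n, n_loci)
  for (k in seq_len(n_pop)) {
    rows <- (k - 1L) * config$sample_n + seq_len(config$sample_n)
    g <- stats::rbinom(config$sample_n * n_loci, 2L,
                       rep(freqs[, k], each = config$sample_n))
    calls[rows, ] <- matrix(g, config$sample_n, n_loci)
  }
  if (config$missing_rate > 0)
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_

  if (is.null(config$route)) {
    xy <- geosphere::destPoint(c(config$origin$lon, config$origin$lat),
                               config$bearing,
                               (seq_len(n_pop) - 1L) * config$step_km * 1000)
  } else xy <- config$route
  breeds <- data.frame(
    breed_id = pop_id,
    breed_name = paste("Synthetic population", seq_len(n_pop)),
    country = "synthetic", subregion = "route",
    lon = xy[, 1], lat = xy[, 2], n = config$sample_n,
    founder_steps = config$founder_steps, stringsAsFactors = FALSE)

  ind <- data.frame(
    individual_id = sprintf("%s_I%03d", rep(pop_id, each = config$sample_n),
                            rep(seq_len(config$sample_n), n_pop)),
    breed_id = rep(pop_id, each = config$sample_n), stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = sprintf("L%05d", seq_len(n_loci)),
                     chrom = "1", pos = seq_len(n_loci),
                     allele_a = "A", allele_b = "B", mapped = TRUE,
                     stringsAsFactors = FALSE)
  list(genotypes = genotypes(calls, ind, snps), breeds = breeds,
       freqs = freqs)
}

#' Expected heterozygosity after serial founder events
#'
#' Closed form for the pure-drift model: heterozygosity at the population
#' frequency level decays by `(1 - 1/(2 Nb))` per founding event, so
#' \deqn{E[He] = E[2 p_0 (1 - p_0)] \left(1 - \frac{1}{2 N_b}\right)^{steps}}
#' with the origin expectation taken under the uniform law
#' (for Uniform(a, b): \eqn{E[2p(1-p)] = 2(E[p] - E[p^2])},
#' \eqn{E[p] = (a+b)/2}, \eqn{E[p^2] = (a^2+ab+b^2)/3}).
#'
#' @param origin_freq `c(low, high)` of the uniform origin frequency law.
#' @param bottleneck_size diploid bottleneck size Nb.
#' @param steps number of founder steps (vectorized).
#' @return Expected heterozygosity, same length as `steps`.
#' @export
expected_he_decay <- function(origin_freq, bottleneck_size, steps) {
  stopifnot(bottleneck_size >= 1, all(steps >= 0))
  a <- origin_freq[1]; b <- origin_freq[2]
  e_p <- (a + b) / 2
  e_p2 <- (a^2 + a * b + b^2) / 3
  2 * (e_p - e_p2) * (1 - 1 / (2 * bottleneck_size))^steps
}

#' Run the full cline pipeline on one simulated dispersal
#'
#' Simulates a dispersal, applies the QC filters, computes per-population
#' diversity, measures geodesic distance of each population to the origin
#' and correlates He (and Ho) with distance -- the end-to-end analysis that
#' should recover a strong negative diversity cline under the pure
#' serial-founder model.
#'
#' @param config a [dispersal_config()].
#' @param qc a [qc_config()]; pass `NULL` to skip filtering.
#' @return A list with the cline results (`he_cline`, `ho_cline`), the
#'   per-population `diversity` table and the QC `report`.
#' @export
run_dispersal_pipeline <- function(config, qc = qc_config()) {
  sim <- simulate_dispersal(config)
  report <- NULL
  g <- sim$genotypes
  if (!is.null(qc)) {
    fl <- filter_variants(g, qc)
    g <- fl$genotypes
    report <- fl$report
  }
  div <- diversity_by_breed(g, reference = NULL)
  tab <- merge(sim$breeds, div, by = "breed_id")
  tab <- distances_to_origin(tab, config$origin)
  list(he_cline = pearson_cline(tab, "he", subset_label = "simulated"),
       ho_cline = pearson_cline(tab, "ho", subset_label = "simulated"),
       diversity = tab[order(tab$founder_steps), ], report = report)
}
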