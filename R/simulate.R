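#' Configuration for the synthetic metacommunity generator
#'
#' Defaults emulate the study design the pipeline is meant for: ~22 coastal
#' samples in 3 bay clusters strung along a ~5-degree latitude arc, a
#' long-tailed lognormal regional OTU pool in the tens of thousands of taxa,
#' sequencing depth just under 29,000 reads per sample, and environmental
#' gradients partially confounded with space. `w_env` and `w_space` dial the
#' strength of niche (environmental filtering) versus dispersal limitation.
#'
#' @param n_otus regional pool size.
#' @param n_samples number of samples.
#' @param n_clusters number of geographic clusters (bays).
#' @param depth reads per sample.
#' @param w_env,w_space non-negative weights of the niche and dispersal
#'   terms; both zero means pure multinomial sampling from the pool.
#' @param niche_breadth Gaussian niche breadth on the standardized
#'   environmental axis.
#' @param dispersal_range e-folding distance (km) of the dispersal kernel.
#' @param lognormal_mu,lognormal_sigma log-scale parameters of the regional
#'   pool abundance distribution.
#' @param env_spatial_confounding in `[0, 1]`; how strongly the latent
#'   environmental axis tracks the spatial position.
#' @param seed integer seed.
#' @export
simulation_config <- function(n_otus = 20000L, n_samples = 22L,
                              n_clusters = 3L, depth = 28923L,
                              w_env = 1, w_space = 1, niche_breadth = 1,
                              dispersal_range = 250,
                              lognormal_mu = 0, lognormal_sigma = 2.5,
                              env_spatial_confounding = 0.4, seed = 1L) {
  cfg <- list(n_otus = as.integer(n_otus), n_samples = as.integer(n_samples),
              n_clusters = as.integer(n_clusters), depth = as.integer(depth),
              w_env = w_env, w_space = w_space, niche_breadth = niche_breadth,
              dispersal_range = dispersal_range, lognormal_mu = lognormal_mu,
              lognormal_sigma = lognormal_sigma,
              env_spatial_confounding = env_spatial_confounding,
              seed = as.integer(seed))
  if (cfg$depth < 100L) abort("depth must be >= 100")
  if (cfg$n_clusters > cfg$n_samples) abort("n_clusters must not exceed n_samples")
  if (cfg$w_env < 0 || cfg$w_space < 0) abort("weights must be non-negative")
  if (cfg$env_spatial_confounding < 0 || cfg$env_spatial_confounding > 1) {
    abort("env_spatial_confounding must lie in [0, 1]")
  }
  if (cfg$niche_breadth <= 0 || cfg$dispersal_range <= 0) {
    abort("niche_breadth and dispersal_range must be positive")
  }
  structure(cfg, class = "rs_sim_config")
}

#' Simulate a metacommunity with niche and dispersal structure
#'
#' Stations sit in `n_clusters` groups along a 1D coastline arc (latitude
#' roughly 20-25 N, longitude 109-119 E). A latent environmental axis is a
#' mix of the spatial position (weight `env_spatial_confounding`) and an
#' independent gradient; the observed physico-chemical variables load on that
#' axis with noise, in realistic units. Each OTU draws a niche optimum on the
#' axis and a dispersal source on the arc; its expected share in a sample is
#'
#' `pool_i * exp(w_env * -(E_s - opt_i)^2 / (2 b^2)) *
#'  exp(w_space * -d_km(s, src_i) / range)`
#'
#' normalized per sample, and counts are a multinomial draw at `depth`. The
#' returned `truth` record holds every latent driver, enough to recompute the
#' expected compositions exactly.
#'
#' @param cfg a [simulation_config()].
#' @return list: `counts` (OTU x sample matrix), `metadata` (tibble),
#'   `truth` (list of latent drivers incl. `expected` compositions).
#' @export
simulate_metacommunity <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "rs_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    # cluster assignment, as even as possible, cluster-ordered along the arc
    cl <- sort(rep_len(seq_len(cfg$n_clusters), n))
    centre <- (cl - 0.5) / cfg$n_clusters
    s <- pmin(1, pmax(0, centre + runif(n, -0.04, 0.04)))  # arc position in [0,1]
    lat <- 20 + 5 * s
    lon <- 109 + 10 * s
    layer <- rep_len(c("surface", "bottom"), n)
    # latent environmental axis, partially confounded with space
    a <- cfg$env_spatial_confounding
    g0 <- rnorm(n)
    e_axis <- a * as.numeric(scale(s)) + (1 - a) * g0
    e_axis <- as.numeric(scale(e_axis))
    loading <- c(temperature = 0.9, salinity = 0.8, pH = 0.3, DO = 0.6,
                 TN = 0.7, SRP = 0.5)
    z <- vapply(loading, function(l) l * e_axis + sqrt(1 - l^2) * rnorm(n),
                numeric(n))
    meta <- tibble(
      sample_id = sprintf("S%02d", seq_len(n)),
      station = sprintf("St%02d", seq_len(n)),
      bay = paste0("Bay", cl),
      layer = layer,
      latitude = lat,
      longitude = lon,
      temperature = 22 + 3 * z[, "temperature"],
      salinity = 31 + 1.5 * z[, "salinity"],
      pH = 8.05 + 0.15 * z[, "pH"],
      DO = pmax(0.5, 7 + 1.2 * z[, "DO"]),
      TN = 0.8 * exp(0.4 * z[, "TN"]),
      SRP = 0.05 * exp(0.5 * z[, "SRP"])
    )
    # regional pool and per-OTU niche/dispersal traits
    pool <- rlnorm(cfg$n_otus, cfg$lognormal_mu, cfg$lognormal_sigma)
    pool <- pool / sum(pool)
    opt <- rnorm(cfg$n_otus, 0, 1.5)
    src <- runif(cfg$n_otus)
    arc_km <- haversine_km(20 + 5 * src, 109 + 10 * src, lat, lon)  # otus x samples
    log_lambda <- matrix(log(pool), cfg$n_otus, n)
    if (cfg$w_env > 0) {
      log_lambda <- log_lambda +
        cfg$w_env * (-outer(opt, e_axis, "-")^2 / (2 * cfg$niche_breadth^2))
    }
    if (cfg$w_space > 0) {
      log_lambda <- log_lambda + cfg$w_space * (-arc_km / cfg$dispersal_range)
    }
    expected <- apply(log_lambda, 2L, function(v) {
      v <- exp(v - max(v)); v / sum(v)
    })
    counts <- vapply(seq_len(n), function(j) {
      as.integer(rmultinom(1L, cfg$depth, expected[, j]))
    }, integer(cfg$n_otus))
    dimnames(counts) <- list(sprintf("OTU%05d", seq_len(cfg$n_otus)),
                             meta$sample_id)
    dimnames(expected) <- dimnames(counts)
    list(counts = counts, metadata = meta,
         truth = list(config = cfg, arc_position = s, env_axis = e_axis,
                      pool = pool, optimum = opt, source = src,
                      expected = expected))
  })
}

# Vectorized haversine between per-OTU source points and per-sample stations.
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  dphi <- outer(phi1, phi2, function(a, b) b - a)
  dlam <- outer(lon1 * rad, lon2 * rad, function(a, b) b - a)
  h <- sin(dphi / 2)^2 + outer(cos(phi1), cos(phi2)) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
}

#' Simulate neutral local communities from a regional pool
#'
#' Draws each local community's composition from a Dirichlet(`Nm x pool`)
#' distribution — the stationary local law whose per-taxon marginals are the
#' Beta distributions of Sloan's model — then samples `depth` reads
#' multinomially. This is the parameter-recovery oracle for [fit_ncm()].
#'
#' @param pool regional relative-abundance vector (sums to 1).
#' @param Nm metacommunity size times immigration rate.
#' @param n_samples,depth sampling design.
#' @param seed integer seed.
#' @return OTU x sample count matrix.
#' @export
simulate_neutral_assembly <- function(pool, Nm, n_samples = 50L,
                                      depth = 10000L, seed = 1L) {
  if (length(pool) < 2L) abort("degenerate pool: need at least 2 taxa")
  if (abs(sum(pool) - 1) > 1e-8) abort("pool must sum to 1")
  if (Nm <= 0) abort("Nm must be positive")
  with_seed(seed, {
    counts <- vapply(seq_len(n_samples), function(j) {
      g <- rgamma(length(pool), shape = Nm * pool, rate = 1)
      if (sum(g) == 0) g[which.max(pool)] <- 1
      as.integer(rmultinom(1L, depth, g / sum(g)))
    }, integer(length(pool)))
    dimnames(counts) <- list(
      names(pool) %||% sprintf("OTU%05d", seq_along(pool)),
      sprintf("S%03d", seq_len(n_samples))
    )
    counts
  })
}
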