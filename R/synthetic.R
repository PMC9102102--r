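#' Configuration for a synthetic EcoPlate experiment
#'
#' Builds the parameter set of the seeded generator. Defaults emulate a
#' five-treatment, four-replicate long-term grassland fertilization design:
#' per-substrate control means are drawn uniformly from 0.3-2.5 OD (so
#' control totals land near 40-50 OD, the magnitude of field EcoPlate
#' profiles at plateau), replicate noise is 10% of the substrate mean, and
#' guild-level multipliers give an organic treatment (`V2`) an inflated
#' community (about +18% total activity), a mineral treatment (`V4`) a
#' deflated one (about -10%), and organo-mineral treatments (`V3`, `V5`)
#' intermediate responses.
#'
#' @param treatments Character vector of treatment labels; the first is the
#'   control.
#' @param n_replicates Replicates per treatment (default 4).
#' @param mu Named per-substrate control means (default: drawn from
#'   `mu_range` using `seed`).
#' @param mu_range Range control means are drawn from when `mu` is absent.
#' @param sigma Named per-substrate replicate noise sd (default
#'   `noise_cv * mu`).
#' @param noise_cv Coefficient of variation of replicate noise.
#' @param kappa Treatments x guilds matrix of positive effect multipliers
#'   (rownames = treatments, colnames = guilds). The control row must be 1.
#' @param seed Integer seed; all randomness derives from it.
#' @param cat Substrate catalog.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(treatments = c("V1", "V2", "V3", "V4", "V5"),
                              n_replicates = 4,
                              mu = NULL, mu_range = c(0.3, 2.5),
                              sigma = NULL, noise_cv = 0.1,
                              kappa = NULL, seed = 1,
                              cat = ecoplate_catalog()) {
  codes <- substrate_codes(cat)
  if (is.null(mu)) {
    mu <- stats::setNames(
      local({
        set.seed(seed)
        stats::runif(length(codes), mu_range[1], mu_range[2])
      }), codes)
  }
  if (is.null(names(mu))) names(mu) <- codes
  if (any(mu <= 0)) stop("all control means mu must be positive")
  if (is.null(sigma)) sigma <- noise_cv * mu
  if (is.null(names(sigma))) names(sigma) <- names(mu)
  if (any(sigma < 0)) stop("noise sd must be non-negative")
  if (is.null(kappa)) kappa <- default_kappa(treatments)
  if (!is.matrix(kappa) || is.null(rownames(kappa)) || is.null(colnames(kappa))) {
    stop("kappa must be a treatments x guilds matrix with dimnames")
  }
  if (!all(treatments %in% rownames(kappa)) ||
      !all(guild_labels() %in% colnames(kappa))) {
    stop("kappa must cover every treatment and every guild")
  }
  if (any(kappa <= 0)) stop("all kappa multipliers must be positive")
  structure(list(treatments = treatments, control = treatments[1],
                 n_replicates = n_replicates, mu = mu, sigma = sigma,
                 kappa = kappa[treatments, guild_labels(), drop = FALSE],
                 seed = seed, catalog = cat),
            class = "simulation_config")
}

# Default guild multipliers: directions and magnitudes of a long-term
# fertilization gradient (organic inflation, mineral deflation).
default_kappa <- function(treatments) {
  base <- rbind(
    V1 = c(AA = 1.00, AM = 1.00, CH = 1.00, CX = 1.00, P = 1.00),
    V2 = c(AA = 1.08, AM = 1.00, CH = 1.30, CX = 1.12, P = 1.35),
    V3 = c(AA = 1.12, AM = 1.00, CH = 1.05, CX = 1.12, P = 1.05),
    V4 = c(AA = 1.00, AM = 0.80, CH = 0.85, CX = 0.95, P = 0.85),
    V5 = c(AA = 1.00, AM = 0.95, CH = 0.95, CX = 0.97, P = 0.95)
  )
  if (all(treatments %in% rownames(base))) {
    return(base[treatments, , drop = FALSE])
  }
  k <- matrix(1, length(treatments), 5,
              dimnames = list(treatments, guild_labels()))
  k
}

#' Generate a synthetic EcoPlate experiment
#'
#' Draws blank-corrected substrate profiles with known ground truth. The
#' control replicate response for substrate `s` is `max(0, N(mu_s,
#' sigma_s))`; under treatment `t` the mean is multiplied by the guild-level
#' effect `kappa[t, g(s)]`. Output is byte-identical for a given config.
#'
#' @param config A [simulation_config()].
#' @return List with `profiles` (profile matrix, one row per sample),
#'   `design` (sample_id, treatment, replicate) and `truth` (per treatment
#'   x guild: `kappa`, `direction` inflated/deflated/neutral, and the
#'   expected top-expansion guild per treatment where one exists).
#' @export
generate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  codes <- names(config$mu)
  guilds <- guild_of(codes, config$catalog)
  set.seed(config$seed)
  rows <- list()
  design <- list()
  for (t in config$treatments) {
    mult <- config$kappa[t, guilds]
    for (r in seq_len(config$n_replicates)) {
      x <- pmax(0, stats::rnorm(length(codes),
                                mean = mult * config$mu,
                                sd = config$sigma))
      id <- paste0(t, "_r", r)
      rows[[id]] <- stats::setNames(x, codes)
      design[[id]] <- data.frame(sample_id = id, treatment = t, replicate = r)
    }
  }
  profiles <- do.call(rbind, rows)
  design <- do.call(rbind, c(design, list(make.row.names = FALSE)))
  direction <- config$kappa
  direction[] <- ifelse(config$kappa > 1, "inflated",
                        ifelse(config$kappa < 1, "deflated", "neutral"))
  top_expansion <- apply(config$kappa, 1, function(k) {
    if (max(k) > 1) names(k)[which.max(k)] else NA_character_
  })
  list(profiles = profiles, design = design,
       truth = list(kappa = config$kappa, direction = direction,
                    top_expansion_guild = top_expansion))
}

#' Write a synthetic experiment as package-canonical CSV fixtures
#'
#' Emits the long-format profile CSV and the design CSV that
#' [read_profiles()] and [read_design()] consume; the round trip is
#' lossless to storage precision.
#'
#' @param experiment A [generate_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_fixture <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  profile_path <- file.path(dir, "profiles.csv")
  design_path <- file.path(dir, "design.csv")
  write_profiles(experiment$profiles, profile_path)
  utils::write.csv(experiment$design, design_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(profiles = profile_path, design = design_path))
}
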