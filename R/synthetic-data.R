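#' Configuration for the plate simulator
#'
#' The default incubation emulates the EcoPlate protocol: absorbance read
#' every 24 h for 100 days of continuous cultivation (times 0, 24, ..., 2400
#' h). Colour development per substrate is logistic with per-substrate
#' asymptote \code{K}, rate \code{r} (per hour) and midpoint \code{t0}
#' (hours); the 750 nm channel carries turbidity only; control wells carry
#' the shared baseline drift only.
#'
#' @param times reading times in hours.
#' @param K,r,t0 per-substrate kinetic parameters: single values are recycled,
#'   \code{NULL} draws them once from the seed (K in U(0.6, 1.8), r in
#'   U(0.005, 0.02)/h, t0 in U(240, 960) h, i.e. midpoints between day 10 and
#'   day 40).
#' @param turbidityMean,turbiditySd 750 nm turbidity level.
#' @param odNoiseSd additive read noise per well and timepoint.
#' @param controlDrift amplitude of the slow shared baseline (OD at the final
#'   timepoint).
#' @param seed RNG seed; a fixed seed makes the output bit-identical.
#' @return a \code{PlateSimConfig} list.
#' @export
plateSimConfig <- function(times = seq(0, 2400, by = 24), K = NULL, r = NULL,
                           t0 = NULL, turbidityMean = 0.05,
                           turbiditySd = 0.01, odNoiseSd = 0.01,
                           controlDrift = 0.02, seed = 1L) {
  stopifnot(all(times >= 0), !is.unsorted(times, strictly = TRUE),
            turbiditySd >= 0, odNoiseSd >= 0, turbidityMean >= 0)
  if (!is.null(K) && any(K < 0)) stop("K must be >= 0")
  if (!is.null(r) && any(r <= 0)) stop("r must be > 0")
  structure(list(times = times, K = K, r = r, t0 = t0,
                 turbidityMean = turbidityMean, turbiditySd = turbiditySd,
                 odNoiseSd = odNoiseSd, controlDrift = controlDrift,
                 seed = as.integer(seed)),
            class = "PlateSimConfig")
}

.logistic <- function(t, K, r, t0) K / (1 + exp(-r * (t - t0)))

#' Simulate dual-wavelength EcoPlate readings
#'
#' Each substrate well's 590 nm signal is a logistic colour-development curve
#' (asymptote scaled by the sample's affinity for that substrate) plus
#' turbidity, a shared baseline drift, and read noise; its 750 nm signal is
#' the turbidity plus noise; control wells carry the baseline only. The
#' output satisfies every loader invariant and, noise-free, the corrected
#' series recovers the logistic curves exactly.
#'
#' @param config a [plateSimConfig()].
#' @param sampleProfile named substrate-affinity vector in [0, 1] (missing
#'   substrates get 0); \code{NULL} draws affinities U(0.2, 1) from the seed.
#' @param layout a \linkS4class{PlateLayout} (bundled map by default).
#' @param plateId,sampleId identifiers for the generated readings.
#' @return list with \code{layout}, \code{readings} (list of
#'   \linkS4class{RawReading}), and \code{params} (the kinetic parameters
#'   actually used).
#' @export
simulatePlate <- function(config, sampleProfile = NULL,
                          layout = ecoPlateLayout(), plateId = "P1",
                          sampleId = "S1") {
  stopifnot(inherits(config, "PlateSimConfig"))
  set.seed(config$seed)
  subs <- substrates(layout)
  nS <- length(subs)
  K <- if (is.null(config$K)) stats::runif(nS, 0.6, 1.8) else
    rep_len(config$K, nS)
  r <- if (is.null(config$r)) stats::runif(nS, 0.005, 0.02) else
    rep_len(config$r, nS)
  t0 <- if (is.null(config$t0)) stats::runif(nS, 240, 960) else
    rep_len(config$t0, nS)
  names(K) <- names(r) <- names(t0) <- subs
  if (is.null(sampleProfile)) {
    sampleProfile <- stats::setNames(stats::runif(nS, 0.2, 1), subs)
  } else {
    aff <- stats::setNames(numeric(nS), subs)
    aff[intersect(names(sampleProfile), subs)] <-
      sampleProfile[intersect(names(sampleProfile), subs)]
    sampleProfile <- aff
  }

  w <- wells(layout)
  times <- config$times
  baseline <- config$controlDrift * times / max(times[length(times)], 1)
  readings <- vector("list", 2L * length(times))
  k <- 0L
  for (j in seq_along(times)) {
    tm <- times[j]
    is_ctrl <- w$substrate == "CONTROL"
    colour <- numeric(nrow(w))
    colour[!is_ctrl] <- .logistic(tm, K[w$substrate[!is_ctrl]] *
                                    sampleProfile[w$substrate[!is_ctrl]],
                                  r[w$substrate[!is_ctrl]],
                                  t0[w$substrate[!is_ctrl]])
    turb <- numeric(nrow(w))
    turb[!is_ctrl] <- stats::rnorm(sum(!is_ctrl), config$turbidityMean,
                                   config$turbiditySd)
    od590 <- colour + turb + baseline[j] +
      stats::rnorm(nrow(w), 0, config$odNoiseSd)
    od750 <- turb + stats::rnorm(nrow(w), 0, config$odNoiseSd)
    k <- k + 1L
    readings[[k]] <- methods::new("RawReading", plateId = plateId,
                                  sampleId = sampleId, timeH = tm,
                                  wavelength = 590,
                                  od = stats::setNames(od590, w$well))
    k <- k + 1L
    readings[[k]] <- methods::new("RawReading", plateId = plateId,
                                  sampleId = sampleId, timeH = tm,
                                  wavelength = 750,
                                  od = stats::setNames(od750, w$well))
  }
  list(layout = layout, readings = readings,
       params = data.frame(substrate = subs, K = unname(K), r = unname(r),
                           t0 = unname(t0),
                           affinity = unname(sampleProfile[subs])))
}

#' Write simulated readings in the loader's CSV dialect
#'
#' @param readings a list of \linkS4class{RawReading}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writePlateReadings <- function(readings, path) {
  df <- do.call(rbind, lapply(readings, function(rr)
    data.frame(plate = rr@plateId, sample = rr@sampleId, time_h = rr@timeH,
               wavelength = rr@wavelength, well = names(rr@od),
               od = unname(rr@od))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Configuration for the community simulator
#'
#' Plants \code{nGuilds} correlated guilds: guild members share a latent
#' Gaussian factor with loading \code{sqrt(withinGuildRho)}, so the latent
#' correlation between any two guild-mates is exactly \code{withinGuildRho};
#' abundances are log-normal around that latent value and counts are Poisson
#' draws (rank statistics downstream see approximately the planted
#' correlation). Guilds may additionally track the depth gradient through
#' \code{depthEffect} (0 by default, keeping the planted structure the only
#' source of correlation).
#'
#' @param nSamples number of samples (split between water-column depths
#'   0/200/800/2000/5000 m and benthic-boundary-layer stations).
#' @param nAsvs number of ASVs (at least \code{nGuilds}).
#' @param nGuilds number of planted guilds.
#' @param withinGuildRho latent within-guild correlation in [0, 1).
#' @param abundLogMean,abundLogSd log-normal abundance parameters.
#' @param depthEffect strength of each guild's depth preference (log scale).
#' @param archaeaFraction fraction of ASVs assigned to Archaea.
#' @param seed RNG seed.
#' @return a \code{CommunitySimConfig} list.
#' @export
communitySimConfig <- function(nSamples = 20L, nAsvs = 80L, nGuilds = 4L,
                               withinGuildRho = 0.95, abundLogMean = 5,
                               abundLogSd = 1, depthEffect = 0,
                               archaeaFraction = 0.3, seed = 1L) {
  stopifnot(nGuilds >= 1L, withinGuildRho >= 0, withinGuildRho < 1,
            nSamples >= 4L, nGuilds < nSamples,
            archaeaFraction >= 0, archaeaFraction <= 1)
  if (nAsvs < nGuilds) stop("nAsvs must be >= nGuilds")
  structure(list(nSamples = as.integer(nSamples), nAsvs = as.integer(nAsvs),
                 nGuilds = as.integer(nGuilds),
                 withinGuildRho = withinGuildRho,
                 abundLogMean = abundLogMean, abundLogSd = abundLogSd,
                 depthEffect = depthEffect,
                 archaeaFraction = archaeaFraction, seed = as.integer(seed)),
            class = "CommunitySimConfig")
}

.ARCH_TAXA <- data.frame(
  phylum = c("Crenarchaeota", "Thermoplasmatota", "Halobacterota"),
  class = c("Nitrososphaeria", "Thermoplasmata", "Halobacteria"))
.BACT_TAXA <- data.frame(
  phylum = c("Proteobacteria", "Proteobacteria", "Actinobacteriota",
             "Bacteroidota", "Cyanobacteria"),
  class = c("Alphaproteobacteria", "Gammaproteobacteria", "Actinobacteria",
            "Bacteroidia", "Cyanobacteriia"))

#' Simulate an ASV table with planted correlated guilds
#'
#' @param config a [communitySimConfig()].
#' @return an \linkS4class{AsvExperiment} whose \code{rowData} carries the
#'   taxonomy plus the planted \code{guild} label and whose \code{colData}
#'   carries the sample metadata (trench, layer, depth and the depth-shaped
#'   environmental profile).
#' @export
simulateAsvTable <- function(config) {
  stopifnot(inherits(config, "CommunitySimConfig"))
  set.seed(config$seed)
  nS <- config$nSamples; nA <- config$nAsvs; nG <- config$nGuilds
  rho <- config$withinGuildRho

  # samples: half water-column (cycled canonical depths), half BBL stations
  n_wc <- ceiling(nS / 2)
  wc_depths <- rep_len(c(0, 200, 800, 2000, 5000), n_wc)
  n_bbl <- nS - n_wc
  bbl_depths <- if (n_bbl) round(seq(2311, 9639, length.out = n_bbl)) else
    numeric(0)
  depth <- c(wc_depths, bbl_depths)
  layer <- c(rep("WC", n_wc), rep("BBL", n_bbl))
  sample_id <- sprintf("S%02d", seq_len(nS))
  meta <- simulateMetadataProfiles(depth)
  meta <- data.frame(sample_id = sample_id,
                     trench = rep_len(c("T1", "T2"), nS),
                     layer = layer, meta)

  guild <- rep_len(seq_len(nG), nA)
  guild <- sort(guild)
  asv_id <- sprintf("ASV%03d", seq_len(nA))

  # latent guild factors, orthogonalised across samples so the planted
  # between-guild correlation is exactly zero (independent draws can
  # correlate by chance at these sample sizes, which would merge guilds)
  f0 <- scale(matrix(stats::rnorm(nS * nG), nS, nG), center = TRUE,
              scale = FALSE)
  f <- t(qr.Q(qr(f0))) * sqrt(nS - 1)   # rows: unit-variance, uncorrelated
  eps <- matrix(stats::rnorm(nA * nS), nA, nS)
  z <- sqrt(rho) * f[guild, , drop = FALSE] + sqrt(1 - rho) * eps

  # optional depth preference per guild (log-depth Gaussian kernel)
  if (config$depthEffect != 0) {
    centers <- rep_len(c(0, 200, 800, 2000, 5000), nG)
    ld <- log10(depth + 10)
    lc <- log10(centers + 10)
    pref <- exp(-outer(lc[guild], ld, "-")^2 / (2 * 0.5^2))
    z <- z + config$depthEffect * pref
  }

  base <- stats::rnorm(nA, config$abundLogMean, 0.5)
  mu <- exp(base + config$abundLogSd * z)
  counts <- matrix(stats::rpois(nA * nS, lambda = mu), nA, nS,
                   dimnames = list(asv_id, sample_id))
  # guard against all-zero samples in extreme configs
  zero <- colSums(counts) == 0
  if (any(zero)) counts[1, zero] <- 1L

  # taxonomy: archaea and bacteria both populate every guild
  domain <- character(nA)
  for (g in seq_len(nG)) {
    ix <- which(guild == g)
    n_arch <- round(config$archaeaFraction * length(ix))
    if (length(ix) >= 2L)    # both domains populate every guild
      n_arch <- min(max(n_arch, 1L), length(ix) - 1L)
    domain[ix] <- c(rep("Archaea", n_arch),
                    rep("Bacteria", length(ix) - n_arch))
  }
  tax_row <- ifelse(domain == "Archaea",
                    sample(nrow(.ARCH_TAXA), nA, replace = TRUE),
                    sample(nrow(.BACT_TAXA), nA, replace = TRUE))
  taxonomy <- data.frame(
    asv = asv_id, domain = domain,
    phylum = ifelse(domain == "Archaea", .ARCH_TAXA$phylum[tax_row],
                    .BACT_TAXA$phylum[tax_row]),
    class = ifelse(domain == "Archaea", .ARCH_TAXA$class[tax_row],
                   .BACT_TAXA$class[tax_row]))

  x <- asvExperiment(counts, taxonomy, meta)
  rowData(x)$guild <- guild
  x
}

#' Depth-shaped environmental metadata
#'
#' Deterministic profiles matching the qualitative hydrography of deep
#' trench water columns: temperature decays from ~19.9 degC at the surface to
#' ~1.1 degC at 5000 m; salinity is lowest at 800 m (the lower boundary of
#' the twilight zone) and rises slightly below it; nitrate+nitrite and
#' phosphate increase with depth; ammonium peaks at the surface.
#'
#' @param depths non-negative depths in metres.
#' @return a data.frame with \code{depth_m}, \code{temperature_C},
#'   \code{salinity}, \code{no3_no2}, \code{nh4}, \code{po4}.
#' @export
simulateMetadataProfiles <- function(depths) {
  if (!length(depths)) stop("empty depth list")
  if (any(depths < 0)) stop("negative depth")
  d <- depths
  temperature <- 1.095 + (19.9 - 1.095) * exp(-d / 570)
  salinity <- ifelse(d <= 800, 35.5 - 1.2 * d / 800,
                     34.3 + 0.4 * (d - 800) / 4200)
  no3_no2 <- 0.5 + 39.5 * (1 - exp(-d / 1500))
  nh4 <- 0.05 + 0.8 * exp(-d / 2000)
  po4 <- 0.1 + 2.9 * (1 - exp(-d / 1200))
  data.frame(depth_m = d, temperature_C = temperature, salinity = salinity,
             no3_no2 = no3_no2, nh4 = nh4, po4 = po4)
}

#' Write an ASV experiment in the loader dialects
#'
#' Writes \code{table.tsv} (samples as rows), \code{taxonomy.tsv} and
#' \code{metadata.csv} under \code{dir}.
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
writeAsvTable <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab_path <- file.path(dir, "table.tsv")
  tax_path <- file.path(dir, "taxonomy.tsv")
  meta_path <- file.path(dir, "metadata.csv")
  m <- t(assay(x, "counts"))
  utils::write.table(data.frame(sample = rownames(m), m, check.names = FALSE),
                     tab_path, sep = "\t", row.names = FALSE, quote = FALSE)
  rd <- rowData(x)
  utils::write.table(data.frame(asv = rownames(x), domain = rd$domain,
                                phylum = rd$phylum, class = rd$class),
                     tax_path, sep = "\t", row.names = FALSE, quote = FALSE)
  cd <- as.data.frame(colData(x))
  utils::write.csv(data.frame(sample_id = colnames(x), cd,
                              row.names = NULL),
                   meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(table = tab_path, taxonomy = tax_path, metadata = meta_path))
}
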