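.defaultPipelineConfig <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    plate = list(simulate = TRUE, n_samples = 3L, step_h = 24, n_days = 100,
                 layout = NULL, readings = NULL, ref_time = "auto",
                 threshold = 0.5),
    community = list(simulate = TRUE, table = NULL, taxonomy = NULL,
                     metadata = NULL, group = "layer", n_perm = 999L,
                     n_samples = 20L, n_asvs = 80L, n_guilds = 4L,
                     within_guild_rho = 0.95),
    network = list(stratum = "layer", top = 200L, r_threshold = 0.6,
                   alpha = 0.05))
}

.mergeConfig <- function(default, user) {
  for (nm in names(user)) {
    if (is.list(default[[nm]]) && is.list(user[[nm]]))
      default[[nm]] <- .mergeConfig(default[[nm]], user[[nm]])
    else default[[nm]] <- user[[nm]]
  }
  default
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- plate simulation or loading,
#' turbidity correction and physiological profiling; community statistics
#' (Bray-Curtis distances and ANOSIM on the configured grouping); and
#' per-stratum co-occurrence networks -- writing every intermediate as plain
#' CSV/TSV plus a JSON manifest that records the config snapshot, the seeds,
#' input-file hashes and output-file hashes, so a re-run from the same
#' manifest reproduces identical outputs.
#'
#' @param config a config list, or a path to a YAML file with the same
#'   structure (see the bundled \code{demo_pipeline.yaml}); unset keys take
#'   defaults.
#' @param outDir output directory (overrides \code{config$out_dir}).
#' @return the manifest, invisibly (also written to
#'   \code{<outDir>/manifest.json}).
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.defaultPipelineConfig(), config)
  if (!is.null(outDir)) cfg$out_dir <- outDir
  if (is.null(cfg$out_dir)) stop("an output directory is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  seed <- as.integer(cfg$seed)
  manifest <- list(package = "hadalCLPP",
                   version = as.character(utils::packageVersion("hadalCLPP")),
                   config = cfg, seeds = list(), inputs = list(),
                   outputs = list())

  ## ---- plate stage -------------------------------------------------------
  if (isTRUE(cfg$plate$simulate)) {
    layout <- ecoPlateLayout()
    times <- seq(0, cfg$plate$n_days * 24, by = cfg$plate$step_h)
    series <- lapply(seq_len(cfg$plate$n_samples), function(s) {
      pseed <- seed * 1000L + s
      sim <- simulatePlate(plateSimConfig(times = times, seed = pseed),
                           plateId = sprintf("P%d", s),
                           sampleId = sprintf("S%02d", s))
      path <- out(sprintf("readings_S%02d.csv", s))
      writePlateReadings(sim$readings, path)
      manifest$seeds[[sprintf("plate_S%02d", s)]] <<- pseed
      correctPlateSeries(loadPlateReadings(path, layout), layout)
    })
  } else {
    if (!file.exists(cfg$plate$layout))
      stop("plate stage: layout file not found: ", cfg$plate$layout)
    if (!file.exists(cfg$plate$readings))
      stop("plate stage: readings file not found: ", cfg$plate$readings)
    layout <- loadPlateLayout(cfg$plate$layout)
    manifest$inputs$layout <- unname(tools::md5sum(cfg$plate$layout))
    manifest$inputs$readings <- unname(tools::md5sum(cfg$plate$readings))
    readings <- loadPlateReadings(cfg$plate$readings, layout)
    by_plate <- split(readings, vapply(readings, function(r) r@plateId, ""))
    series <- lapply(by_plate, correctPlateSeries, layout = layout)
  }
  profiles <- lapply(series, clppProfile, refTime = cfg$plate$ref_time,
                     threshold = cfg$plate$threshold)
  prof_df <- do.call(rbind, lapply(profiles, function(p) {
    cu <- p@awcdByCategory
    ref_cu <- cu[cu$time_h == p@refTime, ]
    row <- data.frame(sample = p@sampleId, ref_time_h = p@refTime,
                      awcd = p@awcdSeries$awcd[match(p@refTime,
                                                     p@awcdSeries$time_h)],
                      richness = p@richness, simpson = p@simpson,
                      shannon = p@shannon,
                      t_exp_start = p@phase[["t_exp_start"]],
                      t_stable_start = p@phase[["t_stable_start"]])
    for (i in seq_len(nrow(ref_cu)))
      row[[paste0("awcd_", ref_cu$category[i])]] <- ref_cu$awcd[i]
    row
  }))
  utils::write.csv(prof_df, out("profile.csv"), row.names = FALSE)
  awcd_long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(sample = p@sampleId, p@awcdSeries)))
  utils::write.csv(awcd_long, out("awcd_series.csv"), row.names = FALSE)

  ## ---- community stage ---------------------------------------------------
  if (isTRUE(cfg$community$simulate)) {
    cseed <- seed * 1000L + 777L
    manifest$seeds$community <- cseed
    asv <- simulateAsvTable(communitySimConfig(
      nSamples = cfg$community$n_samples, nAsvs = cfg$community$n_asvs,
      nGuilds = cfg$community$n_guilds,
      withinGuildRho = cfg$community$within_guild_rho, seed = cseed))
    writeAsvTable(asv, cfg$out_dir)
  } else {
    for (f in c("table", "taxonomy", "metadata")) {
      if (is.null(cfg$community[[f]]) || !file.exists(cfg$community[[f]]))
        stop("community stage: ", f, " file not found: ",
             if (is.null(cfg$community[[f]])) "(unset)" else
               cfg$community[[f]])
      manifest$inputs[[f]] <- unname(tools::md5sum(cfg$community[[f]]))
    }
    asv <- loadAsvTable(cfg$community$table, cfg$community$taxonomy,
                        cfg$community$metadata)
  }
  d <- brayCurtis(asv)
  dm <- as.matrix(d)
  utils::write.table(data.frame(sample = rownames(dm), dm,
                                check.names = FALSE),
                     out("distances.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  div <- shannonEvenness(asv)
  utils::write.csv(div, out("diversity.csv"), row.names = FALSE)
  groups <- colData(asv)[[cfg$community$group]]
  if (is.null(groups))
    stop("community stage: grouping column not in metadata: ",
         cfg$community$group)
  aseed <- seed * 1000L + 888L
  manifest$seeds$anosim <- aseed
  an <- anosimTest(d, groups, nPerm = cfg$community$n_perm, seed = aseed)
  anosim_df <- data.frame(grouping = cfg$community$group,
                          R = an$statistic, p_value = an$p_value,
                          n_perm = an$n_perm)
  utils::write.csv(anosim_df, out("anosim.csv"), row.names = FALSE)

  ## ---- network stage -----------------------------------------------------
  strata <- sort(unique(colData(asv)[[cfg$network$stratum]]))
  nseed <- seed * 1000L + 999L
  manifest$seeds$louvain <- nseed
  net_rows <- list()
  for (st in strata) {
    sel <- colData(asv)[[cfg$network$stratum]] == st
    if (sum(sel) < 4L) {
      net_rows[[st]] <- data.frame(stratum = st, status = "omitted",
                                   n_nodes = NA, n_edges = NA,
                                   modularity_Q = NA, prop_positive = NA)
      next
    }
    net <- cooccurrenceNetwork(asv[, sel], top = cfg$network$top,
                               rThreshold = cfg$network$r_threshold,
                               alpha = cfg$network$alpha, seed = nseed)
    writeNetwork(net, out(sprintf("edges_%s.tsv", st)),
                 out(sprintf("nodes_%s.tsv", st)))
    ss <- net@signSummary
    ov <- ss$prop_positive[ss$stratum == "overall"]
    net_rows[[st]] <- data.frame(
      stratum = st, status = "ok", n_nodes = igraph::vcount(net@graph),
      n_edges = igraph::ecount(net@graph),
      modularity_Q = modularityQ(net),
      prop_positive = if (length(ov)) ov else NA_real_)
  }
  net_df <- do.call(rbind, net_rows)
  utils::write.csv(net_df, out("network_summary.csv"), row.names = FALSE)

  ## ---- manifest ----------------------------------------------------------
  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest$outputs <- as.list(tools::md5sum(outputs))
  names(manifest$outputs) <- basename(outputs)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Re-run a pipeline from its manifest
#'
#' Replays the recorded config snapshot (all stochastic stages are re-seeded
#' from the recorded seeds), reproducing identical outputs.
#'
#' @param manifestPath path to a \code{manifest.json}.
#' @param outDir where to write the replayed outputs (defaults to the
#'   recorded output directory).
#' @return the new manifest, invisibly.
#' @export
replayPipeline <- function(manifestPath, outDir = NULL) {
  man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  runPipeline(man$config, outDir = outDir)
}

#' Human-readable pipeline summary
#'
#' Formats the layout constants, per-sample physiological indices, the ANOSIM
#' result and the per-stratum network summaries from a completed run. The
#' output depends only on the run's files, so replays of one manifest yield a
#' byte-identical report.
#'
#' @param manifest a manifest list as returned by [runPipeline()], or a path
#'   to \code{manifest.json}.
#' @return the report lines, invisibly; printed to the console.
#' @export
pipelineReport <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- manifest$config$out_dir
  need <- c("profile.csv", "anosim.csv", "network_summary.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("incomplete run, missing: ", paste(miss, collapse = ", "))
  layout <- ecoPlateLayout()
  lines <- c(
    sprintf("hadalCLPP pipeline report (package %s)", manifest$version),
    sprintf("layout: %d substrates in %d carbon categories, %d control wells",
            length(substrates(layout)),
            length(unique(substrateCategories(layout))),
            length(controlWells(layout))),
    "", "Per-sample physiological profile:")
  prof <- utils::read.csv(file.path(dir, "profile.csv"))
  lines <- c(lines, sprintf(
    "  %s: AWCD=%.3f richness=%d D=%.3f H=%.3f stable from %s h",
    prof$sample, prof$awcd, prof$richness, prof$simpson, prof$shannon,
    ifelse(is.na(prof$t_stable_start), "n/a",
           format(prof$t_stable_start))))
  an <- utils::read.csv(file.path(dir, "anosim.csv"))
  lines <- c(lines, "", sprintf(
    "ANOSIM (%s): R=%.3f, p=%.4g (%d permutations)",
    an$grouping, an$R, an$p_value, an$n_perm))
  net <- utils::read.csv(file.path(dir, "network_summary.csv"))
  lines <- c(lines, "", "Co-occurrence networks:")
  for (i in seq_len(nrow(net))) {
    if (net$status[i] != "ok") {
      lines <- c(lines, sprintf("  %s: omitted (too few samples)",
                                net$stratum[i]))
    } else {
      lines <- c(lines, sprintf(
        "  %s: %d nodes, %d edges, Q=%.3f, positive edges %.1f%%",
        net$stratum[i], net$n_nodes[i], net$n_edges[i], net$modularity_Q[i],
        100 * net$prop_positive[i]))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
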