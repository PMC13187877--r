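# End-to-end orchestration: synthetic homolog pair -> minimisation -> normal
# modes -> mode diffusivity -> communication maps per temperature ->
# difference maps -> VED profiles -> harmonic trajectories with RMSD/RMSF ->
# constant-velocity pulls. All outputs are plain TSV/JSON with a manifest.

#' Pipeline configuration
#'
#' Flat, serialisable configuration of the full analysis. Defaults mirror the
#' study conditions: a 128-residue pair with 9 vs 2 C-terminal cross-links,
#' temperatures 300 and 340 K, bands centred at 50..400 cm^-1 with 10 modes
#' each, and the standard pulling protocol (1500 kJ mol^-1 nm^-2,
#' 0.01 nm ps^-1, 2 fs, recorded every 1 ps).
#'
#' @param n_residues,strong_links,weak_links homolog-pair geometry
#' @param temperatures numeric vector of temperatures, K (at least one)
#' @param band_centers,modes_per_band frequency bands, cm^-1
#' @param enm_cutoff elastic-network cutoff, A
#' @param enm_k elastic-network spring constant, kcal mol^-1 A^-2; the
#'   default 100 puts the bead-model spectrum across the configured band
#'   range
#' @param scale_bands place the band centres at their relative spectral
#'   position in each model's own spectrum (see [scale_band_centers()]);
#'   default `TRUE` for bead models
#' @param n_frames frames per harmonic trajectory
#' @param threshold_prob percentile at which colour thresholds are rescaled
#'   to each profile's own scale
#' @param pull named list overriding [pull_protocol()] fields
#' @param outdir output directory
#' @param seed master seed; all stage seeds derive from it
#' @return object of class `PipelineConfig`
#' @export
pipeline_config <- function(n_residues = 128L, strong_links = 9L,
                            weak_links = 2L, temperatures = c(300, 340),
                            band_centers = c(50, 100, 150, 200, 300, 400),
                            modes_per_band = 10L, scale_bands = TRUE,
                            enm_cutoff = 12,
                            enm_k = 1, n_frames = 300L,
                            threshold_prob = 0.9, pull = list(),
                            outdir = "vedmap_out", seed = 1L) {
  cfg <- list(n_residues = as.integer(n_residues),
              strong_links = as.integer(strong_links),
              weak_links = as.integer(weak_links),
              temperatures = as.numeric(temperatures),
              band_centers = as.numeric(band_centers),
              modes_per_band = as.integer(modes_per_band),
              scale_bands = isTRUE(scale_bands),
              enm_cutoff = enm_cutoff, enm_k = enm_k,
              n_frames = as.integer(n_frames),
              threshold_prob = threshold_prob,
              pull = pull, outdir = outdir, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config object to validate
#' @export
validate_config <- function(config) {
  if (!length(config$temperatures))
    stop("config error: at least one temperature is required")
  if (any(config$temperatures <= 0))
    stop("config error: temperatures must be positive")
  if (config$strong_links <= config$weak_links)
    stop("config error: strong_links must exceed weak_links")
  if (config$n_frames < 10L)
    stop("config error: n_frames must be >= 10")
  invisible(config)
}

#' Read / write a pipeline configuration file
#'
#' Flat key-value text (YAML) with list support.
#'
#' @param config a [pipeline_config()]
#' @param path file path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.write_tsv <- function(df, path) {
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

.write_map_tsv <- function(map, path) {
  m <- map$matrix
  df <- data.frame(residue = map$labels,
                   formatC(m, digits = 10, format = "g"))
  names(df) <- c("residue", map$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Builds the synthetic homolog pair, fits normal modes to both models,
#' computes mode diffusivity, communication maps and VED profiles at every
#' configured temperature, the hottest-minus-coldest difference map, harmonic
#' trajectories with RMSD/RMSF summaries, and a constant-velocity pull per
#' model and temperature. All outputs are written to `config$outdir` as TSV,
#' plus `manifest.json` listing every file with an MD5 checksum, the
#' parameter echo and the package version. Stage failures are re-raised with
#' the stage name; partial outputs are retained.
#'
#' @param config a [pipeline_config()]
#' @return the report bundle (invisibly): per-model maps, profiles, top
#'   residues, fluctuation summaries, pull results, and the manifest
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character()
  add_file <- function(p) files[length(files) + 1L] <<- p
  pair <- stage("synthesis", make_homolog_pair(
    config$n_residues, config$strong_links, config$weak_links,
    seed = config$seed))
  temps <- sort(config$temperatures)
  bundle <- list(config = config, models = list())
  for (mn in c("A", "B")) {
    mdl <- pair[[mn]]
    pot <- enm_with_links(mdl$structure, mdl$crosslinks,
                          cutoff = config$enm_cutoff, k = config$enm_k)
    fit <- stage(paste0("nma_", mn), nma(mdl$structure, pot))
    D <- stage(paste0("diffusivity_", mn), mode_diffusivity(fit))
    band <- if (config$scale_bands)
      scale_band_centers(fit, config$band_centers, config$modes_per_band)
    else band_spec(config$band_centers, config$modes_per_band)
    maps <- list(); profiles <- list(); tops <- list()
    rmsds <- list(); rmsfs <- list(); pulls <- list()
    for (Tk in temps) {
      key <- sprintf("T%g", Tk)
      maps[[key]] <- stage(paste0("map_", mn), communication_map(
        fit, D, mdl$structure, band, temperature = Tk,
        amplitude_scaling = TRUE))
      add_file(.write_map_tsv(maps[[key]],
        file.path(config$outdir, sprintf("map_%s_%s.tsv", mn, key))))
      profiles[[key]] <- ved_profile(maps[[key]])
      thr <- rescale_thresholds(profiles[[key]], config$threshold_prob)
      tops[[key]] <- top_residues(profiles[[key]], thr)
      add_file(.write_tsv(
        data.frame(residue = names(profiles[[key]]),
                   ved = as.numeric(profiles[[key]])),
        file.path(config$outdir, sprintf("ved_%s_%s.tsv", mn, key))))
      traj <- stage(paste0("trajectory_", mn), simulate_harmonic_trajectory(
        fit, Tk, config$n_frames, seed = config$seed + round(Tk)))
      rmsds[[key]] <- rmsd_series(traj)
      rmsfs[[key]] <- rmsf_per_residue(traj)
      add_file(.write_tsv(
        data.frame(residue = names(rmsfs[[key]]$values),
                   rmsf_A = as.numeric(rmsfs[[key]]$values)),
        file.path(config$outdir, sprintf("rmsf_%s_%s.tsv", mn, key))))
      cg <- build_cg_model(mdl$structure, mdl$crosslinks)
      proto <- do.call(pull_protocol, utils::modifyList(
        list(temperature = Tk, seed = config$seed + round(Tk) + 7L),
        config$pull))
      pulls[[key]] <- stage(paste0("pull_", mn), run_pull(cg, proto))
      add_file(write_force_profile(pulls[[key]]$profile,
        file.path(config$outdir, sprintf("force_%s_%s.tsv", mn, key))))
      add_file(.write_tsv(pulls[[key]]$events,
        file.path(config$outdir, sprintf("ruptures_%s_%s.tsv", mn, key))))
    }
    dmap <- NULL
    if (length(temps) > 1L) {
      dmap <- difference_map(maps[[sprintf("T%g", max(temps))]],
                             maps[[sprintf("T%g", min(temps))]])
      add_file(.write_map_tsv(dmap,
        file.path(config$outdir, sprintf("diffmap_%s.tsv", mn))))
    }
    bundle$models[[mn]] <- list(
      crosslinks = mdl$crosslinks, maps = maps, diff_map = dmap,
      profiles = profiles, top_residues = tops, rmsd = rmsds, rmsf = rmsfs,
      pulls = pulls, thresholds_prob = config$threshold_prob)
  }
  manifest <- list(
    package = "vedmap",
    version = as.character(utils::packageVersion("vedmap")),
    seed = config$seed,
    parameters = unclass(config),
    files = lapply(stats::setNames(files, basename(files)), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  mf <- file.path(config$outdir, "manifest.json")
  writeLines(.to_json(manifest), mf)
  bundle$manifest <- manifest
  bundle$files <- c(files, mf)
  invisible(bundle)
}

# minimal JSON serialiser for the manifest (named lists, vectors, scalars)
.to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      paste0("{", paste(sprintf('"%s": %s', esc(names(x)),
        vapply(x, .to_json, character(1))), collapse = ", "), "}")
    } else {
      paste0("[", paste(vapply(x, .to_json, character(1)), collapse = ", "), "]")
    }
  } else if (is.null(x)) {
    "null"
  } else if (length(x) > 1L) {
    paste0("[", paste(vapply(x, .to_json, character(1)), collapse = ", "), "]")
  } else if (is.character(x)) {
    sprintf('"%s"', esc(x))
  } else if (is.logical(x)) {
    if (x) "true" else "false"
  } else {
    format(x, digits = 12)
  }
}

#' Render a human-readable report from a pipeline bundle
#'
#' Pure formatting: tables of top VED residues per model and temperature,
#' RMSD/RMSF means with SDs, rupture summaries, and the exact thresholds and
#' parameters used. Nothing is recomputed, so the same bundle always renders
#' the same text.
#'
#' @param bundle result of [run_pipeline()]
#' @return character vector of report lines (invisibly); also printed
#' @export
render_report <- function(bundle) {
  need <- c("config", "models")
  miss <- setdiff(need, names(bundle))
  if (length(miss))
    stop("incomplete bundle; missing: ", paste(miss, collapse = ", "))
  cfg <- bundle$config
  ln <- c(sprintf("vedmap pipeline report (seed %d)", cfg$seed),
          sprintf("models: %d residues, %d vs %d cross-links",
                  cfg$n_residues, cfg$strong_links, cfg$weak_links),
          sprintf("bands: %s cm^-1, %d modes each",
                  paste(cfg$band_centers, collapse = ", "),
                  cfg$modes_per_band),
          sprintf("colour thresholds rescaled at the %g percentile of each profile",
                  100 * cfg$threshold_prob), "")
  for (mn in names(bundle$models)) {
    md <- bundle$models[[mn]]
    ln <- c(ln, sprintf("== model %s (%d cross-links) ==", mn,
                        nrow(md$crosslinks)))
    for (key in names(md$maps)) {
      ln <- c(ln, sprintf("-- %s --", key))
      tr <- md$top_residues[[key]]
      ln <- c(ln, "top vibrationally active residues:")
      if (nrow(tr)) {
        ln <- c(ln, sprintf("  %-8s %-12s %s", "residue", "VED(A^2/ps)", "class"),
                sprintf("  %-8s %-12.4g %s", tr$label, tr$value,
                        as.character(tr$class)))
      } else {
        ln <- c(ln, "  (none above the lowest band)")
      }
      ln <- c(ln, sprintf("RMSD %.3f +/- %.3f A (first %d frames excluded)",
                          md$rmsd[[key]]$mean, md$rmsd[[key]]$sd,
                          md$rmsd[[key]]$n_excluded),
              sprintf("RMSF %.3f +/- %.3f A over residues",
                      md$rmsf[[key]]$mean, md$rmsf[[key]]$sd))
      pk <- max_force(md$pulls[[key]]$profile)
      ln <- c(ln, sprintf("pull: max force %.1f kJ/mol/nm at %.1f ps; %d link ruptures",
                          pk, attr(pk, "time"), nrow(md$pulls[[key]]$events)),
              "")
    }
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
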