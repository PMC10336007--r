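#' Run the coarse-graining pipeline from a configuration
#'
#' Orchestrates the pipeline stages in dependency order: `synth_map`
#' (generate a synthetic contact map), `build_ensemble` (two-step
#' map-constrained construction), `coarse_grain` (observables per requested
#' `n_b`), `validate` (map reconstruction SCC), and optionally `ibi`.
#' Outputs are plain-text files under `output_dir` and a JSON manifest with
#' stage provenance (config hash, seeds, file hashes). Completed stages are
#' skipped on re-runs unless `force = TRUE`.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognized sections: `seed`, `map` (synthetic map spec fields),
#'   `ensemble` (`n_configs`, `n_steps_stage`, `dt`, `cutoff`),
#'   `coarse_grain` (`n_b`: vector), `ibi` (`enabled`, `n_b`, `max_iter`,
#'   `kl_tol`), `validate` (`h`, `max_stratum`).
#' @param output_dir Output directory (created if missing).
#' @param force Recompute stages whose outputs already exist.
#' @return The manifest (named list), invisibly.
#' @export
run_pipeline <- function(config, output_dir = "chromcg_out", force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  cfg_hash <- substr(digest_config(config), 1, 12)
  manifest_path <- file.path(output_dir, "manifest.json")
  manifest <- list(config_hash = cfg_hash, seed = seed, stages = list())

  log_stage <- function(name, files, cached, t0) {
    manifest$stages[[name]] <<- list(
      cached = cached,
      wall_s = round(as.numeric(Sys.time()) - t0, 2),
      files = lapply(files, function(f) {
        list(path = f, md5 = unname(tools::md5sum(f)))
      }))
    message(sprintf("[%s] %s (%.1fs)", name,
                    if (cached) "cached" else "done",
                    as.numeric(Sys.time()) - t0))
  }

  # synth_map
  map_path <- file.path(output_dir, "map.tsv")
  t0 <- as.numeric(Sys.time())
  if (force || !file.exists(map_path)) {
    mc <- config$map %||% list()
    spec <- synthetic_map_spec(
      n_bins = mc$n_bins %||% 200L,
      decay_exponent = mc$decay_exponent %||% 1,
      amplitude = mc$amplitude %||% 0.9,
      tad_boundaries = mc$tad_boundaries %||% c(67L, 133L),
      tad_boost = mc$tad_boost %||% 3,
      noise_cv = mc$noise_cv %||% 0,
      seed = seed)
    map <- generate_synthetic_map(spec)
    write_contact_map(map, map_path)
    log_stage("synth_map", list(map_path), FALSE, t0)
  } else {
    map <- read_contact_map(map_path)
    log_stage("synth_map", list(map_path), TRUE, t0)
  }

  # build_ensemble
  ens_path <- file.path(output_dir, "ensemble.tsv")
  ec <- config$ensemble %||% list()
  t0 <- as.numeric(Sys.time())
  if (force || !file.exists(ens_path)) {
    ens <- build_ensemble(map,
                          n_configs = ec$n_configs %||% 50L,
                          n_steps_stage = ec$n_steps_stage %||% 6000L,
                          dt = ec$dt %||% 0.002,
                          seed = seed)
    write_ensemble_tsv(ens, ens_path)
    log_stage("build_ensemble", list(ens_path), FALSE, t0)
  } else {
    ens <- read_ensemble_tsv(ens_path)
    log_stage("build_ensemble", list(ens_path), TRUE, t0)
  }

  # coarse_grain
  cg_path <- file.path(output_dir, "cg_summary.tsv")
  t0 <- as.numeric(Sys.time())
  if (force || !file.exists(cg_path)) {
    n_bs <- (config$coarse_grain %||% list())$n_b %||% c(5L, 10L, 25L)
    summaries <- purrr::map(n_bs, function(nb) {
      obs <- cg_observables(ens, nb)
      agg <- dplyr::summarise(
        dplyr::group_by(obs, .data$quantity),
        mean = mean(.data$value), sd = stats::sd(.data$value),
        n = dplyr::n(), .groups = "drop")
      agg$n_b <- nb
      agg
    })
    utils::write.table(dplyr::bind_rows(summaries), cg_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    log_stage("coarse_grain", list(cg_path), FALSE, t0)
  } else {
    log_stage("coarse_grain", list(cg_path), TRUE, t0)
  }

  # validate
  val_path <- file.path(output_dir, "validation.tsv")
  t0 <- as.numeric(Sys.time())
  if (force || !file.exists(val_path)) {
    vc <- config$validate %||% list()
    recon <- ensemble_contact_map(ens, cutoff = ec$cutoff %||% 2)
    s <- scc(map, recon, h = vc$h %||% 1L, max_stratum = vc$max_stratum)
    utils::write.table(
      data.frame(metric = "scc", value = s,
                 h = vc$h %||% 1L, cutoff = ec$cutoff %||% 2),
      val_path, sep = "\t", row.names = FALSE, quote = FALSE)
    log_stage("validate", list(val_path), FALSE, t0)
  } else {
    log_stage("validate", list(val_path), TRUE, t0)
  }

  # ibi (optional)
  ic <- config$ibi %||% list()
  if (isTRUE(ic$enabled)) {
    pot_path <- file.path(output_dir, "ibi_potential.tsv")
    t0 <- as.numeric(Sys.time())
    if (force || !file.exists(pot_path)) {
      nb <- ic$n_b %||% 5L
      target <- distance_distribution(ens, n_b = nb, pairs = "nonbonded")
      obs <- cg_observables(ens, nb)
      l <- obs$value[obs$quantity == "l_cg"]
      k <- spring_constant(l)
      # IBI runs in l_cg-reduced units
      spec <- cg_polymer_spec(n_beads = n_beads(ens) %/% nb,
                              bond_r0 = 1,
                              bond_k = attr(k, "k_lcg2"))
      target_red <- tibble::tibble(r = target$r / mean(l), p = target$p * mean(l))
      res <- run_ibi(target_red, spec,
                     max_iter = ic$max_iter %||% 15L,
                     kl_tol = ic$kl_tol %||% 0.01,
                     seed = seed)
      write_potential_tsv(res$potential, pot_path)
      log_stage("ibi", list(pot_path), FALSE, t0)
    } else {
      log_stage("ibi", list(pot_path), TRUE, t0)
    }
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}
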