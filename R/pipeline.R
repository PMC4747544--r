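# End-to-end orchestration: filter -> infer -> prior chain -> call ->
# annotate -> report, from a flat sectioned YAML config. Unknown keys are
# errors (silent threshold typos being the main reproducibility hazard).

pipeline_schema <- list(
  region = c("chrom", "start", "end"),
  input = c("genotypes", "fasta", "repeats"),
  simulate = c("background_per_mb", "hotspot_start", "hotspot_end",
               "hotspot_multiplier", "theta", "n_haplotypes",
               "markers_per_mb", "missing_rate"),
  filters = c("min_call_rate", "min_maf", "block_size"),
  prior = c("hotspot_rate_per_mb", "width_min_bp", "width_max_bp",
            "intensity_min", "intensity_max", "background_mean",
            "theta_min", "theta_max"),
  chain = c("iterations", "burnin_frac", "thin", "target_samples"),
  likelihood = c("table_reps", "table_placements", "max_pair_span",
                 "cache_dir"),
  calling = c("bin_width", "bf_threshold", "min_consecutive"))

#' Load and validate a pipeline configuration
#'
#' The config is a YAML document with one section per stage (`region`,
#' `input` or `simulate`, `filters`, `prior`, `chain`, `likelihood`,
#' `calling`); unknown sections or keys are errors.
#'
#' @param x path to a YAML file, or an equivalent nested list.
#' @return Validated config list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  bad <- setdiff(names(cfg), names(pipeline_schema))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    extra <- setdiff(names(cfg[[sec]]), pipeline_schema[[sec]])
    if (length(extra))
      stop("unknown key(s) in [", sec, "]: ", paste(extra, collapse = ", "))
  }
  if (is.null(cfg$region)) stop("config must have a [region] section")
  if (is.null(cfg$input) && is.null(cfg$simulate))
    stop("config needs either [input] paths or a [simulate] section")
  structure(cfg, class = "pipeline_config")
}

cfg_get <- function(cfg, sec, key, default) {
  v <- cfg[[sec]][[key]]
  if (is.null(v)) default else v
}

#' Run the full hotspot-inference pipeline
#'
#' Executes filter, inference, prior chain, bin classification, hotspot
#' calling, optional annotation and reporting; every artifact (tables, BED,
#' run metadata, resolved config) is written under `outdir`. A rerun with
#' the same config and seed reproduces the outputs exactly. Stage failures
#' abort with a stage-tagged condition; artifacts already written are kept.
#'
#' @param config a [pipeline_config()] (or path / list accepted by it).
#' @param outdir run directory, created if needed.
#' @param seed master integer seed; all stage seeds derive from it.
#' @return Invisible list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config, outdir, seed = 1) {
  cfg <- pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(errorCondition(paste0("[stage ", name, "] ", conditionMessage(e)),
                          class = c("rhomap_stage_error", "error"))))
  }
  region <- c(cfg$region$start, cfg$region$end)
  chrom <- cfg$region$chrom
  L <- region[2] - region[1]

  g <- stage("data", {
    if (!is.null(cfg$input$genotypes)) {
      read_genotypes(cfg$input$genotypes, region = region)
    } else {
      hs <- NULL
      if (!is.null(cfg$simulate$hotspot_start))
        hs <- data.frame(start = cfg$simulate$hotspot_start - region[1],
                         end = cfg$simulate$hotspot_end - region[1],
                         multiplier = cfg$simulate$hotspot_multiplier)
      map <- rate_map(L, cfg_get(cfg, "simulate", "background_per_mb", 100), hs)
      s <- simulate_haplotypes(
        population_model(theta = cfg_get(cfg, "simulate", "theta", 0.001)),
        map, n = cfg_get(cfg, "simulate", "n_haplotypes", 44), seed = seed)
      gg <- ascertain_markers(
        s, min_maf = cfg_get(cfg, "filters", "min_maf", 0.1),
        target_density = cfg_get(cfg, "simulate", "markers_per_mb", 82),
        seed = seed + 1, chrom = chrom)
      gg$markers$pos <- gg$markers$pos + as.integer(region[1]) - 1L
      gg$region <- region
      mr <- cfg_get(cfg, "simulate", "missing_rate", 0)
      if (mr > 0) gg <- degrade_genotypes(gg, mr, seed = seed + 2)
      write_rate_map_bed(map, file.path(outdir, "true_rate_map.bed"),
                         chrom = chrom,
                         theta = cfg_get(cfg, "simulate", "theta", 0.001))
      gg
    }
  })

  g <- stage("filter", {
    gf <- apply_filters(g,
                        min_call_rate = cfg_get(cfg, "filters", "min_call_rate", 0.8),
                        min_maf = cfg_get(cfg, "filters", "min_maf", 0.1))
    rep <- attr(gf, "filter_report")
    utils::write.table(
      data.frame(criterion = c("unique_mapping", "call_rate", "maf"),
                 removed = as.integer(rep$removed)),
      file.path(outdir, "filter_report.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    gf
  })
  blocks <- partition_blocks(g, cfg_get(cfg, "filters", "block_size", 20))

  prior <- prior_spec(
    hotspot_rate_per_mb = cfg_get(cfg, "prior", "hotspot_rate_per_mb", 1),
    width_range_bp = c(cfg_get(cfg, "prior", "width_min_bp", 500),
                       cfg_get(cfg, "prior", "width_max_bp", 5000)),
    intensity_range = c(cfg_get(cfg, "prior", "intensity_min", 5),
                        cfg_get(cfg, "prior", "intensity_max", 500)),
    background_mean = cfg_get(cfg, "prior", "background_mean", 100),
    theta_range = c(cfg_get(cfg, "prior", "theta_min", 1e-4),
                    cfg_get(cfg, "prior", "theta_max", 1e-2)))
  chain <- chain_settings(
    iterations = cfg_get(cfg, "chain", "iterations", 20000),
    burnin_frac = cfg_get(cfg, "chain", "burnin_frac", 0.5),
    thin = cfg$chain$thin,
    target_samples = cfg_get(cfg, "chain", "target_samples", 2000),
    seed = seed + 10)

  fit <- stage("infer", {
    g <- phase_genotypes(g, seed = seed + 3)
    n_hap <- 2L * length(g$samples)
    reps <- cfg_get(cfg, "likelihood", "table_reps", 2000)
    plc <- cfg_get(cfg, "likelihood", "table_placements", 5)
    cache <- cfg$likelihood$cache_dir
    tab <- NULL
    if (!is.null(cache))
      tab <- read_table_cache(cache, n_hap, reps * plc, seed + 4)
    if (is.null(tab)) {
      tab <- two_locus_table(n_hap, reps = reps, placements = plc,
                             seed = seed + 4)
      if (!is.null(cache)) write_table_cache(tab, cache)
    }
    infer_rhomap(g, prior = prior, chain = chain, table = tab,
                 max_pair_span = cfg_get(cfg, "likelihood", "max_pair_span", 1e5))
  })

  pfit <- stage("prior", {
    pchain <- chain
    pchain$seed <- as.integer(seed + 20)
    infer_rhomap(g, prior = prior, chain = pchain, likelihood = "constant")
  })

  bw <- cfg_get(cfg, "calling", "bin_width", 200)
  track <- stage("call", {
    tr <- bin_track(fit, pfit, bin_width = bw)
    write_bin_track(tr, file.path(outdir, "bin_track.tsv"), chrom = chrom)
    tr
  })
  calls <- call_hotspots(track,
                         bf_threshold = cfg_get(cfg, "calling", "bf_threshold", 100),
                         min_consecutive = cfg_get(cfg, "calling", "min_consecutive", 2))
  write_hotspot_calls(calls, file.path(outdir, "hotspots"), chrom = chrom)

  annot <- stage("annotate", {
    if (is.null(cfg$input$fasta) || is.null(cfg$input$repeats)) NULL
    else annotate_bins(track, parse_repeat_table(cfg$input$repeats),
                       sequence = read_region_fasta(cfg$input$fasta),
                       chrom = chrom,
                       bf_threshold = cfg_get(cfg, "calling", "bf_threshold", 100))
  })

  report <- stage("report", {
    mids <- (track$start + track$end) / 2
    pr <- predict(fit, mids)
    d <- diff(g$markers$pos)
    rs <- mean_rho(predict(fit, (g$markers$pos[-1] + g$markers$pos[-length(g$markers$pos)]) / 2)$rho_per_mb, d)
    summ <- region_summary(data.frame(
      chr = chrom, n_snps = nrow(g$calls), start = region[1], end = region[2],
      mean_rho = rs$mean_rho_per_mb,
      bins_lt100 = sum(track$bf < cfg_get(cfg, "calling", "bf_threshold", 100)),
      bins_ge100 = sum(track$bf >= cfg_get(cfg, "calling", "bf_threshold", 100))))
    utils::write.table(summ, file.path(outdir, "region_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(calls)) {
      hsum <- hotspot_summary(cbind(chr = chrom, calls))
      utils::write.table(hsum, file.path(outdir, "hotspot_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summ
  })

  meta <- list(seed = seed, config = unclass(cfg),
               block_sizes = blocks$sizes,
               acceptance = fit$acceptance, ess = as.list(fit$ess),
               n_clamped = fit$n_clamped,
               filter_report = attr(g, "filter_report"))
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "resolved_config.yaml"))

  invisible(list(genotypes = g, blocks = blocks, fit = fit,
                 prior_fit = pfit, track = track, calls = calls,
                 annotation = annot, report = report, outdir = outdir))
}
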