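#' Default analysis parameters
#'
#' Single home of the pipeline's numeric constants: 5,000-bp metaprofile
#' half-width, 151-bp Hanning smoothing, background at +2,500 bp, resection
#' window (100, 2500] nt in 100-nt bins, 10-bp hotspot / 40-bp PAR bins with
#' a 51-bin window, 5-kb peak widening, MAPQ >= 20, 1-kb/100-bp Poisson
#' caller windows at BH q < 0.01, and the minimum peak/background enrichment
#' (2x) below which a genotype is reported background-only.
#'
#' @return named list of parameter defaults.
#' @export
default_params <- function() {
  list(
    half_width = 5000L,
    window_len = 151L,
    background_offset = 2500L,
    resection_lo = 100L,
    resection_hi = 2500L,
    resection_bin = 100L,
    bin_size_hotspot = 10L,
    bin_size_par = 40L,
    window_bins = 51L,
    widen_bp = 5000L,
    min_mapq = 20L,
    peak_window = 1000L,
    peak_step = 100L,
    peak_q = 0.01,
    min_enrichment = 2
  )
}

.config_keys <- c("seed", "output_dir", "genome", "catalog", "genotypes", "params")

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a list. Unknown keys (top-level, in `params`,
#' or in genotype entries) are rejected; missing parameters are filled from
#' [default_params()]; basic range checks are applied (odd smoothing
#' windows, positive sizes).
#'
#' Schema: `seed` (required integer); `output_dir`; `genome` (`"default"` or
#' a list of `{name, length}` plus optional `par`); `catalog` (either
#' `synthetic: yes` with optional `n_prdm9`/`n_default`, or `bed: <path>`);
#' `genotypes` — a list of `{name, preset}` entries (synthetic runs) or
#' `{name, replicates: [{stem}, ...]}` pointing at bedGraph pairs.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return a validated `RunConfig` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config$seed is required")
  config$seed <- as.integer(config$seed)
  if (is.na(config$seed)) stop("config$seed must be an integer")

  params <- default_params()
  if (!is.null(config$params)) {
    unknown <- setdiff(names(config$params), names(params))
    if (length(unknown)) stop("unknown params key(s): ", paste(unknown, collapse = ", "))
    params[names(config$params)] <- config$params
  }
  for (k in c("window_len", "window_bins"))
    if (params[[k]] < 1 || params[[k]] %% 2 == 0)
      stop("params$", k, " must be a positive odd integer")
  for (k in c("half_width", "resection_bin", "bin_size_hotspot", "bin_size_par",
              "peak_window", "peak_step"))
    if (params[[k]] <= 0) stop("params$", k, " must be positive")
  if (params$resection_lo >= params$resection_hi)
    stop("params$resection_lo must be below resection_hi")
  config$params <- params

  if (is.null(config$genome)) config$genome <- "default"
  if (is.null(config$catalog)) config$catalog <- list(synthetic = TRUE)
  if (is.null(config$genotypes) || !length(config$genotypes))
    stop("config$genotypes must list at least one genotype")
  for (i in seq_along(config$genotypes)) {
    g <- config$genotypes[[i]]
    unknown <- setdiff(names(g), c("name", "preset", "replicates", "total_dsb_events"))
    if (length(unknown)) stop("unknown genotype key(s): ", paste(unknown, collapse = ", "))
    if (is.null(g$name)) stop("every genotype needs a name")
    if (is.null(g$preset) && is.null(g$replicates))
      stop("genotype '", g$name, "' needs a preset or replicate paths")
    if (!is.null(g$replicates)) {
      stems <- vapply(g$replicates, function(r) r$stem, "")
      missing <- stems[!file.exists(paste0(stems, ".top.bedgraph"))]
      if (length(missing))
        stop("genotype '", g$name, "': bedGraph pair not found for stem ", missing[1])
    }
  }
  if (is.null(config$output_dir)) config$output_dir <- "exo7tseq_run"
  structure(config, class = "RunConfig")
}

.resolve_genome <- function(spec) {
  if (identical(spec, "default") || is.null(spec)) return(default_genome())
  if (inherits(spec, "GenomeModel")) return(spec)
  chrom <- do.call(rbind, lapply(spec$chromosomes, as.data.frame))
  genome_model(chrom, par_interval = spec$par)
}

.resolve_catalog <- function(spec, genome, seed) {
  if (inherits(spec, "HotspotCatalog")) return(spec)
  if (!is.null(spec$bed)) return(read_catalog_bed(spec$bed, genome = genome))
  args <- spec[setdiff(names(spec), "synthetic")]
  do.call(simulate_hotspot_catalog, c(list(genome = genome, seed = seed), args))
}

#' Run the full genotype-comparison pipeline
#'
#' For every configured genotype: obtain replicate tracks (simulated from a
#' preset or read from bedGraph pairs), RPM-scale them, build the replicate-
#' averaged co-oriented metaprofile around PRDM9-directed hotspot centers,
#' smooth, subtract the far-flank background and peak-normalize, compute the
#' resection-length distribution and its mean, call peaks on the pooled raw
#' counts, widen and merge them, classify them against the PRDM9 and default
#' catalogs, quantify usage, and profile the PAR-like interval. Writes
#' per-genotype TSV/BED outputs, a Markdown report, and a run manifest
#' (package version, seed, parameters, input digests); all outputs are
#' deterministic given the config, so reruns are byte-identical.
#'
#' A genotype whose smoothed profile shows less than `min_enrichment`-fold
#' signal over the far-flank background (e.g. a Spo11-null, DSB-independent
#' control) is marked background-only and skips the resection stage.
#'
#' @param config a `RunConfig` (or anything [validate_config()] accepts).
#' @param output_dir overrides `config$output_dir`.
#' @return invisibly, a list of per-genotype results plus the catalogs and
#'   paths of the written files.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- validate_config(config)
  if (is.null(output_dir)) output_dir <- config$output_dir
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params

  genome <- .resolve_genome(config$genome)
  catalog <- .resolve_catalog(config$catalog, genome, config$seed)
  prdm9 <- catalog[catalog$category == "prdm9", , drop = FALSE]
  class(prdm9) <- class(catalog)
  default_cat <- catalog[catalog$category == "default", , drop = FALSE]
  class(default_cat) <- class(catalog)
  write_catalog_bed(catalog, file.path(output_dir, "catalog.bed"))

  results <- list()
  for (gi in seq_along(config$genotypes)) {
    g <- config$genotypes[[gi]]
    stage <- "input"
    res <- tryCatch({
      if (!is.null(g$preset)) {
        cfg_args <- list(name = g$preset, seed = config$seed + 1000L * gi)
        if (!is.null(g$total_dsb_events)) cfg_args$total_dsb_events <- as.integer(g$total_dsb_events)
        gcfg <- do.call(make_genotype_preset, cfg_args)
        sim <- simulate_dataset(genome, catalog, gcfg)
        counts <- sim$counts
        truth <- sim$truth
      } else {
        counts <- lapply(g$replicates, function(r)
          read_bedgraph_pair(r$stem, genome, scale = "raw"))
        truth <- NULL
      }

      stage <- "metaprofile"
      rpm <- lapply(counts, to_rpm)
      profs <- lapply(rpm, aggregate_around_centers, catalog = prdm9,
                      half_width = p$half_width, co_orient = TRUE)
      avg <- average_profiles(profs)
      sm <- smooth_hanning(avg, p$window_len)

      stage <- "resection"
      sub <- subtract_background(sm, p$background_offset)
      win <- sub$offsets > p$resection_lo & sub$offsets <= p$resection_hi
      enr <- if (sub$background_value > 0)
        (max(sub$values[win]) + sub$background_value) / sub$background_value
      else if (max(sub$values[win]) > 0) Inf else 0
      background_only <- enr < p$min_enrichment
      if (!background_only) {
        norm <- normalize_to_resection_peak(sub, p$resection_lo, p$resection_hi)
        dist <- resection_length_distribution(sub, p$resection_lo, p$resection_hi,
                                              p$resection_bin, genotype = g$name)
        write_profile_tsv(norm, file.path(output_dir, paste0(g$name, ".profile.tsv")))
        write_resection_tsv(dist, file.path(output_dir, paste0(g$name, ".resection.tsv")))
      } else {
        norm <- NULL; dist <- NULL
      }

      stage <- "peaks"
      pooled <- pool_counts(counts)
      peaks <- call_peaks(pooled, window = p$peak_window, step = p$peak_step,
                          q_threshold = p$peak_q)
      merged <- widen_and_merge(peaks, widen_bp = p$widen_bp, genome = genome)
      overlap <- classify_overlap(merged, prdm9, default_cat)
      usage <- hotspot_usage(pooled, overlap)
      export_peaks(merged, file.path(output_dir, paste0(g$name, ".peaks.bed")),
                   format = "bed")

      stage <- "par"
      par_total <- NA_real_
      par_profile <- NULL
      if (!is.null(genome$par)) {
        par_by_rep <- vapply(rpm, function(cn)
          interval_signal(cn, genome$par, p$bin_size_par, p$window_bins)$total,
          numeric(1))
        par_total <- mean(par_by_rep)
        par_profile <- interval_signal(rpm[[1]], genome$par,
                                       p$bin_size_par, p$window_bins)$profile
        utils::write.table(par_profile,
                           file.path(output_dir, paste0(g$name, ".par.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }

      list(name = g$name, truth = truth, profile = sub, profile_normalized = norm,
           distribution = dist, background_only = background_only,
           enrichment = enr, peaks = merged, overlap = overlap, usage = usage,
           par_total_rpm = par_total, error = NULL)
    }, error = function(e) {
      stop("pipeline failed for genotype '", g$name, "' at stage [", stage, "]: ",
           conditionMessage(e), call. = FALSE)
    })
    results[[g$name]] <- res
  }

  .write_report(results, config, output_dir)
  .write_manifest(config, output_dir)
  invisible(list(genotypes = results, genome = genome, catalog = catalog,
                 output_dir = output_dir))
}

.write_report <- function(results, config, output_dir) {
  lines <- c("# Exo7/T-seq style pipeline report", "",
             paste0("Seed: ", config$seed), "",
             "## Resection", "",
             "| genotype | mean resection (nt) | background-only |",
             "|---|---|---|")
  for (res in results) {
    m <- if (!is.null(res$distribution))
      sprintf("%.1f", res$distribution$mean_length) else "-"
    lines <- c(lines, sprintf("| %s | %s | %s |", res$name, m,
                              ifelse(res$background_only, "yes", "no")))
  }
  lines <- c(lines, "", "## Peak overlap with hotspot catalogs", "",
             "| genotype | peaks | prdm9_only | default_only | both | neither | default-assoc. signal share |",
             "|---|---|---|---|---|---|---|")
  for (res in results) {
    ov <- res$overlap
    lines <- c(lines, sprintf("| %s | %d | %d | %d | %d | %d | %.3f |",
                              res$name, ov$n_peaks, ov$n_prdm9_only, ov$n_default_only,
                              ov$n_both, ov$n_neither, res$usage$default_associated))
  }
  lines <- c(lines, "", "## PAR-interval signal", "",
             "| genotype | PAR total (RPM) |", "|---|---|")
  for (res in results)
    lines <- c(lines, sprintf("| %s | %.1f |", res$name, res$par_total_rpm))
  writeLines(lines, file.path(output_dir, "report.md"))
}

.write_manifest <- function(config, output_dir) {
  outputs <- sort(setdiff(list.files(output_dir), "manifest.yaml"))
  digests <- as.list(tools::md5sum(file.path(output_dir, outputs)))
  names(digests) <- outputs
  manifest <- list(
    package = "exo7tseq",
    version = as.character(utils::packageVersion("exo7tseq")),
    seed = config$seed,
    params = config$params,
    output_digests = digests
  )
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
}
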