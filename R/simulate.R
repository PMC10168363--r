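#' Simulate a strand-specific DSB end-count dataset
#'
#' Generative model of the signal anatomy the downstream analysis assumes.
#' For each of `total_dsb_events` per replicate:
#'
#' 1. a hotspot category is drawn (`default` with probability
#'    `default_weight`), then a hotspot within the category with probability
#'    proportional to heat (times `par_boost` for hotspots inside the PAR
#'    interval), so the planted category weights are exact event fractions;
#' 2. the DSB position is Normal(center, `dsb_sd`), rounded;
#' 3. the event is assigned to the top or bottom strand with probability 1/2
#'    (rightward vs leftward resection);
#' 4. with probability `central_fraction` the read is a center-proximal
#'    recombination-intermediate end, recorded uniformly within
#'    `+/- dsb_sd` of the DSB position on the chosen strand; otherwise a
#'    resection length `L = resection_min + Gamma(mean = resection_mean -
#'    resection_min, sd = resection_sd)` is drawn (rounded to integer nt) and
#'    the end is recorded at `position + L` (top) or `position - L` (bottom).
#'
#' Background reads are Poisson with mean `background_rate * genome length`,
#' uniform over the genome and across strands. Events whose recorded end
#' falls outside chromosome bounds are discarded entirely (not recorded in
#' the truth), so emitted reads and the truth record reconcile exactly.
#' Replicate `r` is an independent draw seeded at `config$seed + r - 1`;
#' the output is bit-identical for identical inputs and seed.
#'
#' @param genome a `GenomeModel`.
#' @param catalog a `HotspotCatalog`; may only be empty when
#'   `total_dsb_events = 0`.
#' @param config a `GenotypeConfig` (see [make_genotype_preset()]).
#' @return list with `counts` (list of raw `StrandedEndCounts`, one per
#'   replicate) and `truth` (a `SimTruth`: the config, per-hotspot
#'   non-central event counts, all realized resection lengths and their
#'   mean, central/background totals, per replicate and combined).
#' @export
simulate_dataset <- function(genome, catalog, config) {
  stopifnot(inherits(genome, "GenomeModel"), inherits(config, "GenotypeConfig"))
  if (config$total_dsb_events > 0 && nrow(catalog) == 0)
    stop("DSB events requested but the hotspot catalog is empty")
  if (nrow(catalog) > 0) {
    bad <- setdiff(unique(catalog$chrom), names(genome$chrom_lengths))
    if (length(bad)) stop("hotspot outside genome: chromosome ",
                          paste(bad, collapse = ", "))
    if (any(catalog$end > genome$chrom_lengths[catalog$chrom]) || any(catalog$start < 0))
      stop("hotspot outside genome bounds")
  }

  lens <- genome$chrom_lengths
  glen <- genome_length(genome)
  is_par <- if (nrow(catalog)) in_par(genome, catalog$chrom, catalog$center) else logical(0)
  w_hot <- catalog$heat * ifelse(is_par, config$par_boost, 1)

  counts <- vector("list", config$n_replicates)
  reps <- vector("list", config$n_replicates)

  for (r in seq_len(config$n_replicates)) {
    set.seed(config$seed + r - 1L)
    N <- config$total_dsb_events

    if (N > 0) {
      is_default <- stats::runif(N) < config$default_weight
      idx <- integer(N)
      for (cat_name in c("prdm9", "default")) {
        sel <- if (cat_name == "default") is_default else !is_default
        nsel <- sum(sel)
        if (nsel == 0) next
        pool <- which(catalog$category == cat_name)
        wts <- w_hot[pool]
        if (!length(pool) || sum(wts) <= 0)
          stop("no ", cat_name, " hotspot with positive weight, but ",
               cat_name, " events were requested")
        idx[sel] <- pool[sample.int(length(pool), nsel, replace = TRUE, prob = wts)]
      }
      dsb_pos <- round(stats::rnorm(N, catalog$center[idx], config$dsb_sd))
      top <- stats::runif(N) < 0.5
      central <- stats::runif(N) < config$central_fraction
      n_cen <- sum(central)
      L <- numeric(N)
      if (any(!central)) {
        m <- config$resection_mean - config$resection_min
        if (config$resection_sd > 0) {
          shape <- (m / config$resection_sd)^2
          g <- stats::rgamma(sum(!central), shape = shape,
                             scale = config$resection_sd^2 / m)
        } else {
          g <- rep(m, sum(!central))
        }
        L[!central] <- config$resection_min + round(g)
      }
      offset <- numeric(N)
      if (n_cen > 0)
        offset[central] <- sample.int(2L * config$dsb_sd + 1L, n_cen,
                                      replace = TRUE) - config$dsb_sd - 1L
      offset[!central] <- ifelse(top[!central], L[!central], -L[!central])
      end_pos <- dsb_pos + offset
      chrom <- catalog$chrom[idx]
      keep <- end_pos >= 0 & end_pos < lens[chrom]
    } else {
      idx <- integer(0); top <- logical(0); central <- logical(0)
      L <- numeric(0); end_pos <- numeric(0); chrom <- character(0)
      keep <- logical(0)
    }

    # background: uniform over the genome, uniform strand
    B <- stats::rpois(1, config$background_rate * glen)
    if (B > 0) {
      bchrom <- sample(names(lens), B, replace = TRUE, prob = lens)
      bpos <- floor(stats::runif(B) * lens[bchrom])
      btop <- stats::runif(B) < 0.5
    } else {
      bchrom <- character(0); bpos <- numeric(0); btop <- logical(0)
    }

    k_top <- keep & top
    k_bot <- keep & !top
    counts[[r]] <- .counts_from_events(
      genome,
      chrom_top = c(chrom[k_top], bchrom[btop]),
      pos_top = c(end_pos[k_top], bpos[btop]),
      chrom_bottom = c(chrom[k_bot], bchrom[!btop]),
      pos_bottom = c(end_pos[k_bot], bpos[!btop])
    )

    res_kept <- keep & !central
    per_hs <- integer(nrow(catalog))
    if (any(res_kept)) {
      t <- tabulate(idx[res_kept], nbins = nrow(catalog))
      per_hs <- t
    }
    names(per_hs) <- catalog$id
    reps[[r]] <- list(
      per_hotspot_events = per_hs,
      realized_resection_lengths = L[res_kept],
      n_central = sum(keep & central),
      n_background = B,
      n_dropped = sum(!keep),
      total_reads = sum(keep) + B
    )
  }

  per_hs_all <- Reduce(`+`, lapply(reps, `[[`, "per_hotspot_events"))
  lengths_all <- unlist(lapply(reps, `[[`, "realized_resection_lengths"))
  truth <- structure(list(
    config = config,
    per_hotspot_events = per_hs_all,
    realized_resection_lengths = lengths_all,
    realized_mean_resection = if (length(lengths_all)) mean(lengths_all) else NA_real_,
    n_central = sum(vapply(reps, `[[`, numeric(1), "n_central")),
    n_background = sum(vapply(reps, `[[`, numeric(1), "n_background")),
    n_dropped = sum(vapply(reps, `[[`, numeric(1), "n_dropped")),
    total_reads = sum(vapply(reps, `[[`, numeric(1), "total_reads")),
    replicates = reps
  ), class = "SimTruth")

  list(counts = counts, truth = truth)
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth [", x$config$name, "]: ", x$total_reads, " reads over ",
      length(x$replicates), " replicate(s)\n", sep = "")
  cat("  hotspot resection events:", sum(x$per_hotspot_events),
      "| central:", x$n_central, "| background:", x$n_background, "\n")
  if (!is.na(x$realized_mean_resection))
    cat(sprintf("  realized mean resection: %.1f nt\n", x$realized_mean_resection))
  invisible(x)
}

#' Write a simulation truth record as TSV (plus a YAML config dump)
#'
#' @param truth a `SimTruth`.
#' @param stem output path stem; writes `<stem>.truth.tsv` (per-hotspot
#'   event counts) and `<stem>.config.yaml`.
#' @export
write_sim_truth <- function(truth, stem) {
  tsv <- paste0(stem, ".truth.tsv")
  utils::write.table(
    data.frame(hotspot_id = names(truth$per_hotspot_events),
               events = as.integer(truth$per_hotspot_events)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(truth$config), paste0(stem, ".config.yaml"))
  invisible(c(tsv, paste0(stem, ".config.yaml")))
}
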