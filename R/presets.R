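#' Genotype simulation configuration
#'
#' Parameters of the generative model for one genotype: how many DSB events
#' to emit, how they split between PRDM9-directed and default hotspots, how
#' strongly PAR hotspots are boosted, the resection-length distribution, the
#' fraction of center-proximal "recombination intermediate" signal, and the
#' uniform background rate.
#'
#' `prdm9_weight`/`default_weight` are the fractions of DSB events assigned
#' to each hotspot category (they sum to 1); within a category, hotspots are
#' chosen proportional to heat, with PAR hotspots further multiplied by
#' `par_boost`. Resection lengths are drawn as
#' `resection_min + Gamma(mean = resection_mean - resection_min, sd = resection_sd)`,
#' a smooth right-skewed distribution with a hard minimum and expectation
#' exactly `resection_mean`.
#'
#' @param name genotype label.
#' @param total_dsb_events DSB events emitted per replicate.
#' @param default_weight fraction of events at default hotspots, in `[0, 1]`.
#' @param par_boost heat multiplier (>= 0) for hotspots inside the PAR
#'   interval.
#' @param resection_mean,resection_sd,resection_min resection-length
#'   distribution, nt; `resection_mean > resection_min > 0`.
#' @param central_fraction fraction of events emitted as center-proximal
#'   signal instead of a resection endpoint.
#' @param background_rate expected background reads per bp (both strands
#'   combined); background is independent of `total_dsb_events`.
#' @param dsb_sd standard deviation (bp) of DSB positions around the hotspot
#'   center.
#' @param n_replicates number of biological replicates to simulate.
#' @param seed base integer seed; replicate `r` draws at `seed + r - 1`.
#' @return an object of class `GenotypeConfig`.
#' @seealso [make_genotype_preset()] for the study presets.
#' @export
genotype_config <- function(name, total_dsb_events, default_weight,
                            par_boost = 1, resection_mean = 950,
                            resection_sd = 300, resection_min = 300,
                            central_fraction = 0.15, background_rate = 0.02,
                            dsb_sd = 50, n_replicates = 2, seed = 1) {
  total_dsb_events <- as.integer(total_dsb_events)
  if (is.na(total_dsb_events) || total_dsb_events < 0)
    stop("total_dsb_events must be a nonnegative integer")
  if (default_weight < 0 || default_weight > 1)
    stop("default_weight must be in [0, 1]")
  if (central_fraction < 0 || central_fraction > 1)
    stop("central_fraction must be in [0, 1]")
  if (par_boost < 0) stop("par_boost must be >= 0")
  if (resection_min <= 0) stop("resection_min must be > 0")
  if (resection_mean <= resection_min) stop("resection_mean must exceed resection_min")
  if (resection_sd < 0) stop("resection_sd must be >= 0")
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (dsb_sd < 0) stop("dsb_sd must be >= 0")
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(
    name = as.character(name),
    total_dsb_events = total_dsb_events,
    prdm9_weight = 1 - default_weight,
    default_weight = default_weight,
    par_boost = par_boost,
    resection_mean = resection_mean,
    resection_sd = resection_sd,
    resection_min = resection_min,
    central_fraction = central_fraction,
    background_rate = background_rate,
    dsb_sd = dsb_sd,
    n_replicates = n_replicates,
    seed = as.integer(seed)
  ), class = "GenotypeConfig")
}

# Preset table. Ordering constraints encoded here:
#   default_weight: null = dC > EA_over_null > EA > wildtype (wildtype minimum)
#   par_boost: wildtype (and EA alleles) >> null = dC = 0
#   resection_mean: null = dC = wildtype - 100 nt
#   spo11_null emits no DSB events (background-only control)
.preset_table <- list(
  wildtype           = list(default_weight = 0.05, par_boost = 16, resection_mean = 950),
  ankrd31_EA         = list(default_weight = 0.06, par_boost = 16, resection_mean = 950),
  ankrd31_EA_over_null = list(default_weight = 0.15, par_boost = 16, resection_mean = 950),
  ankrd31_dC         = list(default_weight = 0.35, par_boost = 0, resection_mean = 850),
  ankrd31_null       = list(default_weight = 0.35, par_boost = 0, resection_mean = 850),
  spo11_null         = list(default_weight = 0.05, par_boost = 16, resection_mean = 950,
                            total_dsb_events = 0L)
)

#' Genotype presets for the simulated study design
#'
#' Encodes the qualitative genotype effects the analysis is designed to
#' detect: elevated default-hotspot usage and ~100 nt shorter resection in
#' `ankrd31_null` and `ankrd31_dC`; near-wild-type behaviour of the
#' `ankrd31_EA` allele, intermediate default usage for `ankrd31_EA_over_null`;
#' loss of the PAR boost in `ankrd31_null`/`ankrd31_dC`; and a background-only
#' `spo11_null` control with zero DSB events. All presets share the same
#' background rate, so library composition (not depth) is what distinguishes
#' the control.
#'
#' @param name one of `"wildtype"`, `"ankrd31_null"`, `"ankrd31_dC"`,
#'   `"ankrd31_EA"`, `"ankrd31_EA_over_null"`, `"spo11_null"`.
#' @param total_dsb_events,seed,... overrides passed to [genotype_config()].
#' @return a `GenotypeConfig`.
#' @examples
#' make_genotype_preset("wildtype")$default_weight
#' make_genotype_preset("spo11_null")$total_dsb_events  # 0
#' @export
make_genotype_preset <- function(name, total_dsb_events = 200000L, seed = 1, ...) {
  if (!is.character(name) || length(name) != 1 || !name %in% names(.preset_table))
    stop("unknown preset '", paste(name, collapse = ","), "'; valid presets: ",
         paste(names(.preset_table), collapse = ", "))
  args <- .preset_table[[name]]
  if (is.null(args$total_dsb_events)) args$total_dsb_events <- total_dsb_events
  args$name <- name
  args$seed <- seed
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(genotype_config, args)
}

#' @export
print.GenotypeConfig <- function(x, ...) {
  cat("GenotypeConfig '", x$name, "': ", x$total_dsb_events, " DSB events x ",
      x$n_replicates, " replicates\n", sep = "")
  cat(sprintf("  weights prdm9/default: %.2f/%.2f, par_boost %.1f\n",
              x$prdm9_weight, x$default_weight, x$par_boost))
  cat(sprintf("  resection mean %g sd %g min %g nt; central fraction %.2f\n",
              x$resection_mean, x$resection_sd, x$resection_min, x$central_fraction))
  cat(sprintf("  background %.4g reads/bp; seed %d\n", x$background_rate, x$seed))
  invisible(x)
}
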