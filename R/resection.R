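#' Subtract the far-flank background from a profile
#'
#' Estimates background as the profile value at a single offset far from the
#' hotspot center (default +2,500 bp, beyond the span of resection
#' endpoints), subtracts that scalar everywhere, and clamps negative values
#' to zero. On a co-oriented profile there is no distinct -2,500 flank, so
#' the single positive offset is used.
#'
#' @param profile an `AggregateProfile`.
#' @param offset_bp offset whose value is taken as background; must lie
#'   within the profile.
#' @return the background-subtracted `AggregateProfile` (field
#'   `background_value` records the subtracted scalar).
#' @export
subtract_background <- function(profile, offset_bp = 2500) {
  stopifnot(inherits(profile, "AggregateProfile"))
  i <- match(as.integer(offset_bp), profile$offsets)
  if (is.na(i)) stop("offset ", offset_bp, " bp is beyond the profile extent")
  bg <- profile$values[i]
  out <- profile
  out$values <- pmax(profile$values - bg, 0)
  out$background_subtracted <- TRUE
  out$background_value <- bg
  out
}

#' Normalize a profile to the resection-endpoint peak
#'
#' Divides the whole profile by its maximum over offsets in `(lo, hi]`
#' (default 100-2,500 bp, the span where resection endpoints accumulate), so
#' that the resection peak has height exactly 1. Expects a
#' background-subtracted profile.
#'
#' @param profile a background-subtracted `AggregateProfile`.
#' @param lo,hi window bounds, bp (window is `(lo, hi]`).
#' @return the peak-normalized `AggregateProfile`
#'   (`normalization = "peak_normalized"`).
#' @export
normalize_to_resection_peak <- function(profile, lo = 100, hi = 2500) {
  stopifnot(inherits(profile, "AggregateProfile"))
  win <- profile$offsets > lo & profile$offsets <= hi
  if (!any(win)) stop("window (", lo, ", ", hi, "] is beyond the profile extent")
  m <- max(profile$values[win])
  if (m <= 0) stop("no resection signal to normalize")
  out <- profile
  out$values <- profile$values / m
  out$normalization <- "peak_normalized"
  out
}

#' Resection-length distribution from a co-oriented profile
#'
#' Zeroes the profile at offsets at or below `lo` (the hotspot core and the
#' anti-oriented side) and above `hi`, then partitions the remaining signal
#' into consecutive `bin` bp bins over `(lo, hi]` and reports each bin's
#' fraction of the remaining total. With the defaults this gives 24 bins of
#' 100 bp spanning (100, 2500] nt. The summary mean is the fraction-weighted
#' bin midpoint (see [mean_resection_length()]).
#'
#' @param profile a background-subtracted co-oriented `AggregateProfile`.
#' @param lo,hi,bin window and bin width, nt.
#' @param genotype optional label stored in the result.
#' @return an object of class `ResectionDistribution` with `bin_edges`
#'   (length bins+1), `fractions`, `mean_length`, `source_genotype`.
#' @export
resection_length_distribution <- function(profile, lo = 100, hi = 2500,
                                          bin = 100, genotype = NULL) {
  stopifnot(inherits(profile, "AggregateProfile"))
  if (!isTRUE(profile$co_oriented))
    stop("resection distributions require a co-oriented profile")
  if (!isTRUE(profile$background_subtracted))
    stop("resection distributions require a background-subtracted profile")
  edges <- seq(lo, hi, by = bin)
  if (max(profile$offsets) < hi) stop("profile extent is smaller than ", hi, " bp")
  keep <- profile$offsets > lo & profile$offsets <= hi
  off <- profile$offsets[keep]
  val <- profile$values[keep]
  total <- sum(val)
  if (total <= 0) stop("no signal remains in (", lo, ", ", hi, "]")
  idx <- ceiling((off - lo) / bin)  # bin 1 = (lo, lo+bin]
  sums <- vapply(seq_len(length(edges) - 1L),
                 function(b) sum(val[idx == b]), numeric(1))
  structure(list(
    bin_edges = edges,
    fractions = sums / total,
    mean_length = sum((sums / total) * (edges[-length(edges)] + bin / 2)),
    source_genotype = if (is.null(genotype)) NA_character_ else as.character(genotype)
  ), class = "ResectionDistribution")
}

#' Mean resection length of a distribution
#'
#' The fraction-weighted bin midpoint, `sum(fraction_i * midpoint_i)` with
#' midpoints 150, 250, ..., 2450 nt for the default binning.
#'
#' @param dist a `ResectionDistribution`.
#' @return mean resection length, nt.
#' @export
mean_resection_length <- function(dist) {
  stopifnot(inherits(dist, "ResectionDistribution"))
  e <- dist$bin_edges
  mid <- e[-length(e)] + diff(e) / 2
  sum(dist$fractions * mid)
}

#' Compare two resection distributions
#'
#' @param a,b `ResectionDistribution`s on the same binning.
#' @return list with `shift_nt` (`mean(a) - mean(b)`) and `delta_fractions`
#'   (per-bin `a - b`).
#' @export
compare_resection <- function(a, b) {
  stopifnot(inherits(a, "ResectionDistribution"), inherits(b, "ResectionDistribution"))
  if (!identical(a$bin_edges, b$bin_edges)) stop("distributions have different binning")
  list(shift_nt = mean_resection_length(a) - mean_resection_length(b),
       delta_fractions = a$fractions - b$fractions)
}

#' Full resection analysis of replicate tracks
#'
#' Convenience wrapper running the canonical stage order: RPM-scale each
#' replicate, aggregate co-oriented signal around the catalog centers,
#' average replicates, smooth, subtract the far-flank background,
#' peak-normalize, and compute the resection-length distribution.
#'
#' @param counts_list list of raw `StrandedEndCounts` replicates (already
#'   rpm-scaled tracks are used as-is).
#' @param catalog `HotspotCatalog` of centers to aggregate around (typically
#'   the PRDM9-directed set).
#' @param half_width,window_len,background_offset,lo,hi,bin analysis
#'   parameters (defaults: 5,000 bp window, 151-bp Hanning smoothing,
#'   background at +2,500 bp, distribution over (100, 2500] in 100-nt bins).
#' @param smooth_first compute the distribution from the smoothed profile
#'   (default) or from the unsmoothed one (sensitivity checks).
#' @param genotype optional label.
#' @return list with `profile` (smoothed, background-subtracted),
#'   `profile_normalized`, and `distribution`.
#' @export
resection_analysis <- function(counts_list, catalog, half_width = 5000,
                               window_len = 151, background_offset = 2500,
                               lo = 100, hi = 2500, bin = 100,
                               smooth_first = TRUE, genotype = NULL) {
  profs <- lapply(counts_list, function(cn) {
    if (cn$scale == "raw") cn <- to_rpm(cn)
    aggregate_around_centers(cn, catalog, half_width = half_width, co_orient = TRUE)
  })
  avg <- average_profiles(profs)
  sm <- if (smooth_first) smooth_hanning(avg, window_len) else avg
  sub <- subtract_background(sm, background_offset)
  norm <- normalize_to_resection_peak(sub, lo = lo, hi = hi)
  dist <- resection_length_distribution(sub, lo = lo, hi = hi, bin = bin,
                                        genotype = genotype)
  list(profile = sub, profile_normalized = norm, distribution = dist)
}

#' @export
print.ResectionDistribution <- function(x, ...) {
  cat("ResectionDistribution", if (!is.na(x$source_genotype))
    paste0("[", x$source_genotype, "]") else "", ":",
    length(x$fractions), "bins over (", x$bin_edges[1], ",",
    x$bin_edges[length(x$bin_edges)], "] nt\n")
  cat(sprintf("  mean resection length: %.1f nt\n", x$mean_length))
  invisible(x)
}

#' @export
plot.ResectionDistribution <- function(x, ...) {
  mids <- x$bin_edges[-length(x$bin_edges)] + diff(x$bin_edges) / 2
  graphics::barplot(x$fractions, names.arg = mids, space = 0,
                    xlab = "resection length (nt)", ylab = "fraction of signal", ...)
  invisible(x)
}

#' Export a resection distribution as TSV
#'
#' @param dist a `ResectionDistribution`.
#' @param path output path.
#' @export
write_resection_tsv <- function(dist, path) {
  e <- dist$bin_edges
  utils::write.table(
    data.frame(bin_start = e[-length(e)], bin_end = e[-1], fraction = dist$fractions),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
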