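#' Aggregate signal around hotspot centers
#'
#' Builds the average signal profile over a window of `+/- half_width` bp
#' around every hotspot center. Top-strand signal at center offset `+d`
#' contributes to offset `+d`. With `co_orient = TRUE` (the default),
#' bottom-strand signal at `-d` is flipped onto `+d`, so rightward and
#' leftward resection superimpose; with `co_orient = FALSE` the bottom strand
#' contributes at its native offset. The profile value at each offset is the
#' mean over centers (centers whose window runs off a chromosome end
#' contribute zeros beyond the edge and still count).
#'
#' @param counts a `StrandedEndCounts`.
#' @param catalog a `HotspotCatalog`; its chromosomes must exist in the
#'   counts genome.
#' @param half_width window half-width W in bp (profile spans offsets
#'   `-W..W`).
#' @param co_orient flip the bottom strand onto positive offsets.
#' @return an object of class `AggregateProfile` with elements `offsets`,
#'   `values`, `n_centers`, `co_oriented`, `smoothed_window`,
#'   `normalization`.
#' @export
aggregate_around_centers <- function(counts, catalog, half_width = 5000,
                                     co_orient = TRUE) {
  stopifnot(inherits(counts, "StrandedEndCounts"))
  if (half_width <= 0) stop("half_width must be > 0")
  if (nrow(catalog) == 0) stop("catalog is empty")
  bad <- setdiff(unique(catalog$chrom), names(counts$genome$chrom_lengths))
  if (length(bad)) stop("catalog chromosome not in counts genome: ",
                        paste(bad, collapse = ", "))
  W <- as.integer(half_width)
  acc <- numeric(2L * W + 1L)
  for (nm in unique(catalog$chrom)) {
    centers <- catalog$center[catalog$chrom == nm]
    for (strand in c("top", "bottom")) {
      s <- counts[[strand]][[nm]]
      if (!length(s$pos)) next
      for (cc in centers) {
        i1 <- findInterval(cc - W - 1L, s$pos) + 1L
        i2 <- findInterval(cc + W, s$pos)
        if (i2 < i1) next
        d <- s$pos[i1:i2] - cc
        if (strand == "bottom" && co_orient) d <- -d
        idx <- d + W + 1L
        acc[idx] <- acc[idx] + s$count[i1:i2]
      }
    }
  }
  structure(list(
    offsets = seq.int(-W, W),
    values = acc / nrow(catalog),
    n_centers = nrow(catalog),
    co_oriented = co_orient,
    smoothed_window = NULL,
    normalization = counts$scale,
    background_subtracted = FALSE
  ), class = "AggregateProfile")
}

#' Average replicate profiles
#'
#' Pointwise arithmetic mean of profiles with identical offsets,
#' co-orientation, smoothing and normalization state (replicates are
#' averaged at the profile level, after RPM scaling).
#'
#' @param profiles list of `AggregateProfile`s.
#' @return an `AggregateProfile`.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!identical(p$offsets, ref$offsets)) stop("profiles have mismatched offsets")
    if (!identical(p$co_oriented, ref$co_oriented)) stop("mixed co-orientation states")
    if (!identical(p$normalization, ref$normalization)) stop("mixed normalization states")
    if (!identical(p$smoothed_window, ref$smoothed_window)) stop("mixed smoothing states")
    if (!identical(p$n_centers, ref$n_centers)) stop("profiles aggregate different catalogs")
  }
  out <- ref
  out$values <- rowMeans(vapply(profiles, function(p) p$values,
                                numeric(length(ref$values))))
  out
}

#' Hanning (raised-cosine) window coefficients
#'
#' `w[k] = 0.5 * (1 - cos(2*pi*k / (n - 1)))`, `k = 0..n-1`, normalized to
#' unit sum. `n = 1` is the degenerate identity window `[1]`.
#'
#' @param n odd window length.
#' @return numeric vector of length `n` summing to 1.
#' @export
hanning_window <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1 || n %% 2L == 0L) stop("window length must be a positive odd integer")
  if (n == 1L) return(1)
  k <- 0:(n - 1L)
  w <- 0.5 * (1 - cos(2 * pi * k / (n - 1L)))
  w / sum(w)
}

#' Smooth a signal with a Hanning window
#'
#' Convolution with a unit-sum raised-cosine window; the output has the same
#' length as the input. Edges are handled by reflection padding (the signal
#' is mirrored, without repeating the edge sample), which preserves constant
#' signals exactly and avoids artificial decay at profile edges.
#'
#' @param x numeric vector or `AggregateProfile`.
#' @param window_len odd window length, `1 <= window_len <= length(x)`.
#' @return smoothed object of the same type as `x`.
#' @export
smooth_hanning <- function(x, window_len = 151) {
  if (inherits(x, "AggregateProfile")) {
    out <- x
    out$values <- smooth_hanning(x$values, window_len)
    out$smoothed_window <- as.integer(window_len)
    return(out)
  }
  w <- hanning_window(window_len)
  n <- length(x)
  if (window_len > n) stop("window_len must not exceed the signal length")
  if (window_len == 1) return(as.numeric(x))
  h <- (as.integer(window_len) - 1L) %/% 2L
  xp <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  y <- stats::filter(xp, w, method = "convolution", sides = 2)
  as.numeric(y[(h + 1L):(h + n)])
}

# sum sparse counts into consecutive bins anchored at `start`
.bin_sparse <- function(pos, count, start, end, bin_size) {
  nbins <- as.integer(ceiling((end - start) / bin_size))
  v <- numeric(nbins)
  keep <- pos >= start & pos < end
  if (any(keep)) {
    idx <- as.integer((pos[keep] - start) %/% bin_size)
    w <- as.numeric(count[keep])
    o <- order(idx)
    idx <- idx[o]; w <- w[o]
    last <- c(idx[-1] != idx[-length(idx)], TRUE)
    cs <- cumsum(w)
    v[idx[last] + 1L] <- diff(c(0, cs[last]))
  }
  v
}

#' Bin a track or profile and smooth the bins
#'
#' Sums signal into consecutive bins anchored at the interval start (strands
#' summed first when `combine_strands`), then smooths the binned values with
#' a Hanning window of `window_bins` bins. Used for single-locus and
#' PAR-interval views (10-bp / 40-bp bins, 51-bin window).
#'
#' @param x a `StrandedEndCounts` (needs `chrom`, optionally `interval`) or
#'   an `AggregateProfile`.
#' @param bin_size bin width, bp.
#' @param window_bins odd Hanning window length, in bins; `NULL` skips
#'   smoothing.
#' @param combine_strands sum top and bottom strands (counts input only).
#' @param chrom chromosome name (counts input only).
#' @param interval optional `c(start, end)` (0-based half-open); defaults to
#'   the whole chromosome.
#' @return data.frame with `bin_start` and `value` columns (or `top` and
#'   `bottom` when `combine_strands = FALSE`).
#' @export
bin_and_smooth <- function(x, bin_size, window_bins = 51, combine_strands = TRUE,
                           chrom = NULL, interval = NULL) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (inherits(x, "AggregateProfile")) {
    start <- x$offsets[1]
    v <- .bin_sparse(x$offsets, x$values, start, x$offsets[length(x$offsets)] + 1L, bin_size)
    if (!is.null(window_bins)) v <- smooth_hanning(v, window_bins)
    return(data.frame(bin_start = start + bin_size * (seq_along(v) - 1L), value = v))
  }
  stopifnot(inherits(x, "StrandedEndCounts"))
  if (is.null(chrom)) stop("chrom must be given for StrandedEndCounts input")
  if (!chrom %in% names(x$genome$chrom_lengths)) stop("unknown chromosome: ", chrom)
  if (is.null(interval)) interval <- c(0, x$genome$chrom_lengths[[chrom]])
  if (interval[1] < 0 || interval[2] > x$genome$chrom_lengths[[chrom]] ||
      interval[1] >= interval[2])
    stop("interval outside chromosome bounds")
  bt <- .bin_sparse(x$top[[chrom]]$pos, x$top[[chrom]]$count,
                    interval[1], interval[2], bin_size)
  bb <- .bin_sparse(x$bottom[[chrom]]$pos, x$bottom[[chrom]]$count,
                    interval[1], interval[2], bin_size)
  bin_start <- interval[1] + bin_size * (seq_along(bt) - 1L)
  if (combine_strands) {
    v <- bt + bb
    if (!is.null(window_bins)) v <- smooth_hanning(v, window_bins)
    data.frame(bin_start = bin_start, value = v)
  } else {
    if (!is.null(window_bins)) {
      bt <- smooth_hanning(bt, window_bins)
      bb <- smooth_hanning(bb, window_bins)
    }
    data.frame(bin_start = bin_start, top = bt, bottom = bb)
  }
}

#' @export
print.AggregateProfile <- function(x, ...) {
  W <- (length(x$offsets) - 1L) / 2L
  cat("AggregateProfile: +/-", W, "bp around", x$n_centers, "centers",
      if (x$co_oriented) "(co-oriented)" else "(native strands)", "\n")
  cat("  normalization:", x$normalization,
      if (isTRUE(x$background_subtracted)) "(background-subtracted)" else "", "\n")
  if (!is.null(x$smoothed_window))
    cat("  smoothed: ", x$smoothed_window, "-bp Hanning window\n", sep = "")
  invisible(x)
}

#' @export
plot.AggregateProfile <- function(x, ...) {
  plot(x$offsets, x$values, type = "l",
       xlab = "distance from hotspot center (bp)",
       ylab = paste0("signal (", x$normalization, ")"), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Export a profile as TSV
#'
#' @param profile an `AggregateProfile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(data.frame(offset = profile$offsets, value = profile$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
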