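#' Construct a peak set
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `score`.
#' @param provenance `"internal_caller"` or `"imported_narrowPeak"`.
#' @param genome optional `GenomeModel` for bounds checking.
#' @return an object of class `PeakSet` (a sorted data.frame with a
#'   `provenance` attribute).
#' @export
peak_set <- function(peaks, provenance = c("internal_caller", "imported_narrowPeak"),
                     genome = NULL) {
  provenance <- match.arg(provenance)
  peaks <- as.data.frame(peaks)
  if (!all(c("chrom", "start", "end") %in% names(peaks)))
    stop("peaks need columns chrom, start, end")
  if (is.null(peaks$score)) peaks$score <- 0
  peaks <- peaks[c("chrom", "start", "end", "score")]
  peaks$chrom <- as.character(peaks$chrom)
  if (any(peaks$start >= peaks$end)) stop("peaks must have start < end")
  if (any(peaks$start < 0)) stop("peak starts must be >= 0")
  if (!is.null(genome)) {
    bad <- setdiff(unique(peaks$chrom), names(genome$chrom_lengths))
    if (length(bad)) stop("peak chromosome not in genome: ", paste(bad, collapse = ", "))
    if (any(peaks$end > genome$chrom_lengths[peaks$chrom]))
      stop("peak extends beyond chromosome end")
  }
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, class = c("PeakSet", "data.frame"), provenance = provenance)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat("PeakSet (", attr(x, "provenance"), "): ", nrow(x), " peaks\n", sep = "")
  NextMethod()
}

#' Call enrichment peaks with a global Poisson background model
#'
#' A deliberately simple caller used as pipeline plumbing (peaks called with
#' external tools can be brought in via [import_narrowPeak()]). Strands are
#' combined, signal is summed in sliding windows (`window` bp, `step` bp
#' step), each window is scored against a global Poisson rate
#' `lambda = total signal / genome length * window`, p-values are
#' Benjamini-Hochberg adjusted genome-wide, windows with adjusted p below
#' the threshold are retained, and overlapping/adjacent significant windows
#' are fused into peaks scored by `-log10` of the best adjusted p.
#'
#' @param counts a raw-scale `StrandedEndCounts` with nonzero total signal.
#' @param window,step sliding-window geometry, bp (`window` must be a
#'   multiple of `step`).
#' @param q_threshold BH-adjusted p-value cutoff (default 0.01).
#' @return a `PeakSet` with provenance `"internal_caller"`.
#' @export
call_peaks <- function(counts, window = 1000, step = 100, q_threshold = 0.01) {
  stopifnot(inherits(counts, "StrandedEndCounts"))
  if (counts$scale != "raw")
    stop("call_peaks requires raw integer counts (Poisson model)")
  total <- total_signal(counts)
  if (total == 0) stop("empty counts: no signal to call peaks on")
  if (window %% step != 0) stop("window must be a multiple of step")
  k <- as.integer(window / step)
  lambda <- total / genome_length(counts$genome) * window

  win_chrom <- character(0); win_start <- numeric(0); win_count <- numeric(0)
  for (nm in names(counts$genome$chrom_lengths)) {
    len <- counts$genome$chrom_lengths[[nm]]
    nb <- as.integer(len %/% step)
    if (nb < k) next
    bins <- .bin_sparse(counts$top[[nm]]$pos, counts$top[[nm]]$count, 0, nb * step, step) +
      .bin_sparse(counts$bottom[[nm]]$pos, counts$bottom[[nm]]$count, 0, nb * step, step)
    cs <- c(0, cumsum(bins))
    nwin <- nb - k + 1L
    ws <- cs[(k + 1L):(k + nwin)] - cs[1:nwin]
    win_chrom <- c(win_chrom, rep(nm, nwin))
    win_start <- c(win_start, step * (seq_len(nwin) - 1L))
    win_count <- c(win_count, ws)
  }
  p <- stats::ppois(win_count - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  sig <- q < q_threshold
  if (!any(sig))
    return(peak_set(data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0), score = numeric(0)),
                    provenance = "internal_caller"))
  gr <- GenomicRanges::GRanges(
    win_chrom[sig],
    IRanges::IRanges(start = win_start[sig] + 1L, width = window),
    score = -log10(pmax(q[sig], 1e-320))
  )
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  score <- vapply(red$revmap, function(ii) max(gr$score[ii]), numeric(1))
  peak_set(data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                      start = GenomicRanges::start(red) - 1L,
                      end = GenomicRanges::end(red), score = score),
           provenance = "internal_caller", genome = counts$genome)
}

#' Import peaks from a narrowPeak or BED file
#'
#' @param path narrowPeak (BED6+4) or plain BED file.
#' @return a `PeakSet` with provenance `"imported_narrowPeak"`; the score
#'   column is the narrowPeak score field.
#' @export
import_narrowPeak <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[nzchar(lines) & !grepl("^(track|#|browser)", lines)]
  if (!length(data_lines))
    return(peak_set(data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0), score = numeric(0)),
                    provenance = "imported_narrowPeak"))
  fields <- strsplit(data_lines, "\t")
  nf <- lengths(fields)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ok <- length(f) >= 3 && !anyNA(suppressWarnings(as.numeric(f[2:3])))
    if (!ok) {
      lineno <- match(data_lines[i], lines)
      stop("malformed line ", lineno, " in ", path)
    }
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.numeric(vapply(fields, `[`, "", 2L))
  end <- as.numeric(vapply(fields, `[`, "", 3L))
  score <- ifelse(nf >= 5, suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 5) f[5] else "0", ""))), 0)
  score[is.na(score)] <- 0
  peak_set(data.frame(chrom = chrom, start = start, end = end, score = score),
           provenance = "imported_narrowPeak")
}

#' Export peaks as BED or narrowPeak
#'
#' @param peaks a `PeakSet`.
#' @param path output path.
#' @param format `"bed"` (BED6 via rtracklayer) or `"narrowPeak"` (BED6+4).
#' @export
export_peaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "bed") {
    gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
      name = sprintf("peak%d", seq_len(nrow(peaks))),
      score = pmin(pmax(round(peaks$score), 0), 1000))
    rtracklayer::export(gr, path, format = "BED")
  } else {
    df <- data.frame(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
                     format(peaks$end, scientific = FALSE, trim = TRUE),
                     sprintf("peak%d", seq_len(nrow(peaks))),
                     round(peaks$score, 4), ".", round(peaks$score, 4), -1, -1, -1)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Widen peaks and merge the results
#'
#' Grows every peak symmetrically so its total width increases by
#' `widen_bp` (i.e. `widen_bp / 2` per side; set `per_side = TRUE` to grow
#' by `widen_bp` on each side instead), clips to chromosome bounds when a
#' genome is supplied, and merges overlapping or book-ended intervals. A
#' merged peak's score is the maximum of its constituents.
#'
#' @param peaks a `PeakSet`.
#' @param widen_bp total width increase, bp (default 5,000).
#' @param genome optional `GenomeModel` for clipping.
#' @param per_side interpret `widen_bp` as the per-side extension.
#' @return a merged `PeakSet`.
#' @export
widen_and_merge <- function(peaks, widen_bp = 5000, genome = NULL, per_side = FALSE) {
  stopifnot(widen_bp >= 0)
  if (nrow(peaks) == 0) return(peaks)
  half <- if (per_side) widen_bp else widen_bp / 2
  start <- pmax(peaks$start - half, 0)
  end <- peaks$end + half
  if (!is.null(genome)) end <- pmin(end, genome$chrom_lengths[peaks$chrom])
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(start = start + 1L, end = end),
                               score = peaks$score)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)  # merges book-ended runs
  score <- vapply(red$revmap, function(ii) max(gr$score[ii]), numeric(1))
  peak_set(data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                      start = GenomicRanges::start(red) - 1L,
                      end = GenomicRanges::end(red), score = score),
           provenance = attr(peaks, "provenance"), genome = genome)
}

.catalog_granges <- function(catalog) {
  GenomicRanges::GRanges(catalog$chrom,
                         IRanges::IRanges(start = catalog$start + 1L, end = catalog$end))
}

#' Classify peaks by catalog overlap
#'
#' Labels every peak `prdm9_only`, `default_only`, `both` or `neither` by
#' whether it shares at least 1 bp with an interval of the PRDM9-directed
#' and/or the default hotspot catalog (book-ended intervals, sharing zero
#' bases, do not count as overlap). The four categories partition the peak
#' set.
#'
#' @param peaks a `PeakSet` (typically after [widen_and_merge()]).
#' @param prdm9,default_catalog `HotspotCatalog`s.
#' @return an object of class `OverlapSummary` with counts, fractions,
#'   per-peak `labels`, and the classified `peaks`.
#' @export
classify_overlap <- function(peaks, prdm9, default_catalog) {
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  hit_p <- GenomicRanges::countOverlaps(gr, .catalog_granges(prdm9)) > 0
  hit_d <- GenomicRanges::countOverlaps(gr, .catalog_granges(default_catalog)) > 0
  labels <- ifelse(hit_p & hit_d, "both",
                   ifelse(hit_p, "prdm9_only",
                          ifelse(hit_d, "default_only", "neither")))
  n <- nrow(peaks)
  cats <- c("prdm9_only", "default_only", "both", "neither")
  counts <- vapply(cats, function(cc) sum(labels == cc), numeric(1))
  structure(list(
    n_peaks = n,
    n_prdm9_only = counts[["prdm9_only"]],
    n_default_only = counts[["default_only"]],
    n_both = counts[["both"]],
    n_neither = counts[["neither"]],
    fractions = if (n > 0) counts / n else rep(NA_real_, 4),
    labels = labels,
    peaks = peaks
  ), class = "OverlapSummary")
}

#' @export
print.OverlapSummary <- function(x, ...) {
  cat("OverlapSummary:", x$n_peaks, "peaks\n")
  df <- data.frame(count = c(x$n_prdm9_only, x$n_default_only, x$n_both, x$n_neither),
                   fraction = round(x$fractions, 4))
  rownames(df) <- c("prdm9_only", "default_only", "both", "neither")
  print(df)
  invisible(x)
}

# robust per-bp background rate: median of 1-kb bin counts over the genome
.median_background_rate <- function(counts, bin = 1000) {
  meds <- numeric(0)
  for (nm in names(counts$genome$chrom_lengths)) {
    len <- counts$genome$chrom_lengths[[nm]]
    nb <- as.integer(len %/% bin)
    if (nb < 1) next
    b <- .bin_sparse(counts$top[[nm]]$pos, counts$top[[nm]]$count, 0, nb * bin, bin) +
      .bin_sparse(counts$bottom[[nm]]$pos, counts$bottom[[nm]]$count, 0, nb * bin, bin)
    meds <- c(meds, b)
  }
  stats::median(meds) / bin
}

#' Signal-weighted hotspot usage by overlap class
#'
#' Quantifies how the *enriched* signal splits between peak overlap classes:
#' for each classified peak, sums the in-peak signal (both strands), removes
#' the expected background (a robust genome-wide per-bp rate estimated as
#' the median of 1-kb bin counts, times the peak width; clamped at zero),
#' and reports each class's share of the total enrichment. Unlike per-peak
#' count fractions, which saturate once every hotspot of a catalog is
#' detectable, this share tracks the fraction of DSB events at each hotspot
#' class.
#'
#' @param counts the `StrandedEndCounts` the peaks were called from.
#' @param summary an `OverlapSummary` from [classify_overlap()].
#' @return list with `enriched` (named per-class signal), `fractions`
#'   (per-class share), and `default_associated` (share of `default_only`
#'   plus `both`).
#' @export
hotspot_usage <- function(counts, summary) {
  stopifnot(inherits(summary, "OverlapSummary"))
  peaks <- summary$peaks
  bg_rate <- .median_background_rate(counts)
  enr <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    nm <- peaks$chrom[i]
    sig <- 0
    for (strand in c("top", "bottom")) {
      s <- counts[[strand]][[nm]]
      if (!length(s$pos)) next
      i1 <- findInterval(peaks$start[i] - 1L, s$pos) + 1L
      i2 <- findInterval(peaks$end[i] - 1L, s$pos)
      if (i2 >= i1) sig <- sig + sum(s$count[i1:i2])
    }
    enr[i] <- max(sig - bg_rate * (peaks$end[i] - peaks$start[i]), 0)
  }
  cats <- c("prdm9_only", "default_only", "both", "neither")
  by_class <- vapply(cats, function(cc) sum(enr[summary$labels == cc]), numeric(1))
  total <- sum(by_class)
  fr <- if (total > 0) by_class / total else rep(NA_real_, 4)
  names(fr) <- cats
  list(enriched = by_class, fractions = fr,
       default_associated = unname(fr[["default_only"]] + fr[["both"]]))
}

#' Binned, smoothed signal over a genomic interval
#'
#' Combines strands over one interval (e.g. the PAR), bins and
#' Hanning-smooths the signal (delegating to [bin_and_smooth()]), and
#' reports the interval's total signal for between-genotype ratio tests.
#'
#' @param counts a `StrandedEndCounts`.
#' @param interval list/vector with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param bin_size bin width, bp (default 40).
#' @param window_bins Hanning window length in bins (default 51).
#' @return list with `profile` (data.frame `bin_start`, `value`) and `total`
#'   (unsmoothed total signal in the interval, on the track's scale).
#' @export
interval_signal <- function(counts, interval, bin_size = 40, window_bins = 51) {
  interval <- as.list(interval)
  chrom <- interval$chrom
  if (is.null(chrom)) stop("interval needs a chrom field")
  prof <- bin_and_smooth(counts, bin_size = bin_size, window_bins = window_bins,
                         combine_strands = TRUE, chrom = chrom,
                         interval = c(as.numeric(interval$start), as.numeric(interval$end)))
  total <- 0
  for (strand in c("top", "bottom")) {
    s <- counts[[strand]][[chrom]]
    if (!length(s$pos)) next
    keep <- s$pos >= interval$start & s$pos < interval$end
    total <- total + sum(s$count[keep])
  }
  list(profile = prof, total = total)
}
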