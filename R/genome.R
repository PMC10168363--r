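#' Define a genome model
#'
#' A lightweight description of the chromosomes the analysis runs on, with an
#' optional pseudoautosomal-region-like (PAR) interval marking a segment of
#' constitutively elevated DSB activity. All coordinates in the package are
#' 0-based, half-open (BED/bedGraph convention).
#'
#' @param chromosomes either a named numeric vector of chromosome lengths
#'   (bp), or a data.frame with columns `name` and `length`.
#' @param par_interval optional list/vector with fields `chrom`, `start`,
#'   `end` (0-based half-open) marking the PAR-like interval.
#' @return an object of class `GenomeModel` with elements `chrom_lengths`
#'   (named numeric) and `par` (list or `NULL`).
#' @examples
#' gm <- genome_model(c(chr1 = 1e6, chrX = 5e5),
#'                    par_interval = list(chrom = "chrX", start = 4e5, end = 4.5e5))
#' @export
genome_model <- function(chromosomes, par_interval = NULL) {
  if (is.data.frame(chromosomes)) {
    stopifnot(all(c("name", "length") %in% names(chromosomes)))
    lens <- as.numeric(chromosomes$length)
    names(lens) <- as.character(chromosomes$name)
  } else {
    lens <- as.numeric(chromosomes)
    names(lens) <- names(chromosomes)
  }
  if (is.null(names(lens)) || anyNA(names(lens)) || any(names(lens) == ""))
    stop("chromosomes must be named")
  if (anyDuplicated(names(lens)))
    stop("chromosome names must be unique")
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("chromosome lengths must be positive")
  par <- NULL
  if (!is.null(par_interval)) {
    par <- as.list(par_interval)
    stopifnot(all(c("chrom", "start", "end") %in% names(par)))
    par$start <- as.numeric(par$start); par$end <- as.numeric(par$end)
    if (!par$chrom %in% names(lens))
      stop("par_interval chromosome '", par$chrom, "' not in genome")
    if (par$start < 0 || par$end > lens[[par$chrom]] || par$start >= par$end)
      stop("par_interval must lie within its chromosome")
  }
  structure(list(chrom_lengths = lens, par = par), class = "GenomeModel")
}

#' Default synthetic genome
#'
#' Three 4-Mb autosomes plus a 2-Mb "X" carrying a 100-kb PAR-like interval
#' near its distal end. Sized so that a few hundred hotspots can be placed at
#' >= 15 kb spacing, which keeps 5-kb-widened peaks of neighbouring hotspots
#' from merging while the whole pipeline still runs in seconds.
#'
#' @return a `GenomeModel`.
#' @export
default_genome <- function() {
  genome_model(
    c(chr1 = 4e6, chr2 = 4e6, chr3 = 4e6, chrX = 2e6),
    par_interval = list(chrom = "chrX", start = 1.88e6, end = 1.98e6)
  )
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel:", length(x$chrom_lengths), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  for (nm in names(x$chrom_lengths))
    cat("  ", nm, ": ", format(x$chrom_lengths[[nm]], big.mark = ","), " bp\n", sep = "")
  if (!is.null(x$par))
    cat("  PAR-like interval: ", x$par$chrom, ":", x$par$start, "-", x$par$end, "\n", sep = "")
  invisible(x)
}

genome_length <- function(genome) sum(genome$chrom_lengths)

in_par <- function(genome, chrom, pos) {
  if (is.null(genome$par)) return(rep(FALSE, length(pos)))
  chrom == genome$par$chrom & pos >= genome$par$start & pos < genome$par$end
}

#' Construct a hotspot catalog
#'
#' A catalog of DSB hotspots: labelled intervals with a center coordinate, a
#' nonnegative heat score and a category (`"prdm9"` for PRDM9-directed
#' hotspots, `"default"` for promoter/CpG-island default hotspots).
#'
#' @param entries data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `center`, `heat`, `category`.
#' @param genome optional `GenomeModel`; when given, intervals are checked to
#'   lie within it.
#' @return an object of class `HotspotCatalog` (a data.frame).
#' @export
hotspot_catalog <- function(entries, genome = NULL) {
  req <- c("id", "chrom", "start", "end", "center", "heat", "category")
  if (!all(req %in% names(entries)))
    stop("catalog needs columns: ", paste(req, collapse = ", "))
  entries <- as.data.frame(entries)[req]
  entries$id <- as.character(entries$id)
  entries$chrom <- as.character(entries$chrom)
  entries$category <- as.character(entries$category)
  if (anyDuplicated(entries$id)) stop("hotspot ids must be unique")
  if (!all(entries$category %in% c("prdm9", "default")))
    stop("category must be 'prdm9' or 'default'")
  if (any(entries$start >= entries$end)) stop("hotspot intervals must have start < end")
  if (any(entries$center < entries$start | entries$center >= entries$end))
    stop("hotspot centers must lie inside their intervals")
  if (any(entries$heat < 0)) stop("heat scores must be nonnegative")
  if (!is.null(genome)) {
    if (!all(entries$chrom %in% names(genome$chrom_lengths)))
      stop("catalog chromosome not in genome: ",
           paste(setdiff(entries$chrom, names(genome$chrom_lengths)), collapse = ", "))
    lens <- genome$chrom_lengths[entries$chrom]
    if (any(entries$start < 0 | entries$end > lens))
      stop("hotspot interval outside chromosome bounds")
  }
  o <- order(entries$chrom, entries$center)
  entries <- entries[o, , drop = FALSE]
  rownames(entries) <- NULL
  class(entries) <- c("HotspotCatalog", "data.frame")
  entries
}

#' Simulate a hotspot catalog
#'
#' Places PRDM9-directed and default hotspots on a jittered grid with a
#' guaranteed minimum spacing, draws exponentially distributed heat scores
#' once (heats are a property of the catalog and are shared across genotype
#' simulations), and plants a fixed number of PRDM9 hotspots inside the
#' PAR-like interval when the genome has one.
#'
#' @param genome a `GenomeModel`.
#' @param n_prdm9,n_default number of hotspots per category (PAR hotspots
#'   count toward `n_prdm9`).
#' @param n_par number of PRDM9 hotspots planted inside the PAR interval
#'   (0 when the genome has no PAR).
#' @param min_spacing minimum center-to-center distance, bp.
#' @param edge_margin keep-out distance from chromosome ends, bp.
#' @param interval_halfwidth half-width of each hotspot interval, bp.
#' @param heat_rate rate of the exponential heat distribution.
#' @param seed integer seed; the catalog is deterministic given the seed.
#' @return a `HotspotCatalog`.
#' @export
simulate_hotspot_catalog <- function(genome, n_prdm9 = 200, n_default = 200,
                                     n_par = if (is.null(genome$par)) 0L else 5L,
                                     min_spacing = 15000, edge_margin = 10000,
                                     interval_halfwidth = 250, heat_rate = 1,
                                     seed = 1) {
  stopifnot(n_prdm9 >= 0, n_default >= 0, n_par >= 0, n_par <= n_prdm9)
  if (n_par > 0 && is.null(genome$par)) stop("n_par > 0 but genome has no PAR interval")
  set.seed(as.integer(seed))

  grid_place <- function(lo, hi, k) {
    if (k == 0) return(numeric(0))
    step <- (hi - lo) / k
    if (step < min_spacing)
      stop("cannot place ", k, " hotspots in ", hi - lo, " bp at min_spacing ", min_spacing)
    lo + (seq_len(k) - 1) * step + stats::runif(k, 0, step - min_spacing)
  }

  n_auto <- n_prdm9 + n_default - n_par
  # usable span per chromosome (PAR and its spacing buffer excluded)
  usable <- vapply(names(genome$chrom_lengths), function(nm) {
    len <- genome$chrom_lengths[[nm]]
    hi <- len - edge_margin
    if (!is.null(genome$par) && nm == genome$par$chrom)
      hi <- min(hi, genome$par$start - min_spacing)
    max(0, hi - edge_margin)
  }, numeric(1))
  alloc <- round(n_auto * usable / sum(usable))
  # fix rounding so the total matches
  while (sum(alloc) > n_auto) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_auto) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1L

  chroms <- character(0); centers <- numeric(0)
  for (nm in names(genome$chrom_lengths)) {
    len <- genome$chrom_lengths[[nm]]
    hi <- len - edge_margin
    if (!is.null(genome$par) && nm == genome$par$chrom)
      hi <- min(hi, genome$par$start - min_spacing)
    cc <- grid_place(edge_margin, hi, alloc[[nm]])
    chroms <- c(chroms, rep(nm, length(cc))); centers <- c(centers, cc)
  }
  category <- rep("default", n_auto)
  category[sample.int(n_auto, n_prdm9 - n_par)] <- "prdm9"

  if (n_par > 0) {
    pc <- grid_place(genome$par$start + interval_halfwidth,
                     genome$par$end - interval_halfwidth, n_par)
    chroms <- c(chroms, rep(genome$par$chrom, n_par))
    centers <- c(centers, pc)
    category <- c(category, rep("prdm9", n_par))
  }

  centers <- round(centers)
  n <- length(centers)
  heat <- stats::rexp(n, rate = heat_rate)
  o <- order(chroms, centers)
  hotspot_catalog(data.frame(
    id = sprintf("hs%04d", seq_len(n)),
    chrom = chroms[o], start = centers[o] - interval_halfwidth,
    end = centers[o] + interval_halfwidth, center = centers[o],
    heat = heat[o], category = category[o],
    stringsAsFactors = FALSE
  ), genome = genome)
}

#' @export
print.HotspotCatalog <- function(x, ...) {
  cat("HotspotCatalog:", nrow(x), "hotspots (",
      sum(x$category == "prdm9"), "prdm9,", sum(x$category == "default"), "default )\n")
  NextMethod()
}

#' Write a hotspot catalog as BED6
#'
#' The name column carries the category and the score column the heat scaled
#' to integers 0-1000 (relative to the catalog maximum). Centers are not
#' stored; on re-import they are taken as interval midpoints.
#'
#' @param catalog a `HotspotCatalog`.
#' @param path output BED file path.
#' @export
write_catalog_bed <- function(catalog, path) {
  score <- if (nrow(catalog) && max(catalog$heat) > 0)
    as.integer(round(1000 * catalog$heat / max(catalog$heat))) else integer(nrow(catalog))
  gr <- GenomicRanges::GRanges(
    catalog$chrom,
    IRanges::IRanges(start = catalog$start + 1L, end = catalog$end),
    name = catalog$category, score = score
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a hotspot catalog from BED6
#'
#' @param path BED file written by [write_catalog_bed()] (or any BED whose
#'   name column is `prdm9`/`default` and whose score encodes heat).
#' @param genome optional `GenomeModel` for bounds checking.
#' @return a `HotspotCatalog` with ids regenerated and centers at interval
#'   midpoints.
#' @export
read_catalog_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  df <- data.frame(
    id = sprintf("hs%04d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0,
    center = (start0 + end0) %/% 2L,
    heat = if (length(gr)) as.numeric(gr$score) else numeric(0),
    category = if (length(gr)) as.character(gr$name) else character(0),
    stringsAsFactors = FALSE
  )
  hotspot_catalog(df, genome = genome)
}
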