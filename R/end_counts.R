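# Sparse per-strand, per-chromosome count representation: each strand is a
# list (one element per chromosome) of list(pos = 0-based integer positions,
# count = values), positions sorted and unique.

.sparse_normalize <- function(pos, count) {
  stopifnot(length(pos) == length(count))
  if (!length(pos)) return(list(pos = integer(0), count = numeric(0)))
  pos <- as.integer(round(pos))
  count <- as.numeric(count)
  o <- order(pos)
  pos <- pos[o]; count <- count[o]
  last <- c(pos[-1] != pos[-length(pos)], TRUE)  # last entry of each position run
  cs <- cumsum(count)
  total <- diff(c(0, cs[last]))
  keep <- total != 0
  list(pos = pos[last][keep], count = total[keep])
}

.empty_strand <- function(genome) {
  out <- lapply(genome$chrom_lengths, function(l) list(pos = integer(0), count = numeric(0)))
  names(out) <- names(genome$chrom_lengths)
  out
}

#' Construct a stranded end-count track
#'
#' Holds per-base counts of DSB-derived blunted-end positions, one sparse
#' track per strand per chromosome. The top strand carries ends of rightward
#' resection, the bottom strand ends of leftward resection.
#'
#' @param genome a `GenomeModel`.
#' @param top,bottom per-chromosome lists with elements `pos` (0-based
#'   positions) and `count`; missing chromosomes are filled with zeros.
#' @param scale `"raw"` (integer counts) or `"rpm"` (reads per million
#'   mapped).
#' @param total_mapped number of retained reads backing the track (the RPM
#'   denominator).
#' @return an object of class `StrandedEndCounts`.
#' @export
stranded_end_counts <- function(genome, top = NULL, bottom = NULL,
                                scale = c("raw", "rpm"), total_mapped = 0) {
  scale <- match.arg(scale)
  fill <- function(strand) {
    out <- .empty_strand(genome)
    if (!is.null(strand)) {
      bad <- setdiff(names(strand), names(genome$chrom_lengths))
      if (length(bad)) stop("chromosome not in genome: ", paste(bad, collapse = ", "))
      for (nm in names(strand)) {
        s <- .sparse_normalize(strand[[nm]]$pos, strand[[nm]]$count)
        len <- genome$chrom_lengths[[nm]]
        if (length(s$pos) && (min(s$pos) < 0 || max(s$pos) >= len))
          stop("counts outside chromosome bounds on ", nm)
        if (any(s$count < 0)) stop("counts must be nonnegative")
        if (scale == "raw" && any(s$count != round(s$count)))
          stop("raw counts must be integers")
        out[[nm]] <- s
      }
    }
    out
  }
  if (scale == "rpm" && total_mapped <= 0) stop("total_mapped must be > 0 for rpm scale")
  structure(list(genome = genome, top = fill(top), bottom = fill(bottom),
                 scale = scale, total_mapped = as.numeric(total_mapped)),
            class = "StrandedEndCounts")
}

# build raw counts from event vectors (0-based positions)
.counts_from_events <- function(genome, chrom_top, pos_top, chrom_bottom, pos_bottom,
                                total_mapped = length(pos_top) + length(pos_bottom)) {
  mk <- function(chrom, pos) {
    out <- .empty_strand(genome)
    if (length(pos)) {
      sp <- split(pos, chrom)
      for (nm in names(sp)) out[[nm]] <- .sparse_normalize(sp[[nm]], rep(1, length(sp[[nm]])))
    }
    out
  }
  stranded_end_counts(genome, top = mk(chrom_top, pos_top),
                      bottom = mk(chrom_bottom, pos_bottom),
                      scale = "raw", total_mapped = total_mapped)
}

#' Total signal in a track
#'
#' @param counts a `StrandedEndCounts`.
#' @param strand `"both"`, `"top"` or `"bottom"`.
#' @return the sum of all counts.
#' @export
total_signal <- function(counts, strand = c("both", "top", "bottom")) {
  strand <- match.arg(strand)
  s <- 0
  if (strand %in% c("both", "top"))
    s <- s + sum(vapply(counts$top, function(x) sum(x$count), numeric(1)))
  if (strand %in% c("both", "bottom"))
    s <- s + sum(vapply(counts$bottom, function(x) sum(x$count), numeric(1)))
  s
}

#' @export
print.StrandedEndCounts <- function(x, ...) {
  cat("StrandedEndCounts (", x$scale, "): ",
      format(total_signal(x, "top"), big.mark = ","), " top + ",
      format(total_signal(x, "bottom"), big.mark = ","), " bottom counts, ",
      "total_mapped = ", format(x$total_mapped, big.mark = ","), "\n", sep = "")
  print(x$genome)
  invisible(x)
}

#' Extract strand-specific end counts from mapped alignments
#'
#' Counts one blunted DSB end per retained read-1 primary alignment at the
#' base immediately *outward* of the read's 5' alignment end: a forward
#' read 1 with 0-based leftmost aligned base `p` adds a top-strand count at
#' `p - 1`; a reverse read 1 with rightmost aligned base `q` adds a
#' bottom-strand count at `q + 1`. This is the last nucleotide of the ssDNA
#' tail removed by the exonucleases. Set `adjacent_base = FALSE` to count the
#' 5' aligned base itself (a 1-bp convention shift that is invisible at the
#' 100-bp scales of the downstream statistics).
#'
#' Retained alignments are properly paired, first-in-pair, primary,
#' non-supplementary, with MAPQ >= `min_mapq`. Ends falling outside
#' chromosome bounds are dropped with a warning. `total_mapped` is the number
#' of retained read-1 alignments (the RPM denominator).
#'
#' @param bam path to a BAM file of mapped paired-end alignments.
#' @param genome a `GenomeModel`; alignment chromosomes must all be present.
#' @param min_mapq minimum mapping quality (default 20).
#' @param adjacent_base count one base outward of the 5' end (default) or the
#'   5' base itself.
#' @return a raw-scale `StrandedEndCounts`.
#' @export
extract_end_counts <- function(bam, genome, min_mapq = 20, adjacent_base = TRUE) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isFirstMateRead = TRUE,
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq,
                                   what = c("rname", "strand", "pos", "cigar"))
  aln <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(aln$pos)
  if (n == 0)
    return(stranded_end_counts(genome, scale = "raw", total_mapped = 0))
  chrom <- as.character(aln$rname)
  bad <- setdiff(unique(chrom), names(genome$chrom_lengths))
  if (length(bad))
    stop("alignment chromosome not in genome model: ", paste(bad, collapse = ", "))
  fwd <- as.character(aln$strand) == "+"
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
  shift <- if (adjacent_base) 1L else 0L
  # 0-based positions of the counted base
  end_top <- (aln$pos[fwd] - 1L) - shift
  end_bot <- (aln$pos[!fwd] - 1L + width[!fwd] - 1L) + shift
  lens <- genome$chrom_lengths
  ok_top <- end_top >= 0 & end_top < lens[chrom[fwd]]
  ok_bot <- end_bot >= 0 & end_bot < lens[chrom[!fwd]]
  dropped <- sum(!ok_top) + sum(!ok_bot)
  if (dropped > 0)
    warning(dropped, " end position(s) fell outside chromosome bounds and were dropped")
  .counts_from_events(genome,
                      chrom_top = chrom[fwd][ok_top], pos_top = end_top[ok_top],
                      chrom_bottom = chrom[!fwd][ok_bot], pos_bottom = end_bot[ok_bot],
                      total_mapped = n)
}

#' Scale counts to reads per million mapped reads
#'
#' Multiplies every count by `1e6 / total_mapped`. The input must be raw;
#' normalizing twice is an error.
#'
#' @param counts a raw `StrandedEndCounts` with `total_mapped > 0`.
#' @return an rpm-scale `StrandedEndCounts`; the input is not modified.
#' @export
to_rpm <- function(counts) {
  stopifnot(inherits(counts, "StrandedEndCounts"))
  if (counts$scale == "rpm") stop("counts are already rpm-scaled")
  if (counts$total_mapped <= 0) stop("total_mapped must be > 0 to compute RPM")
  f <- 1e6 / counts$total_mapped
  scale_strand <- function(strand)
    lapply(strand, function(x) list(pos = x$pos, count = x$count * f))
  out <- counts
  out$top <- scale_strand(counts$top)
  out$bottom <- scale_strand(counts$bottom)
  out$scale <- "rpm"
  out
}

#' Pool replicate tracks
#'
#' Sums raw counts across replicates (for peak calling on the combined
#' evidence); `total_mapped` is summed.
#'
#' @param counts_list list of raw `StrandedEndCounts` on the same genome.
#' @return a raw `StrandedEndCounts`.
#' @export
pool_counts <- function(counts_list) {
  stopifnot(length(counts_list) >= 1)
  if (any(vapply(counts_list, function(x) x$scale, "") != "raw"))
    stop("pool_counts expects raw counts")
  genome <- counts_list[[1]]$genome
  merge_strand <- function(which_strand) {
    out <- .empty_strand(genome)
    for (nm in names(out)) {
      pos <- unlist(lapply(counts_list, function(x) x[[which_strand]][[nm]]$pos))
      cnt <- unlist(lapply(counts_list, function(x) x[[which_strand]][[nm]]$count))
      out[[nm]] <- .sparse_normalize(pos, cnt)
    }
    out
  }
  stranded_end_counts(genome, top = merge_strand("top"), bottom = merge_strand("bottom"),
                      scale = "raw",
                      total_mapped = sum(vapply(counts_list, function(x) x$total_mapped,
                                                numeric(1))))
}

# ---- bedGraph IO ------------------------------------------------------------

.strand_to_granges <- function(strand, genome) {
  si <- GenomeInfoDb::Seqinfo(names(genome$chrom_lengths),
                              as.integer(genome$chrom_lengths))
  grs <- lapply(names(strand), function(nm) {
    s <- strand[[nm]]
    if (!length(s$pos)) return(NULL)
    # run-length merge adjacent equal-valued positions
    n <- length(s$pos)
    new_run <- c(TRUE, diff(s$pos) != 1L | s$count[-1] != s$count[-n])
    run_id <- cumsum(new_run)
    starts <- s$pos[new_run]
    ends <- s$pos[cumsum(tabulate(run_id))]  # last pos of each run
    GenomicRanges::GRanges(nm, IRanges::IRanges(start = starts + 1L, end = ends + 1L),
                           score = s$count[new_run], seqinfo = si)
  })
  grs <- grs[!vapply(grs, is.null, logical(1))]
  if (!length(grs)) return(GenomicRanges::GRanges())
  do.call(c, grs)
}

#' Write a stranded track as a bedGraph pair
#'
#' Writes two bedGraph files, `<stem>.top.bedgraph` and
#' `<stem>.bottom.bedgraph` (0-based half-open intervals; adjacent positions
#' with equal value are run-length merged). Empty strands yield a
#' header-only file.
#'
#' @param counts a `StrandedEndCounts`.
#' @param stem output path stem.
#' @return the two file paths, invisibly.
#' @export
write_bedgraph_pair <- function(counts, stem) {
  paths <- paste0(stem, c(".top.bedgraph", ".bottom.bedgraph"))
  for (i in 1:2) {
    gr <- .strand_to_granges(if (i == 1) counts$top else counts$bottom, counts$genome)
    if (length(gr) == 0) {
      writeLines("track type=bedGraph", paths[i])
    } else {
      rtracklayer::export(gr, paths[i], format = "bedGraph")
    }
  }
  invisible(paths)
}

.find_malformed_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || grepl("^(track|#|browser)", ln)) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) < 4 || anyNA(suppressWarnings(as.numeric(f[2:4]))))
      return(i)
  }
  NA_integer_
}

.import_bedgraph_track <- function(path, genome) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) {
      bad <- .find_malformed_line(path)
      if (!is.na(bad))
        stop("malformed bedGraph line ", bad, " in ", path, call. = FALSE)
      stop("failed to read bedGraph ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  out <- .empty_strand(genome)
  if (!length(gr)) return(out)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(chrom), names(genome$chrom_lengths))
  if (length(bad)) stop("bedGraph chromosome not in genome model: ", paste(bad, collapse = ", "))
  start0 <- GenomicRanges::start(gr) - 1L
  w <- GenomicRanges::width(gr)
  pos <- sequence(w, from = start0)  # expand intervals to per-base positions
  cnt <- rep(as.numeric(gr$score), w)
  sp_pos <- split(pos, rep(chrom, w))
  sp_cnt <- split(cnt, rep(chrom, w))
  for (nm in names(sp_pos)) out[[nm]] <- .sparse_normalize(sp_pos[[nm]], sp_cnt[[nm]])
  out
}

#' Read a stranded track from a bedGraph pair
#'
#' Reads `<stem>.top.bedgraph` and `<stem>.bottom.bedgraph` and re-expands
#' run-length-merged intervals to per-base counts. The round trip through
#' [write_bedgraph_pair()] is lossless.
#'
#' @param stem path stem, as given to [write_bedgraph_pair()].
#' @param genome a `GenomeModel`.
#' @param scale `"raw"` or `"rpm"` (bedGraph carries no metadata, so the
#'   caller states which scale the track is on).
#' @param total_mapped RPM denominator; defaults to the total count for raw
#'   tracks and must be supplied for rpm tracks.
#' @return a `StrandedEndCounts`.
#' @export
read_bedgraph_pair <- function(stem, genome, scale = c("raw", "rpm"),
                               total_mapped = NULL) {
  scale <- match.arg(scale)
  top <- .import_bedgraph_track(paste0(stem, ".top.bedgraph"), genome)
  bottom <- .import_bedgraph_track(paste0(stem, ".bottom.bedgraph"), genome)
  tot <- sum(vapply(c(top, bottom), function(x) sum(x$count), numeric(1)))
  if (is.null(total_mapped)) {
    if (scale == "rpm") stop("total_mapped must be given for rpm tracks")
    total_mapped <- tot
  }
  stranded_end_counts(genome, top = top, bottom = bottom, scale = scale,
                      total_mapped = total_mapped)
}
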