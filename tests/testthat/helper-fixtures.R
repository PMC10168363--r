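# Small deterministic fixtures and brute-force oracles used across tests.

tiny_genome <- function() {
  genome_model(c(chrA = 1e6, chrB = 1e6, chrX = 5e5),
               par_interval = list(chrom = "chrX", start = 4e5, end = 4.8e5))
}

tiny_catalog <- function(genome = tiny_genome(), seed = 42,
                         n_prdm9 = 40, n_default = 40, n_par = 3) {
  simulate_hotspot_catalog(genome, n_prdm9 = n_prdm9, n_default = n_default,
                           n_par = n_par, seed = seed)
}

split_catalog <- function(catalog) {
  keep_class <- function(df) { class(df) <- class(catalog); df }
  list(prdm9 = keep_class(catalog[catalog$category == "prdm9", , drop = FALSE]),
       default = keep_class(catalog[catalog$category == "default", , drop = FALSE]))
}

# counts object from explicit per-strand position/count vectors on one chromosome
counts_1chr <- function(len = 1e4, chrom = "chrT",
                        top_pos = integer(0), top_count = numeric(0),
                        bottom_pos = integer(0), bottom_count = numeric(0),
                        scale = "raw", total_mapped = sum(top_count) + sum(bottom_count)) {
  gm <- genome_model(stats::setNames(len, chrom))
  top <- list(list(pos = top_pos, count = top_count)); names(top) <- chrom
  bottom <- list(list(pos = bottom_pos, count = bottom_count)); names(bottom) <- chrom
  stranded_end_counts(gm, top = top, bottom = bottom, scale = scale,
                      total_mapped = total_mapped)
}

# ---- SAM fixture ------------------------------------------------------------

# One read-1 alignment per record. flag 99 = paired,proper,mate-reverse,first
# (forward); flag 83 = paired,proper,reverse,first.
sam_record <- function(qname, chrom, pos1, mapq, width = 10L, reverse = FALSE,
                       flag = NULL) {
  if (is.null(flag)) flag <- if (reverse) 83L else 99L
  paste(qname, flag, chrom, pos1, mapq, paste0(width, "M"), "=", pos1, 0,
        paste(rep("A", width), collapse = ""),
        paste(rep("I", width), collapse = ""), sep = "\t")
}

write_sam_bam <- function(records, genome, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("sambam")
    dir.create(dir)
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chrom_lengths),
                      as.integer(genome$chrom_lengths)))
  sam <- file.path(dir, "fixture.sam")
  if (length(records)) {
    chrom <- vapply(strsplit(records, "\t"), `[`, "", 3L)
    pos <- as.integer(vapply(strsplit(records, "\t"), `[`, "", 4L))
    records <- records[order(match(chrom, names(genome$chrom_lengths)), pos)]
  }
  writeLines(c(header, records), sam)
  Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE)
}

# independent per-read extraction oracle: loops over the SAM text records and
# returns dense per-base count vectors per strand and chromosome
sam_extraction_oracle <- function(records, genome, min_mapq = 20) {
  dense <- function() lapply(genome$chrom_lengths, function(l) numeric(l))
  top <- dense(); bottom <- dense(); retained <- 0L
  for (rec in records) {
    f <- strsplit(rec, "\t")[[1]]
    flag <- as.integer(f[2]); mapq <- as.integer(f[5])
    if (bitwAnd(flag, 1L) == 0 || bitwAnd(flag, 2L) == 0) next   # paired & proper
    if (bitwAnd(flag, 64L) == 0) next                            # first in pair
    if (bitwAnd(flag, 4L + 256L + 2048L) != 0) next              # mapped primary
    if (mapq < min_mapq) next
    retained <- retained + 1L
    chrom <- f[3]; pos0 <- as.integer(f[4]) - 1L
    width <- as.integer(sub("M", "", f[6]))
    len <- genome$chrom_lengths[[chrom]]
    if (bitwAnd(flag, 16L) == 0) {
      p <- pos0 - 1L                       # one base left of the 5' end
      if (p >= 0 && p < len) top[[chrom]][p + 1L] <- top[[chrom]][p + 1L] + 1
    } else {
      q <- pos0 + width                    # one base right of the 3'-most base
      if (q >= 0 && q < len) bottom[[chrom]][q + 1L] <- bottom[[chrom]][q + 1L] + 1
    }
  }
  list(top = top, bottom = bottom, retained = retained)
}

# dense per-base matrix of a counts object for one chromosome
dense_strand <- function(counts, chrom, strand) {
  len <- counts$genome$chrom_lengths[[chrom]]
  v <- numeric(len)
  s <- counts[[strand]][[chrom]]
  if (length(s$pos)) v[s$pos + 1L] <- s$count
  v
}

# brute-force aggregation oracle: double loop over (center, offset)
aggregate_oracle <- function(counts, catalog, W, co_orient = TRUE) {
  acc <- numeric(2 * W + 1)
  for (i in seq_len(nrow(catalog))) {
    chrom <- catalog$chrom[i]; cc <- catalog$center[i]
    len <- counts$genome$chrom_lengths[[chrom]]
    top <- dense_strand(counts, chrom, "top")
    bot <- dense_strand(counts, chrom, "bottom")
    for (d in -W:W) {
      pt <- cc + d
      if (pt >= 0 && pt < len) acc[d + W + 1] <- acc[d + W + 1] + top[pt + 1]
      pb <- if (co_orient) cc - d else cc + d
      if (pb >= 0 && pb < len) acc[d + W + 1] <- acc[d + W + 1] + bot[pb + 1]
    }
  }
  acc / nrow(catalog)
}

# direct-summation Hanning convolution oracle with reflection padding
hanning_oracle <- function(x, wl) {
  if (wl == 1) return(x)
  k <- 0:(wl - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / (wl - 1)))
  w <- w / sum(w)
  h <- (wl - 1) / 2
  n <- length(x)
  xp <- c(rev(x[2:(h + 1)]), x, rev(x[(n - h):(n - 1)]))
  vapply(seq_len(n), function(i) sum(w * xp[i:(i + wl - 1)]), numeric(1))
}

# sort-and-sweep interval merge oracle (0-based half-open, merges book-ended)
merge_oracle <- function(df) {
  out <- NULL
  for (nm in sort(unique(df$chrom))) {
    d <- df[df$chrom == nm, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cur <- d[1, ]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur$end) {
        cur$end <- max(cur$end, d$end[i])
        cur$score <- max(cur$score, d$score[i])
      } else {
        out <- rbind(out, cur); cur <- d[i, ]
      }
    }
    out <- rbind(out, cur)
  }
  rownames(out) <- NULL
  out
}

# all-pairs >=1 bp overlap oracle (0-based half-open)
overlap_oracle <- function(peaks, catalog) {
  vapply(seq_len(nrow(peaks)), function(i) {
    any(catalog$chrom == peaks$chrom[i] &
          catalog$start < peaks$end[i] & peaks$start[i] < catalog$end)
  }, logical(1))
}

in_par_test <- function(genome, chrom, pos)
  chrom == genome$par$chrom & pos >= genome$par$start & pos < genome$par$end
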