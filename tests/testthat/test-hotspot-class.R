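test_that("the Poisson caller controls discoveries under a uniform null", {
  gm <- genome_model(c(chr1 = 1e6))
  cat0 <- hotspot_catalog(data.frame(id = "h", chrom = "chr1", start = 1,
                                     end = 2, center = 1, heat = 1,
                                     category = "prdm9"), genome = gm)
  n_windows <- (1e6 / 100) - 9   # 1-kb windows at 100-bp step
  discoveries <- vapply(1:20, function(s) {
    cfg <- genotype_config("null", total_dsb_events = 0, default_weight = 0,
                           background_rate = 0.01, n_replicates = 1, seed = 7000 + s)
    sim <- simulate_dataset(gm, cat0, cfg)
    nrow(call_peaks(sim$counts[[1]]))
  }, numeric(1))
  expect_lte(mean(discoveries), 0.01 * n_windows)
  expect_lte(stats::median(discoveries), 1)  # BH under the null: almost never fires
})

test_that("a single read pile on empty background yields exactly one peak", {
  cn <- counts_1chr(len = 1e5, top_pos = 50000L, top_count = 500)
  pk <- call_peaks(cn)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start[1] <= 50000 && pk$end[1] > 50000)
  expect_equal(attr(pk, "provenance"), "internal_caller")

  expect_error(call_peaks(counts_1chr(len = 1e5)), "empty")
  expect_error(call_peaks(to_rpm(counts_1chr(len = 1e5, top_pos = 1L,
                                             top_count = 10))), "raw")
})

test_that("the caller recovers the hottest planted hotspots", {
  gm <- tiny_genome()
  cat_ <- tiny_catalog(gm)
  cfg <- make_genotype_preset("wildtype", total_dsb_events = 60000L, seed = 88,
                              n_replicates = 1)
  sim <- simulate_dataset(gm, cat_, cfg)
  peaks <- widen_and_merge(call_peaks(sim$counts[[1]]), genome = gm)

  # effective heat = the rate at which the generator samples each hotspot
  w_cat <- ifelse(cat_$category == "prdm9", cfg$prdm9_weight, cfg$default_weight)
  w_par <- ifelse(in_par_test(gm, cat_$chrom, cat_$center), cfg$par_boost, 1)
  eff <- cat_$heat * w_cat * w_par
  hottest <- order(eff, decreasing = TRUE)[seq_len(min(40, nrow(cat_)))]
  hit <- vapply(hottest, function(i)
    any(peaks$chrom == cat_$chrom[i] & peaks$start < cat_$end[i] &
          cat_$start[i] < peaks$end), logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("narrowPeak import/export round-trips coordinates exactly", {
  dir <- withr::local_tempdir()
  set.seed(11)
  pk <- peak_set(data.frame(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                            start = s <- sample.int(1e5, 30),
                            end = s + sample.int(5000, 30),
                            score = round(runif(30) * 100, 4)))
  path <- file.path(dir, "peaks.narrowPeak")
  export_peaks(pk, path, format = "narrowPeak")
  back <- import_narrowPeak(path)
  expect_equal(back$chrom, pk$chrom)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$score, pk$score)
  expect_equal(attr(back, "provenance"), "imported_narrowPeak")

  # byte-level: re-exporting the imported set reproduces the file
  path2 <- file.path(dir, "peaks2.narrowPeak")
  export_peaks(back, path2, format = "narrowPeak")
  expect_identical(readLines(path), readLines(path2))

  # empty file -> empty set
  empty <- file.path(dir, "empty.narrowPeak")
  writeLines(character(0), empty)
  expect_equal(nrow(import_narrowPeak(empty)), 0)

  # malformed line reported with its number
  badf <- file.path(dir, "bad.narrowPeak")
  writeLines(c("chr1\t10\t20\tp1\t5\t.", "chr1\tnope"), badf)
  expect_error(import_narrowPeak(badf), "line 2")
})

test_that("widen-and-merge matches arithmetic and the sort-and-sweep oracle", {
  gm <- genome_model(c(chr1 = 1e6, chr2 = 1e6))

  # single peak (10,000-10,300) widened by 5 kb total -> (7,500-12,800)
  one <- peak_set(data.frame(chrom = "chr1", start = 10000, end = 10300, score = 1))
  w1 <- widen_and_merge(one, 5000)
  expect_equal(c(w1$start, w1$end), c(7500, 12800))

  # peaks 12 kb apart stay separate; 4 kb apart merge
  far <- peak_set(data.frame(chrom = "chr1", start = c(10000, 22300),
                             end = c(10300, 22600), score = 1:2))
  expect_equal(nrow(widen_and_merge(far, 5000)), 2)
  near <- peak_set(data.frame(chrom = "chr1", start = c(10000, 14300),
                              end = c(10300, 14600), score = 1:2))
  m <- widen_and_merge(near, 5000)
  expect_equal(nrow(m), 1)
  expect_equal(m$score, 2)   # merged score is the max of constituents

  # book-ended intervals merge even without widening
  be <- peak_set(data.frame(chrom = "chr1", start = c(100, 200), end = c(200, 300),
                            score = c(1, 5)))
  expect_equal(nrow(widen_and_merge(be, 0)), 1)

  # idempotent at widen 0 on an already-merged set
  set.seed(23)
  rnd <- peak_set(data.frame(chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                             start = s <- sample.int(9e5, 200),
                             end = s + sample.int(20000, 200),
                             score = runif(200)))
  merged <- widen_and_merge(rnd, 0)
  expect_equal(as.data.frame(widen_and_merge(merged, 0)), as.data.frame(merged))

  # 200 random intervals vs the brute-force merge oracle
  oracle <- merge_oracle(as.data.frame(rnd))
  expect_equal(merged$start, oracle$start)
  expect_equal(merged$end, oracle$end)
  expect_equal(merged$score, oracle$score)

  # per-side widening doubles the growth
  wps <- widen_and_merge(one, 5000, per_side = TRUE)
  expect_equal(c(wps$start, wps$end), c(5000, 15300))

  # clipping at chromosome bounds
  edge <- peak_set(data.frame(chrom = "chr1", start = 1000, end = 999000, score = 1))
  we <- widen_and_merge(edge, 5000, genome = gm)
  expect_equal(c(we$start, we$end), c(0, 1e6))
})

test_that("overlap classification matches the all-pairs oracle and partitions peaks", {
  gm <- genome_model(c(chr1 = 1e6))
  mkcat <- function(starts, width = 500, category = "prdm9")
    hotspot_catalog(data.frame(id = sprintf("%s%03d", category, seq_along(starts)),
                               chrom = "chr1", start = starts, end = starts + width,
                               center = starts + width / 2, heat = 1,
                               category = category))
  prdm9 <- mkcat(seq(10000, 200000, by = 10000))
  default <- mkcat(seq(305000, 400000, by = 10000), category = "default")

  # peaks identical to the prdm9 intervals, disjoint from default
  pk_p <- peak_set(data.frame(chrom = prdm9$chrom, start = prdm9$start,
                              end = prdm9$end, score = 0))
  ov <- classify_overlap(pk_p, prdm9, default)
  expect_equal(unname(ov$fractions), c(1, 0, 0, 0))

  # disjoint from both
  pk_n <- peak_set(data.frame(chrom = "chr1", start = 800000, end = 800500, score = 0))
  expect_equal(classify_overlap(pk_n, prdm9, default)$n_neither, 1)

  # book-ended (0 shared bp) does not count as overlap
  pk_b <- peak_set(data.frame(chrom = "chr1", start = prdm9$end[1],
                              end = prdm9$end[1] + 100, score = 0))
  expect_equal(classify_overlap(pk_b, prdm9, default)$n_neither, 1)
  # ...but a single shared base does
  pk_1 <- peak_set(data.frame(chrom = "chr1", start = prdm9$end[1] - 1,
                              end = prdm9$end[1] + 100, score = 0))
  expect_equal(classify_overlap(pk_1, prdm9, default)$n_prdm9_only, 1)

  # 50 random peaks vs two random catalogs: exhaustive intersection oracle
  set.seed(77)
  pk_r <- peak_set(data.frame(chrom = "chr1", start = s <- sample.int(9e5, 50),
                              end = s + sample.int(20000, 50), score = 0))
  ov_r <- classify_overlap(pk_r, prdm9, default)
  hit_p <- overlap_oracle(pk_r, prdm9)
  hit_d <- overlap_oracle(pk_r, default)
  oracle_lab <- ifelse(hit_p & hit_d, "both",
                       ifelse(hit_p, "prdm9_only",
                              ifelse(hit_d, "default_only", "neither")))
  expect_equal(ov_r$labels, oracle_lab)

  # partition: categories are mutually exclusive and exhaustive
  expect_equal(ov_r$n_prdm9_only + ov_r$n_default_only + ov_r$n_both + ov_r$n_neither,
               ov_r$n_peaks)
  expect_equal(sum(ov_r$fractions), 1, tolerance = 1e-12)
})

test_that("interval signal totals and bins match a histogram oracle", {
  gm <- tiny_genome()
  z <- interval_signal(stranded_end_counts(gm), gm$par)
  expect_equal(z$total, 0)
  expect_true(all(z$profile$value == 0))

  cat_ <- tiny_catalog(gm)
  sim <- simulate_dataset(gm, cat_, make_genotype_preset("wildtype",
                                                         total_dsb_events = 20000L,
                                                         seed = 66, n_replicates = 1))
  cn <- sim$counts[[1]]
  res <- interval_signal(cn, gm$par, bin_size = 40, window_bins = 51)
  dense <- dense_strand(cn, "chrX", "top") + dense_strand(cn, "chrX", "bottom")
  in_par_v <- dense[(gm$par$start + 1):gm$par$end]
  expect_equal(res$total, sum(in_par_v))
  oracle_bins <- colSums(matrix(in_par_v, nrow = 40))
  expect_equal(res$profile$value, hanning_oracle(unname(oracle_bins), 51),
               tolerance = 1e-9)
})

test_that("usage fractions track the planted category split", {
  gm <- tiny_genome()
  cat_ <- tiny_catalog(gm)
  sc <- split_catalog(cat_)
  cfg <- genotype_config("mix", total_dsb_events = 60000, default_weight = 0.25,
                         par_boost = 1, background_rate = 0.005,
                         n_replicates = 1, seed = 909)
  sim <- simulate_dataset(gm, cat_, cfg)
  pooled <- sim$counts[[1]]
  ov <- classify_overlap(widen_and_merge(call_peaks(pooled), genome = gm),
                         sc$prdm9, sc$default)
  us <- hotspot_usage(pooled, ov)
  expect_true(abs(us$default_associated - 0.25) <= 0.05)
  expect_equal(sum(us$fractions), 1, tolerance = 1e-9)
})
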