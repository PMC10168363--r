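test_that("genotype presets encode the designed genotype contrasts", {
  expect_error(make_genotype_preset("nosuch"), "valid presets")

  wt <- make_genotype_preset("wildtype")
  ea <- make_genotype_preset("ankrd31_EA")
  eon <- make_genotype_preset("ankrd31_EA_over_null")
  dc <- make_genotype_preset("ankrd31_dC")
  nul <- make_genotype_preset("ankrd31_null")
  spo <- make_genotype_preset("spo11_null")

  # background-only control emits no DSB events
  expect_identical(spo$total_dsb_events, 0L)

  # default-usage ordering: null = dC > EA/- > EA > wildtype (the minimum)
  expect_identical(nul$default_weight, dc$default_weight)
  expect_gt(nul$default_weight, eon$default_weight)
  expect_gt(eon$default_weight, ea$default_weight)
  expect_gt(ea$default_weight, wt$default_weight)
  ws <- vapply(c("wildtype", "ankrd31_EA", "ankrd31_EA_over_null", "ankrd31_dC",
                 "ankrd31_null"), function(p) make_genotype_preset(p)$default_weight,
               numeric(1))
  expect_identical(unname(which.min(ws)), 1L)

  # PAR boost: wildtype >> null ~ 0; wildtype boost is a real boost
  expect_gt(wt$par_boost, 1)
  expect_identical(nul$par_boost, 0)
  expect_identical(dc$par_boost, 0)

  # resection shortening: null and dC sit 100 nt below wild type
  expect_equal(wt$resection_mean - nul$resection_mean, 100)
  expect_equal(wt$resection_mean - dc$resection_mean, 100)

  # weights always complement
  expect_equal(wt$prdm9_weight + wt$default_weight, 1)
})

test_that("null generator and determinism contracts hold", {
  gm <- tiny_genome()
  cat_ <- tiny_catalog(gm)

  cfg0 <- genotype_config("null", total_dsb_events = 0, default_weight = 0.5,
                          background_rate = 0, n_replicates = 2, seed = 9)
  sim0 <- simulate_dataset(gm, cat_, cfg0)
  expect_equal(total_signal(sim0$counts[[1]]), 0)
  expect_equal(total_signal(sim0$counts[[2]]), 0)
  expect_true(all(sim0$truth$per_hotspot_events == 0))
  expect_equal(sim0$truth$total_reads, 0)

  cfg <- make_genotype_preset("wildtype", total_dsb_events = 5000L, seed = 21)
  a <- simulate_dataset(gm, cat_, cfg)
  b <- simulate_dataset(gm, cat_, cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)

  # replicates are distinct draws
  expect_false(identical(a$counts[[1]], a$counts[[2]]))

  # events with an empty catalog is an error
  empty_cat <- hotspot_catalog(data.frame(id = character(0), chrom = character(0),
                                          start = numeric(0), end = numeric(0),
                                          center = numeric(0), heat = numeric(0),
                                          category = character(0)))
  expect_error(simulate_dataset(gm, empty_cat, cfg), "empty")
})

test_that("truth record reconciles exactly with emitted reads", {
  gm <- tiny_genome()
  cat_ <- tiny_catalog(gm)
  cfg <- make_genotype_preset("ankrd31_null", total_dsb_events = 20000L, seed = 4)
  sim <- simulate_dataset(gm, cat_, cfg)

  emitted <- sum(vapply(sim$counts, total_signal, numeric(1)))
  tr <- sim$truth
  expect_equal(emitted, tr$total_reads)
  expect_equal(sum(tr$per_hotspot_events) + tr$n_central + tr$n_background,
               tr$total_reads)
  expect_equal(tr$realized_mean_resection, mean(tr$realized_resection_lengths))

  # per replicate too
  for (r in 1:2) {
    rep <- tr$replicates[[r]]
    expect_equal(total_signal(sim$counts[[r]]), rep$total_reads)
    expect_equal(sum(rep$per_hotspot_events) + rep$n_central + rep$n_background,
                 rep$total_reads)
  }

  # resection geometry: every realized length respects the hard minimum
  expect_true(all(tr$realized_resection_lengths >= cfg$resection_min))
})

test_that("hotspot sampling matches a multinomial oracle on equal-heat hotspots", {
  gm <- genome_model(c(chr1 = 1e6))
  cat_ <- hotspot_catalog(data.frame(
    id = sprintf("h%02d", 1:10), chrom = "chr1",
    start = seq(50e3, 950e3, by = 1e5) - 250,
    end = seq(50e3, 950e3, by = 1e5) + 250,
    center = seq(50e3, 950e3, by = 1e5),
    heat = 1, category = "prdm9"), genome = gm)
  cfg <- genotype_config("flat", total_dsb_events = 10000, default_weight = 0,
                         central_fraction = 0, background_rate = 0,
                         n_replicates = 1, seed = 77)
  sim <- simulate_dataset(gm, cat_, cfg)
  ev <- sim$truth$per_hotspot_events
  expect_equal(sum(ev), 10000)

  # each hotspot within the Poisson 99% band around 1,000
  band <- qpois(c(0.005, 0.995), 1000)
  expect_true(all(ev >= band[1] & ev <= band[2]))

  # independent multinomial oracle: chi-square GOF against equal probabilities
  gof <- suppressWarnings(chisq.test(as.vector(ev), p = rep(0.1, 10)))
  expect_gt(gof$p.value, 1e-3)
})

test_that("strand totals are binomially symmetric across seeds", {
  gm <- genome_model(c(chr1 = 5e5))
  cat_ <- hotspot_catalog(data.frame(
    id = c("a", "b"), chrom = "chr1", start = c(1e5, 3e5) - 250,
    end = c(1e5, 3e5) + 250, center = c(1e5, 3e5), heat = 1,
    category = "prdm9"), genome = gm)
  pass <- 0L
  for (s in 1:20) {
    cfg <- genotype_config("sym", total_dsb_events = 4000, default_weight = 0,
                           background_rate = 0.002, n_replicates = 1, seed = 3000 + s)
    sim <- simulate_dataset(gm, cat_, cfg)
    nt <- total_signal(sim$counts[[1]], "top")
    nb <- total_signal(sim$counts[[1]], "bottom")
    p <- binom.test(nt, nt + nb, 0.5)$p.value
    if (p >= 0.001) pass <- pass + 1L
  }
  expect_gte(pass, 19L)
})

test_that("simulated catalogs respect spacing, bounds and PAR placement", {
  gm <- tiny_genome()
  cat_ <- tiny_catalog(gm, seed = 5)
  expect_s3_class(cat_, "HotspotCatalog")
  expect_equal(sum(cat_$category == "prdm9"), 40)
  expect_equal(sum(cat_$category == "default"), 40)
  for (nm in unique(cat_$chrom)) {
    cc <- sort(cat_$center[cat_$chrom == nm])
    if (length(cc) > 1) expect_true(all(diff(cc) >= 15000))
  }
  expect_true(all(cat_$start >= 0 & cat_$end <= gm$chrom_lengths[cat_$chrom]))
  n_in_par <- sum(in_par_test(gm, cat_$chrom, cat_$center))
  expect_equal(n_in_par, 3)
  expect_true(all(cat_$category[in_par_test(gm, cat_$chrom, cat_$center)] == "prdm9"))

  # heats are a catalog property: same seed, same heats
  expect_identical(cat_$heat, tiny_catalog(gm, seed = 5)$heat)
})

test_that("catalog BED round trip preserves intervals and categories", {
  gm <- tiny_genome()
  cat_ <- tiny_catalog(gm, seed = 8)
  path <- file.path(withr::local_tempdir(), "cat.bed")
  write_catalog_bed(cat_, path)
  back <- read_catalog_bed(path, genome = gm)
  expect_equal(back$chrom, cat_$chrom)
  expect_equal(back$start, cat_$start)
  expect_equal(back$end, cat_$end)
  expect_equal(back$category, cat_$category)
  # heat comes back as the 0-1000 integer rescaling of the original scores
  expect_equal(back$heat, round(1000 * cat_$heat / max(cat_$heat)))
})
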