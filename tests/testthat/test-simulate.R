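g_hg19 <- load_genome("hg19")

test_that("the generator is deterministic and its truth scores exactly", {
  cfg <- sim_config(seed = 1, rho = 0.6, n_loh = 3, n_lst = 5, n_tai = 2)
  t1 <- inject_scars(g_hg19, cfg)
  t2 <- inject_scars(g_hg19, cfg)
  expect_identical(as.data.frame(t1$profile), as.data.frame(t2$profile))
  res <- gis_score(t1$profile, g_hg19)
  expect_equal(c(res$loh, res$lst, res$tai, res$gis), c(3, 5, 2, 10))
  none <- inject_scars(g_hg19, sim_config(seed = 2, rho = 0.6))
  expect_equal(gis_score(none$profile, g_hg19)$gis, 0)
})

test_that("infeasible event requests are rejected", {
  expect_error(inject_scars(g_hg19, sim_config(seed = 1, n_loh = 23)),
               "infeasible")
  expect_error(inject_scars(g_hg19, sim_config(seed = 1, psi_base = 1,
                                               n_tai = 1)),
               "infeasible")
})

test_that("injected truth satisfies the event-qualification construction", {
  set.seed(NULL)
  for (s in c(4, 11)) {
    cfg <- sim_config(seed = s, rho = 0.5, n_loh = 4, n_lst = 3, n_tai = 3)
    truth <- inject_scars(g_hg19, cfg)
    ev <- do.call(rbind, truth$events)
    # each event on its own chromosome
    expect_equal(anyDuplicated(ev$chrom), 0L)
    loh <- truth$events$loh
    expect_true(all(loh$end - loh$start > 15e6))
    tai <- truth$events$tai
    expect_true(all(tai$end - tai$start < 10e6))
    lst <- truth$events$lst
    expect_true(all(lst$n_major == lst$n_minor))  # balanced gains
  }
})

test_that("the forward model reproduces expected LogR/BAF at zero noise", {
  # pure diploid, rho = 1: logr 0 everywhere, informative baf exactly 0.5
  cfg <- sim_config(seed = 9, rho = 1, sigma_logr = 0, sigma_baf = 0)
  sim <- simulate_sample(g_hg19, cfg)
  expect_equal(max(abs(sim$track$logr)), 0)
  expect_equal(unique(sim$track$baf[sim$track$informative]), 0.5)
  expect_true(all(sim$track$baf[!sim$track$informative] %in% c(0, 1)))
})

test_that("a (2,1) gain renders logr log2(1.5) and baf in {1/3, 2/3}", {
  cfg <- sim_config(seed = 10, rho = 1, gamma = 1, sigma_logr = 0,
                    sigma_baf = 0)
  truth <- inject_scars(g_hg19, cfg)
  # overwrite one chromosome with (2,1) and rescale psi accordingly
  s <- as.data.frame(truth$profile)
  s[s$chrom == "chr5", c("n_major", "n_minor")] <- c(2, 1)
  truth$profile <- segment_profile(s$chrom, s$start, s$end, s$n_major,
                                   s$n_minor, sex = "XX")
  len <- truth$profile$end - truth$profile$start
  truth$psi <- sum(len * (truth$profile$n_major + truth$profile$n_minor)) /
    sum(len)
  track <- render_probes(truth, cfg)
  on5 <- track$chrom == "chr5"
  norm <- 2 / truth$psi
  expect_equal(unique(round(track$logr[on5], 10)),
               round(log2(3 * norm / 2), 10))
  bafs <- sort(unique(round(track$baf[on5 & track$informative], 10)))
  expect_equal(bafs, round(c(1 / 3, 2 / 3), 10))
})

test_that("diploid mean logr is near 0 at default noise", {
  cfg <- sim_config(seed = 21, rho = 1)
  sim <- simulate_sample(g_hg19, cfg)
  n <- nrow(sim$track)
  expect_lt(abs(mean(sim$track$logr)), 3 * cfg$sigma_logr / sqrt(n))
})

test_that("zero-noise pipeline round-trips the injected scar counts", {
  for (s in 1:2) {
    cfg <- sim_config(seed = s, rho = 0.4 + 0.1 * s, n_loh = 3, n_lst = 5,
                      n_tai = 2, sigma_logr = 0, sigma_baf = 0)
    sim <- simulate_sample(g_hg19, cfg)
    raw <- segment_track(sim$track)
    fit <- grid_search(raw)
    prof <- fit_profile(raw, fit, g_hg19)
    res <- gis_score(prof, g_hg19)
    expect_equal(c(res$loh, res$lst, res$tai, res$gis), c(3, 5, 2, 10))
    # recovered states equal the truth states over the probe-covered genome
    expect_equal(abs(fit$rho - sim$truth$rho) < 0.005, TRUE)
  }
})

test_that("recovered GIS is within 1 of truth in >= 90% of 50 replicates", {
  hits <- 0L
  for (s in 1:50) {
    cfg <- sim_config(seed = 1000 + s, rho = 0.45 + 0.01 * (s %% 36),
                      n_loh = 3, n_lst = 5, n_tai = 2)
    sim <- simulate_sample(g_hg19, cfg)
    raw <- segment_track(sim$track)
    prof <- fit_profile(raw, grid_search(raw), g_hg19)
    res <- gis_score(prof, g_hg19)
    truth <- gis_score(sim$truth$profile, g_hg19)
    hits <- hits + (abs(res$gis - truth$gis) <= 1)
  }
  expect_gte(hits, 45L)
})

test_that("XY samples carry haploid sex chromosomes without informative probes", {
  cfg <- sim_config(seed = 41, sex = "XY", rho = 0.8, sigma_logr = 0,
                    sigma_baf = 0)
  sim <- simulate_sample(g_hg19, cfg)
  expect_true("chrY" %in% sim$track$chrom)
  sexp <- sim$track$chrom %in% c("chrX", "chrY")
  expect_false(any(sim$track$informative[sexp]))
  p <- sim$truth$profile
  expect_equal(unique(p$n_major[p$chrom == "chrX"]), 1)
  expect_equal(unique(p$n_minor[p$chrom == "chrX"]), 0)
})
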