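test_that("segment_copy_numbers inverts the signal model", {
  expect_equal(segment_copy_numbers(0, 0.5, rho = 1, psi = 2, gamma = 1),
               list(n_a = 1, n_b = 1))
  cn <- segment_copy_numbers(log2(1.5), 1 / 3, rho = 1, psi = 2, gamma = 1)
  expect_equal(cn$n_a, 2)
  expect_equal(cn$n_b, 1)
  cn2 <- segment_copy_numbers(0, 0.5, rho = 0.5, psi = 2, gamma = 1)
  expect_equal(cn2$n_a, 1)
  expect_equal(cn2$n_b, 1)
  expect_error(segment_copy_numbers(0, 0.5, rho = 0, psi = 2), "rho")
})

test_that("forward model and inversion are consistent to machine precision", {
  set.seed(20)
  for (i in 1:400) {
    rho <- runif(1, 0.3, 1)
    psi <- runif(1, 1.5, 4)
    gamma <- sample(c(0.55, 1), 1)
    n_a <- sample(0:4, 1); n_b <- sample(0:n_a, 1)
    total <- n_a + n_b
    r <- gamma * log2((2 * (1 - rho) + rho * total) /
                        (2 * (1 - rho) + rho * psi))
    b <- ((1 - rho) + rho * n_b) / (2 * (1 - rho) + rho * total)
    cn <- segment_copy_numbers(r, b, rho, psi, gamma)
    expect_equal(cn$n_a, n_a, tolerance = 1e-12)
    expect_equal(cn$n_b, n_b, tolerance = 1e-12)
  }
})

# hand-built raw segmentation: exact forward-model means for given states
exact_raw <- function(states, rho, psi, gamma = 0.55, len = 30e6) {
  r <- gamma * log2((2 * (1 - rho) + rho * rowSums(states)) /
                      (2 * (1 - rho) + rho * psi))
  b <- ((1 - rho) + rho * pmax(states[, 1], states[, 2])) /
    (2 * (1 - rho) + rho * rowSums(states))
  structure(data.frame(chrom = paste0("chr", seq_len(nrow(states))),
                       start = 0, end = len, n_probes = 300L,
                       n_informative = 75L, mean_logr = r, mean_mbaf = b),
            sex = "XX", class = c("raw_segmentation", "data.frame"))
}

test_that("grid search lands exactly on the generating grid point", {
  states <- cbind(c(1, 2, 2, 3, 2, 1, 3, 2), c(1, 1, 0, 1, 2, 0, 2, 1))
  psi_true <- mean(rowSums(states))  # 3.0 with these states
  expect_equal(psi_true, 3.0)
  raw <- exact_raw(states, rho = 0.6, psi = psi_true)
  fit <- grid_search(raw)
  expect_equal(fit$rho, 0.60)
  expect_equal(fit$psi, 3.00)
  expect_false(fit$non_identifiable)
  # the arg-min value bounds the whole surface
  expect_true(all(fit$fit_surface >= fit$min_distance - 1e-12))
})

test_that("a flat balanced profile is flagged non-identifiable", {
  raw <- exact_raw(cbind(rep(1, 6), rep(1, 6)), rho = 1, psi = 2)
  fit <- grid_search(raw)
  expect_true(fit$non_identifiable)
})

test_that("the pathology estimate down-ranks, never excludes", {
  states <- cbind(c(1, 2, 2, 3, 2, 1, 3, 2), c(1, 1, 0, 1, 2, 0, 2, 1))
  raw <- exact_raw(states, rho = 0.6, psi = 3)
  # truth fits exactly (distance 0), so even a wrong pathology estimate
  # cannot displace it
  fit <- grid_search(raw, fit_config(pathology_tumor_content = 0.9))
  expect_equal(fit$rho, 0.60)
  expect_equal(fit$psi, 3.00)
})

test_that("fit_profile rounds, orders, merges and satisfies invariants", {
  g <- load_genome("hg19")
  raw <- structure(
    data.frame(chrom = "chr1", start = c(10e6, 60e6, 130e6),
               end = c(60e6, 130e6, 240e6), n_probes = 500L,
               n_informative = 125L,
               mean_logr = c(0, 0.55 * log2(1.5), 0.55 * log2(1.5)),
               mean_mbaf = c(0.5, 2 / 3, 2 / 3)),
    sex = "XX", class = c("raw_segmentation", "data.frame"))
  prof <- fit_profile(raw, fixed_fit(1, 2), g)
  # adjacent same-state segments merged; ends extended to the chromosome
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$start[1L], 0)
  expect_equal(prof$end[2L], genome_chrom(g, "chr1")$length)
  expect_equal(prof$n_major, c(1, 2))
  expect_equal(prof$n_minor, c(1, 1))
  expect_true(all(prof$n_major >= prof$n_minor & prof$n_minor >= 0))
})

test_that("near-integer states round to the nearest integers", {
  g <- load_genome("hg19")
  # means perturbed so continuous copy numbers are (1.95, 1.02)-like
  rho <- 1; psi <- 2; gamma <- 0.55
  total <- 2.97
  r <- gamma * log2(total / 2)
  b <- 1.02 / total
  raw <- structure(
    data.frame(chrom = "chr1", start = 0, end = 249250621,
               n_probes = 2000L, n_informative = 500L,
               mean_logr = r, mean_mbaf = 1 - b),
    sex = "XX", class = c("raw_segmentation", "data.frame"))
  prof <- fit_profile(raw, fixed_fit(rho, psi, gamma), g)
  expect_equal(prof$n_major, 2)
  expect_equal(prof$n_minor, 1)
})

test_that("noisy grid recovery stays within one grid step", {
  g <- load_genome("hg19")
  for (s in 1:3) {
    cfg <- sim_config(seed = 300 + s, rho = 0.5 + 0.1 * s, psi_base = 2,
                      n_loh = 10, n_tai = 10)
    sim <- simulate_sample(g, cfg)
    raw <- segment_track(sim$track)
    fit <- grid_search(raw)
    expect_lte(abs(fit$rho - sim$truth$rho), 0.01 + 1e-9)
    expect_lte(abs(fit$psi - sim$truth$psi), 0.05 + 1e-9)
  }
})
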