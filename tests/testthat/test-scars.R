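# toy genome: p arm 60 Mb, centromere 3 Mb, q arm >= 80 Mb
tg <- toy_genome(5)

diploid_profile <- function(genome) {
  ci <- genome$chromosomes
  segment_profile(ci$chrom, 0, ci$length, 1, 1, sex = "XX")
}

# replace the [start, end) interval of one chromosome with a state
with_event <- function(profile, chrom, start, end, n_major, n_minor) {
  s <- as.data.frame(profile)
  host <- s[s$chrom == chrom, , drop = FALSE]
  pieces <- list()
  for (k in seq_len(nrow(host))) {
    h <- host[k, ]
    if (h$end <= start || h$start >= end) { pieces[[length(pieces) + 1L]] <- h; next }
    if (h$start < start) {
      pieces[[length(pieces) + 1L]] <-
        data.frame(chrom = chrom, start = h$start, end = start,
                   n_major = h$n_major, n_minor = h$n_minor)
    }
    if (h$end > end) {
      pieces[[length(pieces) + 1L]] <-
        data.frame(chrom = chrom, start = end, end = h$end,
                   n_major = h$n_major, n_minor = h$n_minor)
    }
  }
  pieces[[length(pieces) + 1L]] <-
    data.frame(chrom = chrom, start = start, end = end,
               n_major = n_major, n_minor = n_minor)
  out <- rbind(s[s$chrom != chrom, ], do.call(rbind, pieces))
  segment_profile(out$chrom, out$start, out$end, out$n_major, out$n_minor,
                  sex = attr(profile, "sex"))
}

test_that("a diploid genome carries no scars", {
  res <- gis_score(diploid_profile(tg), tg)
  expect_equal(c(res$loh, res$lst, res$tai, res$gis), c(0, 0, 0, 0))
})

test_that("LOH counts runs > 15 Mb, excluding whole chromosomes", {
  p <- diploid_profile(tg)
  # 20 Mb, 16 Mb, 10 Mb interior copy-neutral LOH on different chromosomes
  p <- with_event(p, "chr1", 20e6, 40e6, 2, 0)
  p <- with_event(p, "chr2", 20e6, 36e6, 2, 0)
  p <- with_event(p, "chr3", 20e6, 30e6, 1, 0)
  expect_equal(count_loh(p, tg)$count, 2L)
  # exactly 15 Mb does not count (strict >)
  p15 <- with_event(diploid_profile(tg), "chr1", 20e6, 35e6, 1, 0)
  expect_equal(count_loh(p15, tg)$count, 0L)
  # whole-chromosome LOH is excluded
  whole <- diploid_profile(tg)
  w <- as.data.frame(whole)
  w[w$chrom == "chr2", c("n_major", "n_minor")] <- rep(c(2, 0), each = 1)
  whole <- segment_profile(w$chrom, w$start, w$end, w$n_major, w$n_minor)
  expect_equal(count_loh(whole, tg)$count, 0L)
})

test_that("homozygous deletions join LOH runs without adding length", {
  p <- diploid_profile(tg)
  # 9 Mb LOH | 2 Mb homdel | 9 Mb LOH: one run of summed length 18 Mb
  p <- with_event(p, "chr1", 10e6, 19e6, 1, 0)
  p <- with_event(p, "chr1", 19e6, 21e6, 0, 0)
  p <- with_event(p, "chr1", 21e6, 30e6, 1, 0)
  expect_equal(count_loh(p, tg)$count, 1L)
  # 8 + 2 + 6 = 14 Mb of LOH does not reach the threshold even though the
  # spanned interval is 16 Mb
  q <- diploid_profile(tg)
  q <- with_event(q, "chr1", 10e6, 18e6, 1, 0)
  q <- with_event(q, "chr1", 18e6, 20e6, 0, 0)
  q <- with_event(q, "chr1", 20e6, 26e6, 1, 0)
  expect_equal(count_loh(q, tg)$count, 0L)
})

test_that("LST counts breaks with >= 10 Mb flanks after 3 Mb smoothing", {
  p <- diploid_profile(tg)
  # one p-arm break: 30 Mb (1,1) | 30 Mb (2,1)
  p <- with_event(p, "chr1", 30e6, 60e6, 2, 1)
  expect_equal(count_lst(p, tg)$count, 1L)
  # short interloper removed, flanks merge back: no transition
  q <- diploid_profile(tg)
  q <- with_event(q, "chr2", 28e6, 30e6, 3, 1)
  expect_equal(count_lst(q, tg)$count, 0L)
  # 9 Mb flank does not qualify
  r <- diploid_profile(tg)
  r <- with_event(r, "chr3", 51e6, 60e6, 2, 1)
  expect_equal(count_lst(r, tg)$count, 0L)
  # breaks never span the centromere: state change exactly at the
  # centromere gap (60-63 Mb here) is not an LST
  s <- diploid_profile(tg)
  ci <- genome_chrom(tg, "chr4")
  s <- with_event(s, "chr4", ci$cen_end, ci$length, 2, 2)
  expect_equal(count_lst(s, tg)$count, 0L)
})

test_that("TAI counts telomeric imbalance not crossing the centromere", {
  p <- diploid_profile(tg)
  ci <- genome_chrom(tg, "chr1")
  # q-arm terminal 40 Mb at (2,1)
  p <- with_event(p, "chr1", ci$length - 40e6, ci$length, 2, 1)
  expect_equal(count_tai(p, tg)$count, 1L)
  # whole chromosome at (2,1): excluded
  w <- as.data.frame(diploid_profile(tg))
  w[w$chrom == "chr2", c("n_major", "n_minor")] <- rep(c(2, 1), each = 1)
  expect_equal(count_tai(segment_profile(w$chrom, w$start, w$end,
                                         w$n_major, w$n_minor), tg)$count, 0L)
  # imbalance crossing the centromere: excluded
  x <- diploid_profile(tg)
  ci3 <- genome_chrom(tg, "chr3")
  x <- with_event(x, "chr3", 40e6, ci3$length, 2, 1)
  expect_equal(count_tai(x, tg)$count, 0L)
  # interior imbalance does not touch a telomere
  y <- with_event(diploid_profile(tg), "chr4", 20e6, 50e6, 2, 1)
  expect_equal(count_tai(y, tg)$count, 0L)
})

test_that("GIS is the sum of the three scars and is order-invariant", {
  g <- load_genome("hg19")
  cfg <- sim_config(seed = 77, rho = 0.7, n_loh = 3, n_lst = 5, n_tai = 2)
  truth <- inject_scars(g, cfg)
  res <- gis_score(truth$profile, g)
  expect_equal(res$gis, res$loh + res$lst + res$tai)
  expect_equal(c(res$loh, res$lst, res$tai), c(3, 5, 2))
  # permuting input rows changes nothing (constructor re-sorts)
  s <- as.data.frame(truth$profile)
  set.seed(1)
  s <- s[sample(nrow(s)), ]
  res2 <- gis_score(segment_profile(s$chrom, s$start, s$end, s$n_major,
                                    s$n_minor, sex = "XX"), g)
  expect_equal(res2[c("loh", "lst", "tai", "gis")],
               res[c("loh", "lst", "tai", "gis")])
})

test_that("splitting a segment in two equal-state pieces changes no count", {
  set.seed(55)
  for (i in 1:10) {
    prof <- random_toy_profile(tg)
    base <- oracle_scars(prof, tg)
    s <- as.data.frame(prof)
    k <- sample(nrow(s), 1)
    mid <- floor((s$start[k] + s$end[k]) / 2)
    if (mid <= s$start[k] || mid >= s$end[k]) next
    split_row <- s[k, ]
    s$end[k] <- mid
    split_row$start <- mid
    s <- rbind(s, split_row)
    prof2 <- segment_profile(s$chrom, s$start, s$end, s$n_major, s$n_minor,
                             sex = "XX")
    res <- gis_score(prof2, tg)
    expect_equal(c(res$loh, res$lst, res$tai),
                 c(base$loh, base$lst, base$tai))
  }
})

test_that("scar counts match the brute-force oracle on random profiles", {
  set.seed(99)
  for (i in 1:40) {
    prof <- random_toy_profile(tg)
    res <- gis_score(prof, tg)
    ora <- oracle_scars(prof, tg)
    expect_equal(c(res$loh, res$lst, res$tai, res$gis),
                 c(ora$loh, ora$lst, ora$tai, ora$gis))
  }
})

test_that("adding one qualifying LOH event increases loh by exactly one", {
  g <- load_genome("hg19")
  cfg <- sim_config(seed = 13, rho = 0.7, n_loh = 2, n_lst = 3, n_tai = 1)
  truth <- inject_scars(g, cfg)
  base <- gis_score(truth$profile, g)
  # inject an extra interior 20 Mb copy-neutral LOH on an untouched autosome
  used <- unique(do.call(rbind, truth$events)$chrom)
  free <- setdiff(paste0("chr", 1:22), used)[1L]
  prof2 <- with_event(truth$profile, free, 20e6, 40e6, 2, 0)
  res <- gis_score(prof2, g)
  expect_equal(res$loh, base$loh + 1L)
  expect_equal(res$tai, base$tai)
})
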