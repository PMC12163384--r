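# Independent reference implementations used as oracles.  These are written
# as plain scans/enumerations, deliberately avoiding the vectorized code
# paths of the package.

# --- toy genome -------------------------------------------------------------

toy_genome <- function(n_chrom = 5, p_len = 60e6, cen_len = 3e6,
                       q_len = 80e6) {
  lens <- p_len + cen_len + q_len + (seq_len(n_chrom) - 1) * 5e6
  tab <- data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = lens,
    centromere_start = p_len + 1,        # 1-based inclusive on disk
    centromere_end = p_len + cen_len
  )
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_genome(path)
}

# random full-coverage toy profile on a toy genome
random_toy_profile <- function(genome, max_segments = 12) {
  states <- rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 0), c(2, 0), c(3, 1),
                  c(0, 0), c(3, 2))
  rows <- list()
  for (k in seq_len(nrow(genome$chromosomes))) {
    ci <- genome$chromosomes[k, ]
    n_seg <- sample(1:max_segments, 1)
    cuts <- sort(c(0, ci$length,
                   sample(seq(1e6, ci$length - 1e6, by = 5e5),
                          n_seg - 1)))
    st <- states[sample(nrow(states), n_seg, replace = TRUE), , drop = FALSE]
    rows[[k]] <- data.frame(chrom = ci$chrom, start = cuts[-length(cuts)],
                            end = cuts[-1], n_major = st[, 1],
                            n_minor = st[, 2])
  }
  tab <- do.call(rbind, rows)
  segment_profile(tab$chrom, tab$start, tab$end, tab$n_major, tab$n_minor,
                  sex = "XX")
}

# --- scar-counting oracle ---------------------------------------------------

oracle_scars <- function(profile, genome, cfg = scar_config()) {
  sex <- attr(profile, "sex")
  if (is.null(sex)) sex <- "XX"
  chroms <- unique(profile$chrom)
  if (sex == "XX") chroms <- setdiff(chroms, "chrY")
  if (!cfg$include_x) chroms <- setdiff(chroms, "chrX")
  loh <- 0L; lst <- 0L; tai <- 0L

  for (ch in chroms) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    n <- nrow(s)
    ci <- genome$chromosomes[genome$chromosomes$chrom == ch, ]
    cov_lo <- min(s$start); cov_hi <- max(s$end)
    linked <- rep(FALSE, n)
    if (n > 1L) {
      for (i in 1:(n - 1L)) {
        linked[i] <- (s$start[i + 1L] - s$end[i]) < cfg$lst_smooth
      }
    }

    ## LOH: walk every maximal run of minor-0 rows (homozygous deletions may
    ## sit inside a run but a run starts and ends on a major>=1 row)
    elig <- s$n_minor == 0 & s$n_major >= 1
    hd <- s$n_minor == 0 & s$n_major == 0
    i <- 1L
    while (i <= n) {
      if (!elig[i]) { i <- i + 1L; next }
      j <- i
      while (j < n && linked[j] && (elig[j + 1L] || hd[j + 1L])) j <- j + 1L
      while (!elig[j]) j <- j - 1L
      run_len <- 0
      for (k in i:j) if (elig[k]) run_len <- run_len + s$end[k] - s$start[k]
      whole <- (s$start[i] == cov_lo) && (s$end[j] == cov_hi)
      if (run_len > cfg$loh_min_len &&
          !(cfg$exclude_whole_chromosome && whole)) {
        loh <- loh + 1L
      }
      i <- j + 1L
    }

    ## LST: per arm, smooth by repeatedly deleting the shortest sub-3Mb
    ## segment, then scan adjacent pairs
    for (arm_bounds in list(c(0, ci$cen_start), c(ci$cen_end, ci$length))) {
      a <- s
      a$start <- pmax(a$start, arm_bounds[1L])
      a$end <- pmin(a$end, arm_bounds[2L])
      a <- a[a$start < a$end, , drop = FALSE]
      repeat {
        if (nrow(a) == 0L) break
        lens <- a$end - a$start
        if (all(lens >= cfg$lst_smooth)) break
        drop <- which.min(ifelse(lens < cfg$lst_smooth, lens, Inf))
        a <- a[-drop, , drop = FALSE]
        # pairwise merge of equal-state neighbours
        m <- 1L
        while (m < nrow(a)) {
          if (a$n_major[m] == a$n_major[m + 1L] &&
              a$n_minor[m] == a$n_minor[m + 1L]) {
            a$end[m] <- a$end[m + 1L]
            a <- a[-(m + 1L), , drop = FALSE]
          } else m <- m + 1L
        }
      }
      if (nrow(a) >= 2L) {
        for (k in 1:(nrow(a) - 1L)) {
          len1 <- a$end[k] - a$start[k]
          len2 <- a$end[k + 1L] - a$start[k + 1L]
          gap <- a$start[k + 1L] - a$end[k]
          if ((a$n_major[k] != a$n_major[k + 1L] ||
               a$n_minor[k] != a$n_minor[k + 1L]) &&
              len1 >= cfg$lst_min_seg && len2 >= cfg$lst_min_seg &&
              gap < cfg$lst_smooth) {
            lst <- lst + 1L
          }
        }
      }
    }

    ## TAI: maximal same-imbalance-status runs (gap-bridged), telomere rule
    imb <- s$n_major != s$n_minor
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && linked[j] && imb[j + 1L] == imb[i]) j <- j + 1L
      if (imb[i]) {
        rs <- s$start[i]; re <- s$end[j]
        touches <- (rs == cov_lo) || (re == cov_hi)
        crosses <- rs < ci$cen_start && re > ci$cen_end
        whole <- (rs == cov_lo) && (re == cov_hi)
        if (touches && !crosses && (re - rs) >= cfg$tai_min_len &&
            !(cfg$exclude_whole_chromosome && whole)) {
          tai <- tai + 1L
        }
      }
      i <- j + 1L
    }
  }
  list(loh = loh, lst = lst, tai = tai, gis = loh + lst + tai)
}

# --- segmentation oracle ----------------------------------------------------

# exhaustive enumeration of every segmentation with segments >= min_len;
# returns the minimum objective value
oracle_best_segmentation_cost <- function(y, b, wl, wb, penalty, min_len) {
  n <- length(y)
  seg_cost <- function(i, j) {
    yy <- y[i:j]
    cost <- wl * sum((yy - mean(yy))^2)
    bb <- b[i:j]; bb <- bb[!is.na(bb)]
    if (length(bb) > 0L) cost <- cost + wb * sum((bb - mean(bb))^2)
    cost
  }
  best <- Inf
  recurse <- function(start, acc, k) {
    for (j in seq(start + min_len - 1L, n)) {
      if (n - j != 0L && n - j < min_len) next
      cost <- acc + seg_cost(start, j) + if (k > 0L) penalty else 0
      if (j == n) {
        if (cost < best) best <<- cost
      } else if (cost < best) {
        recurse(j + 1L, cost, k + 1L)
      }
    }
  }
  recurse(1L, 0, 0L)
  best
}

# objective value of a concrete segmentation returned by the DP
segmentation_cost <- function(y, b, ends, wl, wb, penalty) {
  starts <- c(1L, head(ends, -1L) + 1L)
  total <- penalty * (length(ends) - 1L)
  for (k in seq_along(ends)) {
    yy <- y[starts[k]:ends[k]]
    total <- total + wl * sum((yy - mean(yy))^2)
    bb <- b[starts[k]:ends[k]]; bb <- bb[!is.na(bb)]
    if (length(bb) > 0L) total <- total + wb * sum((bb - mean(bb))^2)
  }
  total
}
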