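#' Scar-counting configuration
#'
#' Length thresholds of the three genomic-instability scar rules, in base
#' pairs.
#'
#' @param loh_min_len minimum LOH run length, strict comparison (default
#'   15 Mb; a run counts when longer than this).
#' @param lst_min_seg minimum flanking-segment length at a large-scale state
#'   transition, inclusive comparison (default 10 Mb).
#' @param lst_smooth smoothing threshold: segments shorter than this are
#'   removed before counting transitions, and it is also the maximum allowed
#'   gap at a counted break and the bridging distance across missing data
#'   (default 3 Mb).
#' @param tai_min_len minimum telomeric allelic-imbalance run length
#'   (default 0).
#' @param exclude_whole_chromosome drop LOH/TAI events spanning an entire
#'   chromosome (default TRUE, following the scar literature's exclusion of
#'   whole-chromosome aneuploidy).
#' @param include_x score chromosome X (default TRUE); chrY is scored only
#'   for XY samples regardless.
#' @return list of class `scar_config`.
#' @export
scar_config <- function(loh_min_len = 15e6, lst_min_seg = 10e6,
                        lst_smooth = 3e6, tai_min_len = 0,
                        exclude_whole_chromosome = TRUE, include_x = TRUE) {
  stopifnot(loh_min_len >= 0, lst_min_seg >= 0, lst_smooth >= 0,
            tai_min_len >= 0, lst_smooth < lst_min_seg)
  structure(list(loh_min_len = loh_min_len, lst_min_seg = lst_min_seg,
                 lst_smooth = lst_smooth, tai_min_len = tai_min_len,
                 exclude_whole_chromosome = exclude_whole_chromosome,
                 include_x = include_x),
            class = "scar_config")
}

scar_chromosomes <- function(profile, genome, config) {
  sex <- attr(profile, "sex")
  if (is.null(sex)) sex <- "XX"
  chroms <- intersect(scored_chromosomes(genome, sex), unique(profile$chrom))
  if (!config$include_x) chroms <- setdiff(chroms, "chrX")
  chroms
}

#' Count loss-of-heterozygosity scars
#'
#' An LOH scar is a maximal run of segments with minor copy number 0 and
#' major copy number >= 1, longer than `loh_min_len` (strictly) and not
#' spanning the whole chromosome.  Homozygous-deletion segments (0,0) inside
#' a run do not interrupt it but contribute no length; gaps of missing data
#' shorter than `lst_smooth` are bridged.  Run length is the summed length of
#' the contributing LOH segments.
#'
#' @param profile a [segment_profile()].
#' @param genome a `genome_build`.
#' @param config a [scar_config()].
#' @return list with `count` and `intervals` (data.frame `chrom`, `start`,
#'   `end`, `length` of counted runs).
#' @export
count_loh <- function(profile, genome, config = scar_config()) {
  events <- list()
  for (ch in scar_chromosomes(profile, genome, config)) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    cov_start <- min(s$start); cov_end <- max(s$end)
    is_loh <- s$n_minor == 0 & s$n_major >= 1
    is_homdel <- s$n_minor == 0 & s$n_major == 0

    run_len <- 0; run_start <- NA_real_; run_end <- NA_real_
    flush <- function() {
      if (!is.na(run_start) && run_len > config$loh_min_len) {
        whole <- run_start == cov_start && run_end == cov_end
        if (!(config$exclude_whole_chromosome && whole)) {
          events[[length(events) + 1L]] <<- data.frame(
            chrom = ch, start = run_start, end = run_end, length = run_len)
        }
      }
      run_len <<- 0; run_start <<- NA_real_; run_end <<- NA_real_
    }
    prev_end <- NA_real_
    for (k in seq_len(nrow(s))) {
      gap <- if (is.na(prev_end)) 0 else s$start[k] - prev_end
      if (gap >= config$lst_smooth) flush()
      if (is_loh[k]) {
        if (is.na(run_start)) run_start <- s$start[k]
        run_end <- s$end[k]
        run_len <- run_len + (s$end[k] - s$start[k])
      } else if (!is_homdel[k]) {
        flush()
      }
      prev_end <- s$end[k]
    }
    flush()
  }
  intervals <- if (length(events)) do.call(rbind, events) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               length = numeric(0))
  list(count = nrow(intervals), intervals = intervals)
}

# clip segments of one chromosome to an interval, drop empties
clip_segments <- function(s, lo, hi) {
  s$start <- pmax(s$start, lo)
  s$end <- pmin(s$end, hi)
  s[s$start < s$end, , drop = FALSE]
}

# remove segments shorter than `smooth`, iteratively merging flanking
# same-state neighbours (interval hull) and re-checking until stable
smooth_segments <- function(s, smooth) {
  repeat {
    if (nrow(s) == 0L) return(s)
    len <- s$end - s$start
    short <- which(len < smooth)
    if (length(short) == 0L) return(s)
    drop <- short[which.min(len[short])]
    s <- s[-drop, , drop = FALSE]
    # merge adjacent equal-state rows (hull absorbs the removed interval)
    if (nrow(s) > 1L) {
      same <- s$n_major[-1L] == s$n_major[-nrow(s)] &
        s$n_minor[-1L] == s$n_minor[-nrow(s)]
      grp <- factor(cumsum(c(TRUE, !same)))
      s <- data.frame(chrom = s$chrom[1L],
                      start = as.numeric(tapply(s$start, grp, min)),
                      end = as.numeric(tapply(s$end, grp, max)),
                      n_major = s$n_major[!duplicated(grp)],
                      n_minor = s$n_minor[!duplicated(grp)],
                      stringsAsFactors = FALSE)
    }
  }
}

#' Count large-scale state transitions
#'
#' Per chromosome arm: segments shorter than `lst_smooth` are removed (with
#' same-state flanks merged over the removed interval, iterated to a fixed
#' point); an LST is then an adjacent pair of segments in different
#' allele-specific states, both at least `lst_min_seg` long, separated by a
#' gap smaller than `lst_smooth`.  Breaks never span the centromere.
#'
#' @inheritParams count_loh
#' @return list with `count` and `breakpoints` (data.frame `chrom`, `arm`,
#'   `pos` of counted breaks; `pos` is the midpoint of the inter-segment gap).
#' @export
count_lst <- function(profile, genome, config = scar_config()) {
  breaks <- list()
  for (ch in scar_chromosomes(profile, genome, config)) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    arms <- arm_intervals(genome, ch)
    for (arm in c("p", "q")) {
      ai <- arms[arms$arm == arm, ]
      a <- clip_segments(s, ai$start, ai$end)
      if (nrow(a) < 2L) next
      a <- smooth_segments(a, config$lst_smooth)
      if (nrow(a) < 2L) next
      len <- a$end - a$start
      for (k in seq_len(nrow(a) - 1L)) {
        differs <- a$n_major[k] != a$n_major[k + 1L] ||
          a$n_minor[k] != a$n_minor[k + 1L]
        gap <- a$start[k + 1L] - a$end[k]
        if (differs && len[k] >= config$lst_min_seg &&
            len[k + 1L] >= config$lst_min_seg && gap < config$lst_smooth) {
          breaks[[length(breaks) + 1L]] <- data.frame(
            chrom = ch, arm = arm, pos = (a$end[k] + a$start[k + 1L]) / 2)
        }
      }
    }
  }
  breakpoints <- if (length(breaks)) do.call(rbind, breaks) else
    data.frame(chrom = character(0), arm = character(0), pos = numeric(0))
  list(count = nrow(breakpoints), breakpoints = breakpoints)
}

#' Count telomeric allelic-imbalance scars
#'
#' Adjacent segments with the same imbalance status (imbalance means
#' `n_major != n_minor`) are merged into maximal runs, bridging gaps smaller
#' than `lst_smooth`.  A TAI scar is an imbalanced run that touches a
#' chromosome end (the first or last covered base), does not cross the
#' centromere, spans at least `tai_min_len`, and does not cover the whole
#' chromosome.
#'
#' @inheritParams count_loh
#' @return list with `count` and `intervals`.
#' @export
count_tai <- function(profile, genome, config = scar_config()) {
  events <- list()
  for (ch in scar_chromosomes(profile, genome, config)) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    ci <- genome_chrom(genome, ch)
    cov_start <- min(s$start); cov_end <- max(s$end)
    imb <- s$n_major != s$n_minor
    gap_break <- c(FALSE, (s$start[-1L] - s$end[-nrow(s)]) >=
                     config$lst_smooth)
    grp <- cumsum(c(TRUE, imb[-1L] != imb[-nrow(s)]) | gap_break)
    for (g in unique(grp)) {
      rows <- which(grp == g)
      if (!imb[rows[1L]]) next
      run_start <- s$start[rows[1L]]; run_end <- s$end[rows[length(rows)]]
      span <- run_end - run_start
      touches <- run_start == cov_start || run_end == cov_end
      crosses_cen <- run_start < ci$cen_start && run_end > ci$cen_end
      whole <- run_start == cov_start && run_end == cov_end
      if (touches && !crosses_cen && span >= config$tai_min_len &&
          !(config$exclude_whole_chromosome && whole)) {
        events[[length(events) + 1L]] <- data.frame(
          chrom = ch, start = run_start, end = run_end, length = span)
      }
    }
  }
  intervals <- if (length(events)) do.call(rbind, events) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               length = numeric(0))
  list(count = nrow(intervals), intervals = intervals)
}

#' Genomic instability scar (GIS) score
#'
#' Counts the three scars and sums them: `gis = loh + lst + tai`.
#'
#' @inheritParams count_loh
#' @return list of class `scar_result` with counts `loh`, `lst`, `tai`,
#'   `gis`, and `events` (the per-scar audit intervals/breakpoints).
#' @export
gis_score <- function(profile, genome, config = scar_config()) {
  loh <- count_loh(profile, genome, config)
  lst <- count_lst(profile, genome, config)
  tai <- count_tai(profile, genome, config)
  structure(list(loh = loh$count, lst = lst$count, tai = tai$count,
                 gis = loh$count + lst$count + tai$count,
                 events = list(loh = loh$intervals, lst = lst$breakpoints,
                               tai = tai$intervals)),
            class = "scar_result")
}

#' @export
print.scar_result <- function(x, ...) {
  cat(sprintf("<scar_result> LOH %d + LST %d + TAI %d = GIS %d\n",
              x$loh, x$lst, x$tai, x$gis))
  invisible(x)
}
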