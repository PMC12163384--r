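#' Segmentation configuration
#'
#' @param penalty per-breakpoint penalty of the penalized least-squares
#'   objective, in units of noise variance (default 70).
#' @param min_probes_per_segment minimum probes per segment (default 5).
#' @param weight_logr,weight_baf relative weights of the LogR and mirrored-BAF
#'   residual terms (default 1 each; residuals are already standardized by the
#'   per-track noise estimates).
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(penalty = 70, min_probes_per_segment = 5,
                                weight_logr = 1, weight_baf = 1) {
  stopifnot(penalty > 0, min_probes_per_segment >= 2,
            weight_logr >= 0, weight_baf >= 0)
  structure(list(penalty = penalty,
                 min_probes_per_segment = min_probes_per_segment,
                 weight_logr = weight_logr, weight_baf = weight_baf),
            class = "segmentation_config")
}

#' Mirrored (folded) B-allele frequency
#'
#' Folds BAF about 0.5 so that the two heterozygous bands (genotype AB vs BA)
#' coincide: `|baf - 0.5| + 0.5`, in `[0.5, 1]`.  Only informative
#' (germline-heterozygous) probes carry allelic information, so the fold is
#' defined for those.
#'
#' @param track a [probe_track()].
#' @return Numeric vector of folded values for the informative probes, in
#'   track order.
#' @export
mirror_baf <- function(track) {
  inf <- track$informative
  if (!any(inf)) stop("no informative probes")
  abs(track$baf[inf] - 0.5) + 0.5
}

# MAD-consistent noise sd from first differences of a per-chromosome signal
# (for Gaussian noise, sd(diff) = sqrt(2) * sigma).
estimate_noise_sd <- function(values, chrom, floor = 1e-4) {
  diffs <- unlist(lapply(split(values, chrom), function(v) {
    if (length(v) >= 2L) abs(diff(v)) else numeric(0)
  }), use.names = FALSE)
  if (length(diffs) == 0L) return(floor)
  max(stats::median(diffs) / (sqrt(2) * stats::qnorm(0.75)), floor)
}

# BAF noise sd from homozygous probes: their true BAF sits at 0 or 1 and the
# observed value is clipped to [0, 1], so the squared distance to the nearest
# extreme has expectation sigma^2 / 2.  Falls back to the folded-difference
# estimate when no homozygous probes exist.
estimate_baf_sd <- function(track, floor = 1e-4) {
  hom <- !track$informative
  if (any(hom)) {
    d <- pmin(track$baf[hom], 1 - track$baf[hom])
    return(max(sqrt(2 * mean(d^2)), floor))
  }
  mb <- abs(track$baf[track$informative] - 0.5) + 0.5
  estimate_noise_sd(mb, track$chrom[track$informative], floor)
}

#' Joint piecewise-constant segmentation of LogR and mirrored BAF
#'
#' Per chromosome, finds the segmentation minimizing the sum of squared
#' residuals of LogR (all probes) and mirrored BAF (informative probes) around
#' segment means — each residual standardized by a robust per-track noise
#' estimate — plus `penalty` per breakpoint.  The optimum is computed exactly
#' by dynamic programming; segments shorter than `min_probes_per_segment`
#' probes are disallowed.  Chromosomes with fewer probes than that are emitted
#' as a single segment with a warning.
#'
#' Segment boundaries are placed at midpoints between flanking probes; the
#' first/last segment of each chromosome starts/ends at the outermost probe.
#'
#' @param track a [probe_track()].
#' @param config a [segmentation_config()].
#' @return data.frame of class `raw_segmentation` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `n_probes`, `n_informative`,
#'   `mean_logr`, `mean_mbaf` (NA when a segment has no informative probe);
#'   attributes `sex`, `sigma_logr`, `sigma_baf`.
#' @export
segment_track <- function(track, config = segmentation_config()) {
  mb <- rep(NA_real_, nrow(track))
  if (any(track$informative)) mb[track$informative] <- mirror_baf(track)
  sigma_l <- estimate_noise_sd(track$logr, track$chrom)
  sigma_b <- estimate_baf_sd(track)
  wl <- config$weight_logr / sigma_l^2
  wb <- config$weight_baf / sigma_b^2

  pieces <- lapply(split(seq_len(nrow(track)), track$chrom), function(idx) {
    idx <- idx[order(track$pos[idx])]
    y <- track$logr[idx]; b <- mb[idx]; pos <- track$pos[idx]
    n <- length(idx)
    if (n < config$min_probes_per_segment) {
      warning("chromosome ", track$chrom[idx[1L]], " has ", n,
              " probes (< min_probes_per_segment); emitted as one segment")
      ends <- n
    } else {
      ends <- dp_segment_core(y, b, wl, wb, config$penalty,
                              config$min_probes_per_segment)
    }
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    bounds <- if (n > 1L) (pos[-n] + pos[-1L]) / 2 else numeric(0)
    g_start <- c(pos[1L], bounds)[starts]
    g_end <- c(bounds, pos[n] + 1)[ends]
    data.frame(
      chrom = track$chrom[idx[1L]],
      start = g_start, end = g_end,
      n_probes = ends - starts + 1L,
      n_informative = vapply(seq_along(ends), function(k) {
        sum(!is.na(b[starts[k]:ends[k]]))
      }, integer(1)),
      mean_logr = vapply(seq_along(ends), function(k) {
        mean(y[starts[k]:ends[k]])
      }, numeric(1)),
      # folding noise about 0.5 makes balanced segments look imbalanced;
      # E[(baf-0.5)^2] = delta^2 + sigma^2 gives an unbiased fold estimate
      mean_mbaf = vapply(seq_along(ends), function(k) {
        v <- b[starts[k]:ends[k]]
        if (all(is.na(v))) return(NA_real_)
        msq <- mean((v - 0.5)^2, na.rm = TRUE)
        0.5 + sqrt(max(msq - sigma_b^2, 0))
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces[unique(track$chrom)])
  rownames(out) <- NULL
  structure(out, sex = attr(track, "sex"), sigma_logr = sigma_l,
            sigma_baf = sigma_b,
            class = c("raw_segmentation", "data.frame"))
}
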