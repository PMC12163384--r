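#' Purity/ploidy fit configuration
#'
#' @param rho_grid purity grid (default `seq(0.10, 1.00, 0.01)`); the lower
#'   bound covers the 20% minimum pathologist tumor-content requirement with
#'   margin.
#' @param psi_grid ploidy grid (default `seq(1.0, 5.4, 0.05)`), in average
#'   copies per tumor cell.
#' @param gamma platform compression factor mapping copy-number ratios to
#'   LogR (default 0.55, customary for array platforms).
#' @param pathology_tumor_content optional pathologist purity estimate in
#'   `(0, 1]`; grid solutions outside `tolerance` of it are down-ranked (not
#'   excluded).
#' @param tolerance purity tolerance band around the pathology estimate
#'   (default 0.15).
#' @param downrank_weight multiplicative distance inflation per unit of
#'   excess deviation beyond the tolerance band (default 2).
#' @return list of class `fit_config`.
#' @export
fit_config <- function(rho_grid = seq(0.10, 1.00, by = 0.01),
                       psi_grid = seq(1.0, 5.4, by = 0.05),
                       gamma = 0.55,
                       pathology_tumor_content = NULL,
                       tolerance = 0.15,
                       downrank_weight = 2) {
  stopifnot(length(rho_grid) > 0, length(psi_grid) > 0,
            all(rho_grid > 0 & rho_grid <= 1),
            gamma > 0, gamma <= 1)
  if (!is.null(pathology_tumor_content)) {
    stopifnot(pathology_tumor_content > 0, pathology_tumor_content <= 1)
  }
  structure(list(rho_grid = rho_grid, psi_grid = psi_grid, gamma = gamma,
                 pathology_tumor_content = pathology_tumor_content,
                 tolerance = tolerance, downrank_weight = downrank_weight),
            class = "fit_config")
}

#' Continuous allele-specific copy numbers of one segment
#'
#' Inverts the forward signal model.  With tumor purity `rho`, tumor ploidy
#' `psi` and compression `gamma`, the total signal of a segment with mean
#' LogR `r` is `T = 2^(r/gamma) * (2*(1-rho) + rho*psi)`; the B-allele share
#' `b` then splits it as
#' `n_b = (T*b - (1-rho))/rho` and `n_a = (T*(1-b) - (1-rho))/rho`.
#'
#' @param seg_mean_logr segment mean LogR (vectorized).
#' @param seg_mean_baf segment mean BAF (or mirrored BAF) in `[0, 1]`.
#' @param rho purity in `(0, 1]`.
#' @param psi tumor ploidy (average copy number).
#' @param gamma compression factor.
#' @return list with numeric vectors `n_a` and `n_b` (continuous, may be
#'   negative for inconsistent parameters).
#' @examples
#' segment_copy_numbers(log2(1.5), 1/3, rho = 1, psi = 2, gamma = 1)  # (2, 1)
#' @export
segment_copy_numbers <- function(seg_mean_logr, seg_mean_baf, rho, psi,
                                 gamma = 0.55) {
  if (rho <= 0) stop("rho must be positive")
  total <- 2^(seg_mean_logr / gamma) * (2 * (1 - rho) + rho * psi)
  n_b <- (total * seg_mean_baf - (1 - rho)) / rho
  n_a <- (total * (1 - seg_mean_baf) - (1 - rho)) / rho
  list(n_a = n_a, n_b = n_b)
}

#' Purity/ploidy grid search ("sunrise" fit)
#'
#' For every `(rho, psi)` grid point, converts the informative segment means
#' (those with a mirrored-BAF estimate) to continuous allele-specific copy
#' numbers and scores the length-weighted squared distance to the nearest
#' non-negative integers; returns the arg-min together with the full
#' goodness-of-fit surface.  If a pathology tumor-content estimate is given,
#' solutions whose purity deviates beyond the tolerance band are down-ranked
#' by inflating their distance, never excluded.
#'
#' A profile in which every informative segment is allelically balanced and
#' the LogR is flat carries no purity/ploidy information; the fit is then
#' flagged `non_identifiable` (the surface is still returned).
#'
#' @param raw a [segment_track()] result.
#' @param config a [fit_config()].
#' @return list of class `ploidy_fit`: `rho`, `psi`, `gamma`, `fit_surface`
#'   (matrix rho x psi of raw distances), `rho_grid`, `psi_grid`,
#'   `non_identifiable`, `fixed_by_user` (FALSE).
#' @export
grid_search <- function(raw, config = fit_config()) {
  use <- !is.na(raw$mean_mbaf)
  if (!any(use)) stop("no informative segments (no mirrored-BAF estimates)")
  r <- raw$mean_logr[use]
  b <- raw$mean_mbaf[use]
  w <- (raw$end - raw$start)[use]
  w <- w / sum(w)

  flat <- (max(r) - min(r)) < 0.05 && all(abs(b - 0.5) < 0.02)

  rg <- config$rho_grid; pg <- config$psi_grid
  surface <- matrix(NA_real_, length(rg), length(pg),
                    dimnames = list(rho = sprintf("%.2f", rg),
                                    psi = sprintf("%.2f", pg)))
  for (i in seq_along(rg)) {
    rho <- rg[i]
    for (j in seq_along(pg)) {
      cn <- segment_copy_numbers(r, b, rho, pg[j], config$gamma)
      da <- cn$n_a - pmax(round(cn$n_a), 0)
      db <- cn$n_b - pmax(round(cn$n_b), 0)
      surface[i, j] <- sum(w * (da^2 + db^2))
    }
  }

  ranked <- surface
  if (!is.null(config$pathology_tumor_content)) {
    dev <- pmax(abs(rg - config$pathology_tumor_content) - config$tolerance, 0)
    ranked <- ranked * (1 + config$downrank_weight * dev)
  }

  # The fit surface carries exact affine degeneracies: mapping every state
  # n -> k*n + m (k >= 1, m >= 0 integers) yields another solution with
  # identical residuals at higher ploidy (k = 2, m = 0 is the genome-doubling
  # image; k = 1, m = 1 exists whenever rho < 0.5).  On the coarse grid an
  # image can even beat the true solution by chance, when its psi lies closer
  # to a grid value.  Near-optimal candidates are therefore re-scored with
  # psi refined locally (quasi-continuously), which restores the exact tie,
  # and a tiny additive ploidy/purity preference then resolves it toward the
  # parsimonious solution.
  dist_at <- function(rho, psi) {
    cn <- segment_copy_numbers(r, b, rho, psi, config$gamma)
    da <- cn$n_a - pmax(round(cn$n_a), 0)
    db <- cn$n_b - pmax(round(cn$n_b), 0)
    sum(w * (da^2 + db^2))
  }
  d_star <- min(ranked)
  cand <- which(ranked <= d_star + max(1e-3, 0.05 * d_star))
  if (length(cand) > 400L) cand <- cand[order(ranked[cand])][1:400]
  rho_step <- if (length(rg) > 1L) min(diff(rg)) else 0.01
  psi_step <- if (length(pg) > 1L) min(diff(pg)) else 0.05
  refined <- t(vapply(cand, function(idx) {
    i <- (idx - 1L) %% length(rg) + 1L
    j <- (idx - 1L) %/% length(rg) + 1L
    lo <- c(max(min(rg), rg[i] - 1.5 * rho_step),
            max(min(pg), pg[j] - 1.5 * psi_step))
    hi <- c(min(1, rg[i] + 1.5 * rho_step),
            min(max(pg), pg[j] + 1.5 * psi_step))
    opt <- stats::optim(c(rg[i], pg[j]), function(p) {
      if (any(p < lo) || any(p > hi)) return(Inf)
      dist_at(p[1L], p[2L])
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-12, maxit = 300L))
    c(opt$value, opt$par)
  }, numeric(3)))
  score <- refined[, 1L] + 1e-6 * refined[, 3L] + 1e-9 * (1 - refined[, 2L])
  ord <- order(score, refined[, 3L], -refined[, 2L])
  # report the grid point nearest the winning basin's refined optimum
  i <- which.min(abs(rg - refined[ord[1L], 2L]))
  j <- which.min(abs(pg - refined[ord[1L], 3L]))

  structure(list(rho = rg[i], psi = pg[j], gamma = config$gamma,
                 fit_surface = surface, rho_grid = rg, psi_grid = pg,
                 min_distance = surface[i, j],
                 non_identifiable = flat, fixed_by_user = FALSE),
            class = "ploidy_fit")
}

#' Fixed-parameter fit (manual purity/ploidy adjustment path)
#'
#' Used when the analyst overrides the grid solution, e.g. after comparing the
#' predicted tumor content with the pathologist estimate.
#'
#' @param rho,psi user-chosen purity and ploidy.
#' @param gamma compression factor.
#' @return a `ploidy_fit` flagged `fixed_by_user`.
#' @export
fixed_fit <- function(rho, psi, gamma = 0.55) {
  stopifnot(rho > 0, rho <= 1, psi > 0)
  structure(list(rho = rho, psi = psi, gamma = gamma, fit_surface = NULL,
                 rho_grid = NULL, psi_grid = NULL, min_distance = NA_real_,
                 non_identifiable = FALSE, fixed_by_user = TRUE),
            class = "ploidy_fit")
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat(sprintf("<ploidy_fit> rho = %.2f, psi = %.2f, gamma = %.2f%s%s\n",
              x$rho, x$psi, x$gamma,
              if (isTRUE(x$non_identifiable)) " [non-identifiable]" else "",
              if (isTRUE(x$fixed_by_user)) " [fixed by user]" else ""))
  invisible(x)
}

#' Integer allele-specific copy-number profile from a fitted grid point
#'
#' Converts every segment mean to continuous copy numbers at the fitted
#' `(rho, psi)`, rounds to the nearest non-negative integers (negative values
#' are clamped to 0 and counted), orders alleles as major >= minor, extends
#' the outermost segments of each chromosome to the chromosome ends, and
#' merges adjacent segments in the same state.
#'
#' Segments without a BAF estimate (no informative probes, e.g. the sex
#' chromosomes of an XY sample) get their rounded total split as evenly as
#' the integer allows (major = ceiling, minor = floor of total/2).
#'
#' @param raw a [segment_track()] result.
#' @param fit a `ploidy_fit` from [grid_search()] or [fixed_fit()].
#' @param genome a `genome_build`.
#' @return a [segment_profile()]; attribute `n_clamped` counts alleles
#'   clamped at 0.
#' @export
fit_profile <- function(raw, fit, genome) {
  sex <- attr(raw, "sex")
  if (is.null(sex)) sex <- "XX"
  rho <- fit$rho; psi <- fit$psi; gamma <- fit$gamma
  n_clamped <- 0L

  has_baf <- !is.na(raw$mean_mbaf)
  n_major <- n_minor <- numeric(nrow(raw))
  if (any(has_baf)) {
    cn <- segment_copy_numbers(raw$mean_logr[has_baf], raw$mean_mbaf[has_baf],
                               rho, psi, gamma)
    a <- round(cn$n_a); b <- round(cn$n_b)
    n_clamped <- n_clamped + sum(a < 0) + sum(b < 0)
    a <- pmax(a, 0); b <- pmax(b, 0)
    n_major[has_baf] <- pmax(a, b)
    n_minor[has_baf] <- pmin(a, b)
  }
  if (any(!has_baf)) {
    total <- 2^(raw$mean_logr[!has_baf] / gamma) * (2 * (1 - rho) + rho * psi)
    nt <- round((total - 2 * (1 - rho)) / rho)
    n_clamped <- n_clamped + sum(nt < 0)
    nt <- pmax(nt, 0)
    n_major[!has_baf] <- ceiling(nt / 2)
    n_minor[!has_baf] <- floor(nt / 2)
  }
  if (n_clamped > 0L) {
    warning(n_clamped, " allele value(s) clamped at 0")
  }

  seg <- data.frame(chrom = raw$chrom, start = raw$start, end = raw$end,
                    n_major = n_major, n_minor = n_minor,
                    stringsAsFactors = FALSE)
  # extend to chromosome bounds, then merge same-state neighbours
  pieces <- lapply(split(seg, seg$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    ci <- genome_chrom(genome, s$chrom[1L])
    s$start[1L] <- 0
    s$end[nrow(s)] <- ci$length
    keep <- c(TRUE, s$n_major[-1L] != s$n_major[-nrow(s)] |
                s$n_minor[-1L] != s$n_minor[-nrow(s)])
    grp <- cumsum(keep)
    data.frame(chrom = s$chrom[1L],
               start = tapply(s$start, grp, min),
               end = tapply(s$end, grp, max),
               n_major = s$n_major[keep], n_minor = s$n_minor[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces[unique(seg$chrom)])
  prof <- segment_profile(out$chrom, out$start, out$end, out$n_major,
                          out$n_minor, sex = sex)
  attr(prof, "n_clamped") <- n_clamped
  prof
}
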