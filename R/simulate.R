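#' Simulation configuration
#'
#' Parameters of the clonal-tumor genome simulator that stands in for array
#' data: a purity/ploidy forward model over a diploid (or re-based) genome
#' with injected, unambiguously qualifying scar events.
#'
#' @param seed integer RNG seed; the whole run uses one seeded stream.
#' @param sex `"XX"` or `"XY"`.
#' @param rho tumor purity in `(0, 1]` (default 0.6, a typical pathologist
#'   tumor-content estimate well above the 20% acceptance minimum).
#' @param psi_base baseline ploidy: 2 gives a (1,1) diploid background, 4 a
#'   (2,2) genome-doubled background, 1 a (1,0) haploid-like background.
#' @param n_loh,n_lst,n_tai numbers of injected qualifying events of each
#'   scar type.
#' @param probe_spacing probe spacing in bp (default 100,000).
#' @param sigma_logr,sigma_baf Gaussian noise SDs on LogR and BAF (defaults
#'   0.12 and 0.03).
#' @param het_fraction fraction of probes that are germline-heterozygous
#'   (default 0.25).
#' @param gamma platform compression factor of the forward model (default
#'   0.55, matching the fitting default).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, sex = "XX", rho = 0.6, psi_base = 2,
                       n_loh = 0, n_lst = 0, n_tai = 0,
                       probe_spacing = 1e5, sigma_logr = 0.12,
                       sigma_baf = 0.03, het_fraction = 0.25, gamma = 0.55) {
  stopifnot(sex %in% c("XX", "XY"), rho > 0, rho <= 1, psi_base >= 1,
            n_loh >= 0, n_lst >= 0, n_tai >= 0, probe_spacing > 0,
            sigma_logr >= 0, sigma_baf >= 0,
            het_fraction > 0, het_fraction <= 1)
  structure(list(seed = as.integer(seed), sex = sex, rho = rho,
                 psi_base = psi_base, n_loh = n_loh, n_lst = n_lst,
                 n_tai = n_tai, probe_spacing = probe_spacing,
                 sigma_logr = sigma_logr, sigma_baf = sigma_baf,
                 het_fraction = het_fraction, gamma = gamma),
            class = "sim_config")
}

MB <- 1e6

#' Build a ground-truth genome with injected scar events
#'
#' Starts from a uniform baseline (state `(ceiling(psi_base/2),
#' floor(psi_base/2))` on autosomes; `(1, 0)` on X and Y for XY samples) and
#' places each requested event on its own autosome, so events of different
#' scar types never share a chromosome arm and are separated by far more than
#' 20 Mb:
#'
#' * LOH events straddle the centromere with arm overhangs drawn uniformly in
#'   6.5-9 Mb per side (total span 16-21 Mb, > 15 Mb with margin); each arm
#'   portion is under 10 Mb, so the event's boundaries never qualify as LSTs,
#'   and the run never reaches a telomere, so it cannot count as TAI.  The
#'   state is copy-loss `(1, 0)` or copy-neutral `(2, 0)` at random.
#' * LST events change the q-arm terminal 12-30 Mb to a balanced gain (both
#'   alleles + 1), creating exactly one state transition with >= 10 Mb flanks
#'   and, being balanced, no allelic imbalance.
#' * TAI events change the q-arm terminal 5.5-9.5 Mb to a single-allele gain
#'   (major + 1): an imbalanced telomere-touching run short enough that its
#'   boundary never counts as an LST.
#'
#' @param genome a `genome_build`.
#' @param config a [sim_config()].
#' @return list of class `sim_truth`: `profile` (a [segment_profile()]
#'   covering every scored chromosome end to end), `rho`, `psi` (the
#'   length-weighted mean total copy number of the truth profile), `events`
#'   (per-type interval tables), `config`.
#' @export
inject_scars <- function(genome, config) {
  set.seed(config$seed)
  base_major <- ceiling(config$psi_base / 2)
  base_minor <- floor(config$psi_base / 2)
  if (config$n_tai > 0 && base_major == base_minor + 1) {
    stop("infeasible request: TAI events are indistinguishable from an ",
         "allelically imbalanced baseline (odd psi_base)")
  }
  autosomes <- paste0("chr", 1:22)
  n_events <- config$n_loh + config$n_lst + config$n_tai
  if (n_events > length(autosomes)) {
    stop("infeasible request: ", n_events, " events exceed the ",
         length(autosomes), " available autosomes")
  }
  host <- sample(autosomes, n_events)
  types <- rep(c("loh", "lst", "tai"),
               c(config$n_loh, config$n_lst, config$n_tai))

  events <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), n_major = numeric(0),
                       n_minor = numeric(0), type = character(0),
                       stringsAsFactors = FALSE)
  for (k in seq_along(types)) {
    ci <- genome_chrom(genome, host[k])
    if (types[k] == "loh") {
      o_p <- stats::runif(1, 6.5, 9) * MB
      o_q <- stats::runif(1, 6.5, 9) * MB
      st <- if (stats::runif(1) < 0.5) c(1, 0) else c(2, 0)
      ev <- data.frame(chrom = host[k], start = ci$cen_start - o_p,
                       end = ci$cen_end + o_q, n_major = st[1L],
                       n_minor = st[2L], type = "loh")
    } else if (types[k] == "lst") {
      q_len <- ci$length - ci$cen_end
      d <- stats::runif(1, 12, min(30, q_len / MB - 11)) * MB
      ev <- data.frame(chrom = host[k], start = ci$length - d,
                       end = ci$length, n_major = base_major + 1,
                       n_minor = base_minor + 1, type = "lst")
    } else {
      t_len <- stats::runif(1, 5.5, 9.5) * MB
      ev <- data.frame(chrom = host[k], start = ci$length - t_len,
                       end = ci$length, n_major = base_major + 1,
                       n_minor = base_minor, type = "tai")
    }
    events <- rbind(events, ev)
  }

  rows <- list()
  for (ch in scored_chromosomes(genome, config$sex)) {
    ci <- genome_chrom(genome, ch)
    if (ch %in% c("chrX", "chrY") && config$sex == "XY") {
      bm <- 1; bn <- 0
    } else {
      bm <- base_major; bn <- base_minor
    }
    ev <- events[events$chrom == ch, , drop = FALSE]
    cuts <- sort(unique(c(0, ci$length, ev$start, ev$end)))
    for (i in seq_len(length(cuts) - 1L)) {
      s <- cuts[i]; e <- cuts[i + 1L]
      hit <- which(ev$start <= s & ev$end >= e)
      if (length(hit) == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = s, end = e,
          n_major = ev$n_major[hit], n_minor = ev$n_minor[hit])
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = s, end = e, n_major = bm, n_minor = bn)
      }
    }
  }
  tab <- do.call(rbind, rows)
  profile <- segment_profile(tab$chrom, tab$start, tab$end, tab$n_major,
                             tab$n_minor, sex = config$sex)
  len <- profile$end - profile$start
  psi <- sum(len * (profile$n_major + profile$n_minor)) / sum(len)
  structure(list(profile = profile, rho = config$rho, psi = psi,
                 events = split(events, events$type), config = config),
            class = "sim_truth")
}

#' Render a probe track from a truth genome
#'
#' The exact algebraic inverse of [segment_copy_numbers()]: per probe,
#' expected LogR is
#' `gamma * log2((2*(1-rho) + rho*(n_a+n_b)) / (2*(1-rho) + rho*psi))` and,
#' for informative probes, expected BAF is
#' `((1-rho) + rho*n_b_allele) / (2*(1-rho) + rho*(n_a+n_b))` with the B
#' allele assigned to the major or minor copy at random per probe.
#' Non-informative probes are germline-homozygous (expected BAF 0 or 1).
#' Gaussian noise is then added and BAF is clipped to `[0, 1]`.
#'
#' @param truth a [inject_scars()] result.
#' @param config a [sim_config()] (defaults to the one inside `truth`).
#' @return a [probe_track()].
#' @export
render_probes <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  rho <- truth$rho
  norm_total <- 2 * (1 - rho) + rho * truth$psi
  prof <- truth$profile

  pieces <- lapply(unique(prof$chrom), function(ch) {
    s <- prof[prof$chrom == ch, , drop = FALSE]
    chrom_len <- max(s$end)
    pos <- seq(config$probe_spacing / 2, chrom_len - 1,
               by = config$probe_spacing)
    seg_idx <- findInterval(pos, s$start)
    total <- s$n_major[seg_idx] + s$n_minor[seg_idx]
    logr <- config$gamma *
      log2((2 * (1 - rho) + rho * total) / norm_total)
    hemizygous <- ch %in% c("chrX", "chrY") && config$sex == "XY"
    informative <- if (hemizygous) rep(FALSE, length(pos)) else
      stats::runif(length(pos)) < config$het_fraction
    b_copies <- ifelse(stats::runif(length(pos)) < 0.5,
                       s$n_major[seg_idx], s$n_minor[seg_idx])
    baf <- ifelse(informative,
                  ((1 - rho) + rho * b_copies) /
                    (2 * (1 - rho) + rho * total),
                  ifelse(stats::runif(length(pos)) < 0.5, 0, 1))
    data.frame(chrom = ch, pos = pos, logr = logr, baf = baf,
               informative = informative, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, pieces)
  d$logr <- d$logr + stats::rnorm(nrow(d), 0, config$sigma_logr)
  d$baf <- pmin(pmax(d$baf + stats::rnorm(nrow(d), 0, config$sigma_baf), 0), 1)
  probe_track(sprintf("P%07d", seq_len(nrow(d))), d$chrom, d$pos, d$logr,
              d$baf, d$informative, sex = config$sex)
}

#' Simulate a complete sample (truth + probe track)
#'
#' @param genome a `genome_build`.
#' @param config a [sim_config()].
#' @return list with `truth` (a `sim_truth`) and `track` (a [probe_track()]).
#' @export
simulate_sample <- function(genome, config) {
  truth <- inject_scars(genome, config)
  list(truth = truth, track = render_probes(truth, config))
}
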