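#' Construct a probe track
#'
#' A probe track holds per-probe LogR and B-allele-frequency observations,
#' ordered by position within each chromosome, with a flag marking
#' germline-heterozygous (informative) SNP probes.
#'
#' @param probe_id character probe identifiers.
#' @param chrom chromosome labels.
#' @param pos 0-based probe positions (strictly increasing per chromosome).
#' @param logr log2 intensity ratios (finite).
#' @param baf B-allele frequencies in `[0, 1]`.
#' @param informative logical, `TRUE` for germline-heterozygous SNPs.
#' @param sex `"XX"` or `"XY"`.
#' @return data.frame of class `probe_track` with attribute `sex`.
#' @export
probe_track <- function(probe_id, chrom, pos, logr, baf, informative,
                        sex = "XX") {
  stopifnot(sex %in% c("XX", "XY"))
  x <- data.frame(
    probe_id = as.character(probe_id),
    chrom = as.character(chrom),
    pos = as.numeric(pos),
    logr = as.numeric(logr),
    baf = as.numeric(baf),
    informative = as.logical(informative),
    stringsAsFactors = FALSE
  )
  x <- x[order(match(x$chrom, unique(x$chrom)), x$pos), , drop = FALSE]
  rownames(x) <- NULL
  validate_probe_track(x)
  structure(x, sex = sex, class = c("probe_track", "data.frame"))
}

validate_probe_track <- function(x) {
  if (any(!is.finite(x$logr))) stop("logr must be finite")
  if (any(!is.finite(x$baf)) || any(x$baf < 0 | x$baf > 1)) {
    stop("baf must lie in [0, 1]")
  }
  if (anyNA(x$informative)) stop("informative flag must be TRUE/FALSE")
  dup <- unlist(tapply(x$pos, x$chrom, function(p) duplicated(p)))
  if (any(dup)) stop("duplicate probe positions within a chromosome")
  ok <- tapply(x$pos, x$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(ok))) stop("positions must be strictly increasing")
  invisible(x)
}

#' Read a probe track from TSV
#'
#' Expects a tab-separated file with header columns `probe_id`, `chrom`,
#' `pos`, `logr`, `baf`, `informative`; positions on disk are 1-based.
#'
#' @param path file path.
#' @param sex `"XX"` or `"XY"`.
#' @return a [probe_track()].
#' @export
read_probe_track <- function(path, sex = "XX") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("probe_id", "chrom", "pos", "logr", "baf", "informative")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("probe table is missing column(s): ", paste(missing, collapse = ", "))
  }
  num <- c("pos", "logr", "baf")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(v) && !anyNA(tab[[cn]])) stop("non-numeric values in column ", cn)
    tab[[cn]] <- v
  }
  probe_track(tab$probe_id, tab$chrom, tab$pos - 1, tab$logr, tab$baf,
              as.logical(tab$informative), sex = sex)
}

#' Write a probe track to TSV
#'
#' @param track a [probe_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_probe_track <- function(track, path) {
  out <- as.data.frame(track)
  out$pos <- out$pos + 1  # 1-based on disk
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an allele-specific segment profile
#'
#' The substrate of scar scoring: ordered, non-overlapping segments per
#' chromosome carrying integer major/minor copy numbers with
#' `n_major >= n_minor >= 0`.
#'
#' @param chrom chromosome labels.
#' @param start,end 0-based half-open segment intervals.
#' @param n_major,n_minor non-negative integer allele-specific copy numbers.
#' @param sex `"XX"` or `"XY"`.
#' @return data.frame of class `segment_profile` with attribute `sex`.
#' @export
segment_profile <- function(chrom, start, end, n_major, n_minor, sex = "XX") {
  stopifnot(sex %in% c("XX", "XY"))
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    n_major = as.numeric(n_major),
    n_minor = as.numeric(n_minor),
    stringsAsFactors = FALSE
  )
  x <- x[order(match(x$chrom, unique(x$chrom)), x$start), , drop = FALSE]
  rownames(x) <- NULL
  validate_segment_profile(x)
  structure(x, sex = sex, class = c("segment_profile", "data.frame"))
}

validate_segment_profile <- function(x) {
  if (any(x$n_major < 0 | x$n_minor < 0)) stop("negative copy number")
  if (any(x$n_major != round(x$n_major) | x$n_minor != round(x$n_minor))) {
    stop("copy numbers must be integers")
  }
  if (any(x$n_minor > x$n_major)) stop("n_minor > n_major")
  if (any(x$start >= x$end)) stop("segment with start >= end")
  by_chrom <- split(x, x$chrom)
  for (seg in by_chrom) {
    if (nrow(seg) > 1L && any(seg$start[-1L] < seg$end[-nrow(seg)])) {
      stop("overlapping segments on ", seg$chrom[1L])
    }
  }
  invisible(x)
}

#' Read an allele-specific segment profile from TSV
#'
#' Columns `chrom`, `start`, `end`, `n_major`, `n_minor`; coordinates on disk
#' are 1-based inclusive.
#'
#' @inheritParams read_probe_track
#' @return a [segment_profile()].
#' @export
read_segment_profile <- function(path, sex = "XX") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "n_major", "n_minor")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("segment table is missing column(s): ", paste(missing, collapse = ", "))
  }
  segment_profile(tab$chrom, tab$start - 1, tab$end, tab$n_major, tab$n_minor,
                  sex = sex)
}

#' Write a segment profile (native TSV plus SEG companion)
#'
#' Writes the native allele-specific table (1-based inclusive coordinates) and,
#' alongside it, a SEG-format file of total copy number with
#' `seg.mean = log2(total / 2)` (total 0 is floored at log2 of 0.01 for
#' display).
#'
#' @param profile a [segment_profile()].
#' @param path output path for the native table; the SEG file is written to
#'   `sub("\\\\.tsv$", "", path)` plus `".seg"`.
#' @param sample_id sample name recorded in the SEG file.
#' @return `path`, invisibly.
#' @export
write_segment_profile <- function(profile, path, sample_id = "sample") {
  out <- as.data.frame(profile)
  out$start <- out$start + 1
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  total <- profile$n_major + profile$n_minor
  seg <- data.frame(
    sample = sample_id,
    chrom = profile$chrom,
    loc.start = profile$start + 1,
    loc.end = profile$end,
    num.mark = NA_integer_,
    seg.mean = log2(pmax(total, 0.01) / 2)
  )
  seg_path <- paste0(sub("\\.tsv$", "", path), ".seg")
  utils::write.table(seg, seg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Median absolute pairwise difference (MAPD) of a probe track
#'
#' The array noise metric: the median over consecutive same-chromosome probe
#' pairs of the absolute LogR difference.  Chromosome boundaries contribute no
#' pair, so cross-chromosome jumps are never counted as noise.
#'
#' @param track a [probe_track()].
#' @return A non-negative scalar.
#' @export
mapd <- function(track) {
  diffs <- unlist(lapply(split(track$logr, track$chrom), function(v) {
    if (length(v) >= 2L) abs(diff(v)) else numeric(0)
  }), use.names = FALSE)
  if (length(diffs) == 0L) {
    stop("MAPD undefined: no chromosome has 2 or more probes")
  }
  stats::median(diffs)
}

#' Assemble QC metrics for a sample
#'
#' @param mapd MAPD value (see [mapd()]).
#' @param nd_snp_qc optional ndSNPQC value, a vendor metric computed on normal
#'   diploid SNP markers; it is accepted as externally supplied (no published
#'   formula) and only compared against its threshold.
#' @return list of class `qc_metrics`.
#' @export
qc_metrics <- function(mapd, nd_snp_qc = NULL) {
  stopifnot(is.numeric(mapd), mapd >= 0)
  structure(list(mapd = mapd, nd_snp_qc = nd_snp_qc), class = "qc_metrics")
}

#' Quality-control gate
#'
#' A sample passes iff MAPD <= 0.30 and, when supplied, ndSNPQC >= 26
#' (both comparisons inclusive).  An absent ndSNPQC is reported but is not a
#' failure.
#'
#' @param metrics a [qc_metrics()] object.
#' @param mapd_max MAPD threshold (default 0.30).
#' @param nd_snp_qc_min ndSNPQC threshold (default 26).
#' @return list with elements `pass` (logical) and `reasons` (character vector
#'   naming every violated rule; empty when passing).
#' @export
qc_gate <- function(metrics, mapd_max = 0.30, nd_snp_qc_min = 26) {
  reasons <- character(0)
  if (is.null(metrics$mapd)) {
    reasons <- c(reasons, "MAPD absent")
  } else if (metrics$mapd > mapd_max) {
    reasons <- c(reasons, sprintf("MAPD %.3f > %.2f", metrics$mapd, mapd_max))
  }
  if (!is.null(metrics$nd_snp_qc) && metrics$nd_snp_qc < nd_snp_qc_min) {
    reasons <- c(reasons, sprintf("ndSNPQC %.1f < %g", metrics$nd_snp_qc,
                                  nd_snp_qc_min))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
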