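#' Load a reference genome coordinate model
#'
#' Builds the chromosome/arm/centromere coordinate model consumed by the scar
#' counting rules.  The only bundled build is hg19 (the build used by the
#' scoring pipeline); alternatively a user-supplied table in the same format
#' can be loaded by path.
#'
#' Coordinates are stored internally as 0-based half-open intervals; the
#' on-disk table is 1-based inclusive.  The centromere span of each chromosome
#' separates the p arm `[0, centromere_start)` from the q arm
#' `[centromere_end, length)`.
#'
#' @param build_name `"hg19"` or a path to a tab-separated table with columns
#'   `chrom`, `length`, `centromere_start`, `centromere_end` (1-based
#'   inclusive).
#' @return An object of class `genome_build`: a list with elements `name` and
#'   `chromosomes` (a data.frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end`, 0-based half-open).
#' @examples
#' g <- load_genome("hg19")
#' nrow(g$chromosomes)  # 24
#' @export
load_genome <- function(build_name = "hg19") {
  if (identical(build_name, "hg19")) {
    path <- system.file("extdata", "hg19_genome.tsv", package = "openhrd",
                        mustWork = TRUE)
    name <- "hg19"
  } else if (file.exists(build_name)) {
    path <- build_name
    name <- tools::file_path_sans_ext(basename(build_name))
  } else {
    stop("unknown build: '", build_name,
         "' (only 'hg19' is bundled; otherwise give a path to a genome table)")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "length", "centromere_start", "centromere_end")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("malformed genome table: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  chroms <- data.frame(
    chrom     = as.character(tab$chrom),
    length    = as.numeric(tab$length),
    cen_start = as.numeric(tab$centromere_start) - 1,  # to 0-based half-open
    cen_end   = as.numeric(tab$centromere_end),
    stringsAsFactors = FALSE
  )
  bad <- !(chroms$cen_start > 0 & chroms$cen_start < chroms$cen_end &
             chroms$cen_end < chroms$length)
  if (any(bad) || anyNA(chroms$length)) {
    stop("malformed genome table: inverted or out-of-range centromere span ",
         "for ", paste(chroms$chrom[bad], collapse = ", "))
  }
  if (anyDuplicated(chroms$chrom)) {
    stop("malformed genome table: duplicated chromosome labels")
  }
  structure(list(name = name, chromosomes = chroms), class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build>", x$name, "-", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp\n")
  invisible(x)
}

genome_chrom <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  genome$chromosomes[i, ]
}

#' Classify a genomic position into chromosome arm
#'
#' @param genome a `genome_build` from [load_genome()].
#' @param chrom chromosome label (e.g. `"chr1"`).
#' @param pos 0-based position(s), each in `[0, length)`.
#' @return Character vector over `{"p", "q", "centromeric"}`.
#' @examples
#' g <- load_genome("hg19")
#' arm_of(g, "chr1", 0)  # "p"
#' @export
arm_of <- function(genome, chrom, pos) {
  ci <- genome_chrom(genome, chrom)
  if (any(pos < 0 | pos >= ci$length)) {
    stop("position out of range for ", chrom, " (length ", ci$length, ")")
  }
  ifelse(pos < ci$cen_start, "p",
         ifelse(pos >= ci$cen_end, "q", "centromeric"))
}

#' Arm intervals of a chromosome
#'
#' @inheritParams arm_of
#' @return data.frame with columns `arm`, `start`, `end` (0-based half-open):
#'   the p arm, the centromere span, and the q arm.
#' @keywords internal
arm_intervals <- function(genome, chrom) {
  ci <- genome_chrom(genome, chrom)
  data.frame(
    arm   = c("p", "centromeric", "q"),
    start = c(0, ci$cen_start, ci$cen_end),
    end   = c(ci$cen_start, ci$cen_end, ci$length),
    stringsAsFactors = FALSE
  )
}

#' Chromosomes scored for a sample of a given sex
#'
#' Autosomes and chrX are always scored; chrY only for XY samples.
#' @inheritParams arm_of
#' @param sex `"XX"` or `"XY"`.
#' @keywords internal
scored_chromosomes <- function(genome, sex) {
  stopifnot(sex %in% c("XX", "XY"))
  chroms <- genome$chromosomes$chrom
  if (sex == "XX") chroms <- setdiff(chroms, "chrY")
  chroms
}
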