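#' Run the full scoring pipeline on a probe track
#'
#' Chains QC gating, segmentation, purity/ploidy fitting, integer
#' allele-specific copy-number calling and scar counting; optionally applies
#' a score calibration and the 42-point HRD classification.  QC failure
#' aborts scoring unless `force = TRUE`; a non-identifiable purity/ploidy fit
#' aborts unless `fix_rho`/`fix_psi` are supplied.
#'
#' @param track a [probe_track()] (or a path to a probe TSV).
#' @param genome a `genome_build` (default bundled hg19).
#' @param sex `"XX"` or `"XY"` (used when `track` is a path).
#' @param tumor_content optional pathologist purity estimate, used as a soft
#'   constraint of the grid search.
#' @param nd_snp_qc optional externally supplied ndSNPQC value.
#' @param calibration optional [fit_calibration()] model; when given, the
#'   report carries the corrected score and the HRD call.
#' @param seg_config,fit_cfg,scar_cfg stage configurations.
#' @param fix_rho,fix_psi optional manual purity/ploidy override (both must
#'   be given together).
#' @param force proceed despite QC failure (recorded in the report).
#' @param sample_id sample name recorded in the report.
#' @return list of class `run_report` with elements `sample_id`, `qc`,
#'   `fit`, `profile`, `scars`, `gis_raw`, `gis_corrected`, `hrd_call`,
#'   `version`, `config`.
#' @export
run_pipeline <- function(track, genome = load_genome("hg19"), sex = "XX",
                         tumor_content = NULL, nd_snp_qc = NULL,
                         calibration = NULL,
                         seg_config = segmentation_config(),
                         fit_cfg = fit_config(),
                         scar_cfg = scar_config(),
                         fix_rho = NULL, fix_psi = NULL,
                         force = FALSE, sample_id = "sample") {
  if (is.character(track)) track <- read_probe_track(track, sex = sex)
  sex <- attr(track, "sex")

  metrics <- qc_metrics(mapd(track), nd_snp_qc)
  gate <- qc_gate(metrics)
  if (!gate$pass && !force) {
    stop(openhrd_error("openhrd_qc_error",
                       paste("QC failure:",
                             paste(gate$reasons, collapse = "; "))))
  }

  raw <- segment_track(track, seg_config)

  if (!is.null(fix_rho) || !is.null(fix_psi)) {
    if (is.null(fix_rho) || is.null(fix_psi)) {
      stop("fix_rho and fix_psi must be given together")
    }
    fit <- fixed_fit(fix_rho, fix_psi, fit_cfg$gamma)
  } else {
    cfg <- fit_cfg
    cfg$pathology_tumor_content <- tumor_content
    fit <- grid_search(raw, cfg)
    if (fit$non_identifiable) {
      stop(openhrd_error("openhrd_fit_error",
                         paste("purity/ploidy not identifiable (flat,",
                               "balanced profile); re-run with",
                               "fix_rho/fix_psi")))
    }
  }

  profile <- fit_profile(raw, fit, genome)
  scars <- gis_score(profile, genome, scar_cfg)

  gis_corrected <- NULL; hrd_call <- NULL
  if (!is.null(calibration)) {
    gis_corrected <- apply_calibration(scars$gis, calibration)
    hrd_call <- classify_hrd(gis_corrected)
  }

  structure(list(
    sample_id = sample_id,
    qc = list(mapd = metrics$mapd, nd_snp_qc = metrics$nd_snp_qc,
              pass = gate$pass, reasons = gate$reasons),
    fit = list(rho = fit$rho, psi = fit$psi, gamma = fit$gamma,
               fixed_by_user = fit$fixed_by_user,
               non_identifiable = fit$non_identifiable),
    profile = profile,
    scars = scars,
    gis_raw = scars$gis,
    gis_corrected = gis_corrected,
    hrd_call = hrd_call,
    version = as.character(utils::packageVersion("openhrd")),
    config = list(segmentation = unclass(seg_config),
                  fit = unclass(fit_cfg)[c("gamma")],
                  scars = unclass(scar_cfg),
                  tumor_content = tumor_content)
  ), class = "run_report")
}

openhrd_error <- function(class, message) {
  structure(class = c(class, "error", "condition"),
            list(message = message, call = NULL))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$sample_id, "\n")
  cat(sprintf("  QC: MAPD %.3f -> %s\n", x$qc$mapd,
              if (x$qc$pass) "pass" else
                paste("FAIL:", paste(x$qc$reasons, collapse = "; "))))
  cat(sprintf("  fit: rho %.2f, psi %.2f\n", x$fit$rho, x$fit$psi))
  cat(sprintf("  scars: LOH %d + LST %d + TAI %d = GIS %d\n",
              x$scars$loh, x$scars$lst, x$scars$tai, x$gis_raw))
  if (!is.null(x$gis_corrected)) {
    cat(sprintf("  corrected GIS %.2f -> %s\n", x$gis_corrected, x$hrd_call))
  }
  invisible(x)
}

#' Write a run report (JSON plus plots) to a directory
#'
#' Emits `report.json`, the fitted profile (`profile.tsv` + SEG companion),
#' a BED file of scar events, and the three standard plots: allele-specific
#' copy number (major in red, minor in green), BAF scatter, and the sunrise
#' goodness-of-fit heatmap.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @param track the probe track, for the BAF plot (optional).
#' @param fit the full `ploidy_fit`, for the sunrise plot (optional).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir, track = NULL, fit = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- unclass(report)
  js$profile <- NULL
  js$scars <- list(loh = report$scars$loh, lst = report$scars$lst,
                   tai = report$scars$tai, gis = report$scars$gis)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write_segment_profile(report$profile, file.path(out_dir, "profile.tsv"),
                        sample_id = report$sample_id)
  write_scar_bed(report$scars, file.path(out_dir, "scar_events.bed"))
  plot_ascn_profile(report$profile,
                    path = file.path(out_dir, "ascn_profile.png"))
  if (!is.null(track)) {
    plot_baf(track, path = file.path(out_dir, "baf.png"))
  }
  if (!is.null(fit) && !is.null(fit$fit_surface)) {
    plot_sunrise(fit, path = file.path(out_dir, "sunrise.png"))
  }
  invisible(out_dir)
}

write_scar_bed <- function(scars, path) {
  rows <- list()
  for (type in c("loh", "tai")) {
    ev <- scars$events[[type]]
    if (nrow(ev)) {
      rows[[type]] <- data.frame(chrom = ev$chrom, start = ev$start,
                                 end = ev$end, name = toupper(type))
    }
  }
  lst <- scars$events$lst
  if (!is.null(lst) && nrow(lst)) {
    rows$lst <- data.frame(chrom = lst$chrom, start = floor(lst$pos),
                           end = floor(lst$pos) + 1, name = "LST")
  }
  bed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               name = character(0))
  utils::write.table(format(bed, scientific = FALSE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

genome_offsets <- function(chroms, widths) {
  off <- cumsum(c(0, utils::head(widths, -1)))
  names(off) <- chroms
  off
}

#' Allele-specific copy-number plot
#'
#' Major copy number in red (upper track), minor in green (lower track),
#' chromosomes laid end to end.
#'
#' @param profile a [segment_profile()].
#' @param path optional PNG path; when `NULL`, draws on the active device.
#' @export
plot_ascn_profile <- function(profile, path = NULL) {
  chroms <- unique(profile$chrom)
  widths <- vapply(chroms, function(ch) max(profile$end[profile$chrom == ch]),
                   numeric(1))
  off <- genome_offsets(chroms, widths)
  if (!is.null(path)) grDevices::png(path, width = 1400, height = 400)
  on.exit(if (!is.null(path)) grDevices::dev.off(), add = TRUE)
  ymax <- max(profile$n_major, 4) + 0.5
  graphics::plot(NULL, xlim = c(0, sum(widths)), ylim = c(-0.3, ymax),
                 xlab = "", ylab = "copy number", xaxt = "n",
                 main = "Allele-specific copy number")
  graphics::axis(1, at = off + widths / 2, labels = sub("chr", "", chroms),
                 tick = FALSE, cex.axis = 0.8)
  graphics::abline(v = c(off, sum(widths)), col = "grey85")
  x0 <- off[profile$chrom] + profile$start
  x1 <- off[profile$chrom] + profile$end
  graphics::segments(x0, profile$n_major + 0.07, x1, profile$n_major + 0.07,
                     col = "red", lwd = 3)
  graphics::segments(x0, profile$n_minor - 0.07, x1, profile$n_minor - 0.07,
                     col = "green3", lwd = 3)
  invisible(NULL)
}

#' B-allele frequency plot
#'
#' @param track a [probe_track()].
#' @param path optional PNG path.
#' @export
plot_baf <- function(track, path = NULL) {
  chroms <- unique(track$chrom)
  widths <- vapply(chroms, function(ch) max(track$pos[track$chrom == ch]) + 1,
                   numeric(1))
  off <- genome_offsets(chroms, widths)
  if (!is.null(path)) grDevices::png(path, width = 1400, height = 300)
  on.exit(if (!is.null(path)) grDevices::dev.off(), add = TRUE)
  graphics::plot(off[track$chrom] + track$pos, track$baf, pch = ".",
                 col = ifelse(track$informative, "blue", "grey70"),
                 xlab = "", ylab = "BAF", xaxt = "n", ylim = c(0, 1),
                 main = "B-allele frequency")
  graphics::axis(1, at = off + widths / 2, labels = sub("chr", "", chroms),
                 tick = FALSE, cex.axis = 0.8)
  graphics::abline(h = 0.5, col = "grey50", lty = 2)
  invisible(NULL)
}

#' Sunrise plot (purity/ploidy goodness-of-fit surface)
#'
#' @param fit a `ploidy_fit` from [grid_search()].
#' @param path optional PNG path.
#' @export
plot_sunrise <- function(fit, path = NULL) {
  if (is.null(fit$fit_surface)) stop("fit has no surface (fixed by user?)")
  if (!is.null(path)) grDevices::png(path, width = 600, height = 500)
  on.exit(if (!is.null(path)) grDevices::dev.off(), add = TRUE)
  graphics::image(fit$rho_grid, fit$psi_grid, log10(fit$fit_surface + 1e-6),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "purity (rho)", ylab = "ploidy (psi)",
                  main = "Sunrise: goodness of fit")
  graphics::points(fit$rho, fit$psi, pch = 4, cex = 2, lwd = 3,
                   col = "blue")
  invisible(NULL)
}
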