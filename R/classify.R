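#' Classifier configuration
#'
#' Centralizes every threshold of the five-class topology decision tree. The
#' class definitions in the source taxonomy are descriptive rather than
#' operational; these defaults operationalize them with the quoted ranges
#' (partial-barrel gaps of 28-31 A, flaps of 4-6 strands tilted away from a
#' main sheet of 9-12 strands) and are exposed for calibration.
#'
#' @param cycle_min_strands minimum cycle length for a barrel (default 8).
#' @param class2_gap_min minimum terminal gap for a partial barrel
#'   (Angstrom, default 20).
#' @param flap_min,flap_max strand-count range of a flap (defaults 4, 6).
#' @param main_sheet_min minimum strand count of the main sheet when a flap
#'   is split off (default 9).
#' @param flap_tilt_deg flap strand tilt (vs the barrel axis) at or beyond
#'   which the flap counts as reoriented normal to the axis (default 60).
#' @param pore_min_diameter minimum mid-slab caliper width for an enclosed
#'   pore (Angstrom, default 15).
#' @param cv_max radial coefficient-of-variation bound for cylindrical
#'   geometry (default 0.3).
#' @param coverage_min_deg minimum azimuthal coverage for cylindrical
#'   geometry (degrees, default 170).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(cycle_min_strands = 8L, class2_gap_min = 20,
                              flap_min = 4L, flap_max = 6L,
                              main_sheet_min = 9L, flap_tilt_deg = 60,
                              pore_min_diameter = 15, cv_max = 0.3,
                              coverage_min_deg = 170) {
  cfg <- list(cycle_min_strands = cycle_min_strands,
              class2_gap_min = class2_gap_min, flap_min = flap_min,
              flap_max = flap_max, main_sheet_min = main_sheet_min,
              flap_tilt_deg = flap_tilt_deg,
              pore_min_diameter = pore_min_diameter, cv_max = cv_max,
              coverage_min_deg = coverage_min_deg)
  if (any(unlist(cfg) <= 0)) stop("all classifier thresholds must be positive")
  class(cfg) <- "classifier_config"
  cfg
}

#' Classify a structure into the five-class topology taxonomy
#'
#' Decision tree over the measured geometry: (V) no sheet component of at
#' least 4 strands, or the main sheet is not a cylindrical enclosure (radial
#' spread / azimuthal coverage diagnostics from the axis fit, or mid-slab
#' caliper width below `pore_min_diameter`); (IV) left-handed twist on a
#' cylindrical sheet; (II/III) a flap of `flap_min`-`flap_max` strands split
#' from a main sheet of at least `main_sheet_min` strands - Class III when
#' the flap strands reorient normal to the cylinder axis, Class II when the
#' flap stays axis-parallel and swings radially outward (terminal gap beyond
#' `class2_gap_min`); otherwise (I) a closed or near-closed barrel, with the
#' terminal gap reported.
#'
#' @param g a [build_sheet_graph()] result.
#' @param axis a [fit_axis()] result, or NULL when no axis could be fitted.
#' @param pore a [measure_pore()] result or NULL.
#' @param gap a [measure_nc_gap()] result or NULL.
#' @param handedness `"right"`, `"left"` or NA.
#' @param cfg a [classifier_config()].
#' @param construct_id identifier for the report row.
#' @param tilts optional named vector of per-strand tilts (degrees).
#' @param nterm_contacts optional N-terminal segment contact count.
#' @param mean_conf optional mean model confidence in [0, 1].
#' @return An object of class `topology_report`.
#' @export
classify <- function(g, axis, pore, gap, handedness, cfg = classifier_config(),
                     construct_id = "structure", tilts = NULL,
                     nterm_contacts = NA_integer_, mean_conf = NA_real_) {
  stopifnot(inherits(g, "sheet_graph"), inherits(cfg, "classifier_config"))
  n_strands <- nrow(g$strands)
  comp <- largest_component(g)
  n_stretched <- count_stretched_strands(g)
  flap <- find_flap(g, axis, cfg)

  label <- if (length(comp) < 4L || is.null(axis) || !axis$cylindrical ||
               is.null(pore) || pore$d_max < cfg$pore_min_diameter) {
    "V"
  } else if (!is.na(handedness) && handedness == "left") {
    "IV"
  } else if (!is.null(flap)) {
    if (flap$tilt >= cfg$flap_tilt_deg) "III"
    else if (!is.null(gap) && gap$gap > cfg$class2_gap_min) "II"
    else "I"
  } else "I"

  gap_out <- if (label %in% c("I", "II") && !is.null(gap)) gap$gap else NA_real_
  if (label == "I" && is.na(gap_out)) {
    stop("Class I requires a terminal gap measurement")
  }
  report <- list(
    construct_id = construct_id, class_label = label,
    n_strands = n_strands, nc_gap = gap_out,
    hbonded_termini = if (!is.null(gap)) gap$hbonded else NA,
    handedness = if (label %in% c("I", "II", "IV") && !is.na(handedness))
      handedness else if (label %in% c("III") && !is.na(handedness)) handedness
      else "n/a",
    n_stretched_strands = n_stretched,
    diameter = if (!is.null(pore)) pore$diameter else NA_real_,
    d_max = if (!is.null(pore)) pore$d_max else NA_real_,
    d_min = if (!is.null(pore)) pore$d_min else NA_real_,
    ellipticity = if (!is.null(pore)) pore$ellipticity else NA_real_,
    tilts = tilts, nterm_contacts = nterm_contacts, mean_conf = mean_conf)
  class(report) <- "topology_report"
  report
}

# A flap is a secondary sheet component of flap_min..flap_max strands split
# from a main component of >= main_sheet_min strands; returns its mean
# strand tilt relative to the axis, or NULL when no flap exists.
find_flap <- function(g, axis, cfg) {
  if (is.null(axis) || !length(g$membership)) return(NULL)
  sizes <- table(g$membership)
  if (length(sizes) < 2L) return(NULL)
  main_comp <- as.integer(names(sizes)[which.max(sizes)])
  if (max(sizes) < cfg$main_sheet_min) return(NULL)
  for (cid in setdiff(as.integer(names(sizes)), main_comp)) {
    sz <- sizes[as.character(cid)]
    if (sz >= cfg$flap_min && sz <= cfg$flap_max) {
      idx <- which(g$membership == cid)
      tl <- vapply(g$strands$index[idx], strand_tilt, numeric(1L),
                   axis = axis, g = g)
      return(list(strands = g$strands$index[idx], tilt = mean(tl)))
    }
  }
  NULL
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> %s: Class %s\n", x$construct_id, x$class_label))
  cat(sprintf("  strands %d, N-C gap %s, stretched strands %d, handedness %s\n",
              x$n_strands,
              if (is.na(x$nc_gap)) "-" else sprintf("%.1f A", x$nc_gap),
              x$n_stretched_strands, x$handedness))
  if (!is.na(x$diameter)) {
    cat(sprintf("  pore diameter %.1f A (ellipticity %.2f)\n",
                x$diameter, x$ellipticity))
  }
  invisible(x)
}

#' Tabulate topology reports into a construct-by-construct ledger
#'
#' One row per structure with the class call, terminal gap (the "-"
#' convention marks classes whose gap is not defined), confidence and the
#' extended metric columns. Validates the class/gap invariants before
#' writing.
#'
#' @param reports list of [classify()] results.
#' @param path optional output path; when given, a TSV is written with
#'   numbers at fixed precision so identical analyses yield identical bytes.
#' @return The table as a data.frame, invisibly when `path` is given.
#' @export
tabulate_reports <- function(reports, path = NULL) {
  if (!length(reports)) stop("no reports to tabulate")
  rows <- lapply(reports, function(r) {
    stopifnot(inherits(r, "topology_report"))
    if (r$class_label == "I" && is.na(r$nc_gap)) {
      stop("invariant breach in '", r$construct_id,
           "': Class I report without a gap value")
    }
    if (r$class_label %in% c("III", "IV", "V") && !is.na(r$nc_gap)) {
      stop("invariant breach in '", r$construct_id,
           "': Class ", r$class_label, " report carries a gap value")
    }
    if (r$class_label == "IV" && r$handedness != "left") {
      stop("invariant breach in '", r$construct_id,
           "': Class IV requires left handedness")
    }
    data.frame(
      CONSTRUCT = r$construct_id, CLASS = r$class_label,
      `N-C GAP(A)` = if (is.na(r$nc_gap)) "-" else sprintf("%.1f", r$nc_gap),
      MEAN_CONF = if (is.na(r$mean_conf)) "-" else sprintf("%.2f", r$mean_conf),
      N_STRANDS = r$n_strands,
      N_STRETCHED = r$n_stretched_strands,
      DIAMETER = if (is.na(r$diameter)) "-" else sprintf("%.1f", r$diameter),
      ELLIPTICITY = if (is.na(r$ellipticity)) "-" else sprintf("%.2f", r$ellipticity),
      HANDEDNESS = r$handedness,
      HBONDED_TERMINI = if (is.na(r$hbonded_termini)) "-"
        else if (r$hbonded_termini) "yes" else "no",
      NTERM_CONTACTS = if (is.na(r$nterm_contacts)) "-"
        else as.character(r$nterm_contacts),
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

# JSON-serializable view of a report (per-structure JSON output).
report_as_list <- function(r) {
  out <- unclass(r)
  out$tilts <- if (is.null(out$tilts)) NULL else as.numeric(out$tilts)
  out
}
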