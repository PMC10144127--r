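#' Analysis configuration
#'
#' All thresholds used along the measurement pipeline, in one place.
#'
#' @param hbond_d_max geometric H-bond cutoff (Angstrom, default 5.0).
#' @param hbond_e_cut Kabsch-Sander energy cutoff (kcal/mol, default -0.4).
#' @param stretch stretched-bond threshold (Angstrom, default 3.8).
#' @param min_strand_len minimum strand length (residues, default 3).
#' @param min_bonds minimum inter-strand H-bonds per sheet-graph edge
#'   (default 2).
#' @param slab_half_width mid-barrel slab half-width (Angstrom, default 4).
#' @param contact_cutoff heavy-atom contact cutoff (Angstrom, default 4.0).
#' @param wide_gap gap beyond which the axis-normal projection convention is
#'   used (Angstrom, default 20).
#' @param classifier a [classifier_config()].
#' @return A list of class `barrel_config`.
#' @export
barrel_config <- function(hbond_d_max = 5.0, hbond_e_cut = -0.4, stretch = 3.8,
                          min_strand_len = 3L, min_bonds = 2L,
                          slab_half_width = 4, contact_cutoff = 4.0,
                          wide_gap = 20, classifier = classifier_config()) {
  cfg <- list(hbond_d_max = hbond_d_max, hbond_e_cut = hbond_e_cut,
              stretch = stretch, min_strand_len = min_strand_len,
              min_bonds = min_bonds, slab_half_width = slab_half_width,
              contact_cutoff = contact_cutoff, wide_gap = wide_gap,
              classifier = classifier)
  class(cfg) <- "barrel_config"
  cfg
}

#' Analyze one beta-barrel structure
#'
#' The package's main entry point. Runs the full measurement pipeline -
#' hydrogen-bond detection, strand segmentation, sheet-graph construction,
#' axis fit, pore metrology, terminal-strand gap, per-strand tilt, twist
#' handedness, optional N-terminal contact census - and classifies the
#' topology. Steps that are undefined for a given geometry (no cylindrical
#' sheet, too few strands) are recorded as NULL and reflected in the class
#' call rather than raising errors.
#'
#' @param x a [barrel_structure()] or a path to a PDB/mmCIF file.
#' @param config a [barrel_config()].
#' @param nterm_range optional inclusive residue range of the N-terminal
#'   segment; when given, contacts with all detected strands that lie
#'   C-terminal of the segment are counted.
#' @param id report identifier (defaults to the structure id).
#' @param ... passed to [read_structure()] when `x` is a path.
#' @return An object of class `barrel_analysis`: the structure, all
#'   intermediate measurement objects, and the `topology_report`.
#' @export
analyze_barrel <- function(x, config = barrel_config(), nterm_range = NULL,
                           id = NULL, ...) {
  s <- if (is.character(x)) read_structure(x, ...) else x
  stopifnot(inherits(s, "barrel_structure"))
  id <- id %||% s$id
  cfg <- config

  hb <- detect_hbonds(s, d_max = cfg$hbond_d_max, e_cut = cfg$hbond_e_cut,
                      stretch = cfg$stretch)
  st <- segment_strands(s, hb, min_len = cfg$min_strand_len)
  g <- build_sheet_graph(st, hb, min_bonds = cfg$min_bonds,
                         stretch = cfg$stretch)
  axis <- tryCatch(
    fit_axis(g, cv_max = cfg$classifier$cv_max,
             coverage_min_deg = cfg$classifier$coverage_min_deg),
    error = function(e) NULL)
  pore <- if (!is.null(axis)) {
    tryCatch(measure_pore(s, axis, slab_half_width = cfg$slab_half_width),
             error = function(e) NULL)
  }
  gap <- if (nrow(st) >= 2L) {
    tryCatch(measure_nc_gap(st$index[1L], st$index[nrow(st)], g, axis,
                            wide_gap = cfg$wide_gap),
             error = function(e) NULL)
  }
  handed <- if (!is.null(axis)) {
    tryCatch(sheet_handedness(g, axis), error = function(e) NA_character_)
  } else NA_character_
  tilts <- if (!is.null(axis) && nrow(st)) {
    stats::setNames(vapply(st$index, strand_tilt, numeric(1L),
                           axis = axis, g = g),
                    paste0("b", st$index))
  }
  contacts <- NA_integer_
  if (!is.null(nterm_range) && nrow(st)) {
    targets <- st[st$start > nterm_range[2L], , drop = FALSE]
    if (nrow(targets)) {
      contacts <- tryCatch(
        count_segment_contacts(s, nterm_range, targets,
                               cutoff = cfg$contact_cutoff),
        error = function(e) NA_integer_)
    }
  }
  conf <- if (s$source == "prediction") {
    tryCatch(mean_confidence(s), error = function(e) NA_real_)
  } else NA_real_

  report <- classify(g, axis, pore, gap,
                     handedness = handed %||% NA_character_,
                     cfg = cfg$classifier, construct_id = id, tilts = tilts,
                     nterm_contacts = contacts, mean_conf = conf)
  structure(list(structure = s, hbonds = hb, strands = st, graph = g,
                 axis = axis, pore = pore, gap = gap, handedness = handed,
                 tilts = tilts, report = report, config = cfg),
            class = "barrel_analysis")
}

#' @export
print.barrel_analysis <- function(x, ...) {
  cat(sprintf("<barrel_analysis> %s\n", x$structure$id))
  print(x$report)
  invisible(x)
}

#' @export
summary.barrel_analysis <- function(object, ...) {
  x <- object
  print(x$report)
  cat(sprintf("  H-bonds: %d (%d stretched > %.1f A)\n", nrow(x$hbonds),
              sum(x$hbonds$stretched), x$config$stretch))
  if (!is.null(x$axis)) print(x$axis)
  if (!is.null(x$gap)) print(x$gap)
  if (!is.null(x$tilts)) {
    cat(sprintf("  strand tilts: %.0f-%.0f deg (mean %.0f)\n",
                min(x$tilts), max(x$tilts), mean(x$tilts)))
  }
  invisible(x)
}

#' Plot the mid-barrel cross-section of an analysis
#'
#' Projects the mid-slab CA atoms onto the plane normal to the fitted axis
#' and draws the convex hull with the reported caliper widths.
#'
#' @param x a [analyze_barrel()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.barrel_analysis <- function(x, ...) {
  if (is.null(x$axis)) stop("no fitted axis to plot")
  s <- x$structure
  CA <- as.matrix(s$atoms[s$atoms$elety == "CA", c("x", "y", "z")])
  v <- x$axis$direction
  t <- (CA - matrix(x$axis$origin, nrow(CA), 3L, byrow = TRUE)) %*% v
  mid <- mean(x$axis$z_range)
  sel <- abs(t - mid) <= x$config$slab_half_width
  bs <- plane_basis(v)
  P <- sweep(CA[sel, , drop = FALSE], 2L, x$axis$origin)
  pts <- cbind(P %*% bs$e1, P %*% bs$e2)
  graphics::plot(pts, asp = 1, pch = 16, xlab = "x' (A)", ylab = "y' (A)",
                 main = sprintf("%s: Class %s", s$id, x$report$class_label), ...)
  h <- grDevices::chull(pts)
  graphics::polygon(pts[h, ], border = "grey40")
  if (!is.null(x$pore)) {
    graphics::legend("topleft", bty = "n", legend = sprintf(
      "d_max %.1f  d_min %.1f  ellipticity %.2f",
      x$pore$d_max, x$pore$d_min, x$pore$ellipticity))
  }
  invisible(x)
}

#' Analyze a set of structure files
#'
#' Runs [analyze_barrel()] over files or a directory; per-file failures are
#' collected rather than aborting the batch. Optionally writes one JSON
#' report per structure plus an aggregate TSV ledger.
#'
#' @param paths character vector of files, or a single directory containing
#'   `.pdb`/`.cif` files.
#' @param config a [barrel_config()].
#' @param out_dir optional output directory for per-structure JSON and the
#'   aggregate `reports.tsv`.
#' @param nterm_range optional N-terminal segment range applied to every
#'   structure.
#' @param ... passed to [read_structure()].
#' @return List with `reports` (topology_report list), `failures`
#'   (named character vector of error messages) and `table` (data.frame).
#' @export
analyze_structures <- function(paths, config = barrel_config(), out_dir = NULL,
                               nterm_range = NULL, ...) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif)$", full.names = TRUE)
  }
  if (!length(paths)) stop("no structure files to analyze")
  reports <- list(); failures <- character()
  for (p in paths) {
    res <- tryCatch(analyze_barrel(p, config = config,
                                   nterm_range = nterm_range, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[basename(p)] <- conditionMessage(res)
    } else {
      reports[[length(reports) + 1L]] <- res$report
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(
          report_as_list(res$report),
          file.path(out_dir, paste0(res$report$construct_id, ".json")),
          auto_unbox = TRUE, digits = 6, null = "null")
      }
    }
  }
  if (!length(reports)) {
    stop("all ", length(paths), " structure(s) failed: ",
         paste(failures, collapse = "; "))
  }
  tab <- tabulate_reports(reports,
                          path = if (!is.null(out_dir))
                            file.path(out_dir, "reports.tsv"))
  list(reports = reports, failures = failures, table = tab)
}
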