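# Sequence-construct builder: systematic deletions of annotated segments
# (N-terminal segment, beta-strands), insertions and tandem repeats applied
# to an annotated VDAC base sequence. Strand boundaries are user-supplied
# annotations, not hardcoded: annotation TSVs carry (name, start, end) with
# names "NTERM" and "b1".."b19".

#' Read a segment annotation table
#'
#' @param path TSV with columns `name`, `start`, `end` (1-based inclusive
#'   author numbering).
#' @return data.frame of class `segment_annotation`.
#' @export
read_segment_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  segment_annotation(ann)
}

#' Validate a segment annotation
#'
#' @param ann data.frame with `name`, `start`, `end`.
#' @return The validated annotation, class `segment_annotation`.
#' @export
segment_annotation <- function(ann) {
  stopifnot(all(c("name", "start", "end") %in% names(ann)))
  if (any(ann$start > ann$end)) stop("segment with start > end")
  if (anyDuplicated(ann$name)) stop("duplicate segment names")
  o <- order(ann$start)
  if (any(ann$end[o][-nrow(ann)] >= ann$start[o][-1L])) {
    stop("overlapping segments in annotation")
  }
  # strand names must be ordered along the sequence
  str_idx <- grep("^b[0-9]+$", ann$name)
  if (length(str_idx) > 1L) {
    nums <- as.integer(sub("^b", "", ann$name[str_idx]))
    if (any(diff(ann$start[str_idx][order(nums)]) < 0)) {
      stop("strand annotations out of sequence order")
    }
  }
  class(ann) <- c("segment_annotation", "data.frame")
  ann
}

#' Declarative specification of a sequence construct
#'
#' @param base_id identifier of the base sequence (e.g. "HVDAC1").
#' @param delete character vector of segment names to excise.
#' @param insert list of insertions, each `list(after = <segment name or
#'   absolute position>, seq = <amino-acid text>)`.
#' @param repeat_n tandem repeat count (>= 1).
#' @param linker linker sequence between tandem repeats (may be empty).
#' @return A list of class `construct_spec`.
#' @export
construct_spec <- function(base_id, delete = character(), insert = list(),
                           repeat_n = 1L, linker = "") {
  if (repeat_n < 1L) stop("repeat_n must be >= 1")
  structure(list(base_id = base_id, delete = delete, insert = insert,
                 repeat_n = as.integer(repeat_n), linker = linker),
            class = "construct_spec")
}

# Table-style construct id, e.g. "HVDAC1-N,b(13-14,17-19)".
construct_id <- function(base_id, delete, repeat_n = 1L) {
  parts <- character()
  if ("NTERM" %in% delete) parts <- c(parts, "N")
  nums <- sort(as.integer(sub("^b", "", grep("^b[0-9]+$", delete, value = TRUE))))
  if (length(nums)) {
    runs <- split(nums, cumsum(c(1L, diff(nums) != 1L)))
    lab <- vapply(runs, function(r) {
      if (length(r) == 1L) as.character(r) else paste0(r[1L], "-", r[length(r)])
    }, character(1L))
    parts <- c(parts,
               if (length(nums) == 1L) paste0("b", nums)
               else paste0("b(", paste(lab, collapse = ","), ")"))
  }
  id <- if (length(parts)) paste0(base_id, "-", paste(parts, collapse = ","))
        else base_id
  if (repeat_n > 1L) id <- paste0(id, "_x", repeat_n)
  id
}

#' Apply a construct specification to an annotated sequence
#'
#' Deletion coordinates are resolved against the annotation before any edit
#' and applied right to left, so disjoint deletions are order-independent;
#' insertions are applied next (anchored after a named segment or at an
#' absolute position); the result is concatenated `repeat_n` times with the
#' linker in between. The record id encodes the edits in the construct-table
#' naming style.
#'
#' @param seq amino-acid sequence (single string).
#' @param ann a [segment_annotation()].
#' @param spec a [construct_spec()].
#' @return List with `id` and `seq`.
#' @export
apply_construct <- function(seq, ann, spec) {
  stopifnot(inherits(spec, "construct_spec"))
  ann <- segment_annotation(as.data.frame(ann))
  if (max(ann$end) > nchar(seq)) {
    stop("annotation extends beyond sequence length (", nchar(seq), ")")
  }
  unknown <- setdiff(spec$delete, ann$name)
  if (length(unknown)) {
    stop("unknown segment(s): ", paste(unknown, collapse = ", "))
  }
  dels <- ann[ann$name %in% spec$delete, , drop = FALSE]
  # resolve all coordinates first, then excise right-to-left
  dels <- dels[order(dels$start, decreasing = TRUE), , drop = FALSE]
  out <- seq
  for (k in seq_len(nrow(dels))) {
    out <- paste0(substr(out, 1L, dels$start[k] - 1L),
                  substr(out, dels$end[k] + 1L, nchar(out)))
  }
  # insertions: positions resolved on the edited sequence via a coordinate
  # map from original to edited positions
  if (length(spec$insert)) {
    keep <- rep(TRUE, nchar(seq))
    for (k in seq_len(nrow(dels))) keep[dels$start[k]:dels$end[k]] <- FALSE
    newpos <- cumsum(keep)
    for (ins in spec$insert) {
      pos <- if (is.character(ins$after)) {
        hit <- ann[ann$name == ins$after, , drop = FALSE]
        if (!nrow(hit)) stop("unknown insertion anchor: ", ins$after)
        if (!keep[hit$end]) stop("insertion anchor '", ins$after, "' was deleted")
        newpos[hit$end]
      } else as.integer(ins$after)
      if (pos < 0L || pos > nchar(out)) stop("insertion position out of range")
      out <- paste0(substr(out, 1L, pos), ins$seq,
                    substr(out, pos + 1L, nchar(out)))
    }
  }
  if (spec$repeat_n > 1L) {
    out <- paste(rep(out, spec$repeat_n), collapse = spec$linker)
  }
  list(id = construct_id(spec$base_id, spec$delete, spec$repeat_n), seq = out)
}

#' Enumerate the systematic monomer construct matrix
#'
#' The construct matrix applied to each VDAC: with and without the
#' N-terminal segment, crossed with deletion of zero to three C-terminal
#' strands (b19, b18-19, b17-19) and of the internal hairpin (b13-14) -
#' 16 constructs per base sequence.
#'
#' @param base_id identifier of the base sequence.
#' @param ann a [segment_annotation()] containing at least NTERM, b13, b14,
#'   b17, b18, b19.
#' @return List of 16 [construct_spec()] objects.
#' @export
enumerate_vdac_constructs <- function(base_id, ann) {
  need <- c("NTERM", "b13", "b14", "b17", "b18", "b19")
  miss <- setdiff(need, ann$name)
  if (length(miss)) {
    stop("annotation lacks required segment(s): ", paste(miss, collapse = ", "))
  }
  cterm_sets <- list(character(), "b19", c("b18", "b19"), c("b17", "b18", "b19"))
  hairpin_sets <- list(character(), c("b13", "b14"))
  specs <- list()
  for (nterm in list(character(), "NTERM")) {
    for (ct in cterm_sets) {
      for (hp in hairpin_sets) {
        specs[[length(specs) + 1L]] <-
          construct_spec(base_id, delete = c(nterm, hp, ct))
      }
    }
  }
  specs
}

#' Write sequence records as FASTA
#'
#' @param records list of `list(id, seq)` records (as from
#'   [apply_construct()]).
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(records, path) {
  if (!length(records)) stop("no records to write")
  ids <- vapply(records, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqinr::write.fasta(lapply(records, function(r) strsplit(r$seq, "")[[1L]]),
                      names = ids, file.out = path, nbchar = 60)
  invisible(path)
}

#' Read a FASTA file as id/sequence records
#'
#' @param path FASTA file.
#' @return List of `list(id, seq)` records.
#' @export
read_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  lapply(seq_along(fa), function(i) {
    list(id = attr(fa[[i]], "name"), seq = toupper(as.character(fa[[i]])))
  })
}
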