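#' Detect backbone hydrogen bonds
#'
#' Finds amide-N to carbonyl-O backbone hydrogen bonds using a dual criterion:
#' a geometric donor-acceptor distance cutoff (`d_no <= d_max`) combined with a
#' Kabsch-Sander-style electrostatic energy (`energy < e_cut`). The amide
#' hydrogen, absent from most coordinate files, is reconstructed from ideal
#' geometry: placed 1.0 A from the donor N, anti to the preceding residue's
#' C=O bond. The distance cutoff is deliberately wider than canonical
#' secondary-structure assignment so that *stretched* bonds - registration
#' weakened beyond 3.8 A but still pairing strands - are retained and flagged.
#'
#' @param s a [barrel_structure()].
#' @param d_max maximum donor-N to acceptor-O distance (Angstrom, default 5.0).
#' @param e_cut Kabsch-Sander energy threshold (kcal/mol, default -0.4).
#' @param stretch distance beyond which a bond is flagged stretched
#'   (Angstrom, default 3.8).
#' @return data.frame of class `hbond_set`: one row per bond with donor and
#'   acceptor chain/residue, `d_no`, `energy` and `stretched`.
#' @export
detect_hbonds <- function(s, d_max = 5.0, e_cut = -0.4, stretch = 3.8) {
  stopifnot(inherits(s, "barrel_structure"))
  rt <- residue_table(s)
  N <- atom_coords(s, "N"); CA <- atom_coords(s, "CA")
  C <- atom_coords(s, "C"); O <- atom_coords(s, "O")
  if (all(is.na(O[, 1L]))) stop("no backbone oxygen atoms: cannot detect H-bonds")
  ok <- rt$complete
  # amide H: anti to C(i-1)=O(i-1); only defined when the preceding residue in
  # the same chain is present and backbone-complete; prolines have no amide H
  nres <- nrow(rt)
  prev <- c(NA_integer_, seq_len(nres - 1L))
  same_chain <- c(FALSE, rt$chain[-1L] == rt$chain[-nres] &
                    rt$resno[-1L] == rt$resno[-nres] + 1L)
  H <- matrix(NA_real_, nres, 3L)
  can_donate <- ok & same_chain & rt$resid != "PRO"
  for (i in which(can_donate)) {
    p <- prev[i]
    if (!ok[p]) { can_donate[i] <- FALSE; next }
    co <- C[p, ] - O[p, ]
    H[i, ] <- N[i, ] + co / vnorm(co)
  }
  don <- which(can_donate)
  acc <- which(ok)
  if (!length(don) || !length(acc)) {
    return(empty_hbonds())
  }
  # all donor x acceptor distances (structures here are small enough to do
  # this densely)
  d2 <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A[, , drop = FALSE] %*% t(B)
  }
  dNO <- sqrt(pmax(d2(N[don, , drop = FALSE], O[acc, , drop = FALSE]), 0))
  cand <- which(dNO <= d_max, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_hbonds())
  di <- don[cand[, 1L]]; ai <- acc[cand[, 2L]]
  # exclude self / sequence-adjacent pairs within a chain
  keep <- !(rt$chain[di] == rt$chain[ai] & abs(rt$resno[di] - rt$resno[ai]) < 2L)
  di <- di[keep]; ai <- ai[keep]; d_no <- dNO[cand][keep]
  if (!length(di)) return(empty_hbonds())
  rdist <- function(A, B) sqrt(rowSums((A - B)^2))
  r_on <- d_no
  r_ch <- rdist(C[ai, , drop = FALSE], H[di, , drop = FALSE])
  r_oh <- rdist(O[ai, , drop = FALSE], H[di, , drop = FALSE])
  r_cn <- rdist(C[ai, , drop = FALSE], N[di, , drop = FALSE])
  # Kabsch-Sander electrostatic model: partial charges +-0.42e on C/O and
  # +-0.20e on N/H, f = 332 kcal*A/mol
  energy <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  energy[pmin(r_on, r_ch, r_oh, r_cn) < 0.5] <- -9.9  # steric clash guard
  keep <- energy < e_cut
  hb <- data.frame(
    donor_chain = rt$chain[di][keep], donor_resno = rt$resno[di][keep],
    acceptor_chain = rt$chain[ai][keep], acceptor_resno = rt$resno[ai][keep],
    d_no = d_no[keep], energy = energy[keep],
    stretched = d_no[keep] > stretch, stringsAsFactors = FALSE)
  hb <- hb[order(hb$donor_chain, hb$donor_resno, hb$acceptor_resno), ]
  rownames(hb) <- NULL
  class(hb) <- c("hbond_set", "data.frame")
  hb
}

empty_hbonds <- function() {
  hb <- data.frame(donor_chain = character(), donor_resno = integer(),
                   acceptor_chain = character(), acceptor_resno = integer(),
                   d_no = numeric(), energy = numeric(), stretched = logical(),
                   stringsAsFactors = FALSE)
  class(hb) <- c("hbond_set", "data.frame")
  hb
}

#' Segment beta-strands from ladder hydrogen bonding
#'
#' Residues in extended backbone conformation that participate in ladder
#' (non-local) hydrogen bonding are merged into maximal runs; runs of at least
#' `min_len` residues become strands. Each strand carries its principal
#' direction (oriented N to C) computed from its CA positions.
#'
#' @param s a [barrel_structure()].
#' @param hbonds output of [detect_hbonds()].
#' @param min_len minimum strand length in residues (default 3).
#' @param min_sep minimum sequence separation for an H-bond to count as
#'   ladder (inter-strand) bonding rather than helical (default 3).
#' @param ext_min minimum CA(i-1)-CA(i+1) distance for extended conformation
#'   (Angstrom, default 5.5; helices fall near 5.4, beta strands near 6.5).
#' @return data.frame of class `strand_set` with one row per strand
#'   (`index`, `chain`, `start`, `end`, `n_res`, direction components) and the
#'   per-strand CA coordinate matrices in `attr(, "ca")`.
#' @export
segment_strands <- function(s, hbonds, min_len = 3L, min_sep = 3L, ext_min = 5.5) {
  stopifnot(inherits(s, "barrel_structure"))
  rt <- residue_table(s)
  CA <- atom_coords(s, "CA")
  nres <- nrow(rt)
  key <- paste(rt$chain, rt$resno)
  # ladder participation: donor or acceptor of a bond with partner >= min_sep
  # away in sequence (or on another chain)
  part <- rep(FALSE, nres)
  if (nrow(hbonds)) {
    far <- hbonds$donor_chain != hbonds$acceptor_chain |
      abs(hbonds$donor_resno - hbonds$acceptor_resno) >= min_sep
    hit <- unique(c(paste(hbonds$donor_chain[far], hbonds$donor_resno[far]),
                    paste(hbonds$acceptor_chain[far], hbonds$acceptor_resno[far])))
    part <- key %in% hit
  }
  # extended conformation: CA(i-1)..CA(i+1) span; undefined at chain termini
  ext <- rep(TRUE, nres)
  for (i in seq_len(nres)[-c(1L, nres)]) {
    if (rt$chain[i - 1L] == rt$chain[i] && rt$chain[i + 1L] == rt$chain[i] &&
        !anyNA(CA[c(i - 1L, i + 1L), ])) {
      ext[i] <- vnorm(CA[i + 1L, ] - CA[i - 1L, ]) >= ext_min
    }
  }
  # a residue flanked by two ladder residues counts as strand even without
  # its own bond (edge strands of a sheet bond with alternating residues
  # only); two-residue gaps - e.g. tight hairpin loops - are never bridged
  bridged <- part
  if (nres >= 3L) {
    inner <- 2:(nres - 1L)
    same <- rt$chain[inner - 1L] == rt$chain[inner] &
      rt$chain[inner + 1L] == rt$chain[inner] &
      rt$resno[inner + 1L] - rt$resno[inner - 1L] == 2L
    bridged[inner] <- part[inner] | (part[inner - 1L] & part[inner + 1L] & same)
  }
  mark <- bridged & ext
  mark[is.na(CA[, 1L])] <- FALSE
  # maximal runs of consecutive residues per chain
  brk <- c(TRUE, rt$chain[-1L] != rt$chain[-nres] |
             rt$resno[-1L] != rt$resno[-nres] + 1L | !mark[-1L] | !mark[-nres])
  run <- cumsum(brk)
  strands <- list(); ca_list <- list()
  for (r in unique(run[mark])) {
    idx <- which(run == r & mark)
    if (length(idx) < min_len) next
    coords <- CA[idx, , drop = FALSE]
    dir <- strand_direction(coords)
    strands[[length(strands) + 1L]] <- data.frame(
      chain = rt$chain[idx[1L]], start = rt$resno[idx[1L]],
      end = rt$resno[idx[length(idx)]], n_res = length(idx),
      dx = dir[1L], dy = dir[2L], dz = dir[3L], stringsAsFactors = FALSE)
    ca_list[[length(ca_list) + 1L]] <- coords
  }
  if (!length(strands)) return(empty_strands())
  out <- do.call(rbind, strands)
  rownames(out) <- NULL
  # merge collinear runs separated by at most 5 residues: a mid-strand
  # participation gap splits one strand into two near-collinear halves,
  # whereas genuinely distinct strands across a hairpin run antiparallel
  # and their union strays far from any single line
  repeat {
    merged <- FALSE
    k <- 1L
    while (k < nrow(out)) {
      gap_res <- out$start[k + 1L] - out$end[k] - 1L
      d1 <- c(out$dx[k], out$dy[k], out$dz[k])
      d2 <- c(out$dx[k + 1L], out$dy[k + 1L], out$dz[k + 1L])
      do_merge <- FALSE
      if (out$chain[k] == out$chain[k + 1L] && gap_res >= 0L && gap_res <= 5L &&
          sum(d1 * d2) > cos(rad(40))) {
        idx <- which(rt$chain == out$chain[k] & rt$resno >= out$start[k] &
                       rt$resno <= out$end[k + 1L] & !is.na(CA[, 1L]))
        coords <- CA[idx, , drop = FALSE]
        dir <- strand_direction(coords)
        cc <- sweep(coords, 2L, colMeans(coords))
        resid <- sqrt(rowSums(cc^2) - (cc %*% dir)^2)
        do_merge <- mean(resid) <= 1.3
      }
      if (do_merge) {
        out$end[k] <- out$end[k + 1L]
        out$n_res[k] <- length(idx)
        out$dx[k] <- dir[1L]; out$dy[k] <- dir[2L]; out$dz[k] <- dir[3L]
        ca_list[[k]] <- coords
        out <- out[-(k + 1L), , drop = FALSE]
        ca_list <- ca_list[-(k + 1L)]
        merged <- TRUE
      } else k <- k + 1L
    }
    if (!merged) break
  }
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "ca") <- ca_list
  class(out) <- c("strand_set", "data.frame")
  out
}

empty_strands <- function() {
  out <- data.frame(index = integer(), chain = character(), start = integer(),
                    end = integer(), n_res = integer(), dx = numeric(),
                    dy = numeric(), dz = numeric(), stringsAsFactors = FALSE)
  attr(out, "ca") <- list()
  class(out) <- c("strand_set", "data.frame")
  out
}

# Principal direction of a CA trace, oriented N -> C.
strand_direction <- function(coords) {
  cc <- sweep(coords, 2L, colMeans(coords))
  v <- svd(cc, nu = 0L, nv = 1L)$v[, 1L]
  if (sum(v * (coords[nrow(coords), ] - coords[1L, ])) < 0) v <- -v
  unitv(v)
}

strand_center <- function(g, i) colMeans(attr(g$strands, "ca")[[i]])

strand_dir <- function(strands, i) {
  unname(unlist(strands[strands$index == i, c("dx", "dy", "dz")]))
}

#' Build the strand-pairing sheet graph
#'
#' Strands are nodes; an edge joins two strands connected by at least
#' `min_bonds` inter-strand hydrogen bonds. Each edge carries the pairing
#' sense (parallel/antiparallel, from the dot product of strand directions),
#' the mean donor-acceptor distance over the interface, and a stretched flag
#' (`mean_d_no > stretch`). Connected components partition the strands into
#' sheets; a barrel corresponds to a cycle through at least 8 strands.
#'
#' @param strands a [segment_strands()] result.
#' @param hbonds a [detect_hbonds()] result.
#' @param min_bonds minimum inter-strand H-bonds per edge (default 2).
#' @param stretch interface stretch threshold (Angstrom, default 3.8).
#' @return An object of class `sheet_graph`.
#' @export
build_sheet_graph <- function(strands, hbonds, min_bonds = 2L, stretch = 3.8) {
  stopifnot(inherits(strands, "strand_set"))
  n <- nrow(strands)
  edges <- data.frame(i = integer(), j = integer(), sense = character(),
                      mean_d_no = numeric(), n_bonds = integer(),
                      stretched = logical(), stringsAsFactors = FALSE)
  if (n > 0L && nrow(hbonds) > 0L) {
    res2strand <- function(chain, resno) {
      m <- rep(NA_integer_, length(resno))
      for (k in seq_len(n)) {
        hit <- chain == strands$chain[k] & resno >= strands$start[k] &
          resno <= strands$end[k]
        m[hit] <- strands$index[k]
      }
      m
    }
    si <- res2strand(hbonds$donor_chain, hbonds$donor_resno)
    sj <- res2strand(hbonds$acceptor_chain, hbonds$acceptor_resno)
    keep <- !is.na(si) & !is.na(sj) & si != sj
    if (any(keep)) {
      a <- pmin(si[keep], sj[keep]); b <- pmax(si[keep], sj[keep])
      d <- hbonds$d_no[keep]
      pair <- paste(a, b)
      agg_n <- tapply(d, pair, length)
      agg_d <- tapply(d, pair, mean)
      keep2 <- agg_n >= min_bonds
      if (any(keep2)) {
        ij <- do.call(rbind, strsplit(names(agg_n)[keep2], " "))
        i <- as.integer(ij[, 1L]); j <- as.integer(ij[, 2L])
        sense <- vapply(seq_along(i), function(k) {
          if (sum(strand_dir(strands, i[k]) * strand_dir(strands, j[k])) > 0)
            "parallel" else "antiparallel"
        }, character(1L))
        edges <- data.frame(i = i, j = j, sense = sense,
                            mean_d_no = as.numeric(agg_d[keep2]),
                            n_bonds = as.integer(agg_n[keep2]),
                            stretched = as.numeric(agg_d[keep2]) > stretch,
                            stringsAsFactors = FALSE)
        edges <- edges[order(edges$i, edges$j), ]
        rownames(edges) <- NULL
      }
    }
  }
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) ig <- igraph::add_edges(ig, rbind(edges$i, edges$j))
  membership <- if (n > 0L) igraph::components(ig)$membership else integer()
  structure(list(strands = strands, edges = edges,
                 membership = as.integer(membership), graph = ig),
            class = "sheet_graph")
}

#' @export
print.sheet_graph <- function(x, ...) {
  comp <- if (length(x$membership)) table(x$membership) else integer()
  cat(sprintf("<sheet_graph> %d strands, %d interfaces, %d component(s)\n",
              nrow(x$strands), nrow(x$edges), length(comp)))
  if (nrow(x$edges)) {
    cat(sprintf("  stretched interfaces: %d; cycle through >= 8 strands: %s\n",
                sum(x$edges$stretched), has_barrel_cycle(x)))
  }
  invisible(x)
}

# TRUE iff the pairing graph contains a simple cycle visiting >= min_cycle
# strands (the operational definition of "a barrel exists").
has_barrel_cycle <- function(g, min_cycle = 8L) {
  if (!nrow(g$edges)) return(FALSE)
  for (k in seq_len(nrow(g$edges))) {
    ig2 <- igraph::delete_edges(g$graph, k)
    d <- igraph::distances(ig2, v = g$edges$i[k], to = g$edges$j[k])
    if (is.finite(d) && d + 1L >= min_cycle) return(TRUE)
  }
  FALSE
}

# Indices of strands in the largest connected component.
largest_component <- function(g) {
  if (!length(g$membership)) return(integer())
  tab <- table(g$membership)
  comp <- as.integer(names(tab)[which.max(tab)])
  which(g$membership == comp)
}

#' Count strands with stretched interfaces
#'
#' A strand is counted when it flanks at least one interface whose mean
#' donor-acceptor distance exceeds the threshold; a single dilated interface
#' therefore contributes both of its strands.
#'
#' @param g a [build_sheet_graph()] result.
#' @param threshold stretch threshold (Angstrom, default 3.8).
#' @return Integer number of stretched strands.
#' @export
count_stretched_strands <- function(g, threshold = 3.8) {
  stopifnot(inherits(g, "sheet_graph"))
  if (!nrow(g$edges)) return(0L)
  st <- g$edges$mean_d_no > threshold
  length(unique(c(g$edges$i[st], g$edges$j[st])))
}
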