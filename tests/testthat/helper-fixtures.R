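# Shared fixtures and independent oracles used across the test files.

# uniformly random rotation matrix (quaternion method), deterministic under
# the caller's seed
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# mirror a structure through the xy-plane (flips chirality)
mirror_structure <- function(s) {
  s$atoms$z <- -s$atoms$z
  s
}

# hand-written two-residue PDB text: residues GLY 1 and ALA 2 of chain A,
# full backbone each
two_residue_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00 10.00           C",
    "ATOM      4  O   GLY A   1       1.300   2.400   0.000  1.00 10.00           O",
    "ATOM      5  N   ALA A   2       3.300   1.500   0.000  1.00 20.00           N",
    "ATOM      6  CA  ALA A   2       4.000   2.800   0.000  1.00 20.00           C",
    "ATOM      7  C   ALA A   2       5.500   2.600   0.000  1.00 20.00           C",
    "ATOM      8  O   ALA A   2       6.200   3.600   0.000  1.00 20.00           O",
    "TER", "END")
  writeLines(lines, path)
  path
}

# exhaustive brute-force H-bond oracle: scans every backbone N/O pair under
# the same dual criterion, reconstructing H exactly as specified, entirely
# independent of the package's vectorized implementation
brute_force_hbonds <- function(s, d_max = 5.0, e_cut = -0.4) {
  a <- s$atoms
  rt <- unique(a[, c("chain", "resno")])
  rt <- rt[order(rt$chain, rt$resno), ]
  get <- function(ch, r, el) {
    m <- a[a$chain == ch & a$resno == r & a$elety == el, c("x", "y", "z")]
    if (nrow(m) == 1L) as.numeric(m) else NULL
  }
  out <- list()
  for (i in seq_len(nrow(rt))) {
    chi <- rt$chain[i]; ri <- rt$resno[i]
    Ni <- get(chi, ri, "N"); CAi <- get(chi, ri, "CA")
    Ci <- get(chi, ri, "C"); Oi <- get(chi, ri, "O")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci) || is.null(Oi)) next
    resid_i <- a$resid[a$chain == chi & a$resno == ri][1L]
    Cp <- get(chi, ri - 1L, "C"); Op <- get(chi, ri - 1L, "O")
    CAp <- get(chi, ri - 1L, "CA"); Np <- get(chi, ri - 1L, "N")
    if (is.null(Cp) || is.null(Op) || is.null(CAp) || is.null(Np) ||
        resid_i == "PRO") next
    H <- Ni + (Cp - Op) / sqrt(sum((Cp - Op)^2))
    for (j in seq_len(nrow(rt))) {
      chj <- rt$chain[j]; rj <- rt$resno[j]
      if (chj == chi && abs(rj - ri) < 2L) next
      Nj <- get(chj, rj, "N"); Cj <- get(chj, rj, "C"); Oj <- get(chj, rj, "O")
      if (is.null(Nj) || is.null(Cj) || is.null(Oj) ||
          is.null(get(chj, rj, "CA"))) next
      d <- function(p, q) sqrt(sum((p - q)^2))
      r_on <- d(Ni, Oj)
      if (r_on > d_max) next
      e <- 0.084 * 332 * (1 / r_on + 1 / d(Cj, H) - 1 / d(Oj, H) - 1 / d(Cj, Ni))
      if (min(r_on, d(Cj, H), d(Oj, H), d(Cj, Ni)) < 0.5) e <- -9.9
      if (e < e_cut) {
        out[[length(out) + 1L]] <- data.frame(
          donor_chain = chi, donor_resno = ri,
          acceptor_chain = chj, acceptor_resno = rj,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(donor_chain = character(),
                                      donor_resno = integer(),
                                      acceptor_chain = character(),
                                      acceptor_resno = integer()))
  do.call(rbind, out)
}

bond_key <- function(hb) {
  sort(paste(hb$donor_chain, hb$donor_resno, hb$acceptor_chain,
             hb$acceptor_resno))
}

# toy annotated sequence for construct tests: 60 residues with NTERM and six
# named strands at known positions (synthetic stand-in, not a real VDAC)
toy_annotation <- function() {
  segment_annotation(data.frame(
    name = c("NTERM", "b1", "b13", "b14", "b17", "b18", "b19"),
    start = c(1L, 11L, 21L, 27L, 37L, 44L, 52L),
    end = c(8L, 16L, 25L, 32L, 41L, 49L, 58L),
    stringsAsFactors = FALSE))
}

toy_sequence <- function() {
  paste(rep(c("ACDEFGHIKL", "MNPQRSTVWY"), 3), collapse = "")  # 60 aa
}
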