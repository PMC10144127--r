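test_that("two residues far apart form no bond", {
  path <- withr::local_tempfile(fileext = ".pdb")
  two_residue_pdb(path)
  s <- read_structure(path)
  s$atoms$x[s$atoms$resno == 2] <- s$atoms$x[s$atoms$resno == 2] + 20
  expect_equal(nrow(detect_hbonds(s)), 0L)
})

test_that("ladder H-bond set equals the exhaustive brute-force pair scan", {
  lad <- make_ladder(8, 2.9)
  hb <- detect_hbonds(lad)
  expect_gt(nrow(hb), 0L)
  oracle <- brute_force_hbonds(lad)
  expect_identical(bond_key(hb), bond_key(oracle))
  # also on a small jittered barrel, where the geometry is less regular
  s <- make_barrel(ideal_barrel_params(10, 10, strand_len = 6,
                                       jitter_sigma = 0.2, seed = 11))
  expect_identical(bond_key(detect_hbonds(s)), bond_key(brute_force_hbonds(s)))
})

test_that("uniform dilation past 3.8 A stretches the surviving ladder bonds", {
  lad <- make_ladder(8, 2.9)
  hb0 <- detect_hbonds(lad)
  lad2 <- barrelmetry:::scale_structure(lad, 4.1 / 2.9)
  hb2 <- detect_hbonds(lad2)
  expect_gt(nrow(hb2), 0L)
  expect_true(all(hb2$stretched))
  # the surviving bonds are a subset of the original set
  expect_true(all(bond_key(hb2) %in% bond_key(hb0)))
  # and they match brute force under the same criteria
  expect_identical(bond_key(hb2), bond_key(brute_force_hbonds(lad2)))
})

test_that("the H-bond set is invariant under rigid motion", {
  s <- make_barrel(ideal_barrel_params(10, 10, strand_len = 6))
  hb0 <- detect_hbonds(s)
  set.seed(31)
  for (k in 1:5) {
    s2 <- transform_structure(s, random_rotation(), stats::rnorm(3, 0, 25))
    expect_identical(bond_key(detect_hbonds(s2)), bond_key(hb0))
  }
})

test_that("an all-helical chain yields no strands", {
  # ideal alpha-helix: rise 1.5 A, 100 degrees per residue, radius 2.3 A
  n <- 25L
  t <- seq_len(n)
  ca <- cbind(2.3 * cos(barrelmetry:::rad(100 * t)), 2.3 * sin(barrelmetry:::rad(100 * t)), 1.5 * t)
  # approximate backbone placed off the CA helix so residues are complete
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = "A", resno = i, resid = "ALA",
               elety = c("N", "CA", "C", "O"), elem = c("N", "C", "C", "O"),
               x = ca[i, 1] + c(-0.8, 0, 0.8, 1.1),
               y = ca[i, 2] + c(-0.6, 0, 0.6, 1.4),
               z = ca[i, 3] + c(-0.9, 0, 0.9, 1.2),
               b = 1, stringsAsFactors = FALSE)
  }))
  s <- barrel_structure(atoms, source = "synthetic")
  hb <- detect_hbonds(s)
  st <- segment_strands(s, hb)
  expect_equal(nrow(st), 0L)
})

test_that("strand segmentation recovers the generator's ranges within 1 residue", {
  s <- make_barrel(ideal_barrel_params(12, 12))
  hb <- detect_hbonds(s)
  st <- segment_strands(s, hb)
  tr <- attr(s, "truth")$strand_ranges
  expect_equal(nrow(st), nrow(tr))
  expect_true(all(abs(st$start - tr$start) <= 1))
  expect_true(all(abs(st$end - tr$end) <= 1))
})

test_that("sheet graph of a closed barrel is a single ring with the expected senses", {
  n <- 13L
  s <- make_barrel(ideal_barrel_params(n, n))
  hb <- detect_hbonds(s)
  st <- segment_strands(s, hb)
  g <- build_sheet_graph(st, hb)
  expect_equal(nrow(g$edges), n)
  expect_equal(max(g$membership), 1L)
  expect_true(barrelmetry:::has_barrel_cycle(g))
  # terminal pair of an odd-n barrel is parallel, all others antiparallel
  seam <- g$edges$i == 1L & g$edges$j == n
  expect_equal(g$edges$sense[seam], "parallel")
  expect_true(all(g$edges$sense[!seam] == "antiparallel"))
})

test_that("single strand gives a one-node graph without edges", {
  lad <- make_ladder(8, 2.9)
  hb <- detect_hbonds(lad)
  st <- segment_strands(lad, hb)
  st1 <- st[1, , drop = FALSE]
  attr(st1, "ca") <- attr(st, "ca")[1]
  class(st1) <- class(st)
  g <- build_sheet_graph(st1, hb)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(length(g$membership), 1L)
})

test_that("stretched-strand census counts strands flanking dilated interfaces", {
  base <- make_barrel(ideal_barrel_params(16, 16))
  hb <- detect_hbonds(base); st <- segment_strands(base, hb)
  g <- build_sheet_graph(st, hb)
  expect_equal(count_stretched_strands(g), 0L)
  one <- make_barrel(ideal_barrel_params(16, 16, dilate = 3L))
  hb <- detect_hbonds(one); st <- segment_strands(one, hb)
  expect_equal(count_stretched_strands(build_sheet_graph(st, hb)), 2L)
  four <- make_barrel(ideal_barrel_params(16, 16, dilate = c(2L, 5L, 8L, 11L)))
  hb <- detect_hbonds(four); st <- segment_strands(four, hb)
  g4 <- build_sheet_graph(st, hb)
  expect_equal(count_stretched_strands(g4), 8L)
  # brute-force census: strands incident to an interface whose mean d_no
  # exceeds the threshold
  stretched_nodes <- unique(c(g4$edges$i[g4$edges$mean_d_no > 3.8],
                              g4$edges$j[g4$edges$mean_d_no > 3.8]))
  expect_equal(count_stretched_strands(g4), length(stretched_nodes))
})

test_that("stretched count is monotone in the number of dilated interfaces", {
  sets <- list(integer(0), 3L, c(3L, 7L), c(3L, 7L, 11L), c(2L, 5L, 8L, 11L))
  counts <- vapply(sets, function(dl) {
    s <- make_barrel(ideal_barrel_params(16, 16, dilate = dl))
    hb <- detect_hbonds(s)
    count_stretched_strands(build_sheet_graph(segment_strands(s, hb), hb))
  }, integer(1L))
  expect_true(all(diff(counts) >= 0))
})

test_that("strand count and cycle structure match ground truth across barrel sizes", {
  for (n in c(10L, 13L, 17L, 21L, 24L)) {
    s <- make_barrel(ideal_barrel_params(n, n))
    hb <- detect_hbonds(s)
    st <- segment_strands(s, hb)
    g <- build_sheet_graph(st, hb)
    expect_equal(nrow(st), n, info = paste("n =", n))
    expect_equal(max(g$membership), 1L, info = paste("n =", n))
    expect_true(barrelmetry:::has_barrel_cycle(g), info = paste("n =", n))
  }
})
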