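test_that("empty spec returns the identity sequence", {
  out <- apply_construct(toy_sequence(), toy_annotation(),
                         construct_spec("TOY"))
  expect_identical(out$seq, toy_sequence())
  expect_identical(out$id, "TOY")
})

test_that("single-segment deletion matches manual string surgery", {
  seq <- toy_sequence()
  ann <- segment_annotation(data.frame(name = "seg", start = 11L, end = 15L))
  out <- apply_construct(seq, ann, construct_spec("TOY", delete = "seg"))
  manual <- paste0(substr(seq, 1, 10), substr(seq, 16, nchar(seq)))
  expect_identical(out$seq, manual)
  expect_equal(nchar(out$seq), 55L)
})

test_that("multi-segment deletion is exact in length and order-independent", {
  seq <- toy_sequence(); ann <- toy_annotation()
  dels <- c("NTERM", "b13", "b14", "b17", "b18", "b19")
  out <- apply_construct(seq, ann, construct_spec("HVDAC1", delete = dels))
  seg_len <- sum(ann$end[ann$name %in% dels] - ann$start[ann$name %in% dels] + 1L)
  expect_equal(nchar(out$seq), nchar(seq) - seg_len)
  expect_identical(out$id, "HVDAC1-N,b(13-14,17-19)")
  # permuted deletion order yields the same sequence
  out2 <- apply_construct(seq, ann, construct_spec("HVDAC1", delete = rev(dels)))
  expect_identical(out2$seq, out$seq)
  # manual oracle: excise ranges right-to-left by hand
  manual <- seq
  for (nm in c("b19", "b18", "b17", "b14", "b13", "NTERM")) {
    i <- ann[ann$name == nm, ]
    manual <- paste0(substr(manual, 1, i$start - 1),
                     substr(manual, i$end + 1, nchar(manual)))
  }
  expect_identical(out$seq, manual)
})

test_that("unknown segments and overlapping annotations are rejected", {
  expect_error(apply_construct(toy_sequence(), toy_annotation(),
                               construct_spec("TOY", delete = "b99")),
               "unknown segment")
  bad <- data.frame(name = c("a", "b"), start = c(1L, 5L), end = c(6L, 9L))
  expect_error(segment_annotation(bad), "overlapping")
})

test_that("insertions anchor after a named segment or absolute position", {
  seq <- toy_sequence(); ann <- toy_annotation()
  out <- apply_construct(seq, ann,
                         construct_spec("TOY", insert = list(
                           list(after = "b1", seq = "GSGS"))))
  expect_equal(nchar(out$seq), 64L)
  expect_identical(substr(out$seq, 17, 20), "GSGS")
  out2 <- apply_construct(seq, ann,
                          construct_spec("TOY", insert = list(
                            list(after = 0L, seq = "MM"))))
  expect_identical(substr(out2$seq, 1, 2), "MM")
})

test_that("tandem repeats obey the k*m + (k-1)*l length formula", {
  seq <- toy_sequence(); ann <- toy_annotation()
  for (k in c(2L, 3L)) {
    for (linker in c("", "GSG")) {
      out <- apply_construct(seq, ann,
                             construct_spec("TOY", repeat_n = k,
                                            linker = linker))
      expect_equal(nchar(out$seq), k * 60L + (k - 1L) * nchar(linker))
    }
  }
})

test_that("the systematic construct matrix enumerates 16 specs per VDAC, 48 total", {
  ann <- toy_annotation()
  specs <- enumerate_vdac_constructs("HVDAC1", ann)
  expect_length(specs, 16L)
  ids <- vapply(specs, function(sp) {
    apply_construct(toy_sequence(), ann, sp)$id
  }, character(1))
  expect_false(anyDuplicated(ids) > 0)
  expect_true("HVDAC1" %in% ids)
  expect_true("HVDAC1-N,b(13-14,17-19)" %in% ids)
  expect_true("HVDAC1-b19" %in% ids)
  # half the matrix drops the N-terminal segment
  expect_equal(sum(grepl("-N", ids, fixed = TRUE)), 8L)
  all3 <- unlist(lapply(c("HVDAC1", "HVDAC2", "NCVDAC"),
                        enumerate_vdac_constructs, ann = ann),
                 recursive = FALSE)
  expect_length(all3, 48L)
  # annotation lacking a required strand fails the precondition
  expect_error(enumerate_vdac_constructs("X", ann[ann$name != "b14", ]),
               "lacks required")
})

test_that("FASTA output wraps at 60 columns, round-trips, and rejects duplicates", {
  rec <- list(id = "seventy", seq = paste(rep("A", 70), collapse = ""))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(rec), path)
  lines <- readLines(path)
  expect_equal(sum(!startsWith(lines, ">")), 2L)
  back <- read_fasta(path)
  expect_identical(back[[1]]$seq, rec$seq)
  expect_error(write_fasta(list(), path), "no records")
  expect_error(write_fasta(list(rec, rec), path), "duplicate")
})
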