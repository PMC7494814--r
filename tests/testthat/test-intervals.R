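test_that("extend applies offsets in the 5'->3' reading direction", {
  x <- genomic_intervals("chr13", 119991554, 119991569, "+")
  out <- extend_targets(x, -22, 22)
  expect_equal(c(out$start, out$end), c(119991532, 119991591))
  expect_equal(interval_width(out), 60L)
  expect_equal(out$strand, "+")

  # identity offsets
  expect_equal(extend_targets(x, 0, 0)[, 1:4], x[, 1:4])

  # minus strand mirrors: left gains end_offset, right gains start_offset
  m <- extend_targets(genomic_intervals("chrX", 100, 120, "-"), -16, 5)
  expect_equal(c(m$start, m$end), c(95, 136))

  # strand-agnostic treats minus like plus
  a <- extend_targets(genomic_intervals("chrX", 100, 120, "-"), -16, 5,
                      strand_aware = FALSE)
  expect_equal(c(a$start, a$end), c(84, 125))
})

test_that("up_flank and down_flank anchor at the strand-correct end", {
  p <- genomic_intervals("chr1", 1000, 1016, "+")
  m <- genomic_intervals("chr1", 1000, 1016, "-")

  expect_equal(unlist(up_flank(p, -300, -1)[, c("start", "end")]),
               c(start = 700L, end = 999L))
  expect_equal(unlist(up_flank(m, -300, -1)[, c("start", "end")]),
               c(start = 1017L, end = 1316L))
  expect_equal(unlist(up_flank(p, 0, 0)[, c("start", "end")]),
               c(start = 1000L, end = 1000L))

  expect_equal(unlist(down_flank(p, -16, 30)[, c("start", "end")]),
               c(start = 1000L, end = 1046L))
  expect_equal(unlist(down_flank(p, 1, 1)[, c("start", "end")]),
               c(start = 1017L, end = 1017L))
  expect_equal(unlist(down_flank(m, 1, 20)[, c("start", "end")]),
               c(start = 980L, end = 999L))

  expect_error(up_flank(p, 5, -5), "start_offset <= end_offset")
})

test_that("double_flank returns two tagged flanks per target", {
  x <- genomic_intervals("chr1", 1000, 1016, "+", "site")
  out <- double_flank(x, c(-50, -1), c(1, 50))
  expect_equal(nrow(out), 2L)
  expect_equal(out$name, c("site", "site"))
  expect_setequal(out$flank, c("up", "down"))
  expect_equal(unlist(out[out$flank == "up", c("start", "end")]),
               c(start = 950L, end = 999L))
  expect_equal(unlist(out[out$flank == "down", c("start", "end")]),
               c(start = 1017L, end = 1066L))

  # symmetric offsets on an unstranded target mirror about it, and the
  # flanks never touch the parent when offsets exclude 0
  u <- genomic_intervals("chr2", 500, 520, "*")
  fl <- suppressWarnings(double_flank(u, c(-30, -1), c(1, 30)))
  expect_equal(interval_width(fl), c(30L, 30L))
  expect_true(all(fl$end < 500 | fl$start > 520))

  # cardinality scales with input
  many <- genomic_intervals(rep("chr1", 5), 1000 + 100 * (0:4),
                            1010 + 100 * (0:4), "+")
  expect_equal(nrow(double_flank(many, c(-10, -1), c(1, 10))), 10L)
})

test_that("cut_to_spacer reconstructs width-20 spacers from cut positions", {
  plus <- cut_to_spacer(genomic_intervals("chr1", 500, 500, "+"))
  expect_equal(unlist(plus[, c("start", "end")]), c(start = 483L, end = 502L))
  minus <- cut_to_spacer(genomic_intervals("chr1", 500, 500, "-"))
  expect_equal(unlist(minus[, c("start", "end")]), c(start = 484L, end = 503L))

  set.seed(7)
  pos <- sample(100:10000, 50)
  strand <- sample(c("+", "-"), 50, replace = TRUE)
  out <- cut_to_spacer(genomic_intervals("chr1", pos, pos, strand))
  expect_true(all(interval_width(out) == 20L))

  expect_error(cut_to_spacer(genomic_intervals("chr1", 10, 12, "+")),
               "width-1")
})

test_that("extend is invertible and strand-awareness equals a coordinate flip", {
  set.seed(11)
  L <- 100000L
  for (i in 1:25) {
    s <- sample(5000:90000, 1)
    e <- s + sample(60:500, 1)  # wide enough that shrinking offsets stay valid
    strand <- sample(c("+", "-"), 1)
    a <- sample(-50:50, 1)
    b <- sample(0:50, 1)  # keep width >= 1
    x <- genomic_intervals("chr1", s, e, strand)
    y <- extend_targets(x, a, b)
    back <- extend_targets(y, -a, -b)
    expect_equal(back[, 1:4], x[, 1:4])

    # coordinate-flip oracle: a strand-aware op on a minus interval equals
    # the plus-strand op performed in the flipped coordinate system
    if (strand == "-") {
      flipped <- genomic_intervals("chr1", L - e + 1L, L - s + 1L, "+")
      yf <- extend_targets(flipped, a, b)
      expect_equal(c(L - yf$end + 1L, L - yf$start + 1L), c(y$start, y$end))
      uf <- up_flank(flipped, -20, -1)
      um <- up_flank(x, -20, -1)
      expect_equal(c(L - uf$end + 1L, L - uf$start + 1L), c(um$start, um$end))
    }
  }
})

test_that("out-of-bounds results error by default and clip loudly on request", {
  g <- genome(c(chr1 = strrep("ACGT", 25)))  # 100 bp
  x <- genomic_intervals("chr1", 10, 20, "+")
  expect_error(extend_targets(x, -15, 0, genome = g),
               class = "guidecraft_input_error")
  expect_error(extend_targets(x, 0, 100, genome = g),
               class = "guidecraft_input_error")
  expect_warning(
    out <- extend_targets(x, -15, 100, genome = g, clip = TRUE),
    "clipped"
  )
  expect_equal(c(out$start, out$end), c(1L, 100L))
  expect_error(extend_targets(x, 10, -10), "degenerate")
  expect_warning(
    extend_targets(genomic_intervals("chr1", 30, 40, "*"), -5, 5),
    "unstranded"
  )
})

test_that("built-in presets encode the documented offsets", {
  p <- arithmetic_presets()
  expect_equal(unlist(p[p$preset == "cut_within", c("start_offset", "end_offset")]),
               c(start_offset = -16L, end_offset = 5L))
  expect_equal(unlist(p[p$preset == "block", c("start_offset", "end_offset")]),
               c(start_offset = -22L, end_offset = 22L))
  expect_equal(unlist(p[p$preset == "crispri", c("start_offset", "end_offset")]),
               c(start_offset = -50L, end_offset = 300L))
  expect_false(p$strand_aware[p$preset == "crispri"])
  expect_equal(unlist(p[p$preset == "crispra", c("start_offset", "end_offset")]),
               c(start_offset = -300L, end_offset = 0L))
  expect_equal(p$mode[p$preset == "crispra"], "up_flank")
  expect_true(is.na(p$end_offset[p$preset == "excise"]))

  x <- genomic_intervals("chr1", 1000, 1016, "+")
  expect_error(transform_targets(x, "excise"), "excise_end")
  ex <- transform_targets(x, "excise", excise_end = 30)
  expect_equal(unlist(ex[, c("start", "end")]), c(start = 1000L, end = 1046L))
  expect_error(transform_targets(x, "no_such"), "unknown preset")

  # cut_within emits mirrored per-strand search windows
  cw <- transform_targets(x, "cut_within")
  expect_equal(nrow(cw), 2L)
  expect_equal(cw$start[cw$search_strand == "+"], 984L)
  expect_equal(cw$end[cw$search_strand == "+"], 1021L)
  expect_equal(cw$start[cw$search_strand == "-"], 995L)
  expect_equal(cw$end[cw$search_strand == "-"], 1032L)
})
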