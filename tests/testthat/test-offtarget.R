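WORD <- "GATTACAGATTACAGATTAC"     # 20-mer core used for planting
WORD_PAM <- paste0(WORD, "AGG")

test_that("planted exact copies are counted exactly, by both engines", {
  plants <- tibble::tibble(
    seq = WORD_PAM, chrom = c("chr1", "chr1", "chr2"),
    pos = c(5000, 42000, 12000), strand = c("+", "-", "+"), mm = 0L
  )
  g <- make_genome(c(chr1 = 60000, chr2 = 30000), plants, seed = 8, max_mm = 2)
  for (eng in c("exact", "seeded")) {
    cm <- count_genome_matches(WORD, g, max_mm = 2, engine = eng)
    expect_equal(unname(counts_row(cm$counts, WORD)), c(3L, 0L, 0L))
  }
  bf <- brute_force_matches(WORD, g, max_mm = 2)
  expect_equal(unname(bf$counts), c(3L, 0L, 0L))
})

test_that("exact engine equals the brute-force oracle on planted mismatch neighborhoods", {
  plants <- tibble::tibble(
    seq = WORD_PAM,
    chrom = "chr1",
    pos = c(3000, 20000, 45000, 70000, 110000, 150000),
    strand = c("+", "-", "+", "+", "-", "+"),
    mm = c(0L, 0L, 1L, 2L, 2L, 3L)
  )
  g <- make_genome(c(chr1 = 200000), plants, seed = 19, max_mm = 3)
  bf <- brute_force_matches(WORD, g, max_mm = 3)
  expect_equal(unname(bf$counts), c(2L, 1L, 2L, 1L))

  ex <- count_genome_matches(WORD, g, max_mm = 3, engine = "exact")
  expect_equal(unname(counts_row(ex$counts, WORD)), unname(bf$counts))
  expect_equal(ex$matches[, c("chrom", "start", "strand", "mm")],
               bf$matches[, c("chrom", "start", "strand", "mm")],
               ignore_attr = TRUE)

  # seeded engine: never above exact, equal at m <= 1 (here equal throughout,
  # as the pigeonhole construction is fully sensitive)
  se <- count_genome_matches(WORD, g, max_mm = 3, engine = "seeded")
  se_counts <- counts_row(se$counts, WORD)
  ex_counts <- counts_row(ex$counts, WORD)
  expect_true(all(se_counts <= ex_counts))
  expect_equal(se_counts[c("G0", "G1")], ex_counts[c("G0", "G1")])
  expect_equal(se$matches, ex$matches)
})

test_that("engine counts agree with an independent library matcher", {
  g <- synth_genome(c(chr1 = 30000), seed = 23)
  sp <- find_spacers(genomic_intervals("chr1", 2001, 2300), g)
  expect_gt(nrow(sp), 0)
  spacer <- sp$spacer_seq[1]
  ex <- counts_row(count_genome_matches(spacer, g, max_mm = 2,
                                        engine = "exact")$counts, spacer)
  subject <- Biostrings::DNAString(g$seq[["chr1"]])
  lib_cum <- vapply(0:2, function(m) {
    Biostrings::countPattern(spacer, subject, max.mismatch = m) +
      Biostrings::countPattern(as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(spacer))
      ), subject, max.mismatch = m)
  }, numeric(1))
  expect_equal(unname(cumsum(ex)), unname(lib_cum))
})

test_that("target attribution needs >= 1 base overlap and tolerates empty sets", {
  plants <- tibble::tibble(seq = WORD_PAM, chrom = "chr1",
                           pos = c(1000, 5000), strand = "+", mm = 0L)
  g <- make_genome(c(chr1 = 10000), plants, seed = 4, max_mm = 2)
  gm <- count_genome_matches(WORD, g, max_mm = 2, engine = "exact")

  # abutting (not overlapping) target is not counted
  abut <- genomic_intervals("chr1", c(980, 1020), c(999, 1040), "+")
  t0 <- count_target_matches(gm$matches, abut, max_mm = 2)
  expect_equal(unname(counts_row(t0, WORD)), c(0L, 0L, 0L))

  # 1-base overlap counts
  graze <- genomic_intervals("chr1", 1019, 1040, "+")
  t1 <- count_target_matches(gm$matches, graze, max_mm = 2)
  expect_equal(unname(counts_row(t1, WORD))[1], 1L)

  # a minus-strand target still catches a plus-strand match
  minus_tgt <- genomic_intervals("chr1", 995, 1025, "-")
  t2 <- count_target_matches(gm$matches, minus_tgt, max_mm = 2)
  expect_equal(unname(counts_row(t2, WORD))[1], 1L)

  # no targets at all
  none <- count_target_matches(gm$matches, genomic_intervals(character(0), integer(0), integer(0)), max_mm = 2)
  expect_equal(unname(counts_row(none, WORD)), c(0L, 0L, 0L))
})

test_that("off-target aggregation subtracts and detects bookkeeping bugs", {
  G <- tibble::tibble(spacer_seq = "X", G0 = 5L, G1 = 1L, G2 = 0L)
  T_counts <- tibble::tibble(spacer_seq = "X", T0 = 2L, T1 = 1L, T2 = 0L)
  out <- aggregate_off(G, T_counts, max_mm = 2)
  expect_equal(out$off0, 3L)
  expect_equal(out$off1, 0L)
  expect_equal(out$off, 3L)

  bad <- tibble::tibble(spacer_seq = "X", T0 = 6L, T1 = 0L, T2 = 0L)
  expect_error(aggregate_off(G, bad, max_mm = 2),
               class = "guidecraft_internal_error")
})

test_that("declaring every chromosome a target forces off = 0 everywhere", {
  g <- synth_genome(c(chr1 = 15000, chr2 = 8000), seed = 31)
  sp <- find_spacers(genomic_intervals("chr1", 3001, 3300), g)
  expect_gt(nrow(sp), 0)
  all_chroms <- genomic_intervals(names(seq_lengths(g)), 1,
                                  seq_lengths(g), "*")
  out <- count_offtargets(sp, g, all_chroms, max_mm = 2, engine = "exact")
  expect_true(all(out$off == 0L))
  expect_true(all(out$G0 >= 1L))  # self-match
})

test_that("PAM-restricted counting matches the oracle's PAM filter", {
  g <- synth_genome(c(chr1 = 20000), seed = 37)
  sp <- find_spacers(genomic_intervals("chr1", 5001, 5400), g)
  expect_gt(nrow(sp), 0)
  spacer <- sp$spacer_seq[1]
  for (eng in c("exact", "seeded")) {
    cm <- count_genome_matches(spacer, g, max_mm = 2, engine = eng,
                               pam_mode = "required", pam = "NGG")
    bf <- brute_force_matches(spacer, g, max_mm = 2, pam = "NGG")
    expect_equal(unname(counts_row(cm$counts, spacer)), unname(bf$counts))
  }
  # the PAM-agnostic count can only be larger
  agn <- counts_row(count_genome_matches(spacer, g, max_mm = 2,
                                         engine = "exact")$counts, spacer)
  req <- counts_row(count_genome_matches(spacer, g, max_mm = 2,
                                         engine = "exact",
                                         pam_mode = "required")$counts, spacer)
  expect_true(all(req <= agn))
})

test_that("counting is independent of chromosome partitioning", {
  plants <- tibble::tibble(seq = WORD_PAM, chrom = c("chr1", "chr2"),
                           pos = c(2000, 3000), strand = c("+", "-"), mm = c(1L, 2L))
  g <- make_genome(c(chr1 = 12000, chr2 = 9000), plants, seed = 13, max_mm = 2)
  joint <- counts_row(count_genome_matches(WORD, g, max_mm = 2,
                                           engine = "seeded")$counts, WORD)
  parts <- lapply(names(g$seq), function(ch) {
    sub <- genome(g$seq[ch], assembly = "part")
    counts_row(count_genome_matches(WORD, sub, max_mm = 2,
                                    engine = "seeded")$counts, WORD)
  })
  expect_equal(unname(joint), unname(Reduce(`+`, parts)))
})

test_that("a reverse-complement palindromic window is two matches", {
  # ACGT x 5 is its own reverse complement
  pal <- strrep("ACGT", 5)
  g <- str_genome(paste0(strrep("A", 30), pal, strrep("A", 6), "T", strrep("A", 23)))
  cm <- count_genome_matches(pal, g, max_mm = 0, engine = "exact")
  m <- cm$matches
  both <- m[m$start == 31, ]
  expect_equal(nrow(both), 2L)
  expect_setequal(both$strand, c("+", "-"))
})

test_that("input contracts are enforced", {
  g <- str_genome(random_dna(100, seed = 2))
  expect_error(count_genome_matches(c("ACGT", "ACGTA"), g), "same length")
  expect_error(count_genome_matches("ACGTN", g), "A/C/G/T")
  expect_error(count_genome_matches("ACGT", g, max_mm = 4), "between 0 and 3")
  expect_error(filter_spacers(tibble::tibble(x = 1), "parallel"), "off")
  counts <- tibble::tibble(G0 = c(1L, 2L), off = c(0L, 0L))
  expect_equal(nrow(filter_spacers(counts, "unique")), 1L)
  expect_equal(nrow(filter_spacers(counts, "parallel")), 2L)
  with_off <- tibble::tibble(G0 = 1L, off = 1L)
  expect_equal(nrow(filter_spacers(with_off, "parallel")), 0L)
  expect_equal(nrow(filter_spacers(with_off, "unique")), 1L)
  expect_equal(nrow(filter_spacers(with_off, "unique", require_off_free = TRUE)), 0L)
})
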