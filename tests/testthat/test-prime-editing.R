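# deterministic toy locus: a plus-strand editing spacer at 120 (PAM at
# 140-142) for an edit at 150, and an opposite-strand PAM placed so one
# nicking spacer nicks 47-77 nt downstream
toy_pe_genome <- function(seed = 42) {
  set.seed(seed)
  s <- paste0(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  substr(s, 140, 142) <- "AGG"
  substr(s, 188, 189) <- "CC"
  str_genome(s)
}

test_that("the admissible editing-spacer window is [p - (nrt+16), p - 17]", {
  ed <- edit_spec("chr20", 4699600, "G", "T")
  w <- prime_spacer_start_window(ed, nrt = 16)
  plus <- w[w$strand == "+", ]
  expect_equal(c(plus$lo, plus$hi), c(4699568, 4699583))
  minus <- w[w$strand == "-", ]
  expect_equal(c(minus$lo, minus$hi), c(4699617, 4699632))

  # nrt = 1 collapses the window to a single admissible start
  w1 <- prime_spacer_start_window(ed, nrt = 1)
  expect_equal(w1$lo[w1$strand == "+"], w1$hi[w1$strand == "+"])
  expect_equal(w1$hi[w1$strand == "+"], 4699583)

  # multi-base edits tighten it from both sides
  wm <- prime_spacer_start_window(edit_spec("chr20", 4699600, "GAT", "TCA"),
                                  nrt = 16)
  expect_equal(c(wm$lo[1], wm$hi[1]), c(4699602 - 32, 4699600 - 17))
})

test_that("find_prime_spacers equals brute-force enumeration + positional rule", {
  for (seed in c(5, 17, 29)) {
    set.seed(seed)
    s <- paste0(sample(c("A", "C", "G", "T"), 300, TRUE,
                       prob = c(0.2, 0.2, 0.4, 0.2)), collapse = "")
    g <- str_genome(s)
    p <- 150L
    ed <- edit_spec("chr1", p, substr(s, p, p),
                    if (substr(s, p, p) == "A") "C" else "A")
    params <- prime_params(nrt = 16)
    got <- find_prime_spacers(ed, g, params)

    # oracle: enumerate every spacer/PAM word in the sequence, keep those
    # whose protospacer-relative edit position is in [18, 17 + nrt]
    all_hits <- oracle_find_spacers(s, 1L, pam = "NGG")
    rel <- ifelse(all_hits$strand == "+", p - all_hits$start + 1L,
                  (all_hits$start + 19L) - p + 1L)
    keep <- rel >= 18L & rel <= 17L + 16L
    oracle <- all_hits[keep, , drop = FALSE]
    expect_equal(nrow(got), nrow(oracle))
    expect_equal(got$start, oracle$start)
    expect_equal(got$strand, oracle$strand)
    expect_equal(got$spacer_seq, oracle$spacer_seq)
  }
})

test_that("the 3' extension is RT template then PBS, with the edit on board", {
  g <- toy_pe_genome()
  s <- g$seq[["chr1"]]
  p <- 150L
  ref <- substr(s, p, p)
  alt <- if (ref == "T") "A" else "T"
  ed <- edit_spec("chr1", p, ref, alt)
  es <- find_prime_spacers(ed, g)
  sp <- es[es$start == 120 & es$strand == "+", ]
  expect_equal(nrow(sp), 1L)

  ext <- build_3prime_extension(sp, ed, g)
  # hand-built oracle: protospacer positions 18..33 are genomic 137..152
  post <- substr(s, 137, 152)
  substr(post, p - 137 + 1, p - 137 + 1) <- alt
  expect_equal(ext$rt_template_seq, oracle_revcomp(post))
  expect_equal(ext$pbs_seq, oracle_revcomp(substr(s, 124, 136)))
  expect_equal(ext$three_prime_extension,
               paste0(ext$rt_template_seq, ext$pbs_seq))
  expect_equal(nchar(ext$three_prime_extension), 16L + 13L)

  # null edit reproduces the wild-type reverse complement
  null_ext <- build_3prime_extension(sp, edit_spec("chr1", p, ref, ref), g)
  expect_equal(null_ext$rt_template_seq, oracle_revcomp(substr(s, 137, 152)))

  # insertions and deletions shift the template length by |alt| - |ref|
  ins <- build_3prime_extension(sp, edit_spec("chr1", p, ref,
                                              paste0(ref, "GTC")), g)
  expect_equal(nchar(ins$rt_template_seq), 16L + 3L)
  del <- build_3prime_extension(
    sp, edit_spec("chr1", p, substr(s, p, p + 2L), substr(s, p, p)), g
  )
  expect_equal(nchar(del$rt_template_seq), 16L - 2L)

  # PBS cannot cross the protospacer 5' end
  expect_error(prime_params(pbs_len = 18), "17")
})

test_that("minus-strand extensions mirror the plus-strand construction", {
  # build a genome, design on it, then redo everything on the reverse
  # complement: the minus design must map onto the plus design
  set.seed(77)
  s <- paste0(sample(c("A", "C", "G", "T"), 300, TRUE,
                     prob = c(0.2, 0.2, 0.35, 0.25)), collapse = "")
  L <- nchar(s)
  p <- 160L
  ref <- substr(s, p, p)
  alt <- if (ref == "G") "C" else "G"
  g <- str_genome(s)
  ed <- edit_spec("chr1", p, ref, alt)
  des <- find_prime_spacers(ed, g)

  s_rc <- oracle_revcomp(s)
  p_rc <- L - p + 1L
  g_rc <- str_genome(s_rc)
  ed_rc <- edit_spec("chr1", p_rc, oracle_revcomp(ref), oracle_revcomp(alt))
  des_rc <- find_prime_spacers(ed_rc, g_rc)

  expect_equal(nrow(des), nrow(des_rc))
  # a minus spacer [a, b] maps to a plus spacer [L-b+1, L-a+1] and vice versa
  mapped <- sort(L - des$end + 1L)
  expect_equal(sort(des_rc$start), mapped)
  expect_setequal(des_rc$spacer_seq, des$spacer_seq)

  # per-spacer extensions agree after mirroring
  for (i in seq_len(nrow(des))) {
    row <- des[i, ]
    twin <- des_rc[des_rc$start == L - row$end + 1L &
                     des_rc$strand == setdiff(c("+", "-"), row$strand), ]
    expect_equal(nrow(twin), 1L)
    e1 <- build_3prime_extension(row, ed, g)
    e2 <- build_3prime_extension(twin, ed_rc, g_rc)
    expect_equal(e1$three_prime_extension, e2$three_prime_extension)
  }
})

test_that("nicking spacers obey the nick-to-nick distance window", {
  g <- toy_pe_genome()
  p <- 150L
  s <- g$seq[["chr1"]]
  ed <- edit_spec("chr1", p, substr(s, p, p),
                  if (substr(s, p, p) == "T") "A" else "T")
  es <- find_prime_spacers(ed, g)
  sp <- es[es$start == 120 & es$strand == "+", ]
  n0 <- sp$start + 16L  # nick boundary of the editing spacer

  nk <- find_nicking_spacers(ed, sp, g)
  expect_gt(nrow(nk), 0)
  expect_true(all(nk$strand == "-"))
  expect_equal(nk$nick_distance, (nk$end - 17L) - n0)
  expect_true(all(nk$nick_distance >= 40 & nk$nick_distance <= 90))

  # a window placed past every candidate returns nothing
  far <- find_nicking_spacers(ed, sp, g, prime_params(nick_window = c(95, 99)))
  if (nrow(far) > 0) {
    expect_true(all(far$nick_distance >= 95 & far$nick_distance <= 99))
  }
  none <- find_nicking_spacers(ed, sp, g, prime_params(nick_window = c(0, 0)))
  expect_equal(nrow(none), 0L)

  # constructed single-PAM locus: a nick exactly 60 nt downstream is found,
  # and vanishes when the window stops at 59
  base <- strrep("AT", 200)
  substr(base, 140, 142) <- "AGG"        # editing spacer at 120, nick at 136
  # nicking spacer nick at b-17 = 196 -> b = 213, PAM (CCN) at 191-193
  substr(base, 191, 192) <- "CC"
  g2 <- str_genome(base)
  ref2 <- substr(base, 150, 150)
  ed2 <- edit_spec("chr1", 150L, ref2, if (ref2 == "A") "T" else "A")
  es2 <- find_prime_spacers(ed2, g2)
  sp2 <- es2[es2$start == 120 & es2$strand == "+", ]
  expect_equal(nrow(sp2), 1L)
  hit60 <- find_nicking_spacers(ed2, sp2, g2,
                                prime_params(nick_window = c(40, 90)))
  expect_equal(nrow(hit60), 1L)
  expect_equal(hit60$nick_distance, 60L)
  expect_equal(nrow(find_nicking_spacers(
    ed2, sp2, g2, prime_params(nick_window = c(40, 59))
  )), 0L)
})

test_that("design_prime_editing composes, enforces uniqueness, annotates nickers", {
  g <- toy_pe_genome()
  s <- g$seq[["chr1"]]
  p <- 150L
  ed <- edit_spec("chr1", p, substr(s, p, p),
                  if (substr(s, p, p) == "T") "A" else "T")
  tab <- design_prime_editing(ed, g, engine = "exact")
  expect_true(all(c("editing", "nicking") %in% tab$role))
  ed_rows <- tab[tab$role == "editing", ]
  expect_true(all(ed_rows$G0 == 1L))
  expect_true(all(nchar(ed_rows$three_prime_extension) == 16 + 13))
  nk_rows <- tab[tab$role == "nicking", ]
  expect_true(all(c("off0", "off1", "off2", "off") %in% names(tab)))
  expect_true(all(nk_rows$editing_name %in% ed_rows$name))
  # nicking spacers sit on the strand opposite their editing spacer
  for (i in seq_len(nrow(nk_rows))) {
    es_strand <- ed_rows$strand[ed_rows$name == nk_rows$editing_name[i]]
    expect_true(nk_rows$strand[i] != es_strand)
  }

  # a region without PAMs yields an empty design, not an error
  flat <- str_genome(strrep("AT", 150))
  ed_flat <- edit_spec("chr1", 150L, substr(strrep("AT", 150), 150, 150), "G")
  empty <- design_prime_editing(ed_flat, flat)
  expect_equal(nrow(empty), 0L)
})

test_that("edit specs are validated against the genome", {
  g <- str_genome("ACGTACGTACGTACGTACGT")
  expect_error(find_prime_spacers(edit_spec("chr1", 3L, "T", "A"), g),
               "not the stated ref")
  expect_error(find_prime_spacers(edit_spec("chr1", 19L, "GTC", "A"), g),
               "chromosome end")
  expect_error(edit_spec("chr1", 1, "A", strrep("G", 49)), "48")
  expect_error(edit_spec("chr1", 1, "", "A"), "at least one base")
})
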