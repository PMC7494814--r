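#' Specify a prime edit
#'
#' An edit replaces the plus-strand bases `[position, position + |ref| - 1]`
#' with `alt`. Single-base substitutions, multi-base replacements,
#' insertions (`ref` shorter than `alt`) and deletions (`alt` shorter,
#' possibly empty) are all expressed this way. Prime editors rewrite up
#' to 48 nucleotides, so `|alt| <= 48`.
#'
#' @param chrom Chromosome name.
#' @param position 1-based plus-strand coordinate of the first edited
#'   base.
#' @param ref Plus-strand reference allele (checked against the genome
#'   when validated).
#' @param alt Plus-strand replacement text (may be empty for a pure
#'   deletion).
#' @return A list of class `edit_spec`.
#' @examples
#' edit_spec("chr20", 4699600, "G", "T")
#' @export
edit_spec <- function(chrom, position, ref, alt) {
  ref <- str_to_upper(ref)
  alt <- str_to_upper(alt)
  if (nchar(ref) < 1) gc_input_error("ref must contain at least one base")
  if (str_detect(ref, "[^ACGT]") || (nchar(alt) > 0 && str_detect(alt, "[^ACGT]"))) {
    gc_input_error("ref/alt must contain only A/C/G/T")
  }
  if (nchar(alt) > 48) {
    gc_input_error("prime editing rewrites at most 48 nucleotides (|alt| <= 48)")
  }
  structure(
    list(chrom = as.character(chrom), position = as.integer(position),
         ref = ref, alt = alt),
    class = "edit_spec"
  )
}

validate_edit <- function(edit, genome) {
  stopifnot(inherits(edit, "edit_spec"), inherits(genome, "genome"))
  lens <- seq_lengths(genome)
  if (!edit$chrom %in% names(lens)) {
    gc_input_error(paste0("edit chromosome not in genome: ", edit$chrom))
  }
  last <- edit$position + nchar(edit$ref) - 1L
  if (edit$position < 1L || last > lens[[edit$chrom]]) {
    gc_input_error("edit overlaps a chromosome end")
  }
  obs <- str_sub(genome$seq[[edit$chrom]], edit$position, last)
  if (obs != edit$ref) {
    gc_input_error(sprintf(
      "genome sequence at %s:%d is %s, not the stated ref %s",
      edit$chrom, edit$position, obs, edit$ref
    ))
  }
  invisible(edit)
}

#' Prime-editing design parameters
#'
#' @param nrt Reverse-transcription template length in nt (the part of
#'   the 3' extension copied into the genome, carrying the edit).
#'   Default 16, the value recommended in the original prime-editing
#'   work.
#' @param pbs_len Primer binding site length in nt. Default 13.
#' @param nick_window Nick-to-nick distance range (nt) for PE3 nicking
#'   spacers, measured downstream of the prime-editing nick on the
#'   edited strand. Default `c(40, 90)`.
#' @return A list of class `prime_params`.
#' @export
prime_params <- function(nrt = 16L, pbs_len = 13L, nick_window = c(40L, 90L)) {
  nrt <- as.integer(nrt)
  pbs_len <- as.integer(pbs_len)
  nick_window <- as.integer(nick_window)
  if (nrt < 1L) gc_input_error("nrt must be >= 1")
  if (pbs_len < 1L) gc_input_error("pbs_len must be >= 1")
  if (pbs_len > 17L) {
    gc_input_error("pbs_len must be <= 17 (the PBS cannot cross the protospacer 5' end)")
  }
  if (length(nick_window) != 2L || any(nick_window < 0L) ||
      nick_window[1] > nick_window[2]) {
    gc_input_error("nick_window must be an ordered non-negative pair")
  }
  structure(list(nrt = nrt, pbs_len = pbs_len, nick_window = nick_window),
            class = "prime_params")
}

#' Admissible editing-spacer start window
#'
#' An editing spacer is admissible when every edited base sits at
#' protospacer positions 18 through `17 + nrt` (5'->3'; the nick falls
#' between positions 17 and 18, and the RT template reaches `nrt` bases
#' past it). For a plus-strand spacer and an edit spanning plus-strand
#' positions `[p1, p2]` this means a spacer start in
#' `[p2 - (nrt + 16), p1 - 17]`; the minus-strand window is its mirror in
#' terms of the spacer's 3' coordinate, `[p1 + 17, p2 + nrt + 16]`.
#'
#' @param edit An [edit_spec()].
#' @param nrt RT template length.
#' @return Tibble with one row per strand: `strand`, `lo`, `hi` (range of
#'   the spacer start for `+`, of the spacer end for `-`; empty when
#'   `lo > hi`).
#' @examples
#' prime_spacer_start_window(edit_spec("chr20", 4699600, "G", "T"), nrt = 16)
#' @export
prime_spacer_start_window <- function(edit, nrt = 16L) {
  stopifnot(inherits(edit, "edit_spec"))
  nrt <- as.integer(nrt)
  p1 <- edit$position
  p2 <- edit$position + max(nchar(edit$ref), 1L) - 1L
  tibble(
    strand = c("+", "-"),
    lo = c(p2 - (nrt + 16L), p1 + 17L),
    hi = c(p1 - 17L, p2 + nrt + 16L)
  )
}

#' Find candidate prime-editing spacers
#'
#' Returns every spacer on either strand whose PAM-strand orientation
#' places all edited bases at protospacer-relative positions 18 through
#' `17 + nrt` (insertions are measured against the post-edit template
#' length, which gives the same pre-edit window on the ref span). The
#' search is realized over the strand-specific window around the edit
#' and then filtered by the positional rule. The result may be empty.
#'
#' @param edit An [edit_spec()].
#' @param genome A [genome].
#' @param params A [prime_params()].
#' @param pam IUPAC PAM. Default `"NGG"`.
#' @return A spacer hit tibble (see [find_spacers()]) with the edit
#'   coordinates as target columns.
#' @export
find_prime_spacers <- function(edit, genome, params = prime_params(),
                               pam = "NGG") {
  validate_edit(edit, genome)
  stopifnot(inherits(params, "prime_params"))
  win <- prime_spacer_start_window(edit, params$nrt)
  lens <- seq_lengths(genome)
  L <- lens[[edit$chrom]]
  pam_len <- str_length(pam)
  hits <- list()
  # plus strand: spacer starts in [lo, hi]; full word [s, s+19+pam]
  wp <- win[win$strand == "+", ]
  if (wp$lo <= wp$hi) {
    a <- max(1L, wp$lo)
    b <- min(L, wp$hi + 19L + pam_len)
    if (a <= b) {
      region <- genomic_intervals(edit$chrom, a, b, "*", "edit_window_plus")
      h <- find_spacers(region, genome, pam = pam, strands = "+")
      hits$plus <- h[h$start >= wp$lo & h$start <= wp$hi, ]
    }
  }
  # minus strand: spacer 3' coordinate (genomic end) in [lo, hi];
  # full word [end - 19 - pam, end]
  wm <- win[win$strand == "-", ]
  if (wm$lo <= wm$hi) {
    a <- max(1L, wm$lo - 19L - pam_len)
    b <- min(L, wm$hi)
    if (a <= b) {
      region <- genomic_intervals(edit$chrom, a, b, "*", "edit_window_minus")
      h <- find_spacers(region, genome, pam = pam, strands = "-")
      hits$minus <- h[h$end >= wm$lo & h$end <= wm$hi, ]
    }
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0) return(find_spacers(genomic_intervals(character(0), integer(0), integer(0)), genome))
  out$target_name <- sprintf("%s:%d%s>%s", edit$chrom, edit$position,
                             edit$ref, ifelse(edit$alt == "", "-", edit$alt))
  out$target_start <- edit$position
  out$target_end <- edit$position + nchar(edit$ref) - 1L
  out$target_strand <- "+"
  arrange(out, .data$chrom, .data$start, .data$strand)
}

#' Build the pegRNA 3' extension for an editing spacer
#'
#' The 3' extension is the reverse-transcription template followed by the
#' primer binding site, written 5'->3' as it appears on the gRNA
#' extension. The PBS is the reverse complement of protospacer positions
#' `(17 - pbs_len + 1)..17` (the bases immediately 5' of the nick on the
#' protospacer strand); the RT template is the reverse complement of the
#' edited protospacer-strand sequence from position 18 through
#' `17 + nrt`, with `alt` substituted for `ref`, hence length
#' `nrt + |alt| - |ref|`.
#'
#' @param spacer One spacer hit row (tibble with one row) admissible per
#'   [find_prime_spacers()].
#' @param edit The [edit_spec()].
#' @param genome A [genome].
#' @param params A [prime_params()].
#' @return Tibble with one row: `pbs_seq`, `rt_template_seq`,
#'   `three_prime_extension`.
#' @export
build_3prime_extension <- function(spacer, edit, genome,
                                   params = prime_params()) {
  validate_edit(edit, genome)
  stopifnot(nrow(spacer) == 1)
  nrt <- params$nrt
  pbs_len <- params$pbs_len
  delta <- nchar(edit$alt) - nchar(edit$ref)
  chrom_seq <- genome$seq[[edit$chrom]]
  p1 <- edit$position
  p2 <- p1 + nchar(edit$ref) - 1L
  if (spacer$strand == "+") {
    s <- spacer$start
    nick3 <- s + 17L                 # first protospacer base 3' of the nick
    tail_end <- s + 16L + nrt        # protospacer position 17 + nrt
    if (p1 < nick3 || p2 > tail_end) {
      gc_input_error("spacer is not admissible for this edit (edit outside RT span)")
    }
    left <- if (p1 > nick3) str_sub(chrom_seq, nick3, p1 - 1L) else ""
    right <- if (p2 < tail_end) str_sub(chrom_seq, p2 + 1L, tail_end) else ""
    edited <- paste0(left, edit$alt, right)
    rt_plus <- str_sub(edited, 1L, nrt + delta)
    rt_template <- revcomp(rt_plus)
    pbs <- revcomp(str_sub(chrom_seq, s + 17L - pbs_len, s + 16L))
  } else {
    b <- spacer$end
    nick3 <- b - 17L                 # first base 3' of the nick, minus strand
    tail_end <- b - 16L - nrt
    if (p2 > nick3 || p1 < tail_end) {
      gc_input_error("spacer is not admissible for this edit (edit outside RT span)")
    }
    # edited plus-strand segment spanning protospacer positions 17+nrt .. 18
    left <- if (tail_end < p1) str_sub(chrom_seq, tail_end, p1 - 1L) else ""
    right <- if (p2 < nick3) str_sub(chrom_seq, p2 + 1L, nick3) else ""
    edited <- paste0(left, edit$alt, right)
    # RT template = revcomp(minus-strand downstream) = the edited plus
    # segment itself, trimmed at its 5' (low-coordinate) side
    rt_template <- str_sub(edited, str_length(edited) - (nrt + delta) + 1L,
                           str_length(edited))
    pbs <- str_sub(chrom_seq, b - 16L, b - 16L + pbs_len - 1L)
  }
  if (str_length(rt_template) != nrt + delta) {
    gc_internal_error("RT template length bookkeeping failed")
  }
  tibble(
    pbs_seq = pbs,
    rt_template_seq = rt_template,
    three_prime_extension = paste0(rt_template, pbs)
  )
}

# nick boundary: the cut lies between cut_after and the next base 3' on
# the spacer strand; we represent it by the plus-strand coordinate of the
# base 5' of the boundary (plus spacers) / 3' of it (minus spacers), i.e.
# the boundary sits between `nick_boundary` and `nick_boundary + 1`.
nick_boundary <- function(start, end, strand) {
  ifelse(strand == "+", start + 16L, end - 17L)
}

#' Find PE3 nicking spacers
#'
#' Nicking spacers lie on the strand opposite the editing spacer; their
#' nick must fall 40--90 nt (configurable) downstream of the
#' prime-editing nick, measured nick-to-nick along the edited strand's
#' 3' direction. Each hit is annotated with its `nick_distance`.
#'
#' @param edit The [edit_spec()].
#' @param editing_spacer One spacer hit row.
#' @param genome A [genome].
#' @param params A [prime_params()].
#' @param pam IUPAC PAM. Default `"NGG"`.
#' @return Spacer hit tibble with a `nick_distance` column (may be
#'   empty).
#' @export
find_nicking_spacers <- function(edit, editing_spacer, genome,
                                 params = prime_params(), pam = "NGG") {
  stopifnot(nrow(editing_spacer) == 1)
  win <- params$nick_window
  if (win[2] == 0L) return(mutate(find_spacers(
    genomic_intervals(character(0), integer(0), integer(0)), genome
  ), nick_distance = integer(0)))
  lens <- seq_lengths(genome)
  L <- lens[[edit$chrom]]
  pam_len <- str_length(pam)
  n0 <- nick_boundary(editing_spacer$start, editing_spacer$end,
                      editing_spacer$strand)
  if (editing_spacer$strand == "+") {
    # nicking spacer on minus strand; its boundary b-17 must lie in
    # [n0 + win1, n0 + win2]; search region covers word [end-22-pam, end]
    a <- max(1L, n0 + win[1] - 6L - pam_len)
    b <- min(L, n0 + win[2] + 17L)
    opp <- "-"
  } else {
    # editing on minus: downstream is decreasing coordinates; nicking on
    # plus with boundary s+16 in [n0 - win2, n0 - win1]
    a <- max(1L, n0 - win[2] - 16L)
    b <- min(L, n0 - win[1] + 7L + pam_len)
    opp <- "+"
  }
  if (a > b) return(mutate(find_spacers(
    genomic_intervals(character(0), integer(0), integer(0)), genome
  ), nick_distance = integer(0)))
  region <- genomic_intervals(edit$chrom, a, b, "*", "nick_window")
  h <- find_spacers(region, genome, pam = pam, strands = opp)
  if (nrow(h) == 0) return(mutate(h, nick_distance = integer(0)))
  nb <- nick_boundary(h$start, h$end, h$strand)
  dist <- if (editing_spacer$strand == "+") nb - n0 else n0 - nb
  h$nick_distance <- as.integer(dist)
  h <- h[h$nick_distance >= win[1] & h$nick_distance <= win[2], , drop = FALSE]
  arrange(h, .data$nick_distance)
}

#' Design PE2/PE3 prime-editing reagents for one edit
#'
#' Composes the full design: candidate editing spacers
#' ([find_prime_spacers()]), off-target counting (exact matches only for
#' editing spacers, which must be genome-unique: `G0 = 1`), the pegRNA
#' 3' extension per retained editing spacer
#' ([build_3prime_extension()]), and PE3 nicking spacers with
#' mismatch-aware counts up to `max_mm` ([find_nicking_spacers()]).
#'
#' @inheritParams find_prime_spacers
#' @param max_mm Mismatch budget for nicking-spacer counting. Default 2.
#' @param engine Off-target engine. Default `"seeded"`.
#' @param keep_all Keep editing spacers failing the `G0 = 1` uniqueness
#'   rule (flagged, not dropped)? Default `FALSE`.
#' @return A tibble, one row per reagent, with a `role` column
#'   (`"editing"`/`"nicking"`), pegRNA columns (`pbs_seq`,
#'   `rt_template_seq`, `three_prime_extension`, `nick_distance`) and
#'   off-target counts. Nicking rows reference their editing spacer via
#'   `editing_name`.
#' @export
design_prime_editing <- function(edit, genome, params = prime_params(),
                                 pam = "NGG", max_mm = 2L,
                                 engine = c("seeded", "exact"),
                                 keep_all = FALSE) {
  engine <- match.arg(engine)
  validate_edit(edit, genome)
  editing <- find_prime_spacers(edit, genome, params, pam)
  if (nrow(editing) == 0) return(prime_empty_result())
  # editing spacers: exact-only counting, no cross-target tolerance
  g0 <- count_genome_matches(editing, genome, max_mm = 0L, engine = engine,
                             pam_mode = "agnostic")$counts
  editing <- editing %>% left_join(g0, by = "spacer_seq")
  retained <- if (keep_all) editing else filter(editing, .data$G0 == 1L)
  if (nrow(retained) == 0) return(prime_empty_result())

  ext <- map(seq_len(nrow(retained)), function(i) {
    build_3prime_extension(retained[i, ], edit, genome, params)
  }) %>% bind_rows()
  editing_rows <- bind_cols(retained, ext) %>%
    mutate(role = "editing", nick_distance = NA_integer_, editing_name = .data$name)

  nick_rows <- map(seq_len(nrow(retained)), function(i) {
    h <- find_nicking_spacers(edit, retained[i, ], genome, params, pam)
    if (nrow(h) == 0) return(NULL)
    h$editing_name <- retained$name[i]
    h
  }) %>% bind_rows()
  if (nrow(nick_rows) > 0) {
    # cross-target tolerance is rejected for prime editing: each nicking
    # spacer's only "target" is its own locus, so off0 = G0 - 1 etc.
    nc <- map(seq_len(nrow(nick_rows)), function(i) {
      count_offtargets(nick_rows[i, ], genome,
                       targets = nick_rows[i, c("chrom", "start", "end", "strand", "name")],
                       max_mm = max_mm, engine = engine)
    }) %>% bind_rows()
    nick_rows <- nc %>%
      mutate(role = "nicking", pbs_seq = NA_character_,
             rt_template_seq = NA_character_,
             three_prime_extension = NA_character_)
  }
  out <- bind_rows(editing_rows, nick_rows)
  out %>%
    arrange(factor(.data$role, levels = c("editing", "nicking")),
            .data$chrom, .data$start, .data$strand) %>%
    select("role", "chrom", "start", "end", "strand", "name", "spacer_seq",
           "pam_seq", "cut_after", "target_name", dplyr::any_of(c(
             "G0", "G1", "G2", "G3", "T0", "T1", "T2", "T3",
             "off0", "off1", "off2", "off3", "off"
           )), "pbs_seq", "rt_template_seq", "three_prime_extension",
           "nick_distance", "editing_name")
}

prime_empty_result <- function() {
  tibble(
    role = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), name = character(0),
    spacer_seq = character(0), pam_seq = character(0),
    cut_after = integer(0), target_name = character(0), G0 = integer(0),
    pbs_seq = character(0), rt_template_seq = character(0),
    three_prime_extension = character(0), nick_distance = integer(0),
    editing_name = character(0)
  )
}
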