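count_levels <- function(max_mm) paste0("G", 0:max_mm)

check_max_mm <- function(max_mm) {
  max_mm <- as.integer(max_mm)
  if (is.na(max_mm) || max_mm < 0L || max_mm > 3L) {
    gc_input_error("max_mm must be between 0 and 3")
  }
  max_mm
}

# wide zero-filled count table from a match tibble; prefix "G" or "T"
tabulate_matches <- function(matches, spacer_seqs, max_mm, prefix) {
  grid <- tidyr::expand_grid(spacer_seq = spacer_seqs, mm = 0:max_mm)
  counted <- matches %>%
    count(.data$spacer_seq, .data$mm, name = "n")
  out <- grid %>%
    left_join(counted, by = c("spacer_seq", "mm")) %>%
    mutate(n = as.integer(ifelse(is.na(.data$n), 0L, .data$n))) %>%
    tidyr::pivot_wider(names_from = "mm", values_from = "n",
                       names_prefix = prefix)
  out[match(spacer_seqs, out$spacer_seq), , drop = FALSE]
}

#' Count genome-wide k-mismatch matches for a set of spacers
#'
#' Scans the whole genome (both strands) for windows within `max_mm`
#' Hamming mismatches of each distinct spacer sequence. Two engines are
#' available:
#' \describe{
#'   \item{exact}{exhaustive window scan; full sensitivity at every
#'     mismatch level by construction.}
#'   \item{seeded}{pigeonhole seed-and-verify multi-pattern matcher: each
#'     spacer is split into `max_mm + 1` seeds, any admissible match
#'     preserves one seed exactly, candidates are verified by a Hamming
#'     check. Reports only true matches (precision 1), is guaranteed
#'     complete for `m <= 1`, and never reports more than the exact
#'     engine; it is the fast choice for large spacer sets.}
#' }
#' Counting is PAM-agnostic by default; `pam_mode = "required"` keeps
#' only windows flanked by the PAM pattern in match orientation. Genome
#' `N` matches nothing. A window matching on both strands (a
#' reverse-complement palindrome) is two matches: two distinct Cas9
#' binding events.
#'
#' @param spacers Spacer hit tibble from [find_spacers()], or a character
#'   vector of equal-length spacer sequences.
#' @param genome A [genome].
#' @param max_mm Maximum mismatches, 0--3. Default 2.
#' @param engine `"seeded"` (default) or `"exact"`.
#' @param pam_mode `"agnostic"` (default) or `"required"`.
#' @param pam PAM pattern used when `pam_mode = "required"`.
#' @return A list with `counts` (tibble: `spacer_seq`, `G0..Gk`) and
#'   `matches` (tibble: `spacer_seq`, `chrom`, `start`, `end`, `strand`,
#'   `mm`, `matched_seq`), both sorted deterministically.
#' @examples
#' g <- genome(c(chr1 = "TTTACGTACGTACGTACGTACGTAGGTTT"))
#' hits <- find_spacers(genomic_intervals("chr1", 1, 29), g)
#' count_genome_matches(hits, g, max_mm = 1, engine = "exact")$counts
#' @export
count_genome_matches <- function(spacers, genome, max_mm = 2L,
                                 engine = c("seeded", "exact"),
                                 pam_mode = c("agnostic", "required"),
                                 pam = "NGG") {
  stopifnot(inherits(genome, "genome"))
  engine <- match.arg(engine)
  pam_mode <- match.arg(pam_mode)
  max_mm <- check_max_mm(max_mm)
  seqs <- if (is.character(spacers)) spacers else spacers$spacer_seq
  seqs <- unique(seqs)
  if (length(seqs) == 0) {
    return(list(
      counts = tibble(spacer_seq = character(0)),
      matches = empty_matches()
    ))
  }
  if (length(unique(nchar(seqs))) != 1) {
    gc_input_error("all spacers must have the same length")
  }
  if (any(str_detect(seqs, "[^ACGT]"))) {
    gc_input_error("spacer sequences must contain only A/C/G/T")
  }
  iupac_regex(pam)  # validate pattern early
  fn <- if (engine == "exact") cpp_match_exact else cpp_match_seeded
  raw <- fn(unname(genome$seq), seqs, max_mm, pam, pam_mode == "required")
  W <- nchar(seqs[1])
  matches <- tibble(
    spacer_seq = seqs[raw$query],
    chrom = names(genome$seq)[raw$chrom],
    start = as.integer(raw$start),
    end = as.integer(raw$start + W - 1L),
    strand = as.character(raw$strand),
    mm = as.integer(raw$mm)
  ) %>%
    arrange(.data$spacer_seq, .data$chrom, .data$start, .data$strand)
  matches$matched_seq <- if (nrow(matches) > 0) {
    fetch_seq(genome, matches)
  } else {
    character(0)
  }
  counts <- tabulate_matches(matches, seqs, max_mm, "G")
  list(counts = counts, matches = matches)
}

empty_matches <- function() {
  tibble(spacer_seq = character(0), chrom = character(0), start = integer(0),
         end = integer(0), strand = character(0), mm = integer(0),
         matched_seq = character(0))
}

#' Count genome matches falling inside the target set
#'
#' Target-set-specific filtering distinguishes cross-target matches from
#' true off-targets: `T_m` is the number of genome matches at mismatch
#' level `m` whose matched window overlaps any declared target range by
#' at least one base, on either strand (a minus-strand match inside a
#' plus-strand target counts). The targets must be the same (transformed)
#' ranges used for spacer discovery.
#'
#' @param matches Match tibble from [count_genome_matches()].
#' @param targets Interval tibble of target ranges (empty set gives all
#'   `T_m = 0`).
#' @param max_mm Maximum mismatch level to tabulate.
#' @param spacer_seqs Spacer sequences to tabulate (defaults to those
#'   present in `matches`; pass the full set to keep zero-match spacers).
#' @return Tibble `spacer_seq`, `T0..Tk`.
#' @export
count_target_matches <- function(matches, targets, max_mm = 2L,
                                 spacer_seqs = unique(matches$spacer_seq)) {
  max_mm <- check_max_mm(max_mm)
  in_target <- if (nrow(matches) == 0 || nrow(targets) == 0) {
    matches[0, ]
  } else {
    tgt <- validate_intervals(targets) %>%
      select(chrom, t_start = "start", t_end = "end")
    matches %>%
      mutate(.match_id = dplyr::row_number()) %>%
      inner_join(tgt, by = "chrom", relationship = "many-to-many") %>%
      filter(.data$start <= .data$t_end, .data$end >= .data$t_start) %>%
      distinct(.data$.match_id, .keep_all = TRUE)
  }
  out <- tabulate_matches(in_target, spacer_seqs, max_mm, "T")
  if (length(spacer_seqs) == 0) out <- tibble(spacer_seq = character(0))
  out
}

#' Aggregate off-target counts
#'
#' `off_m = G_m - T_m` for every mismatch level, and `off` is their sum:
#' matches inside the declared target set are not off-targets. A negative
#' difference means the targets were not part of the scanned genome and
#' is raised as an internal-consistency error.
#'
#' @param G Tibble `spacer_seq`, `G0..Gk` from [count_genome_matches()].
#' @param T_counts Tibble `spacer_seq`, `T0..Tk` from
#'   [count_target_matches()].
#' @param max_mm Maximum mismatch level.
#' @return Tibble `spacer_seq`, `G0..Gk`, `T0..Tk`, `off0..offk`, `off`.
#' @examples
#' aggregate_off(
#'   tibble::tibble(spacer_seq = "A", G0 = 2L, G1 = 0L),
#'   tibble::tibble(spacer_seq = "A", T0 = 2L, T1 = 0L),
#'   max_mm = 1
#' )
#' @export
aggregate_off <- function(G, T_counts, max_mm = 2L) {
  max_mm <- check_max_mm(max_mm)
  out <- G %>% inner_join(T_counts, by = "spacer_seq")
  for (m in 0:max_mm) {
    g <- out[[paste0("G", m)]]
    t <- out[[paste0("T", m)]]
    if (any(t > g)) {
      gc_internal_error(sprintf(
        "T%d > G%d for %d spacer(s): targets are not a subset of the scanned genome",
        m, m, sum(t > g)
      ))
    }
    out[[paste0("off", m)]] <- as.integer(g - t)
  }
  out$off <- as.integer(rowSums(as.matrix(out[paste0("off", 0:max_mm)])))
  out
}

#' Genome + target + off-target counting in one call
#'
#' Convenience wrapper: runs [count_genome_matches()],
#' [count_target_matches()] and [aggregate_off()] and joins the counts
#' onto the spacer hit table.
#'
#' @inheritParams count_genome_matches
#' @param targets Declared target ranges for TSSF attribution.
#' @return The spacer tibble with `G0..Gk`, `T0..Tk`, `off0..offk`,
#'   `off` columns appended, plus the match tibble as attribute
#'   `"matches"`.
#' @export
count_offtargets <- function(spacers, genome, targets, max_mm = 2L,
                             engine = c("seeded", "exact"),
                             pam_mode = c("agnostic", "required"),
                             pam = "NGG") {
  gm <- count_genome_matches(spacers, genome, max_mm, engine, pam_mode, pam)
  tm <- count_target_matches(gm$matches, targets, max_mm,
                             spacer_seqs = gm$counts$spacer_seq)
  counts <- aggregate_off(gm$counts, tm, max_mm)
  out <- if (is.character(spacers)) {
    counts
  } else {
    spacers %>% left_join(counts, by = "spacer_seq")
  }
  attr(out, "matches") <- gm$matches
  out
}

#' Filter spacers by off-target policy
#'
#' \describe{
#'   \item{parallel}{keep spacers with `off = 0` up to `max_mm`:
#'     cross-target matches are permitted (they hit other declared
#'     targets, which parallel-targeting applications want).}
#'   \item{unique}{keep spacers whose only exact genome match is their
#'     own locus (`G0 = 1`), the rule for prime editing and classic
#'     single-locus work; with `require_off_free = TRUE` additionally
#'     demand `off = 0` up to `max_mm`.}
#' }
#'
#' @param x Spacer tibble carrying count columns (see
#'   [count_offtargets()]).
#' @param policy `"parallel"` or `"unique"`.
#' @param require_off_free For `policy = "unique"`, also require
#'   `off = 0`.
#' @return The filtered tibble.
#' @export
filter_spacers <- function(x, policy = c("parallel", "unique"),
                           require_off_free = FALSE) {
  policy <- match.arg(policy)
  if (policy == "parallel") {
    if (!("off" %in% names(x))) {
      gc_input_error("parallel policy requires an 'off' column (run count_offtargets first)")
    }
    x %>% filter(.data$off == 0L)
  } else {
    if (!("G0" %in% names(x))) {
      gc_input_error("unique policy requires a 'G0' column (run count_offtargets first)")
    }
    out <- x %>% filter(.data$G0 == 1L)
    if (require_off_free) out <- out %>% filter(.data$off == 0L)
    out
  }
}
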