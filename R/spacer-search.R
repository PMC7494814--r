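IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# IUPAC pattern -> regex character classes over unambiguous bases only, so a
# genome N never satisfies any pattern letter
iupac_regex <- function(pattern) {
  letters <- strsplit(str_to_upper(pattern), "")[[1]]
  bad <- !letters %in% names(IUPAC_SETS)
  if (any(bad)) {
    gc_input_error(paste0(
      "PAM pattern contains non-IUPAC letter(s): ",
      paste(unique(letters[bad]), collapse = ", ")
    ))
  }
  paste0(map_chr(letters, function(l) {
    s <- IUPAC_SETS[[l]]
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }), collapse = "")
}

# all overlapping 1-based match starts of a regex in a string
regex_starts <- function(seq, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Find spacer/PAM sites inside target regions
#'
#' Scans every target range (both strands by default) for words of
#' `spacer_len` unambiguous bases immediately followed, on the same
#' strand, by the IUPAC PAM pattern. The default `N20-NGG` is the
#' wild-type S. pyogenes Cas9 site. Every spacer+PAM word fully contained
#' in a target is reported exactly once per (location, strand, target):
#' a spacer inside two overlapping targets yields two rows, which is what
#' target-set-specific off-target attribution needs; use
#' [dedup_spacers()] for a location-unique library view.
#'
#' Spacers overlapping any non-ACGT genome base are discarded (ambiguous
#' spacers are experimentally unusable). If the target table carries a
#' `search_strand` column (see [transform_targets()]), only that strand
#' is searched per row. `cut_after` is the genomic position of the 17th
#' protospacer base; Cas9 cleaves immediately 3' of it, 3 bases 5' of the
#' PAM.
#'
#' @param targets Interval tibble (resolved against `genome`).
#' @param genome A [genome].
#' @param pam IUPAC PAM pattern 3' of the spacer. Default `"NGG"`.
#' @param spacer_len Spacer length in nt. Default 20.
#' @param strands Strands to search. Default both.
#' @return A tibble of spacer hits sorted by (chrom, start, strand):
#'   columns `chrom`, `start`, `end`, `strand`, `name` (spacer id),
#'   `spacer_seq`, `pam_start`, `pam_end`, `pam_seq`, `cut_after`,
#'   `target_name`, `target_start`, `target_end`, `target_strand`.
#' @examples
#' g <- genome(c(chr1 = "TTTACGTACGTACGTACGTACGTAGGTTT"))
#' find_spacers(genomic_intervals("chr1", 1, 29), g)
#' @export
find_spacers <- function(targets, genome, pam = "NGG", spacer_len = 20L,
                         strands = c("+", "-")) {
  stopifnot(inherits(genome, "genome"))
  spacer_len <- as.integer(spacer_len)
  if (spacer_len < 1L) gc_input_error("spacer_len must be >= 1")
  targets <- validate_intervals(targets, genome)
  pam_rx <- iupac_regex(pam)
  pam_rc_rx <- iupac_regex(revcomp(pam))
  pam_len <- str_length(pam)
  word_len <- spacer_len + pam_len
  plus_rx <- paste0(strrep("[ACGT]", spacer_len), pam_rx)
  minus_rx <- paste0(pam_rc_rx, strrep("[ACGT]", spacer_len))

  rows <- pmap(targets, function(chrom, start, end, strand, name, ...) {
    extra <- list(...)
    row_strands <- if (!is.null(extra$search_strand)) extra$search_strand else strands
    if (end - start + 1L < word_len) return(NULL)
    window <- str_sub(genome$seq[[chrom]], start, end)
    out <- list()
    if ("+" %in% row_strands) {
      i <- regex_starts(window, plus_rx)
      i <- i[i + word_len - 1L <= str_length(window)]
      if (length(i) > 0) {
        s0 <- start + i - 1L
        out$plus <- tibble(
          chrom = chrom, start = s0, end = s0 + spacer_len - 1L, strand = "+",
          spacer_seq = str_sub(window, i, i + spacer_len - 1L),
          pam_start = s0 + spacer_len, pam_end = s0 + word_len - 1L,
          pam_seq = str_sub(window, i + spacer_len, i + word_len - 1L),
          cut_after = if (spacer_len >= 17L) s0 + 16L else NA_integer_
        )
      }
    }
    if ("-" %in% row_strands) {
      i <- regex_starts(window, minus_rx)
      i <- i[i + word_len - 1L <= str_length(window)]
      if (length(i) > 0) {
        w0 <- start + i - 1L              # word start (PAM first on plus)
        s0 <- w0 + pam_len                # spacer start (genomic)
        out$minus <- tibble(
          chrom = chrom, start = s0, end = s0 + spacer_len - 1L, strand = "-",
          spacer_seq = revcomp(str_sub(window, i + pam_len, i + word_len - 1L)),
          pam_start = w0, pam_end = w0 + pam_len - 1L,
          pam_seq = revcomp(str_sub(window, i, i + pam_len - 1L)),
          cut_after = if (spacer_len >= 17L) s0 + spacer_len - 17L else NA_integer_
        )
      }
    }
    if (length(out) == 0) return(NULL)
    res <- bind_rows(out)
    res$target_name <- name
    res$target_start <- start
    res$target_end <- end
    res$target_strand <- strand
    res
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) {
    return(tibble(
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0), name = character(0), spacer_seq = character(0),
      pam_start = integer(0), pam_end = integer(0), pam_seq = character(0),
      cut_after = integer(0), target_name = character(0),
      target_start = integer(0), target_end = integer(0),
      target_strand = character(0)
    ))
  }
  res$start <- as.integer(res$start)
  res$end <- as.integer(res$end)
  res$pam_start <- as.integer(res$pam_start)
  res$pam_end <- as.integer(res$pam_end)
  res$cut_after <- as.integer(res$cut_after)
  res$name <- interval_label(res)
  res <- res %>%
    distinct(.data$chrom, .data$start, .data$strand, .data$target_name,
             .data$target_start, .data$target_end, .keep_all = TRUE) %>%
    arrange(.data$chrom, .data$start, .data$strand) %>%
    select("chrom", "start", "end", "strand", "name", "spacer_seq",
           "pam_start", "pam_end", "pam_seq", "cut_after", "target_name",
           "target_start", "target_end", "target_strand")
  res
}

#' Location-unique view of a spacer hit table
#'
#' Collapses per-target duplicate rows (the same spacer found in several
#' overlapping targets) to one row per (chrom, start, strand), keeping
#' the first target attribution. Use for library export; keep the full
#' table for target-set-specific filtering.
#'
#' @param hits A tibble from [find_spacers()].
#' @return The deduplicated tibble.
#' @export
dedup_spacers <- function(hits) {
  hits %>% distinct(.data$chrom, .data$start, .data$strand, .keep_all = TRUE)
}
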