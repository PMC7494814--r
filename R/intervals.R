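#' Build a tibble of stranded genomic intervals
#'
#' Intervals are the package's universal currency: targets, spacer search
#' regions, spacers, PAMs and nick sites are all rows of the same shape.
#' Coordinates are 1-based and fully closed, so `width = end - start + 1`
#' (the range `chr1:100-119` spans 20 bases). BED input, which is 0-based
#' half-open on disk, is converted at the I/O boundary by [read_bed()].
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer vectors, 1-based closed; `end >= start >= 1`.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded). Recycled.
#' @param name Free-text labels; defaults to `chrom:start-end:strand`.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `name`.
#' @examples
#' genomic_intervals("chr1", 100, 119, "+", "site1")
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", name = NULL) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom))
  )
  x$name <- if (is.null(name)) interval_label(x) else as.character(name)
  validate_intervals(x)
}

interval_label <- function(x) {
  paste0(x$chrom, ":", x$start, "-", x$end, ":", x$strand)
}

#' Validate an interval tibble
#'
#' Checks the coordinate invariants (`start >= 1`, `end >= start`, legal
#' strand codes) and, when a genome is supplied, that every chromosome
#' exists and `end` does not run past its length.
#'
#' @param x A tibble with columns `chrom`, `start`, `end`, `strand`
#'   (and optionally `name`, added if missing).
#' @param genome Optional [genome] object to resolve bounds against.
#' @return `x`, invisibly validated (returned for piping).
#' @export
validate_intervals <- function(x, genome = NULL) {
  required <- c("chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    gc_input_error(paste0(
      "interval table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  x <- as_tibble(x)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (!("name" %in% names(x))) x$name <- interval_label(x)
  if (nrow(x) == 0) return(x)
  if (anyNA(x$start) || anyNA(x$end)) {
    gc_input_error("interval start/end must not be NA")
  }
  if (any(x$start < 1L)) {
    gc_input_error("interval start must be >= 1 (coordinates are 1-based)")
  }
  if (any(x$end < x$start)) {
    bad <- which(x$end < x$start)[1]
    gc_input_error(sprintf(
      "degenerate interval (width < 1) at row %d: %s:%d-%d",
      bad, x$chrom[bad], x$start[bad], x$end[bad]
    ))
  }
  if (!all(x$strand %in% c("+", "-", "*"))) {
    gc_input_error("strand must be one of '+', '-', '*'")
  }
  if (!is.null(genome)) {
    lens <- seq_lengths(genome)
    unknown <- setdiff(unique(x$chrom), names(lens))
    if (length(unknown) > 0) {
      gc_input_error(paste0(
        "chromosome(s) not in genome: ", paste(unknown, collapse = ", ")
      ))
    }
    over <- x$end > lens[x$chrom]
    if (any(over)) {
      bad <- which(over)[1]
      gc_input_error(sprintf(
        "interval exceeds chromosome length at row %d: %s:%d-%d (%s length %d)",
        bad, x$chrom[bad], x$start[bad], x$end[bad], x$chrom[bad],
        lens[x$chrom[bad]]
      ))
    }
  }
  x
}

#' @rdname genomic_intervals
#' @param x An interval tibble.
#' @export
interval_width <- function(x) {
  x$end - x$start + 1L
}

# shared bounds handling: error by default, or clip to [1, chrom length]
# with a warning. Silent truncation would quietly change the search space,
# so clipping is always loud.
check_bounds <- function(x, genome, clip) {
  if (nrow(x) == 0) return(x)
  lens <- if (is.null(genome)) NULL else seq_lengths(genome)
  low <- x$start < 1L
  high <- if (is.null(lens)) rep(FALSE, nrow(x)) else x$end > lens[x$chrom]
  if (!any(low) && !any(high)) return(x)
  if (!clip) {
    bad <- which(low | high)[1]
    gc_input_error(sprintf(
      "resulting interval out of bounds at row %d: %s:%d-%d (use clip = TRUE to truncate)",
      bad, x$chrom[bad], x$start[bad], x$end[bad]
    ))
  }
  warn(sprintf("clipped %d interval(s) to chromosome bounds", sum(low | high)))
  x$start[low] <- 1L
  if (!is.null(lens)) x$end[high] <- unname(lens[x$chrom[high]])
  if (any(x$end < x$start)) {
    gc_input_error("clipping produced a degenerate interval (width < 1)")
  }
  x
}

# strand-aware ops treat '*' as '+', loudly
effective_strand <- function(x, strand_aware) {
  s <- x$strand
  if (strand_aware && any(s == "*")) {
    warn("unstranded ('*') intervals treated as plus-strand for a strand-aware operation")
    s[s == "*"] <- "+"
  }
  if (!strand_aware) s[] <- "+"
  s
}

#' Extend intervals by signed offsets
#'
#' Grows (or shrinks) each interval at both ends. On the plus strand (or
#' with `strand_aware = FALSE`) the new range is
#' `[start + start_offset, end + end_offset]`; on the minus strand with
#' `strand_aware = TRUE` the offsets are applied in the 5'->3' reading
#' direction, i.e. `[start - end_offset, end - start_offset]`. A symmetric
#' `[-22, +22]` extension is the classic pre-search transform for blocking
#' a target site: any spacer/PAM word found in the extended range overlaps
#' the original target by at least one base.
#'
#' @param x Interval tibble.
#' @param start_offset,end_offset Signed integer offsets (5' and 3'
#'   respectively when strand-aware).
#' @param strand_aware Apply offsets in the interval's own reading
#'   direction? Default `TRUE`.
#' @param genome Optional [genome] for bounds checking.
#' @param clip Truncate out-of-bounds results to the chromosome (with a
#'   warning) instead of erroring? Default `FALSE`.
#' @return Interval tibble with strand and name preserved.
#' @examples
#' x <- genomic_intervals("chr13", 119991554, 119991569, "+")
#' extend_targets(x, -22, 22)
#' @export
extend_targets <- function(x, start_offset, end_offset, strand_aware = TRUE,
                           genome = NULL, clip = FALSE) {
  x <- validate_intervals(x)
  if (nrow(x) == 0) return(x)
  s <- effective_strand(x, strand_aware)
  minus <- s == "-"
  new_start <- ifelse(minus, x$start - end_offset, x$start + start_offset)
  new_end <- ifelse(minus, x$end - start_offset, x$end + end_offset)
  out <- x
  out$start <- as.integer(new_start)
  out$end <- as.integer(new_end)
  if (any(out$end < out$start)) {
    gc_input_error("extension offsets produce a degenerate interval (width < 1)")
  }
  check_bounds(out, genome, clip)
}

#' Flank intervals upstream or downstream
#'
#' `up_flank()` anchors at the 5' end of each interval (its `start` on the
#' plus strand, `end` on the minus strand when strand-aware) and returns
#' `[anchor + start_offset, anchor + end_offset]` read 5'->3'.
#' `down_flank()` mirrors this with the 3' end as anchor. A `[-300, 0]`
#' strand-agnostic up-flank of a transcription start site is the standard
#' CRISPRa search region; `[-16, +x]` down-flanks locate nickase pairs in
#' PAM-out orientation for excision.
#'
#' @inheritParams extend_targets
#' @param start_offset,end_offset Signed offsets from the anchor,
#'   `start_offset <= end_offset`.
#' @return Interval tibble, strand and name preserved.
#' @examples
#' tss <- genomic_intervals("chr1", 1000, 1016, "+")
#' up_flank(tss, -300, -1)
#' down_flank(tss, -16, 30)
#' @export
up_flank <- function(x, start_offset, end_offset, strand_aware = TRUE,
                     genome = NULL, clip = FALSE) {
  flank_impl(x, start_offset, end_offset, strand_aware, genome, clip,
             anchor_5prime = TRUE)
}

#' @rdname up_flank
#' @export
down_flank <- function(x, start_offset, end_offset, strand_aware = TRUE,
                       genome = NULL, clip = FALSE) {
  flank_impl(x, start_offset, end_offset, strand_aware, genome, clip,
             anchor_5prime = FALSE)
}

flank_impl <- function(x, start_offset, end_offset, strand_aware, genome,
                       clip, anchor_5prime) {
  if (start_offset > end_offset) {
    gc_input_error("flank offsets must satisfy start_offset <= end_offset")
  }
  x <- validate_intervals(x)
  if (nrow(x) == 0) return(x)
  s <- effective_strand(x, strand_aware)
  minus <- s == "-"
  # genomic anchor: 5' anchor is start (+) / end (-); 3' anchor mirrored
  anchor <- if (anchor_5prime) {
    ifelse(minus, x$end, x$start)
  } else {
    ifelse(minus, x$start, x$end)
  }
  new_start <- ifelse(minus, anchor - end_offset, anchor + start_offset)
  new_end <- ifelse(minus, anchor - start_offset, anchor + end_offset)
  out <- x
  out$start <- as.integer(new_start)
  out$end <- as.integer(new_end)
  check_bounds(out, genome, clip)
}

#' Flank intervals on both sides
#'
#' Returns the [up_flank()] and [down_flank()] results together, two rows
#' per input, each tagged with the parent target's name plus a `flank`
#' column (`"up"`/`"down"`). This is the search region for vicinity
#' targeting, where guides are wanted on both sides of a site but not on
#' it.
#'
#' @inheritParams extend_targets
#' @param up_offsets,down_offsets Length-2 integer vectors
#'   `(start_offset, end_offset)` for the two flanks.
#' @return Interval tibble with `2 * nrow(x)` rows.
#' @examples
#' x <- genomic_intervals("chr1", 1000, 1016, "+", "site")
#' double_flank(x, c(-50, -1), c(1, 50))
#' @export
double_flank <- function(x, up_offsets, down_offsets, strand_aware = TRUE,
                         genome = NULL, clip = FALSE) {
  stopifnot(length(up_offsets) == 2, length(down_offsets) == 2)
  x <- validate_intervals(x)
  up <- up_flank(x, up_offsets[1], up_offsets[2], strand_aware, genome, clip)
  dn <- down_flank(x, down_offsets[1], down_offsets[2], strand_aware, genome, clip)
  up$flank <- rep("up", nrow(up))
  dn$flank <- rep("down", nrow(dn))
  out <- bind_rows(up, dn)
  out[order(rep(seq_len(nrow(x)), 2)), , drop = FALSE]
}

#' Expand cut positions to 20-nt spacer ranges
#'
#' Given width-1 stranded cut-site positions (the convention used by
#' published guide libraries that record a cut coordinate and an
#' orientation), reconstructs the spacer range: `[pos - 17, pos + 2]` for
#' plus-strand spacers and `[pos - 16, pos + 3]` for minus-strand spacers.
#' Every output has width exactly 20.
#'
#' @inheritParams extend_targets
#' @param x Interval tibble of width-1 stranded positions.
#' @return Interval tibble of width-20 spacer ranges.
#' @examples
#' cut_to_spacer(genomic_intervals("chr1", 500, 500, "+"))
#' @export
cut_to_spacer <- function(x, genome = NULL, clip = FALSE) {
  x <- validate_intervals(x)
  if (nrow(x) == 0) return(x)
  if (any(interval_width(x) != 1L)) {
    gc_input_error("cut_to_spacer() requires width-1 input positions")
  }
  if (any(x$strand == "*")) {
    warn("unstranded ('*') cut positions treated as plus-strand")
  }
  minus <- x$strand == "-"
  out <- x
  out$start <- as.integer(ifelse(minus, x$start - 16L, x$start - 17L))
  out$end <- as.integer(ifelse(minus, x$end + 3L, x$end + 2L))
  check_bounds(out, genome, clip)
}

#' Built-in genome-arithmetic presets
#'
#' One named transform per common CRISPR application:
#' \describe{
#'   \item{cut_within}{`[-16, +5]` strand-aware extension, so that the Cas9
#'     cut (after protospacer nucleotide 17) falls inside the original
#'     target. Applied per spacer strand by [transform_targets()].}
#'   \item{block}{`[-22, +22]` extension; every spacer/PAM word in the
#'     extended range overlaps the target by at least one base.}
#'   \item{crispri}{`[-50, +300]` strand-agnostic extension of the TSS.}
#'   \item{crispra}{`[-300, 0]` strand-agnostic upstream flank of the TSS.}
#'   \item{excise}{`[-16, +x]` strand-aware downstream flank; `x` is a
#'     required user parameter (`excise_end`).}
#'   \item{vicinity}{double flank with user offsets.}
#' }
#'
#' @return A tibble describing the presets (name, offsets, mode,
#'   strand-awareness).
#' @export
arithmetic_presets <- function() {
  tibble(
    preset = c("cut_within", "block", "crispri", "crispra", "excise", "vicinity"),
    start_offset = c(-16L, -22L, -50L, -300L, -16L, NA_integer_),
    end_offset = c(5L, 22L, 300L, 0L, NA_integer_, NA_integer_),
    mode = c("extend", "extend", "extend", "up_flank", "down_flank", "double_flank"),
    strand_aware = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
}

#' Transform targets into spacer search regions
#'
#' Applies a named [arithmetic_presets()] transform (or raw offsets with
#' `preset = "extend"`). For `cut_within` the transform is spacer-strand
#' specific and the result carries a `search_strand` column: plus-strand
#' spacers are sought in the `[-16, +5]` extension read on the target's
#' strand, minus-strand spacers in its mirror, which is what makes the
#' cut-inside-target guarantee hold on both strands (see the package
#' vignette). [find_spacers()] honours `search_strand` when present.
#'
#' @inheritParams extend_targets
#' @param preset One of `"cut_within"`, `"block"`, `"crispri"`,
#'   `"crispra"`, `"excise"`, `"vicinity"`, or `"extend"` for raw offsets.
#' @param excise_end Required 3' offset for the `excise` preset (the
#'   `+x` in `[-16, +x]`).
#' @param up_offsets,down_offsets Offset pairs for the `vicinity` preset.
#' @param start_offset,end_offset Raw offsets for `preset = "extend"`.
#' @return Interval tibble of search regions (possibly with a
#'   `search_strand` column).
#' @export
transform_targets <- function(x, preset, genome = NULL, clip = FALSE,
                              excise_end = NULL,
                              up_offsets = c(-50L, -1L),
                              down_offsets = c(1L, 50L),
                              start_offset = NULL, end_offset = NULL) {
  x <- validate_intervals(x, genome)
  switch(preset,
    cut_within = {
      # per-spacer-strand mirrored windows; '*' anchors on '+'
      same <- extend_targets(x, -16L, 5L, TRUE, genome, clip)
      opp <- extend_targets(x, -5L, 16L, TRUE, genome, clip)
      tstrand <- ifelse(x$strand == "-", "-", "+")
      same$search_strand <- tstrand
      opp$search_strand <- ifelse(tstrand == "+", "-", "+")
      bind_rows(same, opp)
    },
    block = extend_targets(x, -22L, 22L, TRUE, genome, clip),
    crispri = extend_targets(x, -50L, 300L, FALSE, genome, clip),
    crispra = up_flank(x, -300L, 0L, FALSE, genome, clip),
    excise = {
      if (is.null(excise_end)) {
        gc_input_error("the excise preset requires `excise_end` (the +x in [-16, +x])")
      }
      down_flank(x, -16L, as.integer(excise_end), TRUE, genome, clip)
    },
    vicinity = double_flank(x, up_offsets, down_offsets, TRUE, genome, clip),
    extend = {
      if (is.null(start_offset) || is.null(end_offset)) {
        gc_input_error("preset 'extend' requires start_offset and end_offset")
      }
      extend_targets(x, start_offset, end_offset, TRUE, genome, clip)
    },
    gc_input_error(paste0("unknown preset: ", preset))
  )
}
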