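#' Read and write BED files
#'
#' BED is 0-based half-open on disk; internally everything is 1-based
#' closed, so a BED line `chr1 99 119` becomes `chr1:100-119` (width 20).
#' `read_bed()` accepts 3- to 6-column BED, maps strand `"."` to `"*"`,
#' validates every record against the genome when one is supplied, and
#' reports malformed or out-of-bounds records with their line numbers.
#' `write_bed()` inverts the conversion (BED6, score 0).
#'
#' @param path File path.
#' @param genome Optional [genome] for bounds validation.
#' @return `read_bed()`: an interval tibble; `write_bed()`: `path`,
#'   invisibly.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) gc_input_error(paste0("BED file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(genomic_intervals(character(0), integer(0), integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    gc_input_error(paste0(
      "malformed BED line(s) (< 3 fields): line ",
      paste(lineno[nf < 3], collapse = ", ")
    ))
  }
  chrom <- map_chr(fields, 1)
  start0 <- suppressWarnings(as.integer(map_chr(fields, 2)))
  end0 <- suppressWarnings(as.integer(map_chr(fields, 3)))
  if (anyNA(start0) || anyNA(end0)) {
    bad <- lineno[is.na(start0) | is.na(end0)]
    gc_input_error(paste0(
      "non-numeric BED coordinates: line ", paste(bad, collapse = ", ")
    ))
  }
  name <- ifelse(nf >= 4, map_chr(fields, function(f) f[min(4, length(f))]), NA)
  strand <- ifelse(nf >= 6, map_chr(fields, function(f) f[min(6, length(f))]), ".")
  strand[!strand %in% c("+", "-")] <- "*"
  if (any(end0 <= start0)) {
    bad <- lineno[end0 <= start0]
    gc_input_error(paste0(
      "BED record with end <= start: line ", paste(bad, collapse = ", ")
    ))
  }
  x <- tibble(chrom = chrom, start = start0 + 1L, end = end0, strand = strand,
              name = ifelse(is.na(name) | name == ".", NA_character_, name))
  x$name <- ifelse(is.na(x$name), interval_label(x), x$name)
  if (!is.null(genome)) {
    lens <- seq_lengths(genome)
    bad <- !(x$chrom %in% names(lens)) | x$end > lens[x$chrom] | is.na(lens[x$chrom])
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      gc_input_error(paste0(
        "BED record(s) outside genome bounds: line ",
        paste(lineno[bad], collapse = ", ")
      ))
    }
  }
  validate_intervals(x, genome)
}

#' @rdname read_bed
#' @param x Interval tibble.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  out <- tibble(
    chrom = x$chrom,
    start = x$start - 1L,
    end = x$end,
    name = x$name,
    score = 0L,
    strand = ifelse(x$strand == "*", ".", x$strand)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

# column typing for result tables: everything matching these prefixes is
# integer, score columns are double, the rest character
result_int_cols <- function(nms) {
  nms[grepl("^(start|end|cut_after|pam_start|pam_end|target_start|target_end|nick_distance|[GT]\\d+|off\\d*|off)$", nms)]
}

#' Write and read result tables
#'
#' Result tables (spacer hits, TSSF counts, prime-editing designs) are
#' serialized as plain TSV with a header row, the package's canonical
#' machine-readable product. `read_results()` restores column types
#' (integer counts/coordinates, double scores) so that
#' `read_results(write_results(x)) == x`.
#'
#' @param x A result tibble.
#' @param path File path.
#' @return `write_results()`: `path` invisibly; `read_results()`: the
#'   tibble.
#' @export
write_results <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) gc_input_error(paste0("results file not found: ", path))
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(hdr) == 0 || anyDuplicated(hdr)) {
    gc_input_error("results file header missing or duplicated")
  }
  types <- setNames(rep(list(readr::col_character()), length(hdr)), hdr)
  for (cc in result_int_cols(hdr)) types[[cc]] <- readr::col_integer()
  for (cc in hdr[grepl("score", hdr)]) types[[cc]] <- readr::col_double()
  x <- readr::read_tsv(path, col_types = do.call(readr::cols, types),
                       na = "NA", progress = FALSE)
  problems <- readr::problems(x)
  if (nrow(problems) > 0) {
    gc_input_error("results file does not parse under the canonical column types")
  }
  x
}
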