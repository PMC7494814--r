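#' Create or load a genome
#'
#' A genome is a named set of uppercase DNA sequences plus an assembly
#' label. `load_genome()` reads a FASTA file (via Biostrings);
#' `genome()` wraps an in-memory named character vector, which is how the
#' synthetic fixtures in [synth_genome()] are built. Only IUPAC DNA
#' letters are accepted; anything else is rejected at load. Search and
#' counting treat non-ACGT genome bases (including `N`) as matching
#' nothing.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param assembly Assembly label carried through run logs.
#' @return An object of class `genome`.
#' @examples
#' g <- genome(c(chr1 = "ACGTACGTAA"), assembly = "toy")
#' seq_lengths(g)
#' @export
genome <- function(seqs, assembly = "custom") {
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyDuplicated(names(seqs))) {
    gc_input_error("genome sequences must have unique, non-empty names")
  }
  seqs <- unlist(seqs)
  seqs <- setNames(str_to_upper(seqs), names(seqs))
  if (any(nchar(seqs) == 0)) {
    gc_input_error("genome sequences must be non-empty")
  }
  bad <- str_detect(seqs, "[^ACGTNRYSWKMBDHV]")
  if (any(bad)) {
    gc_input_error(paste0(
      "non-IUPAC characters in sequence(s): ",
      paste(names(seqs)[bad], collapse = ", ")
    ))
  }
  structure(list(assembly = assembly, seq = seqs), class = "genome")
}

#' @rdname genome
#' @param path Path to a FASTA file.
#' @export
load_genome <- function(path, assembly = NULL) {
  if (!file.exists(path)) {
    gc_input_error(paste0("FASTA file not found: ", path))
  }
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))  # first token of the header
  if (anyDuplicated(nm)) {
    gc_input_error("duplicate FASTA headers")
  }
  names(ss) <- nm
  genome(setNames(as.character(ss), nm),
         assembly = assembly %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path)))
}

#' @export
print.genome <- function(x, ...) {
  lens <- seq_lengths(x)
  cat(sprintf("<genome> %s: %d sequence(s), %s bp total\n",
              x$assembly, length(lens), format(sum(lens), big.mark = ",")))
  invisible(x)
}

#' @rdname genome
#' @param x A `genome`.
#' @export
seq_lengths <- function(x) {
  stopifnot(inherits(x, "genome"))
  setNames(nchar(x$seq), names(x$seq))
}

#' @rdname genome
#' @export
write_genome <- function(x, path) {
  stopifnot(inherits(x, "genome"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$seq), path)
  invisible(path)
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (IUPAC letters allowed).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Fetch interval sequences from a genome
#'
#' Plus-strand and unstranded intervals return the forward slice; minus
#' strand intervals return the reverse complement, so the result always
#' reads 5'->3' on the interval's own strand. The returned string's width
#' equals the interval width.
#'
#' @param g A [genome].
#' @param x Interval tibble.
#' @return Character vector, one sequence per interval row.
#' @examples
#' g <- genome(c(chr1 = "ACGTTACGT"))
#' fetch_seq(g, genomic_intervals("chr1", 1, 5, "+"))
#' fetch_seq(g, genomic_intervals("chr1", 1, 5, "-"))
#' @export
fetch_seq <- function(g, x) {
  stopifnot(inherits(g, "genome"))
  x <- validate_intervals(x, g)
  if (nrow(x) == 0) return(character(0))
  fwd <- str_sub(g$seq[x$chrom], x$start, x$end)
  minus <- x$strand == "-"
  if (any(minus)) fwd[minus] <- revcomp(fwd[minus])
  unname(fwd)
}
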