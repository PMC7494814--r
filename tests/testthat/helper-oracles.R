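# Independent oracles used across the suite. These deliberately share no
# code with the package internals: plain loops, substring and lookup
# tables only.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

oracle_iupac_eq <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  length(sc) == length(pc) &&
    all(vapply(seq_along(pc), function(i) sc[i] %in% IUPAC_ORACLE[[pc[i]]],
               logical(1)))
}

# enumerate every spacer/PAM word on both strands of a window placed at
# genomic [start, ...]; returns genomic spacer coordinates
oracle_find_spacers <- function(window, genomic_start, pam = "NGG",
                                spacer_len = 20L) {
  pam_len <- nchar(pam)
  word_len <- spacer_len + pam_len
  L <- nchar(window)
  out <- list()
  for (i in seq_len(max(L - word_len + 1L, 0L))) {
    word <- substr(window, i, i + word_len - 1L)
    spac <- substr(word, 1L, spacer_len)
    pamf <- substr(word, spacer_len + 1L, word_len)
    if (!grepl("[^ACGT]", spac) && oracle_iupac_eq(pamf, pam)) {
      out[[length(out) + 1L]] <- data.frame(
        start = genomic_start + i - 1L, strand = "+",
        spacer_seq = spac, pam_seq = pamf, stringsAsFactors = FALSE
      )
    }
    # minus strand: reverse complement of the word, PAM first on plus
    rcword <- oracle_revcomp(word)
    rspac <- substr(rcword, 1L, spacer_len)
    rpam <- substr(rcword, spacer_len + 1L, word_len)
    if (!grepl("[^ACGT]", rspac) && oracle_iupac_eq(rpam, pam)) {
      out[[length(out) + 1L]] <- data.frame(
        start = genomic_start + i - 1L + pam_len, strand = "-",
        spacer_seq = rspac, pam_seq = rpam, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), strand = character(0),
                      spacer_seq = character(0), pam_seq = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# genome with one chromosome built from an explicit string
str_genome <- function(seq, chrom = "chr1") {
  genome(stats::setNames(seq, chrom))
}

counts_row <- function(counts, seq) {
  unlist(counts[counts$spacer_seq == seq, -1, drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
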