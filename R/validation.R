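#' Recompute the published reference designs against a local genome
#'
#' Integration check against well-characterised human loci: given a
#' local GRCh38 FASTA (multi-gigabyte, never shipped with the package),
#' re-runs the prime-editing design for the prion-disease locus
#' (chr20:4699600 G>T, the classic PE3 showcase) and reports the editing
#' and nicking spacers found, plus exact-engine genome match counts for
#' the editing spacers. Expected outcome on the primary assembly:
#' four plus-strand editing spacers starting at 4699568, 4699569,
#' 4699575 and 4699578, and two nicking spacers. Which FASTA was scanned
#' matters (alternative haplotype contigs add matches), so the result
#' records the file path and checksum.
#'
#' @param fasta_path Path to a GRCh38 FASTA. An informative classed
#'   error (`guidecraft_input_error`) is raised when the file is absent,
#'   so pipelines can treat the check as unavailable rather than failed.
#' @param max_mm Mismatch depth for the editing-spacer counts (up to 3).
#' @return A list with `design` (the PRNP `guide_design`),
#'   `editing_starts`, `n_editing`, `n_nicking`, `counts` (exact-engine
#'   `G0..Gk` per editing spacer), and `genome_file`/`genome_md5`.
#' @export
check_reference_designs <- function(fasta_path, max_mm = 2L) {
  if (is.null(fasta_path) || !nzchar(fasta_path) || !file.exists(fasta_path)) {
    gc_input_error(paste0(
      "reference genome FASTA not available (looked for: ",
      if (is.null(fasta_path) || !nzchar(fasta_path)) "<unset>" else fasta_path,
      "); supply a local GRCh38 FASTA to run the reference-design check"
    ))
  }
  genome <- load_genome(fasta_path, assembly = "GRCh38")
  design <- run_prime_editing(
    genome, edit_spec("chr20", 4699600L, "G", "T"),
    params = prime_params(nrt = 16L, pbs_len = 13L, nick_window = c(40L, 90L)),
    engine = "seeded", scorer = "ruleset1"
  )
  tab <- tidy(design)
  editing <- tab[tab$role == "editing", ]
  counts <- count_genome_matches(editing$spacer_seq, genome,
                                 max_mm = check_max_mm(max_mm),
                                 engine = "exact")$counts
  list(
    design = design,
    editing_starts = sort(editing$start[editing$strand == "+"]),
    n_editing = nrow(editing),
    n_nicking = sum(tab$role == "nicking"),
    counts = counts,
    genome_file = fasta_path,
    genome_md5 = unname(tools::md5sum(fasta_path))
  )
}
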