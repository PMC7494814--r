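#' Seeded synthetic genomes with planted matches
#'
#' `synth_genome()` draws random background sequence; `make_genome()`
#' additionally plants copies of given words at requested positions,
#' strands and mismatch counts, then verifies with the brute-force oracle
#' that the background contains no additional copy of any planted word
#' within `max_mm` mismatches, regenerating the background (bounded
#' retries) if it does. Everything is reproducible from `seed`.
#'
#' @param lengths Named integer vector: chromosome name -> length.
#' @param gc Background GC fraction. Default 0.5.
#' @param seed Integer seed; the generator uses its own RNG stream and
#'   does not disturb the session RNG.
#' @param assembly Assembly label.
#' @return A [genome].
#' @examples
#' g <- synth_genome(c(chr1 = 500), seed = 1)
#' seq_lengths(g)
#' @export
synth_genome <- function(lengths, gc = 0.5, seed = 1L, assembly = "synthetic") {
  stopifnot(!is.null(names(lengths)), all(lengths >= 1))
  seqs <- with_own_rng(seed, {
    map_chr(as.integer(lengths), function(L) {
      paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
             collapse = "")
    })
  })
  genome(setNames(seqs, names(lengths)), assembly = assembly)
}

# run code under a private RNG stream
with_own_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# mutate exactly `mm` positions of `word`, never inside the last
# `protect_tail` bases (the PAM) unless protect_tail = 0
mutate_word <- function(word, mm, protect_tail = 0L) {
  if (mm == 0L) return(word)
  n <- nchar(word)
  eligible <- seq_len(n - protect_tail)
  if (mm > length(eligible)) {
    gc_input_error("requested more mismatches than mutable positions")
  }
  pos <- sample(eligible, mm)
  chars <- strsplit(word, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste0(chars, collapse = "")
}

#' @rdname synth_genome
#' @param plants Tibble with columns `seq` (word to plant, 5'->3' on
#'   `strand`), `chrom`, `pos` (1-based start of the planted word on the
#'   plus strand), `strand`, and `mm` (mismatches to introduce; never in
#'   the last `protect_tail` bases, so a trailing PAM stays intact).
#' @param max_mm Background is guaranteed free of extra matches to any
#'   planted word within this Hamming distance. Default 3.
#' @param protect_tail Number of trailing bases protected from mutation
#'   (default 3, a PAM).
#' @param max_tries Background regeneration attempts before giving up.
#' @export
make_genome <- function(lengths, plants, gc = 0.5, seed = 1L, max_mm = 3L,
                        protect_tail = 3L, max_tries = 20L,
                        assembly = "synthetic") {
  stopifnot(is.data.frame(plants),
            all(c("seq", "chrom", "pos", "strand", "mm") %in% names(plants)))
  plants <- as_tibble(plants)
  plants$seq <- str_to_upper(plants$seq)
  plants$pos <- as.integer(plants$pos)
  plants$mm <- as.integer(plants$mm)
  width <- nchar(plants$seq)
  # placements must not overlap each other
  if (nrow(plants) > 1) {
    p <- plants[order(plants$chrom, plants$pos), ]
    w <- nchar(p$seq)
    same <- p$chrom[-1] == p$chrom[-nrow(p)]
    if (any(same & p$pos[-1] <= p$pos[-nrow(p)] + w[-nrow(p)] - 1L)) {
      gc_input_error("planted placements overlap")
    }
  }
  if (any(plants$pos < 1L | plants$pos + width - 1L > lengths[plants$chrom])) {
    gc_input_error("planted placement outside the genome plan")
  }

  # the words whose mismatch neighbourhoods the background must avoid:
  # each distinct planted core (without its protected PAM tail is still
  # part of the word; we check the full word)
  base_words <- unique(plants$seq)

  for (try in seq_len(max_tries)) {
    g <- synth_genome(lengths, gc = gc, seed = seed + (try - 1L) * 1000L,
                      assembly = assembly)
    planted <- with_own_rng(seed + try, {
      map_chr(seq_len(nrow(plants)), function(i) {
        mutate_word(plants$seq[i], plants$mm[i], protect_tail)
      })
    })
    seqs <- g$seq
    for (i in seq_len(nrow(plants))) {
      ins <- if (plants$strand[i] == "-") revcomp(planted[i]) else planted[i]
      str_sub(seqs[[plants$chrom[i]]], plants$pos[i],
              plants$pos[i] + width[i] - 1L) <- ins
    }
    g2 <- genome(seqs, assembly = assembly)
    # verify: every mismatch-neighbourhood match of every planted core
    # (the word minus its protected tail, i.e. the spacer without its
    # PAM) must be one of the planted loci. On the minus strand the core
    # starts protect_tail bases into the planted word.
    ok <- TRUE
    for (wd in base_words) {
      core <- if (protect_tail > 0L) {
        str_sub(wd, 1L, nchar(wd) - protect_tail)
      } else {
        wd
      }
      found <- brute_force_matches(core, g2, max_mm = max_mm)$matches
      expected <- plants %>%
        filter(.data$seq == wd) %>%
        mutate(core_start = as.integer(
          ifelse(.data$strand == "-", .data$pos + protect_tail, .data$pos)
        ))
      extra <- found %>%
        anti_join(expected,
                  by = c("chrom" = "chrom", "start" = "core_start",
                         "strand" = "strand"))
      if (nrow(extra) > 0) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      attr(g2, "planted") <- mutate(plants, planted_seq = planted)
      return(g2)
    }
  }
  gc_internal_error(sprintf(
    "could not generate a background free of spurious matches in %d tries (constraints may be unsatisfiable)",
    max_tries
  ))
}

#' Brute-force k-mismatch match oracle
#'
#' Literal scan of every window on both strands computing Hamming
#' distance, with no indexing or heuristics. This is the single source of
#' truth that the exact and seeded engines are property-tested against;
#' it deliberately shares no code with them (vectorised byte comparison
#' in R, versus compiled scanning). Genome bases outside A/C/G/T never
#' match. Optionally restricts to PAM-flanked windows.
#'
#' @param spacer A single spacer sequence (A/C/G/T).
#' @param genome A [genome].
#' @param max_mm Maximum Hamming distance. Default 3.
#' @param pam If non-`NULL`, count only windows followed (in match
#'   orientation) by this IUPAC pattern.
#' @return List with `counts` (named integer `G0..Gk`) and `matches`
#'   (tibble `chrom`, `start`, `end`, `strand`, `mm`).
#' @examples
#' g <- genome(c(chr1 = "ACGTACGTAC"))
#' brute_force_matches("ACGT", g, max_mm = 1)$counts
#' @export
brute_force_matches <- function(spacer, genome, max_mm = 3L, pam = NULL) {
  stopifnot(inherits(genome, "genome"), length(spacer) == 1)
  spacer <- str_to_upper(spacer)
  if (str_detect(spacer, "[^ACGT]")) {
    gc_input_error("oracle spacer must be A/C/G/T only")
  }
  W <- nchar(spacer)
  pat <- list("+" = spacer, "-" = revcomp(spacer))
  res <- list()
  for (chrom in names(genome$seq)) {
    sq <- genome$seq[[chrom]]
    L <- nchar(sq)
    if (L < W) next
    bytes <- utf8ToInt(sq)
    valid <- bytes %in% utf8ToInt("ACGT")
    n_win <- L - W + 1L
    for (strand in c("+", "-")) {
      pb <- utf8ToInt(pat[[strand]])
      mism <- integer(n_win)
      for (j in seq_len(W)) {
        idx <- j:(n_win + j - 1L)
        mism <- mism + as.integer(bytes[idx] != pb[j] | !valid[idx])
      }
      hit <- which(mism <= max_mm)
      if (!is.null(pam) && length(hit) > 0) {
        hit <- hit[vapply(hit, function(i) {
          oracle_pam_ok(sq, i, W, strand, pam)
        }, logical(1))]
      }
      if (length(hit) > 0) {
        res[[paste(chrom, strand)]] <- tibble(
          chrom = chrom, start = as.integer(hit),
          end = as.integer(hit + W - 1L), strand = strand,
          mm = mism[hit]
        )
      }
    }
  }
  matches <- bind_rows(res)
  if (nrow(matches) == 0) {
    matches <- tibble(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0), mm = integer(0))
  }
  matches <- arrange(matches, .data$chrom, .data$start, .data$strand)
  counts <- vapply(0:max_mm, function(m) sum(matches$mm == m), integer(1))
  list(counts = setNames(counts, paste0("G", 0:max_mm)), matches = matches)
}

# PAM check for the oracle: plus-strand match needs the pattern right
# after the window; minus-strand match needs its reverse complement right
# before it (both fully in bounds)
oracle_pam_ok <- function(seq, start, W, strand, pam) {
  pl <- nchar(pam)
  if (strand == "+") {
    piece <- str_sub(seq, start + W, start + W + pl - 1L)
    if (nchar(piece) < pl) return(FALSE)
    iupac_char_match(piece, pam)
  } else {
    if (start - pl < 1L) return(FALSE)
    piece <- str_sub(seq, start - pl, start - 1L)
    iupac_char_match(revcomp(piece), pam)
  }
}

iupac_char_match <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  all(vapply(seq_along(pc), function(i) {
    sc[i] %in% IUPAC_SETS[[pc[i]]]  # genome base must be unambiguous
  }, logical(1)))
}
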