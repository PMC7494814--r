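#' Build 30-nt scoring contexts for spacers
#'
#' On-target efficiency models of the Rule Set 1 family score a 30-mer
#' read 5'->3' on the spacer strand: 4 nt upstream, the 20-nt
#' protospacer, the 3-nt PAM (context positions 25--27) and 3 nt
#' downstream. Minus-strand windows are reverse-complemented so the
#' protospacer always reads 5'->3'. Spacers whose window would cross a
#' chromosome end are flagged unscorable (`scorable = FALSE`,
#' `context30 = NA`), never dropped.
#'
#' @param spacers Spacer hit tibble (see [find_spacers()]).
#' @param genome A [genome].
#' @return `spacers` with `context30` and `scorable` columns appended.
#' @export
build_context <- function(spacers, genome) {
  stopifnot(inherits(genome, "genome"))
  if (nrow(spacers) == 0) {
    return(mutate(spacers, context30 = character(0), scorable = logical(0)))
  }
  lens <- seq_lengths(genome)
  plus <- spacers$strand != "-"
  w_start <- ifelse(plus, spacers$start - 4L, spacers$start - 6L)
  w_end <- ifelse(plus, spacers$end + 6L, spacers$end + 4L)
  ok <- w_start >= 1L & w_end <= lens[spacers$chrom]
  ctx <- rep(NA_character_, nrow(spacers))
  if (any(ok)) {
    win <- tibble(chrom = spacers$chrom[ok],
                  start = as.integer(w_start[ok]),
                  end = as.integer(w_end[ok]),
                  strand = ifelse(plus[ok], "+", "-"))
    ctx[ok] <- fetch_seq(genome, win)
  }
  # windows containing ambiguous bases are unscorable too
  amb <- !is.na(ctx) & str_detect(ctx, "[^ACGT]")
  ctx[amb] <- NA_character_
  mutate(spacers, context30 = ctx, scorable = !is.na(ctx))
}

ruleset1_env <- new.env(parent = emptyenv())

#' Rule Set 1 style coefficient table
#'
#' Loads the coefficient table used by [score_rule_set_1()]: an
#' intercept, sparse position-specific single-nucleotide and dinucleotide
#' weights over the 30-nt context, and GC-count terms (separate weights
#' for protospacers with fewer/more than 10 GC bases). The shipped table
#' (`inst/extdata/ruleset1_synthetic_coefficients.tsv`, MD5
#' `7f45a5ac747bf78fefdc52eb7fe465a0`) is a synthetic stand-in generated
#' once from a fixed seed: it has the authentic feature structure of the
#' published logistic Rule Set 1 model but not its published weights, so
#' scores rank consistently and deterministically without reproducing
#' the original model's numbers.
#'
#' @param path Optional path to an alternative coefficient TSV (columns
#'   `feature`, `pos`, `token`, `weight`).
#' @return Tibble of coefficients.
#' @export
ruleset1_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(ruleset1_env$coef)) return(ruleset1_env$coef)
    path <- system.file("extdata", "ruleset1_synthetic_coefficients.tsv",
                        package = "guidecraft", mustWork = TRUE)
  }
  coef <- readr::read_tsv(path, col_types = readr::cols(
    feature = readr::col_character(), pos = readr::col_integer(),
    token = readr::col_character(), weight = readr::col_double()
  ), progress = FALSE)
  stopifnot(all(c("feature", "pos", "token", "weight") %in% names(coef)))
  ruleset1_env$coef <- coef
  coef
}

#' Score 30-nt contexts with the internal Rule Set 1 style model
#'
#' Computes `plogis(intercept + sum of matching position-specific
#' single-nucleotide weights + sum of matching dinucleotide weights +
#' GC-count terms)` for each context. The GC terms act on the
#' protospacer (context positions 5--24): `gc_low * (10 - gc)` below 10
#' GC bases, `gc_high * (gc - 10)` above. Scores are deterministic and
#' strictly inside (0, 1). See [ruleset1_coefficients()] for the
#' (synthetic) weight table.
#'
#' @param contexts Character vector of 30-mers (`NA` allowed, scored
#'   `NA`).
#' @param coefficients Coefficient tibble; defaults to the shipped table.
#' @return Numeric vector of scores in (0, 1).
#' @examples
#' score_rule_set_1(strrep("ACGTA", 6))
#' @export
score_rule_set_1 <- function(contexts, coefficients = ruleset1_coefficients()) {
  ok <- !is.na(contexts)
  if (any(nchar(contexts[ok]) != 30)) {
    gc_input_error("scoring contexts must be exactly 30 nt")
  }
  if (any(str_detect(contexts[ok], "[^ACGT]"))) {
    gc_input_error("scoring contexts must contain only A/C/G/T")
  }
  out <- rep(NA_real_, length(contexts))
  if (!any(ok)) return(out)
  ctx <- contexts[ok]
  eta <- rep(coefficients$weight[coefficients$feature == "intercept"],
             length(ctx))
  nt <- coefficients[coefficients$feature == "nt", ]
  for (i in seq_len(nrow(nt))) {
    hit <- str_sub(ctx, nt$pos[i], nt$pos[i]) == nt$token[i]
    eta <- eta + nt$weight[i] * hit
  }
  di <- coefficients[coefficients$feature == "dinucleotide", ]
  for (i in seq_len(nrow(di))) {
    hit <- str_sub(ctx, di$pos[i], di$pos[i] + 1L) == di$token[i]
    eta <- eta + di$weight[i] * hit
  }
  gc <- str_length(str_sub(ctx, 5, 24)) -
    str_length(gsub("[GC]", "", str_sub(ctx, 5, 24)))
  w_lo <- coefficients$weight[coefficients$feature == "gc_low"]
  w_hi <- coefficients$weight[coefficients$feature == "gc_high"]
  eta <- eta + ifelse(gc < 10, w_lo * (10 - gc), 0) +
    ifelse(gc > 10, w_hi * (gc - 10), 0)
  out[ok] <- stats::plogis(eta)
  out
}

#' Score contexts with an external adapter command
#'
#' Generic hook for externally trained scorers (e.g. the gradient-boosted
#' 2016 model): the adapter is a shell command reading one 30-mer per
#' line on stdin and writing one numeric score per line on stdout. An
#' absent or failing adapter never aborts a design run: scores come back
#' `NA` with a warning.
#'
#' @param contexts Character vector of 30-mers.
#' @param adapter_cmd Shell command, or `NULL` (all scores `NA`,
#'   silently).
#' @return Numeric vector of scores (`NA` where unscored).
#' @export
score_external <- function(contexts, adapter_cmd = NULL) {
  out <- rep(NA_real_, length(contexts))
  if (is.null(adapter_cmd) || length(contexts) == 0) return(out)
  ok <- !is.na(contexts)
  if (!any(ok)) return(out)
  res <- tryCatch(
    system(adapter_cmd, input = contexts[ok], intern = TRUE),
    error = function(e) e, warning = function(w) w
  )
  if (inherits(res, "condition")) {
    warn(paste0("external scorer failed: ", conditionMessage(res)))
    return(out)
  }
  vals <- suppressWarnings(as.numeric(res))
  if (length(vals) != sum(ok) || anyNA(vals)) {
    warn("external scorer returned malformed output; scores set to NA")
    return(out)
  }
  out[ok] <- vals
  out
}

#' Attach on-target scores to a spacer table
#'
#' Scoring only annotates, never changes the spacer set.
#'
#' @param spacers Spacer hit tibble.
#' @param genome A [genome].
#' @param scorer `"ruleset1"`, `"external"`, or `"none"`.
#' @param adapter_cmd Command for `scorer = "external"` (see
#'   [score_external()]).
#' @return `spacers` with `context30`, `scorable` and `score` columns.
#' @export
score_spacers <- function(spacers, genome,
                          scorer = c("ruleset1", "external", "none"),
                          adapter_cmd = NULL) {
  scorer <- match.arg(scorer)
  out <- build_context(spacers, genome)
  out$score <- switch(scorer,
    ruleset1 = score_rule_set_1(out$context30),
    external = score_external(out$context30, adapter_cmd),
    none = rep(NA_real_, nrow(out))
  )
  out
}
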