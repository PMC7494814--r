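#' Run the parallel-targeting workflow
#'
#' The five-step guide-design workflow for range targets: define ->
#' transform (genome-arithmetic preset) -> find spacers -> count
#' off-targets with target-set-specific filtering -> score. Cross-target
#' matches count as on-target under the `parallel` policy, which is what
#' makes small guide sets possible when thousands of near-identical
#' sites (e.g. transcription-factor binding sites) are targeted at once.
#'
#' @param genome A [genome].
#' @param targets Interval tibble of target ranges.
#' @param preset Genome-arithmetic preset applied before the search
#'   (see [transform_targets()]). Default `"block"` (`[-22, +22]`).
#' @param pam IUPAC PAM pattern. Default `"NGG"`.
#' @param spacer_len Spacer length. Default 20.
#' @param max_mm Mismatch budget for counting/filtering. Default 2.
#' @param engine Off-target engine, `"seeded"` or `"exact"`.
#' @param pam_mode Off-target counting mode. Default `"agnostic"`.
#' @param policy Retention policy for [filter_spacers()]. Default
#'   `"parallel"`.
#' @param scorer On-target scorer (see [score_spacers()]). Default
#'   `"ruleset1"`.
#' @param adapter_cmd External scorer command when
#'   `scorer = "external"`.
#' @param min_score Optional score threshold applied to retained
#'   spacers (unscorable spacers are kept).
#' @param ... Extra arguments passed to [transform_targets()] (e.g.
#'   `excise_end`, `start_offset`/`end_offset` for `preset = "extend"`).
#' @return A `guide_design` object: use [tidy()][generics::tidy] for the
#'   per-spacer table, [glance()][generics::glance] for the one-row run
#'   summary, `autoplot()` for a quick look, and [write_design()] to
#'   serialize.
#' @examples
#' g <- synth_genome(c(chr1 = 3000), seed = 4)
#' t <- genomic_intervals("chr1", c(200, 900), c(219, 919), "+")
#' d <- run_parallel_targeting(g, t, engine = "exact", scorer = "none")
#' glance(d)
#' @export
run_parallel_targeting <- function(genome, targets, preset = "block",
                                   pam = "NGG", spacer_len = 20L,
                                   max_mm = 2L,
                                   engine = c("seeded", "exact"),
                                   pam_mode = c("agnostic", "required"),
                                   policy = "parallel",
                                   scorer = "ruleset1",
                                   adapter_cmd = NULL,
                                   min_score = NULL, ...) {
  engine <- match.arg(engine)
  pam_mode <- match.arg(pam_mode)
  targets <- validate_intervals(targets, genome)
  transformed <- transform_targets(targets, preset, genome = genome, ...)
  spacers <- find_spacers(transformed, genome, pam = pam,
                          spacer_len = spacer_len)
  if (nrow(spacers) > 0) {
    spacers <- count_offtargets(spacers, genome, targets = transformed,
                                max_mm = max_mm, engine = engine,
                                pam_mode = pam_mode, pam = pam)
    spacers <- score_spacers(spacers, genome, scorer = scorer,
                             adapter_cmd = adapter_cmd)
    retained <- filter_spacers(spacers, policy)
    if (!is.null(min_score)) {
      retained <- filter(retained,
                         !.data$scorable | .data$score >= min_score)
    }
  } else {
    retained <- spacers
  }
  row_key <- function(d) paste(d$name, d$target_name, d$target_start, d$target_end)
  spacers$retained <- row_key(spacers) %in% row_key(retained)
  new_guide_design(
    type = "parallel", spacers = spacers, targets = targets,
    transformed = transformed, genome = genome,
    params = list(preset = preset, pam = pam, spacer_len = spacer_len,
                  max_mm = max_mm, engine = engine, pam_mode = pam_mode,
                  policy = policy, scorer = scorer, min_score = min_score)
  )
}

#' Run the prime-editing workflow
#'
#' Delegates to [design_prime_editing()] and wraps the result as a
#' `guide_design` (editing spacers kept only if genome-unique, nicking
#' spacers annotated with mismatch-aware off-target counts and nick
#' distances; both scored).
#'
#' @inheritParams run_parallel_targeting
#' @param edit An [edit_spec()].
#' @param params A [prime_params()].
#' @return A `guide_design` object.
#' @export
run_prime_editing <- function(genome, edit, params = prime_params(),
                              pam = "NGG", max_mm = 2L,
                              engine = c("seeded", "exact"),
                              scorer = "ruleset1", adapter_cmd = NULL) {
  engine <- match.arg(engine)
  designs <- design_prime_editing(edit, genome, params = params, pam = pam,
                                  max_mm = max_mm, engine = engine)
  if (nrow(designs) > 0) {
    designs <- score_spacers(designs, genome, scorer = scorer,
                             adapter_cmd = adapter_cmd)
    designs$retained <- TRUE
  }
  new_guide_design(
    type = "prime", spacers = designs,
    targets = tibble(chrom = edit$chrom, start = edit$position,
                     end = edit$position + nchar(edit$ref) - 1L,
                     strand = "+",
                     name = sprintf("%s:%d%s>%s", edit$chrom, edit$position,
                                    edit$ref,
                                    ifelse(edit$alt == "", "-", edit$alt))),
    transformed = NULL, genome = genome,
    params = list(edit = edit, nrt = params$nrt, pbs_len = params$pbs_len,
                  nick_window = params$nick_window, pam = pam,
                  max_mm = max_mm, engine = engine, scorer = scorer)
  )
}

new_guide_design <- function(type, spacers, targets, transformed, genome,
                             params) {
  structure(
    list(
      type = type, spacers = as_tibble(spacers), targets = targets,
      transformed = transformed, params = params,
      log = design_log(type, spacers, targets, transformed, genome, params)
    ),
    class = "guide_design"
  )
}

design_log <- function(type, spacers, targets, transformed, genome, params) {
  serializable <- params
  if (!is.null(serializable$edit)) {
    serializable$edit <- unclass(serializable$edit)
  }
  list(
    tool = "guidecraft",
    version = as.character(utils::packageVersion("guidecraft")),
    type = type,
    assembly = genome$assembly,
    genome_checksum = rlang::hash(genome$seq),
    config_hash = rlang::hash(serializable),
    params = serializable,
    n_targets = if (is.null(targets)) 0L else nrow(targets),
    n_transformed = if (is.null(transformed)) NA_integer_ else nrow(transformed),
    n_spacers = nrow(spacers),
    n_retained = if ("retained" %in% names(spacers)) sum(spacers$retained) else nrow(spacers)
  )
}

#' @export
print.guide_design <- function(x, ...) {
  cat(sprintf("<guide_design:%s> %d target(s), %d spacer row(s), %d retained\n",
              x$type, x$log$n_targets, x$log$n_spacers, x$log$n_retained))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-spacer table of a guide design
#'
#' @param x A `guide_design`.
#' @param retained_only Drop rows failing the retention policy? Default
#'   `FALSE`.
#' @param ... Unused.
#' @return The spacer tibble (one row per spacer x target attribution).
#' @export
tidy.guide_design <- function(x, retained_only = FALSE, ...) {
  out <- x$spacers
  if (retained_only && "retained" %in% names(out)) {
    out <- filter(out, .data$retained)
  }
  out
}

#' One-row summary of a guide design
#'
#' @param x A `guide_design`.
#' @param ... Unused.
#' @return A one-row tibble with run-level counts and provenance hashes.
#' @export
glance.guide_design <- function(x, ...) {
  tibble(
    type = x$type,
    n_targets = x$log$n_targets,
    n_transformed = x$log$n_transformed,
    n_spacers = x$log$n_spacers,
    n_retained = x$log$n_retained,
    assembly = x$log$assembly,
    genome_checksum = x$log$genome_checksum,
    config_hash = x$log$config_hash
  )
}

#' Plot a guide design
#'
#' Draws targets and spacers as stacked segments per chromosome;
#' retained spacers are opaque, rejected ones faded. A quick visual
#' check, not a publication figure.
#'
#' @param object A `guide_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.guide_design <- function(object, ...) {
  sp <- object$spacers
  tg <- object$targets
  layers <- list(
    ggplot2::geom_segment(
      data = tg,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0, yend = 0),
      linewidth = 3, colour = "grey30"
    )
  )
  if (nrow(sp) > 0) {
    sp <- sp %>%
      group_by(.data$chrom) %>%
      mutate(.lane = dplyr::row_number()) %>%
      ungroup()
    if (!("retained" %in% names(sp))) sp$retained <- TRUE
    layers <- c(layers, list(
      ggplot2::geom_segment(
        data = sp,
        ggplot2::aes(x = .data$start, xend = .data$end, y = .data$.lane,
                     yend = .data$.lane, colour = .data$strand,
                     alpha = .data$retained),
        linewidth = 1.5
      ),
      ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                  guide = "none")
    ))
  }
  ggplot2::ggplot() +
    layers +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = sprintf("guide design (%s)", object$type)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Serialize a guide design
#'
#' Writes the spacer table as TSV (the canonical machine-readable
#' product) and a JSON run log recording the tool version, parameter
#' set, config hash, genome checksum and per-stage counts. Re-running
#' with identical config and inputs yields byte-identical TSV output.
#'
#' @param x A `guide_design`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.log.json`.
#' @return Invisibly, the paths written.
#' @export
write_design <- function(x, prefix) {
  stopifnot(inherits(x, "guide_design"))
  tsv <- paste0(prefix, ".tsv")
  logf <- paste0(prefix, ".log.json")
  tab <- tidy(x)
  if ("context30" %in% names(tab)) tab$context30 <- NULL
  write_results(tab, tsv)
  jsonlite::write_json(x$log, logf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(tsv = tsv, log = logf))
}
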