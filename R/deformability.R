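#' Tetramer-context deformability tables
#'
#' A tetramer table maps each of the 256 DNA 4-mers to a base-pair-step
#' deformability value `V_step` (units deg^3 A^3): the central step of the
#' tetramer, read with one flanking base pair on each side. Published tables
#' often list only the 136 reverse-complement-unique tetramers; the loader
#' can close such a table under reverse complementation. Reverse-complement
#' pairs must agree exactly when both are present - conflicting duplicates
#' are an error, never silently averaged.
#'
#' @param x A data frame with columns `tetramer` and `value`.
#' @param symmetrize Add reverse-complement entries (default `TRUE`).
#' @param strict Require full 256/256 coverage (default `TRUE`).
#' @return A `tetramer_table`: a tibble with columns `tetramer`, `value` and
#'   attribute `coverage` (entries out of 256).
#' @export
tetramer_table <- function(x, symmetrize = TRUE, strict = TRUE) {
  if (!all(c("tetramer", "value") %in% names(x))) {
    abort("need columns `tetramer` and `value`")
  }
  tb <- tibble(tetramer = toupper(as.character(x$tetramer)),
               value = as.numeric(x$value))
  if (any(is.na(tb$value)) || any(tb$value <= 0)) {
    abort("all deformability values must be positive numbers")
  }
  if (any(!stringr::str_detect(tb$tetramer, "^[ACGT]{4}$"))) {
    abort("tetramers must be 4-mers over A/C/G/T")
  }
  if (symmetrize) {
    rc <- tibble(tetramer = vapply(tb$tetramer, reverse_complement, ""),
                 value = tb$value)
    tb <- bind_rows(tb, rc)
  }
  tb <- dplyr::distinct(tb)
  dup <- tb$tetramer[duplicated(tb$tetramer)]
  if (length(dup)) {
    abort(sprintf(
      "conflicting values for tetramer(s) %s after %s",
      paste(unique(dup), collapse = ", "),
      if (symmetrize) "reverse-complement symmetrization" else "deduplication"
    ))
  }
  coverage <- nrow(tb)
  if (strict && coverage < 256L) {
    missing <- setdiff(all_tetramers(), tb$tetramer)
    abort(sprintf("incomplete table: %d/256 tetramers (missing e.g. %s)",
                  coverage, paste(utils::head(missing, 3), collapse = ", ")))
  }
  tb <- arrange(tb, .data$tetramer)
  attr(tb, "coverage") <- coverage
  class(tb) <- c("tetramer_table", class(tb))
  tb
}

all_tetramers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, stringsAsFactors = FALSE)[, 4:1]
  apply(g, 1, paste, collapse = "")
}

#' @rdname tetramer_table
#' @param path TSV/CSV file with columns `tetramer` and `value`.
#' @export
read_tetramer_table <- function(path, symmetrize = TRUE, strict = TRUE) {
  df <- readr::read_delim(path, show_col_types = FALSE, comment = "#")
  tetramer_table(df, symmetrize = symmetrize, strict = strict)
}

#' Per-step deformability values on a (circular) sequence
#'
#' Step `i` sits between base pairs `i` and `i + 1` (modulo the length `L`
#' on circular sequences). Its value is looked up from the tetramer context
#' at positions `i - 1 .. i + 2`, i.e. the step flanked by one base pair on
#' each side, the first flank being 5' on the reference strand. A circular
#' sequence yields exactly `L` step values; a linear one yields `L - 1`, the
#' two terminal steps lacking a flank and therefore `NA`.
#'
#' @param seq A [circular_sequence()] or nucleotide string (length >= 4).
#' @param table A [tetramer_table()] with full coverage.
#' @return A `step_series`: tibble with columns `step`, `tetramer`, `value`
#'   and attributes `L`, `circular`.
#' @export
step_values <- function(seq, table) {
  x <- as_circular_sequence(seq)
  L <- seq_length(x)
  if (L < 4L) abort("sequence must be at least 4 bp")
  if (!inherits(table, "tetramer_table")) table <- tetramer_table(table)
  if (attr(table, "coverage") < 256L) abort("tetramer table is incomplete")
  lut <- stats::setNames(table$value, table$tetramer)
  chars <- strsplit(x$residues, "", fixed = TRUE)[[1]]
  steps <- if (x$circular) seq_len(L) else seq_len(L - 1L)
  tet <- vapply(steps, function(i) {
    idx <- i + (-1L:2L)
    if (!x$circular && (min(idx) < 1L || max(idx) > L)) return(NA_character_)
    paste(chars[circ_pos(idx, L)], collapse = "")
  }, "")
  out <- tibble(step = steps, tetramer = tet,
                value = unname(lut[tet]))
  attr(out, "L") <- L
  attr(out, "circular") <- x$circular
  class(out) <- c("step_series", class(out))
  out
}

#' Sliding k-mer deformability profile
#'
#' Averages the `k - 1` base-pair-step values internal to a `k`-bp window
#' slid one base at a time around the sequence with periodic boundary
#' conditions. The score at centre `c` covers base pairs
#' `c - ceiling(k/2) + 1 .. c + floor(k/2)`: for odd `k` the window is
#' symmetric about `c` (e.g. `k = 35` spans `c` +/- 17 bp); even `k` places
#' `ceiling(k/2)` of its positions at or before the centre, which makes the
#' `k = 2` profile coincide with the step series itself. The profile mean
#' equals the step-series mean exactly on a circle, since every step lies in
#' exactly `k - 1` windows.
#'
#' @param series A [step_values()] result (circular).
#' @param k Window length in bp, `2 <= k <= L`.
#' @return A `kmer_profile`: tibble with columns `position`, `score` and
#'   attributes `k`, `baseline` (mean of all step values).
#' @export
kmer_profile <- function(series, k) {
  if (!inherits(series, "step_series")) abort("`series` must come from step_values()")
  L <- attr(series, "L")
  if (!isTRUE(attr(series, "circular"))) {
    abort("profiles are defined for circular step series")
  }
  if (k < 2L || k > L) abort(sprintf("`k` must be in 2..%d", L))
  v <- series$value
  vdbl <- c(v, v)
  csum <- c(0, cumsum(vdbl))
  first_step <- function(c0) circ_pos(c0 - ceiling(k / 2) + 1L, L)
  starts <- first_step(seq_len(L))
  score <- (csum[starts + k - 1L] - csum[starts]) / (k - 1)
  out <- tibble(position = seq_len(L), score = score)
  attr(out, "k") <- as.integer(k)
  attr(out, "baseline") <- mean(v)
  class(out) <- c("kmer_profile", class(out))
  out
}

#' Percentile rank of a window score within its profile
#'
#' Reports where the window centred at `center` sits among all window scores
#' of the profile: the fraction of scores strictly greater (its "top X %"
#' statement), the fraction strictly smaller ("bottom X %"), the rank from
#' the top with ties counted once, and the number of tied scores.
#'
#' @param profile A [kmer_profile()].
#' @param center Centre position to rank.
#' @return One-row tibble: `center`, `score`, `frac_above`, `frac_below`,
#'   `rank`, `n_tied`.
#' @export
rank_region <- function(profile, center) {
  if (!inherits(profile, "kmer_profile")) abort("`profile` must come from kmer_profile()")
  if (!center %in% profile$position) abort("`center` is not a profile position")
  sc <- profile$score[profile$position == center]
  tibble(
    center = as.integer(center),
    score = sc,
    frac_above = mean(profile$score > sc),
    frac_below = mean(profile$score < sc),
    rank = 1L + sum(profile$score > sc),
    n_tied = sum(profile$score == sc)
  )
}

#' Export a deformability profile to CSV
#'
#' Writes `(position, score, score_minus_baseline)` rows at full precision,
#' so a re-import reproduces the scores bit-for-bit.
#'
#' @param profile A [kmer_profile()].
#' @param path Output CSV path.
#' @param plot Optional path for a profile figure (PNG/PDF by extension).
#' @return `path`, invisibly.
#' @export
export_profile <- function(profile, path, plot = NULL) {
  if (!inherits(profile, "kmer_profile")) abort("`profile` must come from kmer_profile()")
  out <- tibble(
    position = profile$position,
    score = profile$score,
    score_minus_baseline = profile$score - attr(profile, "baseline")
  )
  readr::write_csv(out, path)
  if (!is.null(plot)) {
    ggplot2::ggsave(plot, autoplot(profile), width = 7, height = 4)
  }
  invisible(path)
}

#' Plot a deformability profile
#'
#' Line plot of the window score against position with the whole-sequence
#' baseline drawn dashed; `coord = "polar"` renders the circular-genome view
#' in which the profile is a closed ring.
#'
#' @param object A [kmer_profile()].
#' @param coord `"linear"` (default) or `"polar"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.kmer_profile <- function(object, coord = c("linear", "polar"), ...) {
  coord <- match.arg(coord)
  baseline <- attr(object, "baseline")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = baseline, linetype = "dashed") +
    ggplot2::labs(
      x = "position (bp)",
      y = expression(paste("window deformability (", deg^3, ring(A)^3, ")")),
      title = sprintf("%d-mer deformability profile", attr(object, "k")),
      subtitle = sprintf("baseline (mean of all steps) = %.3g", baseline)
    ) +
    ggplot2::theme_minimal()
  if (coord == "polar") p <- p + ggplot2::coord_polar()
  p
}
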