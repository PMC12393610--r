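#' Position weight matrices with declared motif regions
#'
#' A PWM here is a `4 x W` numeric matrix (rows `A`, `C`, `G`, `T`)
#' carrying optional region lengths splitting the motif into a first
#' periodic region, a core, and a second periodic region. The 130-column
#' gyrase cleavage motif uses regions of 47, 36 and 47 bp. Scores are plain
#' additive lookups of the supplied weights (no background correction or
#' log transform is applied: published motif weights already define sign,
#' positive meaning the sequence fits the motif; pre-transform the matrix
#' if another scale is wanted).
#'
#' @param weights `4 x W` numeric matrix, rows in order `A`, `C`, `G`, `T`
#'   (row names, if present, may come in any order and are honoured).
#' @param region_lengths Integer triple `(first_periodic, core,
#'   second_periodic)` summing to `W`, or `NULL` for undeclared regions.
#'   A 130-column matrix defaults to `c(47, 36, 47)`.
#' @return A `pwm` object.
#' @export
pwm <- function(weights, region_lengths = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != 4L) abort("a PWM needs exactly 4 rows (A, C, G, T)")
  if (!is.numeric(weights) || any(!is.finite(weights))) {
    abort("PWM weights must be finite numbers")
  }
  rn <- rownames(weights)
  if (!is.null(rn)) {
    if (!setequal(toupper(rn), c("A", "C", "G", "T"))) {
      abort("PWM row labels must be A, C, G, T")
    }
    weights <- weights[match(c("A", "C", "G", "T"), toupper(rn)), , drop = FALSE]
  }
  dimnames(weights) <- list(c("A", "C", "G", "T"), NULL)
  W <- ncol(weights)
  if (is.null(region_lengths) && W == 130L) region_lengths <- c(47L, 36L, 47L)
  if (!is.null(region_lengths)) {
    region_lengths <- as.integer(region_lengths)
    if (length(region_lengths) != 3L || any(region_lengths < 0L) ||
        sum(region_lengths) != W) {
      abort(sprintf("region lengths must be three non-negative integers summing to %d", W))
    }
  }
  structure(list(weights = weights, region_lengths = region_lengths),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  W <- ncol(x$weights)
  cat(sprintf("<pwm> 4 x %d", W))
  if (!is.null(x$region_lengths)) {
    cat(sprintf(" (regions %s)", paste(x$region_lengths, collapse = "/")))
  }
  cat("\n")
  invisible(x)
}

#' Read a PWM from TSV
#'
#' Expects 4 rows labelled `A`/`C`/`G`/`T` in the first column and `W`
#' numeric weight columns.
#'
#' @param path TSV file.
#' @param region_lengths Passed to [pwm()].
#' @return A `pwm`.
#' @export
read_pwm <- function(path, region_lengths = NULL) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (nrow(df) != 4L) {
    abort(sprintf("PWM file must have exactly 4 rows, found %d", nrow(df)))
  }
  labels <- toupper(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) abort("PWM body must be numeric with no gaps")
  rownames(m) <- labels
  pwm(m, region_lengths = region_lengths)
}

pwm_center_col <- function(W) as.integer(ceiling(W / 2)) # even widths round 5'

#' Score one motif window on a circular sequence
#'
#' Aligns the PWM's centre column (even widths round toward 5') with
#' `position` on the reference and sums the weight of the observed base in
#' each column. On the reverse strand the reverse complement of the same
#' window is scored.
#'
#' @param seq A [circular_sequence()] or string.
#' @param x A [pwm()].
#' @param position 1-based centre position on the forward strand.
#' @param strand `"forward"` or `"reverse"`.
#' @return One-row tibble: `position`, `strand`, `score`.
#' @export
motif_score_at <- function(seq, x, position, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  seq <- as_circular_sequence(seq)
  stopifnot(inherits(x, "pwm"))
  W <- ncol(x$weights)
  L <- seq_length(seq)
  cc <- pwm_center_col(W)
  start <- position - (cc - 1L)
  if (!seq$circular && (start < 1L || start + W - 1L > L)) {
    abort("motif window does not fit the linear reference")
  }
  window <- circ_substr(seq, start, W)
  if (strand == "reverse") window <- reverse_complement(window)
  obs <- strsplit(window, "", fixed = TRUE)[[1]]
  score <- sum(x$weights[cbind(match(obs, c("A", "C", "G", "T")), seq_len(W))])
  tibble(position = as.integer(position), strand = strand, score = score)
}

#' Score every window of a circular sequence against a PWM
#'
#' @param seq A [circular_sequence()] or string.
#' @param x A [pwm()].
#' @param strands Strands to score (default both).
#' @return Tibble of `position`, `strand`, `score`, class `motif_scan`.
#' @export
motif_scan <- function(seq, x, strands = c("forward", "reverse")) {
  seq <- as_circular_sequence(seq)
  L <- seq_length(seq)
  out <- purrr::map_dfr(strands, function(st) {
    purrr::map_dfr(seq_len(L), function(p) motif_score_at(seq, x, p, st))
  })
  class(out) <- c("motif_scan", class(out))
  out
}

#' Split a motif PWM into its region sub-matrices
#'
#' Returns the three sub-matrices used to compare a sequence against parts
#' of the motif: first periodic region + core, core only, and core + second
#' periodic region. Columns are copied verbatim.
#'
#' @param x A [pwm()] with declared region lengths.
#' @return Named list of three `pwm` objects: `first_core`, `core`,
#'   `core_second`.
#' @export
split_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  rl <- x$region_lengths
  if (is.null(rl)) abort("PWM has no declared region lengths")
  W <- ncol(x$weights)
  i_first <- seq_len(rl[1])
  i_core <- rl[1] + seq_len(rl[2])
  i_second <- rl[1] + rl[2] + seq_len(rl[3])
  sub <- function(cols, regions) pwm(x$weights[, cols, drop = FALSE], regions)
  list(
    first_core = sub(c(i_first, i_core), c(rl[1], rl[2], 0L)),
    core = sub(i_core, c(0L, rl[2], 0L)),
    core_second = sub(c(i_core, i_second), c(0L, rl[2], rl[3]))
  )
}

#' Any positive motif score near a stated centre?
#'
#' Tests whether any score is positive within `radius` bp (inclusive,
#' circular distance) of a centre position, and returns the supporting
#' positions.
#'
#' @param scores A [motif_scan()] result (or tibble with `position`,
#'   `score`).
#' @param center Centre position on the reference.
#' @param L Reference length (defaults to the largest position seen).
#' @param radius Window half-width in bp (default 5, both ends inclusive).
#' @return List with `positive` (logical) and `supporting` (tibble of
#'   positive-scoring rows inside the window).
#' @export
positive_near_center <- function(scores, center, L = max(scores$position),
                                 radius = 5L) {
  d <- abs(scores$position - center)
  circ_d <- pmin(d, L - d)
  inside <- scores[circ_d <= radius, , drop = FALSE]
  supporting <- inside[inside$score > 0, , drop = FALSE]
  list(positive = nrow(supporting) > 0L, supporting = as_tibble(supporting))
}
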