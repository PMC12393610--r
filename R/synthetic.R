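#' Seeded random circular sequences, optionally with a planted R/Y pattern
#'
#' Draws a random circular sequence with the requested expected GC fraction
#' and, optionally, overwrites one window with a nucleotide realization of a
#' given R/Y profile: match positions get a random base of the annotated
#' class, exactly `n_mismatch` seeded-random non-`X` positions get a base of
#' the opposite class, and `X` positions get any base (they stay unresolved
#' whatever the sequence says). Identical arguments always reproduce the
#' identical sequence.
#'
#' @param seed Integer seed.
#' @param length Sequence length in bp.
#' @param gc_fraction Expected GC fraction in `[0, 1]` (default 0.5).
#' @param plant Optional list with elements `profile` (string over
#'   `R`/`Y`/`X`), `position` (1-based plant start) and `n_mismatch`
#'   (default 0).
#' @param circular Circularity flag of the result.
#' @return A [circular_sequence()].
#' @examples
#' synth_sequence(1, 60, plant = list(profile = "RRYYRR", position = 10))
#' @export
synth_sequence <- function(seed, length, gc_fraction = 0.5, plant = NULL,
                           circular = TRUE) {
  if (length < 1L) abort("`length` must be >= 1")
  if (gc_fraction < 0 || gc_fraction > 1) abort("`gc_fraction` must be in [0, 1]")
  withr::with_seed(seed, {
    pr <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
            G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    bases <- sample(names(pr), length, replace = TRUE, prob = pr)
    if (!is.null(plant)) {
      p <- strsplit(toupper(plant$profile), "", fixed = TRUE)[[1]]
      if (length(p) > length) abort("planted profile longer than the sequence")
      n_mm <- plant$n_mismatch %||% 0L
      live <- which(p != "X")
      if (n_mm > length(live)) abort("more mismatches requested than non-X positions")
      mm <- if (n_mm > 0L) sample(live, n_mm) else integer(0)
      # GC-conditional draws keep base composition roughly on target
      draw <- function(class) {
        if (class == "R") sample(c("A", "G"), 1, prob = c(1 - gc_fraction, gc_fraction))
        else sample(c("C", "T"), 1, prob = c(gc_fraction, 1 - gc_fraction))
      }
      flip <- c(R = "Y", Y = "R")
      for (j in seq_along(p)) {
        pos <- circ_pos(plant$position + j - 1L, length)
        cls <- p[j]
        if (cls == "X") cls <- sample(c("R", "Y"), 1)
        if (j %in% mm) cls <- flip[[cls]]
        bases[pos] <- draw(cls)
      }
    }
    circular_sequence(paste(bases, collapse = ""), circular = circular,
                      origin_label = sprintf("synthetic seed=%d", seed))
  })
}

#' Seeded synthetic tetramer deformability tables
#'
#' Complete, reverse-complement-symmetric tables with values drawn
#' uniformly on `[low, high]`; reverse-complement pairs share their value
#' exactly. Useful as a stand-in format example where a published
#' deformability table is not available.
#'
#' @param seed Integer seed.
#' @param low,high Positive value bounds, `0 < low <= high`.
#' @return A [tetramer_table()] with 256/256 coverage.
#' @export
synth_tetramer_table <- function(seed, low = 1, high = 8) {
  if (low <= 0 || high < low) abort("require 0 < low <= high")
  withr::with_seed(seed, {
    tets <- all_tetramers()
    canon <- pmin(tets, vapply(tets, reverse_complement, ""))
    uniq <- unique(canon)
    vals <- stats::setNames(stats::runif(length(uniq), low, high), uniq)
    tetramer_table(
      tibble(tetramer = tets, value = unname(vals[canon])),
      symmetrize = FALSE, strict = TRUE
    )
  })
}

#' Seeded synthetic PWMs with a known consensus
#'
#' Each column gets weight `match_weight` on one seeded-random consensus
#' base and `mismatch_weight` on the others, so the consensus sequence
#' attains the global maximum score by construction.
#'
#' @param seed Integer seed.
#' @param width Number of columns.
#' @param region_lengths Optional region triple passed to [pwm()].
#' @param match_weight,mismatch_weight Column weights (default `2` / `-1`).
#' @return A [pwm()] with attribute `consensus` (the consensus string).
#' @export
synth_pwm <- function(seed, width, region_lengths = NULL,
                      match_weight = 2, mismatch_weight = -1) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    consensus <- sample(bases, width, replace = TRUE)
    m <- matrix(mismatch_weight, 4, width, dimnames = list(bases, NULL))
    m[cbind(match(consensus, bases), seq_len(width))] <- match_weight
    out <- pwm(m, region_lengths = region_lengths)
    attr(out, "consensus") <- paste(consensus, collapse = "")
    out
  })
}
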