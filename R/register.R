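#' Convert a nucleotide sequence to a purine/pyrimidine (R/Y) profile
#'
#' Each adenine and guanine becomes `R`, each thymine and cytosine becomes
#' `Y`. This is the sequence-side half of register mapping: a density-derived
#' R/Y profile (which may additionally contain `X` for unresolved bases) is
#' scanned against the R/Y rendering of the reference produced here.
#'
#' @param seq A [circular_sequence()] or plain nucleotide string.
#' @return A single string over `R`/`Y` with attribute `source = "sequence"`,
#'   of class `ry_profile`.
#' @examples
#' to_ry("GAATTC") # "RRRYYY"
#' @export
to_ry <- function(seq) {
  s <- if (inherits(seq, "circular_sequence")) seq$residues else seq
  if (!is.character(s) || length(s) != 1L) abort("`seq` must be a single string.")
  s <- toupper(s)
  bad <- stringr::str_locate(s, "[^ACGT]")[1, "start"]
  if (!is.na(bad)) {
    abort(sprintf("non-canonical symbol '%s' at position %d",
                  substr(s, bad, bad), bad))
  }
  new_ry_profile(chartr("AGCT", "RRYY", s), source = "sequence")
}

new_ry_profile <- function(symbols, source = c("density", "sequence")) {
  source <- match.arg(source)
  structure(symbols, class = "ry_profile", source = source)
}

#' Declare a density-derived R/Y profile
#'
#' Density-derived profiles may contain `X` marking bases whose density was
#' unresolvable (neither clearly purine- nor pyrimidine-shaped).
#'
#' @param symbols String over `R`/`Y`/`X`.
#' @param source `"density"` (default; `X` allowed) or `"sequence"`.
#' @return An `ry_profile`.
#' @export
ry_profile <- function(symbols, source = c("density", "sequence")) {
  source <- match.arg(source)
  if (!is.character(symbols) || length(symbols) != 1L || nchar(symbols) < 1L) {
    abort("`symbols` must be a single nonempty string.")
  }
  symbols <- toupper(symbols)
  allowed <- if (source == "density") "[^RYX]" else "[^RY]"
  bad <- stringr::str_locate(symbols, allowed)[1, "start"]
  if (!is.na(bad)) {
    abort(sprintf("symbol '%s' at position %d not allowed for source='%s'",
                  substr(symbols, bad, bad), bad, source))
  }
  new_ry_profile(symbols, source = source)
}

#' @export
print.ry_profile <- function(x, ...) {
  cat(sprintf("<ry_profile> %d symbols (source: %s)\n%s\n",
              nchar(unclass(x)), attr(x, "source"), unclass(x)))
  invisible(x)
}

#' Base-pairing complement of an R/Y profile
#'
#' Swaps `R` and `Y` position-wise (each base pair holds one purine and one
#' pyrimidine); `X` is a fixed point. Applying the operation twice restores
#' the input.
#'
#' @param profile An `ry_profile` or string over `R`/`Y`/`X`.
#' @return The complemented `ry_profile`.
#' @examples
#' complement_ry("RYYR") # "YRRY"
#' @export
complement_ry <- function(profile) {
  p <- as_ry(profile)
  new_ry_profile(chartr("RY", "YR", unclass(p)), source = attr(p, "source"))
}

as_ry <- function(profile) {
  if (inherits(profile, "ry_profile")) return(profile)
  ry_profile(profile, source = "density")
}

#' Random-match probability for an R/Y profile
#'
#' Probability that a fixed R/Y profile of length `n` matches a uniformly
#' random R/Y string at a given offset when up to `f` free positions
#' (mismatched or unresolved) are tolerated:
#' \deqn{p = 2^{-n} \sum_{i=0}^{f} \binom{n}{i}.}
#' The complementary "1 in N" odds denominator is the reciprocal rounded to
#' the nearest integer.
#'
#' @param n Profile length (>= 1). Vectorised.
#' @param f Tolerated free positions, `0 <= f <= n`. Vectorised.
#' @return A tibble with columns `n`, `f`, `probability`, `one_in`.
#' @examples
#' match_probability(24, 2) # 301/2^24, "1 in 55738"
#' @export
match_probability <- function(n, f) {
  if (any(n <= 0) || any(f < 0) || any(f > n)) {
    abort("require n >= 1 and 0 <= f <= n")
  }
  p <- purrr::map2_dbl(n, f, function(n1, f1) {
    sum(choose(n1, 0:f1)) / 2^n1
  })
  tibble(n = as.integer(n), f = as.integer(f),
         probability = p, one_in = round(1 / p))
}

#' Count agreements between an assigned profile and a reference profile
#'
#' Position-wise comparison of a density-derived R/Y assignment against the
#' sequence-derived reference pattern. An `X` in the assigned profile counts
#' as unresolved; unequal non-`X` symbols count as mismatches. The three
#' counts always sum to the profile length.
#'
#' @param assigned Density-derived `ry_profile` (may contain `X`).
#' @param reference Sequence-derived `ry_profile` of the same length (no `X`).
#' @return A tibble with columns `n`, `n_agree`, `n_mismatch`, `n_unresolved`.
#' @export
count_agreements <- function(assigned, reference) {
  a <- strsplit(unclass(as_ry(assigned)), "", fixed = TRUE)[[1]]
  r <- strsplit(unclass(as_ry(reference)), "", fixed = TRUE)[[1]]
  if (length(a) != length(r)) {
    abort(sprintf("length mismatch: assigned %d vs reference %d",
                  length(a), length(r)))
  }
  if (any(r == "X")) abort("reference profile must not contain X")
  unres <- a == "X"
  mism <- !unres & a != r
  tibble(
    n = length(a),
    n_agree = sum(!unres & !mism),
    n_mismatch = sum(mism),
    n_unresolved = sum(unres)
  )
}

#' Scan a circular reference with an R/Y profile under a tolerance budget
#'
#' Compares the profile to every start position of the reference's R/Y
#' rendering on both strands. The reverse-strand comparison uses the
#' reversed, R/Y-complemented profile against the forward reference, the
#' reported position being the forward-strand position aligned with the
#' 5'-most symbol after reversal. `X` symbols are compatible with both `R`
#' and `Y` but consume the same tolerance budget as a mismatch: a hit is
#' reported when `n_mismatch + n_unresolved <= max_free`.
#'
#' @param profile Density-derived `ry_profile` or string over `R`/`Y`/`X`.
#' @param ref A [circular_sequence()] (or string; circular by default).
#' @param max_free Maximum tolerated mismatched-plus-unresolved positions.
#' @return A tibble of hits sorted by `free` then `start`, with columns
#'   `start`, `strand`, `n`, `n_agree`, `n_mismatch`, `n_unresolved`, `free`,
#'   `probability`, `is_best`, and attribute `unique_best` (`TRUE` when
#'   exactly one hit attains the minimum `free`).
#' @examples
#' ref <- circular_sequence("GAATTCGGCCATATG")
#' ry_scan(to_ry("GGCC"), ref, max_free = 0)
#' @export
ry_scan <- function(profile, ref, max_free = 0L) {
  p <- as_ry(profile)
  ref <- as_circular_sequence(ref)
  if (max_free < 0) abort("`max_free` must be >= 0")
  n <- nchar(unclass(p))
  L <- seq_length(ref)
  if (n > L) abort(sprintf("profile (%d) longer than reference (%d)", n, L))

  ref_chars <- strsplit(unclass(to_ry(ref)), "", fixed = TRUE)[[1]]
  ref_dbl <- c(ref_chars, ref_chars) # unrolled circle
  starts <- if (ref$circular) seq_len(L) else seq_len(L - n + 1L)

  scan_one <- function(pvec, strand) {
    unres_mask <- pvec == "X"
    n_unres <- sum(unres_mask)
    live <- which(!unres_mask)
    mism <- integer(length(starts))
    for (j in live) {
      mism <- mism + (pvec[j] != ref_dbl[starts + j - 1L])
    }
    tibble(
      start = starts, strand = strand, n = n,
      n_agree = n - mism - n_unres,
      n_mismatch = mism, n_unresolved = n_unres,
      free = mism + n_unres
    )
  }

  pvec <- strsplit(unclass(p), "", fixed = TRUE)[[1]]
  pvec_rev <- rev(chartr("RY", "YR", pvec))
  hits <- bind_rows(
    scan_one(pvec, "forward"),
    scan_one(pvec_rev, "reverse")
  ) |>
    filter(.data$free <= max_free) |>
    arrange(.data$free, .data$start, .data$strand)

  hits$probability <- if (nrow(hits)) {
    match_probability(rep(n, nrow(hits)), hits$free)$probability
  } else {
    numeric(0)
  }
  best <- if (nrow(hits)) min(hits$free) else NA_integer_
  hits$is_best <- if (nrow(hits)) hits$free == best else logical(0)
  attr(hits, "unique_best") <- sum(hits$is_best) == 1L
  class(hits) <- c("ry_scan", class(hits))
  hits
}

#' Map a scan hit back to nucleotide sequence (register assignment)
#'
#' Substitutes the reference sequence back into a matched R/Y window,
#' optionally widening the window into flanking, less well resolved
#' positions. For reverse-strand hits the returned chain sequence is the
#' reverse complement of the reference over the mapped interval.
#'
#' @param hit One row of a [ry_scan()] result (or a list with `start`,
#'   `strand`, `n`).
#' @param ref The [circular_sequence()] the hit refers to.
#' @param extend_left,extend_right Non-negative widening, in bp, applied on
#'   the reference's forward coordinates (left = lower positions).
#' @return A tibble with columns `map_start`, `map_end`, `strand`, `length`,
#'   `chain_sequence`. On a circular reference a window crossing the origin
#'   is reported with `map_start > map_end` (wrap notation).
#' @export
assign_register <- function(hit, ref, extend_left = 0L, extend_right = 0L) {
  ref <- as_circular_sequence(ref)
  if (extend_left < 0 || extend_right < 0) abort("extensions must be >= 0")
  if (is.data.frame(hit)) {
    if (nrow(hit) != 1L) abort("`hit` must be a single hit (one row)")
    hit <- as.list(hit)
  }
  L <- seq_length(ref)
  len <- hit$n + extend_left + extend_right
  if (len > L) abort("extended interval longer than the reference")
  raw_start <- hit$start - extend_left
  if (!ref$circular && (raw_start < 1L || raw_start + len - 1L > L)) {
    abort("extension falls outside a linear reference")
  }
  s <- circ_substr(ref, raw_start, len)
  if (identical(hit$strand, "reverse")) s <- reverse_complement(s)
  tibble(
    map_start = circ_pos(raw_start, L),
    map_end = circ_pos(raw_start + len - 1L, L),
    strand = hit$strand %||% "forward",
    length = len,
    chain_sequence = s
  )
}

#' Find maximal reverse-complement palindromes
#'
#' Reports every maximal substring that equals its own reverse complement
#' and has at least `min_len` bases. Reverse-complement palindromes are
#' necessarily even-length; maximality means the palindrome cannot be
#' extended symmetrically on either side. On circular sequences palindromes
#' may span the origin and are then reported once in wrap notation
#' (`start > end`).
#'
#' @param seq A [circular_sequence()] or nucleotide string.
#' @param min_len Minimum length; even, >= 2.
#' @return A tibble with columns `start`, `end`, `length`.
#' @examples
#' find_palindromes("GAATTC", min_len = 4)
#' @export
find_palindromes <- function(seq, min_len = 4L) {
  if (min_len < 2L || min_len %% 2L != 0L) abort("`min_len` must be even and >= 2")
  x <- as_circular_sequence(seq)
  L <- seq_length(x)
  s <- strsplit(x$residues, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGT", "TGCA", s)
  centers <- if (x$circular) seq_len(L) else seq_len(L - 1L)
  max_r <- floor(L / 2)

  hits <- purrr::map(centers, function(c0) {
    r <- 0L
    while (r < max_r) {
      i <- c0 - r # left position of next shell
      j <- c0 + r + 1L # right position
      if (!x$circular && (i < 1L || j > L)) break
      if (s[circ_pos(i, L)] != comp[circ_pos(j, L)]) break
      r <- r + 1L
    }
    len <- 2L * r
    if (len < min_len) return(NULL)
    tibble(
      start = circ_pos(c0 - r + 1L, L),
      end = circ_pos(c0 + r, L),
      length = len
    )
  })
  out <- bind_rows(hits)
  if (!nrow(out)) {
    out <- tibble(start = integer(), end = integer(), length = integer())
  }
  arrange(out, .data$start)
}

#' Overlap of two inclusive 1-based intervals on a reference
#'
#' Counts the integer positions shared by two intervals on a reference of
#' length `L`. On circular references an interval with `start > end` wraps
#' through the origin.
#'
#' @param a,b Length-2 integer vectors `c(start, end)`.
#' @param L Reference length.
#' @param circular Honour wrap-around intervals?
#' @return Integer overlap in bp.
#' @examples
#' interval_overlap(c(109, 138), c(132, 161), L = 601) # 7
#' @export
interval_overlap <- function(a, b, L, circular = TRUE) {
  expand <- function(iv) {
    if (length(iv) != 2L || anyNA(iv) || any(iv < 1L) || any(iv > L)) {
      abort("intervals must be c(start, end) within 1..L")
    }
    if (iv[1] <= iv[2]) {
      iv[1]:iv[2]
    } else if (circular) {
      c(iv[1]:L, 1:iv[2])
    } else {
      abort("start > end is only valid on a circular reference")
    }
  }
  length(intersect(expand(a), expand(b)))
}
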