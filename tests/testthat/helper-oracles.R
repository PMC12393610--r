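## Independent brute-force oracles. These deliberately share no code with
## the implementation: plain loops, direct definitions, no clever indexing.

oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

## compare a profile to every offset/strand by direct character loops
oracle_scan <- function(profile, ref, circular = TRUE, max_free = 0L) {
  p <- strsplit(profile, "", fixed = TRUE)[[1]]
  r <- strsplit(chartr("AGCT", "RRYY", ref), "", fixed = TRUE)[[1]]
  L <- length(r)
  n <- length(p)
  p_rev <- rev(chartr("RY", "YR", p))
  rows <- list()
  starts <- if (circular) 1:L else 1:(L - n + 1)
  for (strand in c("forward", "reverse")) {
    pv <- if (strand == "forward") p else strsplit(paste(p_rev, collapse = ""), "")[[1]]
    for (s0 in starts) {
      mm <- 0L; un <- 0L
      for (j in 1:n) {
        rj <- r[((s0 + j - 2) %% L) + 1]
        if (pv[j] == "X") un <- un + 1L
        else if (pv[j] != rj) mm <- mm + 1L
      }
      if (mm + un <= max_free) {
        rows[[length(rows) + 1]] <-
          data.frame(start = s0, strand = strand, n_mismatch = mm,
                     n_unresolved = un)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(), strand = character(),
                      n_mismatch = integer(), n_unresolved = integer())
  }
  out[order(out$n_mismatch + out$n_unresolved, out$start, out$strand), ]
}

## all maximal reverse-complement palindromes by exhaustive substring checks
oracle_palindromes <- function(s, min_len, circular = TRUE) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  at <- function(i) chars[((i - 1) %% L) + 1]
  is_pal <- function(a, len) {
    if (!circular && (a < 1 || a + len - 1 > L)) return(FALSE)
    for (j in 0:(len - 1)) {
      if (at(a + j) != chartr("ACGT", "TGCA", at(a + len - 1 - j))) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  max_len <- if (circular) 2 * floor(L / 2) else L
  for (len in seq(2, max_len, by = 2)) {
    if (len < min_len) next
    a_range <- if (circular) 1:L else 1:(L - len + 1)
    for (a in a_range) {
      if (!is_pal(a, len)) next
      # maximal: one-shell extension must fail (or be impossible)
      extendable <- len + 2 <= max_len && is_pal(a - 1, len + 2)
      if (!extendable) {
        rows[[length(rows) + 1]] <-
          data.frame(start = ((a - 1) %% L) + 1,
                     end = ((a + len - 2) %% L) + 1, length = len)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(), length = integer())
  }
  out[order(out$start), ]
}

## hinge/bisector step-parameter extraction (the classical construction:
## RollTilt about the hinge, symmetric half-rotations, bisector mid frame)
oracle_step_params <- function(R1, o1, R2, o2) {
  rodrigues <- function(axis, ang) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  }
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cg <- max(-1, min(1, sum(z1 * z2)))
  gamma <- acos(cg)
  if (gamma > 1e-12) {
    hinge <- pracma::cross(z1, z2)
    R1p <- rodrigues(hinge, gamma / 2) %*% R1
    R2p <- rodrigues(hinge, -gamma / 2) %*% R2
  } else {
    R1p <- R1; R2p <- R2
  }
  zm <- R1p[, 3]
  twist <- atan2(sum(pracma::cross(R1p[, 1], R2p[, 1]) * zm),
                 sum(R1p[, 1] * R2p[, 1]))
  xm <- (R1p[, 1] + R2p[, 1]); xm <- xm / sqrt(sum(xm^2))
  ym <- (R1p[, 2] + R2p[, 2]); ym <- ym / sqrt(sum(ym^2))
  Rm <- cbind(xm, ym, zm)
  d <- as.vector(t(Rm) %*% (o2 - o1))
  if (gamma > 1e-12) {
    # decompose RollTilt onto the mid-frame y (roll) and x (tilt) axes
    hinge_m <- as.vector(t(Rm) %*% (pracma::cross(z1, z2) /
                                      sqrt(sum(pracma::cross(z1, z2)^2))))
    phi <- atan2(hinge_m[1], hinge_m[2]) # angle of hinge from ym, toward xm
    roll <- gamma * cos(phi); tilt <- gamma * sin(phi)
  } else {
    roll <- 0; tilt <- 0
  }
  c(shift = d[1], slide = d[2], rise = d[3],
    tilt = tilt * 180 / pi, roll = roll * 180 / pi, twist = twist * 180 / pi)
}

## per-column PWM summation by explicit loop
oracle_pwm_score <- function(window, weights) {
  obs <- strsplit(window, "", fixed = TRUE)[[1]]
  total <- 0
  for (j in seq_along(obs)) {
    total <- total + unname(weights[match(obs[j], c("A", "C", "G", "T")), j])
  }
  total
}

## sort-based percentile of a score within a profile
oracle_percentile <- function(scores, value) {
  list(frac_above = sum(sort(scores, decreasing = TRUE) > value) / length(scores),
       frac_below = sum(sort(scores) < value) / length(scores))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
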