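#' Classify base-pair steps from z_P
#'
#' `z_P` is the mean out-of-plane z-coordinate (in Angstrom) of the backbone
#' phosphorus atoms in the coordinate frame of a base-pair step. B-form
#' steps have `z_P <= 0.5` A, A-form steps `z_P >= 1.5` A; values strictly
#' between are intermediate.
#'
#' @param zp Numeric vector of z_P values (Angstrom).
#' @return Character vector over `"A"`, `"B"`, `"intermediate"`.
#' @examples
#' classify_zp(c(-0.2, 0.5, 1.0, 1.5)) # B B intermediate A
#' @export
classify_zp <- function(zp) {
  if (any(!is.finite(zp))) abort("`zp` must be finite")
  dplyr::case_when(zp <= 0.5 ~ "B", zp >= 1.5 ~ "A", TRUE ~ "intermediate")
}

#' Classify base-pair steps from z_P(h)
#'
#' `z_P(h)` is the projection, on the local helical axis, of the vector
#' linking the two strands' phosphorus atoms across a base-pair step.
#' Values above 4 A mark the strongly bent, untwisted TA form (as first
#' seen in TATA-box-binding-protein complexes); values below mark B-form.
#' Exactly 4 A is assigned to B (the published criteria use strict
#' inequalities on both sides and leave the boundary unassigned).
#'
#' @param zph Numeric vector of z_P(h) values (Angstrom).
#' @return Character vector over `"B"`, `"TA"`.
#' @export
classify_zph <- function(zph) {
  if (any(!is.finite(zph))) abort("`zph` must be finite")
  ifelse(zph > 4, "TA", "B")
}

#' Default acceptance ranges for intra-base-pair parameters
#'
#' Closed intervals for Shear, Stretch, Stagger (Angstrom) and Buckle,
#' Propeller, Opening (degrees) used by [is_melted()] when no ranges are
#' supplied. These are package defaults chosen as generous envelopes of
#' paired B-form geometry; they are configurable and analyses with specific
#' survey-derived ranges should pass their own.
#'
#' @return Named list of `c(lower, upper)` intervals.
#' @export
default_bp_ranges <- function() {
  list(
    shear = c(-1.5, 1.5), stretch = c(-1.5, 1.5), stagger = c(-2.0, 2.0),
    buckle = c(-25, 25), propeller = c(-30, 15), opening = c(-15, 15)
  )
}

#' Flag melted base pairs from rigid-body parameter ranges
#'
#' A base pair is "melted" when any of its six rigid-body parameters falls
#' outside its closed acceptance interval.
#'
#' @param bp Data frame with columns `shear`, `stretch`, `stagger`,
#'   `buckle`, `propeller`, `opening` (case-insensitive), one row per pair.
#' @param ranges Named list of `c(lower, upper)` per parameter; defaults to
#'   [default_bp_ranges()].
#' @return Logical vector, `TRUE` for melted pairs.
#' @export
is_melted <- function(bp, ranges = default_bp_ranges()) {
  bp <- as_tibble(bp)
  names(bp) <- tolower(names(bp))
  pars <- c("shear", "stretch", "stagger", "buckle", "propeller", "opening")
  missing_col <- setdiff(pars, names(bp))
  if (length(missing_col)) {
    abort(paste("missing base-pair parameter column(s):",
                paste(missing_col, collapse = ", ")))
  }
  names(ranges) <- tolower(names(ranges))
  missing_rng <- setdiff(pars, names(ranges))
  if (length(missing_rng)) {
    abort(paste("no range supplied for:", paste(missing_rng, collapse = ", ")))
  }
  out <- rep(FALSE, nrow(bp))
  for (p in pars) {
    r <- ranges[[p]]
    out <- out | bp[[p]] < r[1] | bp[[p]] > r[2]
  }
  out
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

canonical_step_cols <- function(df, needed) {
  names(df) <- tolower(names(df))
  missing_col <- setdiff(needed, names(df))
  if (length(missing_col)) {
    abort(paste("missing step-parameter column(s):",
                paste(missing_col, collapse = ", ")))
  }
  df
}

#' Rebuild base-pair frames from rigid-body step parameters
#'
#' Generates one coordinate frame (origin + right-handed orthonormal triad)
#' per base pair by sequentially composing the mid-step-triad rigid-body
#' transform: the relative rotation is factored as
#' `Rz(Twist/2 - phi) Ry(Gamma) Rz(Twist/2 + phi)` with
#' `Gamma = sqrt(Tilt^2 + Roll^2)` and `phi = atan2(Tilt, Roll)`, and the
#' displacement `(Shift, Slide, Rise)` is applied in the mid-step triad
#' (rotation split half before and half after), the standard base-pair-step
#' convention of helical-parameter software. Frame 1 sits at the global
#' origin with the identity triad.
#'
#' @param steps Data frame with columns `shift`, `slide`, `rise` (Angstrom)
#'   and `tilt`, `roll`, `twist` (degrees); one row per step.
#' @return A `helix_model`: list with `origins` (`(n+1) x 3` matrix),
#'   `triads` (`3 x 3 x (n+1)` array) and the input `steps`.
#' @examples
#' b <- data.frame(shift = 0, slide = 0, rise = 3.4,
#'                 tilt = 0, roll = 0, twist = 36)
#' m <- rebuild_helix(b[rep(1, 10), ])
#' tidy(m)
#' @export
rebuild_helix <- function(steps) {
  steps <- canonical_step_cols(as_tibble(steps),
                               c("shift", "slide", "rise", "tilt", "roll", "twist"))
  n <- nrow(steps)
  if (n < 1L) abort("need at least one step")
  vals <- as.matrix(steps[, c("shift", "slide", "rise", "tilt", "roll", "twist")])
  if (any(!is.finite(vals))) abort("step parameters must be finite")

  origins <- matrix(0, n + 1L, 3)
  triads <- array(0, c(3, 3, n + 1L))
  R <- diag(3)
  o <- c(0, 0, 0)
  triads[, , 1] <- R
  for (i in seq_len(n)) {
    p <- vals[i, ]
    gamma <- sqrt(p["tilt"]^2 + p["roll"]^2)
    phi <- atan2(p["tilt"], p["roll"]) * 180 / pi
    a <- p["twist"] / 2 - phi
    b <- p["twist"] / 2 + phi
    R_mid <- R %*% rot_z(a) %*% rot_y(gamma / 2) %*% rot_z(phi)
    o <- o + as.vector(R_mid %*% p[c("shift", "slide", "rise")])
    R <- R %*% rot_z(a) %*% rot_y(gamma) %*% rot_z(b)
    origins[i + 1L, ] <- o
    triads[, , i + 1L] <- R
  }
  structure(list(origins = origins, triads = triads, steps = steps),
            class = "helix_model")
}

#' Recover step parameters from consecutive base-pair frames
#'
#' Inverse of [rebuild_helix()]: extracts `(shift, slide, rise, tilt, roll,
#' twist)` for every consecutive frame pair by the Euler z-y-z factorisation
#' of the relative rotation and the mid-step-triad projection of the
#' displacement.
#'
#' @param model A `helix_model`.
#' @return Tibble of step parameters, one row per step.
#' @export
step_parameters <- function(model) {
  stopifnot(inherits(model, "helix_model"))
  n <- nrow(model$origins) - 1L
  purrr::map_dfr(seq_len(n), function(i) {
    R1 <- model$triads[, , i]
    R2 <- model$triads[, , i + 1L]
    rel <- t(R1) %*% R2
    cg <- max(-1, min(1, rel[3, 3]))
    gamma <- acos(cg) * 180 / pi
    if (gamma < 1e-9) {
      twist <- atan2(rel[2, 1], rel[1, 1]) * 180 / pi
      phi <- 0
    } else {
      a <- atan2(rel[2, 3], rel[1, 3]) * 180 / pi
      b <- atan2(rel[3, 2], -rel[3, 1]) * 180 / pi
      twist <- a + b
      phi <- (b - a) / 2
      # canonical branch: Twist in (-180, 180]; the paired factorisation
      # (twist -/+ 360, phi + 180) generates the same rotation
      if (twist > 180) {
        twist <- twist - 360
        phi <- phi + 180
      } else if (twist <= -180) {
        twist <- twist + 360
        phi <- phi + 180
      }
    }
    R_mid <- R1 %*% rot_z(twist / 2 - phi) %*% rot_y(gamma / 2) %*% rot_z(phi)
    d <- as.vector(t(R_mid) %*% (model$origins[i + 1L, ] - model$origins[i, ]))
    tibble(shift = d[1], slide = d[2], rise = d[3],
           tilt = gamma * sin(phi * pi / 180),
           roll = gamma * cos(phi * pi / 180),
           twist = twist)
  })
}

#' @export
print.helix_model <- function(x, ...) {
  n <- nrow(x$origins)
  e2e <- sqrt(sum((x$origins[n, ] - x$origins[1, ])^2))
  cat(sprintf("<helix_model> %d base pairs (%d steps), end-to-end %.1f A\n",
              n, n - 1L, e2e))
  invisible(x)
}

#' @export
tidy.helix_model <- function(x, ...) {
  o <- x$origins
  tibble(bp = seq_len(nrow(o)), x = o[, 1], y = o[, 2], z = o[, 3])
}

#' @export
glance.helix_model <- function(x, ...) {
  n <- nrow(x$origins)
  seg <- diff(x$origins)
  tibble(
    n_bp = n, n_steps = n - 1L,
    end_to_end = sqrt(sum((x$origins[n, ] - x$origins[1, ])^2)),
    contour_length = sum(sqrt(rowSums(seg^2)))
  )
}

#' Plot the rebuilt helix axis
#'
#' Projections of the base-pair origin path onto the xy and xz planes.
#'
#' @param object A `helix_model`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.helix_model <- function(object, ...) {
  td <- tidy(object)
  long <- bind_rows(
    tibble(u = td$x, v = td$y, bp = td$bp, plane = "x-y"),
    tibble(u = td$x, v = td$z, bp = td$bp, plane = "x-z")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$u, y = .data$v, colour = .data$bp)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~plane, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "A", y = "A", colour = "bp") +
    ggplot2::theme_minimal()
}

#' Superhelical handedness of a rebuilt axis
#'
#' Smooths the base-pair origins with two passes of a centred moving
#' average of `smooth_window` points (about one helical turn by default;
#' the second pass suppresses the residual double-helix-period wiggle a
#' single pass leaves behind), then accumulates the signed dihedral angle
#' between successive osculating planes of the smoothed axis - the discrete
#' torsion. Handedness follows the DNA supercoiling convention, under which
#' an underwound, negative-writhe superhelix is called right-handed: mean
#' torsion below `-tau_min` is `"right"`, above `+tau_min` is `"left"`,
#' otherwise `"none"` (a straight axis has exactly zero torsion).
#'
#' @param model A `helix_model` with at least `3 * smooth_window` frames.
#' @param smooth_window Moving-average width in bp (default 10).
#' @param tau_min Dead band on the mean torsion, rad/step (default 1e-3).
#' @return One-row tibble: `handedness`, `mean_torsion`, `n_axis_points`,
#'   `smooth_window`.
#' @export
handedness <- function(model, smooth_window = 10L, tau_min = 1e-3) {
  stopifnot(inherits(model, "helix_model"))
  n <- nrow(model$origins)
  if (n < 3L * smooth_window) {
    abort(sprintf("need at least %d frames for smooth_window = %d",
                  3L * smooth_window, smooth_window))
  }
  sm <- model$origins
  for (pass in 1:2) {
    sm <- apply(sm, 2, function(col) {
      stats::filter(col, rep(1 / smooth_window, smooth_window), sides = 2)
    })
    sm <- sm[stats::complete.cases(sm), , drop = FALSE]
  }
  e <- diff(sm)
  e <- e / sqrt(rowSums(e^2))
  cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  }
  tors <- vapply(2:(nrow(e) - 1L), function(i) {
    b1 <- cross3(e[i - 1L, ], e[i, ])
    b2 <- cross3(e[i, ], e[i + 1L, ])
    if (sqrt(sum(b1^2)) < 1e-12 || sqrt(sum(b2^2)) < 1e-12) return(0)
    atan2(sum(cross3(b1, b2) * e[i, ]), sum(b1 * b2))
  }, numeric(1))
  mt <- mean(tors)
  hand <- if (mt < -tau_min) "right" else if (mt > tau_min) "left" else "none"
  tibble(handedness = hand, mean_torsion = mt,
         n_axis_points = nrow(sm), smooth_window = as.integer(smooth_window))
}

#' Read a per-step descriptor table
#'
#' Consumes CSV exports in the style of helical-analysis software: named
#' columns for the six rigid-body step parameters and/or the conformational
#' descriptors `zp` and `zp_h` (case-insensitive; `zP(h)`, `zp.h` and
#' `zph` are also recognised). Row order is preserved.
#'
#' @param path CSV file.
#' @param require Character vector of columns that must be present, in
#'   canonical lower-case names (e.g. `c("twist", "zp")`).
#' @return Tibble with canonical column names.
#' @export
read_step_table <- function(path, require = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  nm <- tolower(names(df))
  nm <- sub("^zp\\(h\\)$|^zp\\.h$|^zp_h$|^zph$", "zp_h", nm)
  names(df) <- nm
  known <- c("shift", "slide", "rise", "tilt", "roll", "twist", "zp", "zp_h")
  keep <- intersect(nm, known)
  if (!length(keep)) abort("no recognised step-parameter or descriptor columns")
  missing_col <- setdiff(tolower(require %||% character()), nm)
  if (length(missing_col)) {
    abort(paste("missing required column(s):", paste(missing_col, collapse = ", ")))
  }
  num_bad <- keep[!vapply(df[keep], is.numeric, TRUE)]
  if (length(num_bad)) {
    abort(paste("non-numeric values in column(s):", paste(num_bad, collapse = ", ")))
  }
  as_tibble(df[keep])
}

#' Classify a step-descriptor table
#'
#' Adds `form_zp` ([classify_zp()]) and/or `form_zph` ([classify_zph()])
#' columns to a descriptor table, whichever descriptors are present.
#'
#' @param descriptors Tibble from [read_step_table()] or compatible.
#' @return The tibble with classification columns appended.
#' @export
classify_steps <- function(descriptors) {
  d <- as_tibble(descriptors)
  names(d) <- tolower(names(d))
  if (!("zp" %in% names(d)) && !("zp_h" %in% names(d))) {
    abort("need a `zp` and/or `zp_h` column")
  }
  if ("zp" %in% names(d)) d$form_zp <- classify_zp(d$zp)
  if ("zp_h" %in% names(d)) d$form_zph <- classify_zph(d$zp_h)
  d
}

#' Step-parameter presets for superhelix demonstrations
#'
#' Builds the 55-bp demonstration chains: 5-bp stretches of A-like or
#' C-like steps interspersed between 5-bp stretches of ideal B-DNA
#' (`"fig-s4-a"`, `"fig-s4-c"`), or uniform ideal B (`"uniform-b"`).
#' A-like inserts are underwound (negative Slide, positive Roll, Twist
#' 34 deg) and fold the chain into what the supercoiling convention calls a
#' right-handed superhelix; C-like inserts are overwound and fold it
#' left-handed.
#'
#' @param preset One of `"fig-s4-a"`, `"fig-s4-c"`, `"uniform-b"`.
#' @param n_bp Chain length in base pairs (default 55).
#' @return Tibble of `n_bp - 1` step-parameter rows with a `form` column.
#' @export
helix_preset <- function(preset = c("fig-s4-a", "fig-s4-c", "uniform-b"),
                         n_bp = 55L) {
  preset <- match.arg(preset)
  pars <- fixture("figS4_presets")$payload
  insert <- switch(preset, "fig-s4-a" = "A", "fig-s4-c" = "C", "uniform-b" = "B")
  n_blocks <- ceiling(n_bp / 5)
  lab <- rep(rep(c("B", insert), length.out = n_blocks), each = 5L)[seq_len(n_bp)]
  step_lab <- lab[seq_len(n_bp - 1L)] # step i takes the stretch label of bp i
  out <- pars[match(step_lab, pars$form), ]
  out$form <- step_lab
  out <- as_tibble(out)[, c("form", "shift", "slide", "rise", "tilt", "roll", "twist")]
  out
}

#' Write base-pair origins as a pseudo-atom PDB
#'
#' One phosphorus pseudo-atom per base-pair origin, chained so molecular
#' viewers draw the axis path.
#'
#' @param model A `helix_model`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_axis_pdb <- function(model, path) {
  stopifnot(inherits(model, "helix_model"))
  o <- model$origins
  lines <- vapply(seq_len(nrow(o)), function(i) {
    sprintf("ATOM  %5d  P   AXS A%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
            i, i, o[i, 1], o[i, 2], o[i, 3])
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}
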