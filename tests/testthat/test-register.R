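test_that("to_ry maps purines to R and pyrimidines to Y", {
  expect_equal(unclass(to_ry("GAATTC")), "RRRYYY", ignore_attr = TRUE)
  expect_equal(unclass(to_ry("ACGT")), "RYRY", ignore_attr = TRUE)
  expect_equal(unclass(to_ry("A")), "R", ignore_attr = TRUE)
  expect_error(to_ry("ACGN"), "position 4")
})

test_that("to_ry commutes with reverse complementation via profile reversal", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(5:40, 1))
    lhs <- as.character(to_ry(oracle_rc(s)))
    rhs <- paste(rev(strsplit(unclass(complement_ry(to_ry(s))), "")[[1]]),
                 collapse = "")
    expect_equal(lhs, rhs)
  }
})

test_that("complement_ry swaps R/Y, fixes X, and is an involution", {
  expect_equal(as.character(complement_ry("RYYR")), "YRRY")
  expect_equal(as.character(complement_ry("XXX")), "XXX")
  set.seed(4)
  for (i in 1:20) {
    p <- paste(sample(c("R", "Y", "X"), 15, TRUE), collapse = "")
    expect_equal(as.character(complement_ry(complement_ry(p))), p)
  }
})

test_that("match probability reproduces the closed form and its odds form", {
  p24 <- match_probability(24, 2)
  expect_identical(p24$probability, 301 / 2^24)
  expect_identical(p24$one_in, 55738)
  p30 <- match_probability(30, 2)
  expect_identical(p30$probability, 466 / 2^30)
  expect_identical(p30$one_in, 2304167)
  expect_equal(match_probability(1, 0)$probability, 0.5)
  expect_equal(match_probability(17, 17)$probability, 1.0)
  expect_error(match_probability(5, 6))
  expect_error(match_probability(0, 0))
})

test_that("match probability equals exhaustive enumeration at small n", {
  for (n in c(4, 7, 10)) {
    # enumerate all 2^n R/Y strings, count those within f of a fixed profile
    grid <- as.matrix(expand.grid(rep(list(c("R", "Y")), n)))
    profile <- sample(c("R", "Y"), n, TRUE)
    for (f in c(0, 1, 3)) {
      hits <- sum(apply(grid, 1, function(row) sum(row != profile) <= f))
      expect_equal(match_probability(n, f)$probability, hits / 2^n)
    }
  }
})

test_that("match probability is monotone in n and f", {
  expect_true(all(diff(match_probability(5:30, rep(2, 26))$probability) < 0))
  expect_true(all(diff(match_probability(rep(30, 11), 0:10)$probability) > 0))
})

test_that("agreement counting separates mismatches from unresolved bases", {
  r <- count_agreements("RYXRY", "RRYRY")
  expect_equal(r$n_agree, 3L)
  expect_equal(r$n_mismatch, 1L)
  expect_equal(r$n_unresolved, 1L)
  same <- count_agreements("RYRYR", "RYRYR")
  expect_equal(unlist(same[c("n_agree", "n_mismatch", "n_unresolved")]),
               c(n_agree = 5L, n_mismatch = 0L, n_unresolved = 0L))
  expect_error(count_agreements("RY", "RYR"), "length mismatch")
  expect_error(count_agreements("RY", "RX"), "must not contain X")
})

test_that("agreement totals always sum to the profile length", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    a <- paste(sample(c("R", "Y", "X"), n, TRUE, prob = c(.45, .45, .1)), collapse = "")
    r <- paste(sample(c("R", "Y"), n, TRUE), collapse = "")
    cnt <- count_agreements(a, r)
    expect_equal(cnt$n_agree + cnt$n_mismatch + cnt$n_unresolved, n)
  }
})

test_that("scan agrees with the brute-force oracle on small circles", {
  set.seed(31)
  for (i in 1:12) {
    L <- sample(20:64, 1)
    ref <- random_dna(L)
    n <- sample(5:12, 1)
    prof <- paste(sample(c("R", "Y", "X"), n, TRUE, prob = c(.45, .45, .1)),
                  collapse = "")
    mf <- sample(0:3, 1)
    got <- ry_scan(ry_profile(prof), circular_sequence(ref), max_free = mf)
    want <- oracle_scan(prof, ref, circular = TRUE, max_free = mf)
    expect_equal(nrow(got), nrow(want))
    key <- function(d) paste(d$start, d$strand, d$n_mismatch, d$n_unresolved)
    expect_setequal(key(got), key(want))
  }
})

test_that("scan recovers a planted profile as the unique best hit", {
  prof <- paste(sample(c("R", "Y"), 24, TRUE), collapse = "")
  s <- synth_sequence(101, 601, plant = list(profile = prof, position = 112,
                                             n_mismatch = 1))
  hits <- ry_scan(ry_profile(prof), s, max_free = 2)
  best <- hits[hits$is_best, ]
  expect_equal(best$start, 112L)
  expect_equal(best$strand, "forward")
  expect_equal(best$n_mismatch, 1L)
})

test_that("degenerate scans behave as documented", {
  ref <- circular_sequence("GAATTCGGCCTTAAGG")
  allx <- ry_scan(ry_profile("XXXX"), ref, max_free = 4)
  expect_equal(nrow(allx), 2L * 16L) # every start, both strands
  expect_true(all(allx$n_unresolved == 4L))
  self <- ry_scan(to_ry(substr(ref$residues, 5, 10)), ref, max_free = 0)
  expect_true(any(self$start == 5L & self$strand == "forward" &
                    self$n_mismatch == 0L))
  expect_error(ry_scan(ry_profile("RRRRR"),
                       circular_sequence("ACG", circular = FALSE), 0),
               "longer than")
})

test_that("scan is strand-symmetric", {
  set.seed(41)
  for (i in 1:8) {
    L <- sample(20:64, 1)
    ref <- random_dna(L)
    prof <- paste(sample(c("R", "Y"), 8, TRUE), collapse = "")
    rev_prof <- paste(rev(strsplit(unclass(complement_ry(prof)), "")[[1]]),
                      collapse = "")
    fwd <- ry_scan(ry_profile(prof), circular_sequence(ref), max_free = 2)
    swp <- ry_scan(ry_profile(rev_prof), circular_sequence(ref), max_free = 2)
    # the reversed+complemented profile's forward hits are the original's
    # reverse hits at the same reported positions, and vice versa
    expect_setequal(
      paste(fwd$start[fwd$strand == "reverse"], fwd$free[fwd$strand == "reverse"]),
      paste(swp$start[swp$strand == "forward"], swp$free[swp$strand == "forward"])
    )
  }
})

test_that("expected random hit count matches 2 L p within 3 standard errors", {
  set.seed(51)
  L <- 150L; n <- 12L; mf <- 1L
  p <- match_probability(n, mf)$probability
  prof <- paste(sample(c("R", "Y"), n, TRUE), collapse = "")
  counts <- vapply(1:200, function(i) {
    nrow(ry_scan(ry_profile(prof), synth_sequence(1000 + i, L), max_free = mf))
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 2 * L * p), 3 * se + 1e-12)
})

test_that("register assignment substitutes sequence back over the hit window", {
  prof <- paste(sample(c("R", "Y"), 24, TRUE), collapse = "")
  s <- synth_sequence(77, 601, plant = list(profile = prof, position = 112))
  hits <- ry_scan(ry_profile(prof), s, max_free = 0)
  hit <- hits[hits$is_best & hits$start == 112, ][1, ]
  plain <- assign_register(hit, s)
  expect_equal(plain$map_start, 112L)
  expect_equal(plain$map_end, 135L)
  expect_equal(plain$chain_sequence, substr(s$residues, 112, 135))
  ext <- assign_register(hit, s, extend_left = 3, extend_right = 3)
  expect_equal(c(ext$map_start, ext$map_end, ext$length), c(109L, 138L, 30L))
  expect_equal(ext$chain_sequence, substr(s$residues, 109, 138))
})

test_that("forward and reverse assignments over one window are reverse complements", {
  s <- synth_sequence(9, 80)
  fwd <- assign_register(list(start = 10L, strand = "forward", n = 12L), s)
  rev <- assign_register(list(start = 10L, strand = "reverse", n = 12L), s)
  expect_equal(rev$chain_sequence, oracle_rc(fwd$chain_sequence))
})

test_that("assignment respects linear bounds and circular wrap", {
  lin <- circular_sequence("ACGTACGTAC", circular = FALSE)
  expect_error(assign_register(list(start = 1L, strand = "forward", n = 4L),
                               lin, extend_left = 1), "linear")
  circ <- synth_sequence(5, 30)
  wrap <- assign_register(list(start = 28L, strand = "forward", n = 6L), circ)
  expect_equal(c(wrap$map_start, wrap$map_end), c(28L, 3L))
  expect_equal(wrap$chain_sequence,
               paste0(substr(circ$residues, 28, 30), substr(circ$residues, 1, 3)))
})

test_that("palindrome finder reports maximal reverse-complement palindromes", {
  hit <- find_palindromes(circular_sequence("GAATTC", circular = FALSE), 4)
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end, hit$length), c(1L, 6L, 6L))
  expect_equal(nrow(find_palindromes(circular_sequence("AAAA", circular = FALSE), 4)), 0L)
  expect_error(find_palindromes("GAATTC", 5), "even")
})

test_that("palindrome finder matches the exhaustive oracle", {
  set.seed(61)
  for (circ in c(TRUE, FALSE)) {
    s <- random_dna(200)
    got <- find_palindromes(circular_sequence(s, circular = circ), 4)
    want <- oracle_palindromes(s, 4, circular = circ)
    key <- function(d) paste(d$start, d$end, d$length)
    expect_setequal(key(got), key(want))
  }
})

test_that("wrap-spanning palindromes are reported once in wrap notation", {
  # plant GAATTC across the origin of a 20-mer: positions 18,19,20,1,2,3
  base <- strsplit("CCCCCCCCCCCCCCCCCCCC", "")[[1]]
  base[18:20] <- c("G", "A", "A"); base[1:3] <- c("T", "T", "C")
  s <- circular_sequence(paste(base, collapse = ""))
  hits <- find_palindromes(s, 6)
  expect_true(any(hits$start == 18L & hits$end == 3L & hits$length == 6L))
})

test_that("interval overlap honours circular wrap", {
  expect_equal(interval_overlap(c(109, 138), c(132, 161), 601), 7L)
  expect_equal(interval_overlap(c(1, 5), c(10, 20), 601), 0L)
  expect_equal(interval_overlap(c(595, 10), c(1, 5), 601, circular = TRUE), 5L)
  expect_error(interval_overlap(c(0, 5), c(1, 2), 10), "within 1..L")
  expect_error(interval_overlap(c(5, 2), c(1, 2), 10, circular = FALSE))
})
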