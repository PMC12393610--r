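## Transcribed reference payloads used throughout the tests and examples.
## Each fixture is integrity-checked at access time against a frozen md5 of
## its canonical JSON serialization, so an accidental edit fails loudly.

# Density-derived R/Y assignment for the 24 well-resolved G-segment base
# pairs of the wrapped complex (chain E positions 92-115 paired with chain F
# 27-4), alongside the minicircle sequence pattern at the matched register.
# One mismatch (position 102) and one unresolvable base (position 110, X).
table1_payload <- function() {
  assign_e <- "RYYRYRRRRYYRYRRYYRXYRRRY"
  pattern_e <- "RYYRYRRRRYRRYRRYYRRYRRRY"
  to_chr <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
  pattern_f <- chartr("RY", "YR", pattern_e)
  assign_f <- chartr("RY", "YR", assign_e)
  tibble(
    pos_e = 92:115,
    assign_e = to_chr(assign_e),
    pattern_e = to_chr(pattern_e),
    pattern_f = to_chr(pattern_f),
    assign_f = to_chr(assign_f),
    pos_f = 27:4
  )
}

# Same for the 30 bp G-segment of the not-wrapped complex (chain E 1-30,
# chain F 30-1). Two mismatches (positions 26 and 30), no unresolved bases.
table2_payload <- function() {
  assign_e <- "RRRYYYRRRYYYRRYRYYRRRRRRRRRRYR"
  pattern_e <- "RRRYYYRRRYYYRRYRYYRRRRRRRYRRYY"
  to_chr <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
  pattern_f <- chartr("RY", "YR", pattern_e)
  assign_f <- chartr("RY", "YR", assign_e)
  tibble(
    pos_e = 1:30,
    assign_e = to_chr(assign_e),
    pattern_e = to_chr(pattern_e),
    pattern_f = to_chr(pattern_f),
    assign_f = to_chr(assign_f),
    pos_f = 30:1
  )
}

# Ideal-form base-pair-step parameter sextets used by the superhelix
# demonstration chains: B, underwound A-like, overwound C-like.
figs4_payload <- function() {
  tibble(
    form = c("B", "A", "C"),
    shift = c(0, 0, 0),
    slide = c(0, -2.0, 2.0),
    rise = c(3.4, 3.4, 3.4),
    tilt = c(0, 0, 0),
    roll = c(0, 12, -12),
    twist = c(36, 34, 38.298)
  )
}

fixture_builders <- function() {
  list(
    table1 = list(
      build = table1_payload,
      citation = "wrapped-complex G-segment R/Y assignment table"
    ),
    table2 = list(
      build = table2_payload,
      citation = "not-wrapped-complex G-segment R/Y assignment table"
    ),
    palindrome = list(
      build = function() "GAATTC",
      citation = "6 bp palindrome shared by the two G-segments"
    ),
    figS4_presets = list(
      build = figs4_payload,
      citation = "B/A/C step-parameter presets for superhelix demonstrations"
    )
  )
}

fixture_md5 <- c(
  table1 = "f2e64cb199a7e4ef4abc063221f83276",
  table2 = "8bd82e4b9404e229bb1e2d23aecdd537",
  palindrome = "89d271c358d96f9a51121fef7644d30e",
  figS4_presets = "a634ca3c23478ff144d9b1c4e2ddf06a"
)

payload_md5 <- function(payload) {
  txt <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Reference fixtures
#'
#' Returns one of the transcribed reference payloads shipped with the
#' package: `"table1"` / `"table2"` (density-derived R/Y assignment tables
#' for the wrapped and not-wrapped G-segments, as tibbles with chain-E and
#' chain-F columns in the original position numbering), `"palindrome"` (the
#' shared 6 bp G-segment palindrome), or `"figS4_presets"` (the B/A/C
#' step-parameter sextets used by [helix_preset()]). Payloads are verified
#' against embedded checksums so that any edit of the transcription fails
#' loudly.
#'
#' @param name Fixture name.
#' @return A list with elements `name`, `payload`, `citation`.
#' @examples
#' fixture("palindrome")$payload
#' @export
fixture <- function(name) {
  builders <- fixture_builders()
  if (!name %in% names(builders)) {
    abort(sprintf("unknown fixture '%s' (known: %s)", name,
                  paste(names(builders), collapse = ", ")))
  }
  payload <- builders[[name]]$build()
  md5 <- payload_md5(payload)
  if (!identical(md5, unname(fixture_md5[[name]]))) {
    abort(sprintf("fixture '%s' failed its integrity check (md5 %s)", name, md5))
  }
  list(name = name, payload = payload, citation = builders[[name]]$citation)
}
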