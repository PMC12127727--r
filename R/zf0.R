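# Modeled construct: the atypical CCHC zinc-finger domain (ZF0) of human
# BCL11B (UniProt Q9C0K0), residues 54-82 in full-length numbering. One
# interaction site per residue; numbering is never re-indexed to 1-29.

.zf0_first <- 54L
.zf0_last <- 82L

# One-letter sequence of the modeled construct. Positions named in the
# interface contact lists, the mutant panel (I70A, L71A/V72A, I74A, K77A,
# C81H) and the CCHC zinc-coordination motif (C58, C61, H76, C81) are fixed
# by those annotations; the remaining positions follow the UniProt context.
.zf0_seq <- c(
  "D", "L", "L", "T", "C", "G", "Q", "C", "Q", "M", "N", "F", "P", "L", "G",
  "D", "I", "L", "V", "F", "I", "E", "H", "K", "R", "K", "Q", "C", "N"
)

#' Modeled ZF0 construct sequence
#'
#' One-letter amino-acid sequence of the modeled BCL11B ZF0 construct
#' (residues 54-82, UniProt Q9C0K0 numbering), as a named character vector
#' (names are residue numbers).
#'
#' @return Named character vector of length 29.
#' @export
#' @examples
#' zf0_sequence()[c("54", "77")]
zf0_sequence <- function() {
  setNames(.zf0_seq, as.character(.zf0_first:.zf0_last))
}

#' Published interface contact lists of the ZF0 tetramer
#'
#' The residue-pair contact lists of the three core interfaces of the BCL11B
#' ZF0 tetramer: `IF-beta` (beta-sheet stacking interface of the beta-dimer,
#' including the D54-K77 charge-lock salt bridge), `IF-alpha` (hydrophobic
#' dimer-dimer interface) and `IF-gamma` (helical cross-dimer interface).
#' Pairs are ordered (first-chain residue, second-chain residue) under a
#' canonical chain-pair ordering; because the interfaces are two-fold
#' symmetric, each asymmetric pair is listed once (the mirrored orientation
#' is implied).
#'
#' @return A tibble with columns `interface`, `res_a`, `res_b`.
#' @export
#' @examples
#' reference_interfaces()
reference_interfaces <- function() {
  bind_rows(
    tibble(
      interface = "IF-beta",
      res_a = c(54L, 54L, 54L, 55L, 55L, 56L, 67L, 67L, 73L, 54L),
      res_b = c(57L, 58L, 59L, 56L, 57L, 56L, 56L, 73L, 54L, 77L)
    ),
    tibble(
      interface = "IF-alpha",
      res_a = c(67L, 67L, 67L),
      res_b = c(70L, 71L, 74L)
    ),
    tibble(
      interface = "IF-gamma",
      res_a = c(74L, 74L, 74L, 77L, 78L),
      res_b = c(73L, 74L, 77L, 78L, 78L)
    )
  )
}
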