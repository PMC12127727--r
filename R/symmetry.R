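#' Detect chain-permutation symmetry of a complex
#'
#' Enumerates every permutation of the (identical) chains and keeps those
#' whose permuted copy superposes onto the original within
#' `rmsd_tolerance`. For a perfect "dimer of dimers" (D2) tetramer this
#' yields four permutations: the identity and the three double swaps. The
#' returned set is closed under composition (a permutation group); in the
#' rare case where thresholding breaks closure, the highest-RMSD
#' non-identity permutations are dropped until closure holds (with a
#' warning). The symmetry order is the group size.
#'
#' @param complex Complex tibble (`chain`, `resid`, `x`, `y`, `z`).
#' @param rmsd_tolerance RMSD (Angstrom) below which a permuted copy counts
#'   as self-superposable. Default 1.5, well under the 3.8 Angstrom
#'   inter-site spacing.
#' @return Object of class `symmetry_result`: `order`, `permutations`
#'   (matrix, one row per group element, columns = chain slots), `rmsd` per
#'   element, and `chains`.
#' @export
#' @examples
#' fix <- assembled_frame(build_reference_topology())
#' detect_symmetry(fix)$order
detect_symmetry <- function(complex, rmsd_tolerance = 1.5) {
  if (rmsd_tolerance <= 0) abort("rmsd_tolerance must be > 0.")
  cc <- chain_coord_list(complex)
  nc <- length(cc)
  lens <- vapply(cc, nrow, integer(1))
  if (length(unique(lens)) != 1) abort("all chains must have the same length.")
  rids <- lapply(cc, rownames)
  if (!all(vapply(rids, identical, logical(1), y = rids[[1]]))) {
    abort("all chains must share the same residue ids.")
  }
  if (nc > 8) abort("refusing > 8 chains (factorial number of permutations).")
  X <- do.call(rbind, cc)
  perms <- perms_lex(nc)
  rmsds <- vapply(seq_len(nrow(perms)), function(p) {
    Y <- do.call(rbind, cc[perms[p, ]])
    kabsch_superpose(Y, X)$rmsd
  }, numeric(1))
  keep <- which(rmsds <= rmsd_tolerance)

  is_closed <- function(idx) {
    kept <- perms[idx, , drop = FALSE]
    keys <- apply(kept, 1, paste, collapse = "")
    for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
      if (!(paste(kept[i, ][kept[j, ]], collapse = "") %in% keys)) return(FALSE)
    }
    TRUE
  }
  dropped <- FALSE
  while (!is_closed(keep)) {
    worst <- keep[which.max(rmsds[keep] + ifelse(
      apply(perms[keep, , drop = FALSE], 1, function(z) all(z == seq_len(nc))),
      -Inf, 0))]
    keep <- setdiff(keep, worst)
    dropped <- TRUE
  }
  if (dropped) {
    warn("self-superposable permutations did not form a group; highest-RMSD elements dropped to restore closure.")
  }
  structure(
    list(order = length(keep),
         permutations = perms[keep, , drop = FALSE],
         rmsd = rmsds[keep],
         chains = names(cc)),
    class = "symmetry_result"
  )
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf("<symmetry_result> order %d over chains %s\n",
              x$order, paste(x$chains, collapse = "")))
  for (i in seq_len(nrow(x$permutations))) {
    cat(sprintf("  %s  (rmsd %.3f A)\n",
                paste(x$chains[x$permutations[i, ]], collapse = ""), x$rmsd[i]))
  }
  invisible(x)
}

#' Noise-free fully assembled frame of a topology
#'
#' Convenience accessor for the idealized complex (all placements realized,
#' no positional noise) as a single-frame tibble -- the fixture used for
#' symmetry detection, RMSD and crosslink-distance checks.
#'
#' @param topology An `assembly_topology`.
#' @return Tibble `chain`, `resid`, `aa`, `x`, `y`, `z`.
#' @export
assembled_frame <- function(topology) {
  assembled_coordinates(topology)
}
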