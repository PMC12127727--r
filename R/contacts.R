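#' Extract inter-chain residue contacts from an ensemble
#'
#' Records, per frame, every pair of residue sites on *different* chains
#' whose Euclidean distance is at most `cutoff`. Each contact is stored once,
#' under the canonical orientation `chain_a < chain_b` (so `res_a` lives on
#' `chain_a`). Intra-chain pairs are never reported.
#'
#' @param traj Trajectory tibble with columns `frame`, `chain`, `resid`,
#'   `x`, `y`, `z` (see [generate_trajectory()] / [read_ensemble()]).
#' @param cutoff Contact distance cutoff in Angstrom (default 8, the usual
#'   CA-contact convention for single-site-per-residue representations).
#' @return Tibble with columns `frame`, `chain_a`, `res_a`, `chain_b`,
#'   `res_b`, `distance`, carrying attributes `chains`, `residues`, `frames`
#'   and `cutoff` for downstream fingerprinting.
#' @export
#' @examples
#' traj <- generate_trajectory(config = generator_config(n_frames = 3, seed = 2))
#' head(extract_contacts(traj))
extract_contacts <- function(traj, cutoff = 8) {
  if (cutoff <= 0) abort("cutoff must be > 0.")
  if (!nrow(traj)) abort("ensemble is empty.")
  need <- c("frame", "chain", "resid", "x", "y", "z")
  if (!all(need %in% names(traj))) {
    abort(paste("trajectory must have columns:", paste(need, collapse = ", ")))
  }
  traj <- arrange(traj, .data$frame, .data$chain, .data$resid)
  frames <- unique(traj$frame)
  nf <- length(frames)
  sites <- traj[traj$frame == frames[1], c("chain", "resid")]
  ns <- nrow(sites)
  if (nrow(traj) != nf * ns) {
    abort("all frames must contain the same (chain, resid) site set.")
  }
  if (!all(is.finite(as.matrix(traj[, c("x", "y", "z")])))) {
    abort("coordinates must be finite.")
  }
  # inter-chain site pairs, canonical chain order (chain labels sort ascending)
  pair <- which(outer(sites$chain, sites$chain, "!=") & upper.tri(diag(ns)),
                arr.ind = TRUE)
  pi1 <- pair[, 1]; pi2 <- pair[, 2]
  ord <- order(sites$chain[pi1], sites$chain[pi2], sites$resid[pi1],
               sites$resid[pi2])
  pi1 <- pi1[ord]; pi2 <- pi2[ord]

  xyz <- as.matrix(traj[, c("x", "y", "z")])
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    X <- xyz[(f - 1) * ns + seq_len(ns), , drop = FALSE]
    d2 <- (X[pi1, 1] - X[pi2, 1])^2 + (X[pi1, 2] - X[pi2, 2])^2 +
      (X[pi1, 3] - X[pi2, 3])^2
    hit <- which(d2 <= cutoff^2)
    if (length(hit)) {
      res[[f]] <- tibble(
        frame = frames[f],
        chain_a = sites$chain[pi1[hit]], res_a = sites$resid[pi1[hit]],
        chain_b = sites$chain[pi2[hit]], res_b = sites$resid[pi2[hit]],
        distance = sqrt(d2[hit])
      )
    }
  }
  out <- bind_rows(res)
  if (!nrow(out)) {
    out <- tibble(frame = integer(), chain_a = character(), res_a = integer(),
                  chain_b = character(), res_b = integer(), distance = double())
  }
  attr(out, "chains") <- sort(unique(sites$chain))
  attr(out, "residues") <- sort(unique(sites$resid))
  attr(out, "frames") <- frames
  attr(out, "cutoff") <- cutoff
  out
}

# all permutations of 1..n in lexicographic order of the label sequence
perms_lex <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_lex(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# TRUE if sorted index set u is strictly lex-smaller (as a binary vector)
# than v: at the first differing column, the smaller vector carries the 0,
# i.e. its 1s start later.
fp_less <- function(u, v) {
  m <- min(length(u), length(v))
  if (m > 0) {
    i0 <- which(u[seq_len(m)] != v[seq_len(m)])
    if (length(i0)) {
      i0 <- i0[1]
      return(u[i0] > v[i0])
    }
  }
  length(u) < length(v)
}

#' Canonical chain-permutation-invariant contact fingerprints
#'
#' Encodes each frame's inter-chain contacts as a binary vector over all
#' (chain-pair slot, residue pair) columns, after relabeling the chains by
#' the permutation that makes the binary vector lexicographically minimal.
#' Because identical chains carry arbitrary labels, this canonicalization
#' guarantees that any relabeling of the input trajectory produces a
#' bit-identical fingerprint matrix. Ties between permutations are broken by
#' the lexicographically lowest chain-label sequence.
#'
#' @param contacts Output of [extract_contacts()] (its attributes supply the
#'   chain set, residue universe and frame index).
#' @param n_chains Number of chains; defaults to the chains seen by
#'   [extract_contacts()]. Refused above 8 (factorial blow-up): split the
#'   system or restrict to a sub-complex instead.
#' @return An object of class `contact_fingerprints`: list with `matrix`
#'   (frames x P binary), `pair_index` (column map: chain-pair slot and
#'   residue pair per column), `permutations` (per-frame relabeling applied),
#'   `chains`, `residues`, `cutoff`.
#' @export
contact_fingerprints <- function(contacts, n_chains = NULL) {
  chains <- attr(contacts, "chains")
  residues <- attr(contacts, "residues")
  frames <- attr(contacts, "frames")
  if (is.null(chains) || is.null(residues) || is.null(frames)) {
    abort("`contacts` must come from extract_contacts() (attributes missing).")
  }
  if (is.null(n_chains)) n_chains <- length(chains)
  if (n_chains > 8) {
    abort("refusing n_chains > 8: canonicalization enumerates n! chain permutations; analyze sub-complexes instead.")
  }
  nch <- as.integer(n_chains)
  nr <- length(residues)
  nslot <- nch * (nch - 1L) / 2L
  P <- nslot * nr * nr
  slot_of <- matrix(0L, nch, nch)
  s <- 0L
  for (u in seq_len(nch - 1L)) for (v in (u + 1L):nch) {
    s <- s + 1L
    slot_of[u, v] <- s
  }
  perms <- perms_lex(nch)

  ca <- match(contacts$chain_a, chains)
  cb <- match(contacts$chain_b, chains)
  ra <- match(contacts$res_a, residues)
  rb <- match(contacts$res_b, residues)
  byf <- split(seq_len(nrow(contacts)), factor(contacts$frame, levels = frames))

  nf <- length(frames)
  M <- matrix(0L, nf, P)
  perm_used <- character(nf)
  for (f in seq_len(nf)) {
    idx <- byf[[f]]
    if (!length(idx)) {
      perm_used[f] <- paste(seq_len(nch), collapse = "")
      next
    }
    i1 <- ca[idx]; i2 <- cb[idx]; r1 <- ra[idx]; r2 <- rb[idx]
    best <- NULL
    best_p <- 1L
    for (p in seq_len(nrow(perms))) {
      pm <- perms[p, ]
      na <- pm[i1]; nb <- pm[i2]
      flip <- na > nb
      u <- ifelse(flip, nb, na); v <- ifelse(flip, na, nb)
      a <- ifelse(flip, r2, r1); b <- ifelse(flip, r1, r2)
      cols <- sort((slot_of[cbind(u, v)] - 1L) * nr * nr + (a - 1L) * nr + b)
      if (is.null(best) || fp_less(cols, best)) {
        best <- cols
        best_p <- p
      }
    }
    M[f, best] <- 1L
    perm_used[f] <- paste(perms[best_p, ], collapse = "")
  }
  rownames(M) <- as.character(frames)

  slot_pairs <- which(upper.tri(diag(nch)), arr.ind = TRUE)
  slot_pairs <- slot_pairs[order(slot_pairs[, 1], slot_pairs[, 2]), , drop = FALSE]
  pair_index <- tibble(
    column = seq_len(P),
    slot_a = rep(slot_pairs[, 1], each = nr * nr),
    slot_b = rep(slot_pairs[, 2], each = nr * nr),
    res_a = rep(rep(residues, each = nr), times = nslot),
    res_b = rep(residues, times = nslot * nr)
  )
  structure(
    list(matrix = M, pair_index = pair_index,
         permutations = tibble(frame = frames, permutation = perm_used),
         chains = chains[seq_len(min(nch, length(chains)))],
         residues = residues, cutoff = attr(contacts, "cutoff")),
    class = "contact_fingerprints"
  )
}

#' @export
print.contact_fingerprints <- function(x, ...) {
  cat(sprintf("<contact_fingerprints> %d frames x %d pair columns (%d nonzero), cutoff %.1f A\n",
              nrow(x$matrix), ncol(x$matrix), sum(colSums(x$matrix) > 0),
              x$cutoff))
  invisible(x)
}

#' Per-contact occurrence probability over a frame subset
#'
#' The fraction of the selected frames in which each (chain-pair slot,
#' residue pair) contact is present -- the persistence used as edge weight
#' in contact networks when the subset is a cluster.
#'
#' @param fp A [contact_fingerprints()] object.
#' @param frames Frame ids to average over (default: all frames).
#' @param drop_zero Drop contacts never seen in the subset (default TRUE).
#' @return Tibble: `slot_a`, `slot_b`, `res_a`, `res_b`, `probability`.
#' @export
contact_probability <- function(fp, frames = NULL, drop_zero = TRUE) {
  stopifnot(inherits(fp, "contact_fingerprints"))
  all_frames <- as.integer(rownames(fp$matrix))
  if (is.null(frames)) frames <- all_frames
  rows <- match(frames, all_frames)
  if (!length(rows) || anyNA(rows)) abort("empty or unknown frame subset.")
  p <- colMeans(fp$matrix[rows, , drop = FALSE])
  out <- mutate(fp$pair_index, probability = p)
  if (drop_zero) out <- filter(out, .data$probability > 0)
  select(out, -"column")
}
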