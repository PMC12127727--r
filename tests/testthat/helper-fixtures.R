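# Shared fixtures, cached across test files (built once per test run).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

ref_topology <- function() cached("topo", build_reference_topology())

# medium dynamic reference ensemble used by clustering/network tests
ref_run <- function() {
  cached("ref_run", {
    topo <- ref_topology()
    traj <- generate_trajectory(topo, generator_config(n_frames = 600, seed = 421))
    contacts <- extract_contacts(traj)
    fp <- contact_fingerprints(contacts)
    pca <- ccpca(fp)
    clusters <- cluster_states(pca)
    list(topo = topo, traj = traj, contacts = contacts, fp = fp,
         pca = pca, clusters = clusters)
  })
}

# static, noise-free fully assembled ensemble
static_run <- function() {
  cached("static_run", {
    topo <- ref_topology()
    traj <- generate_trajectory(
      topo, generator_config(n_frames = 10, noise_sigma = 0, on_rate = 1,
                             off_rate = 0, seed = 7))
    contacts <- extract_contacts(traj)
    list(topo = topo, traj = traj, contacts = contacts,
         fp = contact_fingerprints(contacts))
  })
}

# tiny hand-built trajectory tibble: chains with one site per residue
toy_traj <- function(coords) {
  # coords: list of frames; each frame a data.frame chain, resid, x, y, z
  dplyr::bind_rows(lapply(seq_along(coords), function(f) {
    d <- tibble::as_tibble(coords[[f]])
    d$frame <- f
    d$aa <- "X"
    d
  }))
}

# brute-force canonical fingerprint oracle: enumerate every chain
# permutation, build the full binary vector, pick the lexicographic minimum
# (as a 0/1 string).
oracle_fingerprint <- function(contacts_frame, chains, residues) {
  nch <- length(chains)
  nr <- length(residues)
  slot_of <- matrix(0L, nch, nch)
  s <- 0L
  for (u in seq_len(nch - 1)) for (v in (u + 1):nch) {
    s <- s + 1L
    slot_of[u, v] <- s
  }
  P <- s * nr * nr
  perms <- NULL
  perm_rec <- function(prefix, rest) {
    if (!length(rest)) {
      perms[[length(perms) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (k in rest) perm_rec(c(prefix, k), setdiff(rest, k))
  }
  perm_rec(integer(), seq_len(nch))
  vecs <- lapply(perms, function(pm) {
    v <- integer(P)
    if (nrow(contacts_frame)) {
      i1 <- pm[match(contacts_frame$chain_a, chains)]
      i2 <- pm[match(contacts_frame$chain_b, chains)]
      r1 <- match(contacts_frame$res_a, residues)
      r2 <- match(contacts_frame$res_b, residues)
      flip <- i1 > i2
      u <- ifelse(flip, i2, i1); w <- ifelse(flip, i1, i2)
      a <- ifelse(flip, r2, r1); b <- ifelse(flip, r1, r2)
      v[(slot_of[cbind(u, w)] - 1L) * nr * nr + (a - 1L) * nr + b] <- 1L
    }
    v
  })
  keys <- vapply(vecs, paste, character(1), collapse = "")
  vecs[[order(keys)[1]]]
}

# relabel the chains of an extract_contacts() result (simulates relabeling
# the input trajectory), preserving the canonical chain_a < chain_b storage
relabel_contacts <- function(contacts, mapping) {
  out <- contacts
  out$chain_a <- unname(mapping[contacts$chain_a])
  out$chain_b <- unname(mapping[contacts$chain_b])
  swap <- out$chain_a > out$chain_b
  tmp_c <- out$chain_a[swap]; tmp_r <- out$res_a[swap]
  out$chain_a[swap] <- out$chain_b[swap]
  out$res_a[swap] <- out$res_b[swap]
  out$chain_b[swap] <- tmp_c
  out$res_b[swap] <- tmp_r
  attr(out, "chains") <- sort(unname(mapping[attr(contacts, "chains")]))
  attr(out, "residues") <- attr(contacts, "residues")
  attr(out, "frames") <- attr(contacts, "frames")
  attr(out, "cutoff") <- attr(contacts, "cutoff")
  out
}

# random proper rotation matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# placement contacts realized in a frame's contact set?
placement_realized <- function(contacts_frame, topo, chain_a, chain_b, interface) {
  pairs <- topo$interfaces[[interface]]$pairs
  have <- paste(contacts_frame$chain_a, contacts_frame$res_a,
                contacts_frame$chain_b, contacts_frame$res_b)
  lo <- min(chain_a, chain_b); hi <- max(chain_a, chain_b)
  want_fwd <- paste(lo, pairs$res_a, hi, pairs$res_b)
  want_rev <- paste(lo, pairs$res_b, hi, pairs$res_a)
  all(want_fwd %in% have | want_rev %in% have)
}
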