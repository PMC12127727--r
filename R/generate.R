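#' Configuration of the synthetic ensemble generator
#'
#' Defaults define the study conditions of the reference ensembles: assembly
#' bonds switch on with probability `on_rate` and off with `off_rate` per
#' frame (fast assembly, slow disassembly -- in the underlying replica
#' ensembles the tetramer, once formed, essentially never dissolved), and
#' sites carry Gaussian positional noise of `noise_sigma` Angstrom.
#'
#' @param n_frames Number of frames to generate.
#' @param noise_sigma Positional noise scale (Angstrom), applied iid per
#'   coordinate.
#' @param on_rate,off_rate Per-frame switching probabilities of each assembly
#'   bond.
#' @param seed Integer seed; identical seeds reproduce bit-identical output.
#' @param mode `"full"` (all assembly stages available), `"dimer_only"`
#'   (cross-dimer bonds suppressed -- emulates the I70A/I74A/K77A mutants,
#'   which crosslink to dimers at most), `"monomer_only"` (no bonds), or
#'   `"decoy"` (replaces a reference topology by [build_decoy_topology()]).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_frames = 2000, noise_sigma = 0.5,
                             on_rate = 0.10, off_rate = 0.01, seed = 1L,
                             mode = c("full", "dimer_only", "monomer_only", "decoy")) {
  mode <- match.arg(mode)
  if (n_frames < 1) abort("n_frames must be >= 1.")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0.")
  for (p in c(on_rate, off_rate)) {
    if (p < 0 || p > 1) abort("on_rate and off_rate must lie in [0, 1].")
  }
  structure(
    list(n_frames = as.integer(n_frames), noise_sigma = noise_sigma,
         on_rate = on_rate, off_rate = off_rate, seed = as.integer(seed),
         mode = mode),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d frames, mode=%s, noise=%.2f A, on=%.3f, off=%.3f, seed=%d\n",
              x$n_frames, x$mode, x$noise_sigma, x$on_rate, x$off_rate, x$seed))
  invisible(x)
}

#' Generate a synthetic multi-chain assembly ensemble
#'
#' Simulates reversible assembly/disassembly of the topology's chains as a
#' Markov chain over assembly bonds (one bond per beta-dimer, one for the
#' dimer-dimer association, which requires both dimers to be formed).
#' Bond states are initialized from the stationary distribution. In every
#' frame, chains connected by "on" bonds keep their reference poses (so all
#' placed interface contacts are realized), while separate components are
#' translated at least 150 Angstrom apart, putting every "off" placement far
#' beyond twice any sensible contact cutoff. Gaussian noise of scale
#' `noise_sigma` is then added to every coordinate.
#'
#' @param topology An [build_reference_topology()] / [build_decoy_topology()]
#'   object.
#' @param config A [generator_config()].
#' @return A tibble with columns `frame`, `chain`, `resid`, `aa`, `x`, `y`,
#'   `z`, carrying the bond-state history as attribute `bond_states` and the
#'   inputs as attributes `topology` and `config`.
#' @export
#' @examples
#' traj <- generate_trajectory(config = generator_config(n_frames = 5, seed = 7))
#' dplyr::count(traj, frame)
generate_trajectory <- function(topology = build_reference_topology(),
                                config = generator_config()) {
  stopifnot(inherits(topology, "assembly_topology"),
            inherits(config, "generator_config"))
  if (config$mode == "decoy" && topology$kind != "decoy") {
    topology <- build_decoy_topology(template = topology$template)
  }
  if (!identical(as.integer(rownames(topology$template)), topology$residues)) {
    abort("topology residue range is inconsistent with its template.")
  }
  bonds <- topology$bonds
  if (config$mode == "dimer_only") {
    bonds <- Filter(function(b) length(b$requires) == 0, bonds)
  } else if (config$mode == "monomer_only") {
    bonds <- list()
  }
  nb <- length(bonds)
  nf <- config$n_frames
  nc <- topology$n_chains
  nr <- length(topology$residues)
  q <- if (config$on_rate + config$off_rate > 0) {
    config$on_rate / (config$on_rate + config$off_rate)
  } else 0

  base <- lapply(topology$chains, function(ch) {
    p <- topology$poses[[ch]]
    sweep(topology$template %*% t(p$R), 2, p$t, "+")
  })
  names(base) <- topology$chains

  set.seed(config$seed)
  state <- logical(nb)
  if (nb > 0) {
    u0 <- runif(nb)
    for (b in seq_len(nb)) { # bonds ordered so prerequisites come first
      ok <- all(state[bonds[[b]]$requires])
      state[b] <- ok && (u0[b] < q)
    }
  }
  U <- if (nb > 0) matrix(runif(nf * nb), nf, nb) else matrix(0, nf, 0)
  S <- matrix(FALSE, nf, nb)
  for (f in seq_len(nf)) {
    for (b in seq_len(nb)) {
      if (!all(state[bonds[[b]]$requires])) {
        state[b] <- FALSE
      } else if (state[b]) {
        if (U[f, b] < config$off_rate) state[b] <- FALSE
      } else {
        if (U[f, b] < config$on_rate) state[b] <- TRUE
      }
    }
    S[f, ] <- state
  }

  sep <- 150
  chain_idx <- setNames(seq_len(nc), topology$chains)
  coords <- array(0, dim = c(nf, nc * nr, 3))
  for (f in seq_len(nf)) {
    comp <- seq_len(nc) # union-find over chains joined by on bonds
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (b in seq_len(nb)) {
      if (S[f, b]) {
        ids <- chain_idx[bonds[[b]]$chains]
        roots <- vapply(ids, find, integer(1))
        comp[roots] <- min(roots)
      }
    }
    roots <- vapply(seq_len(nc), find, integer(1))
    offset_id <- match(roots, sort(unique(roots)))
    for (ci in seq_len(nc)) {
      xyz <- base[[ci]]
      xyz[, 1] <- xyz[, 1] + (offset_id[ci] - 1) * sep
      coords[f, (ci - 1) * nr + seq_len(nr), ] <- xyz
    }
  }
  if (config$noise_sigma > 0) {
    coords <- coords + rnorm(length(coords), 0, config$noise_sigma)
  }

  seq1 <- zf0_sequence()
  out <- tibble(
    frame = rep(seq_len(nf), each = nc * nr),
    chain = rep(rep(topology$chains, each = nr), times = nf),
    resid = rep(rep(topology$residues, times = nc), times = nf),
    aa = rep(rep(unname(seq1[as.character(topology$residues)]), times = nc), times = nf),
    x = as.vector(t(coords[, , 1, drop = TRUE])),
    y = as.vector(t(coords[, , 2, drop = TRUE])),
    z = as.vector(t(coords[, , 3, drop = TRUE]))
  )
  attr(out, "bond_states") <- S
  attr(out, "bonds") <- lapply(bonds, function(b) b[c("id", "chains", "interfaces")])
  attr(out, "topology") <- topology
  attr(out, "config") <- config
  out
}

#' Write a representative noise-free complex structure
#'
#' Writes the fully assembled, noise-free frame of a topology as a
#' single-model PDB file (one CA-like site per residue).
#'
#' @param topology An `assembly_topology`.
#' @param path Output PDB path.
#' @param chains Chains to include (default all); e.g. `c("A", "B")` writes a
#'   single beta-dimer.
#' @return `path`, invisibly.
#' @export
write_fixture_structure <- function(topology, path, chains = topology$chains) {
  if (!all(chains %in% topology$chains)) abort("unknown chain labels.")
  co <- assembled_coordinates(topology)
  write_complex(co[co$chain %in% chains, ], path)
}
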