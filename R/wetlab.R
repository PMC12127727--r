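# Forward models of the two stoichiometry readouts: amine-reactive
# crosslinking band ladders (SDS-PAGE) and SEC stoichiometric factors.

#' Crosslinkable reactive-site pairs of a complex
#'
#' Enumerates pairs of primary-amine sites (lysines and each chain's
#' N-terminus) whose site-site distance is within the linker span plus a
#' slack accounting for sidechain reach beyond the one-site-per-residue
#' representation. Inter-chain pairs are the ones that trap oligomers on a
#' gel; intra-chain pairs (the self-reaction channel that defeats
#' crosslinking of constructs with long disordered tails) are reported
#' separately via the `linkage` column.
#'
#' @param complex Complex tibble (`chain`, `resid`, `aa`, `x`, `y`, `z`).
#' @param linker_span Linker length in Angstrom (default 21.7, the
#'   BS(PEG)5 bis-succinimide ester).
#' @param slack Extra reach in Angstrom added to the span (default 6).
#' @param reactive_aa One-letter codes of reactive residues (default "K").
#' @return Tibble `chain_a`, `res_a`, `chain_b`, `res_b`, `distance`,
#'   `linkage` (`"inter"` or `"intra"`). Zero rows (with a warning) when the
#'   complex has no reactive sites.
#' @export
crosslinkable_pairs <- function(complex, linker_span = 21.7, slack = 6,
                                reactive_aa = "K") {
  if (linker_span <= 0) abort("linker_span must be > 0.")
  need <- c("chain", "resid", "aa", "x", "y", "z")
  if (!all(need %in% names(complex))) {
    abort(paste("complex must have columns:", paste(need, collapse = ", ")))
  }
  sites <- if (nrow(complex)) {
    complex |>
      group_by(.data$chain) |>
      filter(.data$aa %in% reactive_aa | .data$resid == min(.data$resid)) |>
      ungroup() |>
      arrange(.data$chain, .data$resid)
  } else {
    complex
  }
  if (!nrow(sites)) {
    warn("no reactive residues found.")
    return(tibble(chain_a = character(), res_a = integer(),
                  chain_b = character(), res_b = integer(),
                  distance = double(), linkage = character()))
  }
  n <- nrow(sites)
  X <- as.matrix(sites[, c("x", "y", "z")])
  D <- proxy_cross_dist(X, X)
  hit <- which(upper.tri(D) & D <= linker_span + slack, arr.ind = TRUE)
  tibble(
    chain_a = sites$chain[hit[, 1]], res_a = sites$resid[hit[, 1]],
    chain_b = sites$chain[hit[, 2]], res_b = sites$resid[hit[, 2]],
    distance = D[hit],
    linkage = ifelse(sites$chain[hit[, 1]] == sites$chain[hit[, 2]],
                     "intra", "inter")
  ) |>
    arrange(.data$linkage, .data$chain_a, .data$chain_b, .data$res_a, .data$res_b)
}

#' Simulate a crosslinking band ladder
#'
#' For each simulated molecule of an oligomer, every inter-chain linkable
#' edge is crosslinked independently with probability `link_probability`;
#' denaturation then splits the molecule into its covalently connected
#' components, whose sizes are the gel bands. Only distinct species sizes
#' count as bands -- band intensities and migration are not modeled.
#'
#' @param topology Either an `assembly_topology` (linkable edges are its
#'   placements' chain pairs), a complex tibble with `aa` (edges are chain
#'   pairs with at least one inter-chain [crosslinkable_pairs()] hit), or a
#'   single integer assembly order (complete graph on that many chains).
#' @param link_probability Per-edge crosslinking probability in \[0, 1\].
#' @param n_molecules Number of molecules simulated (default 10000).
#' @param seed Integer seed (deterministic ladder per seed).
#' @param ... Passed to [crosslinkable_pairs()] when `topology` is a complex.
#' @return Tibble of class `band_ladder`: `species_size`, `count` (number of
#'   species of that size over all molecules; sizes times counts sum to
#'   `n_molecules` times the order), with attributes `n_bands`, `order`,
#'   `n_molecules`, `link_probability`.
#' @export
#' @examples
#' simulate_crosslink_ladder(4, link_probability = 0.5, n_molecules = 1000, seed = 1)
simulate_crosslink_ladder <- function(topology, link_probability,
                                      n_molecules = 10000, seed = 1L, ...) {
  if (link_probability < 0 || link_probability > 1) {
    abort("link_probability must lie in [0, 1].")
  }
  if (n_molecules < 1) abort("n_molecules must be >= 1.")
  if (inherits(topology, "assembly_topology")) {
    chains <- topology$chains
    edges <- distinct(tibble(
      a = pmin(topology$placements$chain_a, topology$placements$chain_b),
      b = pmax(topology$placements$chain_a, topology$placements$chain_b)
    ))
  } else if (is.data.frame(topology)) {
    xl <- filter(crosslinkable_pairs(topology, ...), .data$linkage == "inter")
    chains <- sort(unique(topology$chain))
    edges <- distinct(tibble(a = pmin(xl$chain_a, xl$chain_b),
                             b = pmax(xl$chain_a, xl$chain_b)))
  } else {
    order <- as.integer(topology)
    if (order < 1) abort("assembly order must be >= 1.")
    chains <- LETTERS[seq_len(order)]
    edges <- if (order > 1) {
      cp <- t(combn(chains, 2))
      tibble(a = cp[, 1], b = cp[, 2])
    } else tibble(a = character(), b = character())
  }
  nc <- length(chains)
  ne <- nrow(edges)
  ia <- match(edges$a, chains)
  ib <- match(edges$b, chains)

  # component-size multiset for each of the 2^ne edge on/off patterns
  sizes_of_pattern <- function(bits) {
    comp <- seq_len(nc)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (e in which(bits)) {
      ra <- find(ia[e]); rb <- find(ib[e])
      comp[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(nc), find, integer(1))
    as.integer(table(roots))
  }
  if (ne > 16) abort("too many linkable edges (> 16); reduce the complex.")
  npat <- 2L^ne
  pattern_sizes <- lapply(seq_len(npat) - 1L, function(code) {
    sizes_of_pattern(as.logical(bitwAnd(code, 2L^(seq_len(ne) - 1L)) > 0))
  })

  set.seed(seed)
  codes <- if (ne > 0) {
    draws <- matrix(runif(n_molecules * ne) < link_probability, n_molecules, ne)
    as.integer(draws %*% 2L^(seq_len(ne) - 1L))
  } else rep(0L, n_molecules)
  tab <- tabulate(codes + 1L, nbins = npat)
  counts <- integer(nc)
  for (pc in which(tab > 0)) {
    sz <- pattern_sizes[[pc]]
    counts <- counts + tabulate(sz, nbins = nc) * tab[pc]
  }
  out <- tibble(species_size = seq_len(nc), count = counts) |>
    filter(.data$count > 0)
  attr(out, "n_bands") <- nrow(out)
  attr(out, "order") <- nc
  attr(out, "n_molecules") <- n_molecules
  attr(out, "link_probability") <- link_probability
  class(out) <- c("band_ladder", class(out))
  out
}

#' @describeIn simulate_crosslink_ladder Number of distinct band sizes.
#' @param ladder A `band_ladder`.
#' @export
n_bands <- function(ladder) attr(ladder, "n_bands")

#' @describeIn simulate_crosslink_ladder Gel-like band plot (band intensity
#'   by species size).
#' @param object A `band_ladder`.
#' @method autoplot band_ladder
#' @export
autoplot.band_ladder <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = 1, y = factor(.data$species_size),
                               alpha = .data$count)) +
    ggplot2::geom_tile(width = 0.5, fill = "grey20") +
    ggplot2::scale_alpha_continuous(range = c(0.15, 1)) +
    ggplot2::labs(y = "species size (monomer units)", x = NULL,
                  alpha = "count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' SEC stoichiometric factor
#'
#' Apparent molecular weight from a size-exclusion-chromatography
#' calibration line (log10 MW linear in elution volume) divided by the
#' monomer molecular weight: approximately the oligomeric order for
#' globular complexes. No rounding is applied.
#'
#' @param elution_volume Elution volume (mL); vectorized.
#' @param slope,intercept Calibration line `log10(MW) = intercept + slope *
#'   volume` (user-supplied; calibration curves are instrument-specific).
#' @param monomer_mw Monomer molecular weight (Da), > 0.
#' @return Stoichiometric factor(s), dimensionless.
#' @export
#' @examples
#' sec_stoichiometric_factor(1.57, slope = -2, intercept = 7.5, monomer_mw = 6000)
sec_stoichiometric_factor <- function(elution_volume, slope, intercept,
                                      monomer_mw) {
  if (any(!is.finite(c(elution_volume, slope, intercept)))) {
    abort("calibration and volume must be finite.")
  }
  if (any(monomer_mw <= 0)) abort("monomer_mw must be > 0.")
  10^(intercept + slope * elution_volume) / monomer_mw
}
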