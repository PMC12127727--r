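#' Define an interface class
#'
#' An interface class is a named set of residue-pair contacts across one
#' chain pair, together with the number of times the class must appear in a
#' full assembly (its multiplicity). Pairs are ordered (first-chain residue,
#' second-chain residue) under a canonical chain-pair ordering; two-fold
#' symmetric interfaces list each asymmetric pair once.
#'
#' @param name Interface label.
#' @param pairs Tibble/data frame with integer columns `res_a`, `res_b`.
#' @param multiplicity_target Number of placements of this class in a full
#'   assembly.
#' @param residues Modeled residue range used for validation.
#' @return An object of class `interface_spec`.
#' @export
#' @examples
#' ref <- reference_interfaces()
#' interface_spec("IF-alpha", ref[ref$interface == "IF-alpha", c("res_a", "res_b")], 2)
interface_spec <- function(name, pairs, multiplicity_target, residues = 54:82) {
  pairs <- as_tibble(pairs)[, c("res_a", "res_b")]
  pairs$res_a <- as.integer(pairs$res_a)
  pairs$res_b <- as.integer(pairs$res_b)
  if (nrow(pairs) == 0) abort("interface pair set must be non-empty.")
  if (anyDuplicated(pairs)) abort("interface pair set contains duplicates.")
  if (!all(unlist(pairs) %in% residues)) {
    abort(sprintf("interface '%s' lists residues outside the modeled range [%d, %d].",
                  name, min(residues), max(residues)))
  }
  multiplicity_target <- as.integer(multiplicity_target)
  if (multiplicity_target < 1) abort("multiplicity_target must be positive.")
  structure(
    list(name = name, pairs = pairs, multiplicity_target = multiplicity_target),
    class = "interface_spec"
  )
}

#' @export
print.interface_spec <- function(x, ...) {
  cat(sprintf("<interface_spec> %s: %d residue pairs, multiplicity target %d\n",
              x$name, nrow(x$pairs), x$multiplicity_target))
  invisible(x)
}

new_assembly_topology <- function(chains, residues, template, poses,
                                  interfaces, placements, bonds, kind) {
  x <- structure(
    list(
      n_chains = length(chains), chains = chains, residues = residues,
      template = template, poses = poses, interfaces = interfaces,
      placements = placements, bonds = bonds, kind = kind
    ),
    class = "assembly_topology"
  )
  validate_assembly_topology(x)
  x
}

validate_assembly_topology <- function(x) {
  pl <- x$placements
  counts <- table(pl$interface)
  for (nm in names(x$interfaces)) {
    tgt <- x$interfaces[[nm]]$multiplicity_target
    got <- if (nm %in% names(counts)) counts[[nm]] else 0L
    if (got != tgt) {
      abort(sprintf("interface '%s' placed %d times but multiplicity target is %d.",
                    nm, got, tgt))
    }
  }
  key <- paste(pmin(pl$chain_a, pl$chain_b), pmax(pl$chain_a, pl$chain_b), pl$interface)
  if (anyDuplicated(key)) {
    abort("a chain pair carries two placements of the same interface.")
  }
  g <- igraph::graph_from_data_frame(
    pl[, c("chain_a", "chain_b")], directed = FALSE,
    vertices = data.frame(name = x$chains)
  )
  if (igraph::components(g)$no != 1L) {
    abort("the chain graph of a full assembly must be connected.")
  }
  invisible(x)
}

#' Reference tetramer topology (dimer of dimers)
#'
#' Builds the four-chain reference assembly: two beta-sheet-stacked dimers
#' (the beta interface on chain pairs A-B and C-D) joined into a D2-symmetric
#' tetramer by the hydrophobic dimer-dimer interface and the helical
#' cross-dimer interface, each also placed twice. Which cross-dimer chain
#' pairs carry the hydrophobic vs the helical interface is not physically
#' identifiable from contacts alone and is configurable via `alpha_pairs`.
#'
#' @param interfaces Interface contact lists (see [reference_interfaces()]).
#' @param template Rigid chain template; defaults to [fold_template()].
#' @param alpha_pairs `"AC"` (default) places the hydrophobic interface on
#'   chain pairs A-C/B-D and the helical one on A-D/B-C; `"AD"` swaps them.
#' @return An `assembly_topology` with 4 chains, 3 interface classes and 6
#'   placements.
#' @export
#' @examples
#' topo <- build_reference_topology()
#' topo$placements
build_reference_topology <- function(interfaces = reference_interfaces(),
                                     template = fold_template(),
                                     alpha_pairs = c("AC", "AD")) {
  alpha_pairs <- match.arg(alpha_pairs)
  residues <- as.integer(rownames(template))
  nms <- unique(interfaces$interface)
  if (length(nms) != 3) abort("expected exactly three interface classes.")
  specs <- lapply(nms, function(nm) {
    interface_spec(nm, interfaces[interfaces$interface == nm, ],
                   multiplicity_target = 2L, residues = residues)
  })
  names(specs) <- nms
  beta <- nms[1]; alpha <- nms[2]; gamma <- nms[3]
  if (alpha_pairs == "AC") {
    cross_a <- list(c("A", "C"), c("B", "D"))
    cross_g <- list(c("A", "D"), c("B", "C"))
    rot <- d2_rotations()
  } else {
    cross_a <- list(c("A", "D"), c("B", "C"))
    cross_g <- list(c("A", "C"), c("B", "D"))
    rot <- d2_rotations()[c("A", "B", "D", "C")]
    names(rot) <- c("A", "B", "C", "D")
  }
  placements <- tibble(
    chain_a = c("A", "C", cross_a[[1]][1], cross_a[[2]][1], cross_g[[1]][1], cross_g[[2]][1]),
    chain_b = c("B", "D", cross_a[[1]][2], cross_a[[2]][2], cross_g[[1]][2], cross_g[[2]][2]),
    interface = c(beta, beta, alpha, alpha, gamma, gamma)
  )
  poses <- lapply(rot, function(R) list(R = R, t = c(0, 0, 0)))
  bonds <- list(
    list(id = 1L, chains = c("A", "B"), interfaces = beta, requires = integer()),
    list(id = 2L, chains = c("C", "D"), interfaces = beta, requires = integer()),
    list(id = 3L, chains = c("A", "B", "C", "D"),
         interfaces = c(alpha, gamma), requires = c(1L, 2L))
  )
  new_assembly_topology(c("A", "B", "C", "D"), residues, template, poses,
                        specs, placements, bonds, kind = "reference")
}

#' Decoy (stacked-dimer) topology
#'
#' An alternative four-chain arrangement used as a negative control: two
#' beta-dimers are joined by a pure translation instead of the two-fold
#' rotations of the reference tetramer, producing cross-dimer contacts whose
#' interface classification differs from the reference one. The translation
#' offset is the smallest (searched on a fixed grid along +y) that keeps all
#' inter-dimer sites at least `min_separation` apart.
#'
#' @inheritParams build_reference_topology
#' @param cutoff Contact distance (Angstrom) used to read off the realized
#'   cross-dimer contacts.
#' @param min_separation Excluded-volume distance (Angstrom).
#' @return An `assembly_topology` of kind `"decoy"`.
#' @export
build_decoy_topology <- function(interfaces = reference_interfaces(),
                                 template = fold_template(),
                                 cutoff = 8, min_separation = 3.8) {
  residues <- as.integer(rownames(template))
  nms <- unique(interfaces$interface)
  beta <- nms[1]
  rot <- d2_rotations()
  dimer <- rbind(template, template %*% rot$B)
  s_grid <- seq(0, 60, by = 0.25)
  ok <- vapply(s_grid, function(s) {
    shifted <- sweep(dimer, 2, c(0, s, 0), "+")
    min(proxy_cross_dist(dimer, shifted)) >= min_separation
  }, logical(1))
  s <- s_grid[which(ok)[1]]
  if (is.na(s)) abort("no valid stacking offset found.")
  tvec <- c(0, s, 0)
  poses <- list(
    A = list(R = rot$A, t = c(0, 0, 0)),
    B = list(R = rot$B, t = c(0, 0, 0)),
    C = list(R = rot$A, t = tvec),
    D = list(R = rot$B, t = tvec)
  )
  coords <- lapply(poses, function(p) sweep(template %*% t(p$R), 2, p$t, "+"))
  specs <- list(interface_spec(
    beta, interfaces[interfaces$interface == beta, ],
    multiplicity_target = 2L, residues = residues
  ))
  names(specs) <- beta
  placements <- tibble(chain_a = c("A", "C"), chain_b = c("B", "D"),
                       interface = beta)
  cross <- list(c("A", "C"), c("A", "D"), c("B", "C"), c("B", "D"))
  k <- 0L
  for (cp in cross) {
    D <- proxy_cross_dist(coords[[cp[1]]], coords[[cp[2]]])
    hits <- which(D <= cutoff, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      k <- k + 1L
      nm <- paste0("stack-", k)
      specs[[nm]] <- interface_spec(
        nm, tibble(res_a = residues[hits[, 1]], res_b = residues[hits[, 2]]),
        multiplicity_target = 1L, residues = residues
      )
      placements <- bind_rows(placements,
                              tibble(chain_a = cp[1], chain_b = cp[2], interface = nm))
    }
  }
  if (k == 0L) abort("decoy stacking produced no cross-dimer contacts.")
  bonds <- list(
    list(id = 1L, chains = c("A", "B"), interfaces = beta, requires = integer()),
    list(id = 2L, chains = c("C", "D"), interfaces = beta, requires = integer()),
    list(id = 3L, chains = c("A", "B", "C", "D"),
         interfaces = setdiff(names(specs), beta), requires = c(1L, 2L))
  )
  new_assembly_topology(c("A", "B", "C", "D"), residues, template, poses,
                        specs, placements, bonds, kind = "decoy")
}

# pairwise distances between the rows of two coordinate matrices
proxy_cross_dist <- function(X, Y) {
  sq <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  sqrt(pmax(sq, 0))
}

#' @export
print.assembly_topology <- function(x, ...) {
  cat(sprintf("<assembly_topology> %s: %d chains (%s), %d interface classes, %d placements\n",
              x$kind, x$n_chains, paste(x$chains, collapse = ""),
              length(x$interfaces), nrow(x$placements)))
  print(x$placements)
  invisible(x)
}

# noise-free coordinates of the fully assembled complex, as a tidy tibble
assembled_coordinates <- function(topology) {
  seq1 <- zf0_sequence()
  purrr::map_dfr(topology$chains, function(ch) {
    p <- topology$poses[[ch]]
    xyz <- sweep(topology$template %*% t(p$R), 2, p$t, "+")
    tibble(
      chain = ch, resid = topology$residues,
      aa = unname(seq1[as.character(topology$residues)]),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  })
}
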