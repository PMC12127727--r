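# Structure I/O goes through bio3d; the package's tidy representation is one
# row per site: chain, resid, aa, x, y, z (plus frame for ensembles).

aa_three <- function(one) {
  out <- bio3d::aa123(one)
  out[is.na(out) | out == "NA"] <- "UNK"
  out
}

traj_to_xyz <- function(traj) {
  traj <- arrange(traj, .data$frame, .data$chain, .data$resid)
  frames <- unique(traj$frame)
  sites <- traj[traj$frame == frames[1], c("chain", "resid", "aa")]
  ns <- nrow(sites)
  if (nrow(traj) != length(frames) * ns) {
    abort("all frames must contain the same (chain, resid) site set.")
  }
  xyz <- matrix(t(as.matrix(traj[, c("x", "y", "z")])), nrow = length(frames),
                byrow = TRUE)
  list(frames = frames, sites = sites, xyz = xyz)
}

#' Write a complex or ensemble as (multi-model) PDB
#'
#' One CA record per site; ensembles (a `frame` column with several values)
#' become multi-model PDB files, the package's primary interchange format.
#'
#' @param x Complex or trajectory tibble (`chain`, `resid`, `aa`, `x`, `y`,
#'   `z`, optionally `frame`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_complex <- function(x, path) {
  if (!"frame" %in% names(x)) x$frame <- 1L
  parts <- traj_to_xyz(x)
  bio3d::write.pdb(
    file = path, xyz = parts$xyz,
    resno = parts$sites$resid, chain = parts$sites$chain,
    resid = aa_three(parts$sites$aa),
    elety = rep("CA", nrow(parts$sites))
  )
  invisible(path)
}

#' @rdname write_complex
#' @param traj Trajectory tibble.
#' @export
write_ensemble <- function(traj, path) write_complex(traj, path)

pdb_to_tibble <- function(pdb, path) {
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  at <- pdb$atom[sel$atom, ]
  if (!nrow(at)) abort(sprintf("no CA records found in '%s'.", path))
  if (any(!is.na(at$insert) & at$insert != "")) {
    abort(sprintf("'%s' uses insertion codes; renumber the structure first.", path))
  }
  key <- paste(at$chain, at$resno)
  if (anyDuplicated(key)) {
    abort(sprintf("residue-numbering collision in '%s' (duplicated chain/resid: %s).",
                  path, key[duplicated(key)][1]))
  }
  nmodel <- nrow(pdb$xyz)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  ns <- nrow(at)
  aa1 <- bio3d::aa321(at$resid)
  aa1[is.na(aa1)] <- "X"
  purrr::map_dfr(seq_len(nmodel), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    tibble(frame = m, chain = at$chain, resid = as.integer(at$resno),
           aa = aa1, x = co[, 1], y = co[, 2], z = co[, 3])
  }) |>
    arrange(.data$frame, .data$chain, .data$resid)
}

#' Read a single-complex structure (PDB/mmCIF)
#'
#' Reads the CA sites of a structure file into the package's tidy complex
#' representation.
#'
#' @param path A PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @return Tibble `chain`, `resid`, `aa`, `x`, `y`, `z`.
#' @export
read_complex <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'.", path))
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  out <- pdb_to_tibble(pdb, path)
  select(filter(out, .data$frame == 1L), -"frame")
}

#' Read a multi-model PDB ensemble
#'
#' @param path Multi-model PDB file (one MODEL per frame).
#' @return Trajectory tibble `frame`, `chain`, `resid`, `aa`, `x`, `y`, `z`.
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'.", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  pdb_to_tibble(pdb, path)
}

#' Export a contact network
#'
#' Writes a [build_network()] result either as GraphML (node attributes:
#' chain, residue, amino acid; edge attribute: persistence) or as an
#' edge-list CSV, chosen by file extension.
#'
#' @param net A `contact_network`.
#' @param path Output file (`.graphml` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    nodes <- distinct(bind_rows(
      tibble(chain = net$chain_a, resid = net$res_a, aa = net$aa_a),
      tibble(chain = net$chain_b, resid = net$res_b, aa = net$aa_b)
    )) |> arrange(.data$chain, .data$resid)
    nodes$name <- paste0(nodes$chain, ":", nodes$aa, nodes$resid)
    edges <- tibble(
      from = paste0(net$chain_a, ":", net$aa_a, net$res_a),
      to = paste0(net$chain_b, ":", net$aa_b, net$res_b),
      persistence = net$persistence
    )
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes[, c("name", "chain", "resid", "aa")])
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write.csv(as_tibble(net), path, row.names = FALSE)
  }
  invisible(path)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    mode = "full",
    alpha_pairs = "AC",
    n_frames = 2000L,
    noise_sigma = 0.5,
    on_rate = 0.10,
    off_rate = 0.01,
    cutoff = 8,
    variance_target = 0.9,
    max_k = 8L,
    silhouette_floor = 0.5,
    display_threshold = 0.25,
    membership_threshold = 0.5,
    merge_threshold = 0.8,
    min_edges_per_link = 3L,
    rmsd_tolerance = 1.5,
    link_probability = 0.5,
    n_molecules = 10000L,
    ensemble = NULL,  # optional multi-model PDB to analyze instead of simulating
    out_dir = NULL
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path.")
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown)) {
    abort(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defs, config, keep.null = TRUE)
  num <- c("seed", "n_frames", "noise_sigma", "on_rate", "off_rate", "cutoff",
           "variance_target", "max_k", "silhouette_floor", "display_threshold",
           "membership_threshold", "merge_threshold", "min_edges_per_link",
           "rmsd_tolerance", "link_probability", "n_molecules")
  for (f in num) {
    if (!is.numeric(out[[f]]) || length(out[[f]]) != 1) {
      abort(sprintf("config field '%s' must be a single number.", f))
    }
  }
  if (!out$mode %in% c("full", "dimer_only", "monomer_only", "decoy")) {
    abort("config field 'mode' must be full/dimer_only/monomer_only/decoy.")
  }
  out
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- force(expr)
  message(sprintf("[%s] %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the end-to-end assembly analysis pipeline
#'
#' Generate (or read) an ensemble, extract contacts, fingerprint, run ccPCA,
#' cluster, build the dominant state's persistence network, classify its
#' interfaces, infer assembly order, detect medoid-frame symmetry and
#' predict the crosslink ladder. When `out_dir` is set, all reports are
#' written there as CSV/GraphML/JSON together with a run manifest (config
#' snapshot, seed, input checksums, package version, timestamps) sufficient
#' to re-run the pipeline bit-identically.
#'
#' @param config Named list or YAML file path; see the pipeline vignette.
#'   Unknown fields are rejected.
#' @return (Invisibly) a named list with every stage's result and the
#'   manifest.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  checksums <- list()
  if (!is.null(cfg$ensemble)) {
    checksums[[cfg$ensemble]] <- unname(tools::md5sum(cfg$ensemble))
    traj <- stage("read", read_ensemble(cfg$ensemble))
    topo <- build_reference_topology(alpha_pairs = cfg$alpha_pairs)
  } else {
    topo <- if (cfg$mode == "decoy") build_decoy_topology() else {
      build_reference_topology(alpha_pairs = cfg$alpha_pairs)
    }
    gcfg <- generator_config(
      n_frames = cfg$n_frames, noise_sigma = cfg$noise_sigma,
      on_rate = cfg$on_rate, off_rate = cfg$off_rate,
      seed = cfg$seed, mode = cfg$mode
    )
    traj <- stage("simulate", generate_trajectory(topo, gcfg))
  }
  contacts <- stage("contacts", extract_contacts(traj, cutoff = cfg$cutoff))
  fp <- stage("fingerprints", contact_fingerprints(contacts))
  pca <- stage("ccpca", ccpca(fp, variance_target = cfg$variance_target))
  clusters <- stage("cluster", cluster_states(
    pca, max_k = cfg$max_k, silhouette_floor = cfg$silhouette_floor))
  dom <- dominant_cluster(clusters)
  net <- stage("network", build_network(
    fp, cluster_frames(clusters, dom$cluster),
    display_threshold = cfg$display_threshold))
  ifc <- stage("interfaces", classify_interfaces(
    fp, cluster_frames(clusters, dom$cluster),
    membership_threshold = cfg$membership_threshold,
    merge_threshold = cfg$merge_threshold))
  asm <- stage("assembly", infer_assembly_order(
    contacts, min_edges_per_link = cfg$min_edges_per_link))
  medoid <- filter(traj, .data$frame == dom$medoid_frame)
  sym <- stage("symmetry", detect_symmetry(medoid,
                                           rmsd_tolerance = cfg$rmsd_tolerance))
  ladder <- stage("xlink", simulate_crosslink_ladder(
    topo, link_probability = cfg$link_probability,
    n_molecules = cfg$n_molecules, seed = cfg$seed))

  manifest <- list(
    package = "oligofinger",
    version = as.character(utils::packageVersion("oligofinger")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_checksums = checksums
  )
  res <- list(topology = topo, trajectory = traj, contacts = contacts,
              fingerprints = fp, ccpca = pca, clusters = clusters,
              dominant = dom, network = net, interfaces = ifc,
              assembly = asm, symmetry = sym, ladder = ladder,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) write_pipeline_reports(res, cfg$out_dir)
  invisible(res)
}

write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write.csv(tidy(res$clusters), p("assignments.csv"), row.names = FALSE)
  sc <- as_tibble(res$ccpca$scores,
                  .name_repair = ~ paste0("PC", seq_len(ncol(res$ccpca$scores))))
  sc$frame <- res$ccpca$frames
  write.csv(sc, p("scores.csv"), row.names = FALSE)
  write.csv(as_tibble(res$clusters), p("cluster_summary.csv"), row.names = FALSE)
  write.csv(as_tibble(res$network), p("network_edges.csv"), row.names = FALSE)
  write_network(res$network, p("network.graphml"))
  flat <- res$interfaces
  flat$placements <- vapply(flat$placements, paste, character(1), collapse = ";")
  flat$pairs <- vapply(flat$pairs, function(d)
    paste(d$res_a, d$res_b, sep = "-", collapse = ";"), character(1))
  write.csv(flat, p("interfaces.csv"), row.names = FALSE)
  jsonlite::write_json(res$interfaces, p("interfaces.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write.csv(res$assembly$histogram, p("assembly_histogram.csv"),
            row.names = FALSE)
  write.csv(as_tibble(res$ladder), p("band_ladder.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}
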