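test_that("network edges carry persistence over cluster frames only", {
  # frame 1&2: contact present; frame 3: absent -> persistence over {1,2} is 1
  tr <- toy_traj(list(
    data.frame(chain = c("A", "B"), resid = 54L, x = c(0, 2), y = 0, z = 0),
    data.frame(chain = c("A", "B"), resid = 54L, x = c(0, 2), y = 0, z = 0),
    data.frame(chain = c("A", "B"), resid = 54L, x = c(0, 99), y = 0, z = 0)
  ))
  fp <- contact_fingerprints(extract_contacts(tr))
  net12 <- build_network(fp, c(1L, 2L), display_threshold = 0.25)
  expect_equal(nrow(net12), 1)
  expect_equal(net12$persistence, 1.0)
  expect_equal(net12$aa_a, "D") # D54, from the construct sequence
  net_all <- build_network(fp, 1:3, display_threshold = 0.7)
  expect_equal(nrow(net_all), 0) # 2/3 < 0.7
  expect_error(build_network(fp, 1:3, display_threshold = 0), "display_threshold")
  expect_error(build_network(fp, 99L), "subset")
})

test_that("the dominant state's network contains the published hydrophobic interface edges", {
  run <- ref_run()
  net <- build_network(run$fp, run$clusters)
  key <- paste(pmin(net$res_a, net$res_b), pmax(net$res_a, net$res_b))
  for (pair in c("67 70", "67 71", "67 74")) { # L67-I70, L67-L71, L67-I74
    hits <- net[key == pair, ]
    expect_gt(nrow(hits), 0)
    expect_gt(max(hits$persistence), 0.9)
  }
  # the beta-sheet charge lock is present too
  expect_true("54 77" %in% key)
})

test_that("reference ensembles classify into three interface classes of multiplicity two", {
  run <- ref_run()
  ifc <- classify_interfaces(run$fp, run$clusters)
  expect_equal(nrow(ifc), 3)
  expect_equal(ifc$multiplicity, rep(2L, 3))
  expect_setequal(ifc$best_match, c("IF-beta", "IF-alpha", "IF-gamma"))
  expect_true(all(ifc$match_recall == 1))
  # every chain-pair slot is used exactly once across classes
  expect_setequal(unlist(ifc$placements),
                  c("A-B", "C-D", "A-C", "B-D", "A-D", "B-C"))
  # classes ranked by descending total persistence
  expect_true(all(diff(ifc$total_persistence) <= 1e-12))
})

test_that("dimer-only (mutant-like) ensembles recover a single beta interface with the charge lock", {
  topo <- ref_topology()
  traj <- generate_trajectory(
    topo, generator_config(n_frames = 400, seed = 17, mode = "dimer_only"))
  fp <- contact_fingerprints(extract_contacts(traj))
  cl <- cluster_states(ccpca(fp))
  ifc <- classify_interfaces(fp, cl)
  expect_equal(nrow(ifc), 1)
  expect_equal(ifc$best_match, "IF-beta")
  keys <- paste(pmin(ifc$pairs[[1]]$res_a, ifc$pairs[[1]]$res_b),
                pmax(ifc$pairs[[1]]$res_a, ifc$pairs[[1]]$res_b))
  expect_true("54 77" %in% keys) # D54-K77
})

test_that("a dissociated state classifies to an empty interface list", {
  mono <- generate_trajectory(
    ref_topology(), generator_config(n_frames = 10, seed = 3, mode = "monomer_only"))
  fp <- suppressWarnings(contact_fingerprints(extract_contacts(mono)))
  ifc <- classify_interfaces(fp, 1:10)
  expect_equal(nrow(ifc), 0)
})

test_that("multiplicity times pair count conserves the per-slot edge total (noise-free)", {
  run <- static_run()
  ifc <- classify_interfaces(run$fp, 1:10)
  pers <- contact_probability(run$fp, 1:10)
  n_edges <- nrow(pers[pers$probability >= 0.5, ])
  expect_equal(sum(ifc$multiplicity * ifc$n_pairs), n_edges)
})

test_that("raising the membership threshold never grows a slot's pair set", {
  run <- ref_run()
  frames <- cluster_frames(run$clusters, dominant_cluster(run$clusters)$cluster)
  pers <- contact_probability(run$fp, frames)
  for (thr in list(c(0.5, 0.7), c(0.7, 0.9))) {
    lo <- pers[pers$probability >= thr[1], ]
    hi <- pers[pers$probability >= thr[2], ]
    key <- function(d) paste(d$slot_a, d$slot_b, d$res_a, d$res_b)
    expect_true(all(key(hi) %in% key(lo)))
  }
})

test_that("assembly order tracks the generator mode", {
  topo <- ref_topology()
  modes <- list(monomer_only = 1L, dimer_only = 2L)
  for (m in names(modes)) {
    traj <- generate_trajectory(
      topo, generator_config(n_frames = 150, seed = 23, mode = m))
    rep <- infer_assembly_order(extract_contacts(traj))
    expect_equal(rep$modal_order, modes[[m]])
  }
  asm <- infer_assembly_order(static_run()$contacts)
  expect_equal(asm$modal_order, 4L)
  expect_equal(sum(asm$histogram$n_frames), 10)
  expect_true(all(asm$per_frame$largest_component >= 1 &
                    asm$per_frame$largest_component <= 4))
  expect_equal(glance(asm)$modal_order, 4L)
})

test_that("sub-threshold contact counts do not link chains", {
  # 2 chains, only 2 residue contacts: below the default min_edges_per_link
  tr <- toy_traj(list(data.frame(
    chain = c("A", "A", "B", "B"), resid = c(54L, 55L, 54L, 55L),
    x = c(0, 3.8, 0, 3.8), y = c(0, 0, 2, 2), z = 0
  )))
  ct <- extract_contacts(tr, cutoff = 4)
  expect_gte(nrow(ct), 2)
  expect_equal(infer_assembly_order(ct, min_edges_per_link = 3)$modal_order, 1L)
  expect_equal(infer_assembly_order(ct, min_edges_per_link = 2)$modal_order, 2L)
})
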