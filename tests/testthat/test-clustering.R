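test_that("well-separated point clouds give two half-populated clusters with oracle medoids", {
  set.seed(123)
  a <- matrix(rnorm(200), 100, 2)
  b <- matrix(rnorm(200), 100, 2) + 30 # centers ~ 30 sigma apart
  cl <- cluster_states(rbind(a, b))
  expect_equal(nrow(cl), 2)
  expect_equal(cl$population, c(0.5, 0.5))
  asg <- tidy(cl)$cluster
  # brute-force nearest-center oracle
  oracle <- ifelse(seq_len(200) <= 100, asg[1], asg[101])
  expect_equal(asg, oracle)
  # medoid: member minimizing summed distance to members
  S <- rbind(a, b)
  for (g in 1:2) {
    rows <- which(asg == g)
    dd <- as.matrix(dist(S[rows, ]))
    expect_equal(cl$medoid_frame[g], rows[which.min(rowSums(dd))])
  }
})

test_that("identical frames collapse to a single full-population cluster", {
  S <- matrix(1.5, 40, 3)
  cl <- cluster_states(S)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$population, 1.0)
  expect_equal(dominant_cluster(cl)$cluster, 1)
})

test_that("partitions are invariant to frame order", {
  run <- ref_run()
  S <- run$pca$scores
  cl1 <- tidy(cluster_states(run$pca))
  set.seed(5)
  ord <- sample(nrow(S))
  S2 <- S[ord, , drop = FALSE]
  rownames(S2) <- rownames(S)[ord]
  cl2 <- tidy(cluster_states(S2))
  merged <- merge(cl1, cl2, by = "frame")
  # same partition as sets: the cluster relabeling must be a bijection
  tab <- table(merged$cluster.x, merged$cluster.y)
  expect_equal(sum(tab > 0), nrow(cl1 |> dplyr::distinct(cluster)))
})

test_that("three planted contact states are recovered with faithful medoids", {
  topo <- ref_topology()
  mk <- function(mode, seed) generate_trajectory(
    topo, generator_config(n_frames = 120, seed = seed, mode = mode,
                           on_rate = 1, off_rate = 0))
  tet <- mk("full", 301)
  dim2 <- mk("dimer_only", 302)
  mono <- mk("monomer_only", 303)
  dim2$frame <- dim2$frame + 120L
  mono$frame <- mono$frame + 240L
  traj <- dplyr::bind_rows(tet, dim2, mono)
  fp <- contact_fingerprints(extract_contacts(traj))
  cl <- cluster_states(ccpca(fp))
  expect_equal(nrow(cl), 3)
  expect_equal(cl$population, rep(1 / 3, 3), tolerance = 1e-12)
  # medoids realize the planted contact sets
  nz <- rowSums(fp$matrix[as.character(cl$medoid_frame), , drop = FALSE] > 0)
  states <- tidy(cl) |>
    dplyr::mutate(state = dplyr::case_when(frame <= 120 ~ "tet",
                                           frame <= 240 ~ "dim",
                                           TRUE ~ "mono"))
  purity <- states |>
    dplyr::count(cluster, state) |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(p = max(n) / sum(n))
  expect_true(all(purity$p == 1))
  med_state <- states$state[match(cl$medoid_frame, states$frame)]
  expect_equal(unname(nz[med_state == "mono"]), 0)
  expect_gt(nz[med_state == "tet"], nz[med_state == "dim"])
  expect_gt(min(nz[med_state != "mono"]), 0)
})

test_that("the dominant cluster takes the largest population, ties to the lowest id", {
  S <- rbind(matrix(rnorm(40, sd = 0.1), 20, 2),
             matrix(rnorm(40, sd = 0.1) + 50, 20, 2))
  cl <- cluster_states(S)
  expect_equal(cl$population, c(0.5, 0.5))
  expect_equal(dominant_cluster(cl)$cluster, 1) # tie -> lowest id
  uneven <- cluster_states(rbind(S, matrix(rnorm(20, sd = 0.1) + 50, 10, 2)))
  expect_equal(dominant_cluster(uneven)$population, 30 / 50)
  expect_error(dominant_cluster(uneven[0, ]), "empty")
})

test_that("rare disassembly concentrates the dominant state", {
  topo <- ref_topology()
  pop <- vapply(c(0.01, 0.15), function(off) {
    traj <- generate_trajectory(
      topo, generator_config(n_frames = 400, seed = 88, off_rate = off))
    fp <- contact_fingerprints(extract_contacts(traj))
    dominant_cluster(cluster_states(ccpca(fp)))$population
  }, numeric(1))
  expect_gt(pop[1], pop[2])
})
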