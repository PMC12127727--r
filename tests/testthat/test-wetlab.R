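test_that("crosslinkable pairs respect the linker span", {
  toy <- tibble::tibble(
    chain = c("A", "A", "B", "B"),
    resid = c(50L, 60L, 50L, 60L),
    aa = c("G", "K", "G", "K"),
    x = c(0, 0, 0, 21), y = c(0, 5, 12, 5), z = 0
  )
  # K60(A) at (0,5,0); K60(B) at (21,5,0): distance exactly 21 <= 21.7
  xl <- crosslinkable_pairs(toy, slack = 0)
  inter <- xl[xl$linkage == "inter", ]
  expect_true(any(inter$res_a == 60 & inter$res_b == 60))
  far <- toy
  far$x[4] <- 30 # 30 A > 21.7
  xl2 <- crosslinkable_pairs(far, slack = 0)
  expect_false(any(xl2$res_a == 60 & xl2$res_b == 60 & xl2$linkage == "inter"))
  # N-termini (lowest resid per chain) are reactive even though not lysine
  expect_true(any(xl$res_a == 50 | xl$res_b == 50))
  expect_warning(out <- crosslinkable_pairs(toy[0, ]), "no reactive")
  expect_equal(nrow(out), 0)
})

test_that("the tetramer fixture offers inter-chain crosslinks through K77", {
  fix <- assembled_frame(ref_topology())
  xl <- crosslinkable_pairs(fix)
  inter <- xl[xl$linkage == "inter", ]
  expect_gt(nrow(inter), 0)
  expect_true(any(inter$res_a == 77 | inter$res_b == 77))
  # intra-chain reactive pairs are reported separately, never mixed in
  expect_true(all(xl$chain_a[xl$linkage == "intra"] ==
                    xl$chain_b[xl$linkage == "intra"]))
  expect_true(all(xl$chain_a[xl$linkage == "inter"] !=
                    xl$chain_b[xl$linkage == "inter"]))
})

test_that("crosslink ladders hit the limiting band counts", {
  full <- simulate_crosslink_ladder(4, link_probability = 1,
                                    n_molecules = 2000, seed = 1)
  expect_equal(n_bands(full), 1)
  expect_equal(full$species_size, 4L)
  none <- simulate_crosslink_ladder(4, link_probability = 0,
                                    n_molecules = 2000, seed = 1)
  expect_equal(n_bands(none), 1)
  expect_equal(none$species_size, 1L)
  mid <- simulate_crosslink_ladder(4, link_probability = 0.5,
                                   n_molecules = 10000, seed = 1)
  expect_equal(n_bands(mid), 4) # monomer, dimer, trimer, tetramer
  dimer <- simulate_crosslink_ladder(2, link_probability = 0.5,
                                     n_molecules = 10000, seed = 1)
  expect_lte(n_bands(dimer), 2)
})

test_that("ladders from the assembly topology match its connectivity", {
  topo <- ref_topology()
  lad <- simulate_crosslink_ladder(topo, link_probability = 0.5,
                                   n_molecules = 10000, seed = 2)
  expect_equal(n_bands(lad), 4)
  # a structure input restricts edges to crosslinkable chain pairs
  fix <- assembled_frame(topo)
  lad2 <- simulate_crosslink_ladder(fix, link_probability = 0.5,
                                    n_molecules = 5000, seed = 2)
  expect_lte(max(lad2$species_size), 4)
  expect_error(simulate_crosslink_ladder(4, link_probability = 1.2), "link_probability")
})

test_that("no species ever exceeds the true assembly order and mass is conserved", {
  for (p in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
    lad <- simulate_crosslink_ladder(4, link_probability = p,
                                     n_molecules = 10000, seed = 31)
    expect_lte(max(lad$species_size), 4)
    expect_equal(sum(lad$species_size * lad$count), 10000 * 4)
  }
})

test_that("mean species size grows with link probability and is seed-stable", {
  mean_size <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(p) {
    lad <- simulate_crosslink_ladder(4, link_probability = p,
                                     n_molecules = 8000, seed = 5)
    sum(lad$species_size * lad$count) / sum(lad$count)
  }, numeric(1))
  expect_true(all(diff(mean_size) > 0))
  l1 <- simulate_crosslink_ladder(4, 0.5, 5000, seed = 9)
  l2 <- simulate_crosslink_ladder(4, 0.5, 5000, seed = 9)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
})

test_that("the SEC stoichiometric factor follows its closed form", {
  # calibration built so the apparent MW is exactly 4 monomers
  mw <- 6500
  vol <- 1.57
  slope <- -2.1
  intercept <- log10(4 * mw) - slope * vol
  expect_equal(sec_stoichiometric_factor(vol, slope, intercept, mw), 4.0,
               tolerance = 1e-12)
  # slope zero: volume-independent
  f <- sec_stoichiometric_factor(c(1, 2, 3), 0, 5, 1000)
  expect_equal(f, rep(1e5 / 1000, 3))
  # random triples against direct arithmetic
  set.seed(8)
  for (i in 1:20) {
    s <- rnorm(1); b <- runif(1, 3, 7); v <- runif(1, 0.5, 3); m <- runif(1, 1e3, 1e5)
    expect_equal(sec_stoichiometric_factor(v, s, b, m), 10^(b + s * v) / m,
                 tolerance = 1e-12)
  }
  expect_error(sec_stoichiometric_factor(1, 1, 1, -5), "monomer_mw")
  expect_error(sec_stoichiometric_factor(Inf, 1, 1, 5), "finite")
})
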