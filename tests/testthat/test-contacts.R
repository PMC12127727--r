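test_that("contact extraction records inter-chain pairs only, symmetrically", {
  tr <- toy_traj(list(data.frame(
    chain = c("A", "A", "B", "B"),
    resid = c(54L, 55L, 54L, 55L),
    x = c(0, 3.8, 0, 50), y = 0, z = 0
  )))
  ct <- extract_contacts(tr, cutoff = 8)
  expect_true(all(ct$chain_a != ct$chain_b))
  # A54-B54 at distance 0, A55-B54 at 3.8; B55 is 50 away from everything
  expect_setequal(paste(ct$res_a, ct$res_b), c("54 54", "55 54"))
  expect_true(all(ct$chain_a == "A" & ct$chain_b == "B"))
  # single chain: no inter-chain pairs exist
  solo <- toy_traj(list(data.frame(chain = "A", resid = 54:56,
                                   x = c(0, 1, 2), y = 0, z = 0)))
  expect_equal(nrow(extract_contacts(solo)), 0)
  expect_error(extract_contacts(tr[0, ]), "empty")
  expect_error(extract_contacts(tr, cutoff = 0), "cutoff")
})

test_that("contact sets are monotone in the cutoff", {
  traj <- ref_run()$traj[ref_run()$traj$frame <= 30, ]
  key <- function(ct) paste(ct$frame, ct$chain_a, ct$res_a, ct$chain_b, ct$res_b)
  c1 <- extract_contacts(traj, cutoff = 5)
  c2 <- extract_contacts(traj, cutoff = 8)
  c3 <- extract_contacts(traj, cutoff = 11)
  expect_true(all(key(c1) %in% key(c2)))
  expect_true(all(key(c2) %in% key(c3)))
})

test_that("the noise-free fixture carries the D54-K77 charge-lock on beta pairs", {
  run <- static_run()
  fr <- run$contacts[run$contacts$frame == 1, ]
  have <- paste(fr$chain_a, fr$res_a, fr$chain_b, fr$res_b)
  expect_true(all(c("A 54 B 77", "A 77 B 54", "C 54 D 77", "C 77 D 54") %in% have))
})

test_that("canonical fingerprints equal the brute-force permutation-enumeration oracle", {
  residues <- 54:58
  chains3 <- c("A", "B", "C")
  # 3-chain toy with a single contact
  tr <- toy_traj(list(data.frame(
    chain = rep(chains3, each = 2), resid = rep(54:55, 3),
    x = c(0, 20, 6, 40, 100, 130), y = 0, z = 0
  )))
  ct <- extract_contacts(tr, cutoff = 7)
  expect_equal(nrow(ct), 1) # only A54-B54 at 6 A
  attr(ct, "residues") <- residues
  fp <- contact_fingerprints(ct)
  oracle <- oracle_fingerprint(ct[ct$frame == 1, ], chains3, residues)
  expect_identical(as.integer(fp$matrix[1, ]), oracle)

  # randomized 4-chain toys, several frames
  set.seed(4242)
  chains4 <- c("A", "B", "C", "D")
  for (rep_i in 1:5) {
    frames <- lapply(1:3, function(f) {
      data.frame(chain = rep(chains4, each = 3), resid = rep(54:56, 4),
                 x = runif(12, 0, 18), y = runif(12, 0, 18), z = runif(12, 0, 18))
    })
    tr4 <- toy_traj(frames)
    ct4 <- extract_contacts(tr4, cutoff = 8)
    attr(ct4, "residues") <- 54:56
    fp4 <- contact_fingerprints(ct4)
    for (f in 1:3) {
      oracle4 <- oracle_fingerprint(ct4[ct4$frame == f, ], chains4, 54:56)
      expect_identical(as.integer(fp4$matrix[f, ]), oracle4)
    }
  }
})

test_that("fingerprints are bit-identical under chain relabelings", {
  run <- ref_run()
  traj <- run$traj[run$traj$frame <= 50, ]
  ct <- extract_contacts(traj)
  fp0 <- contact_fingerprints(ct)$matrix
  set.seed(77)
  for (i in 1:20) {
    pm <- sample(c("A", "B", "C", "D"))
    names(pm) <- c("A", "B", "C", "D")
    fp1 <- contact_fingerprints(relabel_contacts(ct, pm))$matrix
    expect_identical(fp0, fp1)
  }
  # an all-zero frame stays all-zero under the identity permutation
  mono <- generate_trajectory(
    ref_topology(), generator_config(n_frames = 2, seed = 1, mode = "monomer_only"))
  fpm <- contact_fingerprints(extract_contacts(mono))
  expect_true(all(fpm$matrix == 0L))
  expect_equal(fpm$permutations$permutation, c("1234", "1234"))
})

test_that("canonicalization refuses factorial blow-up beyond 8 chains", {
  tr <- toy_traj(list(data.frame(chain = LETTERS[1:9], resid = 54L,
                                 x = seq(0, 80, by = 10), y = 0, z = 0)))
  ct <- extract_contacts(tr)
  expect_error(contact_fingerprints(ct, n_chains = 9), "n_chains > 8")
})

test_that("contact probabilities are subset means with closed-form stationary occupancy", {
  # deterministic halves
  tr <- toy_traj(list(
    data.frame(chain = c("A", "B"), resid = 54L, x = c(0, 1), y = 0, z = 0),
    data.frame(chain = c("A", "B"), resid = 54L, x = c(0, 100), y = 0, z = 0)
  ))
  fp <- contact_fingerprints(extract_contacts(tr))
  pr <- contact_probability(fp)
  expect_equal(pr$probability, 0.5)
  expect_equal(contact_probability(fp, frames = 1)$probability, 1.0)
  expect_error(contact_probability(fp, frames = integer()), "empty")

  # two independent dimer bonds, each a stationary two-state Markov chain
  # with occupancy q = on / (on + off). Lexicographic minimization places a
  # lone dimer in the last chain-pair slot (3-4), and a two-dimer frame in
  # the latest available slot pairing, (1-4) + (2-3); hence
  #   P(beta contact in slot 3-4) = 2 q (1 - q)   (exactly one dimer formed)
  #   P(beta contact in slot 1-4) = q^2           (both dimers formed)
  on <- 0.2; off <- 0.2
  q <- on / (on + off)
  traj <- generate_trajectory(
    ref_topology(),
    generator_config(n_frames = 2000, seed = 202, mode = "dimer_only",
                     on_rate = on, off_rate = off, noise_sigma = 0))
  fp2 <- contact_fingerprints(extract_contacts(traj))
  pr2 <- contact_probability(fp2, drop_zero = FALSE)
  p14 <- pr2$probability[pr2$slot_a == 1 & pr2$slot_b == 4 &
                           pr2$res_a == 54 & pr2$res_b == 57]
  p34 <- pr2$probability[pr2$slot_a == 3 & pr2$slot_b == 4 &
                           pr2$res_a == 54 & pr2$res_b == 57]
  rho <- 1 - on - off
  n_eff <- 2000 * (1 - rho) / (1 + rho)
  se <- function(p) sqrt(p * (1 - p) / n_eff)
  expect_lt(abs(p34 - 2 * q * (1 - q)), 3 * se(2 * q * (1 - q)))
  expect_lt(abs(p14 - q^2), 3 * se(q^2))
})
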