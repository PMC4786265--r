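# Potentials, energies, forces and the Langevin integrator.

test_that("dihedral potential has the stated values and minimum", {
  expect_equal(dihedral_potential(0), 0)
  expect_equal(dihedral_potential(pi), 3)
  expect_equal(dihedral_potential(-pi), 3)
  grid <- seq(-pi, pi, by = 1e-4)
  v <- dihedral_potential(grid)
  expect_lt(abs(grid[which.min(v)]), 1e-4)
  expect_lt(min(v), 1e-7)
  # periodicity
  expect_equal(dihedral_potential(0.7 + 2 * pi), dihedral_potential(0.7))
})

test_that("contact potential minimum sits at r0 with depth -eps", {
  expect_equal(contact_potential(0.5, 0.5, 1), -1)
  expect_lt(abs(contact_potential(50, 0.5, 1)), 1e-10)
  # numerical derivative vanishes at r0
  h <- 1e-7
  for (form in c("lj_12_10", "gaussian")) {
    d <- (contact_potential(0.5 + h, 0.5, 1, form) -
          contact_potential(0.5 - h, 0.5, 1, form)) / (2 * h)
    expect_lt(abs(d), 1e-6)
  }
  expect_error(contact_potential(0, 0.5), "r > 0")
})

test_that("native coordinates minimize every structure-derived term", {
  top <- ci2_ca_topology()
  e <- compute_energy(top)
  expect_lt(abs(e$bonds), 1e-16)
  expect_lt(abs(e$angles), 1e-16)
  expect_lt(abs(e$dihedrals), 1e-12)
  expect_equal(e$contacts, -sum(top$contacts$eps), tolerance = 1e-10)
  expect_equal(e$total, sum(unlist(e[c("bonds", "angles", "dihedrals",
                                       "contacts", "excluded")])))
  # structure-derived forces vanish at the native state (zero out the
  # excluded volume, the only term not anchored at the native geometry)
  top0 <- top; top0$atomtypes$c12 <- 0
  expect_lt(max(abs(compute_forces(top0))), 1e-8)
})

test_that("two isolated atoms at sigma_NC feel exactly epsilon_NC", {
  xyz <- rbind(c(0, 0, 0), c(0.4, 0, 0))
  top <- bare_topology(2, xyz)
  e <- compute_energy(top, xyz)
  expect_equal(e$excluded, 1)
  expect_equal(e$total, 1)
})

test_that("energies match a slow pure-R reference on random configurations", {
  top <- ci2_ca_topology()
  set.seed(14)
  for (rep in 1:3) {
    x <- top$coords + matrix(stats::rnorm(3 * nrow(top$atoms), sd = 0.05), ncol = 3)
    got <- compute_energy(top, x)
    want <- ref_energy(top, x)
    for (term in c("bonds", "angles", "dihedrals", "contacts", "excluded", "total")) {
      expect_equal(got[[term]], want[[term]], tolerance = 1e-10, info = term)
    }
  }
})

test_that("forces are the negative energy gradient on every term", {
  top <- ci2_ca_topology()
  set.seed(15)
  x <- top$coords + matrix(stats::rnorm(3 * nrow(top$atoms), sd = 0.05), ncol = 3)
  f <- compute_forces(top, x)
  # Newton's third law
  expect_lt(max(abs(colSums(f))), 1e-9)
  # per-term finite differences on small isolated systems
  set.seed(16)
  xyz4 <- matrix(stats::rnorm(12), 4, 3)
  cases <- list(
    bonds = bare_topology(4, xyz4, bonds = data.frame(i = 1L, j = 2L, r0 = 0.38, k = 20000),
                          exclusions = all_pairs(4)),
    angles = bare_topology(4, xyz4, angles = data.frame(i = 1L, j = 2L, k = 3L,
                                                        theta0 = 1.9, ktheta = 40),
                           exclusions = all_pairs(4)),
    dihedrals = bare_topology(4, xyz4, dihedrals = data.frame(i = 1L, j = 2L, k = 3L,
                                                              l = 4L, phi0 = 0.4, kd = 1),
                              exclusions = all_pairs(4)),
    contacts = bare_topology(4, xyz4, contacts = data.frame(i = 1L, j = 3L, r0 = 0.5,
                                                            eps = 1, form = "lj_12_10",
                                                            width = NA_real_),
                             exclusions = all_pairs(4)),
    gaussian = bare_topology(4, xyz4, contacts = data.frame(i = 1L, j = 3L, r0 = 0.5,
                                                            eps = 1, form = "gaussian",
                                                            width = 0.05),
                             exclusions = all_pairs(4)),
    excluded = bare_topology(4, xyz4)
  )
  for (nm in names(cases)) {
    chk <- fd_force_dev(cases[[nm]], xyz4)
    expect_lt(chk$dev, 1e-6 * max(1, chk$scale))
  }
  # and on the full system
  full <- fd_force_dev(top, x)
  expect_lt(full$dev / full$scale, 1e-6)
})

test_that("a stretched harmonic bond pulls with eps_b * delta on each atom", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0.39))   # delta = 0.01
  top <- bare_topology(2, xyz, bonds = data.frame(i = 1L, j = 2L, r0 = 0.38, k = 20000),
                       exclusions = rbind(c(1L, 2L)))
  f <- compute_forces(top, xyz)
  expect_equal(sqrt(sum(f[1, ]^2)), 20000 * 0.01, tolerance = 1e-9)
  expect_equal(f[1, 3], 200, tolerance = 1e-9)
  expect_equal(f[2, 3], -200, tolerance = 1e-9)
})

test_that("zero-friction integration conserves energy on the dimer", {
  tset <- parse_template_set(bundled_template("sbm_ca"))
  top <- assemble_topology(make_fixture("dimer"), tset, NULL)
  x0 <- top$coords; x0[2, 3] <- x0[2, 3] + 0.001   # small stretch, E0 = 0.01
  tr <- run_langevin(top, x0, sim_params(dt = 1e-5, gamma = 0, temperature = 0,
                                         n_steps = 1e5, save_every = 500, seed = 1))
  drift <- max(tr$energies$total) - min(tr$energies$total)
  expect_lt(drift, 1e-6)
})

test_that("equipartition: bond-length variance matches k_B T / eps_b", {
  tset <- parse_template_set(bundled_template("sbm_ca"))
  top <- assemble_topology(make_fixture("dimer"), tset, NULL)
  tr <- run_langevin(top, top$coords,
                     sim_params(dt = 5e-4, gamma = 1, temperature = 1,
                                n_steps = 3e6, save_every = 100, seed = 7))
  d <- sqrt(colSums((tr$frames[2, , ] - tr$frames[1, , ])^2))
  d <- d[-(1:3000)]
  expect_equal(mean((d - 0.38)^2), 1 / 20000, tolerance = 0.05)
  # mean potential energy of the single quadratic mode is k_B T / 2
  expect_equal(mean(tr$energies$bonds[-(1:3000)]), 0.5, tolerance = 0.05)
})

test_that("trajectories are bit-identical for the same seed", {
  top <- ci2_ca_topology()
  p <- sim_params(n_steps = 5e3, save_every = 100, seed = 42, temperature = 1.1)
  tr1 <- run_langevin(top, params = p)
  tr2 <- run_langevin(top, params = p)
  expect_identical(tr1$frames, tr2$frames)
  expect_identical(tr1$energies, tr2$energies)
  tr3 <- run_langevin(top, params = sim_params(n_steps = 5e3, save_every = 100,
                                               seed = 43, temperature = 1.1))
  expect_false(identical(tr3$frames, tr2$frames))
  # frame count contract
  expect_equal(dim(tr1$frames)[3], 5e3 / 100 + 1)
})

test_that("the neighbor list loses no interacting pair within the cutoff", {
  # recompute the shifted-truncated excluded-volume sum by direct scan over
  # ALL non-excluded pairs and compare with the engine, which uses the list
  top <- ci2_ca_topology()
  rc <- 0.8
  p1 <- sim_params(n_steps = 2e4, save_every = 500, seed = 3, temperature = 1.2,
                   nb_cutoff = rc)
  tr <- run_langevin(top, params = p1)
  c12 <- top$atomtypes$c12[match(top$atoms$type, top$atomtypes$type)]
  excl_key <- paste(top$exclusions[, 1], top$exclusions[, 2])
  n <- nrow(top$atoms)
  for (fr in c(10, 20, 30, 41)) {
    xyz <- tr$frames[, , fr]
    e_ref <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (paste(i, j) %in% excl_key) next
      d2 <- sum((xyz[i, ] - xyz[j, ])^2)
      if (d2 > rc^2) next
      cc <- sqrt(c12[i] * c12[j])
      e_ref <- e_ref + cc / d2^6 - cc / rc^12
    }
    expect_equal(tr$energies$excluded[fr], e_ref, tolerance = 1e-9)
  }
})

test_that("long dimer runs reproduce the Boltzmann bond-length distribution", {
  tset <- parse_template_set(bundled_template("sbm_ca"))
  top <- assemble_topology(make_fixture("dimer"), tset, NULL)
  tr <- run_langevin(top, top$coords,
                     sim_params(dt = 5e-4, gamma = 2, temperature = 1,
                                n_steps = 2e6, save_every = 400, seed = 12))
  d <- sqrt(colSums((tr$frames[2, , ] - tr$frames[1, , ])^2))[-(1:500)]
  # analytic radial density p(r) ~ r^2 exp(-beta k (r - r0)^2 / 2)
  k <- 20000; r0 <- 0.38
  rs <- seq(r0 - 0.06, r0 + 0.06, length.out = 4001)
  dens <- rs^2 * exp(-k * (rs - r0)^2 / 2)
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  pfun <- stats::approxfun(rs, cdf, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(d, pfun))
  expect_gt(ks$p.value, 0.01)
})

test_that("coordinate blow-up aborts with a diagnostic", {
  tset <- parse_template_set(bundled_template("sbm_ca"))
  top <- assemble_topology(make_fixture("ca_helix", 8), tset, NULL)
  expect_error(run_langevin(top, params = sim_params(dt = 0.5, temperature = 5,
                                                     n_steps = 1e4, save_every = 10,
                                                     seed = 1)),
               "blow-up|non-finite")
})

test_that("reduced temperatures convert to the mdp scale", {
  expect_equal(reduced_to_mdp_temperature(1.17), 140.7, tolerance = 1e-3)
  expect_equal(reduced_to_mdp_temperature(0.97), 116.7, tolerance = 1e-3)
  # agrees with the conventional printed values 140 / 117 to the Kelvin
  expect_lt(abs(reduced_to_mdp_temperature(1.17) - 140), 1)
  expect_lt(abs(reduced_to_mdp_temperature(0.97) - 117), 1)
  expect_equal(reduced_to_mdp_temperature(0), 0)
  expect_error(reduced_to_mdp_temperature(-1), "non-negative")
})
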