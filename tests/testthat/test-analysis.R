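# Q, free-energy profiles, specific heat, contact-formation maps, COM PCA,
# folding-temperature estimation.

native_only_traj <- function(top, n_frames = 5) {
  frames <- array(rep(top$coords, n_frames), dim = c(nrow(top$coords), 3, n_frames))
  frames
}

test_that("Q is 1 at the native state, 0 when extended, and counts correctly", {
  top <- ci2_ca_topology()
  expect_true(all(compute_q(native_only_traj(top), top, 1.5)$q == 1))
  expect_true(all(compute_q(native_only_traj(top), top, 1.2)$q == 1))
  stretched <- top$coords * 10
  fr <- array(stretched, dim = c(nrow(stretched), 3, 1))
  expect_equal(compute_q(fr, top)$q, 0)
  # handcrafted 3-of-4 formed
  xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5), c(3, 3, 3))
  contacts <- data.frame(i = c(1, 1, 1, 1), j = c(2, 3, 4, 5), r0 = 0.5)
  fr <- array(xyz, dim = c(5, 3, 1))
  expect_equal(compute_q(fr, contacts, 1.5)$q, 0.75)
  expect_error(compute_q(fr, contacts[0, ]), "empty contact list")
})

test_that("Q is invariant under rigid rotation and translation", {
  top <- ci2_ca_topology()
  tr <- run_langevin(top, params = sim_params(n_steps = 2e4, save_every = 1000,
                                              seed = 5, temperature = 1.2))
  q0 <- compute_q(tr, top)$q
  th <- 0.93
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- tr$frames
  for (fr in seq_len(dim(moved)[3])) {
    moved[, , fr] <- tr$frames[, , fr] %*% R + matrix(c(5, -3, 2), nrow(top$coords), 3,
                                                      byrow = TRUE)
  }
  expect_equal(compute_q(moved, top)$q, q0, tolerance = 1e-12)
})

test_that("free-energy profiles recover constructed distributions", {
  set.seed(31)
  # uniform series -> flat profile within binning noise
  q <- stats::runif(2e5)
  prof <- free_energy_profile(q, 20)
  expect_lt(max(prof$F, na.rm = TRUE), 0.15)
  # bimodal mixture -> minima at the component means (within one bin)
  q2 <- c(pmin(pmax(stats::rnorm(1e5, 0.25, 0.05), 0), 1),
          pmin(pmax(stats::rnorm(1e5, 0.75, 0.05), 0), 1))
  prof2 <- free_energy_profile(q2, 40)
  mins <- prof2$q[order(prof2$F)][1:2]
  expect_equal(sort(mins), c(0.25, 0.75), tolerance = 0.03)
  # normalization cancels: duplicating the sample leaves F unchanged
  expect_equal(free_energy_profile(c(q2, q2), 40)$F, prof2$F, tolerance = 1e-12)
  expect_error(free_energy_profile(numeric(0)), "empty")
})

test_that("specific heat matches equipartition and finds transition peaks", {
  set.seed(41)
  # energy of a 1-D harmonic oscillator (two quadratic modes): Cv = 1
  series <- list()
  for (T in c(0.8, 1.0, 1.2)) {
    E <- T * (stats::rnorm(2e5)^2 + stats::rnorm(2e5)^2) / 2
    series[[sprintf("%.1f", T)]] <- E
  }
  cv <- specific_heat(series)
  expect_true(all(abs(cv$cv - 1) < 0.05))
  expect_error(specific_heat(series[1:2]), "at least 3")
  expect_error(specific_heat(list(`0.8` = 1, `1` = c(1, 2), `1.2` = c(1, 2))),
               "single-frame")
  # constant energy -> zero fluctuation
  cv0 <- specific_heat(list(`0.9` = rep(5, 100), `1` = rep(5, 100),
                            `1.1` = rep(5, 100)))
  expect_true(all(cv0$cv == 0))
  # two-state model: energy 0 (folded) / dE (unfolded), degeneracy g;
  # the fluctuation peak sits at the equal-population temperature
  dE <- 8; g <- exp(8)   # T_mid = dE / ln g = 1
  temps <- seq(0.7, 1.3, by = 0.1)
  ser <- lapply(temps, function(T) {
    p_unf <- g * exp(-dE / T) / (1 + g * exp(-dE / T))
    stats::rbinom(4e4, 1, p_unf) * dE
  })
  names(ser) <- sprintf("%.1f", temps)
  cv2 <- specific_heat(ser)
  expect_equal(attr(cv2, "tf"), 1.0, tolerance = 0.1 + 1e-9)  # within grid spacing
  # equal-area normalization
  cv3 <- specific_heat(ser, equal_area = TRUE)
  area <- sum(diff(cv3$temperature) * (cv3$cv[-1] + cv3$cv[-nrow(cv3)]) / 2)
  expect_equal(area, 1, tolerance = 1e-12)
})

test_that("contact-formation maps count per-contact frequencies exactly", {
  top <- ci2_ca_topology()
  qs <- compute_q(native_only_traj(top), top)
  map <- contact_formation_map(native_only_traj(top), top, qs, c(0, 1))
  expect_true(all(map$probability == 1))
  expect_true(all(contact_map_difference(map, map)$difference == 0))
  expect_error(contact_formation_map(native_only_traj(top), top, qs, c(0.1, 0.2)),
               "no frames")
  # handcrafted trajectory with known formation counts
  contacts <- data.frame(i = c(1, 1), j = c(2, 3), r0 = 0.5)
  mk_frame <- function(d12, d13) rbind(c(0, 0, 0), c(d12, 0, 0), c(0, d13, 0))
  frames <- array(NA_real_, c(3, 3, 4))
  frames[, , 1] <- mk_frame(0.5, 0.5)   # both formed
  frames[, , 2] <- mk_frame(0.5, 2.0)   # first only
  frames[, , 3] <- mk_frame(0.5, 2.0)   # first only
  frames[, , 4] <- mk_frame(2.0, 2.0)   # none
  qs2 <- compute_q(frames, contacts, 1.5)
  expect_equal(qs2$q, c(1, 0.5, 0.5, 0))
  m <- contact_formation_map(frames, contacts, qs2, c(0, 1))
  expect_equal(m$probability, c(0.75, 0.25))
})

test_that("centre-of-mass PCA separates rigid motion and satisfies the trace identity", {
  # 12 atoms in 3 domains translating along x
  n <- 12; nf <- 50
  base <- matrix(stats::rnorm(3 * n, sd = 0.3), n, 3)
  frames <- array(NA_real_, c(n, 3, nf))
  for (fr in 1:nf) frames[, , fr] <- base + cbind(rep(0.01 * fr, n), 0, 0)
  dom <- rep(1:3, each = 4)
  pca <- compute_com_pca(frames, dom)
  expect_gt(pca$eigenvalues[1] / sum(pca$eigenvalues), 0.999)
  expect_equal(sum(pca$eigenvalues), sum(apply(pca$com, 2, stats::var)),
               tolerance = 1e-12)
  expect_error(compute_com_pca(frames[, , 1, drop = FALSE], dom), "at least 2 frames")
  expect_error(compute_com_pca(frames, rep(1, 5)), "one entry per atom")
  # isotropic COM noise: eigenvalue spread concentrates with frame count
  set.seed(3)
  spread <- function(nf) {
    fr <- array(stats::rnorm(3 * 6 * nf, sd = 0.1), c(6, 3, nf))
    ev <- compute_com_pca(fr, rep(1:3, each = 2))$eigenvalues
    ev[1] / ev[length(ev)]
  }
  expect_lt(spread(20000), spread(100))
})

test_that("T_F estimation recovers a constructed logistic transition", {
  set.seed(51)
  temps <- seq(0.9, 1.4, by = 0.1)
  t_mid <- 1.13
  mk_q <- function(p_fold, n = 3e4) {
    folded <- stats::rbinom(n, 1, p_fold) == 1
    q <- numeric(n)
    q[folded] <- pmin(pmax(stats::rnorm(sum(folded), 0.85, 0.06), 0), 1)
    q[!folded] <- pmin(pmax(stats::rnorm(sum(!folded), 0.15, 0.06), 0), 1)
    q
  }
  series <- lapply(temps, function(T) mk_q(stats::plogis((t_mid - T) / 0.04)))
  names(series) <- sprintf("%.2f", temps)
  est <- estimate_tf_from_profiles(series)
  expect_equal(est$tf, t_mid, tolerance = 0.04)
  expect_gt(est$barrier, 1)
  expect_true(est$q_split > 0.3 && est$q_split < 0.7)
  # symmetric data with exactly equal basins at one temperature returns it
  qsym <- c(mk_q(1, n = 5000), mk_q(0, n = 5000))
  expect_equal(estimate_tf_from_profiles(list(`1.1` = qsym))$tf, 1.1,
               tolerance = 1e-9)
  # monotone single-basin data cannot locate a transition
  flat <- lapply(temps, function(T) pmin(pmax(stats::rnorm(5e3, 0.8, 0.05), 0), 1))
  names(flat) <- sprintf("%.2f", temps)
  expect_error(estimate_tf_from_profiles(flat), "bimodal")
})

test_that("Cv-peak and population-balance T_F agree on synthetic two-state data", {
  set.seed(61)
  dE <- 10; g <- exp(10 / 1.1)   # T_mid = 1.1
  temps <- seq(0.9, 1.3, by = 0.05)
  en <- list(); qs <- list()
  for (T in temps) {
    p_unf <- g * exp(-dE / T) / (1 + g * exp(-dE / T))
    unf <- stats::rbinom(4e4, 1, p_unf) == 1
    en[[sprintf("%.2f", T)]] <- ifelse(unf, dE, 0) + stats::rnorm(4e4, sd = 0.3)
    q <- numeric(4e4)
    q[unf] <- pmin(pmax(stats::rnorm(sum(unf), 0.15, 0.05), 0), 1)
    q[!unf] <- pmin(pmax(stats::rnorm(sum(!unf), 0.85, 0.05), 0), 1)
    qs[[sprintf("%.2f", T)]] <- q
  }
  tf_cv <- attr(specific_heat(en), "tf")
  tf_pop <- estimate_tf_from_profiles(qs)$tf
  expect_equal(tf_cv, 1.1, tolerance = 0.06)
  expect_equal(tf_pop, 1.1, tolerance = 0.06)
  expect_lt(abs(tf_cv - tf_pop), 0.08)
})

test_that("F(Q) from two halves of an equilibrated run agree", {
  # small hairpin: short correlation time, so the halves are well sampled
  tset <- parse_template_set(bundled_template("sbm_ca"))
  hp <- make_fixture("ca_hairpin", 12)
  cmap <- map_contacts_to_cg(cutoff_contact_map(hp, 0.6, 1), hp$atoms$residue, hp, 4)
  top <- assemble_topology(hp, tset, cmap)
  tr <- run_langevin(top, params = sim_params(n_steps = 4e6, save_every = 200,
                                              seed = 77, temperature = 0.8))
  q <- compute_q(tr, top)$q[-(1:2000)]
  h <- length(q) %/% 2
  p1 <- free_energy_profile(q[1:h], 8)
  p2 <- free_energy_profile(q[(h + 1):(2 * h)], 8)
  ok <- !is.na(p1$F) & !is.na(p2$F) & p1$count > 50 & p2$count > 50
  expect_gte(sum(ok), 3)
  expect_lt(max(abs(p1$F[ok] - p2$F[ok])), 0.4)
})
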