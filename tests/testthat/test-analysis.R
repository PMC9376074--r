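# Analysis stack against hand-computed and closed-form values.

test_that("contact counting follows the 0.65 nm cutoff geometry", {
  fr <- rbind(c(0, 0, 0), c(5, 0, 0), c(7, 0, 0))
  expect_equal(contacts(fr, 1, 2)$count, 1)   # 0.5 nm apart
  expect_equal(contacts(fr, 1, 3)$count, 0)   # 0.7 nm apart
  expect_equal(contacts(fr, 1, 2, cutoff_nm = 0.45)$count, 0)
  expect_error(contacts(fr, integer(), 2), "empty")
  expect_error(contacts(fr, c(1, 2), c(2, 3)), "disjoint")
  # symmetric frame equals a brute-force all-pairs scan
  set.seed(8)
  pts <- matrix(runif(60, 0, 15), 20, 3)
  sel_a <- 1:10; sel_b <- 11:20
  brute <- sum(outer(sel_a, sel_b, Vectorize(function(a, b)
    sqrt(sum((pts[a, ] - pts[b, ])^2)) <= 6.5)))
  expect_equal(contacts(pts, sel_a, sel_b)$count, brute)
})

test_that("scripted fixtures yield hand-computed binding frequencies and dissociation times", {
  sc <- make_scripted_trajectory(times = c(0, 1, 2, 3, 4),
                                 contacts_series = c(4, 3, 1, 0, 0))
  # per-frame contact series realized exactly
  cc <- vapply(sc$trajectory$frames, function(f)
    contacts(f, sc$sel_a, sc$sel_b)$count, 0L)
  expect_equal(cc, c(4, 3, 1, 0, 0))
  rec <- first_dissociation(sc$trajectory, sc$sel_a, sc$sel_b)
  expect_equal(rec$time_ns, 3)   # first zero of [4,3,1,0,0] at t=3
  expect_false(rec$censored)
  # transient zero then rebinding: first zero is reported
  sc2 <- make_scripted_trajectory(c(0, 1, 2, 3), c(2, 0, 3, 0))
  expect_equal(first_dissociation(sc2$trajectory, sc2$sel_a,
                                  sc2$sel_b)$time_ns, 1)
  # contacts never zero: censored at the campaign duration
  sc3 <- make_scripted_trajectory(c(0, 1, 2), c(2, 1, 1))
  rec3 <- first_dissociation(sc3$trajectory, sc3$sel_a, sc3$sel_b,
                             duration_ns = 5)
  expect_true(rec3$censored)
  expect_equal(rec3$time_ns, 5)
})

test_that("binding frequency pools (frame, replica) samples over the window", {
  # channel k is in contact whenever the scripted count >= k; with the full
  # window the per-channel frequency is the scripted fraction
  sc <- make_scripted_trajectory(times = 0:9,
                                 contacts_series = c(4, 4, 3, 2, 2, 1, 1, 1, 0, 0))
  sys <- list(system = list(
    beads = sc$beads,
    plastic_ids = sc$sel_b,
    dimer_ids = sc$sel_a),
    trajectory = sc$trajectory)
  # make the B beads 'plastic' and A beads 'dimer' for the profile
  sys$system$beads$entity <- rep(c("dimer", "plastic"),
                                 each = length(sc$sel_a))
  bf_full <- binding_frequency(list(sys), window_fraction = 1)
  expect_equal(bf_full$frequency, sc$expected$channel_frequency)
  # last-40% window: frames 7..10 (counts 1,1,0,0) -> channel 1 freq 0.5
  bf <- binding_frequency(list(sys), window_fraction = 0.4)
  expect_equal(bf$frequency[bf$residue == 1], 0.5)
  expect_equal(sum(bf$frequency[bf$residue > 1]), 0)
  expect_equal(attr(bf, "n_samples"), 4L)
})

test_that("dissociation summaries match hand-calculated statistics", {
  rec <- data.frame(force_pN = 10, replica = 1:4, seed = 1:4,
                    time_ns = c(1, 2, 3, 4), censored = FALSE)
  s <- dissociation_summary(rec)
  expect_equal(s$mean_ns, 2.5)
  expect_equal(s$median_ns, 2.5)
  # linear-interpolation quartiles of {1,2,3,4}
  expect_equal(s$q25_ns, 1.75)
  expect_equal(s$q75_ns, 3.25)
  # single record: mean = median = its time
  s1 <- dissociation_summary(data.frame(force_pN = 0, replica = 1, seed = 1,
                                        time_ns = 7.5, censored = FALSE))
  expect_equal(s1$mean_ns, 7.5)
  expect_equal(s1$median_ns, 7.5)
  # all-censored group is flagged and reported as a lower bound
  sc <- dissociation_summary(data.frame(force_pN = 0, replica = 1:3,
                                        seed = 1:3, time_ns = 2,
                                        censored = TRUE))
  expect_true(sc$all_censored)
  expect_equal(sc$mean_ns, 2)
  expect_true(is.na(sc$mean_observed_ns))
})

test_that("dimer angles follow dot-product geometry and rotation invariance", {
  dm <- build_synthetic_dimer(24, seed = 1)
  rmap <- dm$angle_map$s
  # constructed frames: parallel, orthogonal, antiparallel residue vectors
  fr <- dm$state$positions
  ia <- bead_ids(dm, domain = "A", role = "backbone", residues = rmap)
  ib <- bead_ids(dm, domain = "B", role = "backbone", residues = rmap)
  mk <- function(vB) {
    f <- fr
    f[ia[1], ] <- c(0, 0, 0); f[ia[2], ] <- c(1, 0, 0)
    f[ib[1], ] <- c(5, 5, 5); f[ib[2], ] <- c(5, 5, 5) + vB
    f
  }
  expect_equal(dimer_angle(mk(c(2, 0, 0)), dm), 0)
  expect_equal(dimer_angle(mk(c(0, 3, 0)), dm), 90)
  expect_equal(dimer_angle(mk(c(-1, 0, 0)), dm), 180)
  # a rigid rotation of the whole frame leaves the angle unchanged
  set.seed(21)
  for (k in 1:5) {
    R <- cgdmd:::random_rotation()
    f <- mk(c(0.3, -1.2, 0.5))
    expect_equal(dimer_angle(f %*% t(R), dm), dimer_angle(f, dm),
                 tolerance = 1e-9)
  }
  expect_error(dimer_angle(mk(c(0, 0, 0)), dm), "zero-length")
})

test_that("RMSF matches closed forms and is order-invariant", {
  # static trajectory: all RMSF zero
  fr <- matrix(rnorm(30), 10, 3)
  traj <- structure(list(times = 0:4 / 10,
                         frames = replicate(5, fr, simplify = FALSE)),
                    class = "dmd_trajectory")
  expect_equal(unname(rmsf(traj, 1:10)), rep(0, 10))
  # one bead alternating between +a and -a: RMSF = a
  a <- 1.7
  fr2 <- lapply(1:6, function(k) {
    f <- fr; f[3, 1] <- a * (-1)^k; f
  })
  traj2 <- structure(list(times = (0:5) / 10, frames = fr2),
                     class = "dmd_trajectory")
  expect_equal(unname(rmsf(traj2, 3)[1]), a)
  # invariant to frame order permutation
  perm <- c(4, 1, 6, 3, 2, 5)
  traj3 <- structure(list(times = (0:5) / 10, frames = fr2[perm]),
                     class = "dmd_trajectory")
  expect_equal(rmsf(traj3, 1:10), rmsf(traj2, 1:10))
  expect_error(rmsf(traj2, 1:3, window_ns = c(0, 0.01)), "fewer than 2")
})

test_that("gyration radius matches closed forms and the uniform-sphere law", {
  expect_equal(gyration_radius(matrix(c(1, 2, 3), 1, 3)), 0)
  # two unit-mass beads 2 A apart -> Rg = 1
  expect_equal(gyration_radius(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  # mass weighting: masses 1 and 3 at distance 4 -> com at 3, Rg = sqrt(3)
  expect_equal(gyration_radius(rbind(c(0, 0, 0), c(4, 0, 0)),
                               masses = c(1, 3)), sqrt(3))
  # Monte-Carlo oracle: uniform points in a sphere of radius R
  set.seed(5)
  n <- 1e4; R <- 7
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * R * runif(n)^(1 / 3)
  expect_equal(gyration_radius(u), R * sqrt(3 / 5), tolerance = 0.02)
  # effective diameter of that cloud is ~2R by the documented convention
  expect_equal(2 * sqrt(5 / 3) * gyration_radius(u), 2 * R,
               tolerance = 0.04)
})
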