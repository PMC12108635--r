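# Kabsch superposition, the pivot/center angular framework and trajectory
# statistics.

test_that("Kabsch superposition removes rigid motion, rejects degenerate input, and matches a rotation-grid oracle", {
  X <- rand_cloud(10, seed = 11)
  # identical sets: zero RMSD, identity rotation
  fit0 <- kabsch_superpose(X, X)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  # 90 deg z-rotation plus translation is fully removable
  Y <- sweep(X %*% t(rot_z(90)), 2, c(5, 0, 0), `+`)
  fit <- kabsch_superpose(Y, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$transform(Y), X, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # two unrelated clouds: RMSD agrees with the Euler-grid search oracle
  A <- rand_cloud(10, seed = 21); B <- rand_cloud(10, seed = 22)
  expect_equal(kabsch_superpose(A, B)$rmsd, grid_kabsch_rmsd(A, B),
               tolerance = 1e-3)
  # a mirrored cloud must come back as a proper rotation (det +1)
  M <- A; M[, 1] <- -M[, 1]
  expect_equal(det(kabsch_superpose(M, A)$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
  # cross-check against an established superposition routine
  if (requireNamespace("bio3d", quietly = TRUE)) {
    ref_fit <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.numeric(t(B)), mobile = as.numeric(t(A))))
    expect_equal(kabsch_superpose(A, B)$rmsd,
                 sqrt(mean(rowSums((matrix(ref_fit, ncol = 3, byrow = TRUE) - B)^2))),
                 tolerance = 1e-6)
  }
})

test_that("frame alignment zeroes rigid-body copies, is idempotent, and never increases RMSD", {
  s <- make_structure(rand_cloud(20, seed = 5))
  frames <- lapply(1:6, function(i)
    sweep(coords(s) %*% t(rot_axis(c(1, 1, 0), 15 * i)), 2, c(i, -i, 2), `+`))
  traj <- new_trajectory(s, frames)
  aligned <- align_frames(traj, s)
  expect_lt(max(rmsd_series(aligned, s)), 1e-6)
  # aligning twice changes nothing
  again <- align_frames(aligned, s)
  expect_lt(max(abs(again$frames[[3]] - aligned$frames[[3]])), 1e-6)
  # with internal deformation on top, alignment still never increases
  # the per-frame RMSD relative to the raw frames
  set.seed(31)
  noisy <- new_trajectory(s, lapply(frames, function(f)
    f + matrix(rnorm(length(f), sd = 0.8), nrow(f), 3)))
  raw <- rmsd_series(noisy, s)
  fit <- rmsd_series(align_frames(noisy, s), s)
  expect_true(all(fit <= raw + 1e-9))
  # one displaced atom, alignment quality vs a direct least-squares oracle
  one <- coords(s); one[7, ] <- one[7, ] + c(4, 0, 0)
  tr1 <- align_frames(new_trajectory(s, list(one)), s)
  expect_equal(rmsd_series(tr1, s)[1], grid_kabsch_rmsd(one, coords(s)),
               tolerance = 1e-3)
})

test_that("pivot and center points are coordinate means with exact arithmetic", {
  xyz <- rbind(c(1, 2, 3), c(3, -2, 5), c(0, 0, 0), c(2, 2, 2))
  s <- make_structure(xyz, resid = c(1, 2, 3, 4))
  m <- domain_map(list(VH1 = data.frame(chain = "A", start = 3, end = 4)),
                  list(c("A", 1), c("A", 2)))
  expect_equal(pivot_point(s, m), c(2, 0, 4))
  expect_equal(center_point(s, "VH1", m), c(1, 1, 1))
  # coincident anchors give the anchor point itself
  s2 <- make_structure(rbind(c(1, 1, 1), c(1, 1, 1), c(9, 9, 9)),
                       resid = c(1, 2, 3))
  expect_equal(pivot_point(s2, m), c(1, 1, 1))
  # single-atom subunit: that atom
  m1 <- domain_map(list(VH1 = data.frame(chain = "A", start = 3, end = 3)),
                   list(c("A", 1), c("A", 2)))
  expect_equal(center_point(s, "VH1", m1), c(0, 0, 0))
  # brute-force mean over a toy domain
  tb <- toy_build()
  idx <- select_atoms(tb$structure, "Fc2", tb$map)$indices
  expect_equal(center_point(tb$structure, "Fc2", tb$map),
               colMeans(coords(tb$structure)[idx, ]), tolerance = 1e-12)
  # center/pivot commute with rigid transforms
  R <- rot_axis(c(1, 2, 3), 40); tvec <- c(3, -7, 11)
  s_t <- set_coords(tb$structure,
                    sweep(coords(tb$structure) %*% t(R), 2, tvec, `+`))
  expect_equal(center_point(s_t, "scFv1", tb$map),
               as.numeric(R %*% center_point(tb$structure, "scFv1", tb$map)) + tvec,
               tolerance = 1e-9)
  expect_equal(pivot_point(s_t, tb$map),
               as.numeric(R %*% pivot_point(tb$structure, tb$map)) + tvec,
               tolerance = 1e-9)
})

test_that("XY-plane angles drop z, are symmetric, and are invariant to z-rotation and translation", {
  expect_equal(xy_angle(c(1, 0, 5), c(0, 1, -3), c(0, 0, 0)), 90)
  expect_equal(xy_angle(c(2, 0, 1), c(5, 0, -4), c(0, 0, 0)), 0)
  expect_error(xy_angle(c(0, 0, 7), c(1, 0, 0), c(0, 0, 0)), "undefined angle")
  set.seed(41)
  for (i in 1:10) {
    a <- rnorm(3); b <- rnorm(3); p <- rnorm(3)
    ang <- xy_angle(a, b, p)
    expect_equal(xy_angle(b, a, p), ang)                      # symmetry
    R <- rot_z(runif(1, 0, 360)); tvec <- rnorm(3)
    expect_equal(xy_angle(as.numeric(R %*% a) + tvec,
                          as.numeric(R %*% b) + tvec,
                          as.numeric(R %*% p) + tvec), ang, tolerance = 1e-9)
  }
})

test_that("contraction percent and z-displacement follow their definitions", {
  expect_equal(contraction_percent(10, 10), 0)
  expect_equal(contraction_percent(10, 5.33), 46.7)
  expect_equal(contraction_percent(10, 12), -20)   # extension is negative
  expect_error(contraction_percent(0, 5), "positive")
  expect_equal(z_displacement(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(z_displacement(c(0, 0, 1), c(0, 0, 38), c(0, 0, 0), c(0, 0, 0)), 37)
  # pivot and center translated equally: relative measure unchanged
  expect_equal(z_displacement(c(0, 0, 1), c(0, 0, 6), c(0, 0, 0), c(0, 0, 5)), 0)
})

test_that("RMSD series matches closed forms and a per-frame brute-force oracle", {
  s <- make_structure(rand_cloud(16, seed = 8))
  frozen <- new_trajectory(s, lapply(1:4, function(i) coords(s)))
  expect_equal(rmsd_series(frozen, s), rep(0, 4))
  # one atom displaced by d in one frame: RMSD = d / sqrt(N)
  d <- 3.7
  f2 <- coords(s); f2[5, 1] <- f2[5, 1] + d
  tr <- new_trajectory(s, list(coords(s), f2))
  expect_equal(rmsd_series(tr, s), c(0, d / sqrt(16)), tolerance = 1e-12)
  # random trajectory vs direct per-frame formula
  set.seed(51)
  frames <- lapply(1:5, function(i) coords(s) + matrix(rnorm(48), 16, 3))
  tr2 <- new_trajectory(s, frames)
  direct <- vapply(frames, function(f)
    sqrt(sum((f - coords(s))^2) / 16), numeric(1))
  expect_equal(rmsd_series(tr2, s), direct, tolerance = 1e-9)
})

test_that("per-domain RMSD separates rigid-body motion from internal deformation", {
  tb <- toy_build()
  s <- tb$structure
  # translate VH1 rigidly by 6 A
  idx <- select_atoms(s, "VH1", tb$map)$indices
  f <- coords(s); f[idx, 1] <- f[idx, 1] + 6
  tr <- new_trajectory(s, list(coords(s), f))
  dr_global <- domain_rmsd(tr, s, tb$map, subunits = "VH1", mode = "global-frame")
  dr_refit <- domain_rmsd(tr, s, tb$map, subunits = "VH1", mode = "refit")
  expect_equal(dr_global$VH1, c(0, 6), tolerance = 1e-9)
  expect_lt(dr_refit$VH1[2], 1e-9)
  expect_error(domain_rmsd(tr, s, tb$map, mode = "sideways"))
  # jittered rigid domain: refit RMSD equals the jitter's own statistic
  set.seed(61)
  noise <- matrix(rnorm(length(idx) * 3, sd = 0.5), length(idx), 3)
  f2 <- coords(s); f2[idx, ] <- f2[idx, ] + noise
  tr2 <- new_trajectory(s, list(coords(s), f2))
  refit2 <- domain_rmsd(tr2, s, tb$map, subunits = "VH1", mode = "refit")$VH1[2]
  oracle <- kabsch_superpose(f2[idx, ], coords(s)[idx, ])$rmsd
  expect_equal(refit2, oracle, tolerance = 1e-12)
  expect_lt(abs(refit2 - sqrt(mean(noise^2) * 3)), 0.15)
})

test_that("RMSF matches closed forms and the isotropic-jitter limit", {
  s <- make_structure(rand_cloud(30, seed = 12))
  frozen <- new_trajectory(s, lapply(1:3, function(i) coords(s)))
  expect_equal(rmsf(frozen)$rmsf, rep(0, 30))
  expect_error(rmsf(new_trajectory(s, list(coords(s)))), "at least 2")
  # atom alternating +a/-a in x over two frames has RMSF exactly a
  a <- 1.9
  f1 <- coords(s); f1[4, 1] <- f1[4, 1] + a
  f2 <- coords(s); f2[4, 1] <- f2[4, 1] - a
  r <- rmsf(new_trajectory(s, list(f1, f2)))
  expect_equal(r$rmsf[r$resid == 4], a, tolerance = 1e-12)
  # isotropic jitter sigma per axis converges to sigma * sqrt(3)
  sigma <- 0.3
  set.seed(71)
  frames <- lapply(1:2000, function(i)
    coords(s) + matrix(rnorm(90, sd = sigma), 30, 3))
  rj <- rmsf(new_trajectory(s, frames))
  expect_true(all(abs(rj$rmsf - sigma * sqrt(3)) / (sigma * sqrt(3)) < 0.05))
})

test_that("radius of gyration matches closed forms and the direct formula", {
  one <- make_structure(matrix(c(4, 5, 6), 1, 3))
  expect_equal(radius_of_gyration(one), 0)
  # two equal masses 2d apart: Rg = d
  d <- 2.6
  two <- make_structure(rbind(c(0, 0, 0), c(2 * d, 0, 0)), resid = 1:2)
  expect_equal(radius_of_gyration(two), d, tolerance = 1e-12)
  # random cloud with mixed elements vs the direct mass-weighted formula
  s <- make_structure(rand_cloud(20, seed = 14),
                      atom_name = rep(c("CA", "N", "O", "SD"), 5),
                      element = rep(c("C", "N", "O", "S"), 5))
  w <- s$atoms$mass
  ctr <- colSums(coords(s) * w) / sum(w)
  direct <- sqrt(sum(w * rowSums(sweep(coords(s), 2, ctr)^2)) / sum(w))
  expect_equal(radius_of_gyration(s), direct, tolerance = 1e-9)
  unw <- sqrt(mean(rowSums(sweep(coords(s), 2, colMeans(coords(s)))^2)))
  expect_equal(radius_of_gyration(s, mass_weighted = FALSE), unw,
               tolerance = 1e-9)
})

test_that("centroid frame is the medoid under pairwise superposed RMSD, ties to the lowest index", {
  s <- make_structure(rand_cloud(12, seed = 15))
  # all frames identical: first index wins
  same <- new_trajectory(s, lapply(1:4, function(i) coords(s)))
  expect_equal(centroid_frame(same), 1L)
  # two identical frames and one distant one: the first of the pair
  far <- coords(s) + 50
  tri <- new_trajectory(s, list(coords(s), coords(s), far))
  expect_equal(centroid_frame(tri), 1L)
  # 5-frame toy against an exhaustive independent pairwise matrix
  set.seed(81)
  frames <- lapply(1:5, function(i) coords(s) + matrix(rnorm(36, sd = i), 12, 3))
  tr <- new_trajectory(s, frames)
  if (requireNamespace("bio3d", quietly = TRUE)) {
    M <- matrix(0, 5, 5)
    for (i in 1:4) for (j in (i + 1):5) {
      fitted <- suppressWarnings(
        bio3d::fit.xyz(fixed = as.numeric(t(frames[[i]])),
                       mobile = as.numeric(t(frames[[j]]))))
      M[i, j] <- M[j, i] <-
        sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - frames[[i]])^2)))
    }
    expect_equal(centroid_frame(tr), which.min(rowSums(M) / 4))
  }
})

test_that("closest-frame search honours the exclusion window and matches a brute-force scan", {
  s <- make_structure(rand_cloud(12, seed = 16))
  base <- coords(s)
  # query duplicated outside the window is found with RMSD 0
  frames <- list(base + 20, base + 10, base + 5, base %*% t(rot_z(30)),
                 base + 2, base + 40, base + 60, base + 80, base + 100,
                 sweep(base %*% t(rot_z(55)), 2, c(1, 2, 3), `+`))
  frames[[4]] <- base %*% t(rot_z(170))          # make frame 4 a rigid copy
  tr <- new_trajectory(s, frames)
  res <- closest_frame(tr, query_index = 10, exclusion_window = 1)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)    # frame 4 is rigidly identical
  expect_equal(res$index, 4L)
  # monotone diverging trajectory with window 0: nearest temporal neighbour
  mono <- new_trajectory(s, lapply(1:6, function(i)
    base + matrix(2^i * seq_len(36) / 36, 12, 3)))
  expect_equal(closest_frame(mono, query_index = 6, exclusion_window = 0)$index, 5L)
  expect_error(closest_frame(mono, query_index = 3, exclusion_window = 10),
               "no candidate")
  # brute-force scan agreement on a random trajectory
  set.seed(91)
  rnd <- new_trajectory(s, lapply(1:8, function(i)
    base + matrix(rnorm(36, sd = 3), 12, 3)))
  res2 <- closest_frame(rnd, query_index = 8, exclusion_window = 1)
  brute <- vapply(1:6, function(i)
    kabsch_superpose(rnd$frames[[i]], rnd$frames[[8]])$rmsd, numeric(1))
  expect_equal(res2$index, which.min(brute))
  expect_equal(res2$rmsd, min(brute), tolerance = 1e-12)
})

test_that("geometry summaries are consistent between raw values and the comparison report", {
  tb <- toy_build()
  g0 <- geometry_summary(tb$structure, tb$map)
  expect_true(all(g0$xy_angles >= 0 & g0$xy_angles <= 180))
  expect_true(all(g0$pivot_distances >= 0))
  sc <- motion_script(list(motion_directive("scFv2", c(1, 20), contraction = 0.8),
                           motion_directive("scFv1", c(1, 20), dz = -4)))
  tr <- simulate_trajectory(tb$structure, tb$map, sc, 20, interp = tb$interp)
  g1 <- geometry_summary(frame_structure(tr, 20), tb$map)
  cmp <- comparison_summary(g0, g1)
  expect_equal(unname(cmp$contraction_percent["scFv2"]), 20, tolerance = 1e-6)
  expect_equal(unname(cmp$z_displacement["scFv1"]), -4, tolerance = 1e-9)
  expect_equal(unname(cmp$z_displacement["scFv2"]),
               unname(g1$z_offsets["scFv2"] - g0$z_offsets["scFv2"]),
               tolerance = 1e-12)
})
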