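# Hydrogen-bond / salt-bridge detection and the stand-in contact potential.

# Two short strands facing each other: backbone N (donors) on chain A,
# backbone O (acceptors) on chain B at controllable separation.
facing_strands <- function(gap = 2.9, n = 3) {
  atoms <- rbind(
    data.frame(chain = "A", resid = 1:n, resname = "ALA", atom_name = "N",
               element = "N", x = seq_len(n) * 4, y = 0, z = 0),
    data.frame(chain = "B", resid = 1:n, resname = "ALA", atom_name = "O",
               element = "O", x = seq_len(n) * 4, y = gap, z = 0))
  new_structure(atoms, label = "strands")
}

test_that("hydrogen bonds obey the distance criterion on heavy-atom structures", {
  near <- facing_strands(gap = 2.9)
  ia <- which(near$atoms$chain == "A"); ib <- which(near$atoms$chain == "B")
  hb <- find_hbonds(near, ia, ib)
  expect_equal(nrow(hb), 3)
  expect_true(all(hb$distance <= 3.5))
  far <- facing_strands(gap = 4.0)
  expect_equal(nrow(find_hbonds(far, ia, ib)), 0)
  expect_error(find_hbonds(near, ia, c(ia[1], ib)), "overlap")
  # enlarging the cutoff never loses contacts
  mid <- facing_strands(gap = 3.4)
  n1 <- nrow(find_hbonds(mid, ia, ib, d_cut = 3.5))
  n2 <- nrow(find_hbonds(mid, ia, ib, d_cut = 4.5))
  expect_gte(n2, n1)
})

test_that("hydrogen-bond lists match an all-pairs double-loop scan on a lattice", {
  set.seed(101)
  nm <- sample(c("N", "O", "OG", "NZ", "CA", "CB"), 20, replace = TRUE)
  atoms <- data.frame(
    chain = rep(c("A", "B"), each = 10), resid = rep(1:10, 2),
    resname = "SER", atom_name = nm,
    element = substr(nm, 1, 1),
    x = as.numeric(outer(0:4, c(0, 3.1), `+`))[c(1:10, 1:10)],
    y = rep(c(0, 3.0), each = 10), z = runif(20, -0.5, 0.5))
  s <- new_structure(atoms)
  ia <- 1:10; ib <- 11:20
  got <- find_hbonds(s, ia, ib)
  got_keys <- sort(paste(sub(":", " ", sub("([A-B])([0-9]+)", "\\1 \\2", got$donor)),
                         "->",
                         sub(":", " ", sub("([A-B])([0-9]+)", "\\1 \\2", got$acceptor))))
  donors <- c("N", "NZ", "NE", "NH1", "NH2", "ND1", "NE2", "ND2", "NE1",
              "OG", "OG1", "OH", "SG", "NT")
  acceptors <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH", "OXT",
                 "ND1", "NE2", "SD")
  expect_equal(got_keys, loop_hbond_pairs(s, ia, ib, donors = donors,
                                          acceptors = acceptors))
})

test_that("explicit hydrogens activate the donor-angle criterion", {
  # donor N with H pointing at the acceptor: detected
  atoms <- data.frame(
    chain = c("A", "A", "B"), resid = c(1, 1, 2), resname = "ALA",
    atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
    x = c(0, 1.0, 2.9), y = 0, z = 0)
  s <- new_structure(atoms)
  hb <- find_hbonds(s, 1:2, 3)
  expect_equal(nrow(hb), 1)
  expect_gt(hb$angle, 170)
  # H pointing away: the same geometry is rejected
  atoms$x[2] <- -1.0
  s2 <- new_structure(atoms)
  expect_equal(nrow(find_hbonds(s2, 1:2, 3)), 0)
})

test_that("salt bridges pair basic nitrogens with acidic oxygens inside 4 A", {
  mk <- function(d) new_structure(data.frame(
    chain = c("A", "B"), resid = c(89, 238), resname = c("GLU", "LYS"),
    atom_name = c("OE1", "NZ"), element = c("O", "N"),
    x = c(0, d), y = 0, z = 0))
  sb <- find_salt_bridges(mk(3.5), 1, 2)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 3.5, tolerance = 1e-9)
  expect_equal(nrow(find_salt_bridges(mk(4.5), 1, 2)), 0)
  # a glutamate carboxylate 3.0 A from a lysine amine registers as both a
  # salt bridge and a (distance-criterion) hydrogen bond
  close <- mk(3.0)
  expect_equal(nrow(find_salt_bridges(close, 1, 2)), 1)
  expect_equal(nrow(find_hbonds(close, 1, 2)), 1)
})

test_that("the stand-in pair energy matches closed form, double loop, symmetry and rigid invariance", {
  # two opposite unit charges at 5 A, LJ off: -332.0636 / (4 * 25)
  qp <- list("QP" = c(q = 1, eps = 0, rmin2 = 1),
             "QM" = c(q = -1, eps = 0, rmin2 = 1))
  s <- new_structure(data.frame(
    chain = c("A", "B"), resid = 1:2, resname = "ALA",
    atom_name = c("QP", "QM"), element = "C", x = c(0, 5), y = 0, z = 0))
  expect_equal(pair_energy(s, 1, 2, lj = FALSE, params = qp),
               -332.0636 / 100, tolerance = 1e-9)
  expect_equal(pair_energy(s, 1, 2, params = qp),
               pair_energy(s, 2, 1, params = qp), tolerance = 1e-12)
  # beyond the cutoff the energy is exactly zero
  s_far <- set_coords(s, rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(pair_energy(s_far, 1, 2, params = qp), 0)
  # 30-atom toy vs the unvectorized double loop
  set.seed(111)
  nm30 <- sample(c("N", "CA", "C", "O", "NZ", "OE1"), 30, replace = TRUE)
  tab <- list("N" = c(q = -0.47, eps = 0.2, rmin2 = 1.85),
              "CA" = c(q = 0.07, eps = 0.02, rmin2 = 2.275),
              "C" = c(q = 0.51, eps = 0.11, rmin2 = 2.0),
              "O" = c(q = -0.51, eps = 0.12, rmin2 = 1.7),
              "NZ" = c(q = 0.8, eps = 0.2, rmin2 = 1.85),
              "OE1" = c(q = -0.6, eps = 0.12, rmin2 = 1.7))
  s30 <- new_structure(data.frame(
    chain = rep(c("A", "B"), each = 15), resid = rep(1:15, 2),
    resname = "LYS", atom_name = nm30, element = substr(nm30, 1, 1),
    x = runif(30, 0, 12), y = runif(30, 0, 12), z = runif(30, 0, 12)))
  ia <- 1:15; ib <- 16:30
  expect_equal(pair_energy(s30, ia, ib, params = tab),
               loop_pair_energy(s30, ia, ib, tab), tolerance = 1e-9)
  # whole-structure rigid transform leaves energies and contacts unchanged
  R <- rot_axis(c(2, -1, 1), 77)
  s30_t <- set_coords(s30, sweep(coords(s30) %*% t(R), 2, c(5, 6, 7), `+`))
  expect_equal(pair_energy(s30_t, ia, ib, params = tab),
               pair_energy(s30, ia, ib, params = tab), tolerance = 1e-9)
  expect_equal(nrow(find_hbonds(s30_t, ia, ib)), nrow(find_hbonds(s30, ia, ib)))
  expect_error(pair_energy(s30, ia, ib, params = tab["N"]), "unparameterized")
})

test_that("percent change uses magnitudes with attraction-positive convention", {
  expect_equal(percent_change(-100, -248), 148)
  expect_equal(percent_change(-100, -100), 0)
  expect_equal(percent_change(-100, -77), -23)
  expect_warning(out <- percent_change(0, -5), "undefined")
  expect_true(is.na(out))
})

test_that("the interaction summary is self-consistent and counts engineered linker contacts", {
  tb <- toy_build()
  # identical conformations: zero percent changes, identical contact lists
  rep0 <- interaction_summary(tb$structure, tb$structure, tb$map)
  for (p in rep0$pairs) {
    if (!is.na(p$percent_change)) expect_equal(p$percent_change, 0, tolerance = 1e-9)
    expect_identical(p$hbonds_start, p$hbonds_end)
  }
  expect_identical(rep0$linker_hbond_count$start,
                   rep0$linker_hbond_count$representative)
  # a "locked linkers" pose with 8 engineered donor-acceptor pairs at 3.0 A:
  # replace the linker beads (5+5 GLY CAs) by 8 N/O pairs via a custom map
  atoms <- rbind(
    data.frame(chain = "A", resid = 1:10, resname = "ALA", atom_name = "CA",
               element = "C", x = 1:10 * 8, y = -30, z = 0),
    data.frame(chain = "A", resid = 41:48, resname = "SER", atom_name = "N",
               element = "N", x = 1:8 * 4, y = 0, z = 0),
    data.frame(chain = "B", resid = 1:10, resname = "ALA", atom_name = "CA",
               element = "C", x = 1:10 * 8, y = 33, z = 0),
    data.frame(chain = "B", resid = 41:48, resname = "SER", atom_name = "O",
               element = "O", x = 1:8 * 4, y = 3.0, z = 0))
  locked <- new_structure(atoms, label = "locked-linkers")
  lmap <- domain_map(
    list(VH1 = data.frame(chain = "A", start = 1, end = 5),
         VL1 = data.frame(chain = "A", start = 6, end = 10),
         linker1 = data.frame(chain = "A", start = 41, end = 48),
         VH2 = data.frame(chain = "B", start = 1, end = 5),
         VL2 = data.frame(chain = "B", start = 6, end = 10),
         linker2 = data.frame(chain = "B", start = 41, end = 48),
         Fc1 = data.frame(chain = "A", start = 100, end = 101),
         Fc2 = data.frame(chain = "B", start = 100, end = 101)),
    list(c("A", 41), c("B", 41)))
  expect_equal(nrow(find_hbonds(locked, "linker1", "linker2", map = lmap)), 8)
  # report totals equal independently recomputed pair energies
  sc <- motion_script(motion_directive("scFv1", c(1, 10), contraction = 0.7))
  tr <- simulate_trajectory(tb$structure, tb$map, sc, 10, interp = tb$interp)
  rep1 <- interaction_summary(frame_structure(tr, 1), frame_structure(tr, 10),
                              tb$map)
  direct <- pair_energy(frame_structure(tr, 10), "scFv1", "scFv2",
                        map = tb$map)
  expect_equal(rep1$pairs[["scFv1-scFv2"]]$e_end, direct, tolerance = 1e-12)
})
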