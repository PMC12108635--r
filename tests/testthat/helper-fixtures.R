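# Shared fixtures: hand-written PDB records, tiny structures, and
# independent oracles (rotation-grid Kabsch, double-loop energies).

pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     occ = 1, altloc = " ", element = "") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, altloc, resname, chain, resid, x, y, z, occ, 0, element)
}

make_structure <- function(xyz, chain = "A", resid = seq_len(nrow(xyz)),
                           resname = "ALA", atom_name = "CA",
                           element = "C", label = "toy") {
  xyz <- as.matrix(xyz)
  new_structure(data.frame(
    chain = chain, resid = resid, resname = resname, atom_name = atom_name,
    element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE), label = label)
}

rand_cloud <- function(n, seed = 1, scale = 5) {
  set.seed(seed)
  matrix(rnorm(n * 3, sd = scale), n, 3)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

rot_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2)); th <- deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (u %o% u)
}

# Independent minimum-RMSD oracle: multi-start Nelder-Mead over ZYZ Euler
# angles, translation removed by centring.  Never touches the svd route.
grid_kabsch_rmsd <- function(mobile, reference) {
  A <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  B <- sweep(as.matrix(reference), 2, colMeans(reference))
  euler <- function(p) rot_z(p[1] * 180 / pi) %*%
    rot_axis(c(0, 1, 0), p[2] * 180 / pi) %*% rot_z(p[3] * 180 / pi)
  obj <- function(p) {
    R <- euler(p)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  starts <- expand.grid(a = seq(0, 1.5, by = 0.5) * pi,
                        b = seq(0, 1, by = 1 / 3) * pi,
                        c = seq(0, 1.5, by = 0.5) * pi)
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 3000))
    best <- min(best, o$value)
  }
  best
}

# Unvectorized double-loop stand-in energy with an explicit parameter table
# (named list of c(q, eps, rmin2) keyed by atom name).
loop_pair_energy <- function(structure, ia, ib, params, cutoff = 12,
                             lj = TRUE) {
  a <- structure$atoms
  xyz <- coords(structure)
  e <- 0
  for (i in ia) for (j in ib) {
    pi_ <- params[[a$atom_name[i]]]; pj <- params[[a$atom_name[j]]]
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r > cutoff || r == 0) next
    e <- e + 332.0636 * pi_["q"] * pj["q"] / (4 * r^2)
    if (lj) {
      epsij <- sqrt(pi_["eps"] * pj["eps"])
      rmin <- pi_["rmin2"] + pj["rmin2"]
      e <- e + epsij * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  unname(e)
}

# Double-loop hydrogen-bond scan with the heavy-atom distance criterion.
loop_hbond_pairs <- function(structure, ia, ib, d_cut = 3.5,
                             donors, acceptors) {
  a <- structure$atoms
  xyz <- coords(structure)
  found <- character(0)
  for (pair in list(c("a", "b"), c("b", "a"))) {
    ii <- if (pair[1] == "a") ia else ib
    jj <- if (pair[1] == "a") ib else ia
    for (i in ii) for (j in jj) {
      if (!(a$atom_name[i] %in% donors)) next
      if (!(a$atom_name[j] %in% acceptors)) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r <= d_cut)
        found <- c(found, paste(a$chain[i], a$resid[i], a$atom_name[i], "->",
                                a$chain[j], a$resid[j], a$atom_name[j]))
    }
  }
  sort(unique(found))
}

# Default WT-like toy build shared across geometry/pipeline tests.
toy_build <- function(seed = 1, atoms_per_domain = 30)
  build_toy_scfvfc(toy_build_config(atoms_per_domain = atoms_per_domain,
                                    seed = seed))
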