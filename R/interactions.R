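# Interchain contact detection and a transparent stand-in contact potential.
#
# Hydrogen bonds use geometric criteria (donor-acceptor distance, optional
# D-H...A angle when hydrogens are present).  Salt bridges pair basic
# nitrogens with acidic oxygens.  Group-group energies come from a
# deliberately simple pairwise potential -- Coulomb with distance-dependent
# dielectric eps(r) = 4r plus 12-6 Lennard-Jones with a small built-in
# parameter table -- so that percent-change bookkeeping between
# conformations is fully reproducible.  Energies are labelled "stand-in
# potential" in reports: they are a transparent surrogate, not a force
# field.

.COULOMB_K <- 332.0636   # kcal mol^-1 A e^-2

# Donor-capable and acceptor-capable heavy-atom names (heavy-atom criterion;
# explicit hydrogens refine donors via the angle test when present).
.hb_donor_names <- c("N", "NZ", "NE", "NH1", "NH2", "ND1", "NE2", "ND2",
                     "NE1", "OG", "OG1", "OH", "SG", "NT")
.hb_acceptor_names <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                        "OXT", "ND1", "NE2", "SD")

.sb_basic_names <- c(LYS = "NZ", ARG = "NE", ARG = "NH1", ARG = "NH2",
                     HIS = "ND1", HIS = "NE2")
.sb_acidic_names <- c(ASP = "OD1", ASP = "OD2", GLU = "OE1", GLU = "OE2")

# Stand-in nonbonded parameters: partial charge (e), LJ well depth
# (kcal/mol) and Rmin/2 (A), CHARMM-flavoured magnitudes.  Lookup is
# "RESNAME:ATOM" first, then bare atom name, then an element-class default.
.nb_params <- local({
  p <- function(q, eps, rmin2) c(q = q, eps = eps, rmin2 = rmin2)
  list(
    "N"   = p(-0.47, 0.20, 1.85),
    "CA"  = p( 0.07, 0.02, 2.275),
    "C"   = p( 0.51, 0.11, 2.00),
    "O"   = p(-0.51, 0.12, 1.70),
    "OXT" = p(-0.67, 0.12, 1.70),
    "CB"  = p(-0.10, 0.055, 2.175),
    "CG"  = p(-0.10, 0.055, 2.175),
    "CG1" = p(-0.10, 0.055, 2.175),
    "CG2" = p(-0.10, 0.055, 2.175),
    "CD"  = p(-0.10, 0.055, 2.175),
    "CD1" = p(-0.10, 0.055, 2.175),
    "CD2" = p(-0.10, 0.055, 2.175),
    "CE"  = p( 0.10, 0.055, 2.175),
    "CE1" = p(-0.10, 0.055, 2.175),
    "CE2" = p(-0.10, 0.055, 2.175),
    "CE3" = p(-0.10, 0.055, 2.175),
    "CZ"  = p( 0.10, 0.055, 2.175),
    "CZ2" = p(-0.10, 0.055, 2.175),
    "CZ3" = p(-0.10, 0.055, 2.175),
    "CH2" = p(-0.10, 0.055, 2.175),
    "OG"  = p(-0.66, 0.152, 1.77),
    "OG1" = p(-0.66, 0.152, 1.77),
    "OH"  = p(-0.54, 0.152, 1.77),
    "SG"  = p(-0.23, 0.45, 2.00),
    "SD"  = p(-0.09, 0.45, 2.00),
    "NZ"  = p( 0.80, 0.20, 1.85),   # Lys ammonium (heavy-atom lumped)
    "NE"  = p( 0.20, 0.20, 1.85),
    "NH1" = p( 0.40, 0.20, 1.85),
    "NH2" = p( 0.40, 0.20, 1.85),
    "ND1" = p(-0.36, 0.20, 1.85),
    "ND2" = p(-0.62, 0.20, 1.85),
    "NE1" = p(-0.61, 0.20, 1.85),
    "NE2" = p(-0.36, 0.20, 1.85),
    "OD1" = p(-0.60, 0.12, 1.70),
    "OD2" = p(-0.60, 0.12, 1.70),
    "OE1" = p(-0.60, 0.12, 1.70),
    "OE2" = p(-0.60, 0.12, 1.70),
    "ASN:OD1" = p(-0.55, 0.12, 1.70),
    "GLN:OE1" = p(-0.55, 0.12, 1.70)
  )
})

# Resolve stand-in parameters for a set of atoms; errors list offenders.
.lookup_params <- function(atoms, params = .nb_params) {
  keys1 <- paste0(atoms$resname, ":", atoms$atom_name)
  out <- matrix(NA_real_, nrow(atoms), 3,
                dimnames = list(NULL, c("q", "eps", "rmin2")))
  for (i in seq_len(nrow(atoms))) {
    hit <- params[[keys1[i]]]
    if (is.null(hit)) hit <- params[[atoms$atom_name[i]]]
    if (is.null(hit)) {
      # element-class fallback for generic carbons/hydrogens
      hit <- switch(atoms$element[i],
                    C = params[["CB"]], H = c(q = 0.09, eps = 0.03, rmin2 = 1.34),
                    NULL)
    }
    if (is.null(hit))
      stop("unparameterized atom ", atoms$atom_name[i], " in residue ",
           atoms$resname[i], " ", atoms$chain[i], atoms$resid[i])
    out[i, ] <- hit
  }
  out
}

.group_indices <- function(structure, group, map = NULL) {
  if (is.numeric(group)) return(as.integer(group))
  select_atoms(structure, group, map)$indices
}

.check_disjoint <- function(ia, ib) {
  ov <- intersect(ia, ib)
  if (length(ov)) stop("groups overlap (", length(ov), " shared atoms)")
}

.angle_deg <- function(a, b, c) {     # angle at b
  u <- a - b; v <- c - b
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Detect hydrogen bonds between two atom groups
#'
#' Pairs a donor-capable N/O in one group with an acceptor-capable N/O in
#' the other at donor-acceptor distance below `d_cut`.  When the structure
#' carries explicit hydrogens, a donor hydrogen within 1.25 A must make a
#' D-H...A angle of at least `angle_cut`; heavy-atom-only structures use the
#' distance criterion alone.
#'
#' @param structure a `Structure`.
#' @param group_a,group_b disjoint selections (subunit names, range
#'   data.frames or atom indices).
#' @param d_cut donor-acceptor distance cutoff (Angstrom, default 3.5).
#' @param angle_cut D-H...A angle cutoff (degrees, default 120).
#' @param map optional `DomainMap`.
#' @return data.frame of contacts (kind "hbond"), one row per
#'   donor/acceptor pair, with identities, distance and angle (NA without
#'   hydrogens).
#' @export
find_hbonds <- function(structure, group_a, group_b, d_cut = 3.5,
                        angle_cut = 120, map = NULL) {
  ia <- .group_indices(structure, group_a, map)
  ib <- .group_indices(structure, group_b, map)
  .check_disjoint(ia, ib)
  a <- structure$atoms
  xyz <- coords(structure)
  has_h <- any(a$element == "H")
  find_dir <- function(idon, iacc) {
    don <- idon[a$atom_name[idon] %in% .hb_donor_names & a$element[idon] != "H"]
    acc <- iacc[a$atom_name[iacc] %in% .hb_acceptor_names]
    if (!length(don) || !length(acc)) return(NULL)
    rows <- list()
    for (d in don) for (ac in acc) {
      r <- sqrt(sum((xyz[d, ] - xyz[ac, ])^2))
      if (r > d_cut) next
      ang <- NA_real_
      if (has_h) {
        # hydrogens on the donor: same residue, within 1.25 A
        hs <- which(a$element == "H" & a$chain == a$chain[d] &
                      a$resid == a$resid[d])
        hs <- hs[sqrt(rowSums((xyz[hs, , drop = FALSE] -
                                 matrix(xyz[d, ], length(hs), 3,
                                        byrow = TRUE))^2)) <= 1.25]
        if (length(hs)) {
          angs <- vapply(hs, function(h)
            .angle_deg(xyz[d, ], xyz[h, ], xyz[ac, ]), numeric(1))
          ang <- max(angs)
          if (ang < angle_cut) next
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "hbond",
        donor = paste0(a$chain[d], a$resid[d], ":", a$atom_name[d]),
        acceptor = paste0(a$chain[ac], a$resid[ac], ":", a$atom_name[ac]),
        distance = r, angle = ang, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- rbind(find_dir(ia, ib), find_dir(ib, ia))
  if (is.null(out))
    out <- data.frame(kind = character(), donor = character(),
                      acceptor = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE)
  unique(out)
}

#' Detect salt bridges between two atom groups
#'
#' Pairs a basic nitrogen (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2) in one group
#' with an acidic oxygen (Asp OD1/OD2; Glu OE1/OE2; C-terminal OXT) in the
#' other at distance below `d_cut`.
#'
#' @inheritParams find_hbonds
#' @param d_cut nitrogen-oxygen distance cutoff (Angstrom, default 4.0).
#' @return data.frame of contacts (kind "salt_bridge") with basic/acidic
#'   atom identities and distances.
#' @export
find_salt_bridges <- function(structure, group_a, group_b, d_cut = 4.0,
                              map = NULL) {
  ia <- .group_indices(structure, group_a, map)
  ib <- .group_indices(structure, group_b, map)
  .check_disjoint(ia, ib)
  a <- structure$atoms
  xyz <- coords(structure)
  is_basic <- function(i) any(a$resname[i] == names(.sb_basic_names) &
                                a$atom_name[i] == .sb_basic_names)
  is_acidic <- function(i) (any(a$resname[i] == names(.sb_acidic_names) &
                                  a$atom_name[i] == .sb_acidic_names)) ||
    a$atom_name[i] == "OXT"
  find_dir <- function(ibas, iacd) {
    bas <- ibas[vapply(ibas, is_basic, logical(1))]
    acd <- iacd[vapply(iacd, is_acidic, logical(1))]
    rows <- list()
    for (b in bas) for (ac in acd) {
      r <- sqrt(sum((xyz[b, ] - xyz[ac, ])^2))
      if (r <= d_cut)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "salt_bridge",
          basic = paste0(a$chain[b], a$resid[b], ":", a$atom_name[b]),
          acidic = paste0(a$chain[ac], a$resid[ac], ":", a$atom_name[ac]),
          distance = r, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- rbind(find_dir(ia, ib), find_dir(ib, ia))
  if (is.null(out))
    out <- data.frame(kind = character(), basic = character(),
                      acidic = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  unique(out)
}

#' Stand-in pairwise interaction energy between two groups
#'
#' Sums, over all cross pairs within `cutoff`, a Coulomb term with
#' distance-dependent dielectric eps(r) = 4r
#' (`332.0636 q_i q_j / (4 r^2)`) and a 12-6 Lennard-Jones term
#' (`eps_ij ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)`), with
#' `eps_ij = sqrt(eps_i eps_j)` and `Rmin_ij = Rmin_i/2 + Rmin_j/2`.
#' Parameters come from a small built-in table (or `params`).  This is a
#' transparent stand-in potential for conformation-to-conformation
#' bookkeeping, not a calibrated force field.
#'
#' @inheritParams find_hbonds
#' @param cutoff pair-distance cutoff (Angstrom, default 12).
#' @param lj include the Lennard-Jones term (default TRUE).
#' @param params optional parameter table overriding the built-in one
#'   (named list of `c(q, eps, rmin2)` keyed by "RES:ATOM" or atom name).
#' @return energy in kcal/mol (negative = attractive).
#' @export
pair_energy <- function(structure, group_a, group_b, cutoff = 12,
                        lj = TRUE, map = NULL, params = .nb_params) {
  ia <- .group_indices(structure, group_a, map)
  ib <- .group_indices(structure, group_b, map)
  .check_disjoint(ia, ib)
  xyz <- coords(structure)
  pa <- .lookup_params(structure$atoms[ia, , drop = FALSE], params)
  pb <- .lookup_params(structure$atoms[ib, , drop = FALSE], params)
  A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
  # pairwise distances
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  r <- sqrt(pmax(d2, 0))
  within <- r <= cutoff & r > 0
  if (!any(within)) return(0)
  qq <- outer(pa[, "q"], pb[, "q"])
  e_coul <- .COULOMB_K * qq / (4 * r^2)
  e <- sum(e_coul[within])
  if (lj) {
    epsij <- sqrt(outer(pa[, "eps"], pb[, "eps"]))
    rmin <- outer(pa[, "rmin2"], pb[, "rmin2"], `+`)
    sr6 <- (rmin / pmax(r, 1e-12))^6
    e_lj <- epsij * (sr6^2 - 2 * sr6)
    e <- e + sum(e_lj[within])
  }
  e
}

#' Percent change between two interaction energies
#'
#' Computed on magnitudes: `100 * (|e_end| - |e_start|) / |e_start|`, so a
#' positive value means the attraction strengthened (the convention in
#' which attractive interactions "increase").
#'
#' @param e_start,e_end energies (kcal/mol), `e_start != 0`.
#' @return percent change; `NA` with a warning when `e_start` is 0.
#' @export
percent_change <- function(e_start, e_end) {
  if (any(e_start == 0)) {
    warning("percent change undefined for zero starting energy")
    return(ifelse(e_start == 0, NA_real_,
                  100 * (abs(e_end) - abs(e_start)) / abs(e_start)))
  }
  100 * (abs(e_end) - abs(e_start)) / abs(e_start)
}

#' Start-versus-representative interaction report
#'
#' Assembles hydrogen bonds, salt bridges and stand-in pair energies for the
#' canonical group pairs (VH1-VL1, VH2-VL2, scFv1-scFv2, scFv1-Fc, scFv2-Fc,
#' linker1-linker2) at the start and representative conformations, with
#' percent changes on the energies and the linker-linker hydrogen-bond
#' count.  The interchain total is the stand-in energy between the two
#' half-molecules (scFv1+Fc1 versus scFv2+Fc2).
#'
#' @param start,representative `Structure`s sharing one topology.
#' @param map a `DomainMap`.
#' @param d_cut_hbond,d_cut_salt,cutoff_energy criteria passed through.
#' @return an object of class `EnergyReport`.
#' @export
interaction_summary <- function(start, representative, map,
                                d_cut_hbond = 3.5, d_cut_salt = 4.0,
                                cutoff_energy = 12) {
  if (!identical(start$atoms[, c("chain", "resid", "atom_name")],
                 representative$atoms[, c("chain", "resid", "atom_name")]))
    stop("start and representative conformations have different topologies")
  pair_names <- list(
    c("VH1", "VL1"), c("VH2", "VL2"), c("scFv1", "scFv2"),
    c("scFv1", "Fc1"), c("scFv2", "Fc2"), c("linker1", "linker2"))
  pair_names <- Filter(function(p) {
    ok <- function(nm) !inherits(try(.subunit_ranges(map, nm), silent = TRUE),
                                 "try-error")
    ok(p[1]) && ok(p[2])
  }, pair_names)
  eval_pair <- function(s, p) {
    list(energy = pair_energy(s, p[1], p[2], cutoff = cutoff_energy, map = map),
         hbonds = find_hbonds(s, p[1], p[2], d_cut = d_cut_hbond, map = map),
         salt_bridges = find_salt_bridges(s, p[1], p[2], d_cut = d_cut_salt,
                                          map = map))
  }
  res <- lapply(pair_names, function(p) {
    s0 <- eval_pair(start, p); s1 <- eval_pair(representative, p)
    list(pair = paste(p, collapse = "-"),
         e_start = s0$energy, e_end = s1$energy,
         percent_change = if (s0$energy != 0)
           percent_change(s0$energy, s1$energy) else NA_real_,
         hbonds_start = s0$hbonds, hbonds_end = s1$hbonds,
         salt_start = s0$salt_bridges, salt_end = s1$salt_bridges)
  })
  names(res) <- vapply(res, `[[`, character(1), "pair")
  # interchain total: half-molecule 1 vs half-molecule 2
  half1 <- rbind(.subunit_ranges(map, "scFv1"), .subunit_ranges(map, "Fc1"))
  half2 <- rbind(.subunit_ranges(map, "scFv2"), .subunit_ranges(map, "Fc2"))
  inter_start <- pair_energy(start, half1, half2, cutoff = cutoff_energy)
  inter_end <- pair_energy(representative, half1, half2, cutoff = cutoff_energy)
  ll <- res[["linker1-linker2"]]
  structure(list(
    pairs = res,
    interchain = list(e_start = inter_start, e_end = inter_end,
                      percent_change = if (inter_start != 0)
                        percent_change(inter_start, inter_end) else NA_real_),
    linker_hbond_count = list(
      start = if (!is.null(ll)) nrow(ll$hbonds_start) else NA_integer_,
      representative = if (!is.null(ll)) nrow(ll$hbonds_end) else NA_integer_),
    energy_model = "stand-in potential (Coulomb eps(r)=4r + 12-6 LJ)"
  ), class = "EnergyReport")
}

#' @export
print.EnergyReport <- function(x, ...) {
  cat("EnergyReport [", x$energy_model, "]\n", sep = "")
  for (p in x$pairs)
    cat(sprintf("  %-16s %9.3f -> %9.3f kcal/mol  (%+.1f %%)  hbonds %d -> %d\n",
                p$pair, p$e_start, p$e_end,
                ifelse(is.na(p$percent_change), NaN, p$percent_change),
                nrow(p$hbonds_start), nrow(p$hbonds_end)))
  cat(sprintf("  interchain total %9.3f -> %9.3f kcal/mol  (%+.1f %%)\n",
              x$interchain$e_start, x$interchain$e_end,
              ifelse(is.na(x$interchain$percent_change), NaN,
                     x$interchain$percent_change)))
  if (!is.na(x$linker_hbond_count$start))
    cat(sprintf("  linker-linker hydrogen bonds: %d -> %d\n",
                x$linker_hbond_count$start, x$linker_hbond_count$representative))
  invisible(x)
}
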