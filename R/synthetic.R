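# Synthetic-data generators: toy Y-shaped scFv-Fc builds, scripted
# rigid-body trajectories, two-state melt curves and serial-dilution
# titrations -- every input the pipeline consumes, with known ground truth.
#
# All generators are pure functions of (configuration, seed).

# Run code under a seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Compact random cloud of n points with zero mean, ~radius spread.
.cloud <- function(n, radius) {
  m <- matrix(stats::rnorm(n * 3, sd = radius / 2), n, 3)
  sweep(m, 2, colMeans(m))
}

#' Toy scFv-Fc build configuration
#'
#' Defaults encode the starting geometry of the antibody application: a
#' Y-shaped six-domain arrangement with 67 degrees between the two scFv
#' arms and 105/151 degrees between each scFv and its Fc chain.
#'
#' @param atoms_per_domain pseudo-atoms per domain cloud (default 40).
#' @param angle_scfv1_scfv2,angle_scfv1_fc1,angle_scfv2_fc2 requested
#'   XY-plane separations in degrees, each in (0, 180).
#' @param arm_length pivot-to-scFv-center distance (Angstrom, default 40).
#' @param fc_radius pivot-to-Fc-center XY distance (Angstrom, default 18).
#' @param domain_radius cloud spread (Angstrom, default 3).
#' @param linker_beads,hinge_beads bead counts (defaults 5).
#' @param z_arm,z_fc z-heights of scFv and Fc centers (Angstrom).
#' @param seed RNG seed.
#' @return list of class `ToyBuildConfig`.
#' @export
toy_build_config <- function(atoms_per_domain = 40,
                             angle_scfv1_scfv2 = 67,
                             angle_scfv1_fc1 = 105,
                             angle_scfv2_fc2 = 151,
                             arm_length = 40, fc_radius = 18,
                             domain_radius = 3,
                             linker_beads = 5, hinge_beads = 5,
                             z_arm = 20, z_fc = -18, seed = 1) {
  angles <- c(angle_scfv1_scfv2, angle_scfv1_fc1, angle_scfv2_fc2)
  if (any(angles <= 0 | angles >= 180))
    stop("infeasible angle set: requested angles must lie in (0, 180)")
  if (arm_length <= domain_radius)
    stop("arm_length must exceed domain_radius")
  structure(as.list(environment())[c(
    "atoms_per_domain", "angle_scfv1_scfv2", "angle_scfv1_fc1",
    "angle_scfv2_fc2", "arm_length", "fc_radius", "domain_radius",
    "linker_beads", "hinge_beads", "z_arm", "z_fc", "seed")],
    class = "ToyBuildConfig")
}

#' Build a toy Y-shaped scFv-Fc structure
#'
#' Places six compact pseudo-domain clouds (VH1, VL1, VH2, VL2, Fc1, Fc2)
#' plus linker and hinge beads so that the measured pivot/center XY-plane
#' angles equal the requested ones exactly: the pivot anchors (single-CA
#' proline residues, resid 238 of each chain, mirroring the N-terminal Fc
#' anchor residues) are placed symmetrically about the origin, and each
#' subunit cloud is rigidly translated so its atom-mean lands on the
#' requested azimuth ray.  Deterministic under the config seed.
#'
#' @param config a [toy_build_config()].
#' @return list with `structure` (a `Structure`), `map` (a `DomainMap`) and
#'   `interp` (bead re-interpolation rules consumed by
#'   [simulate_trajectory()]).
#' @export
build_toy_scfvfc <- function(config = toy_build_config()) {
  stopifnot(inherits(config, "ToyBuildConfig"))
  npd <- config$atoms_per_domain
  nl <- config$linker_beads; nh <- config$hinge_beads
  deg2rad <- pi / 180
  # azimuths: scFv2 on the +x axis, scFv1 rotated by the requested
  # separation; Fc azimuths follow from the scFv-Fc separations.
  az <- c(scFv1 = config$angle_scfv1_scfv2, scFv2 = 0,
          Fc1 = config$angle_scfv1_scfv2 - config$angle_scfv1_fc1,
          Fc2 = config$angle_scfv2_fc2)
  ray <- function(nm, r, z) c(r * cos(az[nm] * deg2rad),
                              r * sin(az[nm] * deg2rad), z)
  anchor1 <- c(1.5, 0, -2); anchor2 <- c(-1.5, 0, 2)  # midpoint = origin
  .with_seed(config$seed, {
    rows <- list()
    add_atoms <- function(xyz, chain, resids, resname) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chain = chain, resid = resids, resname = resname, atom_name = "CA",
        element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
    }
    build_arm <- function(chain, arm) {
      target <- ray(paste0("scFv", arm), config$arm_length, config$z_arm)
      off <- c(0, 0, 5)                       # VH above, VL below the arm axis
      vh <- sweep(.cloud(npd, config$domain_radius), 2, off, `+`)
      vl <- sweep(.cloud(npd, config$domain_radius), 2, -off, `+`)
      fr <- seq_len(nl) / (nl + 1)
      li <- outer(1 - fr, colMeans(vh)) + outer(fr, colMeans(vl))
      all_xyz <- rbind(vh, li, vl)
      all_xyz <- sweep(all_xyz, 2, target - colMeans(all_xyz), `+`)
      add_atoms(all_xyz[seq_len(npd), , drop = FALSE], chain, 1:npd, "ALA")
      add_atoms(all_xyz[npd + seq_len(nl), , drop = FALSE], chain,
                npd + 1:nl, "GLY")
      add_atoms(all_xyz[npd + nl + seq_len(npd), , drop = FALSE], chain,
                npd + nl + 1:npd, "ALA")
    }
    build_fc <- function(chain, arm, anchor) {
      target <- ray(paste0("Fc", arm), config$fc_radius, config$z_fc)
      rest <- .cloud(npd - 1, config$domain_radius)
      rest_target <- (npd * target - anchor) / (npd - 1)
      rest <- sweep(rest, 2, rest_target, `+`)
      add_atoms(matrix(anchor, 1, 3), chain, 238L, "PRO")
      add_atoms(rest, chain, 239:(238 + npd - 1), "ALA")
    }
    build_hinge <- function(chain, arm, anchor) {
      scfv_center <- ray(paste0("scFv", arm), config$arm_length, config$z_arm)
      fr <- seq_len(nh) / (nh + 1)
      hx <- outer(1 - fr, scfv_center) + outer(fr, anchor)
      add_atoms(hx, chain, 200:(200 + nh - 1), "GLY")
    }
    build_arm("A", 1); build_hinge("A", 1, anchor1); build_fc("A", 1, anchor1)
    build_arm("B", 2); build_hinge("B", 2, anchor2); build_fc("B", 2, anchor2)
    atoms <- do.call(rbind, rows)
  })
  s <- new_structure(atoms, label = "toy-scFv-Fc")
  rng <- function(ch, a, b) data.frame(chain = ch, start = a, end = b)
  map <- domain_map(
    subunits = list(
      VH1 = rng("A", 1, npd), linker1 = rng("A", npd + 1, npd + nl),
      VL1 = rng("A", npd + nl + 1, 2 * npd + nl),
      hinge1 = rng("A", 200, 200 + nh - 1),
      Fc1 = rng("A", 238, 238 + npd - 1),
      VH2 = rng("B", 1, npd), linker2 = rng("B", npd + 1, npd + nl),
      VL2 = rng("B", npd + nl + 1, 2 * npd + nl),
      hinge2 = rng("B", 200, 200 + nh - 1),
      Fc2 = rng("B", 238, 238 + npd - 1)),
    pivot_anchors = list(c("A", 238), c("B", 238)),
    cdr_loops = list(
      H3.1 = rng("A", 6, min(13, npd)), L1.1 = rng("A", npd + nl + 5,
                                                   npd + nl + 12),
      H3.2 = rng("B", 6, min(13, npd)), L1.2 = rng("B", npd + nl + 5,
                                                   npd + nl + 12)))
  interp <- list(
    list(beads = "linker1", from = list(kind = "center", name = "VH1"),
         to = list(kind = "center", name = "VL1"),
         fracs = seq_len(nl) / (nl + 1)),
    list(beads = "linker2", from = list(kind = "center", name = "VH2"),
         to = list(kind = "center", name = "VL2"),
         fracs = seq_len(nl) / (nl + 1)),
    list(beads = "hinge1", from = list(kind = "center", name = "scFv1"),
         to = list(kind = "anchor", name = 1L),
         fracs = seq_len(nh) / (nh + 1)),
    list(beads = "hinge2", from = list(kind = "center", name = "scFv2"),
         to = list(kind = "anchor", name = 2L),
         fracs = seq_len(nh) / (nh + 1)))
  list(structure = s, map = map, interp = interp)
}

#' Motion directive for one subunit over a frame interval
#'
#' @param subunit subunit name (composites scFv1/scFv2 allowed).
#' @param frames length-2 integer interval `(from, to)` over which the
#'   motion ramps linearly (1-based frame indices).
#' @param contraction pivot-distance scale factor reached at the interval
#'   end (1 = none; 0.5 halves the distance); must be > 0.
#' @param dz z-translation reached at the interval end (Angstrom).
#' @param rotate_deg rotation about the pivot reached at the interval end
#'   (degrees).
#' @param rotate_axis rotation axis (default z).
#' @return list of class `MotionDirective`.
#' @export
motion_directive <- function(subunit, frames, contraction = 1, dz = 0,
                             rotate_deg = 0, rotate_axis = c(0, 0, 1)) {
  if (contraction <= 0) stop("contraction factor must be > 0")
  stopifnot(length(frames) == 2, frames[2] > frames[1])
  structure(list(subunit = subunit, frames = as.integer(frames),
                 contraction = contraction, dz = dz,
                 rotate_deg = rotate_deg,
                 rotate_axis = rotate_axis / sqrt(sum(rotate_axis^2))),
            class = "MotionDirective")
}

#' Motion script: directives plus thermal jitter
#'
#' @param directives list of [motion_directive()]s.  Two directives for the
#'   same subunit must not overlap in frames.
#' @param jitter_sd isotropic Gaussian jitter per axis (Angstrom, default 0).
#' @param seed RNG seed (same seed, same frames).
#' @return list of class `MotionScript`.
#' @export
motion_script <- function(directives = list(), jitter_sd = 0, seed = 1) {
  if (inherits(directives, "MotionDirective")) directives <- list(directives)
  by_sub <- split(directives, vapply(directives, `[[`, character(1), "subunit"))
  for (ds in by_sub) {
    if (length(ds) < 2) next
    iv <- t(vapply(ds, `[[`, integer(2), "frames"))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping frame intervals for subunit ", ds[[1]]$subunit)
  }
  structure(list(directives = directives, jitter_sd = jitter_sd, seed = seed),
            class = "MotionScript")
}

.rotation_matrix <- function(axis, deg) {
  th <- deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Simulate a scripted rigid-body trajectory
#'
#' Each frame starts from the input coordinates; every directive applies,
#' with linear progress over its frame interval, a rigid rotation about the
#' pivot, a rigid translation of the subunit center toward (or away from)
#' the pivot scaling the pivot distance by the contraction factor, and a
#' rigid z-translation.  Linker and hinge beads are then re-placed at their
#' stored fractional positions between their flanking anchors, and isotropic
#' Gaussian jitter is added.  Deterministic under the script seed.
#'
#' @param structure the start `Structure` (frame 1 reproduces it when the
#'   first directive interval starts at frame 1 and jitter is 0).
#' @param map a `DomainMap`.
#' @param script a [motion_script()].
#' @param n_frames number of frames (>= 2).
#' @param interp bead re-interpolation rules (from [build_toy_scfvfc()]);
#'   `NULL` disables re-interpolation.
#' @return a `Trajectory`.
#' @export
simulate_trajectory <- function(structure, map, script, n_frames,
                                interp = NULL) {
  stopifnot(inherits(script, "MotionScript"), n_frames >= 2)
  for (d in script$directives)
    if (d$frames[2] > n_frames)
      stop("directive interval exceeds the frame range (", d$frames[2], " > ",
           n_frames, ")")
  x0 <- coords(structure)
  pivot0 <- pivot_point(structure, map)
  n_atoms <- nrow(x0)
  sub_idx <- lapply(script$directives, function(d)
    select_atoms(structure, d$subunit, map)$indices)
  interp_idx <- NULL
  if (!is.null(interp)) {
    interp_idx <- lapply(interp, function(rule) {
      endpoints_idx <- function(ep) {
        if (ep$kind == "center")
          select_atoms(structure, ep$name, map)$indices
        else {
          anc <- map$pivot_anchors[[ep$name]]
          which(structure$atoms$chain == anc$chain &
                  structure$atoms$resid == anc$resid)
        }
      }
      list(beads = select_atoms(structure, rule$beads, map)$indices,
           from = endpoints_idx(rule$from), to = endpoints_idx(rule$to),
           fracs = rule$fracs)
    })
  }
  frames <- .with_seed(script$seed, {
    lapply(seq_len(n_frames), function(t) {
      x <- x0
      for (k in seq_along(script$directives)) {
        d <- script$directives[[k]]
        p <- min(1, max(0, (t - d$frames[1]) / (d$frames[2] - d$frames[1])))
        if (p == 0) next
        idx <- sub_idx[[k]]
        if (d$rotate_deg != 0) {
          R <- .rotation_matrix(d$rotate_axis, d$rotate_deg * p)
          x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, pivot0) %*% t(R),
                            2, pivot0, `+`)
        }
        if (d$contraction != 1) {
          s_t <- 1 + (d$contraction - 1) * p
          ctr <- colMeans(x[idx, , drop = FALSE])
          shift <- (s_t - 1) * (ctr - pivot0)
          x[idx, ] <- sweep(x[idx, , drop = FALSE], 2, shift, `+`)
        }
        if (d$dz != 0) x[idx, 3] <- x[idx, 3] + d$dz * p
      }
      if (!is.null(interp_idx)) {
        for (rule in interp_idx) {
          from <- colMeans(x[rule$from, , drop = FALSE])
          to <- colMeans(x[rule$to, , drop = FALSE])
          x[rule$beads, ] <- outer(1 - rule$fracs, from) +
            outer(rule$fracs, to)
        }
      }
      if (script$jitter_sd > 0)
        x <- x + matrix(stats::rnorm(n_atoms * 3, sd = script$jitter_sd),
                        n_atoms, 3)
      x
    })
  })
  new_trajectory(structure, frames)
}

#' Generate a synthetic two-state melt curve
#'
#' Logistic unfolding transition
#' `F(T) = low + (high - low) / (1 + exp((tm - T) / steepness))` plus
#' Gaussian noise, replicated on a shared grid; seeded.
#'
#' @param tm midpoint (degC), interior to the grid.
#' @param steepness transition width parameter (degC, default 2).
#' @param low,high folded/unfolded baselines (fluorescence units).
#' @param grid temperature grid (degC, default 10-95 by 0.5).
#' @param noise_sd additive Gaussian noise SD (fluorescence units).
#' @param replicates replicate count (default 3).
#' @param seed RNG seed.
#' @return a `MeltCurve`.
#' @export
generate_melt_curve <- function(tm, steepness = 2, low = 1000, high = 30000,
                                grid = seq(10, 95, by = 0.5), noise_sd = 0,
                                replicates = 3, seed = 1) {
  if (tm <= min(grid) || tm >= max(grid))
    stop("tm must lie inside the temperature grid")
  base <- low + (high - low) / (1 + exp((tm - grid) / steepness))
  F <- .with_seed(seed, {
    vapply(seq_len(replicates), function(r)
      base + stats::rnorm(length(grid), sd = noise_sd),
      numeric(length(grid)))
  })
  melt_curve(grid, F)
}

#' Generate a synthetic binding titration
#'
#' A 12-point threefold serial dilution by default.  The saturation model
#' is `Y = bmax X / (kd + X)`; the logistic model is
#' `Y = bottom + (top - bottom) / (1 + (ec50/X)^h)`.  Noise is
#' multiplicative Gaussian with coefficient of variation `noise_cv`; seeded.
#'
#' @param model `"saturation"` or `"logistic"`.
#' @param params named list: `kd`, `bmax` for saturation; `ec50`, `top`
#'   and optional `bottom` (0), `h` (1) for logistic.  All positive.
#' @param n_points points in the dilution series (default 12).
#' @param dilution serial-dilution factor (default 3).
#' @param top_conc highest concentration (nM, default 300).
#' @param noise_cv coefficient of variation of multiplicative noise.
#' @param replicates replicate count (default 1).
#' @param seed RNG seed.
#' @return a `BindingCurve`.
#' @export
generate_titration <- function(model = c("saturation", "logistic"), params,
                               n_points = 12, dilution = 3, top_conc = 300,
                               noise_cv = 0, replicates = 1, seed = 1) {
  model <- match.arg(model)
  conc <- top_conc / dilution^(seq_len(n_points) - 1)
  mu <- if (model == "saturation") {
    if (is.null(params$kd) || is.null(params$bmax))
      stop("saturation model needs params kd and bmax")
    if (params$kd <= 0 || params$bmax <= 0) stop("params must be positive")
    params$bmax * conc / (params$kd + conc)
  } else {
    if (is.null(params$ec50) || is.null(params$top))
      stop("logistic model needs params ec50 and top")
    h <- if (is.null(params$h)) 1 else params$h
    bottom <- if (is.null(params$bottom)) 0 else params$bottom
    if (params$ec50 <= 0 || params$top <= 0) stop("params must be positive")
    bottom + (params$top - bottom) / (1 + (params$ec50 / conc)^h)
  }
  S <- .with_seed(seed, {
    vapply(seq_len(replicates), function(r)
      mu * (1 + stats::rnorm(length(conc), sd = noise_cv)),
      numeric(length(conc)))
  })
  binding_curve(conc, S)
}
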