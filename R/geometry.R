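# Pivot/center angular framework and trajectory statistics.
#
# All distances are in Angstrom, angles in degrees.  The pivot point is the
# midpoint of the two Fc anchor residues; subunit center points are
# unweighted means of heavy-atom coordinates.  XY-plane angles are unsigned
# (arccos of normalized projected dot product, range [0, 180]).

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' corresponding point sets (correspondence by index).  Reflections are
#' corrected so the returned rotation has determinant +1.
#'
#' @param mobile k x 3 matrix of mobile coordinates.
#' @param reference k x 3 matrix of reference coordinates.
#' @return list with `rotation` (3 x 3, applied on the right of centred row
#'   vectors), `translation` (length-3), `rmsd` (Angstrom), and `transform(x)`
#'   applying the fit to any n x 3 matrix.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be k x 3 matrices of equal size")
  k <- nrow(mobile)
  if (k < 3) stop("Kabsch superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)                     # 3x3 covariance
  s <- svd(H)
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2)
    stop("degenerate point set (collinear or coincident points)")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)                # applied as x %*% R for row vectors
  fitted <- A %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  translation <- cr - cm %*% R
  list(
    rotation = R,
    translation = as.numeric(translation),
    rmsd = rmsd,
    transform = function(x) sweep(as.matrix(x) %*% R, 2,
                                  as.numeric(translation), `+`)
  )
}

# Plain RMSD between two corresponding coordinate sets (no fitting).
.rmsd <- function(x, y) sqrt(mean(rowSums((as.matrix(x) - as.matrix(y))^2)))

#' Align every trajectory frame to a reference structure
#'
#' Each frame is rigid-body fitted to the reference by Kabsch superposition
#' on the selected atoms (alpha-carbons by default) and the transform is
#' applied to the whole frame.  This fixes the laboratory frame -- and with
#' it the XY-plane and z-axis of the angular framework -- to the reference
#' conformation.
#'
#' @param traj a `Trajectory`.
#' @param reference a `Structure` with the same topology; defaults to the
#'   trajectory topology (the energy-minimized start in the antibody
#'   application).
#' @param selection atom selection used for the fit (default `"CA"`).
#' @param map optional `DomainMap` for subunit selections.
#' @return the aligned `Trajectory`.
#' @export
align_frames <- function(traj, reference = traj$topology, selection = "CA",
                         map = NULL) {
  sel_ref <- select_atoms(reference, selection, map)
  sel_mob <- select_atoms(traj$topology, selection, map)
  if (length(sel_ref$indices) != length(sel_mob$indices))
    stop("selection resolves to ", length(sel_mob$indices),
         " atoms in the trajectory but ", length(sel_ref$indices),
         " in the reference")
  ref_xyz <- coords(reference)[sel_ref$indices, , drop = FALSE]
  traj$frames <- lapply(traj$frames, function(fr) {
    fit <- kabsch_superpose(fr[sel_mob$indices, , drop = FALSE], ref_xyz)
    fit$transform(fr)
  })
  traj
}

#' Pivot point of a conformation
#'
#' Midpoint of the two pivot-anchor residues; each anchor position is the
#' mean of that residue's atom coordinates.
#'
#' @param structure a `Structure` (or a trajectory frame via
#'   [frame_structure()]).
#' @param map a `DomainMap` carrying `pivot_anchors`.
#' @return length-3 numeric vector (Angstrom).
#' @export
pivot_point <- function(structure, map) {
  a <- structure$atoms
  pos <- vapply(map$pivot_anchors, function(anc) {
    idx <- which(a$chain == anc$chain & a$resid == anc$resid)
    if (!length(idx))
      stop("pivot anchor ", anc$chain, anc$resid, " resolves to no atoms")
    colMeans(coords(structure)[idx, , drop = FALSE])
  }, numeric(3))
  rowMeans(pos)
}

#' Center point of a subunit
#'
#' Unweighted arithmetic mean of the subunit's heavy-atom coordinates
#' (hydrogens excluded); `ca_only = TRUE` restricts to alpha-carbons.
#'
#' @param structure a `Structure`.
#' @param subunit subunit name (composites scFv1/scFv2 allowed).
#' @param map a `DomainMap`.
#' @param ca_only use alpha-carbons only.
#' @return length-3 numeric vector (Angstrom).
#' @export
center_point <- function(structure, subunit, map, ca_only = FALSE) {
  sel <- select_atoms(structure,
                      if (ca_only) paste0(subunit, ":CA") else subunit, map)
  heavy <- structure$atoms$element[sel$indices] != "H"
  if (!any(heavy)) stop("subunit ", subunit, " has no heavy atoms")
  colMeans(sel$xyz[heavy, , drop = FALSE])
}

#' Unsigned XY-plane angle at the pivot
#'
#' Projects both center-minus-pivot vectors onto the z = 0 plane and returns
#' the arccos of their normalized dot product, in degrees within [0, 180].
#'
#' @param center_a,center_b length-3 center points.
#' @param pivot length-3 pivot point.
#' @return angle in degrees.
#' @export
xy_angle <- function(center_a, center_b, pivot) {
  u <- (center_a - pivot)[1:2]
  v <- (center_b - pivot)[1:2]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("undefined angle: zero-length XY projection")
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Contraction toward the pivot, in percent
#'
#' `100 * (d_start - d_end) / d_start`; positive values mean the subunit
#' moved toward the pivot, negative values extension.
#'
#' @param d_start,d_end pivot-to-center distances (Angstrom), `d_start > 0`.
#' @return percent contraction.
#' @export
contraction_percent <- function(d_start, d_end) {
  if (any(d_start <= 0)) stop("d_start must be positive")
  100 * (d_start - d_end) / d_start
}

#' Signed z-axis displacement relative to the pivot
#'
#' `(center_end.z - pivot_end.z) - (center_start.z - pivot_start.z)`.
#' Both conformations must first be placed in the common laboratory frame
#' (see [align_frames()]), since z-offsets are not rigid-transform invariant.
#'
#' @param center_start,center_end,pivot_start,pivot_end length-3 points.
#' @return displacement in Angstrom (signed).
#' @export
z_displacement <- function(center_start, center_end, pivot_start, pivot_end) {
  (center_end[3] - pivot_end[3]) - (center_start[3] - pivot_start[3])
}

#' Per-conformation geometry summary
#'
#' Computes the pivot point, subunit center points, pairwise XY-plane angles,
#' pivot-to-center distances and signed z-offsets (center z minus pivot z)
#' for one conformation.
#'
#' @param structure a `Structure` (typically a trajectory frame).
#' @param map a `DomainMap`.
#' @param subunits subunit names to summarize.
#' @param pairs list of length-2 character vectors naming the angle pairs.
#' @param xy_distances measure pivot distances in the XY projection instead
#'   of full 3-D (default 3-D).
#' @return an object of class `GeometrySummary`.
#' @export
geometry_summary <- function(structure, map,
                             subunits = c("scFv1", "scFv2", "Fc1", "Fc2"),
                             pairs = list(c("scFv1", "Fc1"), c("scFv2", "Fc2"),
                                          c("scFv1", "scFv2")),
                             xy_distances = FALSE) {
  piv <- pivot_point(structure, map)
  centers <- vapply(stats::setNames(nm = subunits), function(s)
    center_point(structure, s, map), numeric(3))
  dist_of <- function(ctr) {
    d <- ctr - piv
    if (xy_distances) sqrt(sum(d[1:2]^2)) else sqrt(sum(d^2))
  }
  pivot_distances <- apply(centers, 2, dist_of)
  z_offsets <- centers[3, ] - piv[3]
  angles <- vapply(pairs, function(p)
    xy_angle(centers[, p[1]], centers[, p[2]], piv), numeric(1))
  names(angles) <- vapply(pairs, paste, character(1), collapse = "-")
  structure(list(pivot = piv, centers = centers, xy_angles = angles,
                 pivot_distances = pivot_distances, z_offsets = z_offsets,
                 xy_distances = xy_distances, label = structure$label),
            class = "GeometrySummary")
}

#' @export
print.GeometrySummary <- function(x, ...) {
  cat(sprintf("GeometrySummary ('%s')\n", x$label))
  cat(sprintf("  pivot (A): %.2f %.2f %.2f\n", x$pivot[1], x$pivot[2], x$pivot[3]))
  for (nm in names(x$xy_angles))
    cat(sprintf("  angle %-14s %7.1f deg\n", nm, x$xy_angles[nm]))
  for (nm in names(x$pivot_distances))
    cat(sprintf("  %-8s pivot dist %7.2f A   z-offset %+7.2f A\n",
                nm, x$pivot_distances[nm], x$z_offsets[nm]))
  invisible(x)
}

#' Start-versus-end comparison of two geometry summaries
#'
#' Reports per-subunit contraction toward the pivot (percent of the starting
#' pivot distance) and signed z-displacement relative to the pivot, plus the
#' change in each XY-plane angle.
#'
#' @param start,end `GeometrySummary` objects over the same subunits.
#' @return an object of class `ComparisonSummary`.
#' @export
comparison_summary <- function(start, end) {
  stopifnot(inherits(start, "GeometrySummary"), inherits(end, "GeometrySummary"))
  subs <- intersect(names(start$pivot_distances), names(end$pivot_distances))
  contraction <- contraction_percent(start$pivot_distances[subs],
                                     end$pivot_distances[subs])
  zdisp <- vapply(subs, function(s)
    z_displacement(start$centers[, s], end$centers[, s],
                   start$pivot, end$pivot), numeric(1))
  common_angles <- intersect(names(start$xy_angles), names(end$xy_angles))
  dangles <- end$xy_angles[common_angles] - start$xy_angles[common_angles]
  structure(list(contraction_percent = contraction, z_displacement = zdisp,
                 angle_change = dangles,
                 start_label = start$label, end_label = end$label),
            class = "ComparisonSummary")
}

#' @export
print.ComparisonSummary <- function(x, ...) {
  cat(sprintf("ComparisonSummary: '%s' -> '%s'\n", x$start_label, x$end_label))
  for (s in names(x$contraction_percent))
    cat(sprintf("  %-8s contraction %+7.2f %%   z-displacement %+7.2f A\n",
                s, x$contraction_percent[s], x$z_displacement[s]))
  for (a in names(x$angle_change))
    cat(sprintf("  angle %-14s change %+7.2f deg\n", a, x$angle_change[a]))
  invisible(x)
}

# ---- trajectory statistics --------------------------------------------------

#' Per-frame RMSD series
#'
#' RMSD of each frame to the reference over the selection, without
#' re-fitting (apply [align_frames()] first).
#'
#' @param traj an aligned `Trajectory`.
#' @param reference a `Structure`; defaults to the trajectory topology.
#' @param selection atom selection (default `"CA"`).
#' @param map optional `DomainMap`.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = traj$topology, selection = "CA",
                        map = NULL) {
  sel_r <- select_atoms(reference, selection, map)
  sel_m <- select_atoms(traj$topology, selection, map)
  if (length(sel_r$indices) != length(sel_m$indices))
    stop("selection atom-count mismatch between trajectory and reference")
  ref <- coords(reference)[sel_r$indices, , drop = FALSE]
  vapply(traj$frames, function(fr)
    .rmsd(fr[sel_m$indices, , drop = FALSE], ref), numeric(1))
}

#' Per-subunit RMSD series
#'
#' `mode = "global-frame"` measures each subunit in the globally aligned
#' frame, so rigid-body subunit motion contributes; `mode = "refit"`
#' superposes the subunit onto its reference copy first, leaving only
#' internal deformation.
#'
#' @param traj an aligned `Trajectory`.
#' @param reference a `Structure`.
#' @param map a `DomainMap`.
#' @param subunits subunit names.
#' @param mode `"global-frame"` or `"refit"`.
#' @param selection per-subunit atom filter, `"CA"` or `"all"`.
#' @return named list of per-frame RMSD vectors.
#' @export
domain_rmsd <- function(traj, reference = traj$topology, map,
                        subunits = names(map$subunits),
                        mode = c("global-frame", "refit"),
                        selection = "all") {
  mode <- match.arg(mode)
  out <- lapply(stats::setNames(nm = subunits), function(s) {
    sel_name <- if (selection == "CA") paste0(s, ":CA") else s
    idx <- select_atoms(traj$topology, sel_name, map)$indices
    ref <- coords(reference)[idx, , drop = FALSE]
    vapply(traj$frames, function(fr) {
      sub <- fr[idx, , drop = FALSE]
      if (mode == "refit") kabsch_superpose(sub, ref)$rmsd else .rmsd(sub, ref)
    }, numeric(1))
  })
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' RMS deviation of each selected atom about its time-mean position,
#' averaged within residues.  Apply [align_frames()] first for real
#' trajectories, otherwise global motion inflates the fluctuation.
#'
#' @param traj an aligned `Trajectory` with at least two frames.
#' @param selection atom selection (default `"CA"`, giving one value per
#'   residue directly).
#' @param map optional `DomainMap`.
#' @return data.frame with chain, resid and rmsf (Angstrom).
#' @export
rmsf <- function(traj, selection = "CA", map = NULL) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  idx <- select_atoms(traj$topology, selection, map)$indices
  X <- vapply(traj$frames, function(fr) fr[idx, , drop = FALSE],
              matrix(0, length(idx), 3))          # atoms x 3 x frames
  mean_pos <- apply(X, c(1, 2), mean)
  dev2 <- apply((X - array(mean_pos, dim(X)))^2, c(1, 3), sum)
  atom_rmsf <- sqrt(rowMeans(dev2))
  a <- traj$topology$atoms[idx, ]
  agg <- stats::aggregate(atom_rmsf,
                          by = list(chain = a$chain, resid = a$resid), FUN = mean)
  names(agg)[3] <- "rmsf"
  agg[order(agg$chain, agg$resid), ]
}

#' Radius of gyration of one conformation
#'
#' `sqrt(sum(m_i |r_i - rbar|^2) / sum(m_i))` with `rbar` the (mass-weighted)
#' centroid; `mass_weighted = FALSE` uses unit weights.
#'
#' @param structure a `Structure`.
#' @param selection atom selection (default `"all"`).
#' @param map optional `DomainMap`.
#' @param mass_weighted logical.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(structure, selection = "all", map = NULL,
                               mass_weighted = TRUE) {
  sel <- select_atoms(structure, selection, map)
  w <- if (mass_weighted) sel$masses else rep(1, nrow(sel$xyz))
  ctr <- colSums(sel$xyz * w) / sum(w)
  d2 <- rowSums(sweep(sel$xyz, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Per-frame radius-of-gyration series
#'
#' @inheritParams radius_of_gyration
#' @param traj a `Trajectory`.
#' @return numeric vector, one Rg (Angstrom) per frame.
#' @export
rg_series <- function(traj, selection = "all", map = NULL, mass_weighted = TRUE) {
  vapply(seq_len(n_frames(traj)), function(i)
    radius_of_gyration(frame_structure(traj, i), selection, map, mass_weighted),
    numeric(1))
}

# Pairwise superposed RMSD matrix over the selection.
.pairwise_rmsd_matrix <- function(traj, selection = "CA", map = NULL) {
  idx <- select_atoms(traj$topology, selection, map)$indices
  n <- n_frames(traj)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- kabsch_superpose(traj$frames[[j]][idx, , drop = FALSE],
                          traj$frames[[i]][idx, , drop = FALSE])$rmsd
    M[i, j] <- r; M[j, i] <- r
  }
  M
}

#' Representative (centroid) frame of a trajectory
#'
#' The medoid under pairwise superposed RMSD: the frame minimizing the mean
#' RMSD to all other frames, each pair superposed by its own Kabsch fit.
#' Ties break to the lowest index.  This is the single-cluster
#' representative used in trajectory clustering with one cluster.
#'
#' @param traj a `Trajectory`.
#' @param selection atom selection (default `"CA"`).
#' @param map optional `DomainMap`.
#' @return frame index (1-based).
#' @export
centroid_frame <- function(traj, selection = "CA", map = NULL) {
  if (n_frames(traj) == 1) return(1L)
  M <- .pairwise_rmsd_matrix(traj, selection, map)
  means <- rowSums(M) / (ncol(M) - 1)
  which.min(means)            # which.min takes the first (lowest) index on ties
}

#' Structurally closest frame to a query frame
#'
#' Scans all frames outside an exclusion window around the query and returns
#' the one with minimal superposed RMSD to the query frame.  The default
#' window excludes the 10% of frames nearest the query in time, so the match
#' is temporally distinct from the query itself.
#'
#' @param traj a `Trajectory`.
#' @param query_index frame to match (default: last frame).
#' @param exclusion_window half-width in frames; frames with
#'   `|i - query| <= window` are excluded.  Default 10% of the frame count.
#' @param selection atom selection (default `"CA"`).
#' @param map optional `DomainMap`.
#' @param quality_cutoff RMSD (Angstrom) under which the superposition is
#'   flagged as within conventional quality for large predicted structures
#'   (default 10).
#' @return list with `index`, `rmsd`, and `within_cutoff`.
#' @export
closest_frame <- function(traj, query_index = n_frames(traj),
                          exclusion_window = ceiling(0.1 * n_frames(traj)),
                          selection = "CA", map = NULL, quality_cutoff = 10) {
  n <- n_frames(traj)
  stopifnot(query_index >= 1, query_index <= n)
  cand <- which(abs(seq_len(n) - query_index) > exclusion_window)
  if (!length(cand)) stop("exclusion window leaves no candidate frames")
  idx <- select_atoms(traj$topology, selection, map)$indices
  q <- traj$frames[[query_index]][idx, , drop = FALSE]
  r <- vapply(cand, function(i)
    kabsch_superpose(traj$frames[[i]][idx, , drop = FALSE], q)$rmsd, numeric(1))
  best <- which.min(r)
  list(index = cand[best], rmsd = r[best],
       within_cutoff = r[best] <= quality_cutoff)
}

#' Full trajectory statistics bundle
#'
#' Convenience wrapper computing the RMSD series, per-subunit RMSD, RMSF,
#' Rg series, centroid frame and closest frame to the final frame.
#'
#' @param traj an aligned `Trajectory`.
#' @param reference a `Structure`.
#' @param map a `DomainMap`.
#' @param selection atom selection for RMSD/RMSF (default `"CA"`).
#' @return an object of class `TrajectoryStats`.
#' @export
trajectory_stats <- function(traj, reference = traj$topology, map,
                             selection = "CA") {
  structure(list(
    rmsd_series = rmsd_series(traj, reference, selection, map),
    domain_rmsd = domain_rmsd(traj, reference, map,
                              mode = "global-frame", selection = "all"),
    rmsf = rmsf(traj, selection, map),
    rg_series = rg_series(traj),
    centroid_index = centroid_frame(traj, selection, map),
    closest_frame = closest_frame(traj, selection = selection, map = map)
  ), class = "TrajectoryStats")
}

#' @export
print.TrajectoryStats <- function(x, ...) {
  cat(sprintf("TrajectoryStats: %d frames\n", length(x$rmsd_series)))
  cat(sprintf("  RMSD (A): %.2f .. %.2f (final %.2f)\n",
              min(x$rmsd_series), max(x$rmsd_series),
              x$rmsd_series[length(x$rmsd_series)]))
  cat(sprintf("  Rg (A): %.2f .. %.2f\n", min(x$rg_series), max(x$rg_series)))
  cat(sprintf("  centroid frame: %d\n", x$centroid_index))
  cat(sprintf("  closest frame to final: %d (RMSD %.2f A, within cutoff: %s)\n",
              x$closest_frame$index, x$closest_frame$rmsd,
              x$closest_frame$within_cutoff))
  invisible(x)
}
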