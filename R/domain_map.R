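# Domain maps: named subunit selections, pivot anchors, CDR loops.
#
# Subunit ranges are 1-based inclusive (chain, start, end) triples, PDB
# convention.  The composite subunits scFv1/scFv2 resolve to
# VH + VL + linker of the corresponding arm.

#' Construct a domain map
#'
#' @param subunits named list; each element a data.frame (or list of
#'   3-element vectors) with columns chain, start, end.
#' @param pivot_anchors list of two `c(chain, resid)` pairs naming the Fc
#'   anchor residues whose midpoint defines the central pivot (the N-terminal
#'   Fc prolines in the antibody application).
#' @param cdr_loops optional named list of (chain, start, end) loop ranges.
#' @param mutations optional character vector of sequence annotations
#'   (metadata only, e.g. "H310A").
#' @return an object of class `DomainMap`.
#' @export
domain_map <- function(subunits, pivot_anchors, cdr_loops = list(),
                       mutations = character()) {
  norm_ranges <- function(x, what) {
    if (is.data.frame(x)) {
      df <- x
    } else {
      df <- do.call(rbind.data.frame, lapply(x, function(r) {
        as.list(stats::setNames(r, c("chain", "start", "end")))
      }))
    }
    if (!all(c("chain", "start", "end") %in% names(df)))
      stop(what, " ranges need chain, start, end")
    df$chain <- as.character(df$chain)
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    if (any(df$end < df$start)) stop(what, ": range end before start")
    df[, c("chain", "start", "end")]
  }
  if (is.null(names(subunits)) || any(names(subunits) == ""))
    stop("subunits must be a named list")
  subunits <- lapply(stats::setNames(nm = names(subunits)), function(nm)
    norm_ranges(subunits[[nm]], nm))
  if (length(pivot_anchors) != 2L)
    stop("pivot_anchors must name exactly two (chain, resid) residues")
  pivot_anchors <- lapply(pivot_anchors, function(a)
    list(chain = as.character(a[[1]]), resid = as.integer(a[[2]])))
  if (length(cdr_loops))
    cdr_loops <- lapply(stats::setNames(nm = names(cdr_loops)), function(nm)
      norm_ranges(cdr_loops[nm], nm))
  # pairwise overlap check between named subunits on the same chain
  expand <- function(df) unlist(lapply(seq_len(nrow(df)), function(i)
    paste(df$chain[i], df$start[i]:df$end[i])))
  keys <- lapply(subunits, expand)
  nm <- names(subunits)
  for (i in seq_along(keys)) for (j in seq_len(i - 1L)) {
    ov <- intersect(keys[[i]], keys[[j]])
    if (length(ov))
      stop("subunits ", nm[j], " and ", nm[i], " overlap at ", ov[1])
  }
  structure(list(subunits = subunits, pivot_anchors = pivot_anchors,
                 cdr_loops = cdr_loops, mutations = as.character(mutations)),
            class = "DomainMap")
}

#' @export
print.DomainMap <- function(x, ...) {
  cat("DomainMap:", length(x$subunits), "subunits (",
      paste(names(x$subunits), collapse = ", "), ")\n")
  cat("  pivot anchors:",
      paste(vapply(x$pivot_anchors, function(a)
        paste0(a$chain, a$resid), character(1)), collapse = " / "), "\n")
  if (length(x$cdr_loops))
    cat("  CDR loops:", paste(names(x$cdr_loops), collapse = ", "), "\n")
  invisible(x)
}

#' Parse a domain-map configuration file
#'
#' The configuration is YAML with blocks `subunits` (name -> list of
#' `[chain, start, end]` ranges), `pivot_anchors` (two `[chain, resid]`
#' pairs), optional `cdr_loops` and `mutations`.
#'
#' @param path path to a YAML file (or a YAML string).
#' @return a `DomainMap`.
#' @export
parse_domain_map <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  if (is.null(cfg$subunits) || !length(cfg$subunits))
    stop("domain map declares no subunits")
  if (is.null(cfg$pivot_anchors))
    stop("domain map is missing pivot_anchors")
  sub <- lapply(cfg$subunits, function(ranges) {
    if (!is.list(ranges[[1]])) ranges <- list(ranges)
    do.call(rbind.data.frame, lapply(ranges, function(r)
      list(chain = as.character(r[[1]]), start = as.integer(r[[2]]),
           end = as.integer(r[[3]]))))
  })
  cdr <- list()
  if (!is.null(cfg$cdr_loops))
    cdr <- lapply(cfg$cdr_loops, function(r)
      data.frame(chain = as.character(r[[1]]), start = as.integer(r[[2]]),
                 end = as.integer(r[[3]])))
  domain_map(sub, cfg$pivot_anchors, cdr_loops = cdr,
             mutations = as.character(unlist(cfg$mutations)))
}

#' Write a domain map to a YAML configuration file
#'
#' @param map a `DomainMap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_map <- function(map, path) {
  as_ranges <- function(df) lapply(seq_len(nrow(df)), function(i)
    list(df$chain[i], df$start[i], df$end[i]))
  cfg <- list(
    subunits = lapply(map$subunits, as_ranges),
    pivot_anchors = lapply(map$pivot_anchors, function(a) list(a$chain, a$resid))
  )
  if (length(map$cdr_loops))
    cfg$cdr_loops <- lapply(map$cdr_loops, function(df)
      list(df$chain[1], df$start[1], df$end[1]))
  if (length(map$mutations)) cfg$mutations <- as.list(map$mutations)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Resolve a subunit name to its (chain, start, end) ranges, understanding the
# scFvN composites (VHN + VLN + linkerN).
.subunit_ranges <- function(map, name) {
  if (name %in% names(map$subunits)) return(map$subunits[[name]])
  m <- regmatches(name, regexec("^scFv([0-9]+)$", name))[[1]]
  if (length(m)) {
    parts <- paste0(c("VH", "VL", "linker"), m[2])
    have <- intersect(parts, names(map$subunits))
    if (length(have) >= 2L)    # linker optional, VH+VL required
      return(do.call(rbind, map$subunits[have]))
  }
  if (name %in% names(map$cdr_loops)) return(map$cdr_loops[[name]])
  stop("unknown subunit: ", name)
}

.atoms_in_ranges <- function(structure, ranges) {
  a <- structure$atoms
  hit <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(ranges)))
    hit <- hit | (a$chain == ranges$chain[i] &
                    a$resid >= ranges$start[i] & a$resid <= ranges$end[i])
  which(hit)
}

#' Select atoms from a structure
#'
#' `selection` may be a subunit name from the domain map (composites
#' scFv1/scFv2 resolve to VH + VL + linker), a character vector of such
#' names (union), the filter `"CA"` (one alpha-carbon per amino-acid
#' residue), `"all"`, or a data.frame of (chain, start, end) ranges.  A
#' subunit name may be suffixed with `":CA"` to combine both filters.
#'
#' @param structure a `Structure`.
#' @param selection see Details.
#' @param map a `DomainMap`, required for subunit-name selections.
#' @return list with `indices` (atom row indices, order-stable), `xyz`
#'   (k x 3 matrix) and `masses` (a.m.u.).
#' @export
select_atoms <- function(structure, selection = "all", map = NULL) {
  a <- structure$atoms
  idx <- integer(0)
  if (is.data.frame(selection)) {
    idx <- .atoms_in_ranges(structure, selection)
  } else if (is.character(selection)) {
    for (sel in selection) {
      ca_only <- FALSE
      if (grepl(":CA$", sel)) { ca_only <- TRUE; sel <- sub(":CA$", "", sel) }
      if (sel == "all") {
        sub_idx <- seq_len(nrow(a))
      } else if (sel == "CA") {
        sub_idx <- which(a$atom_name == "CA" & a$element == "C")
      } else {
        if (is.null(map)) stop("subunit selection '", sel, "' requires a DomainMap")
        sub_idx <- .atoms_in_ranges(structure, .subunit_ranges(map, sel))
      }
      if (ca_only)
        sub_idx <- sub_idx[a$atom_name[sub_idx] == "CA" & a$element[sub_idx] == "C"]
      idx <- union(idx, sub_idx)
    }
    idx <- sort(idx)
  } else stop("unsupported selection type")
  if (!length(idx)) stop("selection matched no atoms")
  list(indices = idx, xyz = coords(structure)[idx, , drop = FALSE],
       masses = a$mass[idx])
}

#' Validate a domain map against a structure
#'
#' Checks that both pivot anchors resolve to at least one atom and that the
#' required subunits (scFv1, scFv2, Fc1, Fc2) each resolve to atoms.
#'
#' @param map a `DomainMap`.
#' @param structure a `Structure`.
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_domain_map <- function(map, structure) {
  a <- structure$atoms
  for (anc in map$pivot_anchors) {
    n <- sum(a$chain == anc$chain & a$resid == anc$resid)
    if (n == 0)
      stop("pivot anchor ", anc$chain, anc$resid, " resolves to no atoms")
  }
  for (nm in c("scFv1", "scFv2", "Fc1", "Fc2")) {
    idx <- .atoms_in_ranges(structure, .subunit_ranges(map, nm))
    if (!length(idx)) stop("required subunit ", nm, " resolves to no atoms")
  }
  invisible(TRUE)
}
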