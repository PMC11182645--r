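## Post-hoc analysis of MD coordinate series: per-frame chi1 and atom-pair
## distances, summaries, and two-state occupancy fractions.

#' Construct a trajectory object
#'
#' @param topology atom table (columns `chain`, `resno`, `resid`, `elety`).
#' @param xyz numeric array `[frame, atom, 3]` in Angstrom.
#' @param interval_ps sampling interval in picoseconds (default 10).
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(topology, xyz, interval_ps = 10) {
  if (length(dim(xyz)) != 3 || dim(xyz)[3] != 3)
    stop("xyz must be an array [frame, atom, 3]")
  if (dim(xyz)[2] != nrow(topology))
    stop("frame/topology mismatch: ", dim(xyz)[2], " atoms per frame vs ",
         nrow(topology), " topology rows")
  structure(list(topology = topology, xyz = xyz, interval_ps = interval_ps),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, sampled every %g ps (%.2f ns)\n",
              dim(x$xyz)[1], dim(x$xyz)[2], x$interval_ps,
              dim(x$xyz)[1] * x$interval_ps / 1000))
  invisible(x)
}

#' Read a multi-model PDB as a trajectory
#' @param path multi-model PDB file (one MODEL per frame).
#' @param interval_ps sampling interval in ps.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, interval_ps = 10) {
  p <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  a <- p$atom
  topo <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                     elety = a$elety, stringsAsFactors = FALSE)
  nf <- nrow(p$xyz)
  na <- nrow(topo)
  xyz <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf))
    xyz[f, , ] <- matrix(p$xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(topo, xyz, interval_ps = interval_ps)
}

traj_atom_index <- function(traj, sel) {
  if (is.character(sel)) sel <- parse_selector(sel)
  i <- which(traj$topology$chain == sel$chain &
               traj$topology$resno == sel$resno &
               traj$topology$elety == sel$elety)
  if (!length(i))
    stop(sprintf("selection %s/%d/%s not resolvable in trajectory topology",
                 sel$chain, sel$resno, sel$elety))
  i[1]
}

#' Two-state boundary at the minimum-density angle between two chi1 modes
#'
#' Builds a circular histogram (10-degree bins), locates the two dominant
#' modes, and returns the bin-centre angle of minimum density between them
#' (going the short way from mode 1 to mode 2... both inter-mode arcs are
#' scanned; the boundary on each arc is returned).
#'
#' @param chi numeric vector of angles in degrees.
#' @param bin_width histogram bin width in degrees.
#' @return numeric length-2 vector of boundary angles (degrees in (-180,180]).
#' @export
chi1_state_boundary <- function(chi, bin_width = 10) {
  breaks <- seq(-180, 180, by = bin_width)
  h <- graphics::hist(wrap180(chi), breaks = breaks, plot = FALSE)
  counts <- h$counts
  n <- length(counts)
  mids <- h$mids
  ## two dominant modes: largest bin, then largest bin at least 60 deg away
  m1 <- which.max(counts)
  sep <- abs(circular_diff(mids, mids[m1]))
  cand <- which(sep >= 60)
  m2 <- cand[which.max(counts[cand])]
  arc_min <- function(from, to) {
    i <- from
    path <- integer()
    while (i != to) {
      i <- if (i == n) 1L else i + 1L
      if (i != to) path <- c(path, i)
    }
    if (!length(path)) return((mids[from] + bin_width / 2))
    mids[path[which.min(counts[path])]]
  }
  sort(wrap180(c(arc_min(m1, m2), arc_min(m2, m1))))
}

#' Time-series metrics for tracked dihedrals and atom pairs
#'
#' Computes per-frame chi1 series (circular, degrees) for the requested
#' residues and per-frame distances (Angstrom) for the requested atom pairs,
#' with summary statistics. When `chi1_threshold` is supplied (or computed
#' from the series via [chi1_state_boundary()] when `two_state = TRUE`),
#' two-state occupancy fractions are reported.
#'
#' @param traj a [trajectory()].
#' @param chi1_residues list of `list(chain=, resno=)` (or "chain/resno/*"
#'   selector strings) for chi1 tracking.
#' @param distance_pairs list of length-2 selector vectors, e.g.
#'   `list(c("A/140/OE2", "A/401/O4"))`.
#' @param two_state compute two-state fractions for each chi1 series.
#' @param chi1_threshold optional fixed length-2 boundary (degrees) to use
#'   instead of the per-series minimum-density boundary.
#' @return object of class `TrajectoryMetrics`: list with `interval_ps`,
#'   `chi1` (named list of series), `distance` (named list of series),
#'   `summary` (data.frame `series`, `type`, `min`, `max`, `median`),
#'   `states` (data.frame `series`, `boundary_lo`, `boundary_hi`,
#'   `frac_state1`, `frac_state2` — state 1 is the arc containing the
#'   dominant mode).
#' @export
trajectory_metrics <- function(traj, chi1_residues = list(),
                               distance_pairs = list(),
                               two_state = length(chi1_residues) > 0,
                               chi1_threshold = NULL) {
  nf <- dim(traj$xyz)[1]
  chi_series <- list()
  for (r in chi1_residues) {
    if (is.character(r)) { s <- parse_selector(r); r <- list(chain = s$chain, resno = s$resno) }
    idx <- vapply(c("N", "CA", "CB", "CG"), function(a)
      traj_atom_index(traj, list(chain = r$chain, resno = r$resno,
                                 elety = a, alt = NA)), integer(1))
    series <- vapply(seq_len(nf), function(f)
      dihedral_angle(traj$xyz[f, idx[1], ], traj$xyz[f, idx[2], ],
                     traj$xyz[f, idx[3], ], traj$xyz[f, idx[4], ]),
      numeric(1))
    chi_series[[sprintf("%s/%d/chi1", r$chain, r$resno)]] <- series
  }
  dist_series <- list()
  for (pr in distance_pairs) {
    ia <- traj_atom_index(traj, pr[[1]])
    ib <- traj_atom_index(traj, pr[[2]])
    series <- sqrt(rowSums((traj$xyz[, ia, , drop = FALSE] -
                              traj$xyz[, ib, , drop = FALSE])[, 1, ]^2))
    nm <- paste(if (is.character(pr[[1]])) pr[[1]] else "a",
                if (is.character(pr[[2]])) pr[[2]] else "b", sep = "--")
    dist_series[[nm]] <- series
  }
  summ <- do.call(rbind, c(
    lapply(names(chi_series), function(nm) {
      s <- chi_series[[nm]]
      data.frame(series = nm, type = "chi1", min = min(s), max = max(s),
                 median = stats::median(s), stringsAsFactors = FALSE)
    }),
    lapply(names(dist_series), function(nm) {
      s <- dist_series[[nm]]
      data.frame(series = nm, type = "distance", min = min(s), max = max(s),
                 median = stats::median(s), stringsAsFactors = FALSE)
    })))
  states <- NULL
  if (two_state && length(chi_series)) {
    states <- do.call(rbind, lapply(names(chi_series), function(nm) {
      s <- wrap180(chi_series[[nm]])
      bnd <- if (!is.null(chi1_threshold)) sort(wrap180(chi1_threshold))
             else chi1_state_boundary(s)
      inside <- s > bnd[1] & s <= bnd[2]
      ## state 1 = arc containing the dominant mode
      f_in <- mean(inside)
      dom_inside <- {
        h <- graphics::hist(s, breaks = seq(-180, 180, 10), plot = FALSE)
        m <- h$mids[which.max(h$counts)]
        m > bnd[1] & m <= bnd[2]
      }
      f1 <- if (dom_inside) f_in else 1 - f_in
      data.frame(series = nm, boundary_lo = bnd[1], boundary_hi = bnd[2],
                 frac_state1 = f1, frac_state2 = 1 - f1,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(interval_ps = traj$interval_ps, chi1 = chi_series,
                 distance = dist_series, summary = summ, states = states),
            class = "TrajectoryMetrics")
}

#' @export
print.TrajectoryMetrics <- function(x, ...) {
  cat(sprintf("TrajectoryMetrics: %d chi1 series, %d distance series (interval %g ps)\n",
              length(x$chi1), length(x$distance), x$interval_ps))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  if (!is.null(x$states)) print(x$states, row.names = FALSE)
  invisible(x)
}
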