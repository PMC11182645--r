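## Seeded synthetic-data generators. Every generator is a pure function of
## (spec, seed) and returns its ground truth alongside the data, so each
## downstream pipeline stage can be tested by manifest recovery.

#' Default subsite geometry for synthetic fixtures
#'
#' Canonical sites on a straight cleft along x at 5 Angstrom spacing
#' (half-integer registers at the midpoints), with +1' displaced 4 Angstrom
#' above +1.
#'
#' @param spacing inter-site spacing (Angstrom).
#' @param include_prime include the +1' site.
#' @return a [subsite_frame()].
#' @export
default_subsite_geometry <- function(spacing = 5.0, include_prime = TRUE) {
  ints <- INTEGER_LABELS
  x <- subsite_cleft_index(ints) * spacing
  labels <- ints
  xyz <- cbind(x, 0, 0)
  for (h in HALF_LABELS) {
    labels <- c(labels, h)
    xyz <- rbind(xyz, c(subsite_cleft_index(h) * spacing, 0, 0))
  }
  if (include_prime) {
    labels <- c(labels, "+1'")
    xyz <- rbind(xyz, c(subsite_cleft_index("+1") * spacing, 0, 4))
  }
  subsite_frame(labels, xyz)
}

## flat-chair pyranose template: ring atoms on a hexagon (radius 1.45 A) with
## alternating +-0.25 A pucker; C1 points toward the next (reducing-side)
## site. Only centroid geometry and bridging topology matter downstream.
ring_template <- function(centroid, pucker = 0.25, radius = 1.45) {
  names <- c("C1", "C2", "C3", "C4", "C5", "O5")
  ang <- (0:5) * 60 * pi / 180
  z <- rep(c(pucker, -pucker), 3)
  xyz <- cbind(centroid[1] + radius * cos(ang),
               centroid[2] + radius * sin(ang),
               centroid[3] + z)
  rownames(xyz) <- names
  xyz
}

## substituents placed outward from the ring; the bridging O4 is handled by
## the caller (it sits between consecutive rings)
ring_substituents <- function(ring, centroid) {
  out <- function(atom, scale, dz = 0) {
    p <- ring[atom, ]
    p + scale * unit(c(p[1:2] - centroid[1:2], 0)) + c(0, 0, dz)
  }
  subs <- rbind(O3 = out("C3", 1.4), O6 = out("C5", 1.2, 1.0),
                N2 = out("C2", 1.45), C7 = out("C2", 2.6, 0.6))
  subs <- rbind(subs, O7 = subs["C7", ] + c(0, 0.6, 1.05))
  subs
}

atom_row <- function(record, chain, resno, resid, elety, alt, xyz, o, b, elesy) {
  data.frame(record = record, chain = chain, resno = as.integer(resno),
             resid = resid, elety = elety, alt = alt,
             x = xyz[1], y = xyz[2], z = xyz[3], o = o, b = b, elesy = elesy,
             stringsAsFactors = FALSE)
}

## Build one oligosaccharide conformer along the frame. `subsites` are the
## consecutive registers of its rings (non-reducing -> reducing).
build_ligand_conformer <- function(frame, chain, resno_start, alt, subsites,
                                   occupancy, anomer = NULL, jitter = 0,
                                   bfactor = 15) {
  cents <- lapply(subsites, function(lab) {
    i <- which(frame$label == lab)
    if (!length(i)) stop("subsite ", lab, " absent from frame")
    ctr <- as.numeric(frame[i, c("x", "y", "z")])
    if (jitter > 0) {
      d <- stats::rnorm(3)
      ctr <- ctr + unit(d) * stats::runif(1, 0, jitter)
    }
    ctr
  })
  rows <- list()
  rings <- list()
  for (k in seq_along(cents)) {
    ring <- ring_template(cents[[k]])
    rings[[k]] <- ring
    resno <- resno_start + (k - 1)
    for (nm in rownames(ring))
      rows[[length(rows) + 1]] <- atom_row("HETATM", chain, resno, "NAG", nm,
                                           alt, ring[nm, ], occupancy, bfactor,
                                           substr(nm, 1, 1))
    subs <- ring_substituents(ring, cents[[k]])
    for (nm in rownames(subs))
      rows[[length(rows) + 1]] <- atom_row("HETATM", chain, resno, "NAG", nm,
                                           alt, subs[nm, ], occupancy, bfactor,
                                           substr(nm, 1, 1))
    if (k > 1) {
      ## bridging O4 of ring k: apex between previous ring's C1 and this C4
      c1 <- rings[[k - 1]]["C1", ]; c4 <- ring["C4", ]
      mid <- (c1 + c4) / 2
      half <- vnorm(c4 - c1) / 2
      h <- sqrt(max(0.01, 1.43^2 - half^2))
      o4 <- mid + c(0, 0, h)
      rows[[length(rows) + 1]] <- atom_row("HETATM", chain, resno, "NAG", "O4",
                                           alt, o4, occupancy, bfactor, "O")
    } else {
      o4 <- ring["C4", ] + 1.43 * unit(c(ring["C4", 1:2] - cents[[k]][1:2], 0))
      rows[[length(rows) + 1]] <- atom_row("HETATM", chain, resno, "NAG", "O4",
                                           alt, o4, occupancy, bfactor, "O")
    }
    if (k == length(cents) && !is.null(anomer)) {
      ctr <- cents[[k]]
      ring_n <- c(0, 0, 1)  # flat template: normal is z
      o1 <- if (anomer == "alpha") ring["C1", ] + 1.43 * ring_n
            else ring["C1", ] + 1.43 * unit(c(ring["C1", 1:2] - ctr[1:2], 0))
      rows[[length(rows) + 1]] <- atom_row("HETATM", chain, resno, "NAG", "O1",
                                           alt, o1, occupancy, bfactor, "O")
    }
  }
  do.call(rbind, rows)
}

## Build the catalytic triad: D2 with one or two rotamers at exact chi1, and
## D1/E positioned so the carboxylate-distance classifier reproduces the
## requested states.
build_triad_residues <- function(chain, d2_states, d2_occ, d2_chi1,
                                 d1_resno = 136, d2_resno = 138, e_resno = 140,
                                 origin = c(15, -7, 0), bfactor = 10) {
  n <- origin + c(-1.46, 0, 0)
  ca <- origin
  cc <- origin + c(0.55, 1.39, 0)
  o <- cc + c(1.2, 0.4, 0)
  cb <- place_atom(cc, n, ca, 1.53, 110.4, -122)
  rows <- list()
  for (nm in c("N", "CA", "C", "O"))
    rows[[length(rows) + 1]] <- atom_row("ATOM", chain, d2_resno, "ASP", nm, "",
                                         switch(nm, N = n, CA = ca, C = cc, O = o),
                                         1.0, bfactor, substr(nm, 1, 1))
  cg_of <- list(); od_of <- list()
  multi <- length(d2_states) > 1
  for (a in names(d2_states)) {
    alt <- if (multi) a else ""
    cg <- place_atom(n, ca, cb, 1.52, 113.9, d2_chi1[[a]])
    od1 <- place_atom(ca, cb, cg, 1.25, 119, -20)
    od2 <- place_atom(ca, cb, cg, 1.25, 119, 160)
    cg_of[[a]] <- cg; od_of[[a]] <- od1
    for (x in list(list("CB", cb), list("CG", cg), list("OD1", od1),
                   list("OD2", od2))) {
      rows[[length(rows) + 1]] <- atom_row("ATOM", chain, d2_resno, "ASP",
                                           x[[1]], alt, x[[2]], d2_occ[[a]],
                                           bfactor, substr(x[[1]], 1, 1))
    }
  }
  ## partner carboxylates at `dist` A from the matching rotamer's OD1
  place_partner <- function(resno, resid, oname1, oname2, cname, target_alt,
                            backbone_names, dist = 2.6) {
    od <- od_of[[target_alt]]
    cg <- cg_of[[target_alt]]
    dirv <- unit(od - cg)
    o1 <- od + dist * dirv
    cx <- o1 + 1.25 * dirv + c(0, 0, 0.4)
    o2 <- cx + c(0.9, 0.9, -0.4)
    backbone <- o1 + 3.0 * dirv
    out <- list()
    out[[1]] <- atom_row("ATOM", chain, resno, resid, oname1, "", o1, 1.0,
                         bfactor, "O")
    out[[2]] <- atom_row("ATOM", chain, resno, resid, cname, "", cx, 1.0,
                         bfactor, "C")
    out[[3]] <- atom_row("ATOM", chain, resno, resid, oname2, "", o2, 1.0,
                         bfactor, "O")
    for (nm in backbone_names)
      out[[length(out) + 1]] <- atom_row("ATOM", chain, resno, resid, nm, "",
                                         backbone + switch(nm, N = c(0, 0, 0),
                                                           CA = c(1.46, 0, 0),
                                                           CB = c(2.0, 1.4, 0),
                                                           CG = c(3.4, 1.7, 0)),
                                         1.0, bfactor, substr(nm, 1, 1))
    out
  }
  active_alt <- names(d2_states)[d2_states == "active"]
  inactive_alt <- names(d2_states)[d2_states == "inactive"]
  ## when a state has no conformer, its partner residue still exists but sits
  ## well outside hydrogen-bond range of the other rotamer
  e_dist <- if (length(active_alt)) 2.6 else 6.0
  d1_dist <- if (length(inactive_alt)) 2.6 else 6.0
  if (!length(active_alt)) active_alt <- names(d2_states)[1]
  if (!length(inactive_alt)) inactive_alt <- names(d2_states)[1]
  rows <- c(rows, place_partner(e_resno, "GLU", "OE1", "OE2", "CD",
                                active_alt[1], c("N", "CA", "CB", "CG"),
                                dist = e_dist))
  rows <- c(rows, place_partner(d1_resno, "ASP", "OD1", "OD2", "CG",
                                inactive_alt[1], c("N", "CA", "CB"),
                                dist = d1_dist))
  do.call(rbind, rows)
}

#' Generate a multi-conformer structure fixture
#'
#' Builds a synthetic GH18-like active site: oligosaccharide conformers with
#' known subsite registers and occupancies along a straight cleft, plus a
#' catalytic triad whose central aspartate has one or two rotamers
#' constructed so the carboxylate-distance classifier reproduces the
#' requested states. Written as mmCIF and PDB with full altloc bookkeeping.
#'
#' @param spec list with optional elements:
#'   `chains` — named list (per chain id) each with `conformers` (list of
#'   `list(resno, alt, subsites, occupancy, anomer)`) and `d2`
#'   (`list(states, occupancy, chi1)` keyed by altloc);
#'   `frame` — a [subsite_frame()] (default [default_subsite_geometry()]);
#'   `jitter_A` — ring-centroid jitter radius (default 0).
#' @param seed RNG seed.
#' @param dir output directory (default `tempdir()`); set `NULL` to skip
#'   writing files.
#' @return list with `model` (StructureModel), `files` (paths or NULL), and
#'   `manifest` (ground truth: per-ring subsite labels, expected per-subsite
#'   occupancies, D2 states/occupancies/chi1, seed, spec).
#' @export
gen_structure_fixture <- function(spec = list(), seed = 1, dir = tempdir()) {
  set.seed(seed)
  frame <- spec$frame
  if (is.null(frame)) frame <- default_subsite_geometry()
  jitter <- if (is.null(spec$jitter_A)) 0 else spec$jitter_A
  chains <- spec$chains
  if (is.null(chains)) {
    chains <- list(A = list(
      conformers = list(
        list(resno = 401, alt = "A", subsites = c("-3", "-2"), occupancy = 0.40),
        list(resno = 401, alt = "C", subsites = c("-2", "-1"), occupancy = 0.30),
        list(resno = 403, alt = "D", subsites = c("-1", "+1"), occupancy = 0.25)),
      d2 = list(states = c(A = "active", B = "inactive"),
                occupancy = c(A = 0.55, B = 0.45),
                chi1 = c(A = -65, B = 175))))
  }
  rows <- list()
  manifest_rings <- list()
  d2_truth <- list()
  for (ch in names(chains)) {
    cspec <- chains[[ch]]
    ## every chain is an independent copy of the same cleft frame (as with
    ## NCS-related chains sharing identical local site geometry)
    fr <- frame
    occ_sum <- vapply(cspec$conformers, function(cf) cf$occupancy, numeric(1))
    for (cf in cspec$conformers) {
      if (cf$occupancy < 0 || cf$occupancy > 1)
        stop("conformer occupancy outside [0,1]")
      tab <- build_ligand_conformer(fr, ch, cf$resno, cf$alt, cf$subsites,
                                    cf$occupancy,
                                    anomer = cf$anomer, jitter = jitter)
      rows[[length(rows) + 1]] <- tab
      manifest_rings[[length(manifest_rings) + 1]] <- data.frame(
        chain = ch, resno = cf$resno + seq_along(cf$subsites) - 1,
        alt = cf$alt, ring_index = seq_along(cf$subsites),
        subsite = cf$subsites, occupancy = cf$occupancy,
        stringsAsFactors = FALSE)
    }
    ## per-subsite overflow guard on the generator's own bookkeeping
    man <- do.call(rbind, manifest_rings)
    if (!is.null(man)) {
      man_ch <- man[man$chain == ch, ]
      agg <- tapply(man_ch$occupancy, man_ch$subsite, sum)
      if (any(agg > 1 + 0.05))
        stop("conformer spec sums to > 1 occupancy at subsite ",
             names(agg)[which.max(agg)])
    }
    d2 <- cspec$d2
    if (is.null(d2)) d2 <- list(states = c(A = "active"), occupancy = c(A = 1),
                                chi1 = c(A = -65))
    rows[[length(rows) + 1]] <- build_triad_residues(
      ch, d2$states, d2$occupancy, d2$chi1, origin = c(15, -7, 0))
    d2_truth[[ch]] <- d2
  }
  atoms <- do.call(rbind, rows)
  model <- structure_model(atoms, id = sprintf("synthetic_site_seed%d", seed),
                           dialect = "memory")
  files <- NULL
  if (!is.null(dir)) {
    base <- file.path(dir, sprintf("synthetic_site_seed%d", seed))
    files <- c(cif = paste0(base, ".cif"), pdb = paste0(base, ".pdb"))
    write_structure(model, files[["cif"]], format = "mmcif")
    write_structure(model, files[["pdb"]], format = "pdb")
  }
  manifest <- list(
    seed = seed,
    frame = frame,
    rings = do.call(rbind, manifest_rings),
    subsite_occupancy = {
      man <- do.call(rbind, manifest_rings)
      if (is.null(man)) NULL else {
        agg <- stats::aggregate(occupancy ~ chain + subsite, man, sum)
        names(agg)[3] <- "occupancy"
        agg
      }
    },
    d2 = d2_truth,
    jitter_A = jitter,
    files = files)
  list(model = model, files = files, manifest = manifest)
}

#' Generate a Gaussian-atom density map for a model
#'
#' The map is the sum of per-atom isotropic Gaussians with width from the
#' B-factor (`sigma^2 = B / (8 pi^2)`) and amplitude proportional to
#' occupancy times atomic number, sigma-scaled over the grid. Deterministic
#' given its inputs.
#'
#' @param model a StructureModel (subset it first for a local map).
#' @param bfactor optional override for every atom's B (Angstrom^2).
#' @param spacing voxel spacing (Angstrom, default 0.5).
#' @param margin padding around the model's bounding box (default 3).
#' @param bbox optional fixed extent `list(lo = c(x,y,z), hi = c(x,y,z))`
#'   overriding the model-derived bounding box (useful when comparing maps
#'   of different models on one grid).
#' @return a sigma-scaled [density_map()].
#' @export
gen_density_map <- function(model, bfactor = NULL, spacing = 0.5, margin = 3,
                            bbox = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  at <- model$atoms
  zmap <- c(H = 1, C = 6, N = 7, O = 8, S = 16)
  if (is.null(bbox))
    bbox <- list(lo = c(min(at$x), min(at$y), min(at$z)),
                 hi = c(max(at$x), max(at$y), max(at$z)))
  lo <- floor((bbox$lo - margin) / spacing) * spacing
  hi <- ceiling((bbox$hi + margin) / spacing) * spacing
  nx <- round((hi - lo) / spacing) + 1
  gx <- lo[1] + (seq_len(nx[1]) - 1) * spacing
  gy <- lo[2] + (seq_len(nx[2]) - 1) * spacing
  gz <- lo[3] + (seq_len(nx[3]) - 1) * spacing
  vals <- array(0, dim = nx)
  for (i in seq_len(nrow(at))) {
    b <- if (is.null(bfactor)) at$b[i] else bfactor
    s2 <- max(b, 1) / (8 * pi^2)
    amp <- at$o[i] * zmap[[ifelse(at$elesy[i] %in% names(zmap), at$elesy[i], "C")]]
    ex <- exp(-(gx - at$x[i])^2 / (2 * s2))
    ey <- exp(-(gy - at$y[i])^2 / (2 * s2))
    ez <- exp(-(gz - at$z[i])^2 / (2 * s2))
    vals <- vals + amp * (ex %o% ey %o% ez)
  }
  sigma_scale(density_map(vals, origin = lo, spacing = spacing,
                          unit = "absolute"))
}

#' Generate a two-state chi1 jump trajectory with a bounded distance series
#'
#' The chi1 process is a two-state Markov chain over the supplied rotamer
#' angles with Gaussian angular jitter; the distance process is a reflected
#' random walk inside stated bounds. Frames carry a minimal topology: one
#' aspartate (N/CA/CB fixed, CG rotated to the per-frame chi1) and a probe
#' atom pair realising the distance series.
#'
#' @param spec list with optional `n_frames` (default 1000), `interval_ps`
#'   (10), `angles` (`c(state1 = -65, state2 = 175)`), `p12`, `p21`
#'   (transition probabilities per frame, default 0.03 / 0.07),
#'   `jitter_sd` (degrees, default 8), `dist_bounds` (`c(1.5, 2.3)`),
#'   `dist_step_sd` (0.05 Angstrom).
#' @param seed RNG seed.
#' @return list with `traj` (a [trajectory()]) and `manifest` (per-frame
#'   states, realised chi1 and distance series, stationary state fractions,
#'   spec, seed).
#' @export
gen_trajectory <- function(spec = list(), seed = 1) {
  defaults <- list(n_frames = 1000, interval_ps = 10,
                   angles = c(state1 = -65, state2 = 175),
                   p12 = 0.03, p21 = 0.07, jitter_sd = 8,
                   dist_bounds = c(1.5, 2.3), dist_step_sd = 0.05)
  spec <- utils::modifyList(defaults, spec)
  if (spec$p12 < 0 || spec$p12 > 1 || spec$p21 < 0 || spec$p21 > 1)
    stop("transition probabilities must lie in [0, 1]")
  set.seed(seed)
  nf <- spec$n_frames
  state <- integer(nf)
  state[1] <- 1L
  for (f in 2:nf) {
    p <- if (state[f - 1] == 1L) spec$p12 else spec$p21
    flip <- stats::runif(1) < p
    state[f] <- if (flip) 3L - state[f - 1] else state[f - 1]
  }
  chi <- wrap180(spec$angles[state] + stats::rnorm(nf, 0, spec$jitter_sd))
  lo <- spec$dist_bounds[1]; hi <- spec$dist_bounds[2]
  d <- numeric(nf)
  d[1] <- (lo + hi) / 2
  for (f in 2:nf) {
    x <- d[f - 1] + stats::rnorm(1, 0, spec$dist_step_sd)
    while (x < lo || x > hi) x <- ifelse(x < lo, 2 * lo - x, 2 * hi - x)
    d[f] <- x
  }
  ## topology: ASP 138 (N/CA/CB/CG) + probe pair P1 (fixed), P2 (moving)
  n <- c(-1.46, 0, 0); ca <- c(0, 0, 0)
  cc <- c(0.55, 1.39, 0)
  cb <- place_atom(cc, n, ca, 1.53, 110.4, -122)
  topo <- data.frame(chain = "A", resno = c(138, 138, 138, 138, 900, 901),
                     resid = c(rep("ASP", 4), "PRB", "PRB"),
                     elety = c("N", "CA", "CB", "CG", "P1", "P2"),
                     stringsAsFactors = FALSE)
  xyz <- array(NA_real_, c(nf, 6, 3))
  p1 <- c(10, 0, 0)
  for (f in seq_len(nf)) {
    cg <- place_atom(n, ca, cb, 1.52, 113.9, chi[f])
    xyz[f, 1, ] <- n; xyz[f, 2, ] <- ca; xyz[f, 3, ] <- cb; xyz[f, 4, ] <- cg
    xyz[f, 5, ] <- p1
    xyz[f, 6, ] <- p1 + c(d[f], 0, 0)
  }
  traj <- trajectory(topo, xyz, interval_ps = spec$interval_ps)
  list(traj = traj,
       manifest = list(seed = seed, spec = spec, states = state,
                       chi1 = chi, distance = d,
                       frac_state1 = mean(state == 1L),
                       frac_state2 = mean(state == 2L)))
}

#' Write a trajectory as a multi-model PDB
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  nf <- dim(traj$xyz)[1]
  xyz <- t(vapply(seq_len(nf), function(f) as.numeric(t(traj$xyz[f, , ])),
                  numeric(3 * nrow(traj$topology))))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   type = ifelse(traj$topology$resid %in% c("PRB", SUGAR_CODES),
                                 "HETATM", "ATOM"),
                   resno = traj$topology$resno, resid = traj$topology$resid,
                   eleno = seq_len(nrow(traj$topology)),
                   elety = traj$topology$elety, chain = traj$topology$chain,
                   o = rep(1, nrow(traj$topology)),
                   b = rep(0, nrow(traj$topology)))
  invisible(path)
}

#' Default per-pH kinetic ground truth
#'
#' kcat follows the calibrated two-mechanism model (6.3-fold between the pH
#' extremes, secondary optimum at pH 6.5); KM is log-linear in pH from
#' 30 uM at pH 7.4 rising 2.5-fold toward pH 2.0.
#'
#' @param pH_panel assay pH values.
#' @param mechanism a [mechanism_params()] (default [calibrate_mechanism()]).
#' @param KM_ref KM at the high-pH anchor (uM).
#' @param KM_fold KM fold increase from pH 7.4 to pH 2.0.
#' @return data.frame `pH`, `kcat`, `KM`.
#' @export
default_kinetic_truth <- function(pH_panel = c(seq(2, 7, 0.5), 7.4),
                                  mechanism = calibrate_mechanism(),
                                  KM_ref = 30, KM_fold = 2.5) {
  data.frame(pH = pH_panel,
             kcat = mechanism_total(mechanism, pH_panel),
             KM = KM_ref * KM_fold^((7.4 - pH_panel) / 5.4))
}

#' Generate an endpoint-assay plate cohort
#'
#' Emulates the endpoint fluorogenic assay: reaction wells accumulate product
#' linearly at the Michaelis-Menten rate for each (pH, substrate), read as
#' RFU through a standard-curve slope with optional multiplicative Gaussian
#' noise; fluorophore standards are included per pH. Substrate depletion
#' beyond 10 percent of the initial concentration over the time course
#' triggers a warning (the linear-regime assumption is then questionable).
#'
#' @param params list with optional `truth` (data.frame `pH`, `kcat`, `KM`;
#'   default [default_kinetic_truth()]), `enzyme_uM` (0.1), `substrate_uM`
#'   (2-fold series from 117), `timepoints_s` (`c(0,15,30,45,60,90)`),
#'   `replicates` (4), `std_slope` (120 RFU/uM), `std_uM`
#'   (`c(50, 25, 12.5, 6.25, 3.125)`), `std_replicates` (8), `noise_sd_rel`
#'   (relative RFU noise, default 0.03), `product_inhibition` (FALSE),
#'   `inhibition_onset_uM` (80), `inhibition_strength` (0.3), `no_warn`
#'   (suppress the depletion warning).
#' @param seed RNG seed.
#' @return list with `plate` (plate data.frame, `enzyme_uM` attribute set)
#'   and `manifest` (true parameters incl. per-condition rates, seed).
#' @export
gen_kinetics_plate <- function(params = list(), seed = 1) {
  defaults <- list(truth = NULL, enzyme_uM = DEFAULT_ENZYME_UM,
                   substrate_uM = 117 / 2^(0:7),
                   timepoints_s = DEFAULT_TIMEPOINTS, replicates = 4,
                   std_slope = 120, std_uM = c(50, 25, 12.5, 6.25, 3.125),
                   std_replicates = 8, noise_sd_rel = 0.03,
                   product_inhibition = FALSE, inhibition_onset_uM = 80,
                   inhibition_strength = 0.3, no_warn = FALSE)
  params <- utils::modifyList(defaults, params, keep.null = TRUE)
  if (is.null(params$truth)) params$truth <- default_kinetic_truth()
  set.seed(seed)
  truth <- params$truth
  smax <- max(params$substrate_uM)
  rows <- list()
  rate_truth <- list()
  max_depl <- 0
  for (i in seq_len(nrow(truth))) {
    ph <- truth$pH[i]
    vmax <- truth$kcat[i] * params$enzyme_uM
    for (s in params$substrate_uM) {
      v <- vmax * s / (truth$KM[i] + s)
      if (params$product_inhibition && s > params$inhibition_onset_uM) {
        att <- 1 - params$inhibition_strength *
          (s - params$inhibition_onset_uM) / (smax - params$inhibition_onset_uM)
        v <- v * att
      }
      depl <- v * max(params$timepoints_s) / s
      max_depl <- max(max_depl, depl)
      rate_truth[[length(rate_truth) + 1]] <-
        data.frame(pH = ph, substrate_uM = s, rate = v)
      for (rep in seq_len(params$replicates)) for (t in params$timepoints_s) {
        rfu0 <- params$std_slope * v * t
        rfu <- rfu0
        if (params$noise_sd_rel > 0)
          rfu <- max(0, rfu0 + stats::rnorm(1, 0, params$noise_sd_rel *
                                              max(rfu0, 1)))
        rows[[length(rows) + 1]] <- data.frame(
          pH = ph, substrate_uM = s, time_s = t, replicate = rep, rfu = rfu,
          well_type = "reaction", stringsAsFactors = FALSE)
      }
    }
    for (conc in c(params$std_uM, 0)) for (rep in seq_len(params$std_replicates)) {
      rfu0 <- params$std_slope * conc
      rfu <- rfu0
      if (params$noise_sd_rel > 0)
        rfu <- max(0, rfu0 + stats::rnorm(1, 0, params$noise_sd_rel *
                                            max(rfu0, 1)))
      rows[[length(rows) + 1]] <- data.frame(
        pH = ph, substrate_uM = conc, time_s = NA_real_, replicate = rep,
        rfu = rfu, well_type = "standard", stringsAsFactors = FALSE)
    }
  }
  if (max_depl > 0.10 && !params$no_warn)
    warning(sprintf("substrate depletion reaches %.1f%% over the time course; linear-regime assumption is strained",
                    100 * max_depl))
  plate <- do.call(rbind, rows)
  attr(plate, "enzyme_uM") <- params$enzyme_uM
  list(plate = plate,
       manifest = list(seed = seed, params = params, truth = truth,
                       rates = do.call(rbind, rate_truth),
                       max_depletion = max_depl))
}
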