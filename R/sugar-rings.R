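## Sugar rings and ligand instances.
##
## A ligand instance is one conformer of one oligosaccharide molecule: the
## maximal set of GlcNAc (NAG) residues sharing an altloc and connected by
## glycosidic C1(i)-O-C4(i+1) bridges. Rings are ordered from the
## non-reducing end (free O4) to the reducing end (free anomeric C1).

GLYCOSIDIC_MAX <- 1.8  # Angstrom, per-bond ceiling for a bridging oxygen

#' Enumerate ligand instances (oligosaccharide conformers)
#'
#' @param model a StructureModel.
#' @return data.frame with one row per ring per instance: `instance_id`
#'   (chain/min-resno/altloc string), `chain`, `alt`, `resno` (ring residue),
#'   `ring_index` (1 = non-reducing end), `n_rings`, `occupancy`.
#' @export
ligand_instances <- function(model) {
  conf <- ligand_conformers(model)
  empty <- data.frame(instance_id = character(), chain = character(),
                      alt = character(), resno = integer(),
                      ring_index = integer(), n_rings = integer(),
                      occupancy = numeric())
  if (!nrow(conf)) return(empty)
  at <- model$atoms
  out <- list()
  for (key in split(seq_len(nrow(conf)), paste(conf$chain, conf$alt, sep = "\r"))) {
    g <- conf[key, , drop = FALSE]
    pos <- function(resno, name) {
      i <- which(at$chain == g$chain[1] & at$resno == resno &
                   at$alt == g$alt[1] & at$elety == name & at$resid %in% SUGAR_CODES)
      if (!length(i)) return(NULL)
      c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
    }
    n <- nrow(g)
    ## adjacency: edge i -> j when C1(res i) is within reach of O4(res j)
    succ <- rep(NA_integer_, n)
    pred <- rep(NA_integer_, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      c1 <- pos(g$resno[i], "C1"); o4 <- pos(g$resno[j], "O4")
      if (is.null(c1) || is.null(o4)) next
      if (vnorm(c1 - o4) < GLYCOSIDIC_MAX) { succ[i] <- j; pred[j] <- i }
    }
    visited <- rep(FALSE, n)
    for (start in order(g$resno)) {
      if (visited[start] || !is.na(pred[start])) next
      chain_idx <- start
      k <- start
      while (!is.na(succ[k]) && !visited[succ[k]]) {
        k <- succ[k]
        chain_idx <- c(chain_idx, k)
      }
      visited[chain_idx] <- TRUE
      iid <- sprintf("%s/%d/%s", g$chain[1], min(g$resno[chain_idx]),
                     ifelse(g$alt[1] == "", "-", g$alt[1]))
      out[[length(out) + 1]] <- data.frame(
        instance_id = iid, chain = g$chain[1], alt = g$alt[1],
        resno = g$resno[chain_idx], ring_index = seq_along(chain_idx),
        n_rings = length(chain_idx),
        occupancy = g$occupancy[match(g$resno[chain_idx], g$resno)],
        stringsAsFactors = FALSE)
    }
    ## isolated leftovers (shouldn't happen, but keep them as 1-ring instances)
    for (i in which(!visited)) {
      out[[length(out) + 1]] <- data.frame(
        instance_id = sprintf("%s/%d/%s", g$chain[1], g$resno[i],
                              ifelse(g$alt[1] == "", "-", g$alt[1])),
        chain = g$chain[1], alt = g$alt[1], resno = g$resno[i],
        ring_index = 1L, n_rings = 1L, occupancy = g$occupancy[i],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  if (any(res$n_rings > 6))
    warning("ligand instance with more than 6 rings; check linkage detection")
  rownames(res) <- NULL
  res
}

#' Extract sugar rings with anomeric assignment
#'
#' Every ring of every ligand instance is returned. A ring missing one of the
#' six pyranose ring atoms (C1, C2, C3, C4, C5, O5) is skipped with a warning.
#' The anomer is assigned only when the anomeric hydroxyl O1 is present:
#' alpha when the C1->O1 bond is axial to the ring mean plane (angle to the
#' ring normal below 45 degrees), beta when equatorial.
#'
#' @param model a StructureModel.
#' @return list of `SugarRing` objects: each a list with `chain`, `resno`,
#'   `alt`, `instance_id`, `ring_index`, `occupancy`, `centroid`, `normal`,
#'   `anomer` ("alpha"/"beta"/"unknown"), and `atoms` (named position matrix).
#' @export
extract_sugar_rings <- function(model) {
  inst <- ligand_instances(model)
  rings <- list()
  at <- model$atoms
  for (i in seq_len(nrow(inst))) {
    r <- inst[i, ]
    sel <- at$chain == r$chain & at$resno == r$resno & at$alt == r$alt &
      at$resid %in% SUGAR_CODES
    res_atoms <- at[sel, , drop = FALSE]
    m <- as.matrix(res_atoms[, c("x", "y", "z")])
    rownames(m) <- res_atoms$elety
    missing <- setdiff(RING_ATOMS, res_atoms$elety)
    if (length(missing)) {
      warning(sprintf("ring %s/%d altloc '%s' missing atom(s) %s; skipped",
                      r$chain, r$resno, r$alt, paste(missing, collapse = ",")))
      next
    }
    ring_xyz <- m[RING_ATOMS, , drop = FALSE]
    centroid <- colMeans(ring_xyz)
    sv <- svd(sweep(ring_xyz, 2, centroid))
    normal <- sv$v[, 3]
    anomer <- "unknown"
    if ("O1" %in% rownames(m)) {
      v <- unit(m["O1", ] - m["C1", ])
      ang <- acos(min(1, abs(sum(v * normal)))) * 180 / pi
      anomer <- if (ang < 45) "alpha" else "beta"
    }
    rings[[length(rings) + 1]] <- structure(
      list(chain = r$chain, resno = r$resno, alt = r$alt,
           instance_id = r$instance_id, ring_index = r$ring_index,
           occupancy = r$occupancy, centroid = centroid, normal = normal,
           anomer = anomer, atoms = m),
      class = "SugarRing")
  }
  rings
}

#' @export
print.SugarRing <- function(x, ...) {
  cat(sprintf("SugarRing %s ring %d (%s/%d.%s) occ %.2f anomer %s\n",
              x$instance_id, x$ring_index, x$chain, x$resno,
              ifelse(x$alt == "", "-", x$alt), x$occupancy, x$anomer))
  invisible(x)
}
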