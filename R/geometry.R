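## Catalytic-site interaction geometry: pairwise distances over altloc
## combinations, glycosidic-bridge geometry at the -1/+1 cleavage site, and
## the full active-site contact catalog.

HBOND_MAX <- 3.5   # heavy-atom donor-acceptor ceiling, Angstrom
CHPI_MAX <- 4.5    # sugar-ring centroid to indole six-ring centroid, Angstrom

#' Distances between two atom selections over all altloc combinations
#'
#' @param model a StructureModel.
#' @param selector_a,selector_b atom selectors (`"chain/resno/atom[/alt]"`).
#' @return data.frame with `alt_a`, `alt_b`, `distance`, sorted ascending by
#'   distance.
#' @export
pair_distance <- function(model, selector_a, selector_b) {
  ia <- select_atoms(model, selector_a)
  ib <- select_atoms(model, selector_b)
  if (!length(ia)) stop("selector resolves to no atoms: ", selector_a)
  if (!length(ib)) stop("selector resolves to no atoms: ", selector_b)
  at <- model$atoms
  out <- expand.grid(i = ia, j = ib)
  out$alt_a <- at$alt[out$i]
  out$alt_b <- at$alt[out$j]
  out$distance <- sqrt((at$x[out$i] - at$x[out$j])^2 +
                         (at$y[out$i] - at$y[out$j])^2 +
                         (at$z[out$i] - at$z[out$j])^2)
  out <- out[order(out$distance), c("alt_a", "alt_b", "distance")]
  rownames(out) <- NULL
  out
}

## bridging oxygen between consecutive rings i and i+1 of one instance:
## O4 of ring i+1 (bound to C1 of ring i and C4 of its own ring).
bridging_oxygen <- function(model, chain, resno_next, alt) {
  i <- select_atoms(model, list(chain = chain, resno = resno_next,
                                elety = "O4", alt = alt))
  if (!length(i))
    i <- select_atoms(model, list(chain = chain, resno = resno_next,
                                  elety = "O4", alt = NA))
  if (!length(i)) return(NULL)
  as.numeric(model$atoms[i[1], c("x", "y", "z")])
}

#' Glycosidic geometry at the cleavage site
#'
#' For every ligand conformer spanning the -1 and +1 subsites, locates the
#' bridging oxygen between those rings and reports the minimum distance from
#' the catalytic glutamate's carboxylate oxygens to it, plus the
#' C1(-1)-O-C4(+1) bond angle.
#'
#' @param model a StructureModel.
#' @param triad a [triad_spec()].
#' @param assignment a [assign_subsites()] result for this model.
#' @return data.frame with one row per qualifying conformer: `instance_id`,
#'   `alt`, `d_E_Ogly` (Angstrom), `angle_C1_O_C4` (degrees), `occupancy`;
#'   zero rows (with a message) when no conformer spans -1/+1.
#' @export
glycosidic_geometry <- function(model, triad, assignment) {
  at <- model$atoms
  empty <- data.frame(instance_id = character(), alt = character(),
                      d_E_Ogly = numeric(), angle_C1_O_C4 = numeric(),
                      occupancy = numeric())
  iE <- which(at$chain == triad$chain & at$resno == triad$e &
                at$elety %in% c("OE1", "OE2"))
  if (!length(iE)) stop("E carboxylate atoms missing")
  oE <- as.matrix(at[iE, c("x", "y", "z")])
  rows <- list()
  for (iid in unique(assignment$instance_id)) {
    g <- assignment[assignment$instance_id == iid, , drop = FALSE]
    g <- g[order(g$ring_index), ]
    i_m1 <- which(g$subsite == "-1")
    i_p1 <- which(g$subsite == "+1")
    if (!length(i_m1) || !length(i_p1)) next
    if (abs(g$ring_index[i_p1[1]] - g$ring_index[i_m1[1]]) != 1) next
    ## rings run non-reducing -> reducing, so the -1 ring precedes +1 and the
    ## bridge is -1 ring's C1 to +1 ring's O4
    res_m1 <- g$resno[i_m1[1]]; res_p1 <- g$resno[i_p1[1]]; a <- g$alt[i_m1[1]]
    getatom <- function(resno, name) {
      i <- which(at$chain == g$chain[1] & at$resno == resno &
                   at$elety == name & at$alt %in% c(a, ""))
      if (!length(i)) return(NULL)
      as.numeric(at[i[1], c("x", "y", "z")])
    }
    c1 <- getatom(res_m1, "C1")
    c4 <- getatom(res_p1, "C4")
    ogly <- bridging_oxygen(model, g$chain[1], res_p1, a)
    if (is.null(c1) || is.null(c4) || is.null(ogly)) next
    if (vnorm(c1 - ogly) >= GLYCOSIDIC_MAX || vnorm(c4 - ogly) >= GLYCOSIDIC_MAX)
      next
    d <- min(sqrt(rowSums(sweep(oE, 2, ogly)^2)))
    ang <- vertex_angle(c1, ogly, c4)
    rows[[length(rows) + 1]] <- data.frame(
      instance_id = iid, alt = a, d_E_Ogly = d, angle_C1_O_C4 = ang,
      occupancy = g$occupancy[i_m1[1]], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    message("no ligand conformer spans the -1/+1 subsites")
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## indole six-membered-ring atoms of tryptophan
TRP_SIX_RING <- c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")

#' Active-site contact catalog
#'
#' Reports, per chain: the tryptophan stacking registry (Trp ring centroid to
#' sugar-ring centroid, CH-pi class), the Asp213/Tyr141 hydroxyl hydrogen
#' bonds to the -1 and +1 sugars' O6, the E carboxylate to glycosidic-oxygen
#' distance, and the D2-E / D2-D1 carboxylate contacts, each flagged against
#' the distance criteria (hbond <= `hbond_max`, CH-pi <= `chpi_max`).
#' Contacts the literature quotes via hydrogen atoms are measured between the
#' corresponding heavy atoms when hydrogens are absent.
#'
#' @param model a StructureModel.
#' @param frame a [subsite_frame()].
#' @param assignment a [assign_subsites()] result.
#' @param triad a [triad_spec()].
#' @param trp_registry named integer vector mapping subsite labels to Trp
#'   residue numbers (default mouse AMCase registry).
#' @param hbond_max,chpi_max distance criteria in Angstrom.
#' @return data.frame of `ContactRecord`s: `contact`, `chain`, `alt_a`,
#'   `alt_b`, `subsite`, `distance`, `class` ("hbond", "ch-pi", "other"),
#'   `flagged`.
#' @export
contact_report <- function(model, frame, assignment, triad = triad_spec(),
                           trp_registry = c("-3" = 31L, "-1" = 360L,
                                            "+1" = 99L, "+2" = 218L),
                           hbond_max = HBOND_MAX, chpi_max = CHPI_MAX) {
  at <- model$atoms
  rings <- extract_sugar_rings(model)
  rows <- list()
  add <- function(contact, chain, alt_a, alt_b, subsite, d, cls) {
    flagged <- (cls == "hbond" && d <= hbond_max) ||
      (cls == "ch-pi" && d <= chpi_max)
    rows[[length(rows) + 1]] <<- data.frame(
      contact = contact, chain = chain, alt_a = alt_a, alt_b = alt_b,
      subsite = subsite, distance = d,
      class = if (flagged) cls else "other", flagged = flagged,
      stringsAsFactors = FALSE)
  }
  ring_at_subsite <- function(lab) {
    keys <- assignment[assignment$subsite == lab, , drop = FALSE]
    Filter(Negate(is.null), lapply(seq_len(nrow(keys)), function(i) {
      hit <- Filter(function(r) r$resno == keys$resno[i] &&
                      r$alt == keys$alt[i] && r$chain == keys$chain[i], rings)
      if (length(hit)) hit[[1]] else NULL
    }))
  }
  res_atoms <- function(resno, names, alt = NULL) {
    i <- which(at$chain == triad$chain & at$resno == resno & at$elety %in% names)
    if (!is.null(alt)) i <- i[at$alt[i] %in% c(alt, "")]
    if (!length(i)) return(NULL)
    as.matrix(at[i, c("x", "y", "z"), drop = FALSE])
  }
  ## Trp stacking registry
  for (lab in names(trp_registry)) {
    trp <- res_atoms(trp_registry[[lab]], TRP_SIX_RING)
    if (is.null(trp) || nrow(trp) < 6) next
    ctr <- colMeans(trp)
    for (r in ring_at_subsite(lab))
      add(sprintf("Trp%d~ring", trp_registry[[lab]]), r$chain, "", r$alt,
          lab, vnorm(r$centroid - ctr), "ch-pi")
  }
  ## Asp213 / Tyr141 hydroxyl hydrogen bonds to sugar O6
  hb_partners <- list(list(resno = 213L, atom = "OD1", subsite = "-1"),
                      list(resno = 141L, atom = "OH", subsite = "+1"))
  for (p in hb_partners) {
    pa <- res_atoms(p$resno, p$atom)
    if (is.null(pa)) next
    for (r in ring_at_subsite(p$subsite)) {
      if (!"O6" %in% rownames(r$atoms)) next
      add(sprintf("res%d(%s)~O6", p$resno, p$atom), r$chain, "", r$alt,
          p$subsite, min(sqrt(rowSums(sweep(pa, 2, r$atoms["O6", ])^2))),
          "hbond")
    }
  }
  ## E carboxylate to glycosidic oxygen
  gg <- suppressMessages(glycosidic_geometry(model, triad, assignment))
  for (i in seq_len(nrow(gg)))
    add("E(OE)~Ogly", triad$chain, "", gg$alt[i], "-1/+1", gg$d_E_Ogly[i],
        "hbond")
  ## D2 carboxylate contacts, enumerated over D2 altlocs
  oE <- res_atoms(triad$e, c("OE1", "OE2"))
  oD1 <- res_atoms(triad$d1, c("OD1", "OD2"))
  d2sel <- which(at$chain == triad$chain & at$resno == triad$d2 &
                   at$elety %in% c("OD1", "OD2"))
  for (a in sort(unique(at$alt[d2sel]))) {
    od <- as.matrix(at[d2sel[at$alt[d2sel] == a], c("x", "y", "z"), drop = FALSE])
    if (!is.null(oE))
      add("D2(OD)~E(OE)", triad$chain, a, "", "triad",
          min(apply(oE, 1, function(p) min(sqrt(rowSums(sweep(od, 2, p)^2))))),
          "hbond")
    if (!is.null(oD1))
      add("D2(OD)~D1(OD)", triad$chain, a, "", "triad",
          min(apply(oD1, 1, function(p) min(sqrt(rowSums(sweep(od, 2, p)^2))))),
          "hbond")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contact = character(), chain = character(), alt_a = character(),
               alt_b = character(), subsite = character(), distance = numeric(),
               class = character(), flagged = logical())
  rownames(out) <- NULL
  out
}
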