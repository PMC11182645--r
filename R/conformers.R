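## Side-chain dihedrals and active/inactive classification of the central
## catalytic aspartate (D2 of the DxDxE motif).

#' Side-chain chi1 dihedral of one residue conformer
#'
#' Signed N-CA-CB-CG torsion in degrees, in (-180, 180].
#'
#' @param model a StructureModel.
#' @param chain,resno residue address.
#' @param alt altloc of the conformer ("" for the sole conformer). Backbone
#'   atoms (N, CA) may be shared (blank altloc) even when the side chain is
#'   split; the conformer-specific atom is used when both exist.
#' @return chi1 in degrees.
#' @export
chi1 <- function(model, chain, resno, alt = "") {
  get1 <- function(name) {
    at <- model$atoms
    i <- which(at$chain == chain & at$resno == resno & at$elety == name &
                 at$alt == alt)
    if (!length(i))
      i <- which(at$chain == chain & at$resno == resno & at$elety == name &
                   at$alt == "")
    if (!length(i))
      stop(sprintf("chi1: atom %s missing for %s/%d altloc '%s'",
                   name, chain, resno, alt))
    c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
  }
  dihedral_angle(get1("N"), get1("CA"), get1("CB"), get1("CG"))
}

#' Classify D2 conformers as active or inactive
#'
#' Per D2 conformer, the state is `active` when the minimum distance from its
#' carboxylate oxygens (OD1/OD2) to the E glutamate's carboxylate oxygens
#' (OE1/OE2) is smaller than the minimum distance to the D1 aspartate's
#' carboxylate oxygens, `inactive` otherwise. Conformers equidistant within
#' `ambig_tol` are labelled `ambiguous`, excluded from the aggregate active
#' occupancy, and trigger a warning. The decision uses carboxylate geometry
#' rather than a chi1 cutoff so it is robust to backbone differences between
#' chains; chi1 is reported alongside.
#'
#' @param model a StructureModel.
#' @param triad a [triad_spec()].
#' @param ambig_tol ambiguity margin in Angstrom (default 0.05).
#' @return object of class `TriadState`: list with `conformers` (data.frame
#'   `alt`, `chi1`, `d_to_E`, `d_to_D1`, `state`, `occupancy`) and aggregate
#'   occupancies `active_occupancy`, `inactive_occupancy`,
#'   `ambiguous_occupancy`.
#' @export
classify_D2 <- function(model, triad = triad_spec(), ambig_tol = 0.05) {
  check_triad_identity(model, triad)
  at <- model$atoms
  carboxylate <- function(resno, names) {
    i <- which(at$chain == triad$chain & at$resno == resno & at$elety %in% names)
    if (!length(i))
      stop(sprintf("carboxylate atoms (%s) missing for residue %d",
                   paste(names, collapse = "/"), resno))
    as.matrix(at[i, c("x", "y", "z")])
  }
  oE <- carboxylate(triad$e, c("OE1", "OE2"))
  oD1 <- carboxylate(triad$d1, c("OD1", "OD2"))

  d2sel <- at$chain == triad$chain & at$resno == triad$d2 &
    at$elety %in% c("OD1", "OD2")
  if (!any(d2sel)) stop("D2 carboxylate atoms missing")
  alts <- sort(unique(at$alt[d2sel]))
  rows <- lapply(alts, function(a) {
    i <- which(d2sel & at$alt == a)
    od <- as.matrix(at[i, c("x", "y", "z")])
    mind <- function(m) min(apply(m, 1, function(p)
      min(sqrt(rowSums(sweep(od, 2, p)^2)))))
    dE <- mind(oE); dD1 <- mind(oD1)
    state <- if (abs(dE - dD1) < ambig_tol) "ambiguous"
             else if (dE < dD1) "active" else "inactive"
    data.frame(alt = a, chi1 = chi1(model, triad$chain, triad$d2, a),
               d_to_E = dE, d_to_D1 = dD1, state = state,
               occupancy = stats::median(at$o[i]), stringsAsFactors = FALSE)
  })
  conf <- do.call(rbind, rows)
  if (any(conf$state == "ambiguous"))
    warning("D2 conformer(s) equidistant to D1 and E within ", ambig_tol,
            " A: marked ambiguous and excluded from active occupancy")
  st <- structure(list(
    conformers = conf,
    active_occupancy = sum(conf$occupancy[conf$state == "active"]),
    inactive_occupancy = sum(conf$occupancy[conf$state == "inactive"]),
    ambiguous_occupancy = sum(conf$occupancy[conf$state == "ambiguous"]),
    triad = triad), class = "TriadState")
  st
}

#' @export
print.TriadState <- function(x, ...) {
  cat(sprintf("TriadState (chain %s, D2=%d): active occupancy %.3f, inactive %.3f%s\n",
              x$triad$chain, x$triad$d2, x$active_occupancy, x$inactive_occupancy,
              if (x$ambiguous_occupancy > 0)
                sprintf(", ambiguous %.3f", x$ambiguous_occupancy) else ""))
  print(x$conformers, row.names = FALSE)
  invisible(x)
}
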