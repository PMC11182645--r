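## Occupancy auditing, low-occupancy pruning, and splitting a model by the
## central catalytic aspartate's conformation.

#' Catalytic triad specification (DxDxE motif)
#'
#' The GH18 catalytic motif D1-x-D2-x-E: two aspartates and the catalytic
#' glutamate. Defaults follow the mouse AMCase numbering Asp136/Asp138/Glu140.
#'
#' @param chain chain identifier.
#' @param d1,d2,e author residue numbers of the two aspartates and the
#'   glutamate.
#' @return object of class `TriadSpec`.
#' @export
triad_spec <- function(chain = "A", d1 = 136L, d2 = 138L, e = 140L) {
  if (anyDuplicated(c(d1, d2, e))) stop("triad residues must be distinct")
  structure(list(chain = chain, d1 = as.integer(d1), d2 = as.integer(d2),
                 e = as.integer(e)), class = "TriadSpec")
}

#' @export
print.TriadSpec <- function(x, ...) {
  cat(sprintf("TriadSpec: chain %s, D1=%d D2=%d E=%d\n", x$chain, x$d1, x$d2, x$e))
  invisible(x)
}

check_triad_identity <- function(model, triad) {
  at <- model$atoms
  nm <- function(resno) unique(at$resid[at$chain == triad$chain & at$resno == resno])
  for (spec in list(c(triad$d1, "ASP"), c(triad$d2, "ASP"), c(triad$e, "GLU"))) {
    got <- nm(as.integer(spec[1]))
    if (length(got) && !spec[2] %in% got)
      warning(sprintf("triad residue %s expected %s but model has %s",
                      spec[1], spec[2], paste(got, collapse = "/")))
  }
  invisible(TRUE)
}

#' Audit alternative-conformation occupancy sums
#'
#' One row per multi-conformer group (a residue's set of side-chain altlocs,
#' or a ligand residue's set of conformers). The group sum is the total of
#' the per-altloc occupancies; sums above `1 + tol` are flagged.
#'
#' @param model a StructureModel.
#' @param tol overflow tolerance on the occupancy sum (default 1e-6,
#'   matching deposited-model rounding).
#' @return data.frame with columns `chain`, `resno`, `resid`, `kind`
#'   ("protein" or "ligand"), `n_conformers`, `altlocs`, `occupancy_sum`,
#'   `violation`.
#' @export
occupancy_audit <- function(model, tol = 1e-6) {
  at <- model$atoms
  multi <- at[at$alt != "", , drop = FALSE]
  if (!nrow(multi))
    return(data.frame(chain = character(), resno = integer(), resid = character(),
                      kind = character(), n_conformers = integer(),
                      altlocs = character(), occupancy_sum = numeric(),
                      violation = logical()))
  key <- paste(multi$chain, multi$resno, sep = "\r")
  grp <- split(seq_len(nrow(multi)), key)
  out <- do.call(rbind, lapply(grp, function(i) {
    g <- multi[i, , drop = FALSE]
    occ_by_alt <- vapply(split(g$o, g$alt), function(o) {
      if (diff(range(o)) > 1e-3)
        warning(sprintf("residue %s %s/%d: occupancies within one altloc differ by > 1e-3",
                        g$resid[1], g$chain[1], g$resno[1]))
      stats::median(o)
    }, numeric(1))
    s <- sum(occ_by_alt)
    data.frame(chain = g$chain[1], resno = g$resno[1], resid = g$resid[1],
               kind = if (g$resid[1] %in% SUGAR_CODES) "ligand" else "protein",
               n_conformers = length(occ_by_alt),
               altlocs = paste(sort(names(occ_by_alt)), collapse = ""),
               occupancy_sum = s, violation = s > 1 + tol,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$kind, out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove ligand conformers at or below an occupancy threshold
#'
#' Ligand conformers with occupancy `<= threshold` are dropped from the
#' model; protein atoms are untouched.
#'
#' @param model a StructureModel.
#' @param threshold occupancy cutoff (default 0.10; a conformer at exactly
#'   the threshold is removed).
#' @return the pruned StructureModel.
#' @export
prune_low_occupancy <- function(model, threshold = 0.10) {
  lig <- ligand_conformers(model)
  drop <- lig[lig$occupancy <= threshold, , drop = FALSE]
  if (!nrow(drop)) return(model)
  at <- model$atoms
  kill <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(drop)))
    kill <- kill | (at$chain == drop$chain[i] & at$resno == drop$resno[i] &
                      at$alt == drop$alt[i] & at$resid %in% SUGAR_CODES)
  model$atoms <- at[!kill, , drop = FALSE]
  rownames(model$atoms) <- NULL
  if (!nrow(ligand_conformers(model)))
    warning("all ligand conformers pruned; model is now ligand-free")
  model
}

## Side-chain atom names used when splitting/occupancy-normalising D2.
ASP_SIDECHAIN <- c("CB", "CG", "OD1", "OD2", "HB2", "HB3", "HD2")

#' Split a model by the D2 conformation
#'
#' Produces two single-conformer models: one with D2 (the central aspartate)
#' fixed in its inactive rotamer (carboxylate toward D1) and one with D2 in
#' its active rotamer (toward E). In each output D2 carries exactly one
#' conformer at occupancy 1.0; solvent, ligands and all other residues are
#' not modified.
#'
#' @param model a StructureModel.
#' @param triad a [triad_spec()].
#' @return list with elements `inactive` and `active` (either may be `NULL`,
#'   with a warning, when the input has a single D2 conformer).
#' @export
split_by_D2_conformation <- function(model, triad = triad_spec()) {
  st <- classify_D2(model, triad)
  conf <- st$conformers
  if (nrow(conf) > 2)
    stop("D2 has ", nrow(conf), " conformers; at most 2 supported")
  if (nrow(conf) == 2 && length(unique(conf$state)) == 1)
    stop("both D2 conformers classify to the same state ('", conf$state[1], "')")

  keep_one <- function(alt_keep) {
    m <- model
    at <- m$atoms
    is_d2_side <- at$chain == triad$chain & at$resno == triad$d2 &
      at$elety %in% ASP_SIDECHAIN
    drop <- is_d2_side & at$alt != "" & at$alt != alt_keep
    at <- at[!drop, , drop = FALSE]
    sel <- at$chain == triad$chain & at$resno == triad$d2 &
      at$elety %in% ASP_SIDECHAIN
    at$alt[sel] <- ""
    at$o[sel] <- 1.0
    m$atoms <- at
    rownames(m$atoms) <- NULL
    m$id <- paste0(model$id, "_D2", alt_keep)
    m
  }

  out <- list(inactive = NULL, active = NULL)
  for (i in seq_len(nrow(conf))) {
    s <- conf$state[i]
    if (s == "ambiguous") next
    out[[s]] <- keep_one(conf$alt[i])
    out[[s]]$id <- paste0(model$id, "_D2_", s)
  }
  if (is.null(out$inactive))
    warning("no D2 conformer classifies as inactive; 'inactive' slot is empty")
  if (is.null(out$active))
    warning("no D2 conformer classifies as active; 'active' slot is empty")
  out
}
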