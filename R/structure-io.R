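## Multi-conformer structural models: reading, writing, validation.
##
## The internal representation is dialect-free: a StructureModel holds a flat
## atom table with one row per (atom, altloc) record. Blank altloc ("") marks
## the sole conformer; mmCIF "." and "?" are normalised to "".

SUGAR_CODES <- c("NAG")
RING_ATOMS <- c("C1", "C2", "C3", "C4", "C5", "O5")
SUBSTITUENT_ATOMS <- c("O1", "O3", "O4", "O6", "N2", "C7", "O7")

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with columns `record` ("ATOM"/"HETATM"), `chain`,
#'   `resno` (author numbering), `resid` (3-letter residue code), `elety`
#'   (atom name), `alt` (altloc, "" for sole conformer), `x`, `y`, `z`
#'   (Angstrom), `o` (occupancy), `b` (B-factor, Angstrom^2), `elesy`
#'   (element symbol).
#' @param id model identifier.
#' @param ph optional crystallisation/source pH.
#' @param dialect format the model was read from ("pdb", "mmcif", "memory").
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, id = "model", ph = NULL, dialect = "memory") {
  need <- c("record", "chain", "resno", "resid", "elety", "alt",
            "x", "y", "z", "o", "b", "elesy")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms$alt[is.na(atoms$alt) | atoms$alt %in% c(".", "?")] <- ""
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  m <- structure(list(id = id, atoms = atoms, ph = ph, dialect = dialect),
                 class = "StructureModel")
  validate_structure_model(m)
  m
}

#' @export
print.StructureModel <- function(x, ...) {
  at <- x$atoms
  nres <- nrow(unique(at[at$record == "ATOM", c("chain", "resno")]))
  lig <- ligand_conformers(x)
  cat(sprintf("StructureModel '%s': %d atoms, %d protein residues, %d chain(s)\n",
              x$id, nrow(at), nres, length(unique(at$chain))))
  if (nrow(lig))
    cat(sprintf("  ligand conformers: %s\n",
                paste(sprintf("%s/%d%s(occ %.2f)", lig$chain, lig$resno,
                              ifelse(lig$alt == "", "", paste0(".", lig$alt)),
                              lig$occupancy), collapse = " ")))
  if (!is.null(x$ph)) cat(sprintf("  source pH: %.2f\n", x$ph))
  invisible(x)
}

validate_structure_model <- function(m) {
  at <- m$atoms
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("non-finite coordinates in model '", m$id, "'")
  bad <- which(at$o < 0 | at$o > 1 + 1e-6)
  if (length(bad))
    stop(sprintf("occupancy out of [0,1] for atom %s %s/%d/%s (occ=%g)",
                 at$resid[bad[1]], at$chain[bad[1]], at$resno[bad[1]],
                 at$elety[bad[1]], at$o[bad[1]]))
  ## altloc grouping must be resolvable: within one (chain, resno, alt) group
  ## atom names may not repeat
  key <- paste(at$chain, at$resno, at$alt, at$elety)
  if (anyDuplicated(key)) {
    d <- at[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("unresolvable altloc grouping: duplicate atom %s in residue %s %s/%d altloc '%s'",
                 d$elety, d$resid, d$chain, d$resno, d$alt))
  }
  invisible(TRUE)
}

#' Read a multi-conformer structure
#'
#' Altlocs, occupancies and B-factors are preserved; hydrogens are retained if
#' present. PDB and mmCIF dialects are accepted; mmCIF `label_alt_id` values
#' of "." are treated as blank.
#'
#' @param path file path.
#' @param format "pdb", "mmcif", or "auto" (by extension).
#' @param id model id (default: file base name).
#' @param ph optional source pH annotation.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           id = NULL, ph = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
                     stop("cannot infer dialect from extension '", ext,
                          "'; pass format= explicitly"))
  }
  p <- if (format == "pdb") {
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  } else {
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
  }
  a <- p$atom
  atoms <- data.frame(record = a$type, chain = a$chain, resno = a$resno,
                      resid = a$resid, elety = a$elety,
                      alt = ifelse(is.na(a$alt), "", a$alt),
                      x = a$x, y = a$y, z = a$z, o = a$o, b = a$b,
                      elesy = ifelse(is.na(a$elesy), "", a$elesy),
                      stringsAsFactors = FALSE)
  structure_model(atoms, id = if (is.null(id)) basename(path) else id,
                  ph = ph, dialect = format)
}

#' Write a structure in PDB or mmCIF dialect
#'
#' @param model a StructureModel.
#' @param path output path.
#' @param format "pdb" or "mmcif".
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  at <- model$atoms
  if (format == "pdb") {
    bio3d::write.pdb(pdb = NULL, file = path,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     type = at$record, resno = at$resno, resid = at$resid,
                     eleno = seq_len(nrow(at)), elety = at$elety,
                     chain = at$chain, alt = ifelse(at$alt == "", NA, at$alt),
                     o = at$o, b = at$b, elesy = at$elesy)
  } else {
    write_mmcif(model, path)
  }
  invisible(path)
}

## Minimal mmCIF atom_site writer (no installed R package writes mmCIF).
## Emits the standard PDBx column set so that bio3d::read.cif round-trips.
write_mmcif <- function(model, path) {
  at <- model$atoms
  hdr <- c(paste0("data_", gsub("[^A-Za-z0-9_-]", "_", model$id)),
           "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- sprintf("%-6s %-5d %-2s %-4s %-1s %-3s %-2s 1 %-5d ? %9.4f %9.4f %9.4f %6.4f %7.2f ? %-5d %-3s %-2s %-4s 1",
                  at$record, seq_len(nrow(at)),
                  ifelse(at$elesy == "", substr(at$elety, 1, 1), at$elesy),
                  at$elety, ifelse(at$alt == "", ".", at$alt), at$resid,
                  at$chain, at$resno, at$x, at$y, at$z, at$o, at$b,
                  at$resno, at$resid, at$chain, at$elety)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

## Ligand conformer table: one row per (chain, resno, alt) for sugar residues.
## Conformer occupancy is the shared per-atom occupancy of the group.
ligand_conformers <- function(model) {
  at <- model$atoms
  lig <- at[at$resid %in% SUGAR_CODES, , drop = FALSE]
  if (!nrow(lig))
    return(data.frame(chain = character(), resno = integer(),
                      alt = character(), occupancy = numeric()))
  key <- paste(lig$chain, lig$resno, lig$alt, sep = "\r")
  grp <- split(seq_len(nrow(lig)), key)
  out <- do.call(rbind, lapply(grp, function(i) {
    occ <- lig$o[i]
    if (diff(range(occ)) > 1e-3)
      warning(sprintf("ligand %s/%d altloc '%s': atom occupancies differ by > 1e-3",
                      lig$chain[i[1]], lig$resno[i[1]], lig$alt[i[1]]))
    data.frame(chain = lig$chain[i[1]], resno = lig$resno[i[1]],
               alt = lig$alt[i[1]], occupancy = stats::median(occ),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chain, out$resno, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
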