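## Sugar-binding subsite reference frame and occupancy accounting.
##
## Subsites follow the -n (non-reducing) ... +n (reducing) nomenclature with
## cleavage between -1 and +1. Half-integer labels (-3.5, -2.5, -1.5) mark
## intermediate translocation registers midway between canonical sites, and
## +1' is a distinct product-binding position displaced above +1.

SUBSITE_LABELS <- c("-4", "-3.5", "-3", "-2.5", "-2", "-1.5", "-1",
                    "+1", "+2", "+1'")
INTEGER_LABELS <- c("-4", "-3", "-2", "-1", "+1", "+2")
HALF_LABELS <- c("-3.5", "-2.5", "-1.5")

## Cleft coordinate: consecutive canonical sites are one unit apart (there is
## no 0 subsite, so -1 and +1 are adjacent). +1' shares the +1 coordinate.
subsite_cleft_index <- function(label) {
  v <- suppressWarnings(as.numeric(sub("^\\+", "", label)))
  out <- ifelse(label == "+1'", 4,
                ifelse(v < 0, v + 4, v + 3))
  unname(out)
}

#' Construct a subsite reference frame
#'
#' @param labels character vector of subsite labels (subset of
#'   `"-4","-3.5","-3","-2.5","-2","-1.5","-1","+1","+2","+1'"`).
#' @param centroids numeric matrix (length(labels) x 3) of centroid positions
#'   in Angstrom.
#' @param r_max assignment radius in Angstrom (default 2.0).
#' @return object of class `SubsiteFrame` (a data.frame with columns `label`,
#'   `x`, `y`, `z` and attribute `r_max`).
#' @export
subsite_frame <- function(labels, centroids, r_max = 2.0) {
  if (anyDuplicated(labels)) stop("subsite labels must be unique")
  bad <- setdiff(labels, SUBSITE_LABELS)
  if (length(bad)) stop("unknown subsite label(s): ", paste(bad, collapse = ", "))
  centroids <- matrix(as.numeric(centroids), ncol = 3)
  if (nrow(centroids) != length(labels))
    stop("centroid matrix must have one row per label")
  f <- data.frame(label = labels, x = centroids[, 1], y = centroids[, 2],
                  z = centroids[, 3], stringsAsFactors = FALSE)
  f <- f[order(subsite_cleft_index(f$label), f$label == "+1'"), , drop = FALSE]
  rownames(f) <- NULL
  attr(f, "r_max") <- r_max
  class(f) <- c("SubsiteFrame", "data.frame")
  validate_subsite_frame(f)
  f
}

validate_subsite_frame <- function(f) {
  ints <- f[f$label %in% INTEGER_LABELS, , drop = FALSE]
  if (nrow(ints) >= 2) {
    ord <- order(subsite_cleft_index(ints$label))
    ints <- ints[ord, ]
    idx <- subsite_cleft_index(ints$label)
    for (i in seq_len(nrow(ints) - 1)) {
      if (idx[i + 1] - idx[i] != 1) next
      d <- vnorm(as.numeric(ints[i + 1, c("x", "y", "z")]) -
                   as.numeric(ints[i, c("x", "y", "z")]))
      if (d < 4 || d > 6)
        warning(sprintf("centroid spacing %s -> %s is %.2f A (expected 4-6 A)",
                        ints$label[i], ints$label[i + 1], d))
    }
  }
  for (h in intersect(f$label, HALF_LABELS)) {
    v <- as.numeric(sub("^\\+", "", h))
    lo <- as.character(v - 0.5); hi <- as.character(v + 0.5)
    if (all(c(lo, hi) %in% f$label)) {
      mid <- (as.numeric(f[f$label == lo, c("x", "y", "z")]) +
                as.numeric(f[f$label == hi, c("x", "y", "z")])) / 2
      d <- vnorm(as.numeric(f[f$label == h, c("x", "y", "z")]) - mid)
      if (d > 1.5)
        warning(sprintf("half-integer centroid %s lies %.2f A from its flanking midpoint", h, d))
    }
  }
  invisible(TRUE)
}

#' @export
print.SubsiteFrame <- function(x, ...) {
  cat(sprintf("SubsiteFrame: %d subsites, r_max = %.2f A\n", nrow(x), attr(x, "r_max")))
  print.data.frame(x)
  invisible(x)
}

#' Calibrate a subsite frame from a labelled model
#'
#' Integer-site centroids are the arithmetic means of the labelled ring
#' centroids; half-integer centroids missing from the labelling are
#' synthesised as the midpoints of their flanking integer sites. The +1'
#' site is included only when explicitly labelled.
#'
#' @param labeled_model a StructureModel whose rings have known registers.
#' @param label_map data.frame with columns `resno`, `alt`, `ring_index`,
#'   `label` mapping rings to subsite labels. Must cover at least the
#'   integer sites -3 ... +2.
#' @param r_max assignment radius (Angstrom).
#' @return a [subsite_frame()].
#' @export
calibrate_frame <- function(labeled_model, label_map, r_max = 2.0) {
  required <- c("-3", "-2", "-1", "+1", "+2")
  rings <- extract_sugar_rings(labeled_model)
  cents <- list()
  for (lab in unique(label_map$label)) {
    rows <- label_map[label_map$label == lab, , drop = FALSE]
    pts <- list()
    for (i in seq_len(nrow(rows))) {
      hit <- Filter(function(r) r$resno == rows$resno[i] &&
                      r$alt == rows$alt[i] && r$ring_index == rows$ring_index[i],
                    rings)
      if (length(hit)) pts[[length(pts) + 1]] <- hit[[1]]$centroid
    }
    if (length(pts)) cents[[lab]] <- colMeans(do.call(rbind, pts))
  }
  missing <- setdiff(required, names(cents))
  if (length(missing))
    stop("label_map has no example ring for required site(s): ",
         paste(missing, collapse = ", "))
  ## synthesise absent half-integer sites from flanking integer midpoints
  for (h in HALF_LABELS) {
    if (h %in% names(cents)) next
    v <- as.numeric(h)
    lo <- as.character(v - 0.5); hi <- as.character(v + 0.5)
    if (all(c(lo, hi) %in% names(cents)))
      cents[[h]] <- (cents[[lo]] + cents[[hi]]) / 2
  }
  subsite_frame(names(cents), do.call(rbind, cents), r_max = r_max)
}

#' Assign sugar rings to subsites
#'
#' Nearest-centroid assignment: each ring goes to the closest frame centroid
#' within `r_max`, otherwise "unassigned". When two centroids are within
#' 0.05 Angstrom of each other in distance to the ring, the more negative
#' label wins (deterministic tie-break). Consecutive rings of one conformer
#' are expected to occupy consecutive registers; violations warn.
#'
#' @param model a StructureModel.
#' @param frame a [subsite_frame()].
#' @return data.frame of class `SubsiteAssignment`: one row per ring per
#'   conformer with `instance_id`, `chain`, `alt`, `resno`, `ring_index`,
#'   `subsite`, `distance`, `occupancy`.
#' @export
assign_subsites <- function(model, frame) {
  rings <- extract_sugar_rings(model)
  r_max <- attr(frame, "r_max")
  cent <- as.matrix(frame[, c("x", "y", "z")])
  rows <- lapply(rings, function(r) {
    d <- sqrt(colSums((t(cent) - r$centroid)^2))
    ord <- order(d)
    best <- ord[1]
    if (length(ord) > 1 && d[ord[2]] - d[ord[1]] < 0.05) {
      ## tie: prefer the more negative (smaller cleft-index) label
      cand <- c(ord[1], ord[2])
      best <- cand[which.min(subsite_cleft_index(frame$label[cand]))]
    }
    assigned <- d[best] <= r_max
    data.frame(instance_id = r$instance_id, chain = r$chain, alt = r$alt,
               resno = r$resno, ring_index = r$ring_index,
               subsite = if (assigned) frame$label[best] else "unassigned",
               distance = d[best], occupancy = r$occupancy,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(instance_id = character(), chain = character(), alt = character(),
               resno = integer(), ring_index = integer(), subsite = character(),
               distance = numeric(), occupancy = numeric())
  ## register-continuity check per conformer
  for (iid in unique(out$instance_id)) {
    g <- out[out$instance_id == iid, , drop = FALSE]
    g <- g[order(g$ring_index), ]
    lab <- g$subsite[g$subsite != "unassigned"]
    if (length(lab) >= 2) {
      idx <- subsite_cleft_index(lab)
      if (any(abs(diff(idx)) != 1))
        warning(sprintf("conformer %s occupies non-consecutive registers: %s",
                        iid, paste(g$subsite, collapse = " -> ")))
    }
  }
  class(out) <- c("SubsiteAssignment", "data.frame")
  out
}

#' Per-subsite summed occupancy
#'
#' Subsite occupancy is the sum of the occupancies of all alternative ligand
#' conformations whose rings are assigned to that subsite. Unassigned rings
#' are excluded. Sums above `1 + tol` are flagged (independent refinement of
#' overlapping conformers can slightly exceed unity).
#'
#' @param assignment a [assign_subsites()] result.
#' @param tol overflow tolerance before flagging (default 0.05).
#' @return data.frame of class `SubsiteOccupancyTable`: `chain`, `subsite`,
#'   `occupancy`, `n_conformers`, `flag`.
#' @export
subsite_occupancy <- function(assignment, tol = 0.05) {
  a <- assignment[assignment$subsite != "unassigned", , drop = FALSE]
  if (!nrow(a)) {
    out <- data.frame(chain = character(), subsite = character(),
                      occupancy = numeric(), n_conformers = integer(),
                      flag = logical())
    class(out) <- c("SubsiteOccupancyTable", "data.frame")
    return(out)
  }
  key <- paste(a$chain, a$subsite, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(a)), key), function(i) {
    data.frame(chain = a$chain[i[1]], subsite = a$subsite[i[1]],
               occupancy = sum(a$occupancy[i]), n_conformers = length(i),
               stringsAsFactors = FALSE)
  }))
  out$flag <- out$occupancy > 1 + tol
  out <- out[order(out$chain, subsite_cleft_index(out$subsite)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("SubsiteOccupancyTable", "data.frame")
  out
}

#' Write / read a subsite frame as plain text
#'
#' Tab-separated columns `label`, `x`, `y`, `z` with an `r_max` header line.
#' @param frame a [subsite_frame()].
#' @param path file path.
#' @return `path` (write) or a `SubsiteFrame` (read).
#' @export
write_subsite_frame <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# r_max\t%.4f", attr(frame, "r_max")), con)
  utils::write.table(as.data.frame(frame), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_subsite_frame
#' @export
read_subsite_frame <- function(path) {
  lines <- readLines(path)
  r_max <- as.numeric(strsplit(lines[1], "\t")[[1]][2])
  tab <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                           quote = "",  # labels contain the +1' apostrophe
                           colClasses = c("character", rep("numeric", 3)))
  subsite_frame(tab$label, as.matrix(tab[, c("x", "y", "z")]), r_max = r_max)
}
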