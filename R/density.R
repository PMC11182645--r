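## Electron-density maps on an orthogonal grid, CCP4/MRC (mode 2) file I/O,
## and a simplified torsion-density ("Ringer-style") rotamer scan.

#' Construct a density map
#'
#' @param values 3-d numeric array of map values.
#' @param origin position (Angstrom) of the first voxel centre.
#' @param spacing voxel spacing in Angstrom (scalar or length-3).
#' @param unit "sigma" for sigma-scaled values or "absolute".
#' @return object of class `DensityMap`.
#' @export
density_map <- function(values, origin = c(0, 0, 0), spacing = 0.5,
                        unit = c("sigma", "absolute")) {
  unit <- match.arg(unit)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  if (length(dim(values)) != 3) stop("values must be a 3-d array")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), unit = unit),
            class = "DensityMap")
}

#' @export
print.DensityMap <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("DensityMap %dx%dx%d, spacing %.3g/%.3g/%.3g A, %s units\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$unit))
  invisible(x)
}

#' Rescale a map to sigma units (mean 0, sd 1)
#' @param map a [density_map()].
#' @return the sigma-scaled map.
#' @export
sigma_scale <- function(map) {
  v <- map$values
  s <- stats::sd(v)
  map$values <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  map$unit <- "sigma"
  map
}

#' Trilinear interpolation of map values at points
#'
#' @param map a [density_map()].
#' @param pts n x 3 matrix of positions (Angstrom).
#' @return numeric vector of interpolated values.
#' @export
map_interpolate <- function(map, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  d <- dim(map$values)
  g <- sweep(sweep(pts, 2, map$origin), 2, map$spacing, `/`)
  out <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    p <- g[k, ]
    i0 <- floor(p)
    if (any(i0 < 0) || any(i0 + 1 > d - 1))
      stop(sprintf("point (%.2f, %.2f, %.2f) outside map extent",
                   pts[k, 1], pts[k, 2], pts[k, 3]))
    f <- p - i0
    i0 <- i0 + 1  # 1-based
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
      acc <- acc + w * map$values[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    out[k] <- acc
  }
  out
}

## ---- CCP4/MRC mode-2 I/O -------------------------------------------------
## Minimal axis-aligned orthogonal-cell reader/writer (no installed R package
## reads CCP4 maps). Mode 2 = 32-bit float, axis order X,Y,Z.

#' Write a density map as CCP4/MRC (mode 2)
#' @param map a [density_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ccp4 <- function(map, path) {
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                        # NC, NR, NS
  wi(2)                        # MODE 2 (float32)
  wi(round(map$origin / map$spacing))  # NCSTART/NRSTART/NSSTART
  wi(d)                        # NX, NY, NZ sampling
  wf(d * map$spacing); wf(c(90, 90, 90))  # cell
  wi(c(1, 2, 3))               # MAPC/MAPR/MAPS
  v <- map$values
  wf(c(min(v), max(v), mean(v)))
  wi(1); wi(0)                 # ISPG, NSYMBT
  writeBin(raw(100), con)      # EXTRA (25 words)
  wf(c(0, 0, 0))               # ORIGIN (MRC2014); we use start indices
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))             # RMS
  wi(0)                        # NLABL
  writeBin(raw(800), con)      # labels
  wf(as.numeric(v))            # data, X fastest
  invisible(path)
}

#' Read a CCP4/MRC (mode 2) density map
#' @param path file path.
#' @param unit unit annotation for the returned map.
#' @return a [density_map()].
#' @export
read_ccp4 <- function(path, unit = "sigma") {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) CCP4 maps supported")
  start <- ri(3)
  samp <- ri(3)
  cell <- rf(6)
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L)))
    stop("only X,Y,Z axis-ordered maps supported")
  rf(3); ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  vals <- rf(prod(d))
  spacing <- cell[1:3] / samp
  density_map(array(vals, dim = d), origin = start * spacing,
              spacing = spacing, unit = unit)
}

## ---- torsion-density scan ------------------------------------------------

#' Ringer-style torsion-density scan of a side-chain dihedral
#'
#' Rotates the residue's CG atom about its CA-CB axis in `step`-degree
#' increments starting from the modelled chi1, interpolating the map value at
#' each rotated CG position. This scans only the gamma atom (a deliberate
#' simplification of the full published torsion-scan method). Peaks are local
#' maxima on the circular profile above `peak_sigma`.
#'
#' @param map a [density_map()] in the model's frame.
#' @param model a StructureModel.
#' @param chain,resno residue to scan.
#' @param alt altloc of the conformer supplying the starting CG (default "":
#'   first conformer found).
#' @param step angular step in degrees (default 10).
#' @param peak_sigma minimum map value for a reported peak (default 0.3).
#' @return object of class `RingerProfile`: list with `angle` (degrees,
#'   chi1 grid over [0, 360)), `value`, and `peaks` (data.frame `angle`,
#'   `value`).
#' @export
torsion_density_scan <- function(map, model, chain, resno, alt = NULL,
                                 step = 10, peak_sigma = 0.3) {
  at <- model$atoms
  pick <- function(name, a) {
    i <- which(at$chain == chain & at$resno == resno & at$elety == name &
                 (if (is.null(a)) TRUE else at$alt == a))
    if (!length(i) && !is.null(a))
      i <- which(at$chain == chain & at$resno == resno & at$elety == name &
                   at$alt == "")
    if (!length(i)) stop("torsion scan: atom ", name, " not found")
    c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
  }
  n <- pick("N", alt); ca <- pick("CA", alt)
  cb <- pick("CB", alt); cg <- pick("CG", alt)
  chi0 <- dihedral_angle(n, ca, cb, cg)
  nang <- round(360 / step)
  offs <- (seq_len(nang) - 1) * step
  angs <- wrap180(chi0 + offs)
  pos <- matrix(NA_real_, nang, 3)
  for (i in seq_len(nang))
    pos[i, ] <- rotate_about_axis(matrix(cg, 1), cb, ca - cb, offs[i])
  val <- map_interpolate(map, pos)
  ## sort by absolute chi1 angle on [0, 360)
  key <- angs %% 360
  ord <- order(key)
  angle <- key[ord]; value <- val[ord]
  ## circular local maxima above threshold
  nxt <- c(2:nang, 1); prv <- c(nang, 1:(nang - 1))
  ispk <- value > peak_sigma & value >= value[nxt] & value >= value[prv] &
    (value > value[nxt] | value > value[prv])
  flat <- stats::sd(value) < 1e-9
  peaks <- if (flat) data.frame(angle = numeric(), value = numeric())
           else data.frame(angle = angle[ispk], value = value[ispk])
  structure(list(chain = chain, resno = resno, dihedral = "chi1",
                 step = step, angle = angle, value = value, peaks = peaks),
            class = "RingerProfile")
}

#' @export
print.RingerProfile <- function(x, ...) {
  cat(sprintf("RingerProfile %s/%d %s: %d samples (step %g deg), %d peak(s)\n",
              x$chain, x$resno, x$dihedral, length(x$angle), x$step,
              nrow(x$peaks)))
  if (nrow(x$peaks))
    cat(sprintf("  peaks: %s\n",
                paste(sprintf("%.0f deg (%.2f)", x$peaks$angle, x$peaks$value),
                      collapse = ", ")))
  invisible(x)
}
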