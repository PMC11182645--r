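## Small geometry and selection helpers shared across modules.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

#' Signed dihedral angle of four points
#'
#' Returns the torsion a-b-c-d in degrees in (-180, 180], using the
#' atan2 formulation (numerically stable near 0 and 180 degrees).
#'
#' @param a,b,c,d numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## cross product (kept local; avoids importing a package for one primitive)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Angle at vertex b for points a-b-c, in degrees
#' @param a,b,c numeric 3-vectors.
#' @return angle in degrees in [0, 180].
#' @export
vertex_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

## Rotate points about an axis through `origin` along unit vector `axis`
## by `theta` degrees (Rodrigues formula). `pts` is an n x 3 matrix.
rotate_about_axis <- function(pts, origin, axis, theta) {
  k <- unit(axis)
  th <- theta * pi / 180
  pts <- sweep(as.matrix(pts), 2, origin)
  rot <- function(v) {
    v * cos(th) + pracma_cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
  }
  out <- t(apply(pts, 1, rot))
  sweep(out, 2, origin, `+`)
}

## Place atom D given positions of A, B, C and internal coordinates:
## |C-D| = bond, angle(B,C,D) = angle (deg), dihedral(A,B,C,D) = tors (deg).
## Standard NeRF construction, used by the synthetic-structure generator.
place_atom <- function(a, b, c, bond, angle, tors) {
  ang <- angle * pi / 180
  tor <- -tors * pi / 180  # sign matches dihedral_angle(a, b, c, placed)
  d2 <- c(bond * cos(pi - ang),
          bond * sin(pi - ang) * cos(tor),
          bond * sin(pi - ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- cbind(bc, pracma_cross(n, bc), n)
  as.numeric(c + m %*% d2)
}

#' Parse an atom selector string
#'
#' Selectors take the form `"chain/resno/atom"` or `"chain/resno/atom/altloc"`,
#' e.g. `"A/138/OD1"` or `"A/401/C1/B"`. The atom field may be `"*"` to select
#' every atom of the residue.
#'
#' @param sel selector string.
#' @return list with fields `chain`, `resno`, `elety`, `alt` (`NA` = any).
#' @export
parse_selector <- function(sel) {
  parts <- strsplit(sel, "/", fixed = TRUE)[[1]]
  if (length(parts) < 3 || length(parts) > 4)
    stop("selector must be 'chain/resno/atom[/altloc]': ", sel)
  list(chain = parts[1],
       resno = as.integer(parts[2]),
       elety = parts[3],
       alt = if (length(parts) == 4) parts[4] else NA_character_)
}

## Resolve a selector against a model's atom table; returns row indices.
select_atoms <- function(model, sel) {
  if (is.character(sel)) sel <- parse_selector(sel)
  at <- model$atoms
  idx <- at$chain == sel$chain & at$resno == sel$resno
  if (sel$elety != "*") idx <- idx & at$elety == sel$elety
  if (!is.na(sel$alt)) idx <- idx & at$alt == sel$alt
  which(idx)
}

atom_xyz <- function(model, rows) {
  as.matrix(model$atoms[rows, c("x", "y", "z"), drop = FALSE])
}

## circular helpers (degrees)
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

circular_diff <- function(a, b) wrap180(a - b)
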