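# Shared builders for small in-code fixtures.

# one-call atom row with defaults
fx_atom <- function(elety, x, y, z, resno = 1, resid = "ASP", chain = "A",
                    alt = "", o = 1, b = 10, record = "ATOM",
                    elesy = substr(elety, 1, 1)) {
  data.frame(record = record, chain = chain, resno = as.integer(resno),
             resid = resid, elety = elety, alt = alt, x = x, y = y, z = z,
             o = o, b = b, elesy = elesy, stringsAsFactors = FALSE)
}

fx_model <- function(..., id = "fixture") {
  structure_model(do.call(rbind, list(...)), id = id)
}

# independent four-point dihedral oracle: bio3d's torsion, which uses the
# opposite sign handedness (verified on constructed geometry), negated here.
oracle_dihedral <- function(a, b, c, d) {
  -bio3d::torsion.xyz(c(a, b, c, d), atm.inc = 4)
}

# rigid-body transform: rotation about a random axis plus translation
rigid_transform <- function(seed = 1) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- stats::rnorm(3, sd = 10)
  list(R = R, t = tr,
       apply_model = function(model) {
         xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
         model$atoms$x <- xyz[, 1] + tr[1]
         model$atoms$y <- xyz[, 2] + tr[2]
         model$atoms$z <- xyz[, 3] + tr[3]
         model
       },
       apply_frame = function(frame) {
         xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(R)
         frame$x <- xyz[, 1] + tr[1]
         frame$y <- xyz[, 2] + tr[2]
         frame$z <- xyz[, 3] + tr[3]
         frame
       })
}

# a minimal two-ring (chitobiose-like) single-conformer model spanning
# the given subsites, via the package generator with fixed geometry
fx_disaccharide_model <- function(subsites = c("-1", "+1"), occupancy = 1,
                                  alt = "", seed = 1) {
  gen_structure_fixture(
    spec = list(chains = list(A = list(
      conformers = list(list(resno = 401, alt = alt, subsites = subsites,
                             occupancy = occupancy)),
      d2 = list(states = c(A = "active"), occupancy = c(A = 1),
                chi1 = c(A = -65))))),
    seed = seed, dir = NULL)
}

pka_fixture_path <- function(which) {
  p <- system.file("extdata", paste0("synthetic_triad_", which, ".pka"),
                   package = "chitosite")
  if (!nzchar(p))
    p <- file.path("..", "..", "inst", "extdata",
                   paste0("synthetic_triad_", which, ".pka"))
  p
}
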