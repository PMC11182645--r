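test_that("pair distances cover altloc combinations and match the oracle", {
  m <- fx_model(fx_atom("OD1", 0, 0, 0, resno = 1),
                fx_atom("OE1", 3, 0, 0, resno = 2, resid = "GLU"))
  d <- pair_distance(m, "A/1/OD1", "A/2/OE1")
  expect_equal(d$distance, 3.000)
  # random positions vs a Euclidean oracle, all altloc pairs, ascending
  set.seed(14)
  pa <- matrix(rnorm(6), 2, 3); pb <- matrix(rnorm(6), 2, 3)
  m2 <- fx_model(fx_atom("OD1", pa[1, 1], pa[1, 2], pa[1, 3], alt = "A", o = 0.5),
                 fx_atom("OD1", pa[2, 1], pa[2, 2], pa[2, 3], alt = "B", o = 0.5),
                 fx_atom("N2", pb[1, 1], pb[1, 2], pb[1, 3], resno = 2,
                         resid = "NAG", alt = "A", o = 0.5, record = "HETATM"),
                 fx_atom("N2", pb[2, 1], pb[2, 2], pb[2, 3], resno = 2,
                         resid = "NAG", alt = "B", o = 0.5, record = "HETATM"))
  d2 <- pair_distance(m2, "A/1/OD1", "A/2/N2")
  expect_equal(nrow(d2), 4)
  oracle <- sort(as.numeric(outer(1:2, 1:2, Vectorize(function(i, j)
    sqrt(sum((pa[i, ] - pb[j, ])^2))))))
  expect_equal(d2$distance, oracle, tolerance = 1e-9)
  # symmetry
  d3 <- pair_distance(m2, "A/2/N2", "A/1/OD1")
  expect_equal(sort(d3$distance), sort(d2$distance), tolerance = 1e-12)
  expect_error(pair_distance(m2, "A/9/OD1", "A/2/N2"), "no atoms")
})

test_that("glycosidic bridge angle matches closed-form constructions", {
  # collinear C1-O-C4: 180 degrees; tetrahedral: 109.4712 degrees
  expect_equal(vertex_angle(c(-1.4, 0, 0), c(0, 0, 0), c(1.4, 0, 0)), 180)
  th <- 109.4712
  c4 <- 1.4 * c(cos(th * pi / 180), sin(th * pi / 180), 0)
  expect_equal(vertex_angle(c(1.4, 0, 0), c(0, 0, 0), c4), th,
               tolerance = 1e-4)
})

test_that("glycosidic geometry reports the -1/+1 spanning conformer", {
  g <- gen_structure_fixture(seed = 1, dir = NULL)  # conformer D spans -1/+1
  fr <- default_subsite_geometry()
  asn <- assign_subsites(g$model, fr)
  gg <- glycosidic_geometry(g$model, triad_spec(), asn)
  expect_equal(nrow(gg), 1)
  expect_equal(gg$alt, "D")
  expect_true(gg$angle_C1_O_C4 > 0 && gg$angle_C1_O_C4 < 180)
  # E carboxylate distance agrees with a direct pair_distance oracle
  at <- g$model$atoms
  o4 <- unlist(at[at$resno == 404 & at$elety == "O4" & at$alt == "D",
                  c("x", "y", "z")])
  oe <- as.matrix(at[at$resno == 140 & at$elety %in% c("OE1", "OE2"),
                     c("x", "y", "z")])
  expect_equal(gg$d_E_Ogly, min(sqrt(rowSums(sweep(oe, 2, o4)^2))),
               tolerance = 1e-9)
  # no spanning conformer -> empty with a notice
  g2 <- fx_disaccharide_model(subsites = c("-3", "-2"))
  asn2 <- assign_subsites(g2$model, fr)
  expect_message(out <- glycosidic_geometry(g2$model, triad_spec(), asn2),
                 "spans")
  expect_equal(nrow(out), 0)
})

## minimal active site with every catalog partner at a controlled distance
contact_fixture <- function(tyr_off = 0) {
  g <- gen_structure_fixture(
    spec = list(chains = list(A = list(
      conformers = list(
        list(resno = 401, alt = "A", subsites = c("-3", "-2"), occupancy = 0.40),
        list(resno = 403, alt = "D", subsites = c("-1", "+1"), occupancy = 0.30),
        list(resno = 405, alt = "E", subsites = c("+1", "+2"), occupancy = 0.30)),
      d2 = list(states = c(A = "active", B = "inactive"),
                occupancy = c(A = 0.55, B = 0.45),
                chi1 = c(A = -65, B = 175))))), seed = 1, dir = NULL)
  m <- g$model
  rings <- extract_sugar_rings(m)
  asn <- assign_subsites(m, default_subsite_geometry())
  ring_at <- function(lab) {
    key <- asn[asn$subsite == lab, ][1, ]
    Filter(function(r) r$resno == key$resno && r$alt == key$alt, rings)[[1]]
  }
  six <- c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  rows <- list()
  trp <- function(resno, lab, dist = 4.0) {
    ctr <- ring_at(lab)$centroid + c(0, 0, -dist)
    ang <- (0:5) * 60 * pi / 180
    for (i in seq_along(six))
      rows[[length(rows) + 1]] <<- fx_atom(six[i],
                                           ctr[1] + 1.4 * cos(ang[i]),
                                           ctr[2] + 1.4 * sin(ang[i]), ctr[3],
                                           resno = resno, resid = "TRP")
  }
  trp(31, "-3"); trp(360, "-1"); trp(99, "+1"); trp(218, "+2")
  o6 <- function(lab) ring_at(lab)$atoms["O6", ]
  p <- o6("-1") + c(0, 2.8, 0)
  rows[[length(rows) + 1]] <- fx_atom("OD1", p[1], p[2], p[3], resno = 213)
  p <- o6("+1") + c(0, 2.8 + tyr_off, 0)
  rows[[length(rows) + 1]] <- fx_atom("OH", p[1], p[2], p[3], resno = 141,
                                      resid = "TYR")
  m$atoms <- rbind(m$atoms, do.call(rbind, rows))
  m
}

test_that("the contact catalog classifies hydrogen bonds and stacking", {
  m <- contact_fixture()
  fr <- default_subsite_geometry()
  rep <- contact_report(m, fr, assign_subsites(m, fr))
  trps <- rep[grepl("^Trp", rep$contact), ]
  expect_equal(sort(unique(trps$contact)),
               c("Trp218~ring", "Trp31~ring", "Trp360~ring", "Trp99~ring"))
  expect_true(all(trps$class == "ch-pi"))
  hb <- rep[rep$contact %in% c("res213(OD1)~O6", "res141(OH)~O6"), ]
  expect_true(all(hb$class == "hbond"))
  expect_true(all(abs(hb$distance - 2.8) < 1e-6))
  # D2<->E and D2<->D1 carboxylate contacts at the constructed 2.6 A
  tri <- rep[rep$subsite == "triad", ]
  expect_equal(min(tri$distance[tri$contact == "D2(OD)~E(OE)" &
                                  tri$alt_a == "A"]), 2.6, tolerance = 1e-6)
  expect_equal(min(tri$distance[tri$contact == "D2(OD)~D1(OD)" &
                                  tri$alt_a == "B"]), 2.6, tolerance = 1e-6)
})

test_that("out-of-range partners are reported but not hbond-classed", {
  m <- contact_fixture(tyr_off = 1.7)  # Tyr141 OH...O6 at 4.5 A
  fr <- default_subsite_geometry()
  rep <- contact_report(m, fr, assign_subsites(m, fr))
  tyr <- rep[rep$contact == "res141(OH)~O6", ]
  expect_gte(nrow(tyr), 1)  # one record per +1-ring conformer
  expect_true(all(tyr$class == "other"))
  expect_false(any(tyr$flagged))
})

test_that("the catalog is invariant under rigid-body transforms", {
  m <- contact_fixture()
  fr <- default_subsite_geometry()
  rep0 <- contact_report(m, fr, assign_subsites(m, fr))
  tr <- rigid_transform(seed = 8)
  m2 <- tr$apply_model(m)
  fr2 <- tr$apply_frame(fr)
  rep1 <- contact_report(m2, fr2, assign_subsites(m2, fr2))
  expect_equal(rep1$contact, rep0$contact)
  expect_equal(rep1$distance, rep0$distance, tolerance = 1e-9)
  expect_equal(rep1$class, rep0$class)
})
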