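test_that("frame calibration averages labelled ring centroids", {
  # two labelled examples per site: centroid must be the arithmetic mean
  spec <- list(chains = list(A = list(
    conformers = list(
      list(resno = 401, alt = "A", subsites = c("-4", "-3", "-2", "-1", "+1", "+2"),
           occupancy = 0.5),
      list(resno = 411, alt = "B", subsites = c("-4", "-3", "-2", "-1", "+1", "+2"),
           occupancy = 0.5)),
    d2 = NULL)), jitter_A = 0.4)
  g <- gen_structure_fixture(spec, seed = 7, dir = NULL)
  rings <- extract_sugar_rings(g$model)
  label_map <- g$manifest$rings[, c("resno", "alt", "ring_index", "subsite")]
  names(label_map)[4] <- "label"
  fr <- calibrate_frame(g$model, label_map)
  for (lab in c("-3", "-2", "-1", "+1", "+2")) {
    ex <- label_map[label_map$label == lab, ]
    cents <- t(vapply(seq_len(nrow(ex)), function(i) {
      hit <- Filter(function(r) r$resno == ex$resno[i] && r$alt == ex$alt[i],
                    rings)[[1]]
      hit$centroid
    }, numeric(3)))
    expect_equal(as.numeric(fr[fr$label == lab, c("x", "y", "z")]),
                 unname(colMeans(cents)), tolerance = 1e-9)
  }
  # half-integer sites synthesised at flanking midpoints
  expect_true(all(c("-3.5", "-2.5", "-1.5") %in% fr$label))
  mid <- (as.numeric(fr[fr$label == "-3", c("x", "y", "z")]) +
            as.numeric(fr[fr$label == "-2", c("x", "y", "z")])) / 2
  expect_equal(as.numeric(fr[fr$label == "-2.5", c("x", "y", "z")]), mid)
  # +1' only when labelled
  expect_false("+1'" %in% fr$label)
})

test_that("calibration requires every integer site -3..+2", {
  g <- fx_disaccharide_model(subsites = c("-2", "-1"))
  label_map <- data.frame(resno = c(401, 402), alt = "", ring_index = c(1, 2),
                          label = c("-2", "-1"))
  expect_error(calibrate_frame(g$model, label_map), "\\+1")
})

test_that("assignment hits exact centroids at distance zero and obeys ties", {
  fr <- default_subsite_geometry()
  g <- fx_disaccharide_model(subsites = c("-1", "+1"))
  asn <- assign_subsites(g$model, fr)
  expect_equal(sort(asn$subsite), c("+1", "-1"))
  expect_lt(max(asn$distance), 1e-9)
  # tie-break: a ring exactly between -2 and -1.5 goes to the more negative
  m <- g$model
  target <- (as.numeric(fr[fr$label == "-2", c("x", "y", "z")]) +
               as.numeric(fr[fr$label == "-1.5", c("x", "y", "z")])) / 2
  rings <- extract_sugar_rings(m)
  shift <- target - rings[[1]]$centroid
  sel <- m$atoms$resno == 401
  m$atoms[sel, c("x", "y", "z")] <- sweep(as.matrix(m$atoms[sel, c("x", "y", "z")]),
                                          2, -shift)
  m$atoms <- m$atoms[m$atoms$resno != 402, ]  # lone ring, no continuity warning
  asn2 <- assign_subsites(m, fr)
  expect_equal(asn2$subsite[asn2$resno == 401], "-2")
})

test_that("rings beyond r_max are unassigned", {
  fr <- default_subsite_geometry()
  g <- fx_disaccharide_model(subsites = c("-1", "+1"))
  m <- g$model
  sel <- m$atoms$resid == "NAG"
  m$atoms$z[sel] <- m$atoms$z[sel] + 10
  asn <- assign_subsites(m, fr)
  expect_true(all(asn$subsite == "unassigned"))
  expect_equal(nrow(subsite_occupancy(asn)), 0)
})

test_that("half-integer registers and +1' are recovered from placements", {
  spec <- list(chains = list(A = list(
    conformers = list(
      list(resno = 401, alt = "B", subsites = c("-2.5", "-1.5"), occupancy = 0.35),
      list(resno = 403, alt = "A", subsites = c("+1'", "+2"), occupancy = 0.45)),
    d2 = NULL)))
  g <- gen_structure_fixture(spec, seed = 4, dir = NULL)
  asn <- assign_subsites(g$model, default_subsite_geometry())
  man <- g$manifest$rings
  for (i in seq_len(nrow(man))) {
    got <- asn$subsite[asn$resno == man$resno[i] & asn$alt == man$alt[i]]
    expect_equal(got, man$subsite[i])
  }
})

test_that("subsite occupancy implements the summation rule", {
  g <- gen_structure_fixture(seed = 1, dir = NULL)  # A:0.4 (-3,-2), C:0.3 (-2,-1), D:0.25 (-1,+1)
  occ <- subsite_occupancy(assign_subsites(g$model, default_subsite_geometry()))
  expect_equal(occ$occupancy[occ$subsite == "-3"], 0.40)
  expect_equal(occ$occupancy[occ$subsite == "-2"], 0.70)
  expect_equal(occ$occupancy[occ$subsite == "-1"], 0.55)
  expect_equal(occ$occupancy[occ$subsite == "+1"], 0.25)
  # matches the generator's own bookkeeping
  man <- g$manifest$subsite_occupancy
  for (i in seq_len(nrow(man)))
    expect_equal(occ$occupancy[occ$subsite == man$subsite[i]], man$occupancy[i])
})

test_that("occupancy totals conserve the assigned-ring mass", {
  for (seed in 1:3) {
    spec <- list(chains = list(A = list(
      conformers = list(
        list(resno = 401, alt = "A", subsites = c("-3", "-2"), occupancy = 0.30),
        list(resno = 401, alt = "B", subsites = c("-2.5", "-1.5"), occupancy = 0.20),
        list(resno = 403, alt = "C", subsites = c("-1", "+1"), occupancy = 0.45)),
      d2 = NULL)), jitter_A = 0.3)
    g <- gen_structure_fixture(spec, seed = seed, dir = NULL)
    asn <- assign_subsites(g$model, default_subsite_geometry())
    occ <- subsite_occupancy(asn)
    assigned <- asn[asn$subsite != "unassigned", ]
    expect_equal(sum(occ$occupancy), sum(assigned$occupancy))
  }
})

test_that("assignment is invariant under a shared rigid-body transform", {
  g <- gen_structure_fixture(seed = 6, dir = NULL)
  fr <- default_subsite_geometry()
  asn0 <- assign_subsites(g$model, fr)
  tr <- rigid_transform(seed = 11)
  asn1 <- assign_subsites(tr$apply_model(g$model), tr$apply_frame(fr))
  expect_equal(asn1$subsite, asn0$subsite)
  expect_equal(asn1$distance, asn0$distance, tolerance = 1e-9)
})

test_that("labels are recovered perfectly under 0.5 A centroid jitter", {
  for (seed in 1:5) {
    spec <- list(chains = list(A = list(
      conformers = list(
        list(resno = 401, alt = "A", subsites = c("-3", "-2"), occupancy = 0.4),
        list(resno = 401, alt = "B", subsites = c("-2.5", "-1.5"), occupancy = 0.3),
        list(resno = 403, alt = "D", subsites = c("-1", "+1"), occupancy = 0.2)),
      d2 = NULL)), jitter_A = 0.5)
    g <- gen_structure_fixture(spec, seed = seed, dir = NULL)
    asn <- suppressWarnings(assign_subsites(g$model, default_subsite_geometry()))
    man <- g$manifest$rings
    hits <- vapply(seq_len(nrow(man)), function(i)
      asn$subsite[asn$resno == man$resno[i] & asn$alt == man$alt[i]] ==
        man$subsite[i], logical(1))
    expect_true(all(hits))
  }
})

test_that("frame serialisation round-trips", {
  fr <- default_subsite_geometry()
  f <- tempfile(fileext = ".tsv")
  write_subsite_frame(fr, f)
  fr2 <- read_subsite_frame(f)
  expect_equal(fr2$label, fr$label)
  expect_equal(as.matrix(fr2[, c("x", "y", "z")]),
               as.matrix(fr[, c("x", "y", "z")]), tolerance = 1e-6)
  expect_equal(attr(fr2, "r_max"), attr(fr, "r_max"))
})
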