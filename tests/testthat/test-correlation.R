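## build a cohort of single-chain models with prescribed (-1 occupancy,
## active occupancy) pairs
cohort_models <- function(occ_m1, occ_active, seed = 1) {
  lapply(seq_along(occ_m1), function(i) {
    a <- round(occ_active[i], 2)
    o <- round(occ_m1[i], 2)
    d2 <- if (a >= 0.995) {
      list(states = c(A = "active"), occupancy = c(A = 1), chi1 = c(A = -65))
    } else if (a <= 0.005) {
      list(states = c(B = "inactive"), occupancy = c(B = 1), chi1 = c(B = 175))
    } else {
      list(states = c(A = "active", B = "inactive"),
           occupancy = c(A = a, B = round(1 - a, 2)),
           chi1 = c(A = -65, B = 175))
    }
    conf <- if (o > 0)
      list(list(resno = 401, alt = "A", subsites = c("-1", "+1"), occupancy = o))
    else list()
    g <- gen_structure_fixture(
      spec = list(chains = list(A = list(conformers = conf, d2 = d2))),
      seed = seed + i, dir = NULL)
    g$model$id <- sprintf("m%02d", i)
    g$model
  })
}

test_that("the chain table joins subsite occupancy with D2 state per chain", {
  # 3 models x 2 chains = 6 rows
  mk2 <- function(seed) {
    cspec <- list(conformers = list(list(resno = 401, alt = "A",
                                         subsites = c("-1", "+1"),
                                         occupancy = 0.5)),
                  d2 = list(states = c(A = "active", B = "inactive"),
                            occupancy = c(A = 0.6, B = 0.4),
                            chi1 = c(A = -65, B = 175)))
    gen_structure_fixture(spec = list(chains = list(A = cspec, B = cspec)),
                          seed = seed, dir = NULL)$model
  }
  models <- lapply(4:6, mk2)
  tab <- build_chain_table(models, default_subsite_geometry())
  expect_equal(nrow(tab), 6)
  expect_equal(tab$active_occupancy, rep(0.6, 6))
  expect_equal(tab[["occ_-1"]], rep(0.5, 6))
  # chain without ligand: zero occupancies, row kept
  m0 <- cohort_models(0, 0.3)[[1]]
  tab0 <- build_chain_table(list(m0), default_subsite_geometry())
  expect_equal(nrow(tab0), 1)
  expect_true(all(tab0[, grep("^occ_", names(tab0))] == 0))
})

test_that("a perfectly linear cohort gives r = 1 and the constructed slope", {
  occ <- seq(0.2, 0.9, by = 0.1)
  act <- round(0.1 + 0.8 * occ, 2)
  models <- cohort_models(occ, act)
  tab <- build_chain_table(models, default_subsite_geometry())
  res <- correlate_subsites(tab, seed = 1)
  row <- res[res$subsite == "-1", ]
  expect_equal(row$r, 1, tolerance = 1e-9)
  expect_equal(row$slope, 0.8, tolerance = 1e-6)
  expect_equal(row$direction, "positive")
  # closed-form least-squares agreement
  x <- tab[["occ_-1"]]; y <- tab$active_occupancy
  slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r_cf <- slope_cf * sd(x) / sd(y)
  expect_equal(row$slope, slope_cf, tolerance = 1e-9)
  expect_equal(row$r, r_cf, tolerance = 1e-9)
})

test_that("exhaustive permutation p equals the brute-force oracle at n = 6", {
  skip_if_not_installed("pracma")
  set.seed(31)
  x <- c(0.1, 0.5, 0.3, 0.9, 0.7, 0.2)
  y <- c(0.2, 0.6, 0.35, 0.8, 0.75, 0.15)
  tab <- data.frame(model = "m", chain = letters[1:6], active_occupancy = y,
                    `occ_-1` = x, check.names = FALSE)
  names(tab)[4] <- "occ_-1"
  res <- correlate_subsites(tab, seed = 1)
  r_obs <- cor(x, y)
  perms <- pracma::perms(1:6)   # independent permutation enumeration
  rs <- apply(perms, 1, function(p) cor(x, y[p]))
  p_oracle <- mean(abs(rs) >= abs(r_obs) - 1e-12)
  expect_equal(res$p[res$subsite == "-1"], p_oracle, tolerance = 1e-12)
  expect_equal(nrow(perms), 720)
})

test_that("the injected sign pattern across subsites is recovered", {
  ## positive coupling at -1 (and +1, same conformer); negative at -1.5 via a
  ## half-register conformer whose occupancy falls as active occupancy rises
  set.seed(5)
  n <- 10
  act <- round(seq(0.05, 0.95, length.out = n), 2)
  models <- lapply(seq_len(n), function(i) {
    o_can <- round(0.2 + 0.6 * act[i], 2)       # canonical -1/+1 register
    o_half <- round(0.7 - 0.6 * act[i], 2)      # translocation register
    g <- gen_structure_fixture(
      spec = list(chains = list(A = list(
        conformers = list(
          list(resno = 401, alt = "A", subsites = c("-1", "+1"), occupancy = o_can),
          list(resno = 403, alt = "B", subsites = c("-2.5", "-1.5"),
               occupancy = o_half)),
        d2 = list(states = c(A = "active", B = "inactive"),
                  occupancy = c(A = act[i], B = round(1 - act[i], 2)),
                  chi1 = c(A = -65, B = 175))))),
      seed = 100 + i, dir = NULL)
    g$model$id <- sprintf("c%02d", i)
    g$model
  })
  tab <- build_chain_table(models, default_subsite_geometry())
  res <- correlate_subsites(tab, n_perm = 2000, seed = 7)
  expect_equal(res$direction[res$subsite == "-1"], "positive")
  expect_equal(res$direction[res$subsite == "+1"], "positive")
  expect_equal(res$direction[res$subsite == "-1.5"], "negative")
  expect_equal(res$direction[res$subsite == "-2.5"], "negative")
  # zero-variance subsites are direction "none" with undefined r
  expect_equal(res$direction[res$subsite == "-4"], "none")
  expect_true(is.na(res$r[res$subsite == "-4"]))
  # row-order invariance
  res2 <- correlate_subsites(tab[sample(nrow(tab)), ], n_perm = 2000, seed = 7)
  expect_equal(res2$r, res$r, tolerance = 1e-12)
})

test_that("the -1 occupancy threshold rule is recovered at its design rate", {
  ## cohort built so that 90% of high-occupancy chains prefer active
  set.seed(8)
  n <- 20
  high <- rep(c(TRUE, FALSE), each = n / 2)
  act <- ifelse(high, ifelse(seq_len(n) %% 10 == 1, 0.3, 0.8), 0.25)
  occ <- ifelse(high, 0.7, 0.2)
  models <- cohort_models(occ, act, seed = 300)
  tab <- build_chain_table(models, default_subsite_geometry())
  chk <- threshold_rule_check(tab, subsite = "-1", cutoff = 0.5)
  expect_equal(chk$frac_active_high, 0.9)
  expect_equal(chk$frac_active_low, 0)
  expect_equal(sum(chk$counts), n)
  # empty partition reports NA
  chk2 <- threshold_rule_check(tab[tab[["occ_-1"]] > 0.5, ], cutoff = 0.5)
  expect_true(is.na(chk2$frac_active_low))
})

test_that("fewer than three chains is an error", {
  tab <- data.frame(model = "m", chain = c("a", "b"),
                    active_occupancy = c(0.2, 0.4), occ_x = c(0.1, 0.2))
  names(tab)[4] <- "occ_-1"
  expect_error(correlate_subsites(tab), "3 chains")
})
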