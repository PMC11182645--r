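## Cross-chain correlation between per-subsite ligand occupancy and the
## D2 active-conformation occupancy.

#' Build the per-chain observation table
#'
#' One row per chain per model, combining the subsite occupancy table with
#' the D2 active-conformation occupancy. Chains lacking the D2 residue are
#' skipped with a warning; chains without ligand get zero subsite
#' occupancies.
#'
#' @param models list of StructureModels.
#' @param frame a [subsite_frame()].
#' @param triad a [triad_spec()]; its chain field is ignored (every chain in
#'   each model is visited).
#' @return data.frame with `model`, `chain`, `active_occupancy`, and one
#'   `occ_<subsite>` column per frame label.
#' @export
build_chain_table <- function(models, frame, triad = triad_spec()) {
  labs <- frame$label
  rows <- list()
  for (m in models) {
    for (ch in sort(unique(m$atoms$chain))) {
      tri <- triad_spec(ch, triad$d1, triad$d2, triad$e)
      has_d2 <- any(m$atoms$chain == ch & m$atoms$resno == tri$d2 &
                      m$atoms$elety %in% c("OD1", "OD2"))
      if (!has_d2) {
        warning(sprintf("model %s chain %s lacks the D2 residue; skipped",
                        m$id, ch))
        next
      }
      st <- classify_D2(m, tri)
      sub <- m
      sub$atoms <- m$atoms[m$atoms$chain == ch, , drop = FALSE]
      occ <- subsite_occupancy(assign_subsites(sub, frame))
      row <- data.frame(model = m$id, chain = ch,
                        active_occupancy = st$active_occupancy,
                        stringsAsFactors = FALSE)
      for (lab in labs) {
        hit <- occ$occupancy[occ$subsite == lab]
        row[[paste0("occ_", lab)]] <- if (length(hit)) hit[1] else 0
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## all permutations of 1..n (iterative heap's algorithm, used when
## enumerating exhaustively for small cohorts)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

pearson_r <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Correlate subsite occupancy with D2 active occupancy
#'
#' Per subsite: ordinary least-squares slope and Pearson r of the D2 active
#' occupancy against the subsite occupancy across chains, with a two-sided
#' permutation p-value obtained by shuffling the active-occupancy column.
#' For cohorts of up to `exhaustive_max` chains the permutation null is
#' enumerated exhaustively (exact p); larger cohorts use `n_perm` seeded
#' random permutations. Benjamini-Hochberg adjusted p-values are reported
#' alongside the raw ones; the direction is the sign of r when the raw p is
#' below `alpha`.
#'
#' @param table a [build_chain_table()] result (>= 3 chains).
#' @param n_perm number of random permutations (default 10000).
#' @param seed RNG seed for the permutation draw.
#' @param alpha significance level for calling a direction (default 0.05).
#' @param exhaustive_max largest cohort for exhaustive enumeration (default 8).
#' @return data.frame with `subsite`, `n`, `slope`, `r`, `p`, `p_adj`,
#'   `direction` ("positive", "negative", "none").
#' @export
correlate_subsites <- function(table, n_perm = 10000, seed = 1,
                               alpha = 0.05, exhaustive_max = 8) {
  n <- nrow(table)
  if (n < 3) stop("need at least 3 chains, got ", n)
  y <- table$active_occupancy
  occ_cols <- grep("^occ_", names(table), value = TRUE)
  perms <- if (n <= exhaustive_max) all_permutations(n) else NULL
  if (is.null(perms)) {
    rng <- local({ set.seed(seed); replicate(n_perm, sample.int(n)) })
  }
  rows <- lapply(occ_cols, function(cl) {
    x <- table[[cl]]
    lab <- sub("^occ_", "", cl)
    r <- pearson_r(x, y)
    if (is.na(r)) {
      return(data.frame(subsite = lab, n = n, slope = NA_real_, r = NA_real_,
                        p = NA_real_, direction = "none",
                        stringsAsFactors = FALSE))
    }
    slope <- stats::cov(x, y) / stats::var(x)
    if (!is.null(perms)) {
      rs <- apply(perms, 1, function(p) pearson_r(x, y[p]))
      p <- mean(abs(rs) >= abs(r) - 1e-12)
    } else {
      rs <- apply(rng, 2, function(p) pearson_r(x, y[p]))
      p <- (1 + sum(abs(rs) >= abs(r) - 1e-12)) / (1 + n_perm)
    }
    data.frame(subsite = lab, n = n, slope = slope, r = r, p = p,
               direction = "none", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  sig <- !is.na(out$p) & out$p < alpha
  out$direction[sig] <- ifelse(out$r[sig] > 0, "positive", "negative")
  out <- out[, c("subsite", "n", "slope", "r", "p", "p_adj", "direction")]
  rownames(out) <- NULL
  out
}

#' Occupancy-threshold contingency check
#'
#' Partitions chains by whether a subsite's occupancy reaches `cutoff` and
#' reports, per partition, the fraction of chains whose D2 prefers the
#' active conformation (active occupancy > 0.5), with the 2x2 counts.
#'
#' @param table a [build_chain_table()] result.
#' @param subsite subsite label (default "-1").
#' @param cutoff occupancy threshold (default 0.5; partition is `>= cutoff`).
#' @return list with `counts` (2x2 matrix), `frac_active_high`,
#'   `frac_active_low` (NA when a partition is empty), `subsite`, `cutoff`.
#' @export
threshold_rule_check <- function(table, subsite = "-1", cutoff = 0.5) {
  if (!nrow(table)) stop("empty chain table")
  cl <- paste0("occ_", subsite)
  if (!cl %in% names(table)) stop("no column for subsite ", subsite)
  high <- table[[cl]] >= cutoff
  active <- table$active_occupancy > 0.5
  counts <- matrix(c(sum(high & active), sum(high & !active),
                     sum(!high & active), sum(!high & !active)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("occ_high", "occ_low"),
                                   c("active", "not_active")))
  frac <- function(mask) if (any(mask)) mean(active[mask]) else NA_real_
  list(counts = counts, frac_active_high = frac(high),
       frac_active_low = frac(!high), subsite = subsite, cutoff = cutoff)
}
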