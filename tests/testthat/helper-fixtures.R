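# Shared fixtures and independent oracles for the test suite.

# Write a PDB file from a data.frame of atoms (elety, resid, chain, resno,
# x, y, z, element, optional alt/occ/insert). Intentionally independent of
# the package's writer.
write_test_pdb <- function(atoms, path = tempfile(fileext = ".pdb"),
                           models = list(atoms)) {
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    at <- models[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(at))) {
      alt <- if (!is.null(at$alt)) at$alt[i] else " "
      occ <- if (!is.null(at$occ)) at$occ[i] else 1.00
      ins <- if (!is.null(at$insert)) at$insert[i] else " "
      writeLines(sprintf(
        "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, sprintf(" %-3s", at$elety[i]), alt, at$resid[i], at$chain[i],
        at$resno[i], ins, at$x[i], at$y[i], at$z[i], occ, 0.00,
        at$element[i]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

# One CB-only pseudo-residue per row: quick two-state structures with
# exact C-beta placement.
cb_atoms <- function(chain, resno, xyz) {
  data.frame(elety = "CB", resid = "ALA", chain = chain, resno = resno,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = "C",
             stringsAsFactors = FALSE)
}

# Exhaustive four-predicate pair filter: the independent oracle for
# select_pairs. Distances are recomputed here with explicit loops over the
# site coordinates of every frame (no shared code path with the package's
# matrix pipeline); exposure values are supplied by the caller.
brute_force_pairs <- function(ensemble, domains, config, rsasa) {
  labs <- vapply(ensemble, function(s) s$label, "")
  sites <- ensemble[[1]]$sites
  n <- nrow(sites)
  mean_d <- function(label) {
    frames <- ensemble[which(labs == label)]
    acc <- matrix(0, n, n)
    for (f in frames) {
      for (i in seq_len(n - 1)) {
        for (j in seq((i + 1), n)) {
          dd <- sqrt((f$sites$x[i] - f$sites$x[j])^2 +
                     (f$sites$y[i] - f$sites$y[j])^2 +
                     (f$sites$z[i] - f$sites$z[j])^2)
          acc[i, j] <- acc[i, j] + dd
        }
      }
    }
    acc / length(frames)
  }
  dc <- mean_d(config$closed_label)
  dop <- mean_d(config$open_label)
  dom_of <- function(ch, no) {
    for (d in domains) {
      dd <- as.data.frame(d)
      for (r in seq_len(nrow(dd))) {
        if (ch == dd$chain[r] && no >= dd$start[r] && no <= dd$end[r]) {
          return(dd$name[r])
        }
      }
    }
    NA_character_
  }
  doms <- mapply(dom_of, sites$chain, sites$resno)
  lo <- config$distance_center - config$distance_halfwidth
  hi <- config$distance_center + config$distance_halfwidth
  keep <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (dc[i, j] < lo || dc[i, j] > hi) next
      if (rsasa[i] < config$min_relative_sasa ||
          rsasa[j] < config$min_relative_sasa) next
      if (abs(dop[i, j] - dc[i, j]) < config$min_delta_distance) next
      if (doms[i] == doms[j]) next
      keep[[length(keep) + 1]] <- data.frame(
        chain_i = sites$chain[i], res_i = sites$resno[i],
        chain_j = sites$chain[j], res_j = sites$resno[j],
        d_closed = dc[i, j], delta = abs(dop[i, j] - dc[i, j]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(keep)) do.call(rbind, keep) else
    data.frame(chain_i = character(0), res_i = integer(0),
               chain_j = character(0), res_j = integer(0),
               d_closed = double(0), delta = double(0))
}

# public-API relative SASA of the closed state, for feeding the oracle
closed_state_rsasa <- function(ensemble, config) {
  labs <- vapply(ensemble, function(s) s$label, "")
  frames <- ensemble[which(labs == config$closed_label)]
  sites <- ensemble[[1]]$sites
  acc <- 0
  for (f in frames) {
    s <- shrake_rupley_sasa(f, probe = config$sasa_probe_radius,
                            n_points = config$sasa_points)
    m <- match(paste(sites$chain, sites$resno), paste(s$chain, s$resno))
    acc <- acc + relative_sasa(s$sasa[m], s$resid[m])
  }
  acc / length(frames)
}

pair_key <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$chain_i, df$res_i, df$chain_j, df$res_j, sep = ":"))
}

# published-scale steady-state parameters used as generating truth
POP_PARAMS <- list(
  WT = list(K_M = 335, k_cat = 172),
  P167_517 = list(K_M = 219, k_cat = 181))
PLUC_PARAMS <- list(
  WT_noNi = list(K_M = 1.48, V_max = 40200),
  WT_Ni = list(K_M = 1.19, V_max = 37900),
  P202_532_noNi = list(K_M = 21.5, V_max = 20100),
  P202_532_Ni = list(K_M = 2.32, V_max = 904),
  P108_508_noNi = list(K_M = 0.565, V_max = 10600),
  P108_508_Ni = list(K_M = 2.19, V_max = 1240))
FIXTURE_KI <- 500  # uM; substrate-inhibition constant used in fixtures

# 8 substrate concentrations spanning 0-1 mM (2-fold dilution series, uM)
POP_CONC_GRID <- 1000 / 2^(0:7)
# luciferin grid spanning 0-750 uM
PLUC_CONC_GRID <- c(0.94, 1.9, 3.75, 7.5, 15, 30, 60, 125, 250, 500, 750)
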