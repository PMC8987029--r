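# Synthetic inputs for the whole analysis surface: hinge-motion toy
# structures with planted candidate pairs, simulated screening plates with
# dose-dependent phenotypes, saturation curves, and switching series.
# Every generator is deterministic given its seed and emits ground truth
# alongside the data.

#' Specification for a two-domain hinge-motion toy structure
#'
#' The toy emulates a protein whose two rigid pseudo-domains (poly-alanine,
#' explicit CB atoms) open and close about a hinge: domain B is related
#' between the closed and open states by a rotation about a hinge axis.
#' A set of planted cross-domain residue pairs is constructed with
#' closed-state C-beta distances at chosen targets; the hinge opening
#' carries their open-state distances upward.
#'
#' @param residues_per_domain residues in each domain.
#' @param n_planted number of planted cross-domain pairs (ignored when
#'   `planted_targets` is given).
#' @param planted_targets closed-state C-beta target distances (A), one
#'   per planted pair; default all 10.5.
#' @param hinge_angle_closed,hinge_angle_open hinge rotation of domain B
#'   in each state (degrees); equal angles give a degenerate (rigid)
#'   "hinge" with zero distance changes.
#' @param hinge_radius distance (A) from the structure to the hinge axis;
#'   larger values make the opening more translation-like.
#' @param min_spacing minimum C-beta spacing within a domain (A); the
#'   default keeps every pseudo-residue solvent exposed.
#' @param n_frames frames (snapshots) written per state.
#' @param noise_sd per-atom Gaussian jitter (A) applied per frame; keep at
#'   0 for the constructive distance guarantees to hold.
#' @param seed RNG seed.
#' @return a `hinge_toy_spec` list.
#' @export
hinge_toy_spec <- function(residues_per_domain = 100, n_planted = 12,
                           planted_targets = NULL,
                           hinge_angle_closed = 0, hinge_angle_open = 10,
                           hinge_radius = 60, min_spacing = 8,
                           n_frames = 1, noise_sd = 0, seed = 1) {
  if (is.null(planted_targets)) planted_targets <- rep(10.5, n_planted)
  stopifnot(residues_per_domain >= length(planted_targets),
            all(planted_targets > 0), n_frames >= 1, noise_sd >= 0,
            min_spacing > 0, hinge_radius > 0)
  structure(list(residues_per_domain = residues_per_domain,
                 planted_targets = planted_targets,
                 hinge_angle_closed = hinge_angle_closed,
                 hinge_angle_open = hinge_angle_open,
                 hinge_radius = hinge_radius, min_spacing = min_spacing,
                 n_frames = n_frames, noise_sd = noise_sd, seed = seed),
            class = "hinge_toy_spec")
}

# local alanine heavy-atom template, CB at the origin (plausible geometry)
ALA_TEMPLATE <- rbind(
  N  = c(2.01, 1.33, 0.00),
  CA = c(1.52, 0.00, 0.00),
  C  = c(2.06, -0.76, 1.20),
  O  = c(3.26, -0.95, 1.32),
  CB = c(0.00, 0.00, 0.00))
ALA_ELEMENTS <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

# sample n points in a ball of radius r with pairwise spacing >= s
sample_packed_ball <- function(n, s, r) {
  pts <- matrix(NA_real_, n, 3)
  got <- 0
  tries <- 0
  while (got < n) {
    tries <- tries + 1
    if (tries > 200000) stop("cannot pack ", n, " residues at spacing ", s)
    p <- stats::runif(3, -r, r)
    if (sum(p^2) > r^2) next
    if (got > 0) {
      d2 <- rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2, p)^2)
      if (min(d2) < s^2) next
    }
    got <- got + 1
    pts[got, ] <- p
  }
  pts
}

rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3)
}

#' Generate a hinge-motion toy structure with planted candidate pairs
#'
#' Writes a multi-model PDB (closed frames first, then open frames) plus a
#' ground-truth table of all pairwise C-beta distances in both states,
#' computed from the in-memory coordinates before serialization. Planted
#' pairs have closed-state distances within 0.1 A of their targets
#' (guaranteed at `noise_sd = 0`).
#'
#' @param spec a [hinge_toy_spec()].
#' @param dir output directory (created if needed).
#' @param basename file stem for the outputs.
#' @return list with `pdb` (path), `truth_tsv` (path), `truth`
#'   (data.frame: chain_i, res_i, chain_j, res_j, d_closed, d_open,
#'   cross_domain, planted), `planted` (subset), `model_labels`, and
#'   `domains` (list of [domain_definition()]s: chain A = "domainA",
#'   chain B = "domainB").
#' @export
make_hinge_toy <- function(spec, dir = tempdir(), basename = "hinge_toy") {
  stopifnot(inherits(spec, "hinge_toy_spec"))
  set.seed(spec$seed)
  nA <- spec$residues_per_domain
  nB <- spec$residues_per_domain
  k <- length(spec$planted_targets)
  rA <- spec$min_spacing * 0.85 * nA^(1 / 3) + spec$min_spacing
  cbA <- sample_packed_ball(nA, spec$min_spacing, rA)
  # planted A residues: the k most +x residues, partners straight along +x
  planted_i <- order(cbA[, 1], decreasing = TRUE)[seq_len(k)]
  partners <- cbA[planted_i, , drop = FALSE] +
    cbind(spec$planted_targets, 0, 0)
  # remaining B residues: a second packed ball beyond the partners
  nB_free <- nB - k
  cB_center <- c(max(partners[, 1]) + rA + 8, 0, 0)
  cbB_free <- if (nB_free > 0) {
    sweep(sample_packed_ball(nB_free, spec$min_spacing, rA), 2, cB_center, `+`)
  } else matrix(0, 0, 3)
  cbB <- rbind(partners, cbB_free)

  # per-residue atoms: randomly oriented alanine templates on each CB
  build_atoms <- function(cb, chain, resno0 = 1L) {
    n <- nrow(cb)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      R <- random_rotation()
      xyz <- sweep(ALA_TEMPLATE %*% t(R), 2, cb[i, ], `+`)
      out[[i]] <- data.frame(elety = rownames(ALA_TEMPLATE),
                             resid = "ALA", chain = chain,
                             resno = resno0 + i - 1L,
                             element = unname(ALA_ELEMENTS),
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  atomsA <- build_atoms(cbA, "A")
  atomsB <- build_atoms(cbB, "B")

  # hinge: rotation of domain B about the z axis through (0, hinge_radius, 0)
  hinge_state <- function(atoms, angle) {
    H <- c(0, spec$hinge_radius, 0)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, H) %*% t(rot_z(angle)), 2, H, `+`)
    atoms[, c("x", "y", "z")] <- xyz
    atoms
  }
  state_atoms <- function(angle) rbind(atomsA, hinge_state(atomsB, angle))
  closed <- state_atoms(spec$hinge_angle_closed)
  open <- state_atoms(spec$hinge_angle_open)

  # ground truth from in-memory CB coordinates
  cb_of <- function(at) as.matrix(at[at$elety == "CB", c("x", "y", "z")])
  ids <- closed[closed$elety == "CB", c("chain", "resno")]
  dc <- as.matrix(stats::dist(cb_of(closed)))
  dop <- as.matrix(stats::dist(cb_of(open)))
  n <- nrow(ids)
  iu <- which(upper.tri(dc), arr.ind = TRUE)
  truth <- data.frame(chain_i = ids$chain[iu[, 1]], res_i = ids$resno[iu[, 1]],
                      chain_j = ids$chain[iu[, 2]], res_j = ids$resno[iu[, 2]],
                      d_closed = dc[iu], d_open = dop[iu],
                      stringsAsFactors = FALSE)
  truth$cross_domain <- truth$chain_i != truth$chain_j
  # partner of planted A residue planted_i[m] has resno m in chain B
  truth$planted <- truth$cross_domain &
    paste(truth$res_i, truth$res_j) %in% paste(planted_i, seq_len(k))

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb_path <- file.path(dir, paste0(basename, ".pdb"))
  truth_path <- file.path(dir, paste0(basename, "_truth.tsv"))

  # frames: optional jitter; model order = closed frames, then open frames
  nf <- spec$n_frames
  frames <- list()
  labels <- character(0)
  for (st in list(list(a = closed, lab = "closed"),
                  list(a = open, lab = "open"))) {
    for (f in seq_len(nf)) {
      at <- st$a
      if (spec$noise_sd > 0) {
        at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
          matrix(stats::rnorm(nrow(at) * 3, 0, spec$noise_sd), ncol = 3)
      }
      frames[[length(frames) + 1]] <- at
      labels <- c(labels, st$lab)
    }
  }
  write_multimodel_pdb(frames, pdb_path)
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(pdb = pdb_path, truth_tsv = truth_path, truth = truth,
       planted = truth[truth$planted, , drop = FALSE],
       model_labels = labels,
       domains = list(
         domain_definition("domainA", "A", 1L, nA),
         domain_definition("domainB", "B", 1L, nB)))
}

# minimal fixed-width PDB writer for the toy generator
write_multimodel_pdb <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    at <- frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), sprintf(" %-3s", at$elety), at$resid, at$chain,
      at$resno, at$x, at$y, at$z, 1.00, 0.00, at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Specification for a simulated screening plate
#'
#' Emulates a 384-well metal dose-response screen: each variant carries a
#' planted phenotype, its rate responds to the metal concentration through
#' a Hill occupancy curve (h = 2 by default, motivated by the 2:1
#' bipyridine:metal stoichiometry of the intended cross-link), and each
#' well's signal is a linear absorbance ramp plus Gaussian noise. Reads
#' are few and widely spaced (7 reads, 10 min apart), as for a slow
#' thermostable enzyme followed over an hour.
#'
#' @param variants named character vector: phenotype per variant, each of
#'   "inhibited", "activated", "unresponsive", "inactive".
#' @param conc metal concentration grid in uM (must include 0).
#' @param metal metal name used in the descriptor.
#' @param ec50 Hill midpoint (uM); `hill` Hill coefficient.
#' @param residual_fraction residual activity of inhibited variants at
#'   saturating metal.
#' @param activation_gain fractional rate gain of activated variants at
#'   saturating metal (1 = doubling).
#' @param apo_rate apo reaction rate in AU/min.
#' @param baseline starting absorbance (AU).
#' @param noise_sd per-timepoint Gaussian noise (AU).
#' @param replicates wells per condition.
#' @param timepoints,dt number of reads and read interval (s).
#' @param n_blanks blank (no enzyme) wells.
#' @param edta_wells also simulate metal-then-EDTA wells per condition.
#' @param irreversible whether metal binding is irreversible (EDTA wells
#'   then stay at the metal-bound rate, Fe(II)-like).
#' @param seed RNG seed.
#' @return a `plate_sim_spec` list.
#' @export
plate_sim_spec <- function(variants = default_variant_panel(),
                           conc = c(0, 0.1, 1, 10, 100), metal = "Ni",
                           ec50 = 1, hill = 2, residual_fraction = 0.05,
                           activation_gain = 1, apo_rate = 0.02,
                           baseline = 0.05, noise_sd = 0, replicates = 3,
                           timepoints = 7, dt = 600, n_blanks = 8,
                           edta_wells = FALSE, irreversible = FALSE,
                           seed = 1) {
  stopifnot(all(variants %in% c("inhibited", "activated", "unresponsive",
                                "inactive")),
            !is.null(names(variants)), 0 %in% conc, ec50 > 0,
            residual_fraction >= 0, residual_fraction <= 1,
            timepoints >= 5, replicates >= 1)
  structure(list(variants = variants, conc = conc, metal = metal,
                 ec50 = ec50, hill = hill,
                 residual_fraction = residual_fraction,
                 activation_gain = activation_gain, apo_rate = apo_rate,
                 baseline = baseline, noise_sd = noise_sd,
                 replicates = replicates, timepoints = timepoints, dt = dt,
                 n_blanks = n_blanks, edta_wells = edta_wells,
                 irreversible = irreversible, seed = seed),
            class = "plate_sim_spec")
}

#' Default 27-variant phenotype panel for plate simulations
#'
#' Mirrors the composition of a first-pass screen: one wild-type-like
#' reference, a majority of responders and non-responders, and a handful
#' of dead variants.
#'
#' @return named character vector of phenotypes.
#' @export
default_variant_panel <- function() {
  v <- c(WT = "unresponsive",
         stats::setNames(rep("inhibited", 10), sprintf("INH%02d", 1:10)),
         stats::setNames(rep("activated", 5), sprintf("ACT%02d", 1:5)),
         stats::setNames(rep("unresponsive", 6), sprintf("UNR%02d", 1:6)),
         stats::setNames(rep("inactive", 5), sprintf("DEAD%02d", 1:5)))
  v
}

# dose-response multiplier for one phenotype at concentration c (uM)
phenotype_response <- function(phenotype, conc, ec50, hill,
                               residual_fraction, activation_gain) {
  theta <- ifelse(conc <= 0, 0,
                  conc^hill / (ec50^hill + conc^hill))
  switch(phenotype,
         inhibited = 1 - theta * (1 - residual_fraction),
         activated = 1 + theta * activation_gain,
         unresponsive = rep(1, length(conc)) + 0 * conc,
         inactive = 0 * conc,
         stop("unknown phenotype: ", phenotype))
}

make_well_ids <- function(n) {
  per_plate <- 16L * 24L
  rows <- rep(LETTERS[1:16], each = 24)
  cols <- rep(1:24, times = 16)
  base <- sprintf("%s%02d", rows, cols)
  plates <- ceiling(n / per_plate)
  ids <- unlist(lapply(seq_len(plates), function(p)
    if (p == 1) base else paste0("P", p, "-", base)))
  ids[seq_len(n)]
}

#' Simulate a metal dose-response screening plate
#'
#' Writes the two-CSV input convention (raw time-by-well table and well
#' descriptor) plus a ground-truth table of planted rates and phenotypes.
#'
#' @param spec a [plate_sim_spec()].
#' @param dir output directory.
#' @param basename file stem.
#' @return list: `raw_csv`, `descriptor_csv`, `truth_csv` (paths), plus
#'   in-memory `raw`, `descriptor`, `truth` data.frames. Truth columns
#'   include the planted `rate_au_min` for every well.
#' @export
simulate_plate <- function(spec, dir = tempdir(), basename = "plate") {
  stopifnot(inherits(spec, "plate_sim_spec"))
  set.seed(spec$seed)
  vn <- names(spec$variants)
  grid <- expand.grid(variant = vn, conc_uM = spec$conc,
                      edta = if (spec$edta_wells) c(0L, 1L) else 0L,
                      replicate = seq_len(spec$replicates),
                      stringsAsFactors = FALSE)
  # EDTA wells only meaningful after metal exposure
  grid <- grid[!(grid$edta == 1L & grid$conc_uM == 0), , drop = FALSE]
  blanks <- if (spec$n_blanks > 0) {
    data.frame(variant = "blank", conc_uM = 0, edta = 0L,
               replicate = seq_len(spec$n_blanks), stringsAsFactors = FALSE)
  } else NULL
  desc <- rbind(grid, blanks)
  desc$metal <- ifelse(desc$variant == "blank", "none", spec$metal)
  desc$blank <- as.integer(desc$variant == "blank")
  desc$well <- make_well_ids(nrow(desc))
  desc <- desc[, c("well", "variant", "metal", "conc_uM", "edta",
                   "replicate", "blank")]

  pheno <- spec$variants[desc$variant]
  rate <- numeric(nrow(desc))
  for (i in seq_len(nrow(desc))) {
    if (desc$blank[i] == 1) { rate[i] <- 0; next }
    resp <- phenotype_response(pheno[i], desc$conc_uM[i], spec$ec50,
                               spec$hill, spec$residual_fraction,
                               spec$activation_gain)
    if (desc$edta[i] == 1) {
      # chelator strips the metal unless binding is irreversible
      resp <- if (spec$irreversible) resp
              else phenotype_response(pheno[i], 0, spec$ec50, spec$hill,
                                      spec$residual_fraction,
                                      spec$activation_gain)
    }
    rate[i] <- spec$apo_rate * resp
  }
  times <- (seq_len(spec$timepoints) - 1) * spec$dt
  raw <- data.frame(time_s = times)
  for (i in seq_len(nrow(desc))) {
    sig <- spec$baseline + rate[i] / 60 * times
    if (spec$noise_sd > 0) sig <- sig + stats::rnorm(length(sig), 0,
                                                     spec$noise_sd)
    raw[[desc$well[i]]] <- sig
  }
  truth <- cbind(desc, phenotype = ifelse(desc$blank == 1, "blank",
                                          unname(pheno)),
                 rate_au_min = rate)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(basename, c("_raw.csv", "_descriptor.csv",
                                             "_truth.csv")))
  utils::write.csv(raw, paths[1], row.names = FALSE)
  utils::write.csv(desc, paths[2], row.names = FALSE)
  utils::write.csv(truth, paths[3], row.names = FALSE)
  list(raw_csv = paths[1], descriptor_csv = paths[2], truth_csv = paths[3],
       raw = raw, descriptor = desc, truth = truth)
}

#' Simulate a saturation (rate vs substrate) series
#'
#' Rates follow the Michaelis-Menten law, or the substrate-inhibition law
#' when `Ki` is finite, with optional multiplicative Gaussian noise.
#'
#' @param Vmax,Km,Ki model parameters (`Ki = Inf` for plain MM).
#' @param conc substrate concentration grid.
#' @param noise_cv coefficient of variation of the noise (0 = noiseless).
#' @param replicates replicate measurements per concentration.
#' @param seed RNG seed (only used when noise_cv > 0).
#' @return data.frame with conc, rate, replicate, true_rate.
#' @export
simulate_saturation <- function(Vmax, Km, Ki = Inf, conc, noise_cv = 0,
                                replicates = 1, seed = 1) {
  stopifnot(Vmax > 0, Km > 0, Ki > 0)
  true <- if (is.finite(Ki)) si_rate(conc, Vmax, Km, Ki)
          else mm_rate(conc, Vmax, Km)
  out <- data.frame(conc = rep(conc, times = replicates),
                    true_rate = rep(true, times = replicates),
                    replicate = rep(seq_len(replicates), each = length(conc)))
  if (noise_cv > 0) {
    set.seed(seed)
    out$rate <- pmax(0, out$true_rate *
                       (1 + stats::rnorm(nrow(out), 0, noise_cv)))
  } else {
    out$rate <- out$true_rate
  }
  out[, c("conc", "rate", "replicate", "true_rate")]
}

#' Simulate an alternating on/off switching series
#'
#' @param n_rounds total rounds (default 24, alternating metal and
#'   chelator additions).
#' @param on_rate,off_rate underlying rates in the chelator ("on") and
#'   metal ("off") states.
#' @param drift_per_round multiplicative drift applied per round
#'   (e.g. -0.01 for 1% activity loss per round).
#' @param noise_cv multiplicative noise CV.
#' @param first_state state of round 1 ("off": metal added first).
#' @param seed RNG seed.
#' @return data.frame with round, state, rate.
#' @export
simulate_switching <- function(n_rounds = 24, on_rate = 1, off_rate = 0.05,
                               drift_per_round = 0, noise_cv = 0,
                               first_state = "off", seed = 1) {
  stopifnot(n_rounds >= 2, first_state %in% c("on", "off"))
  states <- rep(c(first_state, setdiff(c("on", "off"), first_state)),
                length.out = n_rounds)
  base <- ifelse(states == "on", on_rate, off_rate)
  rate <- base * (1 + drift_per_round)^(seq_len(n_rounds) - 1)
  if (noise_cv > 0) {
    set.seed(seed)
    rate <- pmax(0, rate * (1 + stats::rnorm(n_rounds, 0, noise_cv)))
  }
  data.frame(round = seq_len(n_rounds), state = states, rate = rate)
}
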