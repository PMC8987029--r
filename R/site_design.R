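#' Configuration for linker-group site-pair selection
#'
#' The selection screens residue pairs on four criteria: (1) closed-state
#' C-beta distance inside a window compatible with a metal bis-bipyridine
#' cross-link, (2) solvent exposure of both residues, (3) a sufficient
#' change in distance between the closed and open conformations, and
#' (4) placement on opposite domains. The distance window defaults to
#' 10.5 +/- 1.0 A (the 9.5-11.5 A screen); the underlying geometric
#' constraint from the Zn(Bpy)2 complex is 10.5 +/- 0.5 A and can be set
#' via `distance_halfwidth = 0.5`.
#'
#' @param closed_label,open_label ensemble labels of the two states.
#' @param distance_center centre of the closed-state distance window (A).
#' @param distance_halfwidth half-width of the window (A).
#' @param min_delta_distance minimum |d_open - d_closed| (A).
#' @param min_relative_sasa minimum relative SASA for both residues.
#' @param sasa_probe_radius probe radius (A) for SASA.
#' @param sasa_points sphere sample points per atom (>= 92).
#' @param sasa_both_states require exposure in both states, not just the
#'   closed one.
#' @return a `design_config` list.
#' @export
design_config <- function(closed_label = "closed", open_label = "open",
                          distance_center = 10.5, distance_halfwidth = 1.0,
                          min_delta_distance = 2.0, min_relative_sasa = 0.20,
                          sasa_probe_radius = 1.4, sasa_points = 960,
                          sasa_both_states = FALSE) {
  stopifnot(distance_halfwidth > 0,
            min_relative_sasa >= 0, min_relative_sasa <= 1,
            sasa_points >= 92, min_delta_distance >= 0)
  structure(list(closed_label = closed_label, open_label = open_label,
                 distance_center = distance_center,
                 distance_halfwidth = distance_halfwidth,
                 min_delta_distance = min_delta_distance,
                 min_relative_sasa = min_relative_sasa,
                 sasa_probe_radius = sasa_probe_radius,
                 sasa_points = sasa_points,
                 sasa_both_states = sasa_both_states),
            class = "design_config")
}

#' Define a structural domain as residue ranges
#'
#' @param name domain name.
#' @param chain chain id(s), recycled against start/end.
#' @param start,end inclusive residue-number ranges.
#' @return a `domain_definition` data.frame (name, chain, start, end).
#' @export
domain_definition <- function(name, chain, start, end) {
  d <- data.frame(name = name, chain = chain, start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  stopifnot(all(d$start <= d$end))
  class(d) <- c("domain_definition", "data.frame")
  d
}

# map every site to a domain name; error on uncovered or doubly covered
assign_domains <- function(sites, domains) {
  dom <- do.call(rbind, lapply(domains, as.data.frame))
  out <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(dom))) {
    hit <- sites$chain == dom$chain[i] &
      sites$resno >= dom$start[i] & sites$resno <= dom$end[i]
    clash <- hit & !is.na(out) & out != dom$name[i]
    if (any(clash)) {
      stop("residue ", sites$chain[which(clash)[1]], ":",
           sites$resno[which(clash)[1]], " maps to more than one domain")
    }
    out[hit] <- dom$name[i]
  }
  if (anyNA(out)) {
    miss <- which(is.na(out))[1]
    stop("residue ", sites$chain[miss], ":", sites$resno[miss],
         " is not covered by any domain definition")
  }
  out
}

#' Select and rank residue pairs for linker-group incorporation
#'
#' Applies the four-criterion filter over all residue pairs and ranks the
#' survivors by descending change in C-beta distance between the open and
#' closed states (ties broken by residue identifiers, ascending). When a
#' label has several frames, frame-averaged distance matrices are used.
#' Solvent exposure is assessed in the closed state (first closed frame;
#' optionally also in the open state).
#'
#' @param ensemble a `conf_ensemble` containing both configured labels.
#' @param domains list of [domain_definition()] objects covering every
#'   residue.
#' @param config a [design_config()].
#' @return data.frame of class `pair_candidates` with columns
#'   chain_i, res_i, chain_j, res_j, d_closed, d_open, delta (absolute),
#'   delta_signed (d_open - d_closed), rel_sasa_i, rel_sasa_j, domain_i,
#'   domain_j, rank.
#' @export
select_pairs <- function(ensemble, domains, config = design_config()) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  labs <- vapply(ensemble, function(s) s$label, "")
  for (lab in c(config$closed_label, config$open_label)) {
    if (!lab %in% labs) {
      stop("ensemble has no frames labelled '", lab, "'; available: ",
           paste(unique(labs), collapse = ", "))
    }
  }
  d_closed <- mean_distance_matrix(ensemble, config$closed_label)
  d_open <- mean_distance_matrix(ensemble, config$open_label)
  sites <- ensemble[[1]]$sites
  dom <- assign_domains(sites, domains)

  rsasa <- state_relative_sasa(ensemble, config$closed_label, config)
  if (config$sasa_both_states) {
    rsasa_open <- state_relative_sasa(ensemble, config$open_label, config)
    rsasa <- pmin(rsasa, rsasa_open)
  }

  n <- nrow(sites)
  lo <- config$distance_center - config$distance_halfwidth
  hi <- config$distance_center + config$distance_halfwidth
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dc <- d_closed[i, j]
      if (dc < lo || dc > hi) next
      if (rsasa[i] < config$min_relative_sasa ||
          rsasa[j] < config$min_relative_sasa) next
      dl <- d_open[i, j] - dc
      if (abs(dl) < config$min_delta_distance) next
      if (dom[i] == dom[j]) next
      rows[[length(rows) + 1]] <- data.frame(
        chain_i = sites$chain[i], res_i = sites$resno[i],
        chain_j = sites$chain[j], res_j = sites$resno[j],
        d_closed = dc, d_open = d_open[i, j],
        delta = abs(dl), delta_signed = dl,
        rel_sasa_i = rsasa[i], rel_sasa_j = rsasa[j],
        domain_i = dom[i], domain_j = dom[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chain_i = character(0), res_i = integer(0), chain_j = character(0),
    res_j = integer(0), d_closed = double(0), d_open = double(0),
    delta = double(0), delta_signed = double(0), rel_sasa_i = double(0),
    rel_sasa_j = double(0), domain_i = character(0),
    domain_j = character(0), stringsAsFactors = FALSE)
  ord <- order(-out$delta, out$chain_i, out$res_i, out$chain_j, out$res_j)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("pair_candidates", "data.frame")
  out
}

# relative SASA per site, frame-averaged over all frames with `label`
state_relative_sasa <- function(ensemble, label, config) {
  labs <- vapply(ensemble, function(s) s$label, "")
  frames <- ensemble[which(labs == label)]
  sites <- ensemble[[1]]$sites
  acc <- 0
  for (f in frames) {
    s <- shrake_rupley_sasa(f, probe = config$sasa_probe_radius,
                            n_points = config$sasa_points)
    m <- match(paste(sites$chain, sites$resno), paste(s$chain, s$resno))
    abs_sasa <- s$sasa[m]
    abs_sasa[is.na(abs_sasa)] <- 0
    resid <- if (!is.null(s$resid)) s$resid[m] else sites$resid
    acc <- acc + relative_sasa(abs_sasa, resid)
  }
  acc / length(frames)
}

#' Number of possible double variants of an n-residue protein
#'
#' @param n_residues number of positions (>= 2).
#' @return n*(n-1)/2 as a double.
#' @export
count_double_variants <- function(n_residues) {
  if (!is.numeric(n_residues) || n_residues < 2 ||
      n_residues != round(n_residues)) {
    stop("n_residues must be an integer >= 2")
  }
  choose(n_residues, 2)
}

#' Write ranked pair candidates as TSV
#'
#' @param pairs a `pair_candidates` data.frame from [select_pairs()].
#' @param path output path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.pair_candidates <- function(x, ...) {
  cat("Ranked linker-group pair candidates:", nrow(x), "pair(s)\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
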