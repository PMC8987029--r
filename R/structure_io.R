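#' Read a (multi-model) PDB file into a conformational ensemble
#'
#' Parses a PDB file and extracts, for every residue, a C-beta reference
#' point used for pair-distance screening. Each MODEL record becomes one
#' conformational state ("frame"); frames are tagged with a label so that
#' ensembles can group e.g. "closed" and "open" snapshots of the same
#' protein.
#'
#' Residues without a CB atom (glycine) get a virtual C-beta reconstructed
#' from the backbone N/CA/C atoms with ideal tetrahedral geometry (1.522 A
#' bond, 109.5 degree angles). If backbone atoms are missing the CA position
#' is used; residues with neither CA nor CB are dropped with a warning.
#' For alternate locations the highest-occupancy conformer is kept (ties:
#' first encountered). Insertion codes are rejected. Hydrogens are ignored.
#'
#' @param path path to a PDB file (single- or multi-model).
#' @param labels character vector of state labels, one per selected model
#'   (recycled if length 1). Default labels models "model1", "model2", ...
#' @param models integer vector of model indices to keep, or `"all"`.
#' @return an object of class `conf_ensemble`: a list of `conf_state`
#'   objects. Each state has `$label`, `$source`, `$sites` (data.frame with
#'   chain, resno, resid, x, y, z, virtual_cb) and `$atoms` (heavy-atom
#'   table with element symbols, used for solvent-accessibility).
#' @export
read_structure <- function(path, labels = NULL, models = "all") {
  if (!file.exists(path)) {
    stop("cannot read structure: file not found: ", path)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  atom <- pdb$atom
  if (any(!is.na(atom$insert))) {
    stop("insertion codes are not supported (found in ", path, ")")
  }
  nmod <- nrow(pdb$xyz)
  sel_models <- if (identical(models, "all")) seq_len(nmod) else as.integer(models)
  if (any(sel_models < 1L | sel_models > nmod)) {
    stop("model index out of range; file has ", nmod, " model(s)")
  }
  if (is.null(labels)) labels <- paste0("model", sel_models)
  labels <- rep_len(as.character(labels), length(sel_models))

  # altloc: keep highest occupancy per (chain, resno, elety); tie -> first
  keep <- resolve_altloc(atom)
  # drop hydrogens
  elesy <- atom$elesy
  elesy[is.na(elesy) | elesy == ""] <- substr(gsub("[0-9]", "", atom$elety), 1, 1)[is.na(elesy) | elesy == ""]
  keep <- keep & toupper(elesy) != "H" & atom$type %in% c("ATOM", "HETATM")

  states <- vector("list", length(sel_models))
  for (k in seq_along(sel_models)) {
    m <- sel_models[k]
    xyz <- pdb$xyz[m, ]
    at <- atom[keep, c("elety", "resid", "chain", "resno"), drop = FALSE]
    at$element <- toupper(elesy[keep])
    idx <- which(keep)
    at$x <- xyz[3 * idx - 2]
    at$y <- xyz[3 * idx - 1]
    at$z <- xyz[3 * idx]
    rownames(at) <- NULL
    sites <- extract_cbeta_sites(at, source = basename(path))
    states[[k]] <- new_conf_state(labels[k], sites, at,
                                  source = sprintf("%s#%d", basename(path), m))
  }
  ens <- new_conf_ensemble(states)
  if (nrow(ens[[1]]$sites) == 0) {
    stop("no usable residues (with CA or CB) found in ", path)
  }
  ens
}

# highest-occupancy altloc filter; returns logical keep vector
resolve_altloc <- function(atom) {
  keep <- rep(TRUE, nrow(atom))
  has_alt <- !is.na(atom$alt)
  if (!any(has_alt)) return(keep)
  key <- paste(atom$chain, atom$resno, atom$elety, sep = "|")
  for (k in unique(key[has_alt])) {
    rows <- which(key == k)
    if (length(rows) < 2) next
    occ <- atom$o[rows]
    occ[is.na(occ)] <- 1
    best <- rows[which.max(occ)]  # which.max -> first on ties
    keep[setdiff(rows, best)] <- FALSE
  }
  keep
}

# Build per-residue C-beta table from one model's heavy-atom table.
extract_cbeta_sites <- function(at, source = "") {
  key <- paste(at$chain, at$resno, sep = "|")
  ukey <- unique(key)
  n <- length(ukey)
  out <- data.frame(chain = character(n), resno = integer(n),
                    resid = character(n), x = double(n), y = double(n),
                    z = double(n), virtual_cb = logical(n),
                    stringsAsFactors = FALSE)
  dropped <- character(0)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    rows <- at[key == ukey[i], , drop = FALSE]
    out$chain[i] <- rows$chain[1]
    out$resno[i] <- rows$resno[1]
    out$resid[i] <- rows$resid[1]
    cb <- rows[rows$elety == "CB", , drop = FALSE]
    if (nrow(cb) >= 1) {
      out$x[i] <- cb$x[1]; out$y[i] <- cb$y[1]; out$z[i] <- cb$z[1]
      out$virtual_cb[i] <- FALSE
      next
    }
    nm <- function(e) {
      r <- rows[rows$elety == e, c("x", "y", "z"), drop = FALSE]
      if (nrow(r)) as.numeric(r[1, ]) else NULL
    }
    Np <- nm("N"); CAp <- nm("CA"); Cp <- nm("C")
    if (!is.null(Np) && !is.null(CAp) && !is.null(Cp)) {
      v <- virtual_cbeta(Np, CAp, Cp)
      out$x[i] <- v[1]; out$y[i] <- v[2]; out$z[i] <- v[3]
      out$virtual_cb[i] <- TRUE
    } else if (!is.null(CAp)) {
      out$x[i] <- CAp[1]; out$y[i] <- CAp[2]; out$z[i] <- CAp[3]
      out$virtual_cb[i] <- TRUE
    } else {
      ok[i] <- FALSE
      dropped <- c(dropped, sprintf("%s:%d", rows$chain[1], rows$resno[1]))
    }
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped), " residue(s) lacking CA and CB in ",
            source, ": ", paste(dropped, collapse = ", "))
  }
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconstruct an ideal C-beta position from backbone N, CA, C
#'
#' Places CB at 1.522 A from CA with tetrahedral (109.5 degree) angles to
#' both the N and C directions, on the side of the backbone plane that
#' gives L-amino-acid chirality.
#'
#' @param n,ca,c numeric 3-vectors of backbone atom coordinates (A).
#' @param bond_length CA-CB bond length in A.
#' @return numeric 3-vector: the virtual CB coordinate.
#' @export
virtual_cbeta <- function(n, ca, c, bond_length = 1.522) {
  u1 <- normalize3(n - ca)
  u2 <- normalize3(c - ca)
  theta <- 109.5 * pi / 180
  bis <- normalize3(u1 + u2)
  perp <- normalize3(cross3(u1, u2))
  # direction d = p*(-bis) + q*perp with d . u1 = cos(theta)
  half <- acos(max(-1, min(1, sum(u1 * u2)))) / 2
  p <- -cos(theta) / cos(half)
  q <- sqrt(max(0, 1 - p^2))
  d <- p * (-bis) + q * perp
  ca + bond_length * normalize3(d)
}

normalize3 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

new_conf_state <- function(label, sites, atoms, source = "") {
  stopifnot(is.data.frame(sites))
  if (!all(is.finite(as.matrix(sites[, c("x", "y", "z")])))) {
    stop("non-finite C-beta coordinates in state '", label, "'")
  }
  if (anyDuplicated(paste(sites$chain, sites$resno))) {
    stop("duplicate residue numbers within a chain in state '", label, "'")
  }
  structure(list(label = label, sites = sites, atoms = atoms,
                 source = source),
            class = "conf_state")
}

new_conf_ensemble <- function(states) {
  stopifnot(length(states) >= 1)
  ref <- site_ids(states[[1]])
  for (s in states[-1]) {
    if (!identical(site_ids(s), ref)) {
      stop("all states in an ensemble must share the same residue set ",
           "in the same order")
    }
  }
  structure(states, class = "conf_ensemble")
}

#' Combine conformational states/ensembles into one ensemble
#'
#' @param ... `conf_state` or `conf_ensemble` objects sharing a residue set.
#' @return a `conf_ensemble`.
#' @export
combine_states <- function(...) {
  parts <- list(...)
  states <- list()
  for (p in parts) {
    if (inherits(p, "conf_state")) states <- c(states, list(p))
    else if (inherits(p, "conf_ensemble")) states <- c(states, unclass(p))
    else stop("combine_states() accepts conf_state / conf_ensemble objects")
  }
  new_conf_ensemble(states)
}

site_ids <- function(state) paste(state$sites$chain, state$sites$resno, sep = ":")

#' @export
print.conf_ensemble <- function(x, ...) {
  labs <- vapply(x, function(s) s$label, "")
  cat("Conformational ensemble:", length(x), "frame(s),",
      nrow(x[[1]]$sites), "residues\n")
  cat("  labels:", paste(sprintf("%s (x%d)", names(table(labs)), table(labs)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.conf_state <- function(x, ...) {
  cat("Conformational state '", x$label, "': ", nrow(x$sites),
      " residues (", sum(x$sites$virtual_cb), " virtual C-beta), from ",
      x$source, "\n", sep = "")
  invisible(x)
}

#' Pairwise C-beta distance matrix of one conformational state
#'
#' @param state a `conf_state`.
#' @return symmetric matrix of Euclidean distances in Angstrom, zero
#'   diagonal, dimnames `chain:resno`.
#' @export
cbeta_distance_matrix <- function(state) {
  stopifnot(inherits(state, "conf_state"))
  if (nrow(state$sites) < 2) stop("state needs at least 2 residues")
  xyz <- as.matrix(state$sites[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(site_ids(state), site_ids(state))
  d
}

#' Frame-averaged C-beta distance matrix for one state label
#'
#' Element-wise arithmetic mean of the per-frame distance matrices of all
#' frames carrying `label` (frames stand in for MD snapshots).
#'
#' @param ensemble a `conf_ensemble`.
#' @param label state label to average over.
#' @return symmetric matrix of mean distances (A).
#' @export
mean_distance_matrix <- function(ensemble, label) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  labs <- vapply(ensemble, function(s) s$label, "")
  hit <- which(labs == label)
  if (!length(hit)) {
    stop("no frames with label '", label, "'; available: ",
         paste(unique(labs), collapse = ", "))
  }
  mats <- lapply(ensemble[hit], cbeta_distance_matrix)
  Reduce(`+`, mats) / length(mats)
}

#' Write a distance matrix as TSV with chain:resnum headers
#'
#' @param mat matrix from [cbeta_distance_matrix()] or
#'   [mean_distance_matrix()].
#' @param path output file path.
#' @export
write_distance_tsv <- function(mat, path) {
  df <- data.frame(residue = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
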