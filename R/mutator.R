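# mutator: in-silico point substitution by ideal-geometry side-chain
# replacement with a discrete rotamer search, and steepest-descent energy
# minimization of the resulting structures.

#' @noRd
# Build the heavy side-chain atoms of `resname` onto a backbone frame given
# by coordinates of N, CA, C (3-vectors), for one rotamer (chi vector in
# degrees). Returns a matrix with rownames = atom names (CB first), or an
# empty matrix for GLY.
build_side_chain <- function(resname, n, ca, c, chi = numeric(0)) {
  if (resname == "GLY") {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  pos <- list(N = n, CA = ca, C = c)
  pos$CB <- place_cbeta(n, ca, c)
  topo <- SIDECHAIN_TOPOLOGY[[resname]]
  if (!is.null(topo)) {
    for (i in seq_len(nrow(topo))) {
      tors <- if (topo$chi[i] > 0) chi[topo$chi[i]] + topo$off[i] else topo$off[i]
      pos[[topo$atom[i]]] <- place_atom(pos[[topo$a1[i]]], pos[[topo$a2[i]]],
                                        pos[[topo$a3[i]]], topo$b[i],
                                        topo$ang[i], tors)
    }
  }
  nm <- setdiff(names(pos), c("N", "CA", "C"))
  out <- do.call(rbind, pos[nm])
  dimnames(out) <- list(nm, c("x", "y", "z"))
  out
}

#' @noRd
# Soft steric-overlap score of candidate side-chain atoms against an
# environment coordinate set: sum over pairs closer than 0.9 * (ri + rj) of
# the squared overlap. Lower is better.
clash_score <- function(cand_xyz, cand_radii, env_xyz, env_radii) {
  if (!nrow(cand_xyz) || !nrow(env_xyz)) return(0)
  s <- 0
  for (i in seq_len(nrow(cand_xyz))) {
    d <- sqrt((env_xyz[, 1] - cand_xyz[i, 1])^2 +
                (env_xyz[, 2] - cand_xyz[i, 2])^2 +
                (env_xyz[, 3] - cand_xyz[i, 3])^2)
    lim <- 0.9 * (cand_radii[i] + env_radii)
    ov <- pmax(0, lim - d)
    s <- s + sum(ov^2)
  }
  s
}

#' Introduce a point substitution into a complex
#'
#' Replaces the side chain of the target residue with the mutant residue
#' built from ideal internal-coordinate geometry on the existing backbone
#' (N, CA, C) frame. Candidate conformers come from a small discrete rotamer
#' library; the conformer with the lowest steric-overlap score against the
#' rest of the structure is kept (score ties broken by library order, so the
#' result is deterministic). Backbone atoms (N, CA, C, O, OXT) and every
#' other residue are untouched. A self-mutation (wt == mt) on a residue with
#' a complete side chain returns the complex unchanged; if heavy side-chain
#' atoms are missing they are rebuilt by the same machinery.
#'
#' @param complex a \code{complex3d} object.
#' @param spec a \code{\link{mutation_spec}}; its wild-type code must match
#'   the residue actually present at the position.
#' @return a new \code{complex3d} with the substituted residue.
#' @examples
#' cx <- make_synthetic_complex(chain_lengths = c(6, 6), separation = 25,
#'                              sequence = c("AAKAAA", "AAAAAA"))
#' mt <- mutate_residue(cx, mutation_spec("A", 3, "K", "A"))
#' @export
mutate_residue <- function(complex, spec) {
  stopifnot(inherits(spec, "mutation_spec"))
  idx <- residue_index(complex, spec$chain, spec$position, spec$insert)
  if (!length(idx)) {
    stop(sprintf("no residue at chain %s position %d%s", spec$chain,
                 spec$position, spec$insert))
  }
  a <- complex$atoms
  found3 <- a$resname[idx[1]]
  found1 <- aa_one(found3)
  if (found1 != spec$wt) {
    stop(sprintf("wild-type mismatch at %s:%d: expected %s, found %s",
                 spec$chain, spec$position, spec$wt, found1))
  }
  mt3 <- aa_three(spec$mt)

  res_atoms <- a[idx, , drop = FALSE]
  need_bb <- c("N", "CA", "C")
  if (!all(need_bb %in% res_atoms$atom)) {
    stop(sprintf("incomplete backbone at %s:%d (need N, CA, C)",
                 spec$chain, spec$position))
  }
  expected_sc <- c(if (mt3 != "GLY") "CB",
                   SIDECHAIN_TOPOLOGY[[mt3]]$atom)
  if (spec$wt == spec$mt &&
      all(expected_sc %in% res_atoms$atom)) {
    return(complex)   # identity mutation on a complete residue
  }

  gv <- function(at) as.numeric(res_atoms[res_atoms$atom == at,
                                          c("x", "y", "z")][1, ])
  n <- gv("N"); ca <- gv("CA"); cc <- gv("C")

  env_keep <- a[-idx, , drop = FALSE]
  bb_keep <- res_atoms[res_atoms$atom %in% BACKBONE_ATOMS, , drop = FALSE]
  env_all <- rbind(env_keep, bb_keep)
  env_xyz <- as.matrix(env_all[, c("x", "y", "z")])
  env_radii <- unname(VDW_RADII[env_all$element])
  # the directly bonded/near-frame atoms inevitably contact the new side
  # chain; exclude own backbone plus adjacent-residue C/N from the score
  own_bb <- nrow(env_keep) + seq_len(nrow(bb_keep))
  score_mask <- setdiff(seq_len(nrow(env_all)), own_bb)

  rot <- ROTAMER_LIBRARY[[mt3]]
  best <- NULL; best_score <- Inf
  for (r in seq_len(nrow(rot))) {
    sc <- build_side_chain(mt3, n, ca, cc, chi = rot[r, ])
    if (!nrow(sc)) { best <- sc; best_score <- 0; break }
    radii <- unname(VDW_RADII[substr(rownames(sc), 1, 1)])
    s <- clash_score(sc, radii, env_xyz[score_mask, , drop = FALSE],
                     env_radii[score_mask])
    if (s < best_score - 1e-12) { best <- sc; best_score <- s }
  }

  new_res <- bb_keep[bb_keep$atom %in% c("N", "CA", "C", "O", "OXT"), ,
                     drop = FALSE]
  if (!is.null(best) && nrow(best)) {
    sc_df <- data.frame(chain = spec$chain, resno = spec$position,
                        insert = spec$insert, resname = mt3,
                        atom = rownames(best),
                        element = substr(rownames(best), 1, 1),
                        x = best[, 1], y = best[, 2], z = best[, 3],
                        stringsAsFactors = FALSE)
    new_res <- rbind(new_res, sc_df)
  }
  new_res$resname <- mt3

  out <- a
  # splice the rebuilt residue into the original position
  before <- if (idx[1] > 1) a[seq_len(idx[1] - 1), , drop = FALSE] else a[0, ]
  after <- if (idx[length(idx)] < nrow(a)) {
    a[(idx[length(idx)] + 1):nrow(a), , drop = FALSE]
  } else a[0, ]
  out <- rbind(before, new_res, after)
  new_complex3d(out, complex$het)
}

#' Minimization settings
#'
#' @param max_iterations maximum number of accepted steepest-descent steps
#'   (default 500).
#' @param force_tolerance convergence threshold on the largest atomic force
#'   component, kcal/mol/Angstrom (default 0.1).
#' @param restraint_scheme \code{"backbone-restrained"} (default): harmonic
#'   positional restraints on N, CA, C, O keep wild type and mutant
#'   comparable; \code{"none"}: all atoms free.
#' @param random_seed seed recorded with the run; the minimizer itself is
#'   deterministic (default 0).
#' @return object of class \code{minimization_config}.
#' @export
minimization_config <- function(max_iterations = 500, force_tolerance = 0.1,
                                restraint_scheme = c("backbone-restrained",
                                                     "none"),
                                random_seed = 0) {
  if (max_iterations <= 0) stop("max_iterations must be positive")
  if (force_tolerance <= 0) stop("force_tolerance must be positive")
  restraint_scheme <- match.arg(restraint_scheme)
  structure(list(max_iterations = as.integer(max_iterations),
                 force_tolerance = force_tolerance,
                 restraint_scheme = restraint_scheme,
                 random_seed = as.integer(random_seed)),
            class = "minimization_config")
}

#' Energy-minimize a complex
#'
#' Steepest descent with a backtracking (Armijo) line search on the
#' heavy-atom potential: Lennard-Jones + Coulomb with distance-dependent
#' dielectric over nonbonded pairs (1-2 and 1-3 excluded, 1-4 scaled by 0.5),
#' harmonic restraints holding detected covalent bonds at their ideal
#' lengths, and, under the default scheme, harmonic positional restraints on
#' backbone atoms. Every accepted step lowers the energy, so the returned
#' trace is monotone non-increasing. Fully deterministic for a fixed
#' configuration.
#'
#' @param complex a \code{complex3d} object with complete backbone.
#' @param config a \code{\link{minimization_config}}.
#' @return list with \code{complex} (relaxed structure), \code{trace}
#'   (total energy, kcal/mol, per accepted iterate, element 1 = initial
#'   energy), \code{converged}, \code{iterations},
#'   \code{max_force} (kcal/mol/Angstrom at exit).
#' @export
minimize <- function(complex, config = minimization_config()) {
  stopifnot(inherits(config, "minimization_config"))
  validate_complex(complex)
  sys <- build_system(complex)
  fixed_k <- if (config$restraint_scheme == "backbone-restrained") 10 else 0
  restrained <- if (fixed_k > 0) which(complex$atoms$atom %in% BACKBONE_ATOMS)
  else integer(0)
  res <- minimize_atoms(coords_matrix(complex), sys,
                        max_iterations = config$max_iterations,
                        force_tolerance = config$force_tolerance,
                        restrained = restrained, restraint_k = fixed_k)
  list(complex = set_coords(complex, res$xyz), trace = res$trace,
       converged = res$converged, iterations = res$iterations,
       max_force = res$max_force)
}

#' @noRd
# Assemble the force-field system for a complex: charges, LJ parameters,
# bond list with reference lengths, and the nonbonded pair list with 1-4
# scaling factors.
build_system <- function(complex) {
  a <- complex$atoms
  elem <- a$element
  li <- match(elem, LJ_PARAMS$element)
  if (any(is.na(li))) {
    bad <- which(is.na(li))[1]
    stop(sprintf("no force-field parameters for atom %s (element '%s') in %s %s%d",
                 a$atom[bad], elem[bad], a$resname[bad], a$chain[bad],
                 a$resno[bad]))
  }
  q <- atom_charge(a$resname, a$atom)
  xyz <- coords_matrix(complex)
  bonds <- detect_bonds(xyz, elem)
  excl <- exclusion_classes(nrow(xyz), bonds)
  list(q = q, eps = LJ_PARAMS$eps[li], rmin2 = LJ_PARAMS$rmin2[li],
       bonds = bonds, pairs14 = excl$pairs14, excluded = excl$excluded,
       n = nrow(xyz))
}

#' @noRd
# Covalent bonds by distance: heavy-atom pairs closer than a cutoff that
# widens when sulfur is involved. Returns a 2-column index matrix plus the
# observed lengths (used as harmonic reference lengths).
detect_bonds <- function(xyz, elem) {
  d <- as.matrix(stats::dist(xyz))
  cut <- matrix(1.85, nrow(xyz), nrow(xyz))
  is_s <- elem == "S"
  cut[is_s, ] <- 2.10; cut[, is_s] <- 2.10
  cut[is_s, is_s] <- 2.30
  hit <- which(d > 0.4 & d < cut & upper.tri(d), arr.ind = TRUE)
  list(i = hit[, 1], j = hit[, 2], r0 = d[hit])
}

#' @noRd
# Classify atom pairs by bond-graph separation: excluded (1-2, 1-3) and
# 1-4 (scaled). Everything else is a full nonbonded pair.
exclusion_classes <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_along(bonds$i)) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  excl <- matrix(FALSE, n, n)
  p14 <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    n1 <- adj[[i]]
    excl[i, n1] <- TRUE                       # 1-2
    n2 <- setdiff(unique(unlist(adj[n1])), i)
    excl[i, n2] <- TRUE                       # 1-3
    n3 <- setdiff(unique(unlist(adj[n2])), c(i, n1))
    p14[i, n3] <- TRUE
  }
  p14 <- p14 & !excl
  diag(excl) <- TRUE
  list(excluded = excl | t(excl), pairs14 = p14 | t(p14))
}

COULOMB_K <- 332.06   # kcal/mol * Angstrom / e^2

#' @noRd
# Total potential energy and gradient for the minimizer. `sys` comes from
# build_system (or is constructed directly in tests). Positional restraints
# anchor `restrained` atoms to `ref` with spring constant `restraint_k`.
energy_gradient <- function(xyz, sys, restrained = integer(0),
                            restraint_k = 0, ref = NULL, bond_k = 300) {
  n <- nrow(xyz)
  g <- matrix(0, n, 3)
  e <- 0

  dx <- outer(xyz[, 1], xyz[, 1], "-")
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  r2[sys$excluded] <- Inf
  scale <- matrix(1, n, n)
  scale[sys$pairs14] <- 0.5
  r2[lower.tri(r2, diag = TRUE)] <- Inf
  r <- sqrt(r2)

  fin <- is.finite(r2)
  if (any(fin)) {
    idx <- which(fin, arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    rij <- r[fin]; s <- scale[fin]
    rmin <- sys$rmin2[i] + sys$rmin2[j]
    epsij <- sqrt(sys$eps[i] * sys$eps[j])
    sr6 <- (rmin / rij)^6
    e_lj <- s * epsij * (sr6^2 - 2 * sr6)
    # dE/dr for LJ
    de_lj <- s * epsij * 12 * (-sr6^2 + sr6) / rij
    # Coulomb with distance-dependent dielectric eps(r) = 4r:
    # E = k q q / (4 r^2), dE/dr = -2 k q q / (4 r^3)
    qq <- sys$q[i] * sys$q[j]
    e_el <- s * COULOMB_K * qq / (4 * rij^2)
    de_el <- -2 * s * COULOMB_K * qq / (4 * rij^3)
    e <- e + sum(e_lj) + sum(e_el)
    de <- de_lj + de_el
    ux <- dx[fin] / rij; uy <- dy[fin] / rij; uz <- dz[fin] / rij
    gx <- de * ux; gy <- de * uy; gz <- de * uz
    for (col in 1:3) {
      gv <- switch(col, gx, gy, gz)
      g[, col] <- g[, col] + tapply_sum(i, gv, n) - tapply_sum(j, gv, n)
    }
  }

  if (length(sys$bonds$i)) {
    bi <- sys$bonds$i; bj <- sys$bonds$j
    bd <- xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE]
    bl <- sqrt(rowSums(bd^2))
    stretch <- bl - sys$bonds$r0
    e <- e + sum(bond_k * stretch^2)
    de <- 2 * bond_k * stretch / bl
    gb <- bd * de
    for (col in 1:3) {
      g[, col] <- g[, col] + tapply_sum(bi, gb[, col], n) -
        tapply_sum(bj, gb[, col], n)
    }
  }

  if (restraint_k > 0 && length(restrained)) {
    dr <- xyz[restrained, , drop = FALSE] - ref[restrained, , drop = FALSE]
    e <- e + restraint_k * sum(dr^2)
    g[restrained, ] <- g[restrained, ] + 2 * restraint_k * dr
  }

  list(energy = e, gradient = g)
}

#' @noRd
tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  acc <- rowsum(val, idx)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' @noRd
# Steepest descent with Armijo backtracking. Accepted iterates strictly
# decrease the energy; the trace includes the initial energy.
minimize_atoms <- function(xyz, sys, max_iterations = 500,
                           force_tolerance = 0.1, restrained = integer(0),
                           restraint_k = 0) {
  ref <- xyz
  eg <- energy_gradient(xyz, sys, restrained, restraint_k, ref)
  trace <- eg$energy
  step <- 0.05
  iter <- 0
  max_force <- max(abs(eg$gradient))
  while (iter < max_iterations && max_force > force_tolerance) {
    gnorm <- sqrt(sum(eg$gradient^2))
    if (gnorm < 1e-14) break
    dirn <- -eg$gradient / gnorm
    accepted <- FALSE
    s <- step
    for (bt in 1:40) {
      cand <- xyz + s * dirn
      eg2 <- energy_gradient(cand, sys, restrained, restraint_k, ref)
      if (eg2$energy < eg$energy - 1e-4 * s * gnorm) {
        xyz <- cand; eg <- eg2; accepted <- TRUE
        step <- min(s * 1.6, 0.5)
        break
      }
      s <- s / 2
    }
    if (!accepted) break
    iter <- iter + 1
    trace <- c(trace, eg$energy)
    max_force <- max(abs(eg$gradient))
  }
  list(xyz = xyz, trace = trace, iterations = iter,
       converged = max_force <= force_tolerance, max_force = max_force)
}
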