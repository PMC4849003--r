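# energetics: MM/PBSA-style energy components (molecular mechanics,
# Generalized Born polar solvation, SASA-proportional nonpolar solvation),
# the binding reaction under the single-trajectory convention, and the
# weighted linear combination giving the predicted binding free energy
# change (ddG).

#' Molecular-mechanics energy of a complex
#'
#' Heavy-atom nonbonded energy: Lennard-Jones 12-6 plus Coulomb with a
#' distance-dependent dielectric \eqn{\epsilon(r) = 4r} (which absorbs
#' solvent and polarization screening in the absence of explicit hydrogens).
#' Pairs separated by one or two bonds are excluded, 1-4 pairs are scaled by
#' 0.5.
#'
#' @param complex a \code{complex3d} object.
#' @return named numeric: \code{mm_vdw} and \code{mm_elec} (kcal/mol).
#' @export
mm_energy <- function(complex) {
  sys <- build_system(complex)
  xyz <- coords_matrix(complex)
  mm_pair_energy(xyz, sys)
}

#' @noRd
# Pairwise LJ + screened Coulomb over the system's nonbonded pair list.
mm_pair_energy <- function(xyz, sys) {
  n <- nrow(xyz)
  dx <- outer(xyz[, 1], xyz[, 1], "-")
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  r2[sys$excluded] <- Inf
  scale <- matrix(1, n, n)
  scale[sys$pairs14] <- 0.5
  r2[lower.tri(r2, diag = TRUE)] <- Inf
  fin <- is.finite(r2)
  if (!any(fin)) return(c(mm_vdw = 0, mm_elec = 0))
  idx <- which(fin, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  rij <- sqrt(r2[fin]); s <- scale[fin]
  rmin <- sys$rmin2[i] + sys$rmin2[j]
  epsij <- sqrt(sys$eps[i] * sys$eps[j])
  sr6 <- (rmin / rij)^6
  vdw <- sum(s * epsij * (sr6^2 - 2 * sr6))
  elec <- sum(s * COULOMB_K * sys$q[i] * sys$q[j] / (4 * rij^2))
  c(mm_vdw = vdw, mm_elec = elec)
}

#' Polar solvation free energy (Generalized Born)
#'
#' Still-style pairwise Generalized Born estimate of the electrostatic
#' solvation free energy,
#' \deqn{\Delta G_{pol} = -\frac{1}{2}\,k\,(1 - 1/\epsilon_{out})
#'   \sum_{i,j} \frac{q_i q_j}{f_{GB}(r_{ij}, a_i, a_j)}}
#' with \eqn{f_{GB} = \sqrt{r^2 + a_i a_j \exp(-r^2 / 4 a_i a_j)}},
#' interior dielectric 1 (screening inside the solute is carried by the
#' distance-dependent dielectric of the MM term) and exterior dielectric 80.
#' Born radii are the intrinsic heavy-atom van der Waals radii. For a single
#' ion of charge q and radius a this reduces to the Born formula
#' \eqn{-166.03\, q^2 (1 - 1/80)/a} kcal/mol. The value is \eqn{\le 0}
#' whenever any atomic charge is nonzero.
#'
#' @param complex a \code{complex3d} object.
#' @param epsilon_out exterior (solvent) dielectric constant, default 80.
#' @return kcal/mol (scalar).
#' @export
polar_solvation <- function(complex, epsilon_out = 80) {
  a <- complex$atoms
  radii <- unname(VDW_RADII[a$element])
  if (any(is.na(radii))) {
    bad <- which(is.na(radii))[1]
    stop(sprintf("no Born radius for atom %s (element '%s')",
                 a$atom[bad], a$element[bad]))
  }
  q <- atom_charge(a$resname, a$atom)
  gb_energy(coords_matrix(complex), q, radii, epsilon_out)
}

#' @noRd
gb_energy <- function(xyz, q, radii, epsilon_out = 80) {
  if (all(q == 0)) return(0)
  n <- length(q)
  tau <- 1 - 1 / epsilon_out
  d2 <- as.matrix(stats::dist(xyz))^2
  aa <- outer(radii, radii)
  fgb <- sqrt(d2 + aa * exp(-d2 / (4 * aa)))
  diag(fgb) <- radii
  qq <- outer(q, q)
  -0.5 * COULOMB_K * tau * sum(qq / fgb)
}

#' Nonpolar solvation free energy
#'
#' Linear surface-area model \eqn{\gamma \cdot SASA + b} over the total
#' heavy-atom solvent-accessible surface area of the structure.
#'
#' @param complex a \code{complex3d} object.
#' @param gamma surface tension coefficient, kcal/mol/Angstrom^2
#'   (default 0.005).
#' @param b offset, kcal/mol (default 0).
#' @param probe_radius,sphere_points passed to \code{\link{compute_sasa}}.
#' @return kcal/mol (scalar).
#' @export
nonpolar_solvation <- function(complex, gamma = 0.005, b = 0,
                               probe_radius = 1.4, sphere_points = 960) {
  if (!nrow(complex$atoms)) return(b)
  total <- sum(compute_sasa(complex, probe_radius, sphere_points)$sasa)
  gamma * total + b
}

#' Binding energy components of a complex
#'
#' Computes each energy component for the complex and for the two isolated
#' partners at their complex-frame coordinates (single-trajectory
#' convention), and returns the binding differences
#' \eqn{\Delta G_k = G_k(complex) - G_k(partner_1) - G_k(partner_2)}.
#' Because the partners keep their bound-state geometry, intramolecular MM
#' terms cancel exactly and the MM components reduce to inter-partner
#' interactions.
#'
#' @param complex a \code{complex3d} object.
#' @param partners a \code{\link{partner_definition}}.
#' @param gamma,b nonpolar solvation parameters, see
#'   \code{\link{nonpolar_solvation}}.
#' @param sphere_points SASA sampling density.
#' @return object of class \code{energy_components}: named numeric with
#'   \code{mm_vdw}, \code{mm_elec}, \code{polar_solv}, \code{nonpolar_solv}
#'   (kcal/mol, binding differences).
#' @export
binding_components <- function(complex, partners, gamma = 0.005, b = 0,
                               sphere_points = 960) {
  halves <- split_partners(complex, partners)
  whole <- new_complex3d(rbind(halves$partner1$atoms, halves$partner2$atoms))
  comp <- function(cx) {
    mm <- mm_energy(cx)
    c(mm,
      polar_solv = polar_solvation(cx),
      nonpolar_solv = nonpolar_solvation(cx, gamma = gamma, b = b,
                                         sphere_points = sphere_points))
  }
  out <- comp(whole) - comp(halves$partner1) - comp(halves$partner2)
  structure(out, class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  cat("<binding energy components> (kcal/mol)\n")
  for (nm in names(x)) cat(sprintf("  %-14s %10.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Weights of the linear ddG model
#'
#' The predicted binding free energy change is
#' \deqn{\Delta\Delta G = \sum_k w_k\,(\Delta G_{bind,k}^{MT} -
#'   \Delta G_{bind,k}^{WT}) + w_0.}
#' The default is unit weights and zero intercept: the raw component-sum
#' physics with no empirical calibration. Fitted coefficient sets (and
#' weights for registered extra features) can be supplied here or loaded
#' from a configuration file.
#'
#' @param mm_vdw,mm_elec,polar_solv,nonpolar_solv component coefficients.
#' @param intercept constant offset, kcal/mol.
#' @param ... named coefficients for registered extra features.
#' @return object of class \code{weight_vector}.
#' @examples
#' weight_vector()                      # unit physics weights
#' weight_vector(mm_elec = 0.5, intercept = 0.1)
#' @export
weight_vector <- function(mm_vdw = 1, mm_elec = 1, polar_solv = 1,
                          nonpolar_solv = 1, intercept = 0, ...) {
  extra <- c(...)
  if (length(extra) && is.null(names(extra))) {
    stop("extra feature weights must be named")
  }
  w <- c(mm_vdw = mm_vdw, mm_elec = mm_elec, polar_solv = polar_solv,
         nonpolar_solv = nonpolar_solv, extra)
  structure(list(weights = w, intercept = intercept), class = "weight_vector")
}

#' Read a weight vector from a key = value configuration file
#'
#' Lines of the form \code{name = value}; \code{#} starts a comment. The
#' key \code{intercept} sets the constant term; every other key is a
#' component or feature coefficient.
#'
#' @param path configuration file.
#' @return a \code{\link{weight_vector}}.
#' @export
read_weights <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed weight line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 1)
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  if (any(is.na(vals))) stop("non-numeric weight value for: ",
                             keys[is.na(vals)][1])
  names(vals) <- keys
  intercept <- if ("intercept" %in% keys) vals[["intercept"]] else 0
  vals <- vals[keys != "intercept"]
  defaults <- c(mm_vdw = 1, mm_elec = 1, polar_solv = 1, nonpolar_solv = 1)
  for (nm in names(defaults)) if (!nm %in% names(vals)) vals[nm] <- defaults[nm]
  do.call(weight_vector, c(as.list(vals), list(intercept = intercept)))
}

# --- extra-term registry -----------------------------------------------------
# Hook for auxiliary per-mutation features entering the linear combination
# (default weight 0, so they do not perturb the physics-only prediction
# unless a coefficient is supplied).

.ddg_features <- new.env(parent = emptyenv())

#' Register an auxiliary ddG feature
#'
#' Registered features are evaluated by \code{\link{predict_ddg}} and enter
#' the linear combination with weight 0 unless the active
#' \code{\link{weight_vector}} names them.
#'
#' @param name feature name (also the weight key).
#' @param fn function(wt_min, mt_min, partners, spec) returning one numeric.
#' @return invisibly, the name.
#' @examples
#' register_ddg_feature("hydrophobicity_change",
#'   function(wt_min, mt_min, partners, spec) {
#'     kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
#'             E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
#'             M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
#'             Y = -1.3, V = 4.2)
#'     unname(kd[spec$mt] - kd[spec$wt])
#'   })
#' clear_ddg_features()
#' @export
register_ddg_feature <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .ddg_features)
  invisible(name)
}

#' @rdname register_ddg_feature
#' @export
clear_ddg_features <- function() {
  rm(list = ls(.ddg_features), envir = .ddg_features)
  invisible(NULL)
}

#' @noRd
evaluate_ddg_features <- function(wt_min, mt_min, partners, spec) {
  nms <- ls(.ddg_features)
  if (!length(nms)) return(numeric(0))
  vapply(nms, function(nm) {
    as.numeric(get(nm, envir = .ddg_features)(wt_min, mt_min, partners, spec))
  }, numeric(1))
}

#' Predict the binding free energy change of a mutation
#'
#' Combines the binding energy components of the minimized mutant and
#' wild-type complexes into
#' \eqn{\Delta\Delta G = \sum_k w_k (\Delta G_{bind,k}^{MT} -
#' \Delta G_{bind,k}^{WT}) + w_0}. Sign convention: positive values mean the
#' mutation weakens binding.
#'
#' @param wt_min,mt_min minimized wild-type and mutant \code{complex3d}
#'   objects (same partner definition, same minimization settings).
#' @param partners a \code{\link{partner_definition}}.
#' @param weights a \code{\link{weight_vector}}; must cover every produced
#'   component (registered extra features default to weight 0).
#' @param spec optional \code{\link{mutation_spec}} recorded in the result
#'   and passed to registered features.
#' @param site optional \code{site_location} of the mutation site recorded
#'   in the result.
#' @param gamma,b,sphere_points forwarded to
#'   \code{\link{binding_components}}.
#' @return object of class \code{ddg_prediction}: list with \code{ddg}
#'   (kcal/mol), \code{components_wt}, \code{components_mt},
#'   \code{delta_components}, \code{weights}, \code{site}, \code{mutation}.
#' @export
predict_ddg <- function(wt_min, mt_min, partners, weights = weight_vector(),
                        spec = NULL, site = NULL, gamma = 0.005, b = 0,
                        sphere_points = 960) {
  stopifnot(inherits(weights, "weight_vector"))
  cw <- binding_components(wt_min, partners, gamma = gamma, b = b,
                           sphere_points = sphere_points)
  cm <- binding_components(mt_min, partners, gamma = gamma, b = b,
                           sphere_points = sphere_points)
  delta <- unclass(cm) - unclass(cw)
  feats <- evaluate_ddg_features(wt_min, mt_min, partners, spec)
  delta <- c(delta, feats)
  w <- weights$weights
  core <- c("mm_vdw", "mm_elec", "polar_solv", "nonpolar_solv")
  if (!all(core %in% names(w))) {
    stop("weight vector is missing coefficients for: ",
         paste(setdiff(core, names(w)), collapse = ", "))
  }
  # registered features default to weight 0; unknown weight keys are an error
  stray <- setdiff(names(w), names(delta))
  if (length(stray)) {
    stop("weight(s) for components never produced: ",
         paste(stray, collapse = ", "))
  }
  wfull <- stats::setNames(numeric(length(delta)), names(delta))
  wfull[names(w)] <- w
  ddg <- sum(wfull * delta) + weights$intercept
  structure(list(ddg = ddg, components_wt = cw, components_mt = cm,
                 delta_components = delta, weights = weights, site = site,
                 mutation = spec),
            class = "ddg_prediction")
}

#' @export
print.ddg_prediction <- function(x, ...) {
  if (!is.null(x$mutation)) cat("mutation:", format(x$mutation), "\n")
  if (!is.null(x$site)) cat("site location:", x$site$category, "\n")
  cat(sprintf("predicted ddG (binding): %.4f kcal/mol\n", x$ddg))
  cat("component changes (MT - WT, kcal/mol):\n")
  for (nm in names(x$delta_components)) {
    cat(sprintf("  %-16s %10.4f\n", nm, x$delta_components[[nm]]))
  }
  invisible(x)
}
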