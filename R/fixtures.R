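# fixtures: synthetic inputs that make every stage testable without
# external downloads — ideal-geometry two-chain helical complexes with a
# tunable axis separation, random (calculated, experimental) prediction
# pairs with a target correlation, and loaders for the bundled clinical
# case tables.

#' Build a synthetic two-chain helical complex
#'
#' Constructs two ideal alpha-helices (phi = -57, psi = -47, omega = 180
#' degrees) with side chains built from the ideal-geometry rotamer
#' machinery, aligns each helix with the z axis, and places the second chain
#' at the requested perpendicular axis-to-axis separation (rotated half a
#' turn so the two faces meet). Small separations (<= 8 Angstrom) bury
#' residues and create an interface; large separations (>= 50) leave every
#' residue interior or surface. Fully deterministic for a fixed spec.
#'
#' @param chain_lengths integer vector of length 2, residues per chain
#'   (each >= 3).
#' @param separation axis-to-axis distance in Angstrom (> 0).
#' @param sequence optional character vector of two one-letter sequences
#'   (defaults to poly-alanine).
#' @param chain_ids identifiers for the two chains (default "A", "B").
#' @param seed integer recorded for provenance; the generator itself is
#'   deterministic.
#' @return a \code{complex3d} object.
#' @examples
#' cx <- make_synthetic_complex(chain_lengths = c(8, 8), separation = 7)
#' cx
#' @export
make_synthetic_complex <- function(chain_lengths = c(10, 10), separation = 8,
                                   sequence = NULL, chain_ids = c("A", "B"),
                                   seed = 0) {
  if (length(chain_lengths) != 2 || any(chain_lengths < 3)) {
    stop("chain_lengths must give two lengths >= 3")
  }
  if (separation <= 0) stop("separation must be positive")
  if (is.null(sequence)) {
    sequence <- vapply(chain_lengths, function(n) {
      paste(rep("A", n), collapse = "")
    }, character(1))
  }
  if (length(sequence) != 2) stop("sequence must give two chains")
  if (any(nchar(sequence) != chain_lengths)) {
    stop("sequence lengths must match chain_lengths")
  }

  chainA <- build_helix_chain(sequence[1], chain_ids[1])
  chainB <- build_helix_chain(sequence[2], chain_ids[2])

  xyzA <- align_helix_z(as.matrix(chainA[, c("x", "y", "z")]))
  xyzB <- align_helix_z(as.matrix(chainB[, c("x", "y", "z")]))
  # face the second helix toward the first (half-turn about z), then offset
  # along x by the axis separation
  xyzB <- xyzB %*% diag(c(-1, -1, 1))
  xyzB[, 1] <- xyzB[, 1] + separation

  chainA[, c("x", "y", "z")] <- xyzA
  chainB[, c("x", "y", "z")] <- xyzB
  cx <- new_complex3d(rbind(chainA, chainB))
  validate_complex(cx)
  cx
}

#' @noRd
# One ideal alpha-helix chain with side chains, as an atom data frame.
build_helix_chain <- function(sequence, chain_id) {
  aa1 <- strsplit(sequence, "")[[1]]
  res3 <- aa_three(aa1)
  n_res <- length(res3)
  phi <- -57; psi <- -47; omega <- 180
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.8

  # seed the first three backbone atoms, then extend by NeRF
  bb <- vector("list", n_res)
  n0 <- c(0, 0, 0)
  ca0 <- c(b_n_ca, 0, 0)
  c0 <- place_atom(c(-1, 1, 0), n0, ca0, b_ca_c, a_n_ca_c, phi)
  bb[[1]] <- list(N = n0, CA = ca0, C = c0)
  for (i in seq_len(n_res)[-1]) {
    p <- bb[[i - 1]]
    ni <- place_atom(p$N, p$CA, p$C, b_c_n, a_ca_c_n, psi)
    cai <- place_atom(p$CA, p$C, ni, b_n_ca, a_c_n_ca, omega)
    ci <- place_atom(p$C, ni, cai, b_ca_c, a_n_ca_c, phi)
    bb[[i]] <- list(N = ni, CA = cai, C = ci)
  }

  rows <- list()
  for (i in seq_len(n_res)) {
    p <- bb[[i]]
    # carbonyl O anti to the next amide N (trans peptide)
    o <- place_atom(p$N, p$CA, p$C, b_c_o, a_ca_c_o, psi + 180)
    at <- rbind(N = p$N, CA = p$CA, C = p$C, O = o)
    rot <- ROTAMER_LIBRARY[[res3[i]]]
    sc <- build_side_chain(res3[i], p$N, p$CA, p$C, chi = rot[1, ])
    if (nrow(sc)) at <- rbind(at, sc)
    rows[[i]] <- data.frame(chain = chain_id, resno = i, insert = "",
                            resname = res3[i], atom = rownames(at),
                            element = substr(rownames(at), 1, 1),
                            x = at[, 1], y = at[, 2], z = at[, 3],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @noRd
# Rigidly rotate a chain so its CA-axis (first-to-last CA direction via
# least squares on all atoms) lies along z, centred at the origin.
align_helix_z <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  axis <- prcomp(xc, center = FALSE)$rotation[, 1]
  z <- c(0, 0, 1)
  v <- cross3(axis, z)
  s <- vnorm(v); cth <- sum(axis * z)
  if (s < 1e-10) {
    rot <- if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    rot <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  xc %*% t(rot)
}

#' Generate synthetic (calculated, experimental) prediction pairs
#'
#' Calculated values are drawn from a centred normal; experimental values
#' are the calculated values plus Gaussian noise whose standard deviation is
#' chosen so the population correlation equals the target
#' (\eqn{\sigma_{noise} = \sigma_{calc}\sqrt{1/r^2 - 1}}), or set directly
#' via \code{noise_sd}. Deterministic per seed.
#'
#' @param n number of pairs (>= 2).
#' @param correlation target Pearson correlation in (0, 1]; mutually
#'   exclusive with \code{noise_sd}.
#' @param noise_sd experimental noise standard deviation, kcal/mol.
#' @param sd_calc spread of the calculated values, kcal/mol (default 1.5).
#' @param seed RNG seed (default 0).
#' @return data frame with columns \code{calc}, \code{exp}.
#' @examples
#' p <- make_prediction_pairs(1000, correlation = 0.62, seed = 7)
#' cor(p$calc, p$exp)
#' @export
make_prediction_pairs <- function(n, correlation = NULL, noise_sd = NULL,
                                  sd_calc = 1.5, seed = 0) {
  if (n < 2) stop("n must be >= 2")
  if (is.null(noise_sd)) {
    if (is.null(correlation)) correlation <- 0.62
    if (correlation <= 0 || correlation > 1) {
      stop("target correlation must be in (0, 1]")
    }
    noise_sd <- sd_calc * sqrt(1 / correlation^2 - 1)
  } else if (!is.null(correlation)) {
    stop("give either correlation or noise_sd, not both")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  calc <- stats::rnorm(n, 0, sd_calc)
  expv <- calc + stats::rnorm(n, 0, noise_sd)
  data.frame(calc = calc, exp = expv)
}

#' @noRd
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Load a bundled clinical case table
#'
#' Two variant tables ship with the package, both mapped onto experimental
#' complex structures and annotated with clinical effect classes:
#' \itemize{
#'   \item \code{"angiogenin"}: 14 missense variants of angiogenin in the
#'     ribonuclease inhibitor-angiogenin heterocomplex, with predicted
#'     single-chain ddG values and interface-location labels;
#'   \item \code{"aldolase"}: 18 missense variants of the homodimeric human
#'     liver fructose-1,6-bisphosphate aldolase, with per-chain predictions
#'     (\code{ddg_a}, \code{ddg_b}) and their published sum
#'     (\code{ddg_sum}).
#' }
#'
#' @param name \code{"angiogenin"} or \code{"aldolase"}.
#' @return data frame of case records.
#' @examples
#' nrow(load_case_table("angiogenin"))
#' @export
load_case_table <- function(name = c("angiogenin", "aldolase")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "ddgbind",
                      mustWork = TRUE)
  read_case_table(path)
}
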