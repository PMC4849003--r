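# sasa_interface: Shrake-Rupley solvent-accessible surface area, relative
# SASA against fully-exposed reference values, and interface-location
# classification of residues (core / support / rim / interior / surface).

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley algorithm on heavy atoms: each atom is inflated by the probe
#' radius and sampled with a deterministic quasi-uniform point set; points
#' not buried inside any neighbouring inflated sphere are accessible. The
#' per-residue SASA is the sum over the residue's atoms.
#'
#' @param complex a \code{complex3d} object.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a water
#'   molecule).
#' @param sphere_points number of test points per atom (default 960).
#'   Deterministic for a fixed count.
#' @return data frame with one row per residue: chain, resno, insert,
#'   resname, sasa (Angstrom^2).
#' @examples
#' cx <- make_synthetic_complex(chain_lengths = c(6, 6), separation = 30)
#' head(compute_sasa(cx))
#' @export
compute_sasa <- function(complex, probe_radius = 1.4, sphere_points = 960) {
  a <- complex$atoms
  radii <- unname(VDW_RADII[a$element])
  if (any(is.na(radii))) {
    bad <- which(is.na(radii))[1]
    stop(sprintf("no van der Waals radius for atom %s (element '%s') in %s %s%d",
                 a$atom[bad], a$element[bad], a$resname[bad], a$chain[bad],
                 a$resno[bad]))
  }
  xyz <- coords_matrix(complex)
  per_atom <- sasa_atoms(xyz, radii, probe_radius, sphere_points)
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  res <- residue_table(complex)
  res$sasa <- as.numeric(tapply(per_atom, factor(key, levels = unique(key)),
                                sum))
  res
}

#' @noRd
# Per-atom accessible area. O(n^2) neighbour search; intended for the
# complex sizes this package works at (hundreds to a few thousand atoms).
sasa_atoms <- function(xyz, radii, probe_radius = 1.4, sphere_points = 960) {
  n <- nrow(xyz)
  r_ext <- radii + probe_radius
  pts <- sphere_points(sphere_points)
  out <- numeric(n)
  if (n == 1) {
    return(4 * pi * r_ext^2)
  }
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    # neighbours whose inflated spheres can occlude atom i
    nb <- which(d2[i, ] < (r_ext[i] + r_ext)^2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * r_ext[i]^2
      next
    }
    p <- pts * r_ext[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(acc)) break
      dd <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dd > r_ext[j]^2
    }
    out[i] <- 4 * pi * r_ext[i]^2 * sum(acc) / nrow(p)
  }
  out
}

#' Relative solvent accessibility
#'
#' Ratio of a residue's SASA to its fully exposed reference value
#' (theoretical Gly-X-Gly maximum). A value of 1 corresponds to a totally
#' exposed residue; extended conformers may slightly exceed 1 and the ratio
#' is deliberately not clamped.
#'
#' @param absolute absolute SASA in Angstrom^2.
#' @param residue_type 3-letter residue code.
#' @return dimensionless fraction.
#' @export
relative_sasa <- function(absolute, residue_type) {
  residue_type <- toupper(residue_type)
  ref <- unname(MAX_SASA[residue_type])
  if (any(is.na(ref))) {
    stop("no reference maximum SASA for residue type: ",
         paste(unique(residue_type[is.na(ref)]), collapse = ", "))
  }
  if (any(absolute < 0)) stop("absolute SASA must be non-negative")
  absolute / ref
}

#' Classify a mutation site by interface location
#'
#' Assigns one of five categories from the relative SASA of the residue in
#' the isolated monomer (rSASAm) and in the complex (rSASAc), with
#' \eqn{\Delta rSASA = rSASAm - rSASAc}:
#' \itemize{
#'   \item interface (\eqn{\Delta rSASA > \epsilon}): COR if rSASAm > 0.25
#'     and rSASAc < 0.25; SUP if rSASAm < 0.25 and rSASAc < 0.25; RIM if
#'     rSASAc > 0.25;
#'   \item non-interface (\eqn{\Delta rSASA \le \epsilon}): INT if
#'     rSASAc < 0.25; SUR if rSASAc > 0.25.
#' }
#' COR, SUP and RIM residues are interfacial; INT and SUR are away from the
#' interface. A value exactly at the 25\% boundary is assigned to the
#' "< 25\%" branch (deterministic tie-break).
#'
#' @param rsasa_monomer,rsasa_complex relative SASA fractions (>= 0).
#' @param epsilon burial tolerance separating "no burial" from "buried"
#'   (default 0.005 of relative exposure, absorbing numerical noise in the
#'   exact-zero condition of the definition).
#' @return object of class \code{site_location}: list with \code{category}
#'   ("COR", "SUP", "RIM", "INT" or "SUR"), \code{rsasa_monomer},
#'   \code{rsasa_complex}, \code{delta_rsasa}, \code{interface} (logical).
#' @examples
#' classify_site(0.40, 0.10)$category   # buried on complexation: COR
#' classify_site(0.60, 0.60)$category   # exposed, no burial: SUR
#' @export
classify_site <- function(rsasa_monomer, rsasa_complex, epsilon = 0.005) {
  if (rsasa_monomer < 0 || rsasa_complex < 0) {
    stop("relative SASA fractions must be non-negative")
  }
  if (rsasa_complex > rsasa_monomer + epsilon) {
    stop(sprintf(paste0("rSASA in complex (%.3f) exceeds rSASA in monomer ",
                        "(%.3f): complexation cannot increase exposure"),
                 rsasa_complex, rsasa_monomer))
  }
  delta <- rsasa_monomer - rsasa_complex
  buried <- delta > epsilon
  if (buried) {
    category <- if (rsasa_complex > 0.25) "RIM"
    else if (rsasa_monomer > 0.25) "COR"
    else "SUP"
  } else {
    category <- if (rsasa_complex > 0.25) "SUR" else "INT"
  }
  structure(list(category = category,
                 rsasa_monomer = rsasa_monomer,
                 rsasa_complex = rsasa_complex,
                 delta_rsasa = delta,
                 interface = category %in% c("COR", "SUP", "RIM")),
            class = "site_location")
}

#' @export
print.site_location <- function(x, ...) {
  cat(sprintf("<site> %s (rSASAm %.3f, rSASAc %.3f, delta %.3f)%s\n",
              x$category, x$rsasa_monomer, x$rsasa_complex, x$delta_rsasa,
              if (x$interface) " [interface]" else ""))
  invisible(x)
}

#' Per-residue interface annotation of a complex
#'
#' Computes SASA of each partner in isolation and within the complex
#' (single-trajectory coordinates), converts to relative SASA, and classifies
#' every residue's interface location.
#'
#' @inheritParams split_partners
#' @param probe_radius,sphere_points passed to \code{\link{compute_sasa}}.
#' @param epsilon passed to \code{\link{classify_site}}.
#' @return data frame with one row per residue of the two partners: chain,
#'   resno, insert, resname, sasa_monomer, sasa_complex, rsasa_monomer,
#'   rsasa_complex, delta_rsasa, category.
#' @export
annotate_interface <- function(complex, partners, probe_radius = 1.4,
                               sphere_points = 960, epsilon = 0.005) {
  halves <- split_partners(complex, partners)
  both <- new_complex3d(rbind(halves$partner1$atoms, halves$partner2$atoms))
  in_complex <- compute_sasa(both, probe_radius, sphere_points)
  mono <- rbind(compute_sasa(halves$partner1, probe_radius, sphere_points),
                compute_sasa(halves$partner2, probe_radius, sphere_points))
  key <- function(d) paste(d$chain, d$resno, d$insert, sep = "|")
  idx <- match(key(in_complex), key(mono))
  out <- in_complex
  names(out)[names(out) == "sasa"] <- "sasa_complex"
  out$sasa_monomer <- mono$sasa[idx]
  out$rsasa_monomer <- relative_sasa(out$sasa_monomer, out$resname)
  out$rsasa_complex <- relative_sasa(out$sasa_complex, out$resname)
  # monomer exposure can only shrink on complexation; clip tiny negative
  # sampling noise before classification
  out$rsasa_complex <- pmin(out$rsasa_complex, out$rsasa_monomer)
  out$delta_rsasa <- out$rsasa_monomer - out$rsasa_complex
  out$category <- vapply(seq_len(nrow(out)), function(i) {
    classify_site(out$rsasa_monomer[i], out$rsasa_complex[i],
                  epsilon = epsilon)$category
  }, character(1))
  out[, c("chain", "resno", "insert", "resname", "sasa_monomer",
          "sasa_complex", "rsasa_monomer", "rsasa_complex", "delta_rsasa",
          "category")]
}

#' Write a per-residue interface annotation table as TSV
#' @param annotation output of \code{\link{annotate_interface}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_interface_table <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
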