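# Independent oracles and toy-structure builders used across the suite.
# These deliberately re-derive quantities by different algorithms (random
# sphere sampling, plain double loops, literal truth tables) so they can
# cross-check the package implementation.

# Build a complex3d directly from parallel vectors (bypasses read_pdb).
toy_complex <- function(chain, resno, resname, atom, x, y, z, element = NULL) {
  if (is.null(element)) element <- substr(atom, 1, 1)
  ddgbind:::new_complex3d(data.frame(
    chain = chain, resno = resno, insert = "", resname = resname,
    atom = atom, element = element, x = x, y = y, z = z,
    stringsAsFactors = FALSE))
}

# A lone glycine residue (N, CA, C, O) with realistic geometry.
toy_glycine <- function(origin = c(0, 0, 0)) {
  xyz <- rbind(N = c(0, 0, 0), CA = c(1.458, 0, 0),
               C = c(1.993, 1.427, 0), O = c(1.247, 2.409, 0.1))
  xyz <- sweep(xyz, 2, origin, "+")
  toy_complex("A", 1, "GLY", rownames(xyz), xyz[, 1], xyz[, 2], xyz[, 3])
}

# Monte-Carlo SASA oracle: uniform random points on each inflated sphere
# (rejection-free via normalized Gaussians), independent of the package's
# deterministic spiral point set.
sasa_oracle <- function(xyz, radii, probe = 1.4, npts = 10000, seed = 42) {
  set.seed(seed)
  re <- radii + probe
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    g <- matrix(rnorm(npts * 3), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    pts <- sweep(g * re[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, npts)
    for (j in seq_len(n)[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & (d2 > re[j]^2)
    }
    out[i] <- 4 * pi * re[i]^2 * mean(acc)
  }
  out
}

# Plain double-loop MM oracle: bond graph by breadth-first search, explicit
# exclusion sets, scalar accumulation.
mm_oracle <- function(complex) {
  a <- complex$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  elem <- a$element
  li <- match(elem, ddgbind:::LJ_PARAMS$element)
  eps <- ddgbind:::LJ_PARAMS$eps[li]
  rmin2 <- ddgbind:::LJ_PARAMS$rmin2[li]
  q <- ddgbind:::atom_charge(a$resname, a$atom)

  # bonds by the same distance criterion, but stored as an adjacency list
  bonded <- vector("list", n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    cut <- if (elem[i] == "S" && elem[j] == "S") 2.30
    else if (elem[i] == "S" || elem[j] == "S") 2.10 else 1.85
    if (d > 0.4 && d < cut) {
      bonded[[i]] <- c(bonded[[i]], j); bonded[[j]] <- c(bonded[[j]], i)
    }
  }
  sep <- function(i, j) {   # bond-graph distance up to 4 by BFS
    if (i == j) return(0)
    frontier <- i; seen <- i
    for (k in 1:4) {
      frontier <- setdiff(unique(unlist(bonded[frontier])), seen)
      if (j %in% frontier) return(k)
      seen <- c(seen, frontier)
    }
    Inf
  }
  vdw <- 0; elec <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sep(i, j)                      # bonds separating i and j
    if (s <= 2) next                    # 1-2 and 1-3 are excluded
    scale <- if (s == 3) 0.5 else 1     # 1-4 pairs are halved
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    rm <- rmin2[i] + rmin2[j]
    e <- sqrt(eps[i] * eps[j])
    vdw <- vdw + scale * e * ((rm / r)^12 - 2 * (rm / r)^6)
    elec <- elec + scale * 332.06 * q[i] * q[j] / (4 * r^2)
  }
  c(mm_vdw = vdw, mm_elec = elec)
}

# Literal truth-table evaluator of the five scenario predicate sets,
# written as independent straight-line code over (|calc|, |exp|, signs).
scenario_oracle <- function(calc, expv, id, x, y = NULL, z = NULL) {
  a <- abs(calc); b <- abs(expv)
  sgn <- (calc >= 0) == (expv >= 0)
  tp_mag <- switch(id,
                   a >= x && b >= x,
                   a >= y && b >= y,
                   a >= x && b >= y,
                   a >= x && b >= y,
                   a >= y && b >= x)
  if (tp_mag) return(if (sgn) "tp" else "fp")
  fp <- switch(id,
               a >= x && b < x,
               a >= y && b < x,
               a >= y && b < x,
               a >= x && b < y,
               a >= y && b < z)
  if (fp) return("fp")
  fn <- switch(id,
               a < x && b >= x,
               a < x && b >= y,
               a < x && b >= y,
               a < z && b >= y,
               a < y && b >= x)
  if (fn) return("fn")
  tn <- switch(id,
               a < x && b < x,
               a < x && b < x,
               a < y && b < x,
               a < z && b < y,
               a < y && b < z)
  if (tn) return("tn")
  "gray"
}

# Confusion counts via the oracle.
counts_oracle <- function(pairs, id, x, y = NULL, z = NULL) {
  cls <- mapply(scenario_oracle, pairs$calc, pairs$exp,
                MoreArgs = list(id = id, x = x, y = y, z = z))
  list(tp = sum(cls == "tp"), tn = sum(cls == "tn"),
       fp = sum(cls == "fp"), fn = sum(cls == "fn"),
       n_total = length(cls))
}
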