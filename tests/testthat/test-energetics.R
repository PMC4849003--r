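test_that("two neutral atoms at the LJ minimum give -eps and no electrostatics", {
  # two carbons, resname chosen so both atoms are charge-free
  rmin <- 2 * 1.95
  cx <- toy_complex("A", c(1, 2), "ALA", c("CB", "CB"),
                    x = c(0, rmin), y = c(0, 0), z = c(0, 0))
  mm <- mm_energy(cx)
  expect_equal(unname(mm["mm_vdw"]), -0.105, tolerance = 1e-10)
  expect_equal(unname(mm["mm_elec"]), 0)
})

test_that("unit charges at 4 A with eps(r) = 4r match the Coulomb closed form", {
  # NZ of LYS carries +0.7 and OD1 of ASP -0.7 in the embedded charge set;
  # scale expectations accordingly and verify the 332.06/(4 r^2) kernel
  cx <- toy_complex("A", c(1, 2), c("LYS", "ASP"), c("NZ", "OD1"),
                    x = c(0, 4), y = c(0, 0), z = c(0, 0))
  mm <- mm_energy(cx)
  expect_equal(unname(mm["mm_elec"]), 332.06 * (0.7 * -0.7) / (4 * 4 * 4),
               tolerance = 1e-10)
})

test_that("mm energy equals a brute-force double-loop oracle", {
  cx <- make_synthetic_complex(chain_lengths = c(3, 3), separation = 7,
                               sequence = c("AKA", "ADA"))
  mine <- mm_energy(cx)
  ref <- mm_oracle(cx)
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("Born ion solvation matches the closed form", {
  cx <- toy_complex("A", 1, "LYS", "NZ", 0, 0, 0)   # charge +0.7, radius 1.55
  got <- polar_solvation(cx)
  expect_equal(got, -166.03 * 0.7^2 * (1 - 1 / 80) / 1.55, tolerance = 1e-9)
})

test_that("zero charges give zero polar solvation", {
  cx <- toy_complex("A", c(1, 2), "ALA", c("CB", "CB"),
                    x = c(0, 4), y = c(0, 0), z = c(0, 0))
  expect_equal(polar_solvation(cx), 0)
})

test_that("two-charge GB matches a hand evaluation of the Still formula", {
  cx <- toy_complex("A", c(1, 2), c("LYS", "ASP"), c("NZ", "OD1"),
                    x = c(0, 5), y = c(0, 0), z = c(0, 0))
  q <- c(0.7, -0.7); a <- c(1.55, 1.52); r <- 5
  fgb <- sqrt(r^2 + a[1] * a[2] * exp(-r^2 / (4 * a[1] * a[2])))
  hand <- -0.5 * 332.06 * (1 - 1 / 80) *
    (q[1]^2 / a[1] + q[2]^2 / a[2] + 2 * q[1] * q[2] / fgb)
  expect_equal(polar_solvation(cx), hand, tolerance = 1e-9)
})

test_that("polar solvation is never positive for charged structures", {
  for (sep in c(6, 9, 15)) {
    cx <- make_synthetic_complex(chain_lengths = c(4, 4), separation = sep,
                                 sequence = c("AKDA", "AREA"))
    expect_lte(polar_solvation(cx), 0)
  }
})

test_that("nonpolar solvation is linear in gamma with offset b", {
  cx <- toy_complex("A", 1, "GLY", "CA", 0, 0, 0)
  area <- 4 * pi * (1.70 + 1.4)^2
  v1 <- nonpolar_solvation(cx, gamma = 0.005, b = 0, sphere_points = 960)
  expect_equal(v1, 0.005 * area, tolerance = 1e-3)
  expect_equal(nonpolar_solvation(cx, gamma = 0.010, b = 0,
                                  sphere_points = 960), 2 * v1,
               tolerance = 1e-9)
  expect_equal(nonpolar_solvation(cx, gamma = 0.005, b = 1.5,
                                  sphere_points = 960), v1 + 1.5,
               tolerance = 1e-9)
  empty <- ddgbind:::new_complex3d(cx$atoms[0, ])
  expect_equal(nonpolar_solvation(empty, b = 0.7), 0.7)
})

test_that("partners at huge separation have no MM binding interaction", {
  cx <- make_synthetic_complex(chain_lengths = c(4, 4), separation = 999,
                               sequence = c("AKDA", "AREA"))
  bc <- binding_components(cx, partner_definition("A", "B"),
                           sphere_points = 240)
  expect_lt(abs(bc[["mm_vdw"]]), 1e-6)
  expect_lt(abs(bc[["mm_elec"]]), 1e-4)
})

test_that("binding MM terms equal the inter-chain pair sum (single trajectory)", {
  cx <- make_synthetic_complex(chain_lengths = c(3, 3), separation = 7,
                               sequence = c("AKA", "ADA"))
  bc <- binding_components(cx, partner_definition("A", "B"),
                           sphere_points = 240)
  # oracle: explicit sum over inter-chain atom pairs only (no exclusions
  # cross the chain gap; all scale 1)
  a <- cx$atoms
  A <- a[a$chain == "A", ]; B <- a[a$chain == "B", ]
  li <- function(d) match(d$element, ddgbind:::LJ_PARAMS$element)
  qa <- ddgbind:::atom_charge(A$resname, A$atom)
  qb <- ddgbind:::atom_charge(B$resname, B$atom)
  vdw <- 0; elec <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    r <- sqrt(sum((as.numeric(A[i, c("x", "y", "z")]) -
                     as.numeric(B[j, c("x", "y", "z")]))^2))
    rm <- ddgbind:::LJ_PARAMS$rmin2[li(A)[i]] + ddgbind:::LJ_PARAMS$rmin2[li(B)[j]]
    ep <- sqrt(ddgbind:::LJ_PARAMS$eps[li(A)[i]] * ddgbind:::LJ_PARAMS$eps[li(B)[j]])
    vdw <- vdw + ep * ((rm / r)^12 - 2 * (rm / r)^6)
    elec <- elec + 332.06 * qa[i] * qb[j] / (4 * r^2)
  }
  expect_equal(bc[["mm_vdw"]], vdw, tolerance = 1e-8)
  expect_equal(bc[["mm_elec"]], elec, tolerance = 1e-8)
})

test_that("binding components are invariant under rigid motion", {
  cx <- make_synthetic_complex(chain_lengths = c(4, 4), separation = 8,
                               sequence = c("AKDA", "AREA"))
  pn <- partner_definition("A", "B")
  bc1 <- binding_components(cx, pn, sphere_points = 480)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- ddgbind:::coords_matrix(cx) %*% rot
  xyz <- sweep(xyz, 2, c(11, -4, 3), "+")
  bc2 <- binding_components(ddgbind:::set_coords(cx, xyz), pn,
                            sphere_points = 480)
  expect_lt(max(abs(unclass(bc1)[c("mm_vdw", "mm_elec", "polar_solv")] -
                      unclass(bc2)[c("mm_vdw", "mm_elec", "polar_solv")])),
            1e-4)
  # SASA-based term is sampling-orientation dependent; allow looser agreement
  expect_lt(abs(bc1[["nonpolar_solv"]] - bc2[["nonpolar_solv"]]), 0.02)
})

test_that("predict_ddg honors trivial weight settings and is linear in weights", {
  cx <- make_synthetic_complex(chain_lengths = c(4, 4), separation = 8,
                               sequence = c("AKAA", "ADAA"))
  pn <- partner_definition("A", "B")
  mt <- mutate_residue(cx, mutation_spec("A", 2, "K", "A"))
  cfg <- minimization_config(max_iterations = 30)
  wt_min <- minimize(cx, cfg)$complex
  mt_min <- minimize(mt, cfg)$complex

  p0 <- predict_ddg(wt_min, wt_min, pn, sphere_points = 240)
  expect_equal(p0$ddg, 0)

  pz <- predict_ddg(wt_min, mt_min, pn,
                    weights = weight_vector(0, 0, 0, 0, intercept = 1.5),
                    sphere_points = 240)
  expect_equal(pz$ddg, 1.5)

  # hand-summed component differences under unit weights
  p1 <- predict_ddg(wt_min, mt_min, pn, sphere_points = 240)
  expect_equal(p1$ddg, sum(p1$delta_components), tolerance = 1e-12)

  # linearity: bumping one coefficient shifts ddg by delta * coefficient
  p2 <- predict_ddg(wt_min, mt_min, pn,
                    weights = weight_vector(mm_elec = 3), sphere_points = 240)
  expect_equal(p2$ddg - p1$ddg, 2 * p1$delta_components[["mm_elec"]],
               tolerance = 1e-10)

  expect_error(predict_ddg(wt_min, mt_min, pn,
                           weights = weight_vector(bogus_term = 1),
                           sphere_points = 240), "never produced")
})

test_that("registered extra features enter the combination at their weight", {
  cx <- make_synthetic_complex(chain_lengths = c(4, 4), separation = 9,
                               sequence = c("AKAA", "AAAA"))
  pn <- partner_definition("A", "B")
  spec <- mutation_spec("A", 2, "K", "A")
  mt <- mutate_residue(cx, spec)
  cfg <- minimization_config(max_iterations = 20)
  wt_min <- minimize(cx, cfg)$complex
  mt_min <- minimize(mt, cfg)$complex
  on.exit(clear_ddg_features(), add = TRUE)
  register_ddg_feature("always_two", function(wt, mt, pn, spec) 2)
  base <- predict_ddg(wt_min, mt_min, pn, spec = spec, sphere_points = 240)
  withw <- predict_ddg(wt_min, mt_min, pn, spec = spec,
                       weights = weight_vector(always_two = 0.25),
                       sphere_points = 240)
  expect_equal(withw$ddg - base$ddg, 0.5, tolerance = 1e-10)
})

test_that("weights round-trip through a key=value config file", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# fitted coefficients", "mm_vdw = 0.5", "mm_elec = 0.25",
               "intercept = -0.1"), f)
  w <- read_weights(f)
  expect_equal(unname(w$weights[c("mm_vdw", "mm_elec", "polar_solv")]),
               c(0.5, 0.25, 1))
  expect_equal(w$intercept, -0.1)
})
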