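test_that("self-mutation returns an identical complex", {
  cx <- make_synthetic_complex(chain_lengths = c(5, 5), separation = 9,
                               sequence = c("AKLSV", "AAAAA"))
  out <- mutate_residue(cx, mutation_spec("A", 2, "K", "K"))
  expect_identical(out$atoms, cx$atoms)
})

test_that("ALA->GLY removes CB and leaves the backbone bit-identical", {
  cx <- make_synthetic_complex(chain_lengths = c(6, 6), separation = 12)
  out <- mutate_residue(cx, mutation_spec("A", 3, "A", "G"))
  orig <- cx$atoms[cx$atoms$chain == "A" & cx$atoms$resno == 3, ]
  new <- out$atoms[out$atoms$chain == "A" & out$atoms$resno == 3, ]
  expect_false("CB" %in% new$atom)
  expect_identical(new$resname, rep("GLY", nrow(new)))
  bb <- c("N", "CA", "C", "O")
  expect_identical(new[match(bb, new$atom), c("x", "y", "z")],
                   orig[match(bb, orig$atom), c("x", "y", "z")],
                   ignore_attr = TRUE)
})

test_that("wild-type mismatch is reported with expected vs found", {
  cx <- make_synthetic_complex(chain_lengths = c(5, 5), separation = 12,
                               sequence = c("ARLSV", "AAAAA"))
  expect_error(mutate_residue(cx, mutation_spec("A", 2, "K", "E")),
               "expected K, found R")
  expect_error(mutate_residue(cx, mutation_spec("A", 99, "K", "E")),
               "no residue")
})

test_that("mutation changes only atoms of the target residue", {
  cx <- make_synthetic_complex(chain_lengths = c(6, 6), separation = 9,
                               sequence = c("AALAAA", "AAAAAA"))
  out <- mutate_residue(cx, mutation_spec("A", 3, "L", "W"))
  tgt <- function(d) d$chain == "A" & d$resno == 3
  expect_identical(out$atoms[!tgt(out$atoms), ], cx$atoms[!tgt(cx$atoms), ],
                   ignore_attr = TRUE)
  new <- out$atoms[tgt(out$atoms), ]
  expect_setequal(new$atom,
                  c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1",
                    "CE2", "CE3", "CZ2", "CZ3", "CH2"))
})

test_that("all 20 target residues build complete ideal side chains", {
  cx <- make_synthetic_complex(chain_lengths = c(7, 4), separation = 25)
  for (mt in c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V")) {
    out <- mutate_residue(cx, mutation_spec("A", 4, "A", mt))
    res <- out$atoms[out$atoms$chain == "A" & out$atoms$resno == 4, ]
    want <- c("N", "CA", "C", "O",
              if (mt != "G") "CB",
              ddgbind:::SIDECHAIN_TOPOLOGY[[ddgbind:::aa_three(mt)]]$atom)
    expect_setequal(res$atom, want)
    # built geometry must be reasonable: no pair of new side-chain atoms
    # closer than a covalent bond can be
    xyz <- as.matrix(res[, c("x", "y", "z")])
    if (nrow(xyz) > 1) expect_gt(min(dist(xyz)), 1.15)
  }
})

test_that("rotamer choice avoids clashes when one rotamer is blocked", {
  cx <- make_synthetic_complex(chain_lengths = c(8, 8), separation = 7)
  out <- mutate_residue(cx, mutation_spec("A", 5, "A", "R"))   # buried site
  res <- out$atoms[out$atoms$chain == "A" & out$atoms$resno == 5, ]
  other <- out$atoms[!(out$atoms$chain == "A" & out$atoms$resno == 5), ]
  sc <- as.matrix(res[!res$atom %in% c("N", "CA", "C", "O", "CB"),
                      c("x", "y", "z")])
  env <- as.matrix(other[, c("x", "y", "z")])
  mind <- min(apply(sc, 1, function(p) {
    min(sqrt(colSums((t(env) - p)^2)))
  }))
  expect_gt(mind, 1.5)   # no atom driven inside another residue
})

test_that("a compressed LJ pair relaxes to the scanned pair-potential minimum", {
  # 1-D scan oracle over the isolated pair potential
  eps <- 0.105; rmin <- 2 * 1.95
  sys <- list(q = c(0, 0), eps = rep(eps, 2), rmin2 = rep(1.95, 2),
              bonds = list(i = integer(0), j = integer(0), r0 = numeric(0)),
              pairs14 = matrix(FALSE, 2, 2),
              excluded = diag(2) == 1, n = 2)
  rgrid <- seq(2.5, 6, by = 1e-4)
  e_pair <- eps * ((rmin / rgrid)^12 - 2 * (rmin / rgrid)^6)
  r_opt <- rgrid[which.min(e_pair)]

  xyz <- rbind(c(0, 0, 0), c(0.8 * rmin, 0, 0))
  res <- ddgbind:::minimize_atoms(xyz, sys, max_iterations = 400,
                                  force_tolerance = 1e-4)
  r_final <- sqrt(sum((res$xyz[1, ] - res$xyz[2, ])^2))
  expect_lt(abs(r_final - r_opt) / r_opt, 0.01)
})

test_that("minimization energy traces never increase", {
  cx <- make_synthetic_complex(chain_lengths = c(10, 10), separation = 8,
                               sequence = c("AKLSVAEGYA", "ALAVAKAEAA"))
  res <- minimize(cx, minimization_config(max_iterations = 200))
  expect_true(all(diff(res$trace) <= 1e-9))
  expect_lte(res$trace[length(res$trace)], res$trace[1])
})

test_that("re-minimizing a minimized structure barely moves the energy", {
  # unrestrained, so the relaxed geometry is a genuine fixed point (the
  # default scheme re-anchors its positional restraints at each call)
  cx <- make_synthetic_complex(chain_lengths = c(4, 4), separation = 9)
  cfg <- minimization_config(max_iterations = 4000, force_tolerance = 0.3,
                             restraint_scheme = "none")
  first <- minimize(cx, cfg)
  expect_true(first$converged)
  second <- minimize(first$complex, cfg)
  drop1 <- first$trace[1] - first$trace[length(first$trace)]
  drop2 <- second$trace[1] - second$trace[length(second$trace)]
  expect_lt(drop2, 0.05 * drop1 + 0.05)
})

test_that("identical WT/MT minimization gives zero downstream differences", {
  cx <- make_synthetic_complex(chain_lengths = c(5, 5), separation = 9,
                               sequence = c("AKAAA", "AAAAA"))
  cfg <- minimization_config(max_iterations = 40)
  wt <- minimize(cx, cfg)
  mt <- minimize(mutate_residue(cx, mutation_spec("A", 2, "K", "K")), cfg)
  pn <- partner_definition("A", "B")
  pred <- predict_ddg(wt$complex, mt$complex, pn, sphere_points = 240)
  expect_lt(abs(pred$ddg), 1e-6)
  expect_true(all(abs(pred$delta_components) < 1e-6))
})

test_that("minimization config validates its inputs", {
  expect_error(minimization_config(max_iterations = 0), "positive")
  expect_error(minimization_config(force_tolerance = -1), "positive")
})
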