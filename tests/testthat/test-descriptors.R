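# Surface, shape, partition, logP/logS, acceptor and ESP descriptors against
# analytic and brute-force oracles.

single_sphere <- function(r = 1.7) gen_toy_molecule("single_atom", radius = r)

test_that("SASA matches closed forms for spheres", {
  m <- single_sphere(1.7)
  s <- compute_sasa(m, probe_radius = 1.4)
  expect_rel_equal(attr(s, "total"), 4 * pi * 3.1^2, 0.005)
  # far pair: no occlusion
  p <- gen_toy_molecule("pair", radius = 1.7, separation = 100)
  expect_rel_equal(sasa_total(p), 2 * 4 * pi * 3.1^2, 0.005)
  # coincident-ish pair occludes: analytic two-sphere formula at 2.0 A
  p2 <- gen_toy_molecule("pair", radius = 1.7, separation = 2.0)
  expect_rel_equal(sasa_total(p2), two_sphere_sasa(3.1, 2.0), 0.01)
})

test_that("SASA agrees with a dense random-point oracle on an overlapping pair", {
  xyz <- rbind(c(0, 0, 0), c(2.0, 0, 0))
  oracle <- dense_sasa(xyz, c(1.7, 1.7), probe = 1.4, n_points = 2e5)
  p2 <- gen_toy_molecule("pair", radius = 1.7, separation = 2.0)
  expect_rel_equal(sasa_total(p2, n_points = 960L), oracle, 0.01)
})

test_that("SASA quadrature converges and rejects unusable resolutions", {
  p <- gen_toy_molecule("pair", radius = 1.7, separation = 2.5)
  s1 <- sasa_total(p, n_points = 960L)
  s2 <- sasa_total(p, n_points = 1920L)
  expect_lt(abs(s2 - s1) / s1, 0.005)
  expect_error(compute_sasa(p, n_points = 8), "at least 12")
})

test_that("volume matches analytic sphere and sphere-union values", {
  expect_rel_equal(compute_volume(single_sphere(1.7)),
                   4 / 3 * pi * 1.7^3, 0.01)
  # coincident atoms: union is one sphere
  co <- molecule(data.frame(element = c("C", "C"), x = 0, y = 0, z = 0,
                            radius = 1.7))
  expect_rel_equal(compute_volume(co), 4 / 3 * pi * 1.7^3, 0.01)
  # partial overlap vs the closed-form lens union
  ov <- gen_toy_molecule("pair", radius = 1.7, separation = 2.0)
  expect_rel_equal(compute_volume(ov), sphere_union_volume(1.7, 1.7, 2.0),
                   0.01)
  expect_error(compute_volume(ov, grid_spacing = 0), "positive")
})

test_that("globularity behaves like a shape measure", {
  m <- single_sphere(1.7)
  expect_equal(shape_descriptors(m, probe_radius = 0)$glob, 1, tolerance = 0.01)
  expect_equal(shape_descriptors(m, probe_radius = 1.4)$glob, (1.7 / 3.1)^2,
               tolerance = 0.01)
  # elongating a chain strictly decreases glob
  globs <- vapply(c(1.0, 2.0, 3.0), function(sep) {
    shape_descriptors(gen_toy_molecule("linear_chain", n_atoms = 3,
                                       separation = sep),
                      grid_spacing = 0.15)$glob
  }, numeric(1))
  expect_true(all(diff(globs) < 0))
  expect_true(all(globs > 0 & globs <= 1))
})

test_that("FISA/PISA partition the surface consistently", {
  alkane <- gen_toy_molecule("linear_chain", n_atoms = 4, separation = 1.5)
  expect_equal(surface_partition(alkane)$fisa, 0)
  ring <- gen_toy_molecule("ring", n_atoms = 6)
  spr <- surface_partition(ring)
  expect_equal(spr$pisa, spr$sasa)  # all atoms aromatic C
  ph <- gen_toy_molecule("phenol_like")
  sp <- surface_partition(ph)
  # FISA equals the per-atom O + H(O) sum from compute_sasa
  sr <- compute_sasa(ph)
  o_idx <- which(ph$atoms$element == "O")
  ho <- which(ph$atoms$element == "H" &
                vapply(seq_len(nrow(ph$atoms)), function(k) {
                  any(ph$bonds$i == o_idx & ph$bonds$j == k) ||
                    any(ph$bonds$j == o_idx & ph$bonds$i == k)
                }, logical(1)))
  expect_equal(sp$fisa, sum(sr$sasa[c(o_idx, ho)]))
  expect_lte(sp$fisa + sp$pisa, sp$sasa + 1e-9)
})

test_that("logP is the hand-sum of the contribution table and is additive", {
  # methane: one C_sp3 + four H_C
  ch4 <- molecule(
    data.frame(element = c("C", "H", "H", "H", "H"),
               x = c(0, 1.09, -1.09, 0, 0), y = c(0, 0, 0, 1.09, -1.09),
               z = 0),
    bonds = data.frame(i = 1, j = 2:5))
  lp <- logp_logs(ch4)
  expect_equal(lp$logp, 0.144 + 4 * 0.123, tolerance = 1e-12)
  expect_equal(attr(lp, "scheme")[["logp"]], "lacqsar.clogp.v1")
  # adding one CH2 to an alkane increases logP by a constant increment
  alkane <- function(n) {
    atoms <- data.frame(element = rep(c("C", "H", "H"), n),
                        x = rep(1.5 * seq_len(n), each = 3),
                        y = rep(c(0, 0.9, -0.9), n), z = 0)
    bonds <- rbind(
      if (n > 1) data.frame(i = 3 * (seq_len(n - 1) - 1) + 1,
                            j = 3 * seq_len(n - 1) + 1),
      data.frame(i = rep(3 * (seq_len(n) - 1) + 1, each = 2),
                 j = as.vector(rbind(3 * (seq_len(n) - 1) + 2,
                                     3 * (seq_len(n) - 1) + 3)))
    )
    molecule(atoms, bonds)
  }
  lps <- vapply(2:5, function(n) logp_logs(alkane(n))$logp, numeric(1))
  incs <- diff(lps)
  expect_equal(incs, rep(incs[1], 3), tolerance = 1e-12)
  expect_equal(incs[1], 0.144 + 2 * 0.123, tolerance = 1e-12)
})

test_that("logS follows the solubility regression (negative logP slope)", {
  ph <- gen_toy_molecule("phenol_like")
  r <- logp_logs(ph)
  # returned value is exactly the published regression on the returned terms
  expect_equal(r$logs,
               0.16 - 0.63 * r$logp - 0.0062 * r$mw +
                 0.066 * r$rotatable_bonds - 0.74 * r$aromatic_proportion,
               tolerance = 1e-12)
  expect_equal(attr(r, "scheme")[["logs"]], "ESOL")
})

test_that("acceptor counting follows the documented rule table", {
  expect_equal(count_hb_acceptors(gen_toy_molecule("phenol_like")), 1)
  expect_equal(count_hb_acceptors(gen_toy_molecule("ring", n_atoms = 6)), 0)
  # catechol-like: two phenolic O
  ring <- ring_coords_for_test(6)
  atoms <- data.frame(
    element = c(rep("C", 6), "O", "H", "O", "H"),
    x = c(ring[, 1], 2.75, 3.3, 2.75 * cos(pi / 3), 3.3 * cos(pi / 3)),
    y = c(ring[, 2], 0, 0.8, 2.75 * sin(pi / 3), 3.3 * sin(pi / 3)),
    z = 0, aromatic = c(rep(TRUE, 6), rep(FALSE, 4)))
  bonds <- data.frame(i = c(1:6, 1, 7, 2, 9), j = c(2:6, 1, 7, 8, 9, 10))
  expect_equal(count_hb_acceptors(molecule(atoms, bonds)), 2)
  # carboxylate O pair counts once
  cooh <- molecule(
    data.frame(element = c("C", "O", "O", "H"),
               x = c(0, 1.2, -0.6, -1.2), y = c(0, 0, 1.0, 1.6), z = 0),
    bonds = data.frame(i = c(1, 1, 3), j = c(2, 3, 4), order = c(2, 1, 1)))
  expect_equal(count_hb_acceptors(cooh), 1)
})

test_that("ESP extrema follow Coulomb's law", {
  # charged sphere with accessible surface at 3.0 A
  mq <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0, radius = 1.6,
                            charge = 0.5), formal_charge = 0.5)
  esp <- esp_extrema(mq, probe_radius = 1.4)
  expect_equal(esp$esp_max, 332.0636 * 0.5 / 3.0, tolerance = 1e-6)
  # neutral atom: identically zero
  m0 <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0, charge = 0))
  esp0 <- esp_extrema(m0)
  expect_equal(esp0$esp_max, 0)
  expect_equal(esp0$esp_min, 0)
  expect_error(esp_extrema(single_sphere()), "charges")
})

test_that("diatomic ESP maximum matches a dense-scan oracle", {
  di <- molecule(data.frame(element = c("C", "C"), x = c(0, 2.5), y = 0,
                            z = 0, radius = 1.7, charge = c(0.4, -0.4)),
                 formal_charge = 0)
  esp <- esp_extrema(di, n_points = 4000L)
  # oracle: brute-force scan over ~1e6 random accessible surface points
  set.seed(7)
  xyz <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  R <- 3.1
  pot <- c()
  for (i in 1:2) {
    z <- stats::runif(5e5, -1, 1); th <- stats::runif(5e5, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    pts <- cbind(s * cos(th), s * sin(th), z) * R
    pts <- sweep(pts, 2, xyz[i, ], "+")
    other <- xyz[3 - i, ]
    keep <- (pts[, 1] - other[1])^2 + (pts[, 2] - other[2])^2 +
      (pts[, 3] - other[3])^2 > R^2
    pts <- pts[keep, ]
    d1 <- sqrt(rowSums(sweep(pts, 2, xyz[1, ])^2))
    d2 <- sqrt(rowSums(sweep(pts, 2, xyz[2, ])^2))
    pot <- c(pot, 332.0636 * (0.4 / d1 - 0.4 / d2))
  }
  expect_lt(abs(esp$esp_max - max(pot)), 0.1)
  # maximum sits on the positive side (x < centre)
  expect_lt(attr(esp, "max_point")[1], 1.25)
})

test_that("surface descriptors are invariant under rigid transforms", {
  set.seed(123)
  ph <- assign_simple_charges(gen_toy_molecule("phenol_like"))
  base_sasa <- sasa_total(ph)
  base_vol <- compute_volume(ph)
  base_esp <- esp_extrema(ph)$esp_max
  for (k in 1:5) {
    tr <- random_rigid_transform()
    pht <- transform_molecule(ph, tr)
    expect_rel_equal(sasa_total(pht), base_sasa, 0.01)
    expect_rel_equal(compute_volume(pht), base_vol, 0.02)
    expect_lt(abs(esp_extrema(pht)$esp_max - base_esp), 0.5)
  }
})
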