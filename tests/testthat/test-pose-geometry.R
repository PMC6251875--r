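# Donor selection, electron-transfer distances, active-pose calls and the
# interaction detectors on constructed geometries.

test_that("donor selection prefers the phenolic OH closest to the His", {
  cx <- gen_synthetic_pose(4.2)
  d <- select_donor_atom(cx)
  expect_equal(d$donor_class, "phenolic_OH")
  expect_equal(d$element, "O")
  # two-hydroxyl ligand: the closer O wins
  base <- gen_synthetic_pose(4.0)
  lig <- base$ligand
  ring <- lig$atoms[lig$atoms$aromatic, ]
  # add a second OH on the far side (C4, pointing away from the His)
  far_c <- which(lig$atoms$aromatic)[4]
  dirv <- c(lig$atoms$x[far_c], lig$atoms$y[far_c], lig$atoms$z[far_c])
  dirv <- dirv / sqrt(sum(dirv^2))
  o2 <- c(lig$atoms$x[far_c], lig$atoms$y[far_c], lig$atoms$z[far_c]) +
    1.36 * dirv
  h2 <- o2 + 0.96 * dirv
  atoms <- rbind(lig$atoms,
                 tibble::tibble(element = c("O", "H"),
                                x = c(o2[1], h2[1]), y = c(o2[2], h2[2]),
                                z = c(o2[3], h2[3]),
                                radius = c(1.52, 1.20),
                                aromatic = FALSE,
                                name = c("O98", "H99"), charge = NA_real_))
  bonds <- rbind(lig$bonds,
                 tibble::tibble(i = c(far_c, nrow(atoms) - 1),
                                j = c(nrow(atoms) - 1, nrow(atoms)),
                                order = 1L))
  cx2 <- pose_complex(base$protein, molecule(atoms, bonds),
                      roles = base$roles)
  d2 <- select_donor_atom(cx2)
  dd <- donor_distance(cx2, d2)
  expect_equal(d2$donor_class, "phenolic_OH")
  expect_equal(dd$distance, 4.0, tolerance = 0.02)  # the near O, not the far one
})

test_that("amines and donor-less ligands fall back as documented", {
  base <- gen_synthetic_pose(4.2)
  # aniline-like: swap hydroxyl O for N and give it two hydrogens
  lig <- base$ligand
  o_idx <- which(lig$atoms$element == "O")[1]
  atoms <- lig$atoms
  atoms$element[o_idx] <- "N"
  h2 <- c(atoms$x[o_idx], atoms$y[o_idx] + 0.5, atoms$z[o_idx] + 0.83)
  atoms <- rbind(atoms, tibble::tibble(
    element = "H", x = h2[1], y = h2[2], z = h2[3], radius = 1.2,
    aromatic = FALSE, name = "H98", charge = NA_real_))
  bonds <- rbind(lig$bonds, tibble::tibble(i = o_idx, j = nrow(atoms),
                                           order = 1L))
  amine_cx <- pose_complex(base$protein, molecule(atoms, bonds),
                           roles = base$roles)
  expect_equal(select_donor_atom(amine_cx)$donor_class, "amine_NH2")
  # ketone-like: no OH, no NH2 -> nearest heavy atom
  k_atoms <- lig$atoms[lig$atoms$element != "H", ]
  k_bonds <- lig$bonds[lig$bonds$i <= nrow(k_atoms) &
                         lig$bonds$j <= nrow(k_atoms), ]
  ket_cx <- pose_complex(base$protein, molecule(k_atoms, k_bonds),
                         roles = base$roles)
  dk <- select_donor_atom(ket_cx)
  expect_equal(dk$donor_class, "nearest_heavy")
  expect_equal(dk$element, "O")  # the bare O is nearest to the His
})

test_that("donor distance uses the N-epsilon hydrogen and falls back to NE2", {
  cx <- gen_synthetic_pose(4.20)
  dd <- donor_distance(cx)
  expect_equal(dd$distance, 4.20, tolerance = 0.01)
  expect_equal(dd$reference_atom, "NE2-H")
  # strip hydrogens from the His: distance now referenced to NE2
  noH <- cx
  noH$protein <- noH$protein[noH$protein$element != "H", ]
  dd2 <- donor_distance(noH)
  expect_equal(dd2$reference_atom, "NE2")
  expect_equal(dd2$distance, 4.20 + 1.01, tolerance = 0.02)  # N-H geometry
})

test_that("active-pose classification is strict and monotone", {
  expect_true(classify_active_pose(4.2)$is_active)
  expect_false(classify_active_pose(6.0)$is_active)
  expect_false(classify_active_pose(5.0)$is_active)  # boundary: inactive
  expect_error(classify_active_pose(0), "positive")
  # monotone in distance
  d <- sort(runif(50, 0.1, 10))
  act <- classify_active_pose(d)$is_active
  expect_true(all(diff(as.integer(act)) <= 0))
})

test_that("hydrogen-bond detector applies distance and angle rules", {
  hb_case <- function(dist, ang) {
    cx <- gen_synthetic_pose(4.2, hbond_geometry = list(distance = dist,
                                                        angle = ang))
    hb <- detect_hbonds(cx)
    any(hb$resid == 206)
  }
  expect_true(hb_case(2.8, 180))
  expect_false(hb_case(4.0, 180))   # distance fail
  expect_false(hb_case(3.3, 100))   # angle fail
  expect_true(hb_case(3.3, 130))
})

test_that("salt-bridge detector requires a charged amine near a carboxylate", {
  mk <- function(n_h, noff) {
    # ammonium-like N (with n_h hydrogens) noff A from an Asp carboxylate O
    prot <- tibble::tibble(
      chain = "A", resid = c(206L, 206L, 206L, 458L, 458L, 458L),
      resname = c("ASP", "ASP", "ASP", "HIS", "HIS", "HIS"),
      atom = c("OD1", "OD2", "CG", "NE2", "CE1", "CD2"),
      element = c("O", "O", "C", "N", "C", "C"),
      x = c(0, -1.0, -0.6, 20, 21, 21.5), y = c(0, 1.0, 1.2, 0, 0.5, -0.5),
      z = 0, occupancy = 1)
    n_at <- 1 + n_h
    atoms <- tibble::tibble(
      element = c("N", rep("H", n_h)),
      x = c(noff, noff + 0.5 * seq_len(n_h)),
      y = c(0, rep(0.8, n_h)), z = 0)
    bonds <- if (n_h > 0) tibble::tibble(i = 1, j = 1 + seq_len(n_h),
                                         order = 1L) else NULL
    pose_complex(prot, molecule(atoms, bonds),
                 roles = list(gate_asp = "A/206", catalytic_his = "A/458"))
  }
  sb <- detect_salt_bridges(mk(3, 3.2))
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 3.2, tolerance = 1e-6)
  expect_equal(nrow(detect_salt_bridges(mk(3, 5.5))), 0)  # too far
  expect_equal(nrow(detect_salt_bridges(mk(1, 3.2))), 0)  # neutral amine
})

test_that("pi-pi detector classifies face and edge stacking", {
  face <- detect_pipi(gen_synthetic_pose(
    4.2, stack_geometry = list(distance = 3.8, angle = 0)))
  expect_equal(face$geometry[1], "face")
  edge <- detect_pipi(gen_synthetic_pose(
    4.2, stack_geometry = list(distance = 5.0, angle = 90)))
  expect_equal(edge$geometry[1], "edge")
  none <- detect_pipi(gen_synthetic_pose(
    4.2, stack_geometry = list(distance = 7.0, angle = 0)))
  expect_equal(nrow(none), 0)
  tilted <- detect_pipi(gen_synthetic_pose(
    4.2, stack_geometry = list(distance = 4.0, angle = 45)))
  expect_equal(nrow(tilted), 0)  # 30-60 degree window is not a contact
})

test_that("fingerprints assemble the detectors and the active call", {
  cx <- gen_synthetic_pose(4.2, hbond_geometry = list(distance = 2.8,
                                                      angle = 170))
  fp <- build_fingerprint(cx)
  expect_true(any(fp$contact == "hbond" & fp$resid == 206))
  call <- attr(fp, "active_call")
  expect_true(call$is_active)
  expect_equal(call$distance_to_his, 4.2, tolerance = 0.01)
  # ligand translated 30 A away from the protein: empty fingerprint, inactive
  far <- cx
  far$ligand <- transform_molecule(far$ligand,
                                   list(R = diag(3), t = c(0, -30, 0)))
  fp_far <- build_fingerprint(far)
  expect_equal(nrow(fp_far[fp_far$resid == 206, ]), 0)
  expect_false(attr(fp_far, "active_call")$is_active)
  # an ether-type O close to the N-epsilon H is reported at the catalytic His
  gua <- gen_synthetic_pose(2.4)
  fp_g <- build_fingerprint(gua)
  expect_true(any(fp_g$resid == 458 & fp_g$contact == "hbond"))
})

test_that("all pose measurements are invariant under rigid transforms", {
  set.seed(31)
  cx <- gen_synthetic_pose(4.2, hbond_geometry = list(distance = 2.8,
                                                      angle = 165),
                           stack_geometry = list(distance = 3.8, angle = 5))
  fp0 <- build_fingerprint(cx)
  d0 <- donor_distance(cx)$distance
  for (k in 1:25) {
    tr <- random_rigid_transform()
    cxt <- transform_complex(cx, tr)
    expect_equal(donor_distance(cxt)$distance, d0, tolerance = 1e-9)
    fpt <- build_fingerprint(cxt)
    expect_equal(fpt$contact, fp0$contact)
    expect_equal(fpt$distance, fp0$distance, tolerance = 1e-9)
    expect_equal(fpt$angle, fp0$angle, tolerance = 1e-6)
  }
})

test_that("fingerprints are deterministic for identical input files", {
  cx <- gen_synthetic_pose(3.3, hbond_geometry = list(distance = 3.0,
                                                      angle = 150))
  f <- withr::local_tempfile(fileext = ".pdb")
  lf <- withr::local_tempfile(fileext = ".sdf")
  write_pose_pdb(cx, f)
  write_sdf(cx$ligand, lf)
  roles <- list(gate_asp = "A/206", catalytic_his = "A/458", t1_cu = "A/CU")
  fp1 <- build_fingerprint(load_complex(f, lf, roles))
  fp2 <- build_fingerprint(load_complex(f, lf, roles))
  expect_identical(fp1, fp2)
  expect_gt(nrow(fp1), 0)
})
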