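test_that("depth classification partitions the axis into four regions", {
  expect_identical(as.character(classify_depth(0.5)), "tail")
  expect_identical(as.character(classify_depth(1.5)), "ester")
  expect_identical(as.character(classify_depth(3.0)), "water")
  ## boundaries are half-open; sign is ignored
  expect_identical(as.character(classify_depth(c(1.0, 1.8, 2.8, -0.5))),
                   c("ester", "head", "water", "tail"))
  z <- seq(0, 5, by = 0.01)
  expect_false(anyNA(classify_depth(z)))
  expect_error(bilayer_regions(2, 1.8, 2.8), "boundaries")
})

test_that("density profiles integrate to the selected mass", {
  set.seed(19)
  box <- c(4, 4, 6)
  n <- 400
  pos <- cbind(runif(n, 0, 4), runif(n, 0, 4), runif(n, 0, 6))
  masses <- runif(n, 10, 100)
  prof <- partial_density_profile(list(pos), box, masses,
                                  groups = list(all = seq_len(n)),
                                  n_bins = 40)
  total <- sum(prof$density[, "all"]) * prof$bin_width * box[1] * box[2]
  expect_equal(total, sum(masses), tolerance = 1e-6)
  ## a uniform slab is flat at M / V within binning noise
  expect_lt(stats::sd(prof$density[, "all"]) /
              mean(prof$density[, "all"]), 0.5)
  expect_equal(mean(prof$density[, "all"]),
               sum(masses) / prod(box), tolerance = 1e-6)
})

test_that("empty selections warn and give zero profiles", {
  pos <- matrix(runif(30, 0, 4), ncol = 3)
  expect_warning(
    prof <- partial_density_profile(list(pos), c(4, 4, 4), rep(10, 10),
                                    groups = list(none = integer(),
                                                  all = 1:10)),
    "empty")
  expect_identical(max(prof$density[, "none"]), 0)
})

test_that("head-group densities peak in the expected order", {
  ## built slab: choline outermost, then phosphate, glycerol innermost
  slab <- build_bilayer_slab(32, c(3.5, 3.5, 7))
  topo <- slab$topology
  m <- topo$sites$mass
  groups <- list(ch = which(topo$sites$site_type == "ch"),
                 ph = which(topo$sites$site_type == "ph"),
                 gl = which(topo$sites$site_type == "gl"))
  prof <- partial_density_profile(list(slab$state$positions),
                                  slab$state$box, m, groups,
                                  n_bins = 120)
  peak <- vapply(colnames(prof$density), function(g)
    mean(abs(prof$z[which(prof$density[, g] == max(prof$density[, g]))])),
    numeric(1))
  expect_gt(peak["ch"], peak["ph"])
  expect_gt(peak["ph"], peak["gl"])
})

test_that("ester thickness reads 29 A on the constructed geometry", {
  slab <- build_bilayer_slab(16, c(2.6, 2.6, 7))
  topo <- slab$topology
  est <- which(topo$sites$site_type %in% c("e1", "e2"))
  et <- ester_thickness(slab$state$positions, est, topo$sites$mass)
  expect_equal(et$thickness, 29, tolerance = 1e-6)
  ## symmetric slab: ester midplane at the bilayer center
  expect_equal(et$center_z, 0, tolerance = 1e-9)
  ## rigid translation leaves the thickness unchanged
  shifted <- sweep(slab$state$positions, 2, c(0.3, -0.2, 1.1), "+")
  et2 <- ester_thickness(shifted, est, topo$sites$mass)
  expect_equal(et2$thickness, et$thickness, tolerance = 1e-9)
  ## one-leaflet input is rejected
  upper <- slab$state$positions[, 3] > mean(slab$state$positions[, 3])
  est_up <- intersect(est, which(upper))
  expect_error(ester_thickness(slab$state$positions, est_up,
                               topo$sites$mass, com_idx = est_up),
               "leaflet")
})

test_that("PMF anchors interpolate linearly between bins", {
  flat <- pmf_profile(seq(0, 3.7, length.out = 100), rep(0, 100))
  a <- anchor_pmf(flat)
  expect_identical(names(a), format(c(0, 1.3, 1.7)))
  expect_equal(unname(a), c(0, 0, 0))
  two <- pmf_profile(c(1.2, 1.4), c(2, 4))
  expect_equal(unname(anchor_pmf(two, 1.3)), 3)
  expect_error(anchor_pmf(two, 2.0), "outside")
})

test_that("regression matches the closed-form least squares", {
  ## y = x exactly
  x <- c(A = -7.6, G = 0, L = -20.6, S = 21.2, W = 9.8)
  r <- regress_scale(x, x)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  ## 5-point fixture against hand-computed OLS
  xe <- c(ALA = -7.6, GLY = 0, LEU = -20.6, SER = 21.2, TRP = 9.8)
  ye <- c(ALA = -5.1, GLY = 1.2, LEU = -17.9, SER = 16.4, TRP = 11.0)
  fit <- regress_scale(ye, xe)
  mx <- mean(xe); my <- mean(ye)
  beta <- sum((xe - mx) * (ye - my)) / sum((xe - mx)^2)
  expect_equal(fit$slope, beta, tolerance = 1e-12)
  expect_equal(fit$intercept, my - beta * mx, tolerance = 1e-12)
  expect_equal(fit$pearson_r,
               sum((xe - mx) * (ye - my)) /
                 sqrt(sum((xe - mx)^2) * sum((ye - my)^2)),
               tolerance = 1e-12)
  expect_identical(fit$n, 5L)
})

test_that("shifting the PMF values only moves the intercept", {
  xe <- c(ALA = -7.6, GLY = 0, LEU = -20.6, SER = 21.2, TRP = 9.8)
  ye <- c(ALA = -5.1, GLY = 1.2, LEU = -17.9, SER = 16.4, TRP = 11.0)
  f1 <- regress_scale(ye, xe)
  f2 <- regress_scale(ye + 5, xe)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$pearson_r, f1$pearson_r, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept + 5, tolerance = 1e-12)
})

test_that("exclusions are applied and small sets rejected", {
  xe <- c(ALA = 1, GLY = 2, LEU = 3, SER = 4, LYS = 50)
  ye <- c(ALA = 1.1, GLY = 2.2, LEU = 2.9, SER = 4.4, LYS = -3)
  fit <- regress_scale(ye, xe, exclusions = "LYS")
  expect_identical(fit$n, 4L)
  expect_identical(fit$excluded, "LYS")
  expect_error(regress_scale(ye[1:3], xe[1:3], exclusions = "ALA"),
               "at least 3")
})

test_that("exclusion presets encode the published outlier sets", {
  expect_setequal(exclusion_preset("cyclohexane", "cgprot"),
                  c("ASP", "GLU", "LYS"))
  expect_setequal(exclusion_preset("octanol", "cgprot"),
                  c("ASP", "GLU", "LYS"))
  expect_setequal(exclusion_preset("octanol", "atomistic"),
                  c("ARG", "LYS"))
  expect_setequal(exclusion_preset("ww_octanol_cor", "atomistic"),
                  c("ARG", "LYS"))
  expect_identical(exclusion_preset("ww_octanol_cor", "cgprot"),
                   character())
  expect_setequal(exclusion_preset("ww_popc_interface", "cgprot"),
                  c("HIS", "ARG", "GLN"))
  expect_setequal(exclusion_preset("ww_popc_interface", "atomistic"),
                  c("ARG", "LYS"))
})

test_that("experimental scales load glycine-referenced with POPC offset", {
  scales <- load_experimental_scales()
  expect_setequal(names(scales),
                  c("cyclohexane", "octanol", "ww_octanol_cor", "ww_gxg",
                    "ww_popc_interface"))
  for (s in scales) expect_equal(unname(s$values["GLY"]), 0)
  ## methane, the alanine analog: -7.6 kJ/mol into cyclohexane
  expect_equal(unname(scales$cyclohexane$values["ALA"]), -7.6,
               tolerance = 0.01)
  ## proline has no analog measurement: absent, not zero
  expect_true(is.na(scales$cyclohexane$values["PRO"]))
  expect_identical(scales$cyclohexane$anchor_depth, 0)
  expect_identical(scales$octanol$anchor_depth, 1.3)
  expect_identical(scales$ww_popc_interface$anchor_depth, 1.7)
})

test_that("helix tilt follows the analytic angle and its symmetries", {
  frame <- rbind(c(0, 0, 0), c(1, 0, 1))
  expect_equal(helix_tilt(list(frame), 1, 2)$mean, 45)
  vert <- rbind(c(0, 0, 0), c(0, 0, 2))
  expect_equal(helix_tilt(list(vert), 1, 2)$mean, 0)
  flat <- rbind(c(0, 0, 0), c(1, 1, 0))
  expect_equal(helix_tilt(list(flat), 1, 2)$mean, 90)
  ## swapping ends and rotating about z leave the tilt unchanged
  expect_equal(helix_tilt(list(frame), 2, 1)$mean, 45)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(helix_tilt(list(frame %*% t(R)), 1, 2)$mean, 45)
  expect_error(helix_tilt(list(rbind(c(1, 1, 1), c(1, 1, 1))), 1, 2),
               "coincident")
  expect_error(helix_tilt(list(frame), 2, 2), "distinct")
})

test_that("insertion metrics report means and spreads in Angstrom", {
  topo <- build_peptide_topology("AAAA", group = "PEP")
  bil <- cg_topology(data.frame(name = "X", site_type = "s1", mass = 100,
                                residue_index = 1:2,
                                residue_name = "DOPC", group = "BIL"))
  sys <- merge_topologies(topo, bil)
  pep_idx <- 1:4
  bil_idx <- 5:6
  mk <- function(depth_nm) {
    rbind(cbind(c(0, 0.38, 0.76, 1.14), 0, depth_nm),   # flat at depth
          cbind(c(0, 1), 0, 0))
  }
  ## static single frame: all spreads are zero
  one <- insertion_metrics(list(mk(1.2)), sys, c(1, 4), pep_idx, bil_idx)
  expect_equal(unname(one$z_center), c(12, 0))
  ## two frames with known depths 12 and 14 A -> 13 +/- 1
  two <- insertion_metrics(list(mk(1.2), mk(1.4)), sys, c(1, 4),
                           pep_idx, bil_idx)
  expect_equal(unname(two$z_center), c(13, 1))
  expect_equal(unname(two$z_nterm), c(13, 1))
})

test_that("transmembrane termini sit on opposite leaflets", {
  walp <- build_peptide_topology(peptide_sequence("WALP23"), group = "PEP")
  bil <- cg_topology(data.frame(name = "X", site_type = "s1", mass = 100,
                                residue_index = 1:2,
                                residue_name = "DOPC", group = "BIL"))
  sys <- merge_topologies(walp, bil)
  n_pep <- n_sites(walp)
  ca_coords <- build_ideal_helix(23)
  ca_coords[, 3] <- ca_coords[, 3] - mean(ca_coords[, 3])  # span the center
  pep <- place_peptide_coords(walp, ca_coords)
  frame <- rbind(pep, cbind(c(0, 1), 0, 0))
  met <- insertion_metrics(list(frame), sys, "WALP23",
                           seq_len(n_pep), n_pep + 1:2)
  expect_lt(met$z_nterm[1] * met$z_cterm[1], 0)
  expect_lte(met$tilt_mean, 90)
})
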