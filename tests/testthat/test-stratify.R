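test_that("MCC estimators recover constant and designed cerebellar means", {
  atlas <- small_atlas()
  g <- voxel_grid(array(5.0, dim = atlas$shape),
                  voxel_size_mm = atlas$voxel_size_mm)
  expect_equal(estimate_mcc(g, atlas, "mask3d")$value, 5.0)
  expect_equal(estimate_mcc(g, atlas, "slice2d")$value, 5.0)

  ph <- generate_phantom(atlas, noiseless_spec())
  expect_equal(estimate_mcc(ph, atlas, "mask3d")$value, 1.0)
})

test_that("slice2d MCC equals the direct mean of the densest axial slice", {
  atlas <- small_atlas()
  ph <- generate_phantom(atlas, noiseless_spec())
  # impose an axial gradient so the two estimators disagree
  vals <- ph$values
  for (z in seq_len(dim(vals)[3])) vals[, , z] <- vals[, , z] + 0.01 * z
  g <- voxel_grid(vals, voxel_size_mm = atlas$voxel_size_mm,
                  affine = atlas$affine)
  cmask <- atlas$labels == atlas$label_table[["cerebellum"]]
  z_best <- which.max(apply(cmask, 3, sum))
  manual <- mean(g$values[, , z_best][cmask[, , z_best]])
  est <- estimate_mcc(g, atlas, "slice2d")
  expect_equal(est$value, manual)
  expect_equal(est$n_voxels, sum(cmask[, , z_best]))
  expect_false(isTRUE(all.equal(est$value,
                                estimate_mcc(g, atlas, "mask3d")$value)))
})

test_that("suprathreshold maps use strict inequality and nest across multipliers", {
  atlas <- small_atlas()
  vals <- array(1.0, dim = atlas$shape)
  g <- voxel_grid(vals, voxel_size_mm = atlas$voxel_size_mm)
  mcc <- estimate_mcc(g, atlas)
  # a voxel exactly at 1.65 x MCC is NOT suprathreshold
  vals2 <- vals; vals2[1, 1, 1] <- 1.65 * mcc$value
  g2 <- voxel_grid(vals2, voxel_size_mm = atlas$voxel_size_mm)
  expect_false(any(suprathreshold_map(g2, mcc, 1.65)))
  vals2[1, 1, 1] <- 1.65 * mcc$value + 1e-9
  g3 <- voxel_grid(vals2, voxel_size_mm = atlas$voxel_size_mm)
  expect_equal(sum(suprathreshold_map(g3, mcc, 1.65)), 1L)
  # nesting: anything above 2.80x is above 1.65x
  set.seed(2)
  gr <- voxel_grid(array(runif(prod(atlas$shape), 0, 4), dim = atlas$shape),
                   voxel_size_mm = atlas$voxel_size_mm)
  m280 <- suprathreshold_map(gr, mcc, 2.80)
  m165 <- suprathreshold_map(gr, mcc, 1.65)
  expect_true(all(m165[m280]))
})

test_that("regional scoring honors the minimum cluster size", {
  atlas <- small_atlas()
  tab <- atlas$label_table
  map <- array(FALSE, dim = atlas$shape)
  vox <- which(atlas$labels == tab[["frontal_L"]], arr.ind = TRUE)[1, ]
  map[vox[1], vox[2], vox[3]] <- TRUE
  s1 <- score_regions(map, atlas, "frontal_L", min_cluster_voxels = 1L)
  expect_true(s1$scores[["frontal_L"]])
  expect_equal(s1$max_cluster_voxels[["frontal_L"]], 1L)
  s5 <- score_regions(map, atlas, "frontal_L", min_cluster_voxels = 5L)
  expect_false(s5$scores[["frontal_L"]])
  expect_error(score_regions(map, atlas, "thalamus"), "unknown region")
})

test_that("component labeling and scoring match the flood-fill oracle on 8^3 grids", {
  atlas8 <- region_atlas(
    {
      labs <- array(0L, dim = c(8, 8, 8))
      labs[1:2, 1:2, 1:2] <- 1L          # cerebellum
      labs[5:8, 1:8, 1:8] <- 3L          # one big "frontal_L" block
      labs
    },
    label_table = c(background = 0L, cerebellum = 1L, frontal_L = 3L))
  set.seed(31)
  for (i in 1:25) {
    mask <- array(runif(512) < runif(1, 0.1, 0.5), dim = c(8, 8, 8))
    expect_same_partition(tauvisread:::label_components_26(mask),
                          flood_fill_label(mask), mask)
    for (k in c(1L, 3L, 5L)) {
      got <- score_regions(mask, atlas8, "frontal_L",
                           min_cluster_voxels = k)$scores[["frontal_L"]]
      expect_identical(got,
                       oracle_region_positive(mask, atlas8, "frontal_L", k))
    }
  }
})

test_that("scattered sub-threshold-size voxels do not score a region positive", {
  atlas <- small_atlas()
  tab <- atlas$label_table
  vox <- which(atlas$labels == tab[["parietal_L"]], arr.ind = TRUE)
  map <- array(FALSE, dim = atlas$shape)
  # 4 voxels spaced 2 apart along x: in-region, pairwise non-adjacent
  corner <- vox[which.min(vox[, 1]), ]
  picks <- cbind(corner[1] + c(0L, 2L, 4L, 6L), corner[2], corner[3])
  stopifnot(all(atlas$labels[picks] == tab[["parietal_L"]]))
  for (i in 1:4) map[picks[i, 1], picks[i, 2], picks[i, 3]] <- TRUE
  s <- score_regions(map, atlas, "parietal_L", min_cluster_voxels = 5L)
  expect_false(s$scores[["parietal_L"]])
  expect_equal(s$max_cluster_voxels[["parietal_L"]], 1L)
})

test_that("the default decision table is total and classifies canonical patterns", {
  tab <- default_decision_table()
  sides <- cortical_region_sides()
  mk <- function(pos) {
    s <- stats::setNames(rep(FALSE, 12L), sides)
    s[pos] <- TRUE
    structure(list(scores = s), class = "regional_score_set")
  }
  expect_equal(classify_tier(mk(character(0)), tab), "tau_ad_negative")
  expect_equal(classify_tier(mk("lateral_posterior_temporal_L"), tab),
               "tau_ad_plus")
  expect_equal(classify_tier(mk(c("lateral_posterior_temporal_L",
                                  "parietal_R")), tab),
               "tau_ad_plusplus")
  # frontal or anterior temporal alone is not an AD posterior pattern
  expect_equal(classify_tier(mk("frontal_L"), tab), "tau_ad_negative")
  expect_equal(classify_tier(mk("lateral_anterior_temporal_R"), tab),
               "tau_ad_negative")
  # a non-total table is rejected at construction
  expect_error(decision_table(list(
    list(condition = function(s) any(s), tier = "tau_ad_plus"))),
    "not total")
})

test_that("two-step stratification matches phantom ground truth by construction", {
  atlas <- small_atlas()
  posterior <- list(lateral_posterior_temporal_L = 2.0,
                    lateral_posterior_temporal_R = 2.0,
                    parietal_L = 2.0, parietal_R = 2.0)
  high <- stratify_scan(generate_phantom(atlas, noiseless_spec(
    c(posterior, frontal_L = 3.0))), atlas)
  expect_equal(high$tier, "tau_ad_plusplus")
  expect_true(high$high_tau)
  expect_true(high$step2$scores[["frontal_L"]])

  mid <- stratify_scan(generate_phantom(atlas, noiseless_spec(
    c(posterior, frontal_L = 2.0, frontal_R = 2.0))), atlas)
  expect_equal(mid$tier, "tau_ad_plusplus")
  expect_false(mid$high_tau)

  flat <- stratify_scan(generate_phantom(atlas, noiseless_spec()), atlas)
  expect_equal(flat$tier, "tau_ad_negative")
  expect_false(flat$high_tau)
  expect_null(flat$step2)
})

test_that("stratification is invariant under global intensity scaling", {
  atlas <- small_atlas()
  ph <- generate_phantom(atlas, phantom_spec(
    list(frontal_L = 3.1, parietal_L = 2.2,
         lateral_posterior_temporal_R = 2.4),
    noise_sd = 0.05, smoothing_fwhm_mm = 4, seed = 8L))
  r1 <- stratify_scan(ph, atlas)
  for (c_scale in c(0.25, 7.3)) {
    g2 <- voxel_grid(c_scale * ph$values,
                     voxel_size_mm = atlas$voxel_size_mm,
                     affine = atlas$affine)
    r2 <- stratify_scan(g2, atlas)
    expect_identical(r2$tier, r1$tier)
    expect_identical(r2$high_tau, r1$high_tau)
    expect_identical(r2$step1$scores, r1$step1$scores)
    expect_equal(r2$mcc$value, c_scale * r1$mcc$value)
  }
})

test_that("step-2 positives nest inside step-1 positives under shared region definitions", {
  atlas <- small_atlas()
  cfg <- stratify_config(step2_scheme = "step1")
  ph <- generate_phantom(atlas, phantom_spec(
    list(frontal_L = 3.0, frontal_R = 2.2, parietal_L = 2.9,
         occipital_R = 3.2, lateral_posterior_temporal_L = 1.9),
    noise_sd = 0.05, smoothing_fwhm_mm = 0, seed = 17L))
  r <- stratify_scan(ph, atlas, cfg)
  expect_false(is.null(r$step2))
  pos2 <- names(r$step2$scores)[r$step2$scores]
  expect_true(all(r$step1$scores[pos2]))
})

test_that("raising frontal intensities never turns high_tau off", {
  atlas <- small_atlas()
  base <- generate_phantom(atlas, noiseless_spec(
    list(lateral_posterior_temporal_L = 2.0, parietal_L = 2.0,
         frontal_L = 2.5)))
  fr_mask <- atlas$labels %in%
    atlas$label_table[c("frontal_L", "frontal_R")]
  prev <- FALSE
  for (bump in c(0, 0.2, 0.5, 1.0, 2.0)) {
    v <- base$values
    v[fr_mask] <- v[fr_mask] + bump
    r <- stratify_scan(voxel_grid(v, voxel_size_mm = atlas$voxel_size_mm,
                                  affine = atlas$affine), atlas)
    expect_true(r$high_tau >= prev)  # monotone in the bump
    prev <- r$high_tau
  }
  expect_true(prev)  # eventually high tau
})

test_that("literal extent-free mode scores any single suprathreshold voxel", {
  atlas <- small_atlas()
  ph <- generate_phantom(atlas, noiseless_spec())
  vals <- ph$values
  vox <- which(atlas$labels == atlas$label_table[["occipital_L"]],
               arr.ind = TRUE)[1, ]
  vals[vox[1], vox[2], vox[3]] <- 3.0
  g <- voxel_grid(vals, voxel_size_mm = atlas$voxel_size_mm,
                  affine = atlas$affine)
  literal <- stratify_scan(g, atlas, stratify_config(min_cluster_voxels = 1L))
  expect_equal(literal$tier, "tau_ad_plus")
  robust <- stratify_scan(g, atlas, stratify_config(min_cluster_voxels = 5L))
  expect_equal(robust$tier, "tau_ad_negative")
})
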