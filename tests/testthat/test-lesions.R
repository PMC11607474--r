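test_that("candidate detection finds each disjoint focus and respects the threshold", {
  ph <- make_sphere_phantom(rbind(c(25, 25, 25), c(60, 60, 60)),
                            radii_mm = c(8, 6), peaks = c(8, 6),
                            spacing = c(2, 2, 2))
  comps <- detect_candidates(ph$volume, seed_threshold_suv = 2.5)
  expect_length(comps, 2L)
  # ordered by descending component SUVmax
  expect_equal(max(ph$volume$data[comps[[1]]]), 8)
  # uniform background only: nothing above threshold
  bg <- pet_volume(array(0.5, dim = c(20, 20, 20)), c(2, 2, 2))
  expect_length(detect_candidates(bg, 2.5), 0L)
  # raising the seed threshold never increases the component count
  n_at <- function(thr) length(detect_candidates(ph$volume, thr,
                                                 min_voxels = 1L))
  thrs <- c(1, 2.5, 5, 6.5, 9)
  expect_true(all(diff(sapply(thrs, n_at)) <= 0))
})

test_that("connectivity semantics distinguish touching components", {
  # two 1-voxel foci touching corner-to-corner: one component under 26,
  # two under 6
  arr <- array(0, dim = c(6, 6, 6))
  arr[2, 2, 2] <- 8; arr[3, 3, 3] <- 8
  vol <- pet_volume(arr, c(1, 1, 1))
  expect_length(detect_candidates(vol, 2.5, connectivity = 26, min_voxels = 1), 1L)
  expect_length(detect_candidates(vol, 2.5, connectivity = 6, min_voxels = 1), 2L)
  # face-to-face touching blocks merge under any connectivity
  arr2 <- array(0, dim = c(8, 6, 6))
  arr2[2:3, 2:3, 2:3] <- 8; arr2[4:5, 2:3, 2:3] <- 6
  vol2 <- pet_volume(arr2, c(1, 1, 1))
  expect_length(detect_candidates(vol2, 2.5, connectivity = 6, min_voxels = 1), 1L)
})

test_that("41% isocontour retains a uniform sphere and rasterizes within 5%", {
  ph <- make_sphere_phantom(c(25, 25, 25), 10, 8, spacing = c(1, 1, 1))
  comp <- detect_candidates(ph$volume, 2.5, min_voxels = 1)[[1]]
  les <- segment_41pct(comp, ph$volume)
  expect_equal(les$suv_max, 8)
  expect_equal(les$suv_mean, 8)  # uniform interior
  expect_equal(les$volume_cm3 * 1000, 4188.79, tolerance = 0.05)
  expect_equal(les$centroid_mm, c(25, 25, 25), tolerance = 0.05)
  # identical voxel set as the rasterized ground-truth mask
  expect_identical(les$voxels, sort(ph$ground_truth$lesions[[1]]$voxels))
})

test_that("41% threshold arithmetic on a hand-built component", {
  # voxels 8, 6, 4, 3 in a row: threshold 3.28 keeps {8, 6, 4}, mean 6
  arr <- array(0, dim = c(8, 5, 5))
  arr[2:5, 2, 2] <- c(8, 6, 4, 3)
  vol <- pet_volume(arr, c(1, 1, 1))
  comp <- detect_candidates(vol, 2.5, min_voxels = 1)[[1]]
  les <- segment_41pct(comp, vol)
  expect_equal(les$n_voxels, 3L)
  expect_equal(les$suv_mean, 6)
  # single-voxel component degenerates to that voxel
  arr1 <- array(0, dim = c(5, 5, 5)); arr1[3, 3, 3] <- 5
  vol1 <- pet_volume(arr1, c(1, 1, 1))
  les1 <- segment_41pct(detect_candidates(vol1, 2.5, min_voxels = 1)[[1]], vol1)
  expect_equal(les1$n_voxels, 1L)
})

test_that("relative threshold makes segmentation scale-invariant", {
  ph <- make_sphere_phantom(rbind(c(20, 20, 20), c(45, 45, 45)),
                            radii_mm = c(7, 5), peaks = c(8, 5),
                            spacing = c(2, 2, 2), background = 0.4)
  seg1 <- segment_lesions(ph$volume, min_voxels = 1)
  scaled <- pet_volume(ph$volume$data * 3.7, ph$volume$spacing_mm)
  seg2 <- segment_lesions(scaled, seed_threshold_suv = 2.5 * 3.7,
                          min_voxels = 1)
  expect_identical(lapply(seg1$lesions, `[[`, "voxels"),
                   lapply(seg2$lesions, `[[`, "voxels"))
})

test_that("MTV and TLG aggregate additively and order-invariantly", {
  l1 <- new_lesion(1:10, suv_max = 6, suv_mean = 5, n_voxels = 10,
                   volume_cm3 = 10, centroid_mm = c(0, 0, 0))
  l2 <- new_lesion(11:20, suv_max = 3, suv_mean = 2.5, n_voxels = 10,
                   volume_cm3 = 20, centroid_mm = c(10, 0, 0))
  ls <- lesion_set(list(l1, l2))
  expect_equal(ls$total_mtv_cm3, 30)
  expect_equal(ls$total_tlg, 10 * 5 + 20 * 2.5)  # = 100
  ls_rev <- lesion_set(list(l2, l1))
  expect_equal(ls_rev$total_mtv_cm3, ls$total_mtv_cm3)
  expect_equal(ls_rev$total_tlg, ls$total_tlg)
  # single lesion: MTV is that lesion's volume
  expect_equal(lesion_set(list(l1))$total_mtv_cm3, 10)
})

test_that("patient quantification takes maxima over lesion voxels per map", {
  ph <- make_sphere_phantom(rbind(c(20, 20, 20), c(45, 45, 45)),
                            radii_mm = c(7, 5), peaks = c(8, 5),
                            spacing = c(2, 2, 2))
  ls <- segment_lesions(ph$volume, min_voxels = 1)
  maps <- list(suv_bw = ph$volume,
               suv_lbm = pet_volume(ph$volume$data * 0.8, c(2, 2, 2)),
               suv_bsa = pet_volume(ph$volume$data * 0.25, c(2, 2, 2)))
  q <- quantify_patient(maps, ls)
  expect_equal(q$suv_max_bw, 8)
  expect_equal(q$suv_max_lbm, 8 * 0.8)
  expect_equal(q$suv_max_bsa, 8 * 0.25)
  expect_equal(q$mtv_cm3, ls$total_mtv_cm3)
  expect_equal(q$n_lesions, 2L)
  expect_error(quantify_patient(maps, lesion_set(list())), "empty")
})

test_that("spleen and marrow involvement rules follow the reference ratios", {
  expect_true(organ_involvement(2.0, spleen_suv_mean = 3.2)$spleen_involved)
  expect_false(organ_involvement(2.0, spleen_suv_mean = 2.9)$spleen_involved)
  # boundary: strictly greater than 1.5 x liver required for diffuse rule
  expect_false(organ_involvement(2.0, spleen_suv_mean = 3.0)$spleen_involved)
  expect_true(organ_involvement(2.0, spleen_suv_mean = 1.0,
                                spleen_focal = TRUE)$spleen_involved)
  expect_true(organ_involvement(2.0, marrow_focal = TRUE)$marrow_involved)
  expect_false(organ_involvement(2.0)$marrow_involved)
  expect_error(organ_involvement(NA), "liver")
})
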