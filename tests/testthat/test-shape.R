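test_that("a digital disk reproduces analytic circle geometry", {
  m <- disk_mask(256, 50)
  g <- extract_geometry(m)
  expect_equal(g$A, pi * 2500, tolerance = 0.02)
  expect_true(abs(g$H - 101) <= 1 && abs(g$W - 101) <= 1)
  expect_equal(g$D, 101, tolerance = 0.02)
  expect_equal(g$Mal, 100, tolerance = 0.02)

  f <- compute_features(g)
  expect_length(f, 15)
  expect_named(f, shape_feature_names())
  expect_equal(unname(f["Hcf"]), 1, tolerance = 0.1)
  expect_equal(unname(f["Cu"]), 1, tolerance = 0.1)
  expect_equal(unname(f["El"]), 1, tolerance = 0.1)
  expect_equal(unname(f["As"]), 1, tolerance = 0.1)
  expect_equal(unname(f["Ed"]), 100, tolerance = 0.02)
  # solidity near 1 for a convex region; Cu bounded by the circumscribed circle
  expect_gte(g$A / g$Ca, 0.95)
  expect_lte(unname(f["Cu"]), 1.05)
})

test_that("rectangles reproduce exact box geometry", {
  m <- rect_mask(140, 100, 40)
  g <- extract_geometry(m)
  expect_equal(g$A, 4000)
  expect_equal(g$H, 100L)
  expect_equal(g$W, 40L)

  sq <- rect_mask(140, 100, 100)
  fs <- compute_features(extract_geometry(sq))
  expect_equal(unname(fs["As"]), 1)
  expect_equal(unname(fs["Ra"]), 100)
  expect_equal(unname(fs["Cl"]), 16, tolerance = 0.15)

  r2 <- rect_mask(160, 100, 50)
  fr <- compute_features(extract_geometry(r2))
  expect_equal(unname(fr["As"]), 2)
  expect_equal(unname(fr["Ra"]), sqrt(5000))
})

test_that("the largest component wins and degenerate inputs error", {
  m <- rect_mask(120, 80, 50)
  m[2:3, 2:6] <- 1L                    # 10-px speck
  g <- extract_geometry(m)
  expect_equal(g$A, 4000)
  expect_error(extract_geometry(matrix(0L, 10, 10)), "no foreground")
  line <- matrix(0L, 20, 20)
  line[5, 3:17] <- 1L                  # zero minor axis
  expect_error(compute_features(extract_geometry(line)), "degenerate")
  expect_error(compute_features(structure(list(), class = "x")))
})

test_that("features scale dimensionally with resolution", {
  # the same continuous contour rasterized at 1x and 2x resolution: size
  # features double, shape features are invariant
  for (i in 1:3) {
    m1 <- generate_phantom(tiny_phantom_config(n = 5L, side = 64L,
                                               seed = 13L), i)$mask
    m2 <- generate_phantom(tiny_phantom_config(n = 5L, side = 128L,
                                               seed = 13L), i)$mask
    f1 <- extract_features(m1)
    f2 <- extract_features(m2)
    scale_feats <- c("Ar", "Co", "Ed", "D", "H", "W", "Mal", "Mil", "Ra")
    expect_equal(unname(f2[scale_feats] / f1[scale_feats]),
                 rep(2, length(scale_feats)), tolerance = 0.05)
    inv_feats <- c("El", "As", "Hcf", "Cu", "Cl")
    expect_equal(unname(f2[inv_feats] / f1[inv_feats]),
                 rep(1, length(inv_feats)), tolerance = 0.05)
  }
  # integer pixel replication doubles the perimeter-free size features
  # exactly (replication makes contours blockier, so the arc-length based
  # Hcf/Cl are excluded here)
  mask <- generate_phantom(tiny_phantom_config(n = 5L, side = 64L,
                                               seed = 13L), 1)$mask
  big <- mask[rep(seq_len(nrow(mask)), each = 2),
              rep(seq_len(ncol(mask)), each = 2)]
  f1 <- extract_features(mask)
  f2 <- extract_features(big)
  expect_equal(unname(f2[c("Ar", "Ed", "H", "W")] /
                        f1[c("Ar", "Ed", "H", "W")]),
               rep(2, 4), tolerance = 0.02)
  expect_equal(unname(f2[c("El", "As", "Cu")] / f1[c("El", "As", "Cu")]),
               rep(1, 3), tolerance = 0.05)
})

test_that("90-degree rotation swaps H/W and preserves invariant features", {
  cfg <- tiny_phantom_config(n = 2L, side = 64L, seed = 17L)
  mask <- generate_phantom(cfg, 2)$mask
  rot <- t(mask)[, rev(seq_len(nrow(mask)))]   # rotate 90 degrees
  f <- extract_features(mask)
  fr <- extract_features(rot)
  expect_equal(unname(fr["H"]), unname(f["W"]))
  expect_equal(unname(fr["W"]), unname(f["H"]))
  expect_equal(unname(fr["As"]), 1 / unname(f["As"]), tolerance = 1e-12)
  exact <- c("Ar", "Co", "P", "Ed", "Hcf", "Cl")
  expect_equal(unname(fr[exact]), unname(f[exact]), tolerance = 1e-12)
  expect_equal(unname(fr[c("Mal", "Mil", "D", "El", "Cu")]),
               unname(f[c("Mal", "Mil", "D", "El", "Cu")]), tolerance = 1e-9)
})

test_that("geometry invariants hold on generated masks", {
  cfg <- tiny_phantom_config(n = 6L, side = 96L, seed = 19L)
  for (i in 1:6) {
    g <- extract_geometry(generate_phantom(cfg, i)$mask)
    expect_lte(g$A, g$Ca)
    expect_gte(g$Mal, g$Mil)
    f <- compute_features(g)
    expect_true(all(is.finite(f)) && all(f > 0))
    expect_gte(unname(f["El"]), 1)
    expect_lte(unname(f["Cu"]), 1.05)
    expect_gte(unname(f["D"]), unname(f["Ed"]) * 0.999)
  }
})

test_that("both diameter conventions are available and ordered", {
  mask <- rect_mask(80, 30, 60)
  g1 <- extract_geometry(mask, diameter = "enclosing")
  g2 <- extract_geometry(mask, diameter = "centroid")
  # for a symmetric rectangle both equal the diagonal
  expect_equal(g1$D, g2$D, tolerance = 1e-9)
  expect_equal(g1$D, sqrt(30^2 + 60^2), tolerance = 0.05)
})

test_that("feature tables carry one named row per mask", {
  masks <- list(a = disk_mask(48, 15), b = rect_mask(48, 20, 10))
  tab <- features_table(masks)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$sample_id, c("a", "b"))
  expect_true(all(shape_feature_names() %in% names(tab)))
})
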