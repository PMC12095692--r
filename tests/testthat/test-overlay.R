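test_that("overlay of a rigidly moved copy recovers the full combo of 2", {
  tmpl <- toy_template()
  moved <- move_molecule(tmpl, random_rigid(11))
  ov <- optimize_overlay(moved, tmpl, n_starts = 8, seed = 1)
  expect_equal(ov$combo, 2, tolerance = 1e-3)
  expect_equal(ov$shape_tanimoto, 1, tolerance = 1e-3)
  expect_equal(ov$color_tanimoto, 1, tolerance = 1e-3)
})

test_that("self overlay scores combo 2 and is the top screen rank", {
  tmpl <- toy_template()
  ov <- optimize_overlay(tmpl, tmpl, n_starts = 5, seed = 1)
  expect_equal(ov$combo, 2, tolerance = 1e-6)
})

test_that("more starts never lower the returned score", {
  a <- carbon_toy(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.7, 1.2, 0.4)), "a")
  b <- carbon_toy(rbind(c(0, 0, 0), c(1.4, 0.3, 0), c(0.5, 1.0, 0.8)), "b")
  s1 <- optimize_overlay(a, b, n_starts = 1, seed = 5)$combo
  s16 <- optimize_overlay(a, b, n_starts = 16, seed = 5)$combo
  expect_gte(s16, s1 - 1e-12)
  expect_error(optimize_overlay(a, b, n_starts = 0), ">= 1")
})

test_that("the optimizer matches the exhaustive pose-grid oracle", {
  pairs <- list(
    list(q = carbon_toy(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.7, 1.2, 0)),
                        "q3"),
         r = carbon_toy(rbind(c(0, 0, 0), c(1.4, 0.4, 0), c(0.4, 1.3, 0)),
                        "r3")),
    list(q = carbon_toy(rbind(c(0, 0, 0), c(1.5, 0, 0)), "q2"),
         r = carbon_toy(rbind(c(0, 0, 0), c(1.2, 0, 0.8), c(2.2, 0.5, 1)),
                        "r2")))
  for (pr in pairs) {
    opt <- optimize_overlay(pr$q, pr$r, n_starts = 16, seed = 3)$combo
    grid <- pose_grid_oracle(pr$q, pr$r)
    expect_equal(opt, grid, tolerance = 1e-2)
    expect_gte(opt, grid - 1e-2) # grid is a lower bound up to resolution
  }
})

test_that("optimize_overlay is deterministic for a fixed seed", {
  a <- carbon_toy(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.7, 1.2, 0.4)), "a")
  b <- carbon_toy(rbind(c(0, 0, 0), c(1.4, 0.3, 0), c(0.5, 1.0, 0.8)), "b")
  o1 <- optimize_overlay(a, b, n_starts = 8, seed = 9)
  o2 <- optimize_overlay(a, b, n_starts = 8, seed = 9)
  expect_identical(o1$combo, o2$combo)
  expect_identical(o1$transform$R, o2$transform$R)
})

test_that("screening ranks the template first and the census is exact", {
  tmpl <- toy_template()
  # strictly positive noise so the template is the unique combo-2 member
  lib <- gen_molecule_library(tmpl, n = 6, noise_levels = c(0.2, 0.5),
                              n_decoys = 2, seed = 4)
  lib <- c(list(tmpl), lib)
  rep <- screen_library(tmpl, lib, thresholds = c(1.5, 1.4, 1.3),
                        n_starts = 5, seed = 2)
  expect_s3_class(rep, "lf_screen")
  expect_equal(rep$id[1], "toy_template")
  expect_equal(rep$combo[1], 2, tolerance = 1e-6)
  # ranking non-increasing in combo
  expect_true(all(diff(rep$combo) <= 1e-12))
  # census equals a brute-force recount and is non-increasing in threshold
  census <- screen_census(rep)
  expect_equal(names(census), c("1.5", "1.4", "1.3"))
  for (th in c(1.5, 1.4, 1.3)) {
    expect_equal(unname(census[as.character(th)]), sum(rep$combo > th))
  }
  expect_true(all(diff(census) >= 0)) # thresholds given in decreasing order
})

test_that("molecules failing feature assignment are reported, not dropped", {
  tmpl <- toy_template()
  bare <- molecule("no_bonds", tibble::tibble(element = "C", x = 0, y = 0,
                                              z = 0))
  expect_warning(
    rep <- screen_library(tmpl, list(tmpl, bare), n_starts = 5, seed = 1),
    "skipped")
  expect_equal(nrow(rep), 1)
  expect_match(attr(rep, "skipped"), "no_bonds")
})

test_that("pharmacophore anchors match by kind within tolerance", {
  tmpl <- toy_template()
  feats <- assign_features(tmpl)
  anchors <- dplyr::bind_rows(
    tibble::tibble(name = "benzodioxole_ring", kind = "ring",
                   x = feats$x[feats$kind == "ring"][1],
                   y = feats$y[feats$kind == "ring"][1],
                   z = feats$z[feats$kind == "ring"][1]),
    tibble::tibble(name = "carboxylate", kind = "anion",
                   x = feats$x[feats$kind == "anion"][1],
                   y = feats$y[feats$kind == "anion"][1],
                   z = feats$z[feats$kind == "anion"][1]))
  ov <- optimize_overlay(tmpl, tmpl, n_starts = 5, seed = 1)
  chk <- pharmacophore_point_check(ov, tmpl, anchors)
  expect_true(all(chk$matched)) # template vs itself matches every anchor

  # a query lacking rings cannot match a ring anchor
  chain <- carbon_toy(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)), "chain")
  ov2 <- optimize_overlay(chain, tmpl, n_starts = 5, seed = 1)
  chk2 <- pharmacophore_point_check(ov2, chain, anchors)
  expect_false(any(chk2$matched[chk2$kind == "anion"]))
  expect_false(any(chk2$matched[chk2$kind == "ring"]))

  # threshold boundary: hydrophobe 1.2 A from the anchor
  hydro_q <- carbon_toy(rbind(c(1.2, 0, 0), c(2.7, 0, 0)), "hydro")
  fq <- assign_features(hydro_q)
  anchor_h <- tibble::tibble(name = "h", kind = "hydrophobe", x = 0.75,
                             y = 0, z = 0)
  identity_ov <- structure(list(transform = rigid_transform()),
                           class = "lf_overlay")
  d <- sqrt(sum((unlist(fq[1, c("x", "y", "z")]) -
                   c(0.75, 0, 0))^2)) # 1.2 A by construction
  expect_equal(d, 1.2, tolerance = 1e-9)
  expect_true(pharmacophore_point_check(identity_ov, hydro_q, anchor_h,
                                        tolerance = 1.5)$matched)
  expect_false(pharmacophore_point_check(identity_ov, hydro_q, anchor_h,
                                         tolerance = 1.0)$matched)
})
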