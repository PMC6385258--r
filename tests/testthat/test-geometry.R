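test_that("alpha shapes close around spherical point clouds", {
  pts <- sphere_points(500, radius = 20, seed = 2)
  s <- build_surface(pts, alpha_radius = 50)
  expect_true(s$closed)
  expect_lt(abs(s$volume - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.1)
  # Euler: a closed triangulated sphere over n vertices has 2n - 4 facets
  expect_equal(nrow(s$facets), 2 * 500 - 4)
  # alpha -> infinity gives the convex hull; a tetrahedron has 4 facets
  tet <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  s2 <- build_surface(tet, alpha_radius = 1e6)
  expect_equal(nrow(s2$facets), 4)
  expect_true(s2$closed)
  flat <- cbind(runif(30), runif(30), 0)
  expect_error(build_surface(flat), "coplanar")
  expect_error(build_surface(tet[1:3, ]), "at least 4")
})

test_that("relative distances follow sphere geometry", {
  s <- build_surface(sphere_points(500, radius = 20, seed = 2),
                     alpha_radius = 50)
  ctr <- c(30, 30, 30)
  expect_equal(relative_distance(ctr, ctr, s), 0)
  expect_lt(abs(relative_distance(c(40, 30, 30), ctr, s) - 0.5), 0.02)
  expect_lt(abs(relative_distance(c(50, 30, 30), ctr, s) - 1), 0.05)
  # monotonicity: moving radially outward never decreases rho
  rhos <- vapply(seq(2, 19, by = 1), function(r)
    relative_distance(ctr + c(r * 0.6, r * 0.64, r * 0.48), ctr, s),
    numeric(1))
  expect_true(all(diff(rhos) > 0))
})

test_that("rho is invariant under joint rigid motion", {
  pts <- sphere_points(300, radius = 15, center = c(0, 0, 0), seed = 4)
  ctr <- c(0, 0, 0)
  spot <- c(6, 3, 5)
  s <- build_surface(pts, alpha_radius = 50)
  rho0 <- relative_distance(spot, ctr, s)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(40, 50, 60)
  pts_t <- sweep(pts %*% t(R), 2, shift, `+`)
  s_t <- build_surface(pts_t, alpha_radius = 50)
  rho1 <- relative_distance(as.numeric(R %*% spot) + shift,
                            as.numeric(R %*% ctr) + shift, s_t)
  expect_lt(abs(rho0 - rho1), 0.01)
})

test_that("internalized fractions match point-in-shrunk-sphere oracle", {
  s <- build_surface(sphere_points(500, radius = 20, seed = 5),
                     alpha_radius = 50)
  ctr <- c(30, 30, 30)
  set.seed(6)
  rr <- runif(300, 0, 1.1)
  dirs <- matrix(rnorm(900), ncol = 3); dirs <- dirs / sqrt(rowSums(dirs^2))
  spots <- sweep(dirs * rr * 20, 2, ctr, `+`)
  rho <- vapply(seq_len(300), function(i)
    relative_distance(spots[i, ], ctr, s), numeric(1))
  # oracle: point inside the 0.8-scaled sphere about the nucleus
  agree <- mean((rho <= 0.8) == (rr <= 0.8))
  expect_gte(agree, 0.99)
  # trivial fractions
  expect_equal(internalized_fraction(rep(1, 4), rep(0, 4))$fraction, 1)
  expect_equal(internalized_fraction(rep(1, 4), rep(1, 4))$fraction, 0)
  expect_error(internalized_fraction(numeric(0), numeric(0)), "N = 0")
  # count-weighted: one internal 3-QD endosome vs three external singles
  ir <- internalized_fraction(c(3, 1, 1, 1), c(0.4, 1, 1, 1))
  expect_equal(ir$fraction, 0.5)
})

test_that("membrane accuracy measures point-to-surface distances", {
  pts <- sphere_points(400, radius = 20, seed = 7)
  s <- build_surface(pts, alpha_radius = 50)
  ma0 <- membrane_accuracy(s, s$vertices)
  expect_lt(ma0$max, 1e-9)
  # radially offset reference: mean distance ~ offset plus a small positive
  # bias from the faceted (chordal) surface lying just inside the sphere
  ref <- sphere_points(200, radius = 21, seed = 8)
  ma1 <- membrane_accuracy(s, ref)
  expect_lt(abs(ma1$mean - 1), 0.25)
  expect_error(membrane_accuracy(s, matrix(numeric(0), 0, 3)), "empty")
})

test_that("pattern registration recovers rotations and symmetry", {
  mask <- matrix(FALSE, 60, 40); mask[10:50, 15:25] <- TRUE
  c1 <- list(mask = mask, spots = cbind(x = c(20, 40), y = c(18, 22)))
  r_id <- register_and_project(list(c1, c1))
  expect_equal(r_id$transforms$angle[2] %% (2 * pi), 0, tolerance = 1e-6)
  expect_equal(length(r_id$excluded), 0)
  # 90-degree rotated copy
  mask90 <- t(mask)[, 60:1]
  c2 <- list(mask = mask90,
             spots = cbind(x = c(18, 22), y = c(60 - 20 + 1, 60 - 40 + 1)))
  r90 <- register_and_project(list(c1, c2))
  ang <- (r90$transforms$angle[2] %% (2 * pi)) * 180 / pi
  expect_lt(min(abs(ang - c(90, 270))), 1)
  expect_equal(nrow(r90$spots), 4)
  # rotated spots land on the reference spots
  d <- as.matrix(dist(r90$spots[, 1:2]))
  expect_lt(sort(d[1, 3:4])[1], 1)
  # layouts mirrored about the pattern centroid give a symmetric 1D histogram
  cm <- list(mask = mask, spots = cbind(x = 60 - c(20, 40), y = c(18, 22)))
  rs <- register_and_project(list(c1, cm), min_overlap = 0.5)
  h <- rs$hist1d$counts
  expect_equal(h, rev(h))
  # a pattern of different geometry cannot align and is excluded
  bad_mask <- matrix(FALSE, 60, 40); bad_mask[28:36, 16:24] <- TRUE
  expect_warning(rx <- register_and_project(list(c1, list(mask = bad_mask,
                                                          spots = cbind(x = 1, y = 1)))),
                 "excluded")
  expect_equal(rx$excluded, 2L)
})

test_that("surfaces export as valid OFF meshes", {
  tet <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  s <- build_surface(tet, alpha_radius = 1e6)
  path <- tempfile(fileext = ".off")
  write_surface_off(s, path)
  lines <- readLines(path)
  expect_equal(lines[1], "OFF")
  expect_equal(strsplit(lines[2], " ")[[1]], c("4", "4", "0"))
})
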