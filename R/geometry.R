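# --- 3D Delaunay tetrahedralization (incremental Bowyer-Watson) ------------
#
# Points are inserted one at a time into a super-tetrahedron; every
# tetrahedron whose circumsphere contains the new point is removed and the
# cavity re-triangulated around the point. A deterministic sub-resolution
# jitter breaks cospherical/coplanar degeneracies (e.g. points sampled on an
# exact sphere), which is far below any biological length scale here.

tetra_circumsphere <- function(p) {
  a <- p[1, ]
  M <- 2 * (p[2:4, , drop = FALSE] - rep(a, each = 3))
  rhs <- rowSums(p[2:4, , drop = FALSE]^2) - sum(a^2)
  ctr <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(ctr)) return(list(center = a, r2 = Inf))
  list(center = as.numeric(ctr), r2 = sum((a - ctr)^2))
}

delaunay_3d <- function(pts, jitter = 1e-6, seed = 7L) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) stop_bad_arg("need at least 4 points")
  span <- max(apply(pts, 2, function(x) diff(range(x))), 1)
  pts_j <- pts + with_seed(seed,
                           matrix(stats::runif(3 * n, -1, 1), n, 3)) * jitter * span
  ctr0 <- colMeans(pts_j)
  R <- max(sqrt(rowSums(sweep(pts_j, 2, ctr0)^2))) * 20 + span
  super <- rbind(ctr0 + c(0, 0, 3 * R),
                 ctr0 + c(-2 * R, -2 * R, -R),
                 ctr0 + c(2 * R, -2 * R, -R),
                 ctr0 + c(0, 2.5 * R, -R))
  verts <- rbind(pts_j, super)
  cap <- 16 * n + 64
  tets <- matrix(0L, cap, 4)
  centers <- matrix(0, cap, 3)
  r2 <- rep(NA_real_, cap)
  alive <- logical(cap)
  n_tet <- 1L
  tets[1, ] <- as.integer(n + 1:4)
  cs <- tetra_circumsphere(verts[tets[1, ], , drop = FALSE])
  centers[1, ] <- cs$center; r2[1] <- cs$r2; alive[1] <- TRUE
  grow <- function() {
    cap2 <- 2 * cap
    tets <<- rbind(tets, matrix(0L, cap2 - cap, 4))
    centers <<- rbind(centers, matrix(0, cap2 - cap, 3))
    r2 <<- c(r2, rep(NA_real_, cap2 - cap))
    alive <<- c(alive, logical(cap2 - cap))
    cap <<- cap2
  }
  face_rows <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (ip in seq_len(n)) {
    p <- verts[ip, ]
    act <- which(alive[seq_len(n_tet)])
    dx <- centers[act, 1] - p[1]; dy <- centers[act, 2] - p[2]
    dz <- centers[act, 3] - p[3]
    bad <- act[(dx * dx + dy * dy + dz * dz) < r2[act]]
    if (!length(bad)) next # cannot happen inside the super-tetra
    faces <- matrix(0L, 4 * length(bad), 3)
    for (bi in seq_along(bad)) {
      tv <- tets[bad[bi], ]
      for (fi in 1:4)
        faces[4 * (bi - 1) + fi, ] <- sort(tv[face_rows[fi, ]])
    }
    fkey <- paste(faces[, 1], faces[, 2], faces[, 3])
    once <- !(fkey %in% fkey[duplicated(fkey)])
    alive[bad] <- FALSE
    for (fi in which(once)) {
      if (n_tet + 1L > cap) grow()
      n_tet <- n_tet + 1L
      tv <- c(faces[fi, ], ip)
      tets[n_tet, ] <- tv
      cs <- tetra_circumsphere(verts[tv, , drop = FALSE])
      centers[n_tet, ] <- cs$center; r2[n_tet] <- cs$r2
      alive[n_tet] <- TRUE
    }
  }
  keep <- which(alive[seq_len(n_tet)])
  keep <- keep[apply(tets[keep, , drop = FALSE] <= n, 1, all)]
  list(tetra = tets[keep, , drop = FALSE],
       circumradius = sqrt(r2[keep]),
       points = pts_j, points_raw = pts)
}

#' Reconstruct a closed membrane surface from a stain point cloud
#'
#' Builds the 3D alpha complex of the membrane-stain coordinates: Delaunay
#' tetrahedra with circumradius at most `alpha_radius` are retained and the
#' triangles bounding the retained solid form the membrane surface. The
#' alpha radius is interpreted in lateral-pixel units; z coordinates are
#' rescaled into the same units by `z_scale` (axial spacing over pixel
#' size) before tetrahedralization so the shape is computed in isotropic
#' space.
#'
#' @param points `n x 3` matrix of membrane-stain coordinates
#'   (`x`, `y` in pixels, `z` in planes).
#' @param alpha_radius alpha-shape radius (pixel units; default 50).
#' @param z_scale axial-to-lateral unit conversion applied to `z`
#'   (default 1, i.e. already isotropic).
#' @return a `membrane_surface`: `vertices` (isotropic coordinates),
#'   `facets` (boundary-triangle vertex indices), `tetra` (retained
#'   tetrahedra), `closed` flag, `volume` (enclosed, in cubic pixel
#'   units), `alpha_radius`, `z_scale`.
#' @export
build_surface <- function(points, alpha_radius = 50, z_scale = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop_bad_arg("need at least 4 membrane points")
  pts <- points
  pts[, 3] <- pts[, 3] * z_scale
  rk <- qr(sweep(pts, 2, colMeans(pts)))$rank
  if (rk < 3) stop_bad_arg("membrane points are coplanar; cannot build a 3D surface")
  dt <- delaunay_3d(pts)
  keep <- dt$circumradius <= alpha_radius
  if (!any(keep)) stop_bad_arg("alpha_radius smaller than every circumradius; empty shape")
  tetra <- dt$tetra[keep, , drop = FALSE]
  faces <- matrix(0L, 4 * nrow(tetra), 3)
  face_rows <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (ti in seq_len(nrow(tetra))) for (fi in 1:4)
    faces[4 * (ti - 1) + fi, ] <- sort(tetra[ti, face_rows[fi, ]])
  fkey <- paste(faces[, 1], faces[, 2], faces[, 3])
  boundary <- faces[!(fkey %in% fkey[duplicated(fkey)]), , drop = FALSE]
  edges <- rbind(boundary[, c(1, 2)], boundary[, c(1, 3)], boundary[, c(2, 3)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  closed <- all(table(ekey) == 2)
  v <- dt$points
  vol <- sum(vapply(seq_len(nrow(tetra)), function(ti) {
    m <- v[tetra[ti, 2:4], , drop = FALSE] - rep(v[tetra[ti, 1], ], each = 3)
    abs(det(m)) / 6
  }, numeric(1)))
  structure(list(vertices = v, facets = boundary, tetra = tetra,
                 closed = closed, volume = vol,
                 alpha_radius = alpha_radius, z_scale = z_scale),
            class = "membrane_surface")
}

# Ray / triangle-soup intersection (Moller-Trumbore), returning all ray
# parameters t > eps with origin `orig` and direction `dir` (unnormalized).
ray_surface_t <- function(orig, dir, surface) {
  v <- surface$vertices
  f <- surface$facets
  v0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v0
  e2 <- v[f[, 3], , drop = FALSE] - v0
  cross_rows <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                     a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                     a[, 1] * b[, 2] - a[, 2] * b[, 1])
  dmat <- matrix(dir, nrow(f), 3, byrow = TRUE)
  h <- cross_rows(dmat, e2)
  a <- rowSums(e1 * h)
  s <- matrix(orig, nrow(f), 3, byrow = TRUE) - v0
  eps <- 1e-12 * max(1, sum(dir^2))
  fi <- ifelse(abs(a) > eps, 1 / a, NA_real_)
  u <- fi * rowSums(s * h)
  q <- cross_rows(s, e1)
  vv <- fi * rowSums(dmat * q)
  t <- fi * rowSums(e2 * q)
  tol <- 1e-9
  ok <- !is.na(fi) & u >= -tol & vv >= -tol & (u + vv) <= 1 + tol & t > 1e-9
  t[ok]
}

#' Relative radial distance of a spot from the membrane
#'
#' Casts a ray from the nucleus centroid through the spot centroid and
#' intersects it with the membrane surface; the relative distance is the
#' ratio of nucleus-to-spot over nucleus-to-surface Euclidean distances.
#' Where the ray crosses the boundary several times (concave cells) the
#' outermost crossing is used, so the distance is measured against the
#' cell's outer envelope rather than against an invagination.
#'
#' @param spot spot centroid `(x, y, z)` (`z` in planes; rescaled by the
#'   surface's `z_scale`).
#' @param nucleus nucleus centroid `(x, y, z)`, strictly inside the surface.
#' @param surface a [build_surface()] result.
#' @return relative distance `rho >= 0` (0 at the nucleus, 1 on the
#'   surface), or `NA` with a warning when the ray exits an open surface
#'   without crossing it.
#' @export
relative_distance <- function(spot, nucleus, surface) {
  s <- as.numeric(spot[1:3]); nu <- as.numeric(nucleus[1:3])
  s[3] <- s[3] * surface$z_scale
  nu[3] <- nu[3] * surface$z_scale
  d <- s - nu
  if (sqrt(sum(d^2)) < 1e-12) return(0)
  t <- ray_surface_t(nu, d, surface)
  if (!length(t)) {
    warning("ray from nucleus through spot does not cross the surface; spot unresolved")
    return(NA_real_)
  }
  1 / max(t)
}

#' Internalized fraction of a cell's bound ligand
#'
#' A spot is internalized when its relative radial distance is at most
#' `threshold` (default 0.8). The internalized fraction is the calibrated
#' quantum-dot-count-weighted share of internalized spots.
#'
#' @param n_qd_spot calibrated quantum-dot count per spot.
#' @param rho relative distances per spot ([relative_distance()]).
#' @param threshold internalization cutoff on `rho` (default 0.8).
#' @param nucleus optional nucleus centroid carried into the result.
#' @return an `internalization_result`: per-spot table (`rho`,
#'   `internalized`, `n_qd_spot`), `fraction`, `N_cell`, `nucleus`.
#' @export
internalized_fraction <- function(n_qd_spot, rho, threshold = 0.8,
                                  nucleus = NULL) {
  stopifnot(length(n_qd_spot) == length(rho))
  total <- sum(n_qd_spot)
  if (total <= 0) stop_bad_arg("cell has no calibrated signal (N = 0)")
  internal <- !is.na(rho) & rho <= threshold
  f <- sum(n_qd_spot[internal]) / total
  structure(list(spots = data.frame(rho = rho, internalized = internal,
                                    n_qd_spot = n_qd_spot),
                 fraction = f, N_cell = total, threshold = threshold,
                 nucleus = nucleus),
            class = "internalization_result")
}

# Unsigned distance from one point to a triangle (Ericson's clamped
# barycentric projection), vectorized over triangles; returns the minimum.
point_surface_distance <- function(p, surface) {
  v <- surface$vertices
  f <- surface$facets
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  pm <- matrix(as.numeric(p), nrow(f), 3, byrow = TRUE)
  ap <- pm - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- pm - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- pm - c_
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- pmax(va + vb + vc, .Machine$double.eps)
  vban <- vb / denom; wan <- vc / denom
  # start from interior projection, then clamp to edges / vertices
  close <- a + vban * ab + wan * ac
  reg_a <- d1 <= 0 & d2 <= 0
  reg_b <- d3 >= 0 & d4 <= d3
  reg_c <- d6 >= 0 & d5 <= d6
  reg_ab <- !reg_a & !reg_b & vc <= 0 & d1 >= 0 & d3 <= 0
  reg_ac <- !reg_a & !reg_c & vb <= 0 & d2 >= 0 & d6 <= 0
  reg_bc <- !reg_b & !reg_c & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  t_ab <- ifelse(d1 - d3 != 0, d1 / (d1 - d3), 0)
  t_ac <- ifelse(d2 - d6 != 0, d2 / (d2 - d6), 0)
  t_bc <- ifelse((d4 - d3) + (d5 - d6) != 0,
                 (d4 - d3) / ((d4 - d3) + (d5 - d6)), 0)
  close[reg_ab, ] <- a[reg_ab, , drop = FALSE] +
    t_ab[reg_ab] * ab[reg_ab, , drop = FALSE]
  close[reg_ac, ] <- a[reg_ac, , drop = FALSE] +
    t_ac[reg_ac] * ac[reg_ac, , drop = FALSE]
  close[reg_bc, ] <- b[reg_bc, , drop = FALSE] +
    t_bc[reg_bc] * (c_[reg_bc, , drop = FALSE] - b[reg_bc, , drop = FALSE])
  close[reg_a, ] <- a[reg_a, , drop = FALSE]
  close[reg_b, ] <- b[reg_b, , drop = FALSE]
  close[reg_c, ] <- c_[reg_c, , drop = FALSE]
  min(sqrt(rowSums((pm - close)^2)))
}

#' Accuracy of a membrane surface against a reference point cloud
#'
#' Unsigned distance from every reference point (e.g. a manually segmented
#' membrane standard) to the reconstructed surface.
#'
#' @param surface a [build_surface()] result.
#' @param reference `n x 3` reference points (`z` in planes; rescaled by
#'   the surface's `z_scale`).
#' @return list with per-point `distances`, `mean`, `max`, and a
#'   3D-plottable `table` (reference coordinates plus distance).
#' @export
membrane_accuracy <- function(surface, reference) {
  reference <- as.matrix(reference)
  if (!nrow(reference)) stop_bad_arg("reference point cloud is empty")
  ref <- reference
  ref[, 3] <- ref[, 3] * surface$z_scale
  d <- vapply(seq_len(nrow(ref)), function(i)
    point_surface_distance(ref[i, ], surface), numeric(1))
  list(distances = d, mean = mean(d), max = max(d),
       table = data.frame(x = reference[, 1], y = reference[, 2],
                          z = reference[, 3], distance = d))
}

#' Export a membrane surface as an OFF mesh
#'
#' @param surface a [build_surface()] result.
#' @param path output file.
#' @export
write_surface_off <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(surface$vertices), nrow(surface$facets)), con)
  utils::write.table(format(surface$vertices, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, surface$facets - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

mask_axes <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(px)
  cv <- stats::cov(px)
  eg <- eigen(cv, symmetric = TRUE)
  list(center = ctr, axes = eg$vectors, px = px)
}

rot2 <- function(theta) matrix(c(cos(theta), sin(theta),
                                 -sin(theta), cos(theta)), 2, 2)

# Jaccard overlap between the transformed pixel set and the reference mask:
# a small pattern fully inside a larger one does not score as aligned.
mask_overlap <- function(px_t, ref_mask) {
  pi_ <- round_half_up(px_t)
  d <- dim(ref_mask)
  inb <- pi_[, 1] >= 1 & pi_[, 1] <= d[1] & pi_[, 2] >= 1 & pi_[, 2] <= d[2]
  hit <- rep(FALSE, nrow(pi_))
  hit[inb] <- ref_mask[pi_[inb, , drop = FALSE]]
  inter <- sum(hit)
  inter / (nrow(pi_) + sum(ref_mask) - inter)
}

#' Register patterned cells and project ligand localizations
#'
#' Aligns each cell's adhesion-pattern mask to the first cell's mask by a
#' rigid transform (centroid translation plus principal-axis rotation; the
#' 180-degree ambiguity is resolved by maximizing mask overlap), applies
#' the same transform to the cell's spot coordinates, and accumulates a 2D
#' z-projected heat map on the reference pattern plane and a 1D histogram
#' along the reference long axis. Cells whose aligned pattern overlaps the
#' reference by less than `min_overlap` are excluded with a warning.
#'
#' @param cells list of cells, each a list with `mask` (logical matrix)
#'   and `spots` (matrix with columns `x`, `y`, ...).
#' @param min_overlap exclusion threshold on aligned mask overlap
#'   (default 0.8).
#' @param n_bins_1d bins of the 1D projection histogram.
#' @return list: `heatmap` (counts on the reference grid), `hist1d`
#'   (`mids`, `counts`), `spots` (all aligned coordinates), `transforms`
#'   (angle, overlap per cell), `excluded` (indices).
#' @export
register_and_project <- function(cells, min_overlap = 0.8, n_bins_1d = 25) {
  stopifnot(length(cells) >= 1)
  ref <- mask_axes(cells[[1]]$mask)
  ref_dim <- dim(cells[[1]]$mask)
  heat <- matrix(0, ref_dim[1], ref_dim[2])
  all_spots <- list()
  transforms <- data.frame(cell = seq_along(cells), angle = NA_real_,
                           overlap = NA_real_)
  excluded <- integer(0)
  ref_angle <- atan2(ref$axes[2, 1], ref$axes[1, 1])
  for (ci in seq_along(cells)) {
    cur <- mask_axes(cells[[ci]]$mask)
    cur_angle <- atan2(cur$axes[2, 1], cur$axes[1, 1])
    best <- NULL
    for (flip in c(0, pi)) {
      th <- ref_angle - cur_angle + flip
      Rm <- rot2(th)
      px_t <- sweep(sweep(cur$px, 2, cur$center) %*% t(Rm), 2, ref$center, `+`)
      ov <- mask_overlap(px_t, cells[[1]]$mask)
      if (is.null(best) || ov > best$ov) best <- list(th = th, ov = ov)
    }
    transforms$angle[ci] <- best$th
    transforms$overlap[ci] <- best$ov
    if (best$ov < min_overlap) {
      warning("cell ", ci, " excluded: aligned pattern overlap ",
              signif(best$ov, 3), " < ", min_overlap)
      excluded <- c(excluded, ci)
      next
    }
    sp <- as.matrix(cells[[ci]]$spots)
    if (nrow(sp)) {
      xy <- sweep(sweep(sp[, 1:2, drop = FALSE], 2, cur$center) %*%
                    t(rot2(best$th)), 2, ref$center, `+`)
      sp_t <- cbind(xy, sp[, -(1:2), drop = FALSE])
      all_spots[[length(all_spots) + 1]] <- sp_t
      pr <- round_half_up(xy)
      inb <- pr[, 1] >= 1 & pr[, 1] <= ref_dim[1] &
        pr[, 2] >= 1 & pr[, 2] <= ref_dim[2]
      for (i in which(inb)) heat[pr[i, 1], pr[i, 2]] <- heat[pr[i, 1], pr[i, 2]] + 1
    }
  }
  spots_mat <- if (length(all_spots)) do.call(rbind, all_spots) else
    matrix(numeric(0), 0, 2)
  long_axis <- ref$axes[, 1]
  half_len <- max(abs(sweep(ref$px, 2, ref$center) %*% long_axis)) + 1
  breaks <- seq(-half_len, half_len, length.out = n_bins_1d + 1)
  proj <- if (nrow(spots_mat))
    sweep(spots_mat[, 1:2, drop = FALSE], 2, ref$center) %*% long_axis
  else numeric(0)
  counts <- if (length(proj))
    tabulate(pmin(pmax(findInterval(proj, breaks, rightmost.closed = TRUE), 1),
                  n_bins_1d), nbins = n_bins_1d)
  else integer(n_bins_1d)
  list(heatmap = heat,
       hist1d = list(mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                     counts = counts),
       spots = spots_mat, transforms = transforms, excluded = excluded)
}
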