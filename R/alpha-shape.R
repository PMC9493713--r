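#' 3D Delaunay tetrahedralization (Bowyer-Watson)
#'
#' Incremental insertion with a super-tetrahedron. Points receive a tiny
#' deterministic jitter (relative to the cloud extent) to break exact
#' degeneracies such as grids of cospherical points; the perturbation is far
#' below any physically meaningful scale and is the same across calls, so
#' results are reproducible without touching R's RNG.
#'
#' @param pts n x 3 numeric matrix (n >= 4).
#' @param jitter relative jitter magnitude (default 1e-8 of the extent).
#' @return list with `points` (jittered coordinates actually triangulated),
#'   `tetra` (m x 4 vertex indices) and `circum_r2` (squared circumradii).
#' @keywords internal
delaunay_3d <- function(pts, jitter = 1e-8) {
  pts <- rbind3(pts)
  n <- nrow(pts)
  stopifnot(n >= 4)
  ctr <- colMeans(pts)
  extent <- max(apply(pts, 2, function(v) diff(range(v))), 1e-12)
  # deterministic per-cell jitter; the hash must be non-linear in the index
  # or structured clouds (grids) stay degenerate after jittering
  h <- outer(seq_len(n), c(1, 2, 3), function(i, k) {
    s <- sin(i * 12.9898 + k * 78.233) * 43758.5453
    (s - floor(s)) - 0.5
  })
  p <- pts + h * (jitter * extent)
  L <- 1000 * extent
  super <- rbind(ctr + L * c(0, 0, 4),
                 ctr + L * c(3.7, 0, -2),
                 ctr + L * c(-1.85, 3.2, -2),
                 ctr + L * c(-1.85, -3.2, -2))
  verts <- rbind(p, super)
  cap <- 16L * n + 64L
  tet <- matrix(0L, cap, 4)
  cc <- matrix(0, cap, 3)
  r2 <- numeric(cap)
  cerr <- numeric(cap)   # estimated absolute error of the circumcenter
  alive <- logical(cap)
  m <- 0L
  # append a batch of tetrahedra (rows of vmat), computing circumspheres
  append_tets <- function(vmat) {
    k <- nrow(vmat)
    if (m + k > cap) {
      cap <<- max(2L * cap, m + k)
      tet2 <- matrix(0L, cap, 4); tet2[seq_len(m), ] <- tet[seq_len(m), ]
      tet <<- tet2
      cc2 <- matrix(0, cap, 3); cc2[seq_len(m), ] <- cc[seq_len(m), ]
      cc <<- cc2
      length(r2) <<- cap
      length(cerr) <<- cap
      length(alive) <<- cap
    }
    rows <- m + seq_len(k)
    tet[rows, ] <<- vmat
    a <- verts[vmat[, 1], , drop = FALSE]
    b <- verts[vmat[, 2], , drop = FALSE] - a
    c_ <- verts[vmat[, 3], , drop = FALSE] - a
    d <- verts[vmat[, 4], , drop = FALSE] - a
    # circumcenter relative to a: solve [b;c;d] x = [|b|^2;|c|^2;|d|^2]/2
    # inverse of the row matrix has columns (c x d, d x b, b x c) / det
    rb <- rowSums(b^2) / 2; rc <- rowSums(c_^2) / 2; rd <- rowSums(d^2) / 2
    cxd <- rowcross(c_, d); dxb <- rowcross(d, b); bxc <- rowcross(b, c_)
    det_ <- b[, 1] * cxd[, 1] + b[, 2] * cxd[, 2] + b[, 3] * cxd[, 3]
    ok <- is.finite(det_) & abs(det_) > 0
    ux <- rb * cxd[, 1] + rc * dxb[, 1] + rd * bxc[, 1]
    uy <- rb * cxd[, 2] + rc * dxb[, 2] + rd * bxc[, 2]
    uz <- rb * cxd[, 3] + rc * dxb[, 3] + rd * bxc[, 3]
    ccx <- ifelse(ok, ux / det_, Inf)
    ccy <- ifelse(ok, uy / det_, Inf)
    ccz <- ifelse(ok, uz / det_, Inf)
    cc[rows, 1] <<- ccx + a[, 1]
    cc[rows, 2] <<- ccy + a[, 2]
    cc[rows, 3] <<- ccz + a[, 3]
    r2[rows] <<- ifelse(ok, ccx^2 + ccy^2 + ccz^2, Inf)
    # condition-aware circumcenter error: rounding in the Cramer numerators
    # scales with vertex magnitudes (not the possibly-cancelled results),
    # amplified by 1/det; drives marginal tests to the robust predicate
    s_ <- pmax(abs(b[, 1]), abs(b[, 2]), abs(b[, 3]),
               abs(c_[, 1]), abs(c_[, 2]), abs(c_[, 3]),
               abs(d[, 1]), abs(d[, 2]), abs(d[, 3]))
    cerr[rows] <<- ifelse(ok,
      1e-14 * (s_^4 + (abs(ccx) + abs(ccy) + abs(ccz)) * s_^3) / abs(det_),
      Inf)
    alive[rows] <<- TRUE
    m <<- m + k
  }
  append_tets(matrix(c(n + 1L, n + 2L, n + 3L, n + 4L), 1))
  nbig <- as.double(n) + 5
  # deterministic shuffle of insertion order (avoids pathological grid order)
  ord <- order((seq_len(n) * 48271) %% 65537)
  for (i in ord) {
    act <- which(alive[seq_len(m)])
    d2 <- (cc[act, 1] - p[i, 1])^2 + (cc[act, 2] - p[i, 2])^2 +
      (cc[act, 3] - p[i, 3])^2
    # fast path: circumsphere comparison with a conservative error band;
    # marginal or degenerate cases go to the robust dd in-sphere predicate
    margin <- d2 - r2[act]
    rr <- sqrt(pmin(r2[act], 1e300)) + sqrt(d2)
    band <- 4 * pmin(cerr[act], 1e300) * rr +
      1e-9 * (d2 + pmin(r2[act], 1e300)) + 1e-300
    confident <- is.finite(margin) & abs(margin) > band
    inside <- confident & margin < 0
    suspect <- which(!confident)
    if (length(suspect)) {
      sidx <- act[suspect]
      inside[suspect] <- insphere_robust(
        verts[tet[sidx, 1], , drop = FALSE], verts[tet[sidx, 2], , drop = FALSE],
        verts[tet[sidx, 3], , drop = FALSE], verts[tet[sidx, 4], , drop = FALSE],
        p[i, ])
    }
    bad <- act[inside]
    if (!length(bad)) # safety net; unreachable with exact predicates
      bad <- act[which.min(d2 - r2[act])]
    tv <- tet[bad, , drop = FALSE]
    faces <- rbind(tv[, c(2, 3, 4), drop = FALSE],
                   tv[, c(1, 3, 4), drop = FALSE],
                   tv[, c(1, 2, 4), drop = FALSE],
                   tv[, c(1, 2, 3), drop = FALSE])
    f1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
    f3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
    f2 <- as.integer(faces[, 1] + faces[, 2] + faces[, 3]) - f1 - f3
    key <- (f1 * nbig + f2) * nbig + f3
    dup <- key %in% key[duplicated(key)]
    alive[bad] <- FALSE
    nf <- which(!dup)
    if (length(nf))
      append_tets(cbind(faces[nf, , drop = FALSE], i))
  }
  keep <- which(alive[seq_len(m)])
  keep <- keep[rowSums(tet[keep, , drop = FALSE] <= n) == 4L]
  list(points = p, tetra = tet[keep, , drop = FALSE],
       circum_r2 = r2[keep])
}

# row-wise cross product of two n x 3 matrices
#' @keywords internal
rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @keywords internal
circumsphere <- function(a, b, c, d) {
  A <- 2 * rbind(b - a, c - a, d - a)
  rhs <- c(sum(b^2) - sum(a^2), sum(c^2) - sum(a^2), sum(d^2) - sum(a^2))
  ctr <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(ctr) || !all(is.finite(ctr)))
    return(list(center = c(Inf, Inf, Inf), r2 = Inf))
  list(center = ctr, r2 = sum((ctr - a)^2))
}

#' @keywords internal
tetra_volumes <- function(points, tetra) {
  if (nrow(tetra) == 0) return(numeric(0))
  a <- points[tetra[, 1], , drop = FALSE]
  u <- points[tetra[, 2], , drop = FALSE] - a
  v <- points[tetra[, 3], , drop = FALSE] - a
  w <- points[tetra[, 4], , drop = FALSE] - a
  dets <- u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
    u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
    u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  abs(dets) / 6
}

#' Alpha-shape volume of a 3D point cloud
#'
#' Computes the Delaunay tetrahedralization and sums the volumes of all
#' tetrahedra whose circumradius is at most `alpha` (the alpha complex under
#' the circumradius-threshold convention, in the same length units as the
#' coordinates -- cm here). As `alpha -> Inf` this converges to the convex
#' hull volume. Disconnected components all count toward the total.
#'
#' @param points n x 3 matrix (cm), n >= 4.
#' @param alpha circumradius threshold (cm), > 0 (may be `Inf`).
#' @return volume in cm^3; 0 (with a warning) for a degenerate coplanar cloud,
#'   0 (silently) if no tetrahedron survives the alpha test.
#' @examples
#' tet <- rbind(c(0,0,0), c(1,0,0), c(0.5, sqrt(3)/2, 0),
#'              c(0.5, sqrt(3)/6, sqrt(2/3)))
#' alpha_shape_volume(tet, 2)  # sqrt(2)/12
#' @export
alpha_shape_volume <- function(points, alpha) {
  points <- rbind3(points)
  if (nrow(points) < 4) stop("need >= 4 points", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a single positive length (cm)", call. = FALSE)
  sv <- svd(sweep(points, 2, colMeans(points)), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    warning("degenerate (coplanar) point cloud; volume 0")
    return(0)
  }
  dt <- delaunay_3d(points)
  keep <- dt$circum_r2 <= alpha^2
  if (!any(keep)) return(0)
  sum(tetra_volumes(dt$points, dt$tetra[keep, , drop = FALSE]))
}

#' Boundary mesh of the alpha complex
#'
#' Triangular faces belonging to exactly one kept tetrahedron, oriented
#' outward (away from the owning tetrahedron's opposite vertex).
#'
#' @inheritParams alpha_shape_volume
#' @return list with `vertices` (n x 3) and `faces` (f x 3 vertex indices);
#'   empty faces if the complex has no volume.
#' @export
alpha_shape_mesh <- function(points, alpha) {
  points <- rbind3(points)
  dt <- delaunay_3d(points)
  keep <- which(dt$circum_r2 <= alpha^2)
  tet <- dt$tetra[keep, , drop = FALSE]
  if (nrow(tet) == 0)
    return(list(vertices = points, faces = matrix(0L, 0, 3)))
  face_idx <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  faces <- matrix(0L, 4 * nrow(tet), 3)
  opp <- integer(4 * nrow(tet))
  k <- 0L
  for (ti in seq_len(nrow(tet))) for (fi in 1:4) {
    k <- k + 1L
    faces[k, ] <- tet[ti, face_idx[fi, ]]
    opp[k] <- tet[ti, fi]
  }
  fs <- t(apply(faces, 1, sort))
  key <- paste(fs[, 1], fs[, 2], fs[, 3])
  boundary <- !(key %in% key[duplicated(key)])
  faces <- faces[boundary, , drop = FALSE]
  opp <- opp[boundary]
  # orient each boundary face so its normal points away from the opposite vertex
  for (j in seq_len(nrow(faces))) {
    a <- dt$points[faces[j, 1], ]; b <- dt$points[faces[j, 2], ]
    c_ <- dt$points[faces[j, 3], ]
    nrm <- cross3(b - a, c_ - a)
    if (sum(nrm * (dt$points[opp[j], ] - a)) > 0)
      faces[j, ] <- faces[j, c(1, 3, 2)]
  }
  list(vertices = points, faces = faces)
}

#' Check that a triangle mesh is watertight (edge-manifold and closed)
#'
#' Every edge must be shared by exactly two faces.
#'
#' @param mesh list with `faces` as returned by [alpha_shape_mesh].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2)
}

#' Export a triangle mesh as Wavefront OBJ
#' @param mesh list with `vertices` and `faces`.
#' @param path output path.
#' @export
write_obj <- function(mesh, path) {
  v <- sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
               mesh$vertices[, 3])
  f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c(v, f), path)
  invisible(path)
}
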