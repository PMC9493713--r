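# Double-double ("compensated") arithmetic for robust geometric predicates.
# All operations are elementwise over vectors, so predicate evaluation stays
# vectorized across many tetrahedra. ~32 significant digits: enough to decide
# in-sphere tests that plain doubles get wrong for near-degenerate tetrahedra
# (the classic failure mode of incremental Delaunay on structured clouds).

#' @keywords internal
dd <- function(hi, lo = 0) list(hi = hi, lo = lo + numeric(length(hi)))

# error-free sum of two doubles
#' @keywords internal
two_sum <- function(a, b) {
  s <- a + b
  bb <- s - a
  list(hi = s, lo = (a - (s - bb)) + (b - bb))
}

# error-free product (Dekker splitting; no fma in base R)
#' @keywords internal
two_prod <- function(a, b) {
  p <- a * b
  ca <- 134217729 * a; ah <- ca - (ca - a); al <- a - ah
  cb <- 134217729 * b; bh <- cb - (cb - b); bl <- b - bh
  list(hi = p, lo = ((ah * bh - p) + ah * bl + al * bh) + al * bl)
}

#' @keywords internal
dd_add <- function(x, y) {
  s <- two_sum(x$hi, y$hi)
  t <- two_sum(x$lo, y$lo)
  lo <- s$lo + t$hi
  hi2 <- s$hi + lo
  e <- lo - (hi2 - s$hi)
  lo2 <- e + t$lo
  hi3 <- hi2 + lo2
  list(hi = hi3, lo = lo2 - (hi3 - hi2))
}

#' @keywords internal
dd_neg <- function(x) list(hi = -x$hi, lo = -x$lo)

#' @keywords internal
dd_sub <- function(x, y) dd_add(x, dd_neg(y))

#' @keywords internal
dd_mul <- function(x, y) {
  p <- two_prod(x$hi, y$hi)
  lo <- p$lo + (x$hi * y$lo + x$lo * y$hi)
  hi <- p$hi + lo
  list(hi = hi, lo = lo - (hi - p$hi))
}

#' @keywords internal
dd_sign <- function(x) {
  s <- sign(x$hi)
  z <- s == 0
  s[z] <- sign(x$lo[z])
  s
}

# exact dd difference of two plain doubles
#' @keywords internal
dd_diff <- function(a, b) two_sum(a, -b)

# 3x3 determinant with dd rows u, v, w (each a list of 3 dd scalars/vectors)
#' @keywords internal
dd_det3 <- function(u, v, w) {
  t1 <- dd_sub(dd_mul(v[[2]], w[[3]]), dd_mul(v[[3]], w[[2]]))
  t2 <- dd_sub(dd_mul(v[[1]], w[[3]]), dd_mul(v[[3]], w[[1]]))
  t3 <- dd_sub(dd_mul(v[[1]], w[[2]]), dd_mul(v[[2]], w[[1]]))
  dd_add(dd_sub(dd_mul(u[[1]], t1), dd_mul(u[[2]], t2)), dd_mul(u[[3]], t3))
}

# Robust in-sphere test, vectorized over tetrahedra.
# a, b, c, d: n x 3 matrices of tetra vertices; p: length-3 point.
# Returns TRUE where p lies strictly inside the circumsphere of (a,b,c,d),
# independent of vertex orientation. Points exactly on the sphere (to dd
# precision) are "outside".
#' @keywords internal
insphere_robust <- function(a, b, c, d, p) {
  rel <- function(m) lapply(1:3, function(k) dd_diff(m[, k], p[k]))
  ra <- rel(a); rb <- rel(b); rc <- rel(c); rd <- rel(d)
  lift <- function(r) dd_add(dd_add(dd_mul(r[[1]], r[[1]]),
                                    dd_mul(r[[2]], r[[2]])),
                             dd_mul(r[[3]], r[[3]]))
  la <- lift(ra); lb <- lift(rb); lc <- lift(rc); ld <- lift(rd)
  det <- dd_add(
    dd_sub(dd_mul(la, dd_det3(rb, rc, rd)), dd_mul(lb, dd_det3(ra, rc, rd))),
    dd_sub(dd_mul(lc, dd_det3(ra, rb, rd)), dd_mul(ld, dd_det3(ra, rb, rc))))
  sub3 <- function(x, y) lapply(1:3, function(k) dd_sub(x[[k]], y[[k]]))
  orient <- dd_det3(sub3(ra, rd), sub3(rb, rd), sub3(rc, rd))
  dd_sign(det) * dd_sign(orient) < 0
}
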