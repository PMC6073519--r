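# Small numeric utilities: neighbor search, rotations, misc.

#' @importFrom data.table data.table := .N setkey setkeyv rbindlist as.data.table
#' @importFrom rlang hash
NULL

.unit <- function(v) v / sqrt(sum(v^2))

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  u <- .unit(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c1 * diag(3) + s1 * ux + (1 - c1) * (u %o% u)
}

# All unordered point pairs within `cutoff`, via a cell list.  Returns a
# data.table with columns i, j (i < j), d.  Pure R but vectorized: beads are
# binned into cubic cells of side `cutoff` and only the 14 half-space
# neighbor offsets are joined.
neighbor_pairs <- function(xyz, cutoff) {
  stopifnot(cutoff > 0)
  n <- nrow(xyz)
  if (n < 2) return(data.table(i = integer(), j = integer(), d = numeric()))
  cx <- floor(xyz[, 1] / cutoff); cy <- floor(xyz[, 2] / cutoff); cz <- floor(xyz[, 3] / cutoff)
  cx <- cx - min(cx); cy <- cy - min(cy); cz <- cz - min(cz)
  nx <- max(cx) + 2L; ny <- max(cy) + 2L
  cell_id <- function(a, b, c) 1 + a + b * nx + c * nx * ny
  pts <- data.table(idx = seq_len(n), cid = cell_id(cx, cy, cz))
  setkey(pts, cid)
  offs <- rbind(
    c(0, 0, 0),
    c(1, 0, 0), c(-1, 1, 0), c(0, 1, 0), c(1, 1, 0),
    c(-1, -1, 1), c(0, -1, 1), c(1, -1, 1),
    c(-1, 0, 1), c(0, 0, 1), c(1, 0, 1),
    c(-1, 1, 1), c(0, 1, 1), c(1, 1, 1)
  )
  out <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    src <- data.table(idx = seq_len(n),
                      cid = cell_id(cx + o[1], cy + o[2], cz + o[3]))
    m <- pts[src, on = "cid", allow.cartesian = TRUE, nomatch = NULL]
    # m: idx = points in the shifted cell (target), i.idx = source point
    a <- m$i.idx; b <- m$idx
    if (all(o == 0)) { keep <- a < b } else { keep <- a != b }
    a <- a[keep]; b <- b[keep]
    if (!length(a)) next
    ii <- pmin(a, b); jj <- pmax(a, b)
    out[[k]] <- data.table(i = ii, j = jj)
  }
  pr <- unique(rbindlist(out))
  if (!nrow(pr)) return(data.table(i = integer(), j = integer(), d = numeric()))
  d2 <- (xyz[pr$i, 1] - xyz[pr$j, 1])^2 + (xyz[pr$i, 2] - xyz[pr$j, 2])^2 +
    (xyz[pr$i, 3] - xyz[pr$j, 3])^2
  pr[, d := sqrt(d2)]
  pr[d <= cutoff][order(i, j)]
}

# stable integer re-indexing helper
.reindex <- function(x, old) match(x, old)
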