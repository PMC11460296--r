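#' Read a planar contour structure set
#'
#' Parses a structure-set record in the planar-contour convention of DICOM
#' RT-STRUCT: per structure, a sequence of contours, each a flat list of 3D
#' point coordinates in patient millimetres (the semantic content of the
#' Contour Data tag (3006,0050)). The record is supplied either as a JSON
#' file of the form
#' `{"structures": [{"name": ..., "contours": [{"points": [x1,y1,z1,...]}]}]}`
#' or as the equivalent R list. This dialect carries the contour payload
#' only; writing clinical DICOM files is out of scope.
#'
#' @param source path to a JSON structure-set file, or an R list with a
#'   `structures` element
#' @return a `contour_set`: named list, one element per structure, each a
#'   list of polygons (n x 3 matrices of patient-mm points)
#' @export
read_rtstruct <- function(source) {
  if (is.character(source)) {
    if (!file.exists(source)) stop("cannot read structure set: ", source)
    source <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  }
  if (!is.list(source) || is.null(source$structures))
    stop("structure set record has no 'structures' sequence")
  out <- list()
  for (st in source$structures) {
    if (is.null(st$name)) stop("structure without a name")
    polys <- list()
    for (ct in st$contours) {
      pts <- unlist(ct$points, use.names = FALSE)
      if (is.null(pts)) stop("contour with missing contour data")
      if (length(pts) %% 3 != 0)
        stop("contour data length not divisible by 3 (structure '",
             st$name, "')")
      polys[[length(polys) + 1]] <-
        matrix(as.numeric(pts), ncol = 3, byrow = TRUE)
    }
    out[[st$name]] <- polys
  }
  if (length(out) == 0 || all(vapply(out, length, 1L) == 0))
    warning("structure set contains no contours")
  structure(out, class = "contour_set")
}

#' Write a contour set as a JSON structure-set record
#' @param contours a `contour_set`
#' @param path output JSON path
#' @export
write_rtstruct <- function(contours, path) {
  rec <- list(structures = lapply(names(contours), function(nm) {
    list(name = nm, contours = lapply(contours[[nm]], function(p)
      list(points = as.numeric(t(p)))))
  }))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize planar contours onto a voxel grid
#'
#' Converts per-slice contour polygons into voxel masks on the given
#' geometry. A voxel is set iff its centre lies inside the polygon under the
#' even-odd rule; several polygons on one slice combine by even-odd parity,
#' so holes (and rings) are supported. Each polygon is assigned to the
#' nearest grid slice; a polygon plane farther than half the slice spacing
#' from every slice is an error. Boundary handling follows the half-open
#' convention: a centre exactly on an edge counts as inside only for edges
#' on the lower-index side, which makes rasterization deterministic and
#' adjacent tilings non-overlapping.
#'
#' @param contours a `contour_set` (see [read_rtstruct()]); structures named
#'   `gland`/`prostate` and `pz` are mapped to the two masks
#' @param geometry geometry list (see [geometry_of()])
#' @return a [structure_mask_set()]
#' @export
rasterize <- function(contours, geometry) {
  gl <- contours[[intersect(c("gland", "prostate"), names(contours))[1]]]
  pz <- contours[["pz"]]
  gland_mask <- rasterize_structure(gl, geometry)
  pz_mask <- if (is.null(pz)) NULL else rasterize_structure(pz, geometry)
  structure_mask_set(gland_mask, pz_mask, geometry)
}

rasterize_structure <- function(polys, geometry) {
  d <- geometry$dim
  mask <- array(0L, d)
  if (is.null(polys) || length(polys) == 0) return(mask)
  for (p in polys) {
    idx <- patient_to_index(p, geometry)
    z <- idx[, 3]
    if (diff(range(z)) > 1e-6 + 1e-9 * max(1, abs(mean(z))))
      stop("contour vertices are not coplanar within tolerance")
    zbar <- mean(z)
    slice <- round(zbar)
    if (abs(zbar - slice) > 0.5 || slice < 0 || slice > d[3] - 1)
      stop(sprintf(
        "orphan contour: plane at slice index %.3f is farther than half the slice spacing from any grid slice",
        zbar))
    if (nrow(idx) < 3 || polygon_area(idx[, 1], idx[, 2]) <= 1e-12) {
      warning("degenerate contour (zero area) ignored")
      next
    }
    inside <- even_odd_inside(idx[, 1], idx[, 2], d[1], d[2])
    mask[, , slice + 1L] <- (mask[, , slice + 1L] + inside) %% 2L
  }
  mask
}

polygon_area <- function(u, v) {
  n <- length(u)
  j <- c(n, seq_len(n - 1))
  abs(sum(u[j] * v - u * v[j])) / 2
}

# Even-odd crossing parity over the full (row, col) pixel-centre grid.
# Half-open rule: rays are cast along +col; the vertex test uses strict
# inequality in row and strict inequality against the intersection column,
# so centres on upper/right edges are excluded and tilings stay disjoint.
even_odd_inside <- function(u, v, nrow, ncol) {
  uc <- matrix(0:(nrow - 1), nrow, ncol)
  vc <- matrix(rep(0:(ncol - 1), each = nrow), nrow, ncol)
  parity <- matrix(0L, nrow, ncol)
  n <- length(u)
  for (e in seq_len(n)) {
    u1 <- u[e]; v1 <- v[e]
    u2 <- u[e %% n + 1]; v2 <- v[e %% n + 1]
    if (u1 == u2) next
    crosses <- (u1 > uc) != (u2 > uc)
    vint <- v1 + (uc - u1) * (v2 - v1) / (u2 - u1)
    parity <- parity + (crosses & (vc < vint))
  }
  matrix(as.integer(parity %% 2L), nrow, ncol)
}

#' Convert voxel masks back to planar boundary contours
#'
#' Traces per-slice boundary polygons along the pixel-square edges of each
#' mask so that re-rasterization on the same grid reproduces the mask
#' voxel-exactly (holes come out as separate even-odd polygons).
#'
#' @param masks a [structure_mask_set()]
#' @return a `contour_set` with entries `gland` and (if present) `pz`
#' @export
masks_to_contours <- function(masks) {
  out <- list()
  out$gland <- mask_to_polys(masks$gland, masks$geometry)
  if (!is.null(masks$pz)) out$pz <- mask_to_polys(masks$pz, masks$geometry)
  structure(out, class = "contour_set")
}

mask_to_polys <- function(mask, geometry) {
  d <- dim(mask)
  polys <- list()
  for (s in seq_len(d[3])) {
    sl <- mask[, , s]
    if (!any(sl == 1)) next
    loops <- trace_slice_loops(sl)
    for (lp in loops) {
      idx <- cbind(lp[, 1], lp[, 2], s - 1)
      polys[[length(polys) + 1]] <- index_to_patient(idx, geometry)
    }
  }
  polys
}

# Boundary edges of the union of pixel squares, chained into closed loops.
# Vertices sit on the half-integer lattice so no pixel centre can fall on an
# edge; parity of the traced polygons therefore reproduces the mask exactly.
trace_slice_loops <- function(sl) {
  nr <- nrow(sl); nc <- ncol(sl)
  occ <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && sl[i, j] == 1
  # directed edges (from, to) on the corner lattice; corner (a,b) is index
  # coordinate (a - 1.5, b - 1.5) for a in 1..nr+1
  from <- list(); to <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (sl[i, j] != 1) next
    if (!occ(i - 1, j)) { from[[length(from) + 1]] <- c(i, j); to[[length(to) + 1]] <- c(i, j + 1) }       # top
    if (!occ(i + 1, j)) { from[[length(from) + 1]] <- c(i + 1, j + 1); to[[length(to) + 1]] <- c(i + 1, j) } # bottom
    if (!occ(i, j - 1)) { from[[length(from) + 1]] <- c(i + 1, j); to[[length(to) + 1]] <- c(i, j) }       # left
    if (!occ(i, j + 1)) { from[[length(from) + 1]] <- c(i, j + 1); to[[length(to) + 1]] <- c(i + 1, j + 1) } # right
  }
  if (length(from) == 0) return(list())
  key <- function(p) paste(p[1], p[2])
  bystart <- split(seq_along(from), vapply(from, key, ""))
  used <- logical(length(from))
  loops <- list()
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    loop <- list(from[[e0]])
    used[e0] <- TRUE
    cur <- to[[e0]]
    while (!identical(cur, from[[e0]])) {
      loop[[length(loop) + 1]] <- cur
      cand <- bystart[[key(cur)]]
      cand <- cand[!used[cand]]
      e <- cand[1]
      used[e] <- TRUE
      cur <- to[[e]]
    }
    m <- do.call(rbind, loop)
    loops[[length(loops) + 1]] <- cbind(m[, 1] - 1.5, m[, 2] - 1.5)
  }
  loops
}
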