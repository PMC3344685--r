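#' Construct a section plane
#'
#' A section plane is defined by its unit normal, a signed offset from the
#' block center along that normal, and a physical thickness. The in-plane
#' "vertical" axis used to orient cycloid test grids is, by convention,
#' the normalized projection of the global z-axis onto the plane (the
#' projection of the x-axis when the plane is perpendicular to z). Any
#' fixed convention yields a valid surface estimator under IUR sampling;
#' this one is deterministic and reproducible.
#'
#' @param normal numeric length-3; normalized internally.
#' @param offset signed distance (mm) of the plane from the block center.
#' @param thickness physical section thickness (mm); 0.005 matches a
#'   conventional paraffin section, 0.002 a resin section.
#' @param block numeric length-3 block edge lengths (mm), used to anchor
#'   the plane to a block center.
#' @return An object of class `section_plane` with fields `normal`,
#'   `offset`, `thickness`, `vertical_axis`, the in-plane basis `e1`,
#'   `e2 = vertical_axis`, and the plane reference point `p0`.
#' @export
section_plane <- function(normal, offset = 0, thickness = 0.005,
                          block = c(1, 1, 1)) {
  stopifnot(length(normal) == 3, thickness > 0)
  n <- normal / sqrt(sum(normal^2))
  zproj <- c(0, 0, 1) - sum(c(0, 0, 1) * n) * n
  if (sqrt(sum(zproj^2)) < 1e-8)
    zproj <- c(1, 0, 0) - sum(c(1, 0, 0) * n) * n
  e2 <- zproj / sqrt(sum(zproj^2))
  e1 <- c(n[2] * e2[3] - n[3] * e2[2],
          n[3] * e2[1] - n[1] * e2[3],
          n[1] * e2[2] - n[2] * e2[1])
  structure(list(normal = n, offset = offset, thickness = thickness,
                 vertical_axis = e2, e1 = e1, e2 = e2,
                 block = block, p0 = block / 2 + offset * n),
            class = "section_plane")
}

#' Sample an isotropic uniform random (IUR) section plane
#'
#' Digital analogue of the orientator protocol used at the bench: rather
#' than physically rotating slabs, the plane normal is drawn uniformly on
#' the unit hemisphere (azimuth uniform on `[0, 2*pi)`, cosine of the
#' colatitude uniform on `[0, 1]`) and the offset uniformly over the
#' block's support along the normal. The two procedures induce the same
#' IUR law; direct sampling is simpler and exactly testable.
#'
#' @param block numeric length-3 block edge lengths (mm), or a
#'   `label_volume` whose block is used.
#' @param rng_seed integer seed.
#' @param thickness section thickness (mm).
#' @return A [section_plane()].
#' @export
sample_iur_plane <- function(block = c(1, 1, 1), rng_seed = 1L,
                             thickness = 0.005) {
  if (inherits(block, "label_volume")) block <- block$block
  with_seed(rng_seed, {
    z <- runif(1)                       # cos(colatitude) ~ U(0,1)
    az <- runif(1, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    n <- c(r * cos(az), r * sin(az), z)
    corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))) *
      rep(block, each = 8)
    proj <- drop(corners %*% n) - sum(block / 2 * n)
    off <- runif(1, min(proj), max(proj))
    section_plane(n, offset = off, thickness = thickness, block = block)
  })
}

#' Analytic area of the intersection of a plane with the block
#'
#' Clips the block (a box) with the plane and returns the area of the
#' resulting convex polygon. Used as the oracle for the area-conservation
#' property of systematic field tilings.
#'
#' @param plane a `section_plane`.
#' @param block numeric length-3 block edges (mm); defaults to the
#'   plane's anchored block.
#' @return Area in mm^2 (0 when the plane misses the block).
#' @export
plane_block_area <- function(plane, block = plane$block) {
  n <- plane$normal
  p0 <- block / 2 + plane$offset * n
  verts <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))) *
    rep(block, each = 8)
  edges <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                 c(1, 3), c(2, 4), c(5, 7), c(6, 8),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  pts <- matrix(numeric(0), ncol = 3)
  s <- drop(verts %*% n) - sum(p0 * n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if ((s[a] <= 0 && s[b] >= 0) || (s[a] >= 0 && s[b] <= 0)) {
      if (abs(s[a] - s[b]) < 1e-14) next
      t <- s[a] / (s[a] - s[b])
      pts <- rbind(pts, verts[a, ] + t * (verts[b, ] - verts[a, ]))
    }
  }
  if (nrow(pts) < 3) return(0)
  u <- drop((pts - rep(p0, each = nrow(pts))) %*% plane$e1)
  v <- drop((pts - rep(p0, each = nrow(pts))) %*% plane$e2)
  keep <- !duplicated(round(cbind(u, v), 12))
  u <- u[keep]; v <- v[keep]
  if (length(u) < 3) return(0)
  o <- order(atan2(v - mean(v), u - mean(u)))
  u <- u[o]; v <- v[o]
  i2 <- c(seq_along(u)[-1], 1)
  abs(sum(u * v[i2] - u[i2] * v)) / 2
}

#' Extract a digital section from a label volume
#'
#' The digital microtome: lays a pixel grid over the plane's intersection
#' with the block and assigns each pixel the label of the voxel containing
#' the pixel center's 3D position (0 outside the block). Particles whose
#' centers lie within `thickness/2` of the plane are projected into the
#' field with class, in-plane position and signed depth retained.
#'
#' @param volume a `label_volume`.
#' @param plane a `section_plane`.
#' @param pixel_size pixel edge (mm); defaults to the voxel size.
#' @return An object of class `section_field`: `labels` (2D integer
#'   matrix, rows along `e1`, columns along the vertical axis `e2`),
#'   `pixel_size`, `plane`, `origin` (in-plane coordinates of the field's
#'   lower-left corner) and `particles`.
#' @export
extract_section <- function(volume, plane, pixel_size = volume$voxel_size) {
  stopifnot(inherits(volume, "label_volume"),
            inherits(plane, "section_plane"), pixel_size > 0)
  block <- volume$block
  n <- plane$normal
  p0 <- block / 2 + plane$offset * n
  corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))) *
    rep(block, each = 8)
  rel <- corners - rep(p0, each = 8)
  a <- drop(rel %*% plane$e1)
  b <- drop(rel %*% plane$e2)
  na <- max(1L, ceiling((max(a) - min(a)) / pixel_size))
  nb <- max(1L, ceiling((max(b) - min(b)) / pixel_size))
  av <- min(a) + (seq_len(na) - 0.5) * pixel_size
  bv <- min(b) + (seq_len(nb) - 0.5) * pixel_size
  vs <- volume$voxel_size
  dims <- volume$dims
  lab <- matrix(LAB_OUTSIDE, na, nb)
  # 3D position of each pixel center, one coordinate at a time
  for (coord in 1:3) {
    assign(c("px", "py", "pz")[coord],
           p0[coord] + outer(av * plane$e1[coord], bv * plane$e2[coord], "+"))
  }
  ix <- floor(px / vs); iy <- floor(py / vs); iz <- floor(pz / vs)
  ok <- ix >= 0 & ix < dims[1] & iy >= 0 & iy < dims[2] & iz >= 0 & iz < dims[3]
  idx <- ix[ok] + dims[1] * (iy[ok] + dims[2] * iz[ok]) + 1
  lab[ok] <- volume$labels[idx]
  if (!any(ok)) stop("plane does not intersect the block")
  parts <- volume$particles
  if (nrow(parts) > 0) {
    pc <- as.matrix(parts[, c("x", "y", "z")])
    rel <- pc - rep(p0, each = nrow(pc))
    depth <- drop(rel %*% n)
    keep <- abs(depth) <= plane$thickness / 2
    parts <- data.frame(class = parts$class[keep],
                        u = drop(rel[keep, , drop = FALSE] %*% plane$e1),
                        v = drop(rel[keep, , drop = FALSE] %*% plane$e2),
                        depth = depth[keep], stringsAsFactors = FALSE)
  } else {
    parts <- data.frame(class = character(0), u = numeric(0), v = numeric(0),
                        depth = numeric(0), stringsAsFactors = FALSE)
  }
  section_field(lab, pixel_size, plane = plane,
                origin = c(min(a), min(b)), particles = parts)
}

# Sample an IUR plane that actually yields pixels: planes grazing a block
# corner can hold no pixel center and are rejected and redrawn (their
# tissue area is ~0, so rejection does not bias area-weighted pooling).
iur_section <- function(volume, rng_seed, thickness = 0.005,
                        pixel_size = volume$voxel_size, max_tries = 20L) {
  for (k in seq_len(max_tries)) {
    pl <- sample_iur_plane(volume, rng_seed = child_seed(rng_seed, k - 1),
                           thickness = thickness)
    sec <- tryCatch(extract_section(volume, pl, pixel_size),
                    error = function(e) NULL)
    if (!is.null(sec)) return(list(plane = pl, section = sec))
  }
  stop("could not sample an intersecting IUR plane")
}

#' Construct a section field from a 2D label image
#'
#' The container for one sampled microscopic field: a 2D integer label map
#' (1 lumen, 2 epithelium, 3 stroma, 0 outside the tissue block) with its
#' pixel size and provenance. User-supplied 2D label maps enter the
#' estimator layer through this constructor.
#'
#' @param labels integer matrix with codes in `{0, 1, 2, 3}`.
#' @param pixel_size pixel edge (mm).
#' @param plane the generating [section_plane()], or `NULL` for imported
#'   data.
#' @param origin in-plane coordinates (mm) of the field's lower-left
#'   corner.
#' @param particles optional data frame (`class`, `u`, `v`, `depth`).
#' @return An object of class `section_field`.
#' @export
section_field <- function(labels, pixel_size, plane = NULL, origin = c(0, 0),
                          particles = NULL) {
  stopifnot(is.matrix(labels), pixel_size > 0,
            all(labels %in% 0:3))
  if (is.null(particles))
    particles <- data.frame(class = character(0), u = numeric(0),
                            v = numeric(0), depth = numeric(0),
                            stringsAsFactors = FALSE)
  structure(list(labels = matrix(as.integer(labels), nrow(labels)),
                 pixel_size = pixel_size, plane = plane,
                 origin = origin, particles = particles),
            class = "section_field")
}

#' @export
print.section_field <- function(x, ...) {
  cat("Section field:", nrow(x$labels), "x", ncol(x$labels), "px of",
      x$pixel_size, "mm;",
      round(100 * mean(x$labels != LAB_OUTSIDE)), "% tissue\n")
  invisible(x)
}

# All tiles of a full systematic tiling of a section with square fields of
# `fpx` pixels, given start indices (si, sj) in (-fpx, 0]. Tiles are
# returned in row-major order; border tiles are padded with 0 (outside).
tile_indices <- function(dimx, dimy, fpx, si, sj) {
  starts_i <- seq(si, dimx - 1, by = fpx)
  starts_j <- seq(sj, dimy - 1, by = fpx)
  expand.grid(i = starts_i, j = starts_j)
}

crop_tile <- function(section, i0, j0, fpx) {
  lab <- matrix(LAB_OUTSIDE, fpx, fpx)
  ii <- max(1, i0):min(nrow(section$labels), i0 + fpx - 1)
  jj <- max(1, j0):min(ncol(section$labels), j0 + fpx - 1)
  if (length(ii) > 0 && length(jj) > 0)
    lab[ii - i0 + 1, jj - j0 + 1] <- section$labels[ii, jj, drop = FALSE]
  ps <- section$pixel_size
  section_field(lab, ps, plane = section$plane,
                origin = section$origin + c(i0 - 1, j0 - 1) * ps,
                particles = section$particles)
}

#' Sample systematic uniform random fields from a section
#'
#' Lays a systematic grid of square fields over the section with a single
#' uniform random start, discards fields wholly outside the tissue, and
#' takes a systematic subsample of the remaining fields (constant stride,
#' uniform random phase) so the `n_fields` selected fields spread evenly
#' over the whole section rather than clustering at one edge. The default
#' `n_fields = 22` matches a conventional sampling effort of twenty-two
#' fields per specimen.
#'
#' @param section a `section_field` (typically a whole section from
#'   [extract_section()]).
#' @param n_fields number of tissue-containing fields required.
#' @param field_edge field edge length (mm).
#' @param rng_seed integer seed for the random grid start.
#' @param keep_empty return all tiles of the tiling (including
#'   tissue-free ones) instead of the first `n_fields`; used for
#'   exhaustive-tiling checks.
#' @param allow_fewer return the available tissue-containing fields
#'   instead of raising an error when the section is too small to yield
#'   `n_fields` of them (ratio-of-sums pooling remains valid with
#'   unequal field counts).
#' @return List of `section_field` crops (constant size
#'   `round(field_edge / pixel_size)` pixels), with attributes
#'   `n_available` (tissue-containing tiles in the full tiling) and
#'   `n_taken`. When pooling across sections of different sizes, weight
#'   each section's pooled pixel sums by `n_available / n_taken` — the
#'   inverse field-inclusion probability — so that every tissue pixel
#'   carries equal weight regardless of how small its section was.
#' @export
systematic_fields <- function(section, n_fields = 22L, field_edge,
                              rng_seed = 1L, keep_empty = FALSE,
                              allow_fewer = FALSE) {
  stopifnot(inherits(section, "section_field"), n_fields >= 1,
            field_edge > 0)
  ps <- section$pixel_size
  fpx <- max(1L, as.integer(round(field_edge / ps)))
  dimx <- nrow(section$labels); dimy <- ncol(section$labels)
  with_seed(rng_seed, {
    si <- 1L - sample.int(fpx, 1) + 1L   # start in (1 - fpx, 1]
    sj <- 1L - sample.int(fpx, 1) + 1L
    tiles <- tile_indices(dimx, dimy, fpx, si, sj)
    if (keep_empty) {
      return(lapply(seq_len(nrow(tiles)), function(t)
        crop_tile(section, tiles$i[t], tiles$j[t], fpx)))
    }
    # tissue-containing tiles, in grid order
    has_tissue <- vapply(seq_len(nrow(tiles)), function(t) {
      ii <- max(1, tiles$i[t]):min(dimx, tiles$i[t] + fpx - 1L)
      jj <- max(1, tiles$j[t]):min(dimy, tiles$j[t] + fpx - 1L)
      any(section$labels[ii, jj] != LAB_OUTSIDE)
    }, logical(1))
    avail <- which(has_tissue)
    if (length(avail) == 0)
      stop("section contains no tissue-containing fields")
    if (length(avail) < n_fields && !allow_fewer)
      stop("section too small: only ", length(avail),
           " tissue-containing fields available, ", n_fields, " requested")
    n_take <- min(n_fields, length(avail))
    stride <- length(avail) / n_take
    phase <- runif(1, 0, stride)
    pick <- avail[pmin(length(avail),
                       floor(phase + (seq_len(n_take) - 1) * stride) + 1L)]
    structure(lapply(pick, function(t)
      crop_tile(section, tiles$i[t], tiles$j[t], fpx)),
      n_available = length(avail), n_taken = n_take)
  })
}

#' Build an optical disector stack
#'
#' Pairs a reference section with a look-up section a height `h` above it
#' (along the plane normal) and records, for every particle in the slab,
#' its in-plane position relative to the reference field's lower-left
#' corner and its height above the reference plane. Counting itself is
#' performed by [nv_optical_disector()] under the standard rule: a
#' particle is scored when its counting point lies in `[0, h)` — in focus
#' strictly below the look-up plane, reference plane inclusive — and
#' falls inside the counting frame under the forbidden-line rule.
#'
#' @param volume a `label_volume` with seeded particles.
#' @param plane the reference `section_plane`.
#' @param h disector height (mm), `0 < h <=` block extent.
#' @param pixel_size pixel edge (mm).
#' @return An object of class `disector_stack`: `reference` and `lookup`
#'   `section_field`s sharing the lateral frame, `h`, and `particles`
#'   (`class`, `u`, `v` field-local, `height` in `[0, h)` flagged by
#'   `inside`).
#' @export
make_disector <- function(volume, plane, h, pixel_size = volume$voxel_size) {
  stopifnot(inherits(volume, "label_volume"),
            inherits(plane, "section_plane"))
  if (h <= 0) stop("disector height h must be > 0")
  if (h > max(volume$block)) stop("disector height exceeds the block extent")
  ref <- extract_section(volume, plane, pixel_size)
  lookup_plane <- section_plane(plane$normal, plane$offset + h,
                                plane$thickness, block = volume$block)
  # the look-up plane is a focal plane and may lie at or beyond the block
  # surface; it is then an empty field
  lookup <- tryCatch(extract_section(volume, lookup_plane, pixel_size),
                     error = function(e) section_field(
                       matrix(LAB_OUTSIDE, nrow(ref$labels),
                              ncol(ref$labels)),
                       pixel_size, plane = lookup_plane,
                       origin = ref$origin))
  n <- plane$normal
  p0 <- volume$block / 2 + plane$offset * n
  parts <- volume$particles
  if (nrow(parts) > 0) {
    pc <- as.matrix(parts[, c("x", "y", "z")])
    rel <- pc - rep(p0, each = nrow(pc))
    height <- drop(rel %*% n)
    keep <- height > -h & height < 2 * h   # slab neighborhood bookkeeping
    parts <- data.frame(class = parts$class[keep],
                        u = drop(rel[keep, , drop = FALSE] %*% plane$e1) -
                          ref$origin[1],
                        v = drop(rel[keep, , drop = FALSE] %*% plane$e2) -
                          ref$origin[2],
                        height = height[keep], stringsAsFactors = FALSE)
  } else {
    parts <- data.frame(class = character(0), u = numeric(0), v = numeric(0),
                        height = numeric(0), stringsAsFactors = FALSE)
  }
  parts$inside <- parts$height >= 0 & parts$height < h
  structure(list(reference = ref, lookup = lookup, h = h,
                 particles = parts), class = "disector_stack")
}

#' @export
print.disector_stack <- function(x, ...) {
  cat("Disector stack: h =", x$h, "mm;", sum(x$particles$inside),
      "particles inside the probe\n")
  invisible(x)
}
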