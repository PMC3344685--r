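#' Organ volume from fresh weight
#'
#' The prostate's specific gravity is taken as 1.0, so 1.0 mg of fresh
#' tissue corresponds to 1.0 mm^3: `Vt = weight * 1.0`.
#'
#' @param fresh_weight_mg fresh organ weight in mg (nonnegative).
#' @return Total organ volume Vt in mm^3.
#' @examples
#' volume_from_weight(423.08)  # 423.08 mm^3
#' @export
volume_from_weight <- function(fresh_weight_mg) {
  if (any(fresh_weight_mg < 0)) stop("fresh weight must be nonnegative")
  fresh_weight_mg * 1.0
}

#' Delesse area-fraction estimate of volume density
#'
#' By the Delesse principle the areal fraction of a compartment on a
#' uniform random section equals its volume fraction (A_A = V_V). The
#' estimate pools all fields by ratio of sums — total compartment pixel
#' area over total tissue pixel area — not as a mean of per-field ratios,
#' so fields with little tissue receive their proper weight.
#'
#' @param fields a `section_field` or list of them.
#' @param compartment label code or name (`"lumen"`, `"epithelium"`,
#'   `"stroma"`).
#' @return Volume density as a fraction in `[0, 1]`.
#' @export
vv_area_fraction <- function(fields, compartment) {
  if (inherits(fields, "section_field")) fields <- list(fields)
  code <- compartment_code(compartment)
  num <- 0; den <- 0
  for (f in fields) {
    num <- num + sum(f$labels == code)
    den <- den + sum(f$labels != LAB_OUTSIDE)
  }
  if (den == 0) stop("fields contain no tissue pixels")
  num / den
}

#' Absolute compartment volume from volume density
#'
#' `V = Vv(%) * Vt / 100`: the compartment volume is the volume density in
#' percent times the organ's total volume over 100.
#'
#' @param vv_percent volume density in percent, `[0, 100]`.
#' @param vt total organ volume (mm^3).
#' @return Compartment volume in mm^3.
#' @examples
#' absolute_volume(19.49, 260.24)  # 50.72 mm^3
#' @export
absolute_volume <- function(vv_percent, vt) {
  if (any(vv_percent < 0 | vv_percent > 100))
    stop("vv_percent must lie in [0, 100]")
  vv_percent * vt / 100
}

#' Unbiased counting frame
#'
#' A rectangular sampling frame with inclusion edges on the right and
#' upper sides and forbidden (exclusion) edges on the left and lower
#' sides plus their extensions: the left edge extends upward beyond the
#' frame and the forbidden line continues downward from the lower-right
#' corner. A profile is counted when it intersects the frame and touches
#' no forbidden line; profiles touching only inclusion edges are counted.
#' Under a contiguous tiling of frames every profile is counted exactly
#' once.
#'
#' @param origin numeric length-2, lower-left corner (mm), relative to the
#'   field's lower-left corner.
#' @param width,height frame dimensions (mm), positive.
#' @return An object of class `counting_frame`.
#' @export
counting_frame <- function(origin, width, height) {
  stopifnot(length(origin) == 2, width > 0, height > 0)
  structure(list(origin = origin, width = width, height = height,
                 area = width * height), class = "counting_frame")
}

# Frame rectangle in pixel indices of a field: columns cx0..cx1 (along
# rows of the label matrix) and rows cy0..cy1, for pixel centers inside
# the closed frame rectangle.
frame_pixels <- function(frame, pixel_size) {
  cx0 <- ceiling(frame$origin[1] / pixel_size + 0.5)
  cx1 <- floor((frame$origin[1] + frame$width) / pixel_size + 0.5)
  cy0 <- ceiling(frame$origin[2] / pixel_size + 0.5)
  cy1 <- floor((frame$origin[2] + frame$height) / pixel_size + 0.5)
  c(cx0 = cx0, cx1 = cx1, cy0 = cy0, cy1 = cy1)
}

#' Count glandular tubule profiles in an unbiased counting frame
#'
#' A tubule profile is recognized by its lumen: one connected lumen
#' region (8-connectivity) together with the epithelial ring around it
#' is one glandular transection. Counting lumen components is what makes
#' the rule work in gland-dense tissue, where the epithelium of
#' neighboring tubules fuses into a single connected mass; lumen-free
#' epithelial shavings (end-cap grazes, tangential cuts, digitization
#' fragments) are not glandular profiles and are never counted. A
#' profile is counted when its lumen has at least one pixel inside the
#' frame and no pixel on the forbidden line: the pixel column left of
#' the frame together with its upward extension, the pixel row below the
#' frame, and the downward extension at the frame's right edge. This
#' discrete rule reproduces the classical forbidden-line construction
#' and counts every profile exactly once under a contiguous frame
#' tiling.
#'
#' @param field a `section_field`.
#' @param frame a [counting_frame()] positioned in field-local mm.
#' @param min_lumen_area profile recognition threshold (mm^2): a
#'   component only qualifies as a glandular profile when its lumen area
#'   reaches this value. A transversal cut shows at least the minimal
#'   lumen cross-section `pi * r^2`, so half of that is a natural
#'   threshold separating true transections from end-cap grazes and
#'   digitization fragments; 0 (the default) disables the filter.
#' @return Integer profile count.
#' @export
profile_count <- function(field, frame, min_lumen_area = 0) {
  stopifnot(inherits(field, "section_field"),
            inherits(frame, "counting_frame"))
  profile_components(field, min_lumen_area)$count(frame)
}

# Label the lumen components of a field once and return a closure that
# counts them inside any counting frame under the forbidden-line rule;
# lets a whole tiling of frames reuse one component labeling.
profile_components <- function(field, min_lumen_area = 0) {
  lab <- field$labels
  bin <- (lab == LAB_LUMEN) + 0L
  comp <- cpp_label_components(as.integer(bin), nrow(bin), ncol(bin), 8L)
  dim(comp) <- dim(bin)
  min_px <- max(1, ceiling(min_lumen_area / field$pixel_size^2))
  sizes <- tabulate(comp[comp > 0])
  keep_ids <- which(sizes >= min_px)
  keep <- comp > 0 & matrix(comp %in% keep_ids, nrow(comp))
  on <- which(keep, arr.ind = TRUE)
  id <- comp[on]
  i <- on[, 1]; j <- on[, 2]
  ps <- field$pixel_size
  count <- function(frame) {
    if (length(id) == 0) return(0L)
    fp <- frame_pixels(frame, ps)
    in_frame <- i >= fp["cx0"] & i <= fp["cx1"] &
      j >= fp["cy0"] & j <= fp["cy1"]
    forbidden <-
      (i == fp["cx0"] - 1 & j >= fp["cy0"]) |
      (j == fp["cy0"] - 1 & i >= fp["cx0"] - 1 & i <= fp["cx1"]) |
      (i == fp["cx1"] + 1 & j <= fp["cy0"] - 1)
    length(setdiff(unique(id[in_frame]), unique(id[forbidden])))
  }
  list(count = count, n_components = length(unique(id)))
}

#' Length density from profile counts
#'
#' For isotropic uniform random sections the expected number of tubule
#' transections per unit sampled area Q_A relates to the length density of
#' the tubule axes by `Lv = 2 * Q_A`.
#'
#' @param q_a profiles per mm^2 of sampled frame area (nonnegative).
#' @return Length density Lv in mm^-2.
#' @examples
#' lv_from_qa(13.55)  # 27.10 mm^-2
#' @export
lv_from_qa <- function(q_a) {
  if (any(q_a < 0)) stop("q_a must be nonnegative")
  2 * q_a
}

#' Total tubule length from length density
#'
#' `L = Lv * Vt`, in mm. With `paper_scale = TRUE` the result is divided
#' by 1000 to match the reporting scale of the reference study's summary
#' table, whose printed lengths satisfy `L = Lv * Vt / 1000` (e.g.
#' 19.10 x 423.08 = 8081, printed 8.07). Internally all lengths stay in
#' mm; the flag only affects reporting.
#'
#' @param lv length density (mm^-2).
#' @param vt total organ volume (mm^3).
#' @param paper_scale divide by 1000 to mirror the published table.
#' @return Total length (mm, or mm/1000 on the reporting scale).
#' @examples
#' total_length(2, 10)                       # 20 mm
#' total_length(19.10, 423.08, paper_scale = TRUE)  # 8.08
#' @export
total_length <- function(lv, vt, paper_scale = FALSE) {
  if (any(lv < 0) || any(vt < 0)) stop("lv and vt must be nonnegative")
  out <- lv * vt
  if (paper_scale) out / 1000 else out
}

#' Cycloid test grid
#'
#' A grid of cycloid arcs tiling a rectangular field, with the minor axis
#' of every arc aligned with the section's vertical axis (the second,
#' column axis of a `section_field`). One full arch of a cycloid with
#' rolling-circle radius `r` spans `2*pi*r` horizontally, `2*r`
#' vertically, and has arc length `8*r`. Arcs are stored as polylines
#' resampled at equal arc-length steps, which the intercept counter and
#' test-line length measure share.
#'
#' @param width,height field dimensions (mm).
#' @param arc_radius rolling-circle radius `r` (mm).
#' @param spacing vertical distance between arch baselines (mm); default
#'   `3 * arc_radius`.
#' @param step arc-length sampling step (mm); default `arc_radius / 20`.
#' @return An object of class `cycloid_grid`: list of polylines
#'   (`data.frame(x, y)`), the sampling `step`, and `total_length` (mm)
#'   of arc inside the field.
#' @export
cycloid_grid <- function(width, height, arc_radius, spacing = 3 * arc_radius,
                         step = arc_radius / 20) {
  stopifnot(width > 0, height > 0, arc_radius > 0, spacing > 0, step > 0)
  r <- arc_radius
  # equal arc-length parameterization: s(t) = 4r(1 - cos(t/2)) on [0, 2pi]
  s <- seq(0, 8 * r, by = step)
  tt <- 2 * acos(pmax(-1, 1 - s / (4 * r)))
  x0 <- r * (tt - sin(tt))
  y0 <- r * (1 - cos(tt))
  arcs <- list()
  total <- 0
  ybase <- seq(0, height, by = spacing)
  for (yb in ybase) {
    xb <- seq(0, width, by = 2 * pi * r)
    for (x00 in xb) {
      x <- x00 + x0
      y <- yb + y0
      keep <- x >= 0 & x <= width & y >= 0 & y <= height
      if (sum(keep) < 2) next
      arcs[[length(arcs) + 1L]] <- data.frame(x = x[keep], y = y[keep])
      total <- total + (sum(keep) - 1) * step
    }
  }
  structure(list(arcs = arcs, step = step, arc_radius = r,
                 total_length = total), class = "cycloid_grid")
}

# Label sequence under a polyline, sampled at its vertices.
polyline_labels <- function(field, arc) {
  ps <- field$pixel_size
  i <- floor(arc$x / ps) + 1L
  j <- floor(arc$y / ps) + 1L
  ok <- i >= 1 & i <= nrow(field$labels) & j >= 1 & j <= ncol(field$labels)
  lab <- rep(LAB_OUTSIDE, nrow(arc))
  lab[ok] <- field$labels[cbind(i[ok], j[ok])]
  lab
}

#' Count cycloid test-line intercepts with a compartment boundary
#'
#' Samples the tissue label along every arc at the grid's equal
#' arc-length step and counts transversal crossings of the boundary
#' between the two compartments (default lumen|epithelium): each direct
#' transition between the pair counts once. Digitization noise is removed
#' by a crossing-parity rule: label runs shorter than `min_run`
#' (default one pixel of arc length) are discarded before transitions are
#' counted, so a jagged voxelized boundary grazed tangentially does not
#' generate spurious crossing pairs.
#'
#' @param field a `section_field`.
#' @param grid a [cycloid_grid()] laid over the field (field-local mm).
#' @param boundary length-2 vector of label codes or names.
#' @param min_run minimum run length (mm) for a label run to count as a
#'   real phase; default `field$pixel_size`.
#' @return Integer number of intercepts.
#' @export
cycloid_intercepts <- function(field, grid, boundary = c("lumen", "epithelium"),
                               min_run = field$pixel_size) {
  stopifnot(inherits(field, "section_field"), inherits(grid, "cycloid_grid"))
  pair <- sort(compartment_code(boundary))
  n_int <- 0L
  for (arc in grid$arcs) {
    lab <- polyline_labels(field, arc)
    r <- rle(lab)
    keep <- r$lengths * grid$step >= min_run
    vals <- r$values[keep]
    if (length(vals) < 2) next
    vals <- vals[c(TRUE, diff(vals) != 0)]   # merge repeats after filtering
    a <- vals[-length(vals)]; b <- vals[-1]
    n_int <- n_int + sum(pmin(a, b) == pair[1] & pmax(a, b) == pair[2])
  }
  n_int
}

#' Test-line length over a reference space
#'
#' Total arc length of a cycloid grid lying over pixels of the given
#' labels (default: all tissue), the denominator of the surface density
#' estimator.
#'
#' @param field a `section_field`.
#' @param grid a [cycloid_grid()].
#' @param labels label codes or names defining the reference space.
#' @return Length in mm.
#' @export
test_line_length <- function(field, grid, labels = c("lumen", "epithelium",
                                                     "stroma")) {
  codes <- compartment_code(labels)
  total <- 0
  for (arc in grid$arcs) {
    lab <- polyline_labels(field, arc)
    # each vertex after the first closes one step of arc length
    total <- total + sum(lab[-1] %in% codes) * grid$step
  }
  total
}

#' Surface density from cycloid intercepts
#'
#' The classical vertical-section estimator `Sv = 2 * I / L_T`, with `I`
#' the number of boundary intercepts and `L_T` the test-line length lying
#' over the reference space. When the test length was measured over a
#' wider space, `reference_area_fraction` rescales it.
#'
#' @param total_intercepts intercept count `I`.
#' @param total_test_length test-line length (mm) over the reference
#'   space.
#' @param reference_area_fraction fraction of the test length lying over
#'   the reference space (default 1).
#' @return Surface density Sv in mm^-1.
#' @export
sv_from_intercepts <- function(total_intercepts, total_test_length,
                               reference_area_fraction = 1) {
  lt <- total_test_length * reference_area_fraction
  if (lt <= 0) stop("total test-line length over the reference space is zero")
  2 * total_intercepts / lt
}

#' Total epithelial surface from surface density
#'
#' In `"paper"` mode, `S = Sv * Vt / 100`, mirroring the reference
#' study's reporting convention; the dimensionally standard `"standard"`
#' mode returns `S = Sv * Vt` (mm^2). The two differ by exactly 100x.
#'
#' @param sv surface density (mm^-1).
#' @param vt total organ volume (mm^3).
#' @param mode `"paper"` or `"standard"`.
#' @return Surface in the selected convention.
#' @export
epithelial_surface <- function(sv, vt, mode = c("paper", "standard")) {
  mode <- match.arg(mode)
  if (any(sv < 0) || any(vt < 0)) stop("sv and vt must be nonnegative")
  if (mode == "paper") sv * vt / 100 else sv * vt
}

#' Numerical density by the optical disector
#'
#' Scores every particle of the class whose counting point (the particle
#' position; particles are points) lies in focus strictly below the
#' look-up plane — height in `[0, h)` above the reference plane — and
#' inside the counting frame under the forbidden-line rule (inclusion
#' right/upper edges, exclusion left/lower edges), then divides by the
#' sampled reference volume: stroma area inside the frame on the
#' reference section times the disector height. A particle exactly in
#' focus at the look-up plane is never counted, so stacked disectors
#' count each particle exactly once.
#'
#' @param stack a [make_disector()] stack.
#' @param particle_class `"mast_cell"` or `"macrophage"`.
#' @param frame a [counting_frame()] in field-local mm; default covers
#'   the whole reference field.
#' @return Numerical density in particles per mm^3 of stroma; the raw
#'   count and sampled volume are attached as attributes `count` and
#'   `volume`.
#' @export
nv_optical_disector <- function(stack, particle_class = "mast_cell",
                                frame = NULL) {
  stopifnot(inherits(stack, "disector_stack"))
  ref <- stack$reference
  ps <- ref$pixel_size
  if (is.null(frame))
    frame <- counting_frame(c(0, 0), nrow(ref$labels) * ps,
                            ncol(ref$labels) * ps)
  if (stack$h <= 0) stop("disector height must be positive")
  p <- stack$particles
  sel <- p$class == particle_class & p$height >= 0 & p$height < stack$h &
    p$u > frame$origin[1] & p$u <= frame$origin[1] + frame$width &
    p$v > frame$origin[2] & p$v <= frame$origin[2] + frame$height
  count <- sum(sel)
  fp <- frame_pixels(frame, ps)
  ii <- max(1, fp["cx0"]):min(nrow(ref$labels), fp["cx1"])
  jj <- max(1, fp["cy0"]):min(ncol(ref$labels), fp["cy1"])
  stroma_area <- sum(ref$labels[ii, jj] == LAB_STROMA) * ps^2
  vol <- stroma_area * stack$h
  if (vol <= 0) stop("sampled reference volume is zero")
  structure(count / vol, count = count, volume = vol)
}

#' Assemble one animal's estimate record
#'
#' Bundles the raw counts and reference measures of one animal and
#' derives every reported quantity from them: total volume from fresh
#' weight, relative prostate weight (mg per 100 g body weight), pooled
#' volume densities and absolute compartment volumes, `Q_A`,
#' `Lv = 2 Q_A` and total length, `Sv = 2 I / L_T` and total surface,
#' and per-class disector numerical densities. Derived fields reproduce
#' exactly from the stored raw counts.
#'
#' @param animal_id identifier.
#' @param fresh_weight_mg prostate fresh weight (mg).
#' @param body_weight_g body weight (g).
#' @param compartment_areas named numeric, pooled pixel areas (mm^2) for
#'   `lumen`, `epithelium`, `stroma`.
#' @param profile_counts total profiles counted and `frame_area` sampled
#'   (mm^2), as `c(count = , area = )`.
#' @param intercepts total cycloid intercepts and `test_length` (mm) over
#'   tissue, as `c(count = , length = )`.
#' @param disector named list per particle class with `count` and
#'   `volume` (mm^3 of stroma sampled).
#' @param paper_scale report total length on the published table's scale.
#' @param surface_mode `"paper"` or `"standard"` for total surface.
#' @return An object of class `estimate_record` (a one-row data frame
#'   with the raw counts kept in attributes).
#' @export
build_estimate_record <- function(animal_id, fresh_weight_mg, body_weight_g,
                                  compartment_areas, profile_counts,
                                  intercepts, disector,
                                  paper_scale = TRUE,
                                  surface_mode = "paper") {
  need <- c("lumen", "epithelium", "stroma")
  if (!all(need %in% names(compartment_areas)))
    stop("incomplete sampling: compartment areas must name ",
         paste(need, collapse = ", "))
  for (nm in c("count", "area")) if (!nm %in% names(profile_counts))
    stop("incomplete sampling: profile_counts lacks '", nm, "'")
  for (nm in c("count", "length")) if (!nm %in% names(intercepts))
    stop("incomplete sampling: intercepts lacks '", nm, "'")
  vt <- volume_from_weight(fresh_weight_mg)
  tissue <- sum(compartment_areas[need])
  vv <- compartment_areas[need] / tissue
  qa <- unname(profile_counts["count"] / profile_counts["area"])
  lv <- lv_from_qa(qa)
  sv <- sv_from_intercepts(unname(intercepts["count"]),
                           unname(intercepts["length"]))
  nv <- vapply(disector, function(d) d$count / d$volume, numeric(1))
  rec <- data.frame(animal_id = animal_id,
                    weight_mg = fresh_weight_mg,
                    body_weight_g = body_weight_g,
                    relative_weight = fresh_weight_mg / body_weight_g * 100,
                    vt = vt,
                    vv_lumen = unname(vv["lumen"]),
                    vv_epithelium = unname(vv["epithelium"]),
                    vv_stroma = unname(vv["stroma"]),
                    v_lumen = absolute_volume(100 * unname(vv["lumen"]), vt),
                    v_epithelium = absolute_volume(100 * unname(vv["epithelium"]), vt),
                    v_stroma = absolute_volume(100 * unname(vv["stroma"]), vt),
                    q_a = qa, lv = lv,
                    l_total = total_length(lv, vt, paper_scale = paper_scale),
                    sv = sv,
                    s_total = epithelial_surface(sv, vt, mode = surface_mode),
                    stringsAsFactors = FALSE)
  for (cl in names(nv)) rec[[paste0("nv_", cl)]] <- unname(nv[cl])
  structure(rec,
            raw = list(compartment_areas = compartment_areas,
                       profile_counts = profile_counts,
                       intercepts = intercepts, disector = disector),
            class = c("estimate_record", "data.frame"))
}

#' Write or read estimate records as CSV
#'
#' Records round-trip unchanged through a plain CSV; a JSON sidecar
#' (`<path>.json`) documents the column units.
#'
#' @param records a data frame of estimate records (rows bound together).
#' @param path CSV file path.
#' @return `read_estimate_records` returns the data frame.
#' @export
write_estimate_records <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  units <- list(weight_mg = "mg", body_weight_g = "g",
                relative_weight = "mg/100g", vt = "mm^3",
                vv = "fraction", v = "mm^3", q_a = "mm^-2", lv = "mm^-2",
                l_total = "mm (or mm/1000 on the reporting scale)",
                sv = "mm^-1", s_total = "Sv*Vt/100 (paper mode)",
                nv = "mm^-3 of stroma")
  jsonlite::write_json(units, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_estimate_records
#' @export
read_estimate_records <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
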