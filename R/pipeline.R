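#' Study configuration
#'
#' Bundles everything needed to simulate and analyze a full cohort study:
#' the six-group design (three ages x control/CBZ, five animals per
#' group), per-group generative parameters, the sampling effort of the
#' stereological workup, and reporting flags. Defaults reproduce the
#' published reference study: weights, length densities and 93-day
#' volume densities come from [reference_tables()]; volume densities for
#' the unpublished 43- and 63-day ages reuse the 93-day control triple
#' (no compartment alterations were reported at those ages); particle
#' densities and nuclear transmittances are synthetic defaults chosen to
#' mirror the reported direction of the mast-cell, macrophage and
#' androgen-receptor findings. Hormone levels are annotation columns
#' only — they parameterize nothing mechanistic.
#'
#' @param groups optional data frame overriding the per-group generative
#'   parameters (see the default for the required columns).
#' @param n_animals animals per group.
#' @param block_edge phantom block edge (mm); the per-animal phantom is a
#'   sampled tissue block, not the whole organ.
#' @param voxel_size phantom voxel edge (mm).
#' @param tubule_length target centerline length per tubule (mm); the
#'   per-animal length is adjusted so tubule count times length matches
#'   the animal's drawn length density exactly. Long wrapped tubules
#'   keep the density of gland ends — the one geometric bias of profile
#'   counting — low.
#' @param sections_per_animal IUR sections cut per animal.
#' @param fields_per_section systematic fields per section for the
#'   Delesse estimate.
#' @param field_edge Delesse field edge (mm).
#' @param frame_edge unbiased counting frame edge (mm) for profile
#'   counting.
#' @param cycloid_radius cycloid rolling-circle radius (mm).
#' @param disector_height optical disector height (mm).
#' @param disectors_per_animal number of IUR disector stacks sampled per
#'   animal; enough stacks are needed for the sampled stroma volume to
#'   collect a usable particle count.
#' @param section_thickness physical section thickness (mm).
#' @param nuclei_per_animal nuclei rendered per animal for densitometry.
#' @param nuclei_per_group nuclei scored per group (IOD).
#' @param paper_scale report total length on the published scale.
#' @param surface_mode `"paper"` or `"standard"` total surface.
#' @param rng_seed master seed; every stage derives its own stream.
#' @return An object of class `study_config`.
#' @export
study_config <- function(groups = NULL,
                         n_animals = 5L,
                         block_edge = 0.8,
                         voxel_size = 0.008,
                         tubule_length = 3,
                         sections_per_animal = 2L,
                         fields_per_section = 22L,
                         field_edge = 0.15,
                         frame_edge = 0.2,
                         cycloid_radius = 0.03,
                         disector_height = 0.06,
                         disectors_per_animal = 12L,
                         section_thickness = 0.005,
                         nuclei_per_animal = 30L,
                         nuclei_per_group = 100L,
                         paper_scale = TRUE,
                         surface_mode = "paper",
                         rng_seed = 1L) {
  if (is.null(groups)) {
    ref <- reference_tables()
    m <- ref$morphometry
    v93 <- ref$volumes
    vv_of <- function(group, comp) {
      v93$vv_mean[v93$group == group & v93$compartment == comp]
    }
    groups <- data.frame(
      group = m$group, age = m$age, treatment = m$treatment,
      weight_mean = m$weight_mean, weight_sd = m$weight_sd,
      body_weight = m$weight_mean / m$rel_weight_mean * 100,
      lv_mean = m$lv_mean, lv_sd = m$lv_sd,
      stringsAsFactors = FALSE)
    # Vv triples: published for the 93-day groups only
    groups$vv_lumen <- ifelse(groups$group == "CBZ93",
                              vv_of("CBZ93", "lumen"), vv_of("C93", "lumen"))
    groups$vv_epithelium <- ifelse(groups$group == "CBZ93",
                                   vv_of("CBZ93", "epithelium"),
                                   vv_of("C93", "epithelium"))
    groups$vv_lumen_sd <- ifelse(groups$group == "CBZ93", 6.67, 9.40)
    groups$vv_epithelium_sd <- ifelse(groups$group == "CBZ93", 4.68, 5.90)
    # Synthetic stromal cell intensities (per mm^3 of stroma), mirroring
    # the reported directions: mast cells raised in CBZ63/CBZ93,
    # macrophages raised in CBZ63 and depressed in CBZ93.
    groups$nv_mast_cell <- c(150, 180, 150, 300, 200, 350)
    groups$nv_macrophage <- c(100, 120, 100, 220, 200, 90)
    # Nuclear transmittance: CBZ93 nuclei transmit twice the light of
    # controls (weaker androgen-receptor staining, lower IOD).
    groups$transmittance <- c(0.35, 0.35, 0.35, 0.35, 0.35, 0.70)
    h <- ref$hormones
    groups$testosterone_mean <- h$testosterone_mean
    groups$testosterone_sd <- h$testosterone_sd
    groups$estradiol_mean <- h$estradiol_mean
    groups$estradiol_sd <- h$estradiol_sd
  }
  stopifnot(!anyDuplicated(groups$group), n_animals >= 2,
            all(groups$weight_sd >= 0), all(groups$lv_sd >= 0))
  structure(list(groups = groups, n_animals = as.integer(n_animals),
                 block_edge = block_edge, voxel_size = voxel_size,
                 tubule_length = tubule_length,
                 sections_per_animal = as.integer(sections_per_animal),
                 fields_per_section = as.integer(fields_per_section),
                 field_edge = field_edge, frame_edge = frame_edge,
                 cycloid_radius = cycloid_radius,
                 disector_height = disector_height,
                 disectors_per_animal = as.integer(disectors_per_animal),
                 section_thickness = section_thickness,
                 nuclei_per_animal = as.integer(nuclei_per_animal),
                 nuclei_per_group = as.integer(nuclei_per_group),
                 paper_scale = paper_scale, surface_mode = surface_mode,
                 rng_seed = as.integer(rng_seed)),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study config:", nrow(x$groups), "groups x", x$n_animals,
      "animals; seed", x$rng_seed, "; hash", config_hash(x), "\n")
  invisible(x)
}

# Truncated normal draw by rejection (light tails, few retries needed).
rnorm_trunc <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- out < lower
  tries <- 0
  while (any(bad) && tries < 100) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lower
    tries <- tries + 1
  }
  pmax(out, lower)
}

#' Simulate a cohort of animals and their phantom specifications
#'
#' Draws per-animal generative values (normal weight, volume densities,
#' length density, hormone annotations) for every group and instantiates
#' a phantom specification per animal. Tubule radii are solved from the
#' animal's target volume fractions and length density with an overlap
#' correction: for Poisson-distributed tubule axes the nearest-axis
#' distance satisfies `P(D <= d) = 1 - exp(-Lv pi d^2)`, which is
#' inverted for the lumen and outer radii so the realized (overlapping)
#' compartment fractions track the gland-dense targets. The tubule count
#' and per-animal length are chosen so `count * length / volume` equals
#' the drawn length density exactly. Fully reproducible from the config
#' seed.
#'
#' @param config a [study_config()].
#' @return List with `frame` (the cohort data frame, one row per animal)
#'   and `specs` (list of [phantom_spec()], one per animal, same order).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "study_config"))
  g <- config$groups
  n <- config$n_animals
  block <- rep(config$block_edge, 3)
  rows <- list(); specs <- list()
  with_seed(config$rng_seed, {
    for (k in seq_len(nrow(g))) {
      weight <- rnorm_trunc(n, g$weight_mean[k], g$weight_sd[k], 5)
      vv_lu <- rnorm_trunc(n, g$vv_lumen[k], g$vv_lumen_sd[k], 5) / 100
      vv_ep <- rnorm_trunc(n, g$vv_epithelium[k], g$vv_epithelium_sd[k],
                           5) / 100
      scale_vv <- pmin(1, 0.85 / (vv_lu + vv_ep))  # keep some stroma
      vv_lu <- vv_lu * scale_vv; vv_ep <- vv_ep * scale_vv
      lv <- rnorm_trunc(n, g$lv_mean[k], g$lv_sd[k], 5)
      testo <- rnorm(n, g$testosterone_mean[k], g$testosterone_sd[k])
      estra <- rnorm(n, g$estradiol_mean[k], g$estradiol_sd[k])
      for (a in seq_len(n)) {
        id <- sprintf("%s_%d", g$group[k], a)
        # Overlap-corrected packing. For a Poisson process of tubule
        # axes with length density lv, the distance from a point to the
        # nearest axis satisfies P(D <= d) = 1 - exp(-lv * pi * d^2), and
        # under the nearest-centerline labeling the point is lumen when
        # D <= r_lu and glandular when D <= r_out. Inverting gives the
        # radii that realize the target volume fractions at gland-dense
        # packing where tubules overlap heavily.
        v_tot <- min(0.85, vv_lu[a] + vv_ep[a])
        v_lu <- min(vv_lu[a], v_tot - 0.01)
        r_out <- sqrt(-log(1 - v_tot) / (pi * lv[a]))
        r_lu <- sqrt(-log(1 - v_lu) / (pi * lv[a]))
        # the Poisson-line inversion needs several well-mixed tubules and
        # tubules much narrower than the block; cap the outer radius and
        # floor the count, preserving the lumen share and exact lv
        if (r_out > 0.22 * min(block)) {
          shrink <- 0.22 * min(block) / r_out
          r_out <- r_out * shrink
          r_lu <- r_lu * shrink
        }
        count <- max(4L, as.integer(ceiling(
          lv[a] * prod(block) / config$tubule_length)))
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, group = g$group[k], age = g$age[k],
          treatment = g$treatment[k], weight = weight[a],
          body_weight = g$body_weight[k],
          testosterone = testo[a], estradiol = estra[a],
          transmittance = g$transmittance[k],
          target_vv_lumen = vv_lu[a], target_vv_epithelium = vv_ep[a],
          target_lv = lv[a], r_lu = r_lu, r_out = r_out,
          target_nv_mast_cell = g$nv_mast_cell[k],
          target_nv_macrophage = g$nv_macrophage[k],
          stringsAsFactors = FALSE)
        # per-animal tubule length adjusted so count * L / V equals the
        # drawn target lv exactly; long tubules keep the density of
        # gland ends (the one geometric bias of profile counting) low
        specs[[length(specs) + 1L]] <- phantom_spec(
          block_edge_lengths = block, voxel_size = config$voxel_size,
          tubule_count = count, tubule_lumen_radius = r_lu,
          epithelium_thickness = r_out - r_lu,
          tubule_length = lv[a] * prod(block) / count,
          rng_seed = child_seed(config$rng_seed, 1000 + length(specs)))
      }
    }
  })
  frame <- do.call(rbind, rows)
  rownames(frame) <- NULL
  list(frame = frame, specs = specs)
}

# Q_A measurement on one whole section: a complete tiling of unbiased
# counting frames covers the section (profiles stay labeled on the full
# section, so the forbidden-line rule sees profile parts beyond each
# frame and every profile is counted exactly once across the tiling).
# The denominator is the delineated tissue area within the frames —
# profiles per unit tissue area — since frame area falling outside the
# tissue contains no glands and would deflate Q_A.
qa_section <- function(section, frame_edge, rng_seed = 1L,
                       min_lumen_area = 0) {
  ps <- section$pixel_size
  fpx <- max(1L, as.integer(round(frame_edge / ps)))
  dimx <- nrow(section$labels); dimy <- ncol(section$labels)
  tiles <- with_seed(rng_seed, {
    si <- 2L - sample.int(fpx, 1)
    sj <- 2L - sample.int(fpx, 1)
    tile_indices(dimx, dimy, fpx, si, sj)
  })
  pc <- profile_components(section, min_lumen_area)
  count <- 0L; area <- 0
  for (t in seq_len(nrow(tiles))) {
    i0 <- tiles$i[t]; j0 <- tiles$j[t]
    ii <- max(1, i0):min(dimx, i0 + fpx - 1)
    jj <- max(1, j0):min(dimy, j0 + fpx - 1)
    tissue <- sum(section$labels[ii, jj] != LAB_OUTSIDE)
    if (tissue == 0) next
    fr <- counting_frame(c((i0 - 1) * ps, (j0 - 1) * ps),
                         fpx * ps, fpx * ps)
    count <- count + pc$count(fr)
    area <- area + tissue * ps^2
  }
  c(count = count, area = area)
}

#' Run the full simulated study
#'
#' End-to-end driver in the study's order: simulate the cohort, build and
#' seed each animal's phantom, cut IUR sections, sample systematic
#' fields, apply every estimator (Delesse volume densities, profile
#' counts in tissue-filled counting frames, cycloid intercepts, optical
#' disectors), assemble per-animal estimate records, run the
#' densitometry arm, and compute group summaries and the statistical
#' layer. Deterministic under the config seed.
#'
#' @param config a [study_config()].
#' @param progress print per-animal progress to stderr.
#' @return An object of class `study_report`; see [report_markdown()].
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  sim <- simulate_cohort(config)
  frame <- sim$frame
  recs <- list()
  for (a in seq_len(nrow(frame))) {
    if (progress) message("animal ", frame$animal_id[a])
    seed_a <- child_seed(config$rng_seed, 2000 + a)
    vol <- build_phantom(sim$specs[[a]])
    vol <- seed_particles(vol,
                          c(mast_cell = frame$target_nv_mast_cell[a],
                            macrophage = frame$target_nv_macrophage[a]),
                          rng_seed = child_seed(seed_a, 1))
    areas <- c(lumen = 0, epithelium = 0, stroma = 0)
    qa <- c(count = 0, area = 0)
    icpt <- c(count = 0, length = 0)
    dis <- list(mast_cell = list(count = 0, volume = 0),
                macrophage = list(count = 0, volume = 0))
    s <- 0L
    repeat {
      s <- s + 1L
      # sample the planned number of sections, continuing (up to 4x)
      # while any probe has still sampled no tissue at all
      if (s > config$sections_per_animal) {
        complete <- qa["area"] > 0 && icpt["length"] > 0
        if (complete || s > 4L * config$sections_per_animal) break
      }
      seed_s <- child_seed(seed_a, 10 + s)
      ss <- iur_section(vol, rng_seed = seed_s,
                        thickness = config$section_thickness)
      plane <- ss$plane
      sec <- ss$section
      ps <- sec$pixel_size
      fields <- tryCatch(
        systematic_fields(sec, config$fields_per_section,
                          config$field_edge,
                          rng_seed = child_seed(seed_s, 1),
                          allow_fewer = TRUE),
        error = function(e) stop("sampling stage failed for ",
                                 frame$animal_id[a], ": ",
                                 conditionMessage(e)))
      w_ht <- attr(fields, "n_available") / attr(fields, "n_taken")
      for (f in fields) for (cp in names(areas))
        areas[cp] <- areas[cp] +
          w_ht * sum(f$labels == compartment_code(cp)) * ps^2
      # in gland-dense tissue lumen patches are eroded by neighboring
      # glands, so profile recognition uses a lenient speckle filter
      # (4 px) rather than the sparse-tissue half-disc threshold
      qa <- qa + qa_section(sec, config$frame_edge,
                            rng_seed = child_seed(seed_s, 2),
                            min_lumen_area = 4 * ps^2)
      grid <- cycloid_grid(nrow(sec$labels) * ps, ncol(sec$labels) * ps,
                           config$cycloid_radius)
      icpt["count"] <- icpt["count"] + cycloid_intercepts(sec, grid)
      icpt["length"] <- icpt["length"] + test_line_length(sec, grid)
    }
    # dedicated IUR disector stacks (decoupled from the section planes)
    for (k in seq_len(config$disectors_per_animal)) {
      seed_k <- child_seed(seed_a, 500 + k)
      plane <- iur_section(vol, rng_seed = seed_k,
                           thickness = config$section_thickness)$plane
      stk <- make_disector(vol, plane, config$disector_height)
      for (cl in names(dis)) {
        # a stack may sample no stroma at all; it contributes nothing
        nv <- tryCatch(nv_optical_disector(stk, cl),
                       error = function(e) NULL)
        if (!is.null(nv)) {
          dis[[cl]]$count <- dis[[cl]]$count + attr(nv, "count")
          dis[[cl]]$volume <- dis[[cl]]$volume + attr(nv, "volume")
        }
      }
    }
    recs[[a]] <- build_estimate_record(
      frame$animal_id[a], frame$weight[a], frame$body_weight[a],
      compartment_areas = areas, profile_counts = qa, intercepts = icpt,
      disector = dis, paper_scale = config$paper_scale,
      surface_mode = config$surface_mode)
  }
  records <- do.call(rbind, lapply(recs, as.data.frame))
  records$group <- frame$group
  records$age <- frame$age
  records$treatment <- frame$treatment

  # densitometry arm: one rendered image per animal, pooled per group
  images <- lapply(split(seq_len(nrow(frame)), frame$group), function(idx) {
    lapply(idx, function(a)
      render_nuclei_image(n_nuclei = config$nuclei_per_animal,
                          transmittance = frame$transmittance[a],
                          rng_seed = child_seed(config$rng_seed, 3000 + a)))
  })
  rois <- sample_nuclei(images,
                        n_per_group = min(config$nuclei_per_group,
                                          config$n_animals *
                                            config$nuclei_per_animal),
                        rng_seed = child_seed(config$rng_seed, 4000))
  iod <- iod_group_summary(rois)

  endpoints <- c("weight_mg", "vt", "vv_lumen", "vv_epithelium",
                 "vv_stroma", "v_lumen", "v_epithelium", "v_stroma",
                 "lv", "l_total", "sv", "s_total",
                 "nv_mast_cell", "nv_macrophage")
  anova <- NULL
  if (length(unique(records$treatment)) >= 2 &&
      length(unique(records$age)) >= 2) {
    anova <- lapply(endpoints, function(e)
      two_way_anova(records, e, "treatment", "age"))
    names(anova) <- endpoints
  }
  pairwise <- list()
  for (age in unique(records$age)) {
    ctl <- records[records$age == age & records$treatment == "control", ]
    cbz <- records[records$age == age & records$treatment != "control", ]
    for (e in endpoints) {
      tt <- student_t(ctl[[e]], cbz[[e]])
      mw <- mann_whitney(ctl[[e]], cbz[[e]])
      pairwise[[length(pairwise) + 1L]] <- data.frame(
        age = age, endpoint = e, t = tt$statistic, p_t = tt$p,
        u = mw$statistic, p_mw = mw$p,
        significant = tt$p <= 0.05, stringsAsFactors = FALSE)
    }
  }
  pairwise <- do.call(rbind, pairwise)

  tabs <- list(
    morphometry = make_group_table(records, c("weight_mg",
                                              "relative_weight", "vt",
                                              "lv", "l_total")),
    volumes = make_group_table(records, c("vv_lumen", "vv_epithelium",
                                          "vv_stroma", "v_lumen",
                                          "v_epithelium", "v_stroma")),
    surfaces = make_group_table(records, c("sv", "s_total")),
    particles = make_group_table(records, c("nv_mast_cell",
                                            "nv_macrophage")),
    iod = iod)
  structure(list(config = config, seed = config$rng_seed,
                 hash = config_hash(config), cohort = frame,
                 records = records, tables = tabs, anova = anova,
                 pairwise = pairwise),
            class = "study_report")
}

make_group_table <- function(records, endpoints) {
  groups <- unique(records$group)
  out <- data.frame(group = groups, stringsAsFactors = FALSE)
  for (e in endpoints) {
    gs <- group_summary(records, e)
    out[[e]] <- sprintf("%.2f ± %.2f",
                        gs$mean[match(groups, gs$group)],
                        gs$sd[match(groups, gs$group)])
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (seed", x$seed, ", config", x$hash, ")\n")
  cat("Mean ± SD; n =", x$config$n_animals, "per group\n\n")
  cat("Morphometry:\n")
  print(x$tables$morphometry, row.names = FALSE)
  cat("\nVolume densities and volumes:\n")
  print(x$tables$volumes, row.names = FALSE)
  cat("\nNumerical densities (per mm^3 stroma):\n")
  print(x$tables$particles, row.names = FALSE)
  cat("\nIOD:\n")
  print(x$tables$iod, row.names = FALSE)
  invisible(x)
}

#' Render a study report as Markdown
#'
#' @param report a `study_report`.
#' @param path optional file to write to.
#' @return Character vector of Markdown lines, invisibly when written.
#' @export
report_markdown <- function(report, path = NULL) {
  md_table <- function(df) {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r)
      paste0("| ", paste(format(r, trim = TRUE), collapse = " | "), " |"))
    c(hdr, sep, rows)
  }
  lines <- c(paste("# Simulated stereology study (seed", report$seed,
                   ", config", report$hash, ")"), "",
             paste("Mean ± SD; n =", report$config$n_animals,
                   "per group."), "",
             "## Morphometry", md_table(report$tables$morphometry), "",
             "## Volume densities and compartment volumes",
             md_table(report$tables$volumes), "",
             "## Epithelial surface", md_table(report$tables$surfaces), "",
             "## Stromal cell numerical densities",
             md_table(report$tables$particles), "",
             "## Integrated optical density",
             md_table(report$tables$iod), "",
             "## Pairwise control vs CBZ tests",
             md_table(report$pairwise))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Detection power for a group contrast by repeated simulation
#'
#' Repeatedly draws the cohort's generative endpoint values (no phantom
#' sampling: the endpoint is drawn directly from its group law, as the
#' fresh weight is in the full pipeline) and applies the pooled t test to
#' one control/treated pair, returning the fraction of simulated studies
#' in which the contrast is significant at p <= 0.05.
#'
#' @param config a [study_config()].
#' @param pair length-2 group labels to contrast.
#' @param endpoint generative endpoint; currently `"weight"`.
#' @param n_studies number of simulated studies.
#' @param rng_seed integer seed.
#' @return Fraction in `[0, 1]`, with attribute `n` = `n_studies`.
#' @export
simulated_power <- function(config, pair = c("C93", "CBZ93"),
                            endpoint = "weight", n_studies = 200L,
                            rng_seed = 1L) {
  stopifnot(inherits(config, "study_config"), endpoint == "weight")
  g <- config$groups
  ga <- g[g$group == pair[1], ]; gb <- g[g$group == pair[2], ]
  stopifnot(nrow(ga) == 1, nrow(gb) == 1)
  n <- config$n_animals
  hits <- with_seed(rng_seed, {
    sum(vapply(seq_len(n_studies), function(k) {
      a <- rnorm_trunc(n, ga$weight_mean, ga$weight_sd, 5)
      b <- rnorm_trunc(n, gb$weight_mean, gb$weight_sd, 5)
      student_t(a, b)$p <= 0.05
    }, logical(1)))
  })
  structure(hits / n_studies, n = n_studies)
}
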