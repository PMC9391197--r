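# mean-one lognormal multipliers with a given coefficient of variation
rln1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Parameters of the deterministic toe template
#'
#' A toe configuration is generated along a vertical midline: the toe base
#' (midpoint of LM1/LM2) at the origin, the pad starting `proximal_len_mm`
#' up the midline, the widest points (LM5/LM6) `pad_width_mm` apart at
#' `widest_point_fraction` along the pad, the pad ending at
#' `proximal_len_mm + pad_len_mm`, and the claw base (LM9) a further
#' `distal_len_mm` up. The five landmarked lamellae are horizontal rows
#' `lamella_spacing_mm` apart, the first `lamella_start_fraction` of the
#' pad length below the distal pad end. `outline_bulge` (mm) bows the
#' outline curves outward and the lamella free edges distad.
#'
#' @param proximal_len_mm,pad_len_mm,pad_width_mm,distal_len_mm Segment
#'   lengths in mm.
#' @param widest_point_fraction Position of LM5/LM6 along the pad (0-1).
#' @param lamella_start_fraction Distance of the first lamella row from
#'   the distal pad end, as a fraction of pad length.
#' @param lamella_spacing_mm Distance between adjacent lamella rows.
#' @param outline_bulge Curve bow amplitude in mm.
#' @return A `toe_template_params` list.
#' @export
toe_template_params <- function(proximal_len_mm = 6.63, pad_len_mm = 3.20,
                                pad_width_mm = 1.69, distal_len_mm = 2.0,
                                widest_point_fraction = 0.55,
                                lamella_start_fraction = 0.18,
                                lamella_spacing_mm = 0.15,
                                outline_bulge = 0.08) {
  p <- list(proximal_len_mm = proximal_len_mm, pad_len_mm = pad_len_mm,
            pad_width_mm = pad_width_mm, distal_len_mm = distal_len_mm,
            widest_point_fraction = widest_point_fraction,
            lamella_start_fraction = lamella_start_fraction,
            lamella_spacing_mm = lamella_spacing_mm,
            outline_bulge = outline_bulge)
  lens <- unlist(p[1:4])
  if (any(!is.finite(unlist(p))) || any(lens <= 0)) {
    abort("All template lengths must be positive and finite.")
  }
  if (widest_point_fraction <= 0 || widest_point_fraction >= 1 ||
      lamella_start_fraction <= 0 || lamella_start_fraction >= 1) {
    abort("Fractions must lie strictly in (0, 1).")
  }
  structure(p, class = "toe_template_params")
}

#' Build the deterministic toe configuration for a parameter set
#'
#' @param params A [toe_template_params()] list.
#' @param scheme A `toe_scheme`.
#' @return An unstripped `toe_config` (side `"left"`, coordinates in mm)
#'   whose linear measurements reproduce the parameters exactly: pad width
#'   and length, proximal length, and lamella height equal the requested
#'   values, and curve endpoints coincide with their anchors.
#' @export
build_template <- function(params, scheme = toe_scheme()) {
  w <- params$pad_width_mm
  pl <- params$pad_len_mm
  pr <- params$proximal_len_mm
  dl <- params$distal_len_mm
  s <- params$lamella_spacing_mm
  y1 <- pr + pl * (1 - params$lamella_start_fraction)
  ys <- y1 - (0:4) * s
  if (min(ys) <= pr) {
    abort("Lamella rows do not fit inside the pad (reduce spacing or start fraction).")
  }
  lm <- matrix(NA_real_, 19L, 2L)
  lm[1L, ] <- c(-0.25 * w, 0); lm[2L, ] <- c(0.25 * w, 0)
  lm[3L, ] <- c(-0.275 * w, pr); lm[4L, ] <- c(0.275 * w, pr)
  lm[5L, ] <- c(-0.5 * w, pr + params$widest_point_fraction * pl)
  lm[6L, ] <- c(0.5 * w, pr + params$widest_point_fraction * pl)
  lm[7L, ] <- c(-0.3 * w, pr + pl); lm[8L, ] <- c(0.3 * w, pr + pl)
  lm[9L, ] <- c(0, pr + pl + dl)
  left_idx <- c(10L, 12L, 14L, 16L, 18L)
  right_idx <- c(11L, 13L, 15L, 17L, 19L)
  lm[left_idx, ] <- cbind(-0.42 * w, ys)
  lm[right_idx, ] <- cbind(0.42 * w, ys)

  curve_pts <- function(a, b, n, amp, toward) {
    t <- seq(0, 1, length.out = n)
    base <- outer(1 - t, a) + outer(t, b)
    chord <- b - a
    nrm <- c(-chord[2L], chord[1L]) / sqrt(sum(chord^2))
    if (sum(nrm * toward) < 0) nrm <- -nrm
    out <- base + outer(sin(pi * t) * amp, nrm)
    out[1L, ] <- a; out[n, ] <- b
    out
  }
  curves <- vector("list", nrow(scheme$curves))
  for (i in seq_len(nrow(scheme$curves))) {
    a <- lm[scheme$curves$from[i], ]
    b <- lm[scheme$curves$to[i], ]
    if (scheme$curves$role[i] == "toe_outline") {
      mid_x <- (a[1L] + b[1L]) / 2
      curves[[i]] <- curve_pts(a, b, scheme$curves$n_raw[i],
                               params$outline_bulge,
                               toward = c(sign(mid_x + 1e-12), 0))
    } else {
      curves[[i]] <- curve_pts(a, b, scheme$curves$n_raw[i],
                               0.4 * params$outline_bulge, toward = c(0, 1))
    }
  }
  structure(list(specimen_id = "template", fixed = lm, curves = curves,
                 side = "left", mirrored = FALSE, stripped = FALSE),
            class = "toe_config")
}

#' Bend a toe configuration about its base
#'
#' The dominant nuisance in scanned toe images is how straight the toe lay
#' at imaging time. This applies a smooth constant-curvature bend: every
#' point at height y above the toe base is rotated by `curvature * y`
#' radians (about the instantaneous bending centre), which maps the
#' midline onto a circular arc and preserves its arc length exactly.
#' `curvature = 0` is the identity; applying `-curvature` afterwards
#' restores the original configuration to first order in the curvature.
#'
#' @param config A `toe_config` (template orientation: midline vertical,
#'   base at the LM1/LM2 midpoint).
#' @param curvature Signed curvature in radians per mm; positive bends
#'   toward +x.
#' @return The bent configuration.
#' @export
apply_bend <- function(config, curvature) {
  stopifnot_scalar_number(curvature, "curvature")
  if (curvature == 0) return(config)
  base <- (config$fixed[1L, ] + config$fixed[2L, ]) / 2
  extent <- max(abs(config_points(config)[, 2L] - base[2L]))
  if (abs(curvature) * extent > 1) {
    abort("Curvature too extreme for the toe extent (injectivity lost).")
  }
  r <- 1 / curvature
  bend <- function(m) {
    x <- m[, 1L] - base[1L]
    y <- m[, 2L] - base[2L]
    theta <- curvature * y
    cbind(base[1L] + r - (r - x) * cos(theta),
          base[2L] + (r - x) * sin(theta))
  }
  config$fixed <- bend(config$fixed)
  config$curves <- purrr::map(config$curves, bend)
  config
}

# per-habitat calibration: printed group means (and sds where printed) of
# the five landmark-derived traits, plus defaults for quantities the
# study does not print (distal segment, SVL, spread of proximal length
# and lamella spacing, which reuse the pad-length coefficient of
# variation)
habitat_calibration <- function() {
  tibble(
    habitat = c("urban", "forest"),
    pad_width = c(1.86, 1.69), pad_width_sd = c(0.28, 0.27),
    pad_len = c(3.61, 3.20), pad_len_sd = c(0.47, 0.43),
    proximal = c(7.01, 6.63),
    distal = c(2.1, 2.0),
    spacing = c(0.17, 0.15),
    count_mean = c(22.44, 21.87), count_sd = c(1.3, 1.5),
    svl_mean = c(58, 55), svl_sd = c(5, 5)
  )
}

#' Specification of a synthetic toe population
#'
#' Defines the sampling design the generator draws from: two habitats
#' crossed with five municipalities, 13-20 specimens per cell by default,
#' per-cell trait means, a shared per-specimen size factor (lognormal)
#' plus trait-specific lognormal spread matched by moments to the printed
#' raw-scale standard deviations, fixed-sign municipality offsets of
#' about 3 percent on all lengths, a random toe-curvature nuisance, and
#' per-point digitization noise.
#'
#' `paper_population_spec()` uses the study's printed group means as the
#' habitat effects; `null_population_spec()` gives both habitats the
#' pooled means (all effects zeroed) for calibration runs.
#'
#' @param n_per_cell Specimens per habitat x municipality cell: a single
#'   number, a vector of 10, or `NULL` to draw 13-20 at random at
#'   sampling time.
#' @param n_total Alternatively, a total sample size distributed evenly
#'   across the 10 cells.
#' @param bend_sd Standard deviation of the per-specimen curvature
#'   (radians per mm).
#' @param noise_sd_mm Standard deviation of the per-coordinate
#'   digitization noise.
#' @param shared_size_cv Coefficient of variation of the per-specimen
#'   size factor shared by all length traits.
#' @param seed Default seed used by [sample_population()].
#' @return A `toe_population_spec`.
#' @export
paper_population_spec <- function(n_per_cell = NULL, n_total = NULL,
                                  bend_sd = 0.015, noise_sd_mm = 0.02,
                                  shared_size_cv = 0.12, seed = 1L) {
  build_population_spec(habitat_calibration(), n_per_cell, n_total,
                        bend_sd, noise_sd_mm, shared_size_cv, seed)
}

#' @rdname paper_population_spec
#' @export
null_population_spec <- function(n_per_cell = NULL, n_total = NULL,
                                 bend_sd = 0.015, noise_sd_mm = 0.02,
                                 shared_size_cv = 0.12, seed = 1L) {
  cal <- habitat_calibration()
  pooled <- cal
  for (col in setdiff(names(cal), "habitat")) {
    pooled[[col]] <- rep(mean(cal[[col]]), 2L)
  }
  build_population_spec(pooled, n_per_cell, n_total,
                        bend_sd, noise_sd_mm, shared_size_cv, seed)
}

build_population_spec <- function(cal, n_per_cell, n_total, bend_sd,
                                  noise_sd_mm, shared_size_cv, seed) {
  spec_cv <- function(total_sd, mean, shared) {
    total_cv <- total_sd / mean
    sqrt(pmax(total_cv^2 - shared^2, 1e-6))
  }
  cal$pad_width_cv <- spec_cv(cal$pad_width_sd, cal$pad_width, shared_size_cv)
  cal$pad_len_cv <- spec_cv(cal$pad_len_sd, cal$pad_len, shared_size_cv)
  # spread of unprinted traits assumes the pad-length coefficient of variation
  len_total_cv <- cal$pad_len_sd / cal$pad_len
  cal$proximal_cv <- sqrt(pmax(len_total_cv^2 - shared_size_cv^2, 1e-6))
  cal$distal_cv <- cal$proximal_cv
  cal$spacing_cv <- cal$proximal_cv
  muni <- tibble(
    municipality = MUNICIPALITIES,
    muni_factor = c(1.03, 0.97, 1.03, 0.97, 1.00)
  )
  cells <- tidyr::crossing(habitat = c("urban", "forest"),
                           municipality = MUNICIPALITIES)
  cells <- left_join(cells, cal, by = "habitat")
  cells <- left_join(cells, muni, by = "municipality")
  if (!is.null(n_total)) {
    base <- n_total %/% 10L
    extra <- n_total %% 10L
    cells$n <- base + as.integer(seq_len(10L) <= extra)
  } else if (!is.null(n_per_cell)) {
    cells$n <- as.integer(rep(n_per_cell, length.out = 10L))
  } else {
    cells$n <- NA_integer_  # drawn 13-20 at sampling time
  }
  structure(list(
    cells = cells, shared_size_cv = shared_size_cv, bend_sd = bend_sd,
    noise_sd_mm = noise_sd_mm,
    widest_point_fraction = 0.55, lamella_start_fraction = 0.18,
    outline_bulge = 0.08,
    area_coef = 0.605, area_cv = 0.05,
    area_replicate_sd = sqrt(0.010), n_area_replicates = 3L,
    n_replicated = 150L,
    scale_mm_per_px = scale_from_dpi(2400), seed = seed
  ), class = "toe_population_spec")
}

#' Draw a synthetic toe population
#'
#' For every specimen: template parameters are drawn lognormally around
#' the cell means (a shared size factor times trait-specific factors,
#' times the municipality offset), the deterministic template is built and
#' bent by a Normal(0, `bend_sd`) curvature, Gaussian digitization noise
#' is added to every digitized point (curve endpoints share their anchor's
#' click, as in a real digitizer), and a random half of specimens are
#' emitted as right-side toes (pre-reflected, so the ingestion pipeline's
#' mirroring is exercised). Lamella counts are rounded Normal draws per
#' cell; digitized pad areas are generated from the drawn dimensions with
#' measurement error, replicated three times for a subset of specimens.
#' Fully reproducible from the seed.
#'
#' @param spec A `toe_population_spec`.
#' @param seed Seed overriding the spec's.
#' @param scheme A `toe_scheme`.
#' @return A list of class `toe_population`: `records` (raw TPS-style
#'   records in pixels with mm-per-px scale), `metadata`, `truth`
#'   (ground-truth parameter table), `area_replicates`, `spec`. Feed
#'   `records` and `metadata` to [assemble_dataset()], or export with
#'   [write_tps()].
#' @export
sample_population <- function(spec, seed = NULL, scheme = toe_scheme()) {
  set.seed(seed %||% spec$seed)
  cells <- spec$cells
  records <- list()
  meta <- list()
  truth <- list()
  reps <- list()
  counter <- 0L
  sc <- spec$scale_mm_per_px
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    n <- if (is.na(cell$n)) sample(13:20, 1L) else cell$n
    mf <- cell$muni_factor
    size <- rln1(n, spec$shared_size_cv)
    pw <- cell$pad_width * mf * size * rln1(n, cell$pad_width_cv)
    pl <- cell$pad_len * mf * size * rln1(n, cell$pad_len_cv)
    pr <- cell$proximal * mf * size * rln1(n, cell$proximal_cv)
    dl <- cell$distal * mf * size * rln1(n, cell$distal_cv)
    sp <- cell$spacing * mf * size * rln1(n, cell$spacing_cv)
    count <- pmax(1L, round(rnorm(n, cell$count_mean, cell$count_sd)))
    svl <- rnorm(n, cell$svl_mean, cell$svl_sd)
    # extreme bends were re-imaged or replaced in the field protocol;
    # truncate the curvature distribution accordingly
    curv <- pmin(pmax(rnorm(n, 0, spec$bend_sd), -2.5 * spec$bend_sd),
                 2.5 * spec$bend_sd)
    side <- ifelse(runif(n) < 0.5, "right", "left")
    area_true <- spec$area_coef * pw * (pl + 0.35 * pr)
    area_obs <- area_true * rln1(n, spec$area_cv)
    ids <- sprintf("%s%02d_%03d", substr(cell$habitat, 1L, 1L), ci,
                   counter + seq_len(n))
    for (j in seq_len(n)) {
      cfg <- build_template(toe_template_params(
        proximal_len_mm = pr[j], pad_len_mm = pl[j], pad_width_mm = pw[j],
        distal_len_mm = dl[j],
        widest_point_fraction = spec$widest_point_fraction,
        lamella_start_fraction = spec$lamella_start_fraction,
        lamella_spacing_mm = sp[j], outline_bulge = spec$outline_bulge),
        scheme)
      cfg <- apply_bend(cfg, curv[j])
      # digitization noise per digitized point; curve endpoints reuse the
      # anchor's (noised) click as tpsDig does
      noise <- function(m) m + matrix(rnorm(length(m), 0, spec$noise_sd_mm),
                                      nrow(m), 2L)
      cfg$fixed <- noise(cfg$fixed)
      for (k in seq_along(cfg$curves)) {
        cv <- noise(cfg$curves[[k]])
        cv[1L, ] <- cfg$fixed[scheme$curves$from[k], ]
        cv[nrow(cv), ] <- cfg$fixed[scheme$curves$to[k], ]
        cfg$curves[[k]] <- cv
      }
      if (side[j] == "right") {
        cx <- mean(config_points(cfg)[, 1L])
        refl <- function(m) { m[, 1L] <- 2 * cx - m[, 1L]; m }
        cfg$fixed <- refl(cfg$fixed)
        cfg$curves <- purrr::map(cfg$curves, refl)
      }
      records[[counter + j]] <- list(
        specimen_id = ids[j],
        landmarks = cfg$fixed / sc,
        curves = purrr::map(cfg$curves, ~ .x / sc),
        scale_mm_per_px = sc,
        image = sprintf("%s.tif", ids[j]))
    }
    meta[[ci]] <- tibble(
      specimen_id = ids, habitat = cell$habitat,
      municipality = cell$municipality, side = side, svl_mm = svl,
      lamella_count = count, measured_pad_area_mm2 = area_obs)
    truth[[ci]] <- tibble(
      specimen_id = ids, habitat = cell$habitat,
      municipality = cell$municipality, side = side,
      size_factor = size, pad_width_mm = pw, pad_len_mm = pl,
      proximal_len_mm = pr, distal_len_mm = dl,
      lamella_spacing_mm = sp, lamella_count = count,
      curvature = curv, area_true_mm2 = area_true)
    counter <- counter + n
  }
  meta <- bind_rows(meta)
  truth <- bind_rows(truth)
  # replicated digitized-area measurements for a subset of specimens
  n_rep_spec <- min(spec$n_replicated, nrow(meta))
  rep_ids <- meta$specimen_id[sort(sample.int(nrow(meta), n_rep_spec))]
  area_obs <- setNames(meta$measured_pad_area_mm2, meta$specimen_id)
  reps <- purrr::map_dfr(rep_ids, function(id) {
    tibble(specimen_id = id,
           replicate = seq_len(spec$n_area_replicates),
           value = area_obs[[id]] +
             rnorm(spec$n_area_replicates, 0, spec$area_replicate_sd))
  })
  meta$measured_pad_area_mm2[match(rep_ids, meta$specimen_id)] <-
    vapply(split(reps$value, reps$specimen_id)[rep_ids], mean, numeric(1))
  structure(list(records = records, metadata = meta, truth = truth,
                 area_replicates = reps, spec = spec),
            class = "toe_population")
}

#' @export
print.toe_population <- function(x, ...) {
  cat(sprintf("<toe_population> %d synthetic specimens (%d urban, %d forest)\n",
              nrow(x$metadata), sum(x$metadata$habitat == "urban"),
              sum(x$metadata$habitat == "forest")))
  invisible(x)
}
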