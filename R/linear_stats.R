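#' Landmark-derived linear measurements of one toe
#'
#' Distances taken on the unaligned millimetre coordinates:
#' pad width = |LM5 - LM6|; pad length = |mid(LM3, LM4) - mid(LM7, LM8)|;
#' proximal toe segment = |mid(LM1, LM2) - mid(LM3, LM4)|; total toe
#' length = pad length + proximal length (exactly, by construction);
#' lamella height = the mean of the eight adjacent lamella-edge distances
#' (10-12, 12-14, 14-16, 16-18 on the left and 11-13, 13-15, 15-17, 17-19
#' on the right). The landmark-polygon pad area and centroid size are
#' attached. All measurements are invariant to rotation, translation and
#' mirroring, and scale linearly with the configuration.
#'
#' @param config A stripped `toe_config` in mm.
#' @param scheme A `toe_scheme`.
#' @return A one-row tibble.
#' @export
measure_configuration <- function(config, scheme = toe_scheme()) {
  as_tibble(measure_one(config, scheme))
}

measure_one <- function(config, scheme) {
  lm <- config$fixed
  if (nrow(lm) < scheme$n_fixed || !all(is.finite(lm))) {
    abort(sprintf("Specimen %s: missing or non-finite landmarks.",
                  config$specimen_id))
  }
  d <- function(a, b) sqrt(sum((a - b)^2))
  mid <- function(i, j) (lm[i, ] + lm[j, ]) / 2
  pad_width <- d(lm[5L, ], lm[6L, ])
  pad_length <- d(mid(3L, 4L), mid(7L, 8L))
  proximal <- d(mid(1L, 2L), mid(3L, 4L))
  hp <- scheme$height_pairs
  seg <- lm[hp[, 1L], , drop = FALSE] - lm[hp[, 2L], , drop = FALSE]
  list(
    specimen_id = config$specimen_id,
    pad_width_mm = pad_width,
    pad_length_mm = pad_length,
    proximal_len_mm = proximal,
    total_toe_len_mm = pad_length + proximal,
    lamella_height_mm = mean(sqrt(rowSums(seg^2))),
    lm_polygon_area_mm2 = polygon_area(config, scheme),
    centroid_size_mm = centroid_size(config_points(config))
  )
}

#' Measurement table for a prepared dataset
#'
#' Applies [measure_configuration()] to every specimen and joins the
#' metadata, yielding the table all univariate analyses run on.
#'
#' @param dataset A prepared `toe_dataset` (see [prepare_configurations()]).
#' @param scheme A `toe_scheme`.
#' @return A tibble, one row per specimen.
#' @export
measure_dataset <- function(dataset, scheme = toe_scheme()) {
  if (is.null(dataset$configs)) {
    abort("Dataset must be prepared (validate/strip/mirror) before measuring.")
  }
  rows <- purrr::map(unname(dataset$configs), measure_one, scheme = scheme)
  m <- tibble(
    specimen_id = purrr::map_chr(rows, "specimen_id"),
    pad_width_mm = purrr::map_dbl(rows, "pad_width_mm"),
    pad_length_mm = purrr::map_dbl(rows, "pad_length_mm"),
    proximal_len_mm = purrr::map_dbl(rows, "proximal_len_mm"),
    total_toe_len_mm = purrr::map_dbl(rows, "total_toe_len_mm"),
    lamella_height_mm = purrr::map_dbl(rows, "lamella_height_mm"),
    lm_polygon_area_mm2 = purrr::map_dbl(rows, "lm_polygon_area_mm2"),
    centroid_size_mm = purrr::map_dbl(rows, "centroid_size_mm")
  )
  stopifnot(all(m$total_toe_len_mm == m$pad_length_mm + m$proximal_len_mm))
  left_join(m, dataset$metadata, by = "specimen_id")
}

#' Toepad outline polygon area
#'
#' Shoelace (surveyor's) area of the closed pad-and-toe outline distal of
#' the LM3--LM4 chord: LM3, the outline semilandmarks up the left side
#' through LM5 and LM7 to the toe tip LM9, and back down the right side
#' through LM8 and LM6 to LM4. The proximal boundary is the straight
#' LM3--LM4 chord, which deliberately differs from a digitized pad area
#' bounded at the nearest phalangeal joint; the two are never conflated.
#' Orientation-independent; a self-intersecting outline yields a warning
#' and the absolute shoelace value.
#'
#' @param config A stripped `toe_config` in mm.
#' @param scheme A `toe_scheme`.
#' @return Area in mm^2.
#' @export
polygon_area <- function(config, scheme = toe_scheme()) {
  poly <- pad_outline(config, scheme)
  if (nrow(poly) < 3L) abort("Polygon needs at least 3 points.")
  if (!polygon_is_simple(poly)) {
    warn(sprintf("Specimen %s: pad outline self-intersects; absolute shoelace area returned.",
                 config$specimen_id))
  }
  shoelace(poly)
}

# the closed pad-and-toe outline distal of the LM3--LM4 chord, chained
# through the outline curves that do not touch the toe base
pad_outline <- function(config, scheme = toe_scheme()) {
  if (!isTRUE(config$stripped)) {
    abort(sprintf("Specimen %s must be stripped for polygon_area.",
                  config$specimen_id))
  }
  sub <- scheme$curves[scheme$curves$role == "toe_outline" &
                         scheme$curves$from != 1L & scheme$curves$from != 2L &
                         scheme$curves$to != 1L & scheme$curves$to != 2L, ]
  counts <- table(c(sub$from, sub$to))
  ends <- as.integer(names(counts)[counts == 1L])
  start <- min(ends)
  path <- list()
  cur <- start
  used <- rep(FALSE, nrow(sub))
  repeat {
    path[[length(path) + 1L]] <- config$fixed[cur, , drop = FALSE]
    nxt <- which(!used & (sub$from == cur | sub$to == cur))
    if (!length(nxt)) break
    nxt <- nxt[1L]
    used[nxt] <- TRUE
    cv <- config$curves[[sub$curve[nxt]]]
    if (sub$from[nxt] == cur) {
      path[[length(path) + 1L]] <- cv
      cur <- sub$to[nxt]
    } else {
      path[[length(path) + 1L]] <- cv[rev(seq_len(nrow(cv))), , drop = FALSE]
      cur <- sub$from[nxt]
    }
  }
  do.call(rbind, path)
}

shoelace <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# all-pairs segment-intersection scan over the closed polygon, vectorized
polygon_is_simple <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  x1 <- p[, 1L]; y1 <- p[, 2L]
  dx <- p[nxt, 1L] - x1; dy <- p[nxt, 2L] - y1
  d1x <- matrix(dx, n, n); d1y <- matrix(dy, n, n)          # segment i by row
  d2x <- matrix(dx, n, n, byrow = TRUE); d2y <- matrix(dy, n, n, byrow = TRUE)
  ddx <- matrix(x1, n, n, byrow = TRUE) - matrix(x1, n, n)  # a1[k] - a1[i]
  ddy <- matrix(y1, n, n, byrow = TRUE) - matrix(y1, n, n)
  denom <- d1x * d2y - d1y * d2x
  t1 <- (ddx * d2y - ddy * d2x) / denom
  t2 <- (ddx * d1y - ddy * d1x) / denom
  eps <- 1e-10
  hit <- abs(denom) > 1e-14 & t1 > eps & t1 < 1 - eps & t2 > eps & t2 < 1 - eps
  # only non-adjacent pairs (k >= i + 2, excluding the 1..n closure pair)
  mask <- outer(seq_len(n), seq_len(n), function(i, k) k >= i + 2L)
  mask[1L, n] <- FALSE
  !any(hit & mask)
}

#' Welch two-sample t-test with optional transform
#'
#' Two-sided unequal-variance t-test (Welch-Satterthwaite degrees of
#' freedom) on optionally transformed values, with per-group means and
#' 95 percent confidence intervals reported on the transformed and
#' back-transformed scales (back-transformed by inverting the transform on
#' the CI bounds).
#'
#' @param values_a,values_b Numeric vectors (each n >= 2).
#' @param transform `"none"`, `"ln"` or `"sqrt"`; `ln`/`sqrt` require
#'   positive values.
#' @param label_a,label_b Group labels carried into the result.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, per-group
#'   transformed means/CIs, back-transformed means/CIs, `transform`.
#' @export
welch_t_test <- function(values_a, values_b, transform = c("none", "ln", "sqrt"),
                         label_a = "a", label_b = "b") {
  transform <- match.arg(transform)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort("Each group needs at least 2 values.")
  }
  tf <- switch(transform, none = identity, ln = log, sqrt = sqrt)
  inv <- switch(transform, none = identity, ln = exp, sqrt = function(z) z^2)
  if (transform != "none") {
    bad_a <- which(values_a <= 0); bad_b <- which(values_b <= 0)
    if (length(bad_a) || length(bad_b)) {
      abort(sprintf("Non-positive values under %s transform (group a: %s; group b: %s).",
                    transform,
                    paste(bad_a, collapse = ","), paste(bad_b, collapse = ",")))
    }
  }
  xa <- tf(values_a); xb <- tf(values_b)
  tt <- t.test(xa, xb, var.equal = FALSE)
  ci <- function(x) {
    m <- mean(x); half <- qt(0.975, length(x) - 1L) * sd(x) / sqrt(length(x))
    c(m - half, m + half)
  }
  ca <- ci(xa); cb <- ci(xb)
  tibble(
    group_a = label_a, group_b = label_b, transform = transform,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(xa), ci_lo_a = ca[1L], ci_hi_a = ca[2L],
    mean_b = mean(xb), ci_lo_b = cb[1L], ci_hi_b = cb[2L],
    back_mean_a = inv(mean(xa)), back_ci_lo_a = inv(ca[1L]),
    back_ci_hi_a = inv(ca[2L]),
    back_mean_b = inv(mean(xb)), back_ci_lo_b = inv(cb[1L]),
    back_ci_hi_b = inv(cb[2L])
  )
}

#' The full battery of habitat comparisons on linear measurements
#'
#' Runs, urban versus forest (or any focal/reference pair): the natural-log
#' pad width-to-length ratio, ln total toe length, ln pad-to-total length
#' proportion, ln proximal length, ln pad area, square-root lamella count,
#' and ln lamella height — each as a Welch two-sided t-test. Raw-scale
#' group mean ratios are attached for the ratio rows.
#'
#' @param measurements A measurement table from [measure_dataset()].
#' @param group Grouping column (default `"habitat"`).
#' @param focal,reference The two group labels compared (focal first).
#' @param area_column Column used for the area test; defaults to the
#'   digitized `measured_pad_area_mm2`, falling back to the landmark
#'   polygon area when absent.
#' @return A tibble, one row per test.
#' @export
ratio_analysis <- function(measurements, group = "habitat",
                           focal = "urban", reference = "forest",
                           area_column = NULL) {
  m <- measurements
  g <- m[[group]]
  if (!all(c(focal, reference) %in% g)) {
    abort("Focal or reference group absent from the data.")
  }
  if (is.null(area_column)) {
    area_column <- if ("measured_pad_area_mm2" %in% names(m) &&
                       !anyNA(m$measured_pad_area_mm2)) {
      "measured_pad_area_mm2"
    } else "lm_polygon_area_mm2"
  }
  vars <- list(
    width_length_ratio = list(v = m$pad_width_mm / m$pad_length_mm, tr = "ln"),
    total_toe_length = list(v = m$total_toe_len_mm, tr = "ln"),
    pad_proportion = list(v = m$pad_length_mm / m$total_toe_len_mm, tr = "ln"),
    proximal_length = list(v = m$proximal_len_mm, tr = "ln"),
    pad_area = list(v = m[[area_column]], tr = "ln"),
    lamella_count = list(v = m$lamella_count, tr = "sqrt"),
    lamella_height = list(v = m$lamella_height_mm, tr = "ln")
  )
  purrr::imap_dfr(vars, function(spec, nm) {
    va <- spec$v[g == focal]; vb <- spec$v[g == reference]
    res <- welch_t_test(va, vb, transform = spec$tr,
                        label_a = focal, label_b = reference)
    bind_cols(tibble(measure = nm), res,
              tibble(raw_mean_focal = mean(va), raw_mean_reference = mean(vb)))
  })
}

#' Percent difference of a focal mean relative to a reference mean
#'
#' `100 * (focal - reference) / reference`, reported to two decimals.
#'
#' @param mean_focal,mean_reference Group means (`mean_reference` > 0).
#' @return A number (percent).
#' @examples
#' percent_difference(1.86, 1.69) # 10.06
#' @export
percent_difference <- function(mean_focal, mean_reference) {
  stopifnot_scalar_number(mean_focal, "mean_focal")
  stopifnot_scalar_number(mean_reference, "mean_reference")
  if (mean_reference <= 0) abort("`mean_reference` must be positive.")
  round(100 * (mean_focal - mean_reference) / mean_reference, 2L)
}

#' Type-II analysis of variance for a Gaussian linear model
#'
#' Fits a linear model on (transformed) measurement columns and reports
#' the type-II ANOVA table (each term adjusted for every term that does
#' not contain it; interactions last), using `car::Anova`. Named canned
#' models cover the lamella analyses: how pad area relates to lamella
#' height, count and their interaction; lamella height and count each
#' against pad length, habitat and their interaction; and height against
#' count.
#'
#' @param measurements Measurement table from [measure_dataset()].
#' @param model One of `"area_lamellae"`, `"height_by_length"`,
#'   `"count_by_length"`, `"height_by_count"`, or a formula on the derived
#'   columns `ln_area`, `ln_height`, `sqrt_count`, `ln_pad_length`,
#'   `habitat`.
#' @param area_column Area column for `ln_area` (see [ratio_analysis()]).
#' @return A tibble: `term`, `SS`, `df`, `F`, `p_value`.
#' @export
glm_anova_type2 <- function(measurements,
                            model = c("area_lamellae", "height_by_length",
                                      "count_by_length", "height_by_count"),
                            area_column = NULL) {
  if (is.null(area_column)) {
    area_column <- if ("measured_pad_area_mm2" %in% names(measurements) &&
                       !anyNA(measurements$measured_pad_area_mm2)) {
      "measured_pad_area_mm2"
    } else "lm_polygon_area_mm2"
  }
  d <- tibble(
    ln_area = log(measurements[[area_column]]),
    ln_height = log(measurements$lamella_height_mm),
    sqrt_count = sqrt(measurements$lamella_count),
    ln_pad_length = log(measurements$pad_length_mm),
    habitat = factor(measurements$habitat)
  )
  f <- if (inherits(model, "formula")) model else {
    switch(match.arg(model),
      area_lamellae = ln_area ~ ln_height * sqrt_count,
      height_by_length = ln_height ~ ln_pad_length * habitat,
      count_by_length = sqrt_count ~ ln_pad_length * habitat,
      height_by_count = ln_height ~ sqrt_count)
  }
  d <- d[complete.cases(d[, all.vars(f), drop = FALSE]), , drop = FALSE]
  fit <- lm(f, data = d)
  if (anyNA(coef(fit))) {
    abort(sprintf("Rank-deficient design; aliased terms: %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  a <- car::Anova(fit, type = 2)
  tibble(term = rownames(a), SS = a[["Sum Sq"]], df = a[["Df"]],
         F = a[["F value"]], p_value = a[["Pr(>F)"]])
}

#' Repeatability of replicated measurements
#'
#' One-way random-effects variance decomposition across specimens:
#' among-specimen and within-specimen (replicate) variance components and
#' the intraclass correlation ICC = among / (among + within). Unbalanced
#' replication is handled with the standard harmonic-style coefficient.
#'
#' @param replicates A data frame with columns `specimen_id` and `value`
#'   (one row per replicate measurement); at least 2 specimens with at
#'   least 2 replicates each.
#' @return A list: `icc`, `within_var`, `among_var`, `n_specimens`,
#'   `n_obs`.
#' @export
icc_repeatability <- function(replicates) {
  assert_columns(replicates, c("specimen_id", "value"), "replicates")
  replicates <- replicates[is.finite(replicates$value), ]
  counts <- table(replicates$specimen_id)
  if (length(counts) < 2L) abort("Need at least 2 specimens.")
  if (all(counts < 2L)) abort("Need replicated measurements (>= 2 per specimen).")
  if (any(counts < 2L)) {
    warn(sprintf("%d specimen(s) with a single replicate retained.",
                 sum(counts < 2L)))
  }
  fit <- aov(value ~ factor(specimen_id), data = replicates)
  s <- summary(fit)[[1L]]
  msb <- s[["Mean Sq"]][1L]
  msw <- s[["Mean Sq"]][2L]
  n_tot <- nrow(replicates)
  a <- length(counts)
  k0 <- (n_tot - sum(counts^2) / n_tot) / (a - 1L)
  among <- max((msb - msw) / k0, 0)
  within <- msw
  list(icc = among / (among + within), within_var = within, among_var = among,
       n_specimens = a, n_obs = n_tot)
}
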