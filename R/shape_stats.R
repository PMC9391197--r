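# ---- residual-randomization permutation ANOVA engine ----------------------
#
# Type-II sums of squares on a multivariate response via trace sums of
# nested linear models; significance by residual randomization (RRPP):
# for each term, the residuals of its reduced model are permuted and the
# term's F recomputed, the observed arrangement counting as one
# permutation. All terms share one permutation schedule so results are
# reproducible from the seed alone.
rrpp_anova <- function(y, design, formula, n_perm = 999L, seed = NULL) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  design[] <- lapply(design, function(col) {
    if (is.character(col)) factor(col) else col
  })
  n <- nrow(y)
  if (nrow(design) != n) abort("Design rows must match specimens.")
  tt <- terms(formula)
  labels <- attr(tt, "term.labels")
  if (!length(labels)) abort("Model formula has no terms.")
  fmat <- attr(tt, "factors")

  total_ss <- sum(sweep(y, 2L, colMeans(y))^2)
  if (total_ss < 1e-12) abort("Response is constant: no shape variation.")

  qmat <- function(keep) {
    x <- if (!length(keep)) matrix(1, n, 1L) else {
      model.matrix(as.formula(paste("~", paste(keep, collapse = "+"))), design)
    }
    qr_x <- qr(x)
    qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  }

  term_vars <- lapply(labels, function(l) rownames(fmat)[fmat[, l] > 0])
  # type II: the reduced model for a term holds every term not containing it
  null_terms <- lapply(seq_along(labels), function(i) {
    keep <- purrr::map_lgl(seq_along(labels), function(j) {
      j != i && !all(term_vars[[i]] %in% term_vars[[j]])
    })
    labels[keep]
  })

  q_global <- qmat(labels)
  df_res <- n - ncol(q_global)
  if (df_res <= 0) abort("More model degrees of freedom than specimens.")

  if (!is.null(seed)) set.seed(seed)
  perms <- rbind(seq_len(n),
                 t(replicate(n_perm, sample.int(n))))

  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    q_null <- qmat(null_terms[[i]])
    q_full <- qmat(c(null_terms[[i]], labels[i]))
    df_i <- ncol(q_full) - ncol(q_null)
    if (df_i <= 0) {
      abort(sprintf("Term '%s' has zero degrees of freedom.", labels[i]))
    }
    f0 <- q_null %*% crossprod(q_null, y)
    e <- y - f0
    c_null0 <- crossprod(q_null, f0)
    c_full0 <- crossprod(q_full, f0)
    c_glob0 <- crossprod(q_global, f0)
    d0 <- tcrossprod(f0, e)  # n x n: d0[i, j] = f0[i, ] . e[j, ]
    ss_f0 <- sum(f0^2)
    ss_e <- sum(e^2)
    idx <- seq_len(n)

    fstats <- numeric(nrow(perms))
    ss_obs <- NA_real_
    for (p in seq_len(nrow(perms))) {
      pm <- perms[p, ]
      ep <- e[pm, , drop = FALSE]
      a_full <- c_full0 + crossprod(q_full, ep)
      a_null <- c_null0 + crossprod(q_null, ep)
      a_glob <- c_glob0 + crossprod(q_global, ep)
      ss_y <- ss_f0 + ss_e + 2 * sum(d0[cbind(idx, pm)])
      ss_term <- sum(a_full^2) - sum(a_null^2)
      rss_glob <- ss_y - sum(a_glob^2)
      fstats[p] <- (ss_term / df_i) / (rss_glob / df_res)
      if (p == 1L) ss_obs <- ss_term
    }
    f_obs <- fstats[1L]
    p_perm <- mean(fstats >= f_obs - 1e-12)
    z <- if (sd(fstats[-1L]) > 0) {
      (f_obs - mean(fstats[-1L])) / sd(fstats[-1L])
    } else NA_real_
    rows[[i]] <- tibble(
      term = labels[i], df = df_i, SS = ss_obs, MS = ss_obs / df_i,
      Rsq = ss_obs / total_ss, F = f_obs, Z = z, p_perm = p_perm)
  }

  rss_full <- sum((y - q_global %*% crossprod(q_global, y))^2)
  table <- bind_rows(
    bind_rows(rows),
    tibble(term = "Residuals", df = df_res, SS = rss_full,
           MS = rss_full / df_res, Rsq = rss_full / total_ss,
           F = NA_real_, Z = NA_real_, p_perm = NA_real_),
    tibble(term = "Total", df = n - 1L, SS = total_ss, MS = NA_real_,
           Rsq = 1, F = NA_real_, Z = NA_real_, p_perm = NA_real_)
  )
  structure(list(table = table, n_perm = n_perm, seed = seed,
                 formula = formula, ss_type = "II"),
            class = "toe_anova")
}

#' @export
print.toe_anova <- function(x, ...) {
  cat(sprintf("Procrustes ANOVA (type II SS, %d permutations, RRPP)\n",
              x$n_perm))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Procrustes ANOVA of shape on a design
#'
#' Variance partitioning of the flattened Procrustes coordinates under a
#' linear model (default `~ habitat * municipality`) with type-II sums of
#' squares: each main effect is adjusted for the other, the interaction
#' for both. Significance per term comes from residual randomization: the
#' residuals of the term's reduced model are permuted `n_perm` times and
#' `p = (permuted F >= observed F, observed included) / (n_perm + 1)`.
#' Results are deterministic given the seed.
#'
#' @param aligned A `toe_aligned` sample.
#' @param design Data frame of predictors, one row per specimen; defaults
#'   to the metadata carried by `aligned`.
#' @param formula Right-hand-side model formula.
#' @param n_perm Number of random permutations (in addition to the
#'   observed arrangement).
#' @param seed Integer seed for the permutation schedule.
#' @return A `toe_anova` with a per-term table (`term`, `df`, `SS`, `MS`,
#'   `Rsq`, `F`, `Z`, `p_perm`) plus residual and total rows.
#' @export
procrustes_anova <- function(aligned, design = NULL,
                             formula = ~ habitat * municipality,
                             n_perm = 999L, seed = NULL) {
  design <- design %||% aligned$metadata
  if (is.null(design)) abort("No design supplied and no metadata carried.")
  rrpp_anova(aligned_matrix(aligned), design, formula,
             n_perm = n_perm, seed = seed)
}

#' Morphological disparity by group
#'
#' Procrustes variance per group (mean squared distance to the group mean)
#' computed on the residuals of a nuisance model (default: shape ~
#' municipality), with pairwise absolute differences tested by permuting
#' group labels.
#'
#' @param aligned A `toe_aligned` sample.
#' @param group Name of the grouping column (default `"habitat"`).
#' @param partial Name of a nuisance factor whose model residuals carry
#'   the disparity comparison, or `NULL` for none.
#' @param design Data frame of predictors; defaults to carried metadata.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return A `toe_disparity`: `pv` (per-group Procrustes variance),
#'   `pairs` (ordered pairs with `abs_diff`, `relative_excess` =
#'   (PV_a - PV_b)/PV_b, and permutation p), `n_perm`, `seed`.
#' @export
morphological_disparity <- function(aligned, group = "habitat",
                                    partial = "municipality", design = NULL,
                                    n_perm = 999L, seed = NULL) {
  design <- design %||% aligned$metadata
  if (is.null(design)) abort("No design supplied and no metadata carried.")
  y <- aligned_matrix(aligned)
  g <- droplevels(factor(design[[group]]))
  if (anyNA(g)) abort("Missing group labels.")
  if (any(table(g) < 3L)) {
    abort("Every group needs at least 3 specimens for disparity.")
  }
  if (!is.null(partial)) {
    x <- model.matrix(~ factor(design[[partial]]))
    y <- y - x %*% solve(crossprod(x), crossprod(x, y))
  } else {
    y <- sweep(y, 2L, colMeans(y))
  }

  pv_of <- function(labels) {
    vapply(levels(g), function(lv) {
      sel <- labels == lv
      r <- y[sel, , drop = FALSE]
      r <- sweep(r, 2L, colMeans(r))
      sum(r^2) / nrow(r)
    }, numeric(1))
  }
  pv_obs <- pv_of(g)

  pairs <- expand.grid(a = levels(g), b = levels(g),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  obs_diff <- abs(pv_obs[pairs$a] - pv_obs[pairs$b])

  if (!is.null(seed)) set.seed(seed)
  count <- rep(1L, nrow(pairs))  # observed counts as one permutation
  for (i in seq_len(n_perm)) {
    pv_p <- pv_of(sample(g))
    count <- count + as.integer(abs(pv_p[pairs$a] - pv_p[pairs$b]) >=
                                  obs_diff - 1e-15)
  }
  structure(list(
    pv = tibble(group = levels(g), n = as.integer(table(g)),
                procrustes_variance = unname(pv_obs)),
    pairs = tibble(group_a = pairs$a, group_b = pairs$b,
                   abs_diff = unname(obs_diff),
                   relative_excess = unname((pv_obs[pairs$a] - pv_obs[pairs$b]) /
                                              pv_obs[pairs$b]),
                   p_perm = unname(count / (n_perm + 1L))),
    n_perm = n_perm, seed = seed
  ), class = "toe_disparity")
}

#' @export
print.toe_disparity <- function(x, ...) {
  cat(sprintf("Morphological disparity (%d permutations)\n", x$n_perm))
  print(as.data.frame(x$pv), digits = 4)
  print(as.data.frame(x$pairs), digits = 4)
  invisible(x)
}

#' Principal component analysis of aligned shapes
#'
#' Eigendecomposition of the covariance of the flattened Procrustes
#' coordinates. Extreme-shape projections per axis place the consensus at
#' the minimum and maximum observed scores.
#'
#' @param aligned A `toe_aligned` sample (n >= 3).
#' @param extreme_axes Axes for which extreme shapes are reconstructed.
#' @return A `toe_pca`: `eig` (eigenvalue/percent table), `scores`
#'   (matrix), `scores_tbl` (tibble with metadata), `rotation`, `center`,
#'   `consensus`, `extremes`.
#' @export
shape_pca <- function(aligned, extreme_axes = 1:3) {
  y <- aligned_matrix(aligned)
  if (nrow(y) < 3L) abort("PCA needs at least 3 specimens.")
  pc <- prcomp(y, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  pct <- 100 * ev / sum(ev)
  eig <- tibble(axis = seq_along(ev), eigenvalue = ev, percent = pct,
                cumulative = cumsum(pct))
  extreme_axes <- extreme_axes[extreme_axes <= ncol(pc$x)]
  extremes <- purrr::map(extreme_axes, function(ax) {
    s <- pc$x[, ax]
    list(min = unflat_coords(pc$center + min(s) * pc$rotation[, ax]),
         max = unflat_coords(pc$center + max(s) * pc$rotation[, ax]),
         min_score = min(s), max_score = max(s))
  })
  names(extremes) <- paste0("PC", extreme_axes)
  scores_tbl <- tibble(specimen_id = rownames(y))
  if (!is.null(aligned$metadata)) {
    scores_tbl <- left_join(scores_tbl, aligned$metadata, by = "specimen_id")
  }
  scores_tbl <- bind_cols(scores_tbl,
                          as_tibble(pc$x[, seq_len(min(5L, ncol(pc$x))),
                                         drop = FALSE]))
  structure(list(eig = eig, scores = pc$x, scores_tbl = scores_tbl,
                 rotation = pc$rotation, center = pc$center,
                 consensus = unflat_coords(pc$center), extremes = extremes),
            class = "toe_pca")
}

#' @export
print.toe_pca <- function(x, ...) {
  cat("Shape PCA\n")
  print(as.data.frame(head(x$eig, 5L)), digits = 4)
  invisible(x)
}

#' Between-group principal component analysis
#'
#' PCA of the group mean shapes (at most g - 1 informative axes), with all
#' specimens projected onto those axes.
#'
#' @param aligned A `toe_aligned` sample.
#' @param group Grouping column name in the carried metadata (or a vector
#'   of labels).
#' @return A `toe_bgpca`: `eig`, `scores_tbl`, `rotation`, `center`,
#'   `group_means` (score-space means per group).
#' @export
between_group_pca <- function(aligned, group = "habitat") {
  y <- aligned_matrix(aligned)
  g <- bg_labels(aligned, group)
  if (nlevels(g) < 2L) abort("Between-group PCA needs at least 2 groups.")
  means <- do.call(rbind, lapply(levels(g), function(lv) {
    colMeans(y[g == lv, , drop = FALSE])
  }))
  rownames(means) <- levels(g)
  pc <- prcomp(means, center = TRUE, scale. = FALSE)
  n_axes <- nlevels(g) - 1L
  rot <- pc$rotation[, seq_len(n_axes), drop = FALSE]
  ev <- pc$sdev[seq_len(n_axes)]^2
  scores <- sweep(y, 2L, pc$center) %*% rot
  colnames(scores) <- paste0("bgPC", seq_len(n_axes))
  scores_tbl <- tibble(specimen_id = rownames(y), group = g)
  scores_tbl <- bind_cols(scores_tbl, as_tibble(scores))
  gm <- sweep(means, 2L, pc$center) %*% rot
  structure(list(
    eig = tibble(axis = seq_len(n_axes), eigenvalue = ev,
                 percent = if (sum(ev) > 0) 100 * ev / sum(ev) else 0 * ev),
    scores = scores, scores_tbl = scores_tbl, rotation = rot,
    center = pc$center, group_means = gm
  ), class = "toe_bgpca")
}

bg_labels <- function(aligned, group) {
  if (length(group) == 1L && is.character(group)) {
    if (is.null(aligned$metadata)) abort("No metadata carried; pass labels.")
    droplevels(factor(aligned$metadata[[group]]))
  } else {
    droplevels(factor(group))
  }
}

#' Group mean shapes before or after alignment
#'
#' Arithmetic mean per landmark per group, either in Procrustes shape
#' space or on the millimetre coordinates after a translation-only
#' registration to a common centroid (which preserves absolute size).
#'
#' @param x A `toe_aligned` (for `space = "procrustes"`) or a prepared
#'   `toe_dataset` (for `space = "pre_alignment_mm"`).
#' @param group Grouping column name or label vector.
#' @param space `"procrustes"` or `"pre_alignment_mm"`.
#' @return A named list of 123 x 2 mean-shape matrices.
#' @export
group_mean_shapes <- function(x, group = "habitat",
                              space = c("procrustes", "pre_alignment_mm")) {
  space <- match.arg(space)
  if (space == "procrustes") {
    if (!inherits(x, "toe_aligned")) abort("Procrustes means need a toe_aligned.")
    y <- aligned_matrix(x)
    g <- bg_labels(x, group)
  } else {
    if (!inherits(x, "toe_dataset") || is.null(x$configs)) {
      abort("Pre-alignment means need a prepared toe_dataset.")
    }
    mats <- purrr::map(x$configs, ~ center_points(config_points(.x)))
    y <- do.call(rbind, purrr::map(mats, flat_coords))
    ids <- names(x$configs)
    g <- if (length(group) == 1L && is.character(group)) {
      droplevels(factor(x$metadata[[group]][match(ids, x$metadata$specimen_id)]))
    } else droplevels(factor(group))
  }
  if (any(table(g) == 0L)) abort("Empty group.")
  out <- lapply(levels(g), function(lv) {
    unflat_coords(colMeans(y[g == lv, , drop = FALSE]))
  })
  names(out) <- levels(g)
  attr(out, "space") <- space
  out
}

# ---- canonical variate analysis ------------------------------------------

# CVA in a retained principal-component score space. Axes solve the
# generalized eigenproblem of between-group vs pooled within-group
# covariance, scaled so the pooled within-group variance along each axis
# is 1 (canonical variate score units).
cva_core <- function(scores, g) {
  n <- nrow(scores)
  lv <- levels(g)
  means <- do.call(rbind, lapply(lv, function(l) {
    colMeans(scores[g == l, , drop = FALSE])
  }))
  resid <- scores - means[as.integer(g), , drop = FALSE]
  w <- crossprod(resid) / (n - length(lv))
  grand <- colMeans(scores)
  bc <- sweep(means, 2L, grand)
  b <- crossprod(bc * sqrt(as.integer(table(g)))) / (length(lv) - 1L)
  r <- tryCatch(chol(w), error = function(e) {
    abort("Singular within-group covariance; retain fewer dimensions.")
  })
  rinv <- backsolve(r, diag(ncol(w)))
  m <- t(rinv) %*% b %*% rinv
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  n_axes <- length(lv) - 1L
  axes <- rinv %*% eg$vectors[, seq_len(n_axes), drop = FALSE]
  cv_scores <- scores %*% axes
  group_means <- means %*% axes
  sep <- if (length(lv) == 2L) {
    abs(group_means[1L, 1L] - group_means[2L, 1L])
  } else NA_real_
  list(axes = axes, scores = cv_scores, group_means = group_means,
       eigenvalues = eg$values[seq_len(n_axes)], separation = sep)
}

#' Canonical variate analysis of aligned shapes
#'
#' Shapes are first reduced to principal-component scores retaining
#' `min(` dimensions explaining at least `retain` of the variance,
#' `n - g - 1)` axes; the CV axes then solve the between- versus pooled
#' within-group generalized eigenproblem in that score space, normalized
#' so within-group variance along each axis is one (Mahalanobis-style
#' canonical variate units). Exactly g - 1 axes are returned. For two
#' groups, `separation` is the absolute difference of the group mean
#' scores on the single axis. The percent of total shape variation
#' captured by an axis is the variance of the data projected on the
#' unit-norm shape-space direction of that axis.
#'
#' @param aligned A `toe_aligned` sample.
#' @param group Grouping column name or label vector.
#' @param retain Fraction of variance the retained PC space must explain.
#' @return A `toe_cva`: `scores_tbl`, `axes`, `k` (retained dimensions),
#'   `separation`, `percent_variation`, `shape_direction` (unit shape-space
#'   vector), `extremes` (projected shapes at the observed score extremes),
#'   `group_means`.
#' @export
cva <- function(aligned, group = "habitat", retain = 0.95) {
  y <- aligned_matrix(aligned)
  g <- bg_labels(aligned, group)
  if (nlevels(g) < 2L) abort("CVA needs at least 2 groups.")
  n <- nrow(y)
  pc <- prcomp(y, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  share <- cumsum(ev) / sum(ev)
  k <- min(which(share >= retain)[1L], n - nlevels(g) - 1L,
           sum(pc$sdev > 1e-10))
  if (is.na(k) || k < 1L) abort("No retainable dimensions for CVA.")
  s <- pc$x[, seq_len(k), drop = FALSE]
  core <- cva_core(s, g)

  v_shape <- pc$rotation[, seq_len(k), drop = FALSE] %*% core$axes[, 1L]
  v_unit <- v_shape / sqrt(sum(v_shape^2))
  yc <- sweep(y, 2L, pc$center)
  pct <- 100 * var(as.vector(yc %*% v_unit)) / sum(ev)

  cv1 <- core$scores[, 1L]
  bvec <- as.vector(crossprod(yc, cv1 - mean(cv1))) / ((n - 1) * var(cv1))
  extremes <- list(
    min = unflat_coords(pc$center + (min(cv1) - mean(cv1)) * bvec),
    max = unflat_coords(pc$center + (max(cv1) - mean(cv1)) * bvec),
    min_score = min(cv1), max_score = max(cv1))

  scores_tbl <- tibble(specimen_id = rownames(y), group = g)
  colnames(core$scores) <- paste0("CV", seq_len(ncol(core$scores)))
  scores_tbl <- bind_cols(scores_tbl, as_tibble(core$scores))
  structure(list(
    scores_tbl = scores_tbl, scores = core$scores, axes = core$axes,
    k = k, separation = core$separation, percent_variation = pct,
    shape_direction = v_unit, extremes = extremes,
    group_means = core$group_means, eigenvalues = core$eigenvalues,
    retain = retain
  ), class = "toe_cva")
}

#' @export
print.toe_cva <- function(x, ...) {
  cat(sprintf("CVA: %d axis/axes in %d retained PC dimensions\n",
              ncol(x$scores), x$k))
  if (!is.na(x$separation)) {
    cat(sprintf("  group separation: %.3f CV units; %.2f%% of shape variation\n",
                x$separation, x$percent_variation))
  }
  invisible(x)
}

#' Label-randomization null for the CVA separation
#'
#' CV analyses separate even arbitrary groups in high-dimensional shape
#' data. To calibrate the observed separation, group labels are permuted
#' (preserving group sizes) `n_rand` times, the full CVA re-run each time,
#' and the observed separation compared with the null distribution; the
#' verdict flags whether the observed separation exceeds the null maximum.
#'
#' @param aligned A `toe_aligned` sample.
#' @param group Grouping column name or label vector (2 groups).
#' @param retain Retention rule passed to [cva()].
#' @param n_rand Number of randomized datasets (>= 2).
#' @param seed Integer seed.
#' @return A `toe_cva_null`: `separations` (length `n_rand`), and a
#'   summary with `mean`, `sd`, `max`, `observed`, `exceeds_max`.
#' @export
cva_randomization_null <- function(aligned, group = "habitat", retain = 0.95,
                                   n_rand = 100L, seed = NULL) {
  if (n_rand < 2L) abort("Need at least 2 randomized datasets.")
  y <- aligned_matrix(aligned)
  g <- bg_labels(aligned, group)
  if (nlevels(g) != 2L) abort("The randomization null is defined for 2 groups.")
  n <- nrow(y)
  pc <- prcomp(y, center = TRUE, scale. = FALSE)
  share <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- min(which(share >= retain)[1L], n - nlevels(g) - 1L,
           sum(pc$sdev > 1e-10))
  s <- pc$x[, seq_len(k), drop = FALSE]
  observed <- cva_core(s, g)$separation
  if (!is.null(seed)) set.seed(seed)
  seps <- vapply(seq_len(n_rand), function(i) {
    cva_core(s, factor(sample(g), levels = levels(g)))$separation
  }, numeric(1))
  structure(list(
    separations = seps,
    n_rand = n_rand, mean = mean(seps), sd = sd(seps), max = max(seps),
    observed = observed, exceeds_max = observed > max(seps), seed = seed
  ), class = "toe_cva_null")
}

#' @export
print.toe_cva_null <- function(x, ...) {
  cat(sprintf(
    "CVA null (%d randomized datasets): separation %.3f +/- %.3f, max %.3f\n",
    x$n_rand, x$mean, x$sd, x$max))
  cat(sprintf("Observed separation %.3f (%s the null maximum)\n", x$observed,
              if (x$exceeds_max) "exceeds" else "within"))
  invisible(x)
}

#' Test for allometry of toepad shape
#'
#' Procrustes ANOVA of shape on log size (centroid size, digitized pad
#' area, or snout-vent length), plus the correlation of the first three PC
#' scores with log size.
#'
#' @param aligned A `toe_aligned` sample.
#' @param size `"centroid_size"`, `"measured_area"` or `"svl"`; the latter
#'   two are read from the carried metadata.
#' @param n_perm,seed Permutation settings (see [procrustes_anova()]).
#' @return A `toe_allometry`: `anova` (a `toe_anova` for the log-size
#'   term), `pc_correlations` (tibble), `size_type`.
#' @export
allometry_test <- function(aligned, size = c("centroid_size", "measured_area",
                                             "svl"),
                           n_perm = 999L, seed = NULL) {
  size <- match.arg(size)
  vals <- switch(size,
    centroid_size = aligned$csize,
    measured_area = aligned$metadata$measured_pad_area_mm2,
    svl = aligned$metadata$svl_mm)
  if (is.null(vals) || anyNA(vals)) abort("Size values unavailable.")
  if (any(vals <= 0)) abort("Size values must be positive.")
  an <- rrpp_anova(aligned_matrix(aligned),
                   data.frame(log_size = log(vals)), ~ log_size,
                   n_perm = n_perm, seed = seed)
  pc <- shape_pca(aligned)
  pc_cor <- tibble(
    axis = paste0("PC", 1:3),
    r = vapply(1:3, function(ax) cor(pc$scores[, ax], log(vals)), numeric(1)))
  structure(list(anova = an, pc_correlations = pc_cor, size_type = size),
            class = "toe_allometry")
}

#' @export
print.toe_allometry <- function(x, ...) {
  cat(sprintf("Allometry test (size = %s)\n", x$size_type))
  print(x$anova)
  print(as.data.frame(x$pc_correlations), digits = 3)
  invisible(x)
}
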