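#' Centroid size of a point configuration
#'
#' The square root of the summed squared distances of all points from their
#' centroid; the standard geometric-morphometric size measure removed
#' during Procrustes alignment. Invariant to translation and rotation and
#' homogeneous of degree one under uniform scaling.
#'
#' @param points A k x 2 coordinate matrix (k >= 2).
#' @return A positive number.
#' @examples
#' centroid_size(rbind(c(0, 0), c(3, 4))) # sqrt(12.5)
#' @export
centroid_size <- function(points) {
  if (!is.matrix(points) || nrow(points) < 2L) {
    abort("`points` must be a matrix with at least two rows.")
  }
  cs <- sqrt(sum(center_points(points)^2))
  if (cs == 0) abort("All points are identical: centroid size is zero.")
  cs
}

#' Ordinary (two-shape) Procrustes superimposition
#'
#' Finds the rotation of `b` that best matches `a` in the least-squares
#' sense, after centering both and scaling both to unit centroid size.
#' Reflections are excluded (determinant +1) unless `allow_reflection` is
#' set; side differences should be handled by explicit mirroring instead.
#'
#' @param a,b k x 2 point matrices with equal row counts.
#' @param allow_reflection Permit an improper (reflecting) transform.
#' @return A list: `rotation` (2 x 2 matrix applied to `b`), `angle`
#'   (radians), `distance` (the minimized Procrustes distance; symmetric in
#'   `a` and `b`).
#' @export
ordinary_procrustes <- function(a, b, allow_reflection = FALSE) {
  if (!identical(dim(a), dim(b))) {
    abort("Point counts of `a` and `b` differ.")
  }
  a <- center_points(a); a <- a / sqrt(sum(a^2))
  b <- center_points(b); b <- b / sqrt(sum(b^2))
  r <- fit_rotation(b, a, allow_reflection = allow_reflection)
  d <- sqrt(sum((a - b %*% r)^2))
  list(rotation = r, angle = atan2(r[2L, 1L], r[1L, 1L]), distance = d)
}

#' Euclidean distance between aligned shapes
#'
#' The norm of the coordinate difference of two already-superimposed
#' shapes; the metric underlying disparity and the Procrustes ANOVA sums
#' of squares.
#'
#' @param a,b Aligned k x 2 matrices of equal dimension.
#' @return A non-negative number; zero iff the shapes are identical.
#' @export
procrustes_distance <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("Shape dimensions differ.")
  sqrt(sum((a - b)^2))
}

#' Thin-plate-spline bending energy matrix
#'
#' Builds the bending energy matrix of a reference configuration from the
#' kernel U(r) = r^2 log r^2: the upper-left k x k block of the inverse of
#' the bordered TPS system. The result is symmetric, positive
#' semi-definite, and annihilates affine deformations of the reference.
#' The quadratic form t(z) B z is the bending energy of a deformation with
#' target heights z at the reference points.
#'
#' @param reference A k x 2 matrix of reference points (not all collinear,
#'   no duplicates).
#' @return A k x k matrix.
#' @export
bending_energy_matrix <- function(reference) {
  k <- nrow(reference)
  d2 <- as.matrix(stats::dist(reference))^2
  dup <- which(d2 < 1e-24 & upper.tri(d2), arr.ind = TRUE)
  if (nrow(dup)) {
    abort(sprintf("Duplicate reference points (kernel singular): %s",
                  paste(sprintf("(%d,%d)", dup[, 1L], dup[, 2L]),
                        collapse = ", ")))
  }
  kern <- d2 * log(d2)
  diag(kern) <- 0
  q <- cbind(1, reference)
  l <- rbind(cbind(kern, q), cbind(t(q), matrix(0, 3L, 3L)))
  linv <- tryCatch(solve(l), error = function(e) {
    abort("TPS system is singular (reference points collinear?).")
  })
  b <- linv[seq_len(k), seq_len(k), drop = FALSE]
  (b + t(b)) / 2
}

# bending energy of a deformation d (k x 2 displacement from reference)
bending_energy <- function(b, d) {
  sum(d[, 1L] * (b %*% d[, 1L])) + sum(d[, 2L] * (b %*% d[, 2L]))
}

# Slide one specimen's semilandmarks along their curve tangents to
# minimize TPS bending energy relative to the consensus. Exact linear
# solve restricted to the tangent directions; fixed landmarks and anchors
# never move. Returns the updated coordinates plus energies.
slide_one <- function(coords, consensus, b, roles) {
  sl <- which(roles$role == "semilandmark")
  tang <- coords[roles$nxt[sl], , drop = FALSE] -
    coords[roles$prev[sl], , drop = FALSE]
  len <- sqrt(rowSums(tang^2))
  frozen <- len < 1e-12
  if (any(frozen)) {
    warn(sprintf("%d semilandmark(s) with coincident neighbours held fixed.",
                 sum(frozen)))
  }
  act <- sl[!frozen]
  if (!length(act)) {
    e <- bending_energy(b, coords - consensus)
    return(list(coords = coords, energy_before = e, energy_after = e))
  }
  u <- tang[!frozen, , drop = FALSE] / len[!frozen]
  d <- coords - consensus
  e_before <- bending_energy(b, d)
  b_ss <- b[act, act, drop = FALSE]
  m <- b_ss * (tcrossprod(u[, 1L]) + tcrossprod(u[, 2L]))
  rhs <- u[, 1L] * (b %*% d[, 1L])[act] + u[, 2L] * (b %*% d[, 2L])[act]
  alpha <- tryCatch(solve(m, -rhs), error = function(e) {
    solve(m + diag(1e-10 * mean(diag(m)), nrow(m)), -rhs)
  })
  new_coords <- coords
  new_coords[act, ] <- coords[act, ] + alpha * u
  e_after <- bending_energy(b, new_coords - consensus)
  if (e_after > e_before + 1e-12 * max(1, abs(e_before))) {
    # exact minimizer cannot increase energy; guard against numerics
    new_coords <- coords
    e_after <- e_before
  }
  list(coords = new_coords, energy_before = e_before, energy_after = e_after)
}

#' Slide semilandmarks along their curves by minimizing bending energy
#'
#' Each semilandmark is displaced only along its tangent direction (the
#' chord between its two curve neighbours); the displacements jointly
#' minimize the thin-plate-spline bending energy of the specimen relative
#' to the consensus. Fixed landmarks and anchor points never move, and
#' total bending energy cannot increase. Semilandmarks whose neighbours
#' coincide are held fixed with a warning.
#'
#' @param coords An n x k x 2 array (or single k x 2 matrix) of aligned
#'   coordinates.
#' @param consensus The k x 2 consensus shape the energy is measured
#'   against.
#' @param roles Role table from [scheme_roles()].
#' @return A list: `coords` (same shape as input), `energy_before`,
#'   `energy_after` (totals across specimens).
#' @export
slide_semilandmarks <- function(coords, consensus, roles) {
  b <- bending_energy_matrix(consensus)
  single <- is.matrix(coords)
  if (single) coords <- array(coords, c(1L, dim(coords)))
  e0 <- 0; e1 <- 0
  for (i in seq_len(dim(coords)[1L])) {
    res <- slide_one(coords[i, , ], consensus, b, roles)
    coords[i, , ] <- res$coords
    e0 <- e0 + res$energy_before
    e1 <- e1 + res$energy_after
  }
  list(coords = if (single) coords[1L, , ] else coords,
       energy_before = e0, energy_after = e1)
}

#' Generalized Procrustes alignment with optional semilandmark sliding
#'
#' Iteratively centers every configuration, scales it to unit centroid
#' size, rotates it onto the evolving consensus (proper rotations only),
#' and updates the consensus until the mean consensus displacement falls
#' below `tol`. With `slide = TRUE`, semilandmarks are then slid along
#' their curve tangents to minimize bending energy against the consensus,
#' re-superimposing after each pass, for up to `max_slide_iter` passes;
#' sliding stops as soon as a pass fails to reduce total bending energy, so
#' the logged energies are non-increasing. The final sample is rotated to
#' a canonical orientation (consensus major axis vertical), making the
#' result independent of input order and of arbitrary rotation,
#' translation or scaling of the inputs.
#'
#' @param dataset A prepared `toe_dataset` (see [prepare_configurations()]),
#'   or a plain list of stripped `toe_config`s.
#' @param scheme A `toe_scheme`.
#' @param max_iter Maximum GPA iterations.
#' @param tol Convergence tolerance on mean consensus displacement.
#' @param slide Slide semilandmarks by bending energy.
#' @param max_slide_iter Maximum sliding passes after initial convergence.
#' @param tangent_project Orthogonally project aligned shapes onto the
#'   tangent space at the consensus (off by default).
#' @return A `toe_aligned` object: `coords` (n x 123 x 2 array of
#'   Procrustes coordinates, unit centroid size), `csize` (original
#'   centroid sizes, mm), `consensus` (123 x 2), `roles`, `iterations`,
#'   `sliding_log` (total bending energy per sliding pass), `converged`,
#'   and the dataset's `metadata` when available.
#' @export
gpa_align <- function(dataset, scheme = toe_scheme(), max_iter = 100L,
                      tol = 1e-6, slide = TRUE, max_slide_iter = 5L,
                      tangent_project = FALSE) {
  configs <- if (inherits(dataset, "toe_dataset")) dataset$configs else dataset
  if (is.null(configs) || length(configs) < 2L) {
    abort("Need at least two prepared configurations to align.")
  }
  if (!all(purrr::map_lgl(configs, ~ isTRUE(.x$stripped)))) {
    abort("All configurations must be stripped before alignment.")
  }
  roles <- scheme_roles(scheme)
  n <- length(configs)
  k <- nrow(roles)
  ids <- unname(purrr::map_chr(configs, "specimen_id"))

  coords <- array(0, c(n, k, 2L), dimnames = list(ids, NULL, c("x", "y")))
  csize <- numeric(n)
  for (i in seq_len(n)) {
    p <- config_points(configs[[i]])
    if (nrow(p) != k) {
      abort(sprintf("Specimen %s has %d points; scheme expects %d.",
                    ids[i], nrow(p), k))
    }
    p <- center_points(p)
    csize[i] <- centroid_size(p)
    coords[i, , ] <- p / csize[i]
  }

  consensus <- coords[1L, , ]
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    for (i in seq_len(n)) {
      coords[i, , ] <- coords[i, , ] %*%
        fit_rotation(coords[i, , ], consensus)
    }
    new_consensus <- apply(coords, c(2L, 3L), mean)
    new_consensus <- center_points(new_consensus)
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- mean(sqrt(rowSums((new_consensus - consensus)^2)))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("GPA did not converge in %d iterations.", max_iter))
  }

  sliding_log <- numeric(0)
  if (slide) {
    prev_energy <- Inf
    for (pass in seq_len(max_slide_iter)) {
      saved <- coords
      res <- slide_semilandmarks(coords, consensus, roles)
      if (res$energy_after >= prev_energy) { coords <- saved; break }
      coords <- res$coords
      sliding_log <- c(sliding_log, res$energy_after)
      # re-superimpose after sliding and refresh the consensus
      for (i in seq_len(n)) {
        p <- center_points(coords[i, , ])
        p <- p / sqrt(sum(p^2))
        coords[i, , ] <- p %*% fit_rotation(p, consensus)
      }
      consensus <- apply(coords, c(2L, 3L), mean)
      consensus <- center_points(consensus)
      consensus <- consensus / sqrt(sum(consensus^2))
      if (prev_energy - res$energy_after <
          tol * max(1, abs(res$energy_after))) {
        prev_energy <- res$energy_after
        break
      }
      prev_energy <- res$energy_after
    }
  }

  # canonical orientation: consensus major axis vertical, toe tip up
  ev <- eigen(cov(consensus), symmetric = TRUE)
  v1 <- ev$vectors[, 1L]
  rot <- cbind(c(v1[2L], -v1[1L]), v1)  # proper rotation sending v1 -> +y
  if (det(rot) < 0) rot <- -rot
  cons_rot <- consensus %*% rot
  if (cons_rot[which.max(abs(cons_rot[, 2L])), 2L] < 0) {
    rot <- rot %*% rot2(pi)
    cons_rot <- consensus %*% rot
  }
  for (i in seq_len(n)) coords[i, , ] <- coords[i, , ] %*% rot
  # stored consensus is the arithmetic mean of the final aligned sample
  consensus <- apply(coords, c(2L, 3L), mean)

  if (tangent_project) {
    cvec <- flat_coords(consensus)
    cvec <- cvec / sqrt(sum(cvec^2))
    for (i in seq_len(n)) {
      y <- flat_coords(coords[i, , ])
      y <- y - (sum(y * cvec) - sum(flat_coords(consensus) * cvec)) * cvec
      coords[i, , ] <- unflat_coords(y)
    }
  }

  meta <- if (inherits(dataset, "toe_dataset")) dataset$metadata else NULL
  structure(list(
    coords = coords, csize = setNames(csize, ids), consensus = consensus,
    roles = roles, iterations = iterations, sliding_log = sliding_log,
    converged = converged, metadata = meta
  ), class = "toe_aligned")
}

#' @export
print.toe_aligned <- function(x, ...) {
  cat(sprintf("<toe_aligned> %d specimens x %d points; %d GPA iterations%s\n",
              dim(x$coords)[1L], dim(x$coords)[2L], x$iterations,
              if (length(x$sliding_log))
                sprintf(", %d sliding passes", length(x$sliding_log)) else ""))
  invisible(x)
}

# n x 2k matrix of flattened aligned coordinates
aligned_matrix <- function(aligned) {
  n <- dim(aligned$coords)[1L]
  y <- t(apply(aligned$coords, 1L, flat_coords))
  rownames(y) <- dimnames(aligned$coords)[[1L]]
  y
}

#' Procrustes variance of a set of aligned shapes
#'
#' Mean squared Procrustes distance to the sample mean shape.
#'
#' @param aligned A `toe_aligned` object or an n x 2k coordinate matrix.
#' @return A non-negative number.
#' @export
procrustes_variance <- function(aligned) {
  y <- if (inherits(aligned, "toe_aligned")) aligned_matrix(aligned) else aligned
  yc <- sweep(y, 2L, colMeans(y))
  sum(yc^2) / nrow(y)
}
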