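# fixtures are built in code: no data files

# a random raw record (pixel units) for round-trip properties
random_record <- function(id, n_lm = 5L, n_curves = 2L, with_scale = TRUE) {
  list(
    specimen_id = id,
    landmarks = matrix(round(runif(n_lm * 2L, 0, 1000), 3L), n_lm, 2L),
    curves = replicate(n_curves, {
      np <- sample(3:6, 1L)
      matrix(round(runif(np * 2L, 0, 1000), 3L), np, 2L)
    }, simplify = FALSE),
    scale_mm_per_px = if (with_scale) round(runif(1L, 0.005, 0.02), 6L) else NA_real_,
    image = paste0(id, ".tif")
  )
}

# default forest-like template, stripped, ready for measurement
stripped_template <- function(params = toe_template_params(),
                              scheme = toe_scheme()) {
  strip_anchor_semilandmarks(build_template(params, scheme), scheme)
}

# fabricate a toe_aligned from a flat n x 2k score matrix
fake_aligned <- function(y, metadata = NULL) {
  n <- nrow(y)
  k <- ncol(y) / 2L
  ids <- rownames(y) %||% sprintf("s%03d", seq_len(n))
  coords <- array(0, c(n, k, 2L), dimnames = list(ids, NULL, c("x", "y")))
  for (i in seq_len(n)) coords[i, , ] <- matrix(y[i, ], ncol = 2L)
  if (!is.null(metadata) && !"specimen_id" %in% names(metadata)) {
    metadata$specimen_id <- ids
  }
  structure(list(coords = coords, csize = stats::setNames(rep(1, n), ids),
                 consensus = matrix(colMeans(y), ncol = 2L),
                 roles = NULL, iterations = 0L, sliding_log = numeric(0),
                 converged = TRUE, metadata = metadata),
            class = "toe_aligned")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

outline_polygon <- function(cfg, scheme = toe_scheme()) {
  toemorph:::pad_outline(cfg, scheme)
}

# Monte Carlo point-in-polygon area oracle (vectorized ray casting)
rasterized_area <- function(poly, n_samples = 1e6) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  px <- runif(n_samples, xr[1], xr[2])
  py <- runif(n_samples, yr[1], yr[2])
  m <- nrow(poly)
  nxt <- c(2:m, 1L)
  inside <- rep(FALSE, n_samples)
  for (e in seq_len(m)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    x2 <- poly[nxt[e], 1]; y2 <- poly[nxt[e], 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  mean(inside) * diff(xr) * diff(yr)
}

# prepared dataset from a synthetic population
prepared_population <- function(spec, seed = NULL) {
  pop <- sample_population(spec, seed = seed)
  prepare_configurations(assemble_dataset(pop$records, pop$metadata))
}
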