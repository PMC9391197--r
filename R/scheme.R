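#' The toe digitization template
#'
#' The packaged landmarking scheme for anole rear-toe images: 19 fixed
#' landmarks and 13 curves of 10 points each. Landmarks 1--2 sit at the toe
#' base, 3--4 where the pad begins to widen, 5--6 at the widest points of
#' the pad, 7--8 at the distal end of the pad, and 9 at the claw base.
#' Landmarks 10--19 mark the left/right edges of lamellae five through ten
#' (distal to proximal, left indices even-offset 10,12,...,18 and right
#' 11,13,...,19). Eight curves outline the toe through the consecutive
#' outline landmarks 1-3-5-7-9-8-6-4-2 and five curves trace the free edge
#' of each landmarked lamella. Each curve carries 10 digitized points whose
#' first and last coincide with its anchor landmarks; those duplicates are
#' removed by [strip_anchor_semilandmarks()], leaving 8 semilandmarks per
#' curve and 19 + 13 x 8 = 123 points per specimen.
#'
#' @param anchor_tol Tolerance (mm) for curve endpoints coinciding with
#'   their anchor landmarks during stripping. Digitized data rarely snap
#'   exactly; endpoints farther than this produce a warning.
#' @return A `toe_scheme` object.
#' @export
toe_scheme <- function(anchor_tol = 0.02) {
  outline <- matrix(c(1, 3, 3, 5, 5, 7, 7, 9, 9, 8, 8, 6, 6, 4, 4, 2),
                    ncol = 2L, byrow = TRUE)
  lamella <- matrix(c(10, 11, 12, 13, 14, 15, 16, 17, 18, 19),
                    ncol = 2L, byrow = TRUE)
  curves <- tibble(
    curve = 1:13,
    from = as.integer(c(outline[, 1L], lamella[, 1L])),
    to = as.integer(c(outline[, 2L], lamella[, 2L])),
    n_raw = 10L,
    role = c(rep("toe_outline", 8L), rep("lamella_edge", 5L))
  )
  new_toe_scheme(n_fixed = 19L, curves = curves, anchor_tol = anchor_tol)
}

new_toe_scheme <- function(n_fixed, curves, anchor_tol) {
  if (n_fixed != 19L) abort("Scheme must declare 19 fixed landmarks.")
  if (nrow(curves) != 13L) abort("Scheme must declare 13 curves.")
  if (sum(curves$role == "toe_outline") != 8L ||
      sum(curves$role == "lamella_edge") != 5L) {
    abort("Scheme must have 8 toe_outline and 5 lamella_edge curves.")
  }
  if (any(curves$from < 1L | curves$from > n_fixed) ||
      any(curves$to < 1L | curves$to > n_fixed)) {
    abort("Curve anchors must reference valid landmark indices.")
  }
  curves$from <- as.integer(curves$from)
  curves$to <- as.integer(curves$to)
  curves$n_raw <- as.integer(curves$n_raw)
  lam <- curves[curves$role == "lamella_edge", ]
  structure(list(
    n_fixed = as.integer(n_fixed),
    curves = curves,
    # left/right lamella landmark pairs, distal to proximal
    lamella_pairs = cbind(lam$from, lam$to),
    # adjacent-landmark pairs averaged into lamella height:
    # left chain 10-12-14-16-18 and right chain 11-13-15-17-19
    height_pairs = matrix(c(10, 12, 12, 14, 14, 16, 16, 18,
                            11, 13, 13, 15, 15, 17, 17, 19),
                          ncol = 2L, byrow = TRUE),
    anchor_tol = anchor_tol
  ), class = "toe_scheme")
}

#' @export
print.toe_scheme <- function(x, ...) {
  cat(sprintf("<toe_scheme> %d fixed landmarks, %d curves (%d outline + %d lamella), %d raw points/curve\n",
              x$n_fixed, nrow(x$curves), sum(x$curves$role == "toe_outline"),
              sum(x$curves$role == "lamella_edge"), x$curves$n_raw[1L]))
  invisible(x)
}

#' Read or write a scheme file
#'
#' Schemes are serialized as YAML (fixed landmark count, per-curve anchors,
#' raw point counts and roles). The packaged default scheme lives at
#' `system.file("extdata", "toe_scheme.yaml", package = "toemorph")`;
#' alternative schemes with the same grammar may be supplied so the curve
#' anchoring can be changed without touching code.
#'
#' @param path Path to a scheme YAML file.
#' @return For `read_scheme`, a `toe_scheme`; for `write_scheme`, `path`
#'   invisibly.
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  curves <- purrr::map_dfr(y$curves, as_tibble)
  curves$curve <- seq_len(nrow(curves))
  curves <- curves[, c("curve", "from", "to", "n_raw", "role")]
  new_toe_scheme(n_fixed = y$n_fixed, curves = curves,
                 anchor_tol = y$anchor_tol %||% 0.02)
}

#' @rdname read_scheme
#' @param scheme A `toe_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  y <- list(
    n_fixed = scheme$n_fixed,
    anchor_tol = scheme$anchor_tol,
    curves = purrr::pmap(scheme$curves[, c("from", "to", "n_raw", "role")],
                         function(from, to, n_raw, role) {
                           list(from = from, to = to, n_raw = n_raw, role = role)
                         })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Validate a raw record against the scheme
#'
#' Accepts exactly the scheme's landmark count and curve structure (13
#' curves of 10 points each for the packaged scheme) and returns a typed
#' configuration; anything else is rejected with an error naming the
#' specimen and the defect. Validation is total: no silent coercion.
#'
#' @param raw A raw record (coordinates in mm; see [assemble_dataset()]).
#' @param scheme A `toe_scheme`.
#' @param side `"left"` or `"right"`; right-side toes are mirrored later by
#'   [mirror_configuration()].
#' @return A `toe_config` with fields `specimen_id`, `fixed` (19 x 2),
#'   `curves` (list of 13 matrices), `side`, `mirrored`, `stripped`.
#' @export
validate_configuration <- function(raw, scheme = toe_scheme(), side = "left") {
  id <- raw$specimen_id %||% "?"
  if (!side %in% c("left", "right")) {
    abort(sprintf("Specimen %s: side must be 'left' or 'right'.", id))
  }
  n_lm <- nrow(raw$landmarks)
  if (n_lm != scheme$n_fixed) {
    abort(sprintf("Specimen %s: expected %d landmarks, found %d.",
                  id, scheme$n_fixed, n_lm))
  }
  if (length(raw$curves) != nrow(scheme$curves)) {
    abort(sprintf("Specimen %s: expected %d curves, found %d.",
                  id, nrow(scheme$curves), length(raw$curves)))
  }
  for (i in seq_along(raw$curves)) {
    np <- nrow(raw$curves[[i]])
    if (np != scheme$curves$n_raw[i]) {
      abort(sprintf("Specimen %s: curve %d has %d points, expected %d.",
                    id, i, np, scheme$curves$n_raw[i]))
    }
  }
  all_pts <- rbind(raw$landmarks, do.call(rbind, raw$curves))
  if (!all(is.finite(all_pts))) {
    abort(sprintf("Specimen %s: non-finite coordinates.", id))
  }
  structure(list(
    specimen_id = id,
    fixed = raw$landmarks,
    curves = raw$curves,
    side = side,
    mirrored = FALSE,
    stripped = FALSE
  ), class = "toe_config")
}

#' @export
print.toe_config <- function(x, ...) {
  cat(sprintf("<toe_config> %s: %d landmarks + %d curve points (%s%s%s)\n",
              x$specimen_id, nrow(x$fixed),
              sum(purrr::map_int(x$curves, nrow)), x$side,
              if (x$mirrored) ", mirrored" else "",
              if (x$stripped) ", stripped" else ""))
  invisible(x)
}

#' Remove the curve endpoints that duplicate anchor landmarks
#'
#' Each digitized curve carries 10 points whose first and last coincide
#' with its anchor landmarks; they are removed here, leaving the 8 interior
#' semilandmarks per curve that enter all downstream analyses. Endpoints
#' farther than the scheme's anchor tolerance from their anchor trigger a
#' warning (with the distance) but are stripped anyway.
#'
#' @param config A validated `toe_config`.
#' @param scheme A `toe_scheme`.
#' @return The configuration with 8-point curves and `stripped = TRUE`.
#' @export
strip_anchor_semilandmarks <- function(config, scheme = toe_scheme()) {
  if (isTRUE(config$stripped)) {
    abort(sprintf("Specimen %s is already stripped.", config$specimen_id))
  }
  for (i in seq_along(config$curves)) {
    cv <- config$curves[[i]]
    a <- config$fixed[scheme$curves$from[i], ]
    b <- config$fixed[scheme$curves$to[i], ]
    d_start <- sqrt(sum((cv[1L, ] - a)^2))
    d_end <- sqrt(sum((cv[nrow(cv), ] - b)^2))
    if (d_start > scheme$anchor_tol || d_end > scheme$anchor_tol) {
      warn(sprintf(
        "Specimen %s, curve %d: endpoint %.4g mm from its anchor (tolerance %.4g); stripped anyway.",
        config$specimen_id, i, max(d_start, d_end), scheme$anchor_tol))
    }
    config$curves[[i]] <- cv[2:(nrow(cv) - 1L), , drop = FALSE]
  }
  config$stripped <- TRUE
  config
}

#' Mirror a right-side configuration
#'
#' Reflects x coordinates about the vertical axis through the
#' configuration's centroid so right-toe images become comparable with
#' left-toe images. Landmark numbering is anatomical (left/right of the
#' toe) and is not changed by mirroring. Left-side configurations are
#' returned unchanged; mirroring an already-mirrored right toe errors.
#' Applying the reflection twice restores the original coordinates, and all
#' inter-point distances are preserved.
#'
#' @param config A `toe_config`.
#' @param quiet Suppress the no-op message for left-side input.
#' @return The (possibly) mirrored configuration with its `mirrored` flag set.
#' @export
mirror_configuration <- function(config, quiet = FALSE) {
  if (config$side == "left") {
    if (!quiet) inform(sprintf("Specimen %s is left-sided; not mirrored.",
                               config$specimen_id))
    return(config)
  }
  if (isTRUE(config$mirrored)) {
    abort(sprintf("Specimen %s is already mirrored; refusing to mirror twice.",
                  config$specimen_id))
  }
  cx <- mean(config_points(config)[, 1L])
  reflect <- function(m) { m[, 1L] <- 2 * cx - m[, 1L]; m }
  config$fixed <- reflect(config$fixed)
  config$curves <- purrr::map(config$curves, reflect)
  config$mirrored <- TRUE
  config
}

#' Flatten a configuration into the canonical point matrix
#'
#' Fixed landmarks occupy rows 1--19 in scheme order; curve points follow
#' curve by curve in digitized order, giving 123 rows for the packaged
#' scheme. The accompanying role table records, for each semilandmark, its
#' two sliding neighbours on its curve (anchor landmarks included as
#' neighbours at curve ends).
#'
#' @param config A stripped `toe_config`.
#' @param scheme A `toe_scheme`.
#' @return A list with `coords` (123 x 2 matrix) and `roles` (tibble with
#'   columns `index`, `role`, `curve`, `prev`, `nxt`).
#' @export
flatten_configuration <- function(config, scheme = toe_scheme()) {
  if (!isTRUE(config$stripped)) {
    abort(sprintf("Specimen %s must be stripped before flattening.",
                  config$specimen_id))
  }
  coords <- config_points(config)
  list(coords = coords, roles = scheme_roles(scheme))
}

#' Role and neighbour table for a scheme
#'
#' @param scheme A `toe_scheme`.
#' @return Tibble with one row per flattened point (fixed landmarks first).
#' @export
scheme_roles <- function(scheme = toe_scheme()) {
  n_keep <- scheme$curves$n_raw - 2L
  n_total <- scheme$n_fixed + sum(n_keep)
  role <- c(rep("fixed", scheme$n_fixed),
            rep("semilandmark", sum(n_keep)))
  curve <- c(rep(NA_integer_, scheme$n_fixed),
             rep(scheme$curves$curve, n_keep))
  prv <- rep(NA_integer_, n_total)
  nxt <- rep(NA_integer_, n_total)
  offset <- scheme$n_fixed
  for (i in seq_len(nrow(scheme$curves))) {
    k <- n_keep[i]
    idx <- offset + seq_len(k)
    prv[idx] <- c(scheme$curves$from[i], idx[-k])
    nxt[idx] <- as.integer(c(idx[-1L], scheme$curves$to[i]))
    offset <- offset + k
  }
  tibble(index = seq_len(n_total), role = role, curve = curve,
         prev = prv, nxt = nxt)
}

# validate + strip + mirror every record of an assembled dataset
#' Prepare an assembled dataset for alignment
#'
#' Validates every record against the scheme, strips anchor-duplicate curve
#' endpoints, and mirrors right-side toes, yielding side-normalized
#' 123-point configurations.
#'
#' @param dataset A `toe_dataset` from [assemble_dataset()].
#' @param scheme A `toe_scheme`.
#' @return The dataset with a `configs` element (named list of prepared
#'   `toe_config`s) added.
#' @export
prepare_configurations <- function(dataset, scheme = toe_scheme()) {
  sides <- dataset$metadata$side[match(
    purrr::map_chr(dataset$records, "specimen_id"),
    dataset$metadata$specimen_id)]
  configs <- purrr::map2(dataset$records, sides, function(r, s) {
    cfg <- validate_configuration(r, scheme, side = s)
    cfg <- strip_anchor_semilandmarks(cfg, scheme)
    mirror_configuration(cfg, quiet = TRUE)
  })
  names(configs) <- purrr::map_chr(configs, "specimen_id")
  dataset$configs <- configs
  dataset$scheme <- scheme
  dataset
}
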