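#' Long per-point table of aligned coordinates
#'
#' One row per specimen-point in Procrustes units, ready for CSV export
#' or plotting.
#'
#' @param aligned A `toe_aligned`.
#' @return A tibble: `specimen_id`, `point_index`, `point_role`, `x`, `y`.
#' @export
aligned_points <- function(aligned) {
  ids <- dimnames(aligned$coords)[[1L]]
  roles <- aligned$roles$role
  purrr::map_dfr(seq_along(ids), function(i) {
    tibble(specimen_id = ids[i],
           point_index = seq_len(dim(aligned$coords)[2L]),
           point_role = roles,
           x = aligned$coords[i, , 1L],
           y = aligned$coords[i, , 2L])
  })
}

#' Package a shape matrix as a TPS-style record
#'
#' Wraps a 123 x 2 shape (a consensus, a group mean, or a projected
#' extreme) as a raw record so it can be written with [write_tps()]. The
#' points are split back into the scheme's fixed landmarks and curves.
#'
#' @param shape A k x 2 coordinate matrix in scheme point order.
#' @param id Record identifier.
#' @param scheme A `toe_scheme`.
#' @return A raw record (see [read_tps()]).
#' @export
shape_record <- function(shape, id = "shape", scheme = toe_scheme()) {
  n_keep <- scheme$curves$n_raw - 2L
  expected <- scheme$n_fixed + sum(n_keep)
  if (nrow(shape) != expected) {
    abort(sprintf("Shape has %d points; scheme expects %d.",
                  nrow(shape), expected))
  }
  curves <- vector("list", nrow(scheme$curves))
  offset <- scheme$n_fixed
  for (i in seq_along(curves)) {
    curves[[i]] <- shape[offset + seq_len(n_keep[i]), , drop = FALSE]
    offset <- offset + n_keep[i]
  }
  list(specimen_id = id,
       landmarks = shape[seq_len(scheme$n_fixed), , drop = FALSE],
       curves = curves, scale_mm_per_px = NA_real_, image = NA_character_)
}

#' @rdname shape_record
#' @param aligned A `toe_aligned`.
#' @export
consensus_record <- function(aligned, id = "consensus",
                             scheme = toe_scheme()) {
  shape_record(aligned$consensus, id = id, scheme = scheme)
}
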