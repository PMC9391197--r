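#' Read landmark records from a TPS file
#'
#' Parses the tpsDig dialect of the TPS landmark format: records are
#' delimited by `LM=` headers and may carry `CURVES=`/`POINTS=` curve
#' blocks and `IMAGE=`, `ID=` and `SCALE=` fields. Keys are recognized
#' case-insensitively; LF and CRLF line endings are both accepted. Point
#' order is preserved exactly as stored.
#'
#' `SCALE=` is interpreted as millimetres per pixel (coordinates are
#' multiplied by it to obtain mm). TPS dialects vary on this point; supply
#' pre-scaled data or a DPI-derived scale via [scale_from_dpi()] if your
#' files use the inverse convention.
#'
#' @param path Path to a TPS file.
#' @return A list of raw records, each a list with elements `specimen_id`,
#'   `landmarks` (n x 2 matrix, pixels), `curves` (list of point matrices),
#'   `scale_mm_per_px` (positive number or `NA`), `image` (string or `NA`).
#' @seealso [write_tps()], [assemble_dataset()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) abort(sprintf("TPS file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("TPS file is empty: %s", path))

  is_lm <- grepl("^lm\\s*=", lines, ignore.case = TRUE)
  if (!is_lm[1L]) {
    abort("Malformed TPS file: first record lacks an LM= header.")
  }
  starts <- which(is_lm)
  ends <- c(starts[-1L] - 1L, length(lines))
  purrr::map2(starts, ends, function(s, e) {
    parse_tps_record(lines[s:e], record_index = match(s, starts))
  })
}

key_value <- function(line) {
  m <- regmatches(line, regexec("^([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1L]]
  if (length(m) < 3L) return(NULL)
  list(key = toupper(m[2L]), value = trimws(m[3L]))
}

parse_coord_line <- function(line) {
  vals <- suppressWarnings(as.numeric(strsplit(line, "\\s+")[[1L]]))
  if (length(vals) != 2L || anyNA(vals)) return(NULL)
  vals
}

parse_tps_record <- function(lines, record_index) {
  id <- NA_character_
  image <- NA_character_
  scale <- NA_real_
  n_lm <- NULL
  n_curves <- 0L
  landmarks <- list()
  curves <- list()
  cur_curve <- NULL
  cur_curve_n <- NULL
  state <- "landmarks"

  flush_curve <- function() {
    if (is.null(cur_curve)) return(invisible())
    if (length(cur_curve) != cur_curve_n) {
      abort(sprintf(
        "Record %d (%s): curve %d declares POINTS=%d but has %d points.",
        record_index, id %||% "?", length(curves) + 1L, cur_curve_n,
        length(cur_curve)))
    }
    curves[[length(curves) + 1L]] <<- do.call(rbind, cur_curve)
    cur_curve <<- NULL
  }

  for (line in lines) {
    kv <- key_value(line)
    if (!is.null(kv)) {
      switch(kv$key,
        LM = {
          n_lm <- as.integer(kv$value)
        },
        CURVES = {
          flush_curve()
          n_curves <- as.integer(kv$value)
          state <- "curves"
        },
        POINTS = {
          flush_curve()
          cur_curve <- list()
          cur_curve_n <- as.integer(kv$value)
          state <- "curve_points"
        },
        IMAGE = image <- kv$value,
        ID = id <- kv$value,
        SCALE = scale <- as.numeric(kv$value),
        abort(sprintf("Record %d: unrecognized TPS key '%s'.",
                      record_index, kv$key))
      )
      next
    }
    pt <- parse_coord_line(line)
    if (is.null(pt)) {
      abort(sprintf("Record %d: cannot parse line '%s'.", record_index, line))
    }
    if (state == "curve_points") {
      cur_curve[[length(cur_curve) + 1L]] <- pt
    } else {
      landmarks[[length(landmarks) + 1L]] <- pt
    }
  }
  flush_curve()

  if (is.null(n_lm)) {
    abort(sprintf("Record %d lacks an LM= header.", record_index))
  }
  if (length(landmarks) != n_lm) {
    abort(sprintf("Record %d (%s): LM=%d declared but %d landmark rows found.",
                  record_index, id %||% "?", n_lm, length(landmarks)))
  }
  if (length(curves) != n_curves) {
    abort(sprintf("Record %d (%s): CURVES=%d declared but %d curve blocks found.",
                  record_index, id %||% "?", n_curves, length(curves)))
  }
  if (!is.na(scale) && scale <= 0) {
    abort(sprintf("Record %d (%s): SCALE must be positive.", record_index,
                  id %||% "?"))
  }
  lm_mat <- if (n_lm > 0L) do.call(rbind, landmarks) else matrix(numeric(), 0L, 2L)
  list(
    specimen_id = if (is.na(id)) sprintf("record_%d", record_index) else id,
    landmarks = lm_mat,
    curves = curves,
    scale_mm_per_px = scale,
    image = image
  )
}

#' Write landmark records to a TPS file
#'
#' Inverse of [read_tps()]: coordinates are written with 17 significant
#' digits, so a read/write round trip reproduces them exactly. A record
#' without a scale gets no `SCALE=` line.
#'
#' @param records A list of raw records as returned by [read_tps()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(records, path) {
  if (!length(records)) abort("Cannot write an empty record list.")
  fmt_pt <- function(m) sprintf("%.17g %.17g", m[, 1L], m[, 2L])
  blocks <- purrr::map(records, function(r) {
    if (is.null(r$landmarks) || nrow(r$landmarks) < 1L) {
      abort(sprintf("Record '%s' has no landmarks.", r$specimen_id %||% "?"))
    }
    out <- c(sprintf("LM=%d", nrow(r$landmarks)), fmt_pt(r$landmarks))
    if (length(r$curves)) {
      out <- c(out, sprintf("CURVES=%d", length(r$curves)))
      for (cv in r$curves) {
        out <- c(out, sprintf("POINTS=%d", nrow(cv)), fmt_pt(cv))
      }
    }
    if (!is.null(r$image) && !is.na(r$image)) {
      out <- c(out, sprintf("IMAGE=%s", r$image))
    }
    out <- c(out, sprintf("ID=%s", r$specimen_id))
    if (!is.null(r$scale_mm_per_px) && !is.na(r$scale_mm_per_px)) {
      out <- c(out, sprintf("SCALE=%.17g", r$scale_mm_per_px))
    }
    out
  })
  writeLines(unlist(blocks), path, useBytes = TRUE)
  invisible(path)
}

#' Millimetres per pixel from a scan resolution
#'
#' Flatbed scans at a known resolution have a fixed physical pixel pitch of
#' 25.4 / dpi millimetres.
#'
#' @param dpi Scan resolution in dots per inch (> 0).
#' @return Scale in mm per pixel.
#' @examples
#' scale_from_dpi(2400) # 0.010583...
#' @export
scale_from_dpi <- function(dpi) {
  stopifnot_scalar_number(dpi, "dpi")
  if (dpi <= 0) abort("`dpi` must be positive.")
  25.4 / dpi
}

#' Join landmark records to specimen metadata and convert to millimetres
#'
#' Inner-joins raw records to a metadata table on `specimen_id`, multiplies
#' every coordinate by the record's mm-per-pixel scale (falling back to a
#' DPI-derived scale when a record has none), and validates the metadata's
#' closed categorical sets. Records without any usable scale, and records
#' without a metadata row, are dropped with a logged reason.
#'
#' @param records List of raw records from [read_tps()] or
#'   [sample_population()].
#' @param metadata A data frame with columns `specimen_id`, `habitat`
#'   (`"urban"` or `"forest"`), `municipality` (San Juan, Arecibo,
#'   Aguadilla, Mayagüez or Ponce), `side` (`"left"`/`"right"`), `svl_mm`,
#'   `lamella_count`, and optionally `measured_pad_area_mm2`.
#' @param dpi Optional scan resolution used for records lacking `SCALE=`.
#' @return A `toe_dataset`: list with `records` (coordinates in mm),
#'   `metadata` (tibble, row order matching records) and `dropped`
#'   (tibble of specimen_id and reason).
#' @export
assemble_dataset <- function(records, metadata, dpi = NULL) {
  metadata <- as_tibble(metadata)
  assert_columns(metadata,
                 c("specimen_id", "habitat", "municipality", "side",
                   "svl_mm", "lamella_count"),
                 "metadata")
  if (anyDuplicated(metadata$specimen_id)) {
    dup <- unique(metadata$specimen_id[duplicated(metadata$specimen_id)])
    abort(sprintf("Duplicate specimen_id in metadata: %s",
                  paste(dup, collapse = ", ")))
  }
  ids <- purrr::map_chr(records, "specimen_id")
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate specimen_id in records: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  bad_hab <- setdiff(unique(metadata$habitat), HABITATS)
  if (length(bad_hab)) {
    abort(sprintf("Unknown habitat value(s): %s", paste(bad_hab, collapse = ", ")))
  }
  bad_mun <- setdiff(unique(metadata$municipality), MUNICIPALITIES)
  if (length(bad_mun)) {
    abort(sprintf("Unknown municipality value(s): %s",
                  paste(bad_mun, collapse = ", ")))
  }

  dropped <- tibble(specimen_id = character(), reason = character())
  fallback <- if (!is.null(dpi)) scale_from_dpi(dpi) else NA_real_

  kept <- list()
  for (r in records) {
    if (!r$specimen_id %in% metadata$specimen_id) {
      dropped <- bind_rows(dropped, tibble(specimen_id = r$specimen_id,
                                           reason = "no metadata row"))
      next
    }
    sc <- r$scale_mm_per_px %||% NA_real_
    if (is.na(sc)) sc <- fallback
    if (is.na(sc)) {
      dropped <- bind_rows(dropped, tibble(specimen_id = r$specimen_id,
                                           reason = "no scale and no dpi"))
      next
    }
    r$landmarks <- r$landmarks * sc
    r$curves <- purrr::map(r$curves, ~ .x * sc)
    r$scale_mm_per_px <- sc
    kept[[length(kept) + 1L]] <- r
  }
  if (nrow(dropped)) {
    inform(sprintf("assemble_dataset: dropped %d record(s): %s",
                   nrow(dropped),
                   paste(sprintf("%s (%s)", dropped$specimen_id,
                                 dropped$reason), collapse = "; ")))
  }
  kept_ids <- purrr::map_chr(kept, "specimen_id")
  meta <- metadata[match(kept_ids, metadata$specimen_id), , drop = FALSE]
  structure(list(records = kept, metadata = meta, dropped = dropped),
            class = "toe_dataset")
}

#' @export
print.toe_dataset <- function(x, ...) {
  n <- length(x$records %||% x$configs)
  cat(sprintf("<toe_dataset> %d specimens (%s)\n", n,
              if (!is.null(x$configs)) "validated configurations" else "raw records in mm"))
  if (!is.null(x$metadata)) {
    tab <- table(x$metadata$habitat)
    cat("  habitat:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Long per-point table of a dataset's coordinates
#'
#' One row per specimen-point: `specimen_id`, `point_index` (flattened,
#' landmarks first then curve points), `point_role`, `x_mm`, `y_mm`.
#' Works on assembled datasets (raw records) and prepared datasets
#' (validated configurations).
#'
#' @param dataset A `toe_dataset`.
#' @return A tibble.
#' @export
dataset_points <- function(dataset) {
  items <- dataset$configs %||% dataset$records
  purrr::map_dfr(items, function(r) {
    if (inherits(r, "toe_config")) {
      pts <- config_points(r)
      roles <- c(rep("fixed", nrow(r$fixed)),
                 rep("semilandmark", nrow(pts) - nrow(r$fixed)))
      id <- r$specimen_id
    } else {
      pts <- rbind(r$landmarks, do.call(rbind, r$curves))
      roles <- c(rep("fixed", nrow(r$landmarks)),
                 rep("semilandmark", nrow(pts) - nrow(r$landmarks)))
      id <- r$specimen_id
    }
    tibble(specimen_id = id, point_index = seq_len(nrow(pts)),
           point_role = roles, x_mm = pts[, 1L], y_mm = pts[, 2L])
  })
}
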