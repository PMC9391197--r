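#' Run the full toe-shape analysis pipeline
#'
#' Orchestrates the analysis sequence end to end: ingestion (join to
#' metadata, scale to mm), validation/stripping/mirroring, generalized
#' Procrustes alignment with semilandmark sliding, the multivariate suite
#' (Procrustes ANOVA of shape on habitat x municipality, disparity, PCA,
#' between-group PCA, CVA with its label-randomization null), linear
#' measurement extraction, the univariate test battery, the type-II GLM
#' tables, and measurement repeatability when replicates are present.
#' Every random stage derives its seed from `seed`, so rerunning with the
#' same inputs and seed reproduces every number exactly.
#'
#' @param x A `toe_population` (from [sample_population()]), an assembled
#'   `toe_dataset`, or a path to a TPS file.
#' @param metadata Metadata data frame or CSV path (required when `x` is
#'   a TPS path).
#' @param area_replicates Optional replicate table for
#'   [icc_repeatability()]; taken from a `toe_population` automatically.
#' @param scheme A `toe_scheme`.
#' @param n_perm Permutations for ANOVA and disparity.
#' @param n_rand Randomized datasets for the CVA null.
#' @param seed Master seed.
#' @param slide Slide semilandmarks during alignment.
#' @param dpi Fallback scan resolution for records lacking `SCALE=`.
#' @param out_dir If non-NULL, write result tables (CSV), QC plots (PDF)
#'   and a JSON manifest there.
#' @return A `toe_results` bundle.
#' @export
run_pipeline <- function(x, metadata = NULL, area_replicates = NULL,
                         scheme = toe_scheme(), n_perm = 999L, n_rand = 100L,
                         seed = 1L, slide = TRUE, dpi = NULL, out_dir = NULL) {
  if (inherits(x, "toe_population")) {
    area_replicates <- area_replicates %||% x$area_replicates
    dataset <- assemble_dataset(x$records, x$metadata, dpi = dpi)
  } else if (inherits(x, "toe_dataset")) {
    dataset <- x
  } else if (is.character(x)) {
    if (is.null(metadata)) abort("Supply metadata alongside a TPS path.")
    if (is.character(metadata)) {
      metadata <- utils::read.csv(metadata, check.names = FALSE)
    }
    dataset <- assemble_dataset(read_tps(x), metadata, dpi = dpi)
  } else {
    abort("`x` must be a toe_population, toe_dataset, or TPS path.")
  }
  dataset <- prepare_configurations(dataset, scheme)
  aligned <- gpa_align(dataset, scheme, slide = slide)

  anova <- procrustes_anova(aligned, n_perm = n_perm, seed = seed)
  disparity <- morphological_disparity(aligned, n_perm = n_perm,
                                       seed = seed + 1L)
  pca <- shape_pca(aligned)
  bgpca <- between_group_pca(aligned)
  cva_res <- cva(aligned)
  cva_null <- cva_randomization_null(aligned, n_rand = n_rand,
                                     seed = seed + 2L)
  measurements <- measure_dataset(dataset, scheme)
  ratio_tests <- ratio_analysis(measurements)
  glms <- list(
    area_lamellae = glm_anova_type2(measurements, "area_lamellae"),
    height_by_length = glm_anova_type2(measurements, "height_by_length"),
    count_by_length = glm_anova_type2(measurements, "count_by_length"),
    height_by_count = glm_anova_type2(measurements, "height_by_count"))
  icc <- if (!is.null(area_replicates) && nrow(area_replicates)) {
    icc_repeatability(area_replicates)
  }
  qc <- qc_overlays(dataset, aligned)

  bundle <- structure(list(
    dataset = dataset, aligned = aligned, anova = anova,
    disparity = disparity, pca = pca, bgpca = bgpca, cva = cva_res,
    cva_null = cva_null, measurements = measurements,
    ratio_tests = ratio_tests, glms = glms, icc = icc, qc = qc,
    settings = list(n_perm = n_perm, n_rand = n_rand, seed = seed,
                    slide = slide)
  ), class = "toe_results")
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

#' @export
print.toe_results <- function(x, ...) {
  cat(sprintf("<toe_results> %d specimens; seed %d, %d permutations\n",
              nrow(x$measurements), x$settings$seed, x$settings$n_perm))
  hab <- x$anova$table[x$anova$table$term == "habitat", ]
  if (nrow(hab)) {
    cat(sprintf("  shape ~ habitat: F = %.2f, Rsq = %.3f, p = %.4g\n",
                hab$F, hab$Rsq, hab$p_perm))
  }
  cat(sprintf("  CVA separation %.2f (null max %.2f); disparity p = %.3f\n",
              x$cva$separation, x$cva_null$max,
              x$disparity$pairs$p_perm[1L]))
  invisible(x)
}

write_results <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    write.csv(as.data.frame(df), file.path(out_dir, name), row.names = FALSE)
  }
  wr(bundle$anova$table, "procrustes_anova.csv")
  wr(bundle$disparity$pairs, "disparity_pairs.csv")
  wr(bundle$disparity$pv, "disparity_variance.csv")
  wr(bundle$pca$eig, "pca_eigenvalues.csv")
  wr(bundle$pca$scores_tbl, "pca_scores.csv")
  wr(bundle$cva$scores_tbl, "cva_scores.csv")
  wr(bundle$measurements, "measurements.csv")
  wr(bundle$ratio_tests, "ratio_tests.csv")
  for (nm in names(bundle$glms)) wr(bundle$glms[[nm]], paste0("glm_", nm, ".csv"))
  wr(bundle$qc$outliers, "qc_outliers.csv")
  ggplot2::ggsave(file.path(out_dir, "qc_pre_alignment.pdf"),
                  bundle$qc$pre_plot, width = 6, height = 6)
  ggplot2::ggsave(file.path(out_dir, "qc_post_alignment.pdf"),
                  bundle$qc$post_plot, width = 6, height = 6)
  ggplot2::ggsave(file.path(out_dir, "pca_scores.pdf"),
                  autoplot(bundle$pca), width = 6, height = 5)
  ggplot2::ggsave(file.path(out_dir, "cva_histogram.pdf"),
                  autoplot(bundle$cva), width = 6, height = 4)
  manifest <- list(
    package_version = as.character(utils::packageVersion("toemorph")),
    r_version = R.version.string,
    settings = bundle$settings,
    n_specimens = nrow(bundle$measurements),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Pre/post alignment QC overlays and outlier scores
#'
#' Overlays every specimen's points before (translation-registered mm) and
#' after alignment, and scores each specimen by its Procrustes distance to
#' the consensus, sorted descending (ties broken by specimen id) for
#' review of bent or mis-digitized toes.
#'
#' @param dataset A prepared `toe_dataset`.
#' @param aligned The matching `toe_aligned`.
#' @return A list: `pre_plot`, `post_plot` (ggplots), `outliers` (tibble).
#' @export
qc_overlays <- function(dataset, aligned) {
  pre <- purrr::imap_dfr(dataset$configs, function(cfg, id) {
    p <- center_points(config_points(cfg))
    tibble(specimen_id = id, x = p[, 1L], y = p[, 2L])
  })
  ids <- dimnames(aligned$coords)[[1L]]
  post <- purrr::map_dfr(seq_along(ids), function(i) {
    tibble(specimen_id = ids[i],
           x = aligned$coords[i, , 1L], y = aligned$coords[i, , 2L])
  })
  overlay <- function(df, title, unit) {
    ggplot(df, aes(x = .data$x, y = .data$y, group = .data$specimen_id)) +
      geom_point(alpha = 0.2, size = 0.4) +
      coord_equal() +
      labs(title = title, x = paste0("x (", unit, ")"),
           y = paste0("y (", unit, ")")) +
      theme_minimal()
  }
  d <- vapply(seq_along(ids), function(i) {
    procrustes_distance(aligned$coords[i, , ], aligned$consensus)
  }, numeric(1))
  outliers <- tibble(specimen_id = ids, distance_to_consensus = d)
  outliers <- arrange(outliers, desc(.data$distance_to_consensus),
                      .data$specimen_id)
  list(
    pre_plot = overlay(pre, "Before alignment (centred)", "mm"),
    post_plot = overlay(post, "After Procrustes alignment", "Procrustes units"),
    outliers = outliers)
}
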