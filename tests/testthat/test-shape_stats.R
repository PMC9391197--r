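make_design <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    habitat = sample(c("urban", "forest"), n, replace = TRUE),
    municipality = sample(c("San Juan", "Ponce", "Arecibo"), n, replace = TRUE))
}

test_that("the RRPP engine reproduces car's type-II table on one response", {
  skip_if_not_installed("car")
  set.seed(11)
  n <- 60
  d <- make_design(n)
  y <- matrix(rnorm(n, sd = 2) +
                2 * (d$habitat == "urban") +
                as.numeric(factor(d$municipality)), ncol = 1)
  ours <- toemorph:::rrpp_anova(y, d, ~ habitat * municipality,
                                n_perm = 49, seed = 5)$table
  fit <- lm(y ~ habitat * municipality, data = d)
  ref <- car::Anova(fit, type = 2)
  for (term in c("habitat", "municipality", "habitat:municipality")) {
    i <- match(term, ours$term)
    j <- match(term, rownames(ref))
    expect_equal(ours$SS[i], ref[["Sum Sq"]][j], tolerance = 1e-8)
    expect_equal(ours$df[i], ref[["Df"]][j])
    expect_equal(ours$F[i], ref[["F value"]][j], tolerance = 1e-8)
  }
})

test_that("type-II sums of squares are additive on balanced designs", {
  set.seed(12)
  d <- tidyr::crossing(habitat = c("urban", "forest"),
                       municipality = c("San Juan", "Ponce"),
                       rep = 1:8)
  y <- matrix(rnorm(nrow(d) * 6), nrow(d), 6)
  tab <- toemorph:::rrpp_anova(y, d, ~ habitat * municipality,
                               n_perm = 9, seed = 1)$table
  terms_ss <- sum(tab$SS[!tab$term %in% c("Residuals", "Total")])
  resid_ss <- tab$SS[tab$term == "Residuals"]
  total_ss <- tab$SS[tab$term == "Total"]
  expect_equal(terms_ss + resid_ss, total_ss, tolerance = 1e-8)
})

test_that("Procrustes ANOVA is seed-deterministic and rotation-invariant", {
  ds <- prepared_population(paper_population_spec(n_per_cell = 5, seed = 31))
  al <- gpa_align(ds, slide = FALSE)
  a1 <- procrustes_anova(al, n_perm = 99, seed = 17)
  a2 <- procrustes_anova(al, n_perm = 99, seed = 17)
  expect_identical(a1$table, a2$table)

  # rotating the whole aligned sample leaves every SS unchanged
  al_rot <- al
  r <- toemorph:::rot2(0.6458)
  for (i in seq_len(dim(al$coords)[1])) {
    al_rot$coords[i, , ] <- al$coords[i, , ] %*% r
  }
  a3 <- procrustes_anova(al_rot, n_perm = 99, seed = 17)
  expect_equal(a3$table$SS, a1$table$SS, tolerance = 1e-8)

  # total SS = (n - 1) x total shape variance
  n <- dim(al$coords)[1]
  y <- toemorph:::aligned_matrix(al)
  expect_equal(a1$table$SS[a1$table$term == "Total"],
               sum(sweep(y, 2, colMeans(y))^2), tolerance = 1e-10)
})

test_that("disparity sees symmetric scatters as equal and scaling quadratically", {
  set.seed(13)
  base <- matrix(rnorm(30 * 8, sd = 0.1), 30, 8)
  base <- sweep(base, 2, colMeans(base))
  y <- rbind(base, -base)  # mirror copy: identical dispersion
  meta <- tibble::tibble(habitat = rep(c("urban", "forest"), each = 30))
  al <- fake_aligned(y, meta)
  d <- morphological_disparity(al, partial = NULL, n_perm = 99, seed = 1)
  expect_equal(d$pv$procrustes_variance[1], d$pv$procrustes_variance[2],
               tolerance = 1e-10)
  expect_equal(d$pairs$relative_excess, c(0, 0), tolerance = 1e-10)

  # scaling one group's residuals by 1.2 scales its variance by 1.44
  y2 <- rbind(base, 1.2 * base)
  al2 <- fake_aligned(y2, meta)
  d2 <- morphological_disparity(al2, partial = NULL, n_perm = 99, seed = 1)
  pv <- setNames(d2$pv$procrustes_variance, d2$pv$group)
  expect_equal(unname(pv["urban"] / pv["forest"]), 1 / 1.44, tolerance = 1e-10)

  expect_error(morphological_disparity(
    fake_aligned(y[1:32, ], meta[1:32, ]), partial = NULL), "at least 3")
})

test_that("disparity label permutation is calibrated under homogeneity", {
  set.seed(14)
  ps <- replicate(100, {
    y <- matrix(rnorm(24 * 6), 24, 6)
    meta <- tibble::tibble(habitat = rep(c("urban", "forest"), each = 12))
    d <- morphological_disparity(fake_aligned(y, meta), partial = NULL,
                                 n_perm = 39, seed = sample.int(1e6, 1))
    d$pairs$p_perm[1]
  })
  # p-values should be roughly uniform: mean near 0.5, no mass collapse
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  # discrete permutation p-values tie; the KS statistic is still informative
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("shape PCA has a complete orthogonal basis", {
  ds <- prepared_population(paper_population_spec(n_per_cell = 3, seed = 33))
  al <- gpa_align(ds, slide = FALSE)
  pc <- shape_pca(al)
  expect_equal(sum(pc$eig$percent), 100, tolerance = 1e-6)
  # reconstruction from all axes reproduces every aligned shape
  y <- toemorph:::aligned_matrix(al)
  recon <- sweep(pc$scores %*% t(pc$rotation), 2, pc$center, "+")
  expect_equal(max(abs(recon - y)), 0, tolerance = 1e-8)
  # scores are centred and uncorrelated across axes
  expect_equal(max(abs(colMeans(pc$scores))), 0, tolerance = 1e-10)
  cc <- crossprod(pc$scores[, 1:5])
  expect_equal(max(abs(cc[upper.tri(cc)])), 0, tolerance = 1e-8)

  # rank-1 data: PC1 carries 100 percent
  set.seed(15)
  dir <- rnorm(10)
  y1 <- outer(rnorm(12), dir)
  rownames(y1) <- sprintf("s%02d", 1:12)
  pc1 <- shape_pca(fake_aligned(y1))
  expect_equal(pc1$eig$percent[1], 100, tolerance = 1e-8)
  expect_error(shape_pca(fake_aligned(y1[1:2, ])), "at least 3")
})

test_that("between-group PCA yields g - 1 axes and clusters strong effects", {
  set.seed(16)
  n <- 40
  mu <- c(rep(0, 20), rep(3, 20))
  y <- matrix(rnorm(n * 10, sd = 0.3), n, 10) + mu
  meta <- tibble::tibble(habitat = rep(c("forest", "urban"), each = 20))
  bg <- between_group_pca(fake_aligned(y, meta))
  expect_identical(ncol(bg$scores), 1L)
  # specimens cluster around their group's mean score
  sc <- bg$scores_tbl$bgPC1
  g <- bg$scores_tbl$group
  expect_gt(abs(mean(sc[g == "urban"]) - mean(sc[g == "forest"])),
            4 * (sd(sc[g == "urban"]) + sd(sc[g == "forest"])) / 2)

  # identical group means: zero variance on all axes
  y0 <- rbind(diag(4), diag(4))
  meta0 <- tibble::tibble(habitat = rep(c("a", "b"), each = 4))
  bg0 <- between_group_pca(fake_aligned(y0, meta0), group = "habitat")
  expect_equal(bg0$eig$eigenvalue, 0, tolerance = 1e-12)
  expect_error(between_group_pca(
    fake_aligned(y0[1:4, ], meta0[1:4, ])), "at least 2")
})

test_that("group mean shapes average per landmark in both spaces", {
  ds <- prepared_population(paper_population_spec(n_per_cell = 2, seed = 35))
  al <- gpa_align(ds, slide = FALSE)
  gm <- group_mean_shapes(al, space = "procrustes")
  y <- toemorph:::aligned_matrix(al)
  hab <- al$metadata$habitat
  expect_equal(gm$urban,
               toemorph:::unflat_coords(colMeans(y[hab == "urban", ])),
               tolerance = 1e-12)

  # two identical shapes: mean equals the shape; two shapes: midpoint
  a <- matrix(rnorm(12), 6, 2)
  b <- matrix(rnorm(12), 6, 2)
  y2 <- rbind(toemorph:::flat_coords(a), toemorph:::flat_coords(b))
  al2 <- fake_aligned(y2, tibble::tibble(habitat = c("x", "x")))
  gm2 <- group_mean_shapes(al2, space = "procrustes")
  expect_equal(gm2$x, (a + b) / 2, tolerance = 1e-12)

  # pre-alignment means preserve absolute size contrasts from the generator
  pre <- group_mean_shapes(ds, space = "pre_alignment_mm")
  m <- measure_dataset(ds)
  expect_equal(diff(range(pre$urban[, 2])) > diff(range(pre$forest[, 2])),
               mean(m$total_toe_len_mm[m$habitat == "urban"]) >
                 mean(m$total_toe_len_mm[m$habitat == "forest"]))
})

test_that("CVA returns g - 1 axes and matches lda's discriminant direction", {
  skip_if_not_installed("MASS")
  ds <- prepared_population(paper_population_spec(n_per_cell = 5, seed = 37))
  al <- gpa_align(ds, slide = FALSE)
  cv <- cva(al)
  expect_identical(ncol(cv$scores), 1L)
  expect_gt(cv$separation, 0)
  expect_gt(cv$percent_variation, 0)

  # the CV axis must be collinear with lda's discriminant in the retained
  # PC score space
  y <- toemorph:::aligned_matrix(al)
  pc <- prcomp(y)
  s <- pc$x[, seq_len(cv$k)]
  ld <- MASS::lda(s, grouping = al$metadata$habitat)
  ours <- cv$scores[, 1]
  theirs <- as.vector(s %*% ld$scaling[, 1])
  expect_gt(abs(cor(ours, theirs)), 1 - 1e-8)
})

test_that("CVA separates same-distribution groups only modestly", {
  set.seed(18)
  y <- matrix(rnorm(80 * 12), 80, 12)
  meta <- tibble::tibble(habitat = rep(c("urban", "forest"), 40))
  cv <- cva(fake_aligned(y, meta), retain = 0.999)
  within_sd <- 1  # by construction in CV units
  expect_lt(cv$separation, 2.5)
})

test_that("the CVA randomization null is deterministic and calibrated", {
  ds <- prepared_population(paper_population_spec(n_per_cell = 4, seed = 39))
  al <- gpa_align(ds, slide = FALSE)
  n1 <- cva_randomization_null(al, n_rand = 25, seed = 9)
  n2 <- cva_randomization_null(al, n_rand = 25, seed = 9)
  expect_identical(n1$separations, n2$separations)
  expect_identical(length(n1$separations), 25L)
  expect_error(cva_randomization_null(al, n_rand = 1), "at least 2")

  # zero-effect data: the observed separation sits inside the null
  set.seed(19)
  inside <- replicate(20, {
    y <- matrix(rnorm(40 * 16), 40, 16)
    meta <- tibble::tibble(habitat = rep(c("urban", "forest"), each = 20))
    nl <- cva_randomization_null(fake_aligned(y, meta), n_rand = 30,
                                 seed = sample.int(1e6, 1))
    !nl$exceeds_max
  })
  expect_gte(mean(inside), 0.8)
})

test_that("allometry is absent under isometry and found when shape tracks size", {
  scheme <- toe_scheme()
  set.seed(20)
  iso <- lapply(1:24, function(i) {
    cfg <- stripped_template()
    s <- runif(1, 0.6, 1.8)
    # noise applied before scaling so shape scatter is size-independent
    cfg$fixed <- (cfg$fixed + matrix(rnorm(38, 0, 1e-3), 19, 2)) * s
    cfg$curves <- lapply(cfg$curves, function(m) {
      (m + matrix(rnorm(length(m), 0, 1e-3), nrow(m), 2)) * s
    })
    cfg$specimen_id <- paste0("iso", i)
    cfg
  })
  al <- gpa_align(iso, slide = FALSE)
  a_iso <- allometry_test(al, size = "centroid_size", n_perm = 199, seed = 4)
  expect_lt(a_iso$anova$table$Rsq[1], 0.1)
  expect_gt(a_iso$anova$table$p_perm[1], 0.05)

  # pad length growing super-isometrically with size: strong association
  allo <- lapply(1:24, function(i) {
    s <- runif(1, 0.6, 1.8)
    p <- toe_template_params(pad_len_mm = 3.2 * s^1.8)
    cfg <- stripped_template(p)
    cfg$fixed <- cfg$fixed * s
    cfg$curves <- lapply(cfg$curves, function(m) m * s)
    cfg$specimen_id <- paste0("al", i)
    cfg
  })
  al2 <- gpa_align(allo, slide = FALSE)
  a_allo <- allometry_test(al2, size = "centroid_size", n_perm = 199, seed = 4)
  expect_lt(a_allo$anova$table$p_perm[1], 0.05)
  expect_gt(a_allo$anova$table$Rsq[1], 0.3)
  expect_identical(nrow(a_allo$pc_correlations), 3L)
})
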