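test_that("measurements match hand-built constructions", {
  cfg <- stripped_template()
  # overwrite landmarks with hand-placed points
  cfg$fixed[5, ] <- c(0, 0)
  cfg$fixed[6, ] <- c(0, 2)
  m <- suppressWarnings(measure_configuration(cfg))
  expect_equal(m$pad_width_mm, 2.0)

  # collinear midpoints at (0,0), (0,6), (0,9): proximal 6, pad 3, total 9
  cfg2 <- stripped_template()
  cfg2$fixed[1, ] <- c(-1, 0); cfg2$fixed[2, ] <- c(1, 0)
  cfg2$fixed[3, ] <- c(-1, 6); cfg2$fixed[4, ] <- c(1, 6)
  cfg2$fixed[7, ] <- c(-1, 9); cfg2$fixed[8, ] <- c(1, 9)
  m2 <- suppressWarnings(measure_configuration(cfg2))
  expect_equal(m2$proximal_len_mm, 6)
  expect_equal(m2$pad_length_mm, 3)
  expect_equal(m2$total_toe_len_mm, 9)

  # rotation/translation invariance and exact mirroring of all measures
  cfg3 <- stripped_template()
  m3 <- measure_configuration(cfg3)
  r <- toemorph:::rot2(0.7)
  cfg3r <- cfg3
  cfg3r$fixed <- sweep(cfg3$fixed %*% r, 2, c(4, -1), "+")
  cfg3r$curves <- lapply(cfg3$curves, function(x) sweep(x %*% r, 2, c(4, -1), "+"))
  m3r <- measure_configuration(cfg3r)
  expect_equal(as.data.frame(m3r[, -1]), as.data.frame(m3[, -1]),
               tolerance = 1e-10)
  cfg3m <- cfg3
  cfg3m$side <- "right"
  m3m <- measure_configuration(mirror_configuration(cfg3m))
  expect_equal(as.data.frame(m3m[, -1]), as.data.frame(m3[, -1]),
               tolerance = 1e-10)
})

test_that("shoelace area evaluates known polygons", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(toemorph:::shoelace(square), 1.0)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(toemorph:::shoelace(tri), 6.0)
  # orientation independence
  expect_equal(toemorph:::shoelace(square[4:1, ]), 1.0)
  expect_true(toemorph:::polygon_is_simple(square))
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_false(toemorph:::polygon_is_simple(bowtie))
})

test_that("the pad outline area is invariant and close to its construction", {
  cfg <- stripped_template(toe_template_params(outline_bulge = 1e-9))
  a <- polygon_area(cfg)
  # with no bulge the outline is the polygon through the fixed landmarks
  lm <- cfg$fixed
  poly <- rbind(lm[3, ], lm[5, ], lm[7, ], lm[9, ], lm[8, ], lm[6, ], lm[4, ])
  expect_equal(a, toemorph:::shoelace(poly), tolerance = 1e-6)

  r <- toemorph:::rot2(1.2)
  cfg_r <- cfg
  cfg_r$fixed <- sweep(cfg$fixed %*% r, 2, c(2, 3), "+")
  cfg_r$curves <- lapply(cfg$curves, function(m) sweep(m %*% r, 2, c(2, 3), "+"))
  expect_equal(polygon_area(cfg_r), a, tolerance = 1e-10)
})

test_that("shoelace area matches Monte Carlo rasterization on random outlines", {
  set.seed(23)
  for (i in 1:5) {
    cfg <- stripped_template(toe_template_params(
      pad_width_mm = runif(1, 1.2, 2.5),
      pad_len_mm = runif(1, 2.5, 4.5),
      outline_bulge = runif(1, 0.02, 0.15)))
    expect_equal(polygon_area(cfg),
                 rasterized_area(outline_polygon(cfg), 1e5),
                 tolerance = 0.02)
  }
})

test_that("the Welch t-test matches the hand formula", {
  a <- c(1.2, 2.9, 3.1)
  b <- c(2.0, 2.2, 4.4)
  res <- welch_t_test(a, b)
  # hand-evaluated Welch statistic and Satterthwaite df
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$statistic, t_hand, tolerance = 1e-6)
  expect_equal(res$df, df_hand, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-6)

  # identical groups: t = 0, p = 1
  res0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # antisymmetry
  swapped <- welch_t_test(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)

  # transforms apply and back-transform the group summaries
  rln <- welch_t_test(a, b, transform = "ln")
  expect_equal(rln$mean_a, mean(log(a)))
  expect_equal(rln$back_mean_a, exp(mean(log(a))))
  expect_error(welch_t_test(c(-1, 2), c(1, 2), transform = "ln"),
               "Non-positive")
})

test_that("the ratio battery composes plain Welch tests with no hidden state", {
  ds <- prepared_population(paper_population_spec(n_per_cell = 4, seed = 41))
  m <- measure_dataset(ds)
  battery <- ratio_analysis(m)
  expect_identical(nrow(battery), 7L)
  manual <- welch_t_test(
    m$pad_width_mm[m$habitat == "urban"] / m$pad_length_mm[m$habitat == "urban"],
    m$pad_width_mm[m$habitat == "forest"] / m$pad_length_mm[m$habitat == "forest"],
    transform = "ln")
  row <- battery[battery$measure == "width_length_ratio", ]
  expect_equal(row$statistic, manual$statistic)
  expect_equal(row$df, manual$df)
  expect_equal(row$p_value, manual$p_value)
  expect_true(all(m$total_toe_len_mm == m$pad_length_mm + m$proximal_len_mm))
})

test_that("isometric groups show no ratio difference", {
  # same template shapes, group-specific scale only: ratios are invariant
  set.seed(24)
  mk <- function(scale, id) {
    cfg <- stripped_template()
    noise <- function(m) (m + matrix(rnorm(length(m), 0, 0.01),
                                     nrow(m), 2)) * scale
    cfg$fixed <- noise(cfg$fixed)
    cfg$curves <- lapply(cfg$curves, noise)
    cfg$specimen_id <- id
    cfg
  }
  configs <- c(lapply(1:15, function(i) mk(1.3, paste0("u", i))),
               lapply(1:15, function(i) mk(1.0, paste0("f", i))))
  meta <- tibble::tibble(specimen_id = sapply(configs, `[[`, "specimen_id"),
                         habitat = rep(c("urban", "forest"), each = 15),
                         municipality = "Ponce", side = "left",
                         svl_mm = 50,
                         lamella_count = pmax(1, round(rnorm(30, 22, 1.4))),
                         measured_pad_area_mm2 = NA_real_)
  ds <- structure(list(configs = setNames(configs, meta$specimen_id),
                       metadata = meta), class = "toe_dataset")
  m <- measure_dataset(ds)
  row <- ratio_analysis(m)[1, ]  # width/length ratio
  expect_gt(row$p_value, 0.05)
})

test_that("percent difference reproduces its arithmetic", {
  expect_equal(percent_difference(1.86, 1.69), 10.06)
  expect_equal(percent_difference(3, 3), 0)
  expect_equal(percent_difference(2, 1), 100)
  expect_error(percent_difference(1, 0), "positive")
})

test_that("type-II GLM tables are correct on orthogonal designs and errors", {
  set.seed(25)
  # balanced orthogonal design: type II equals sequential type I
  d <- tidyr::crossing(habitat = c("urban", "forest"), rep = 1:20)
  m <- tibble::tibble(
    habitat = d$habitat,
    pad_length_mm = exp(rnorm(40, 1, 0.1)),
    lamella_height_mm = exp(rnorm(40, -1.8, 0.1)),
    lamella_count = 22, lm_polygon_area_mm2 = 6,
    measured_pad_area_mm2 = exp(rnorm(40, 1.8, 0.1)))
  t2 <- glm_anova_type2(m, "height_by_length")
  fit <- lm(log(lamella_height_mm) ~ log(pad_length_mm) * habitat, data = m)
  t1 <- anova(fit)
  expect_equal(t2$SS[t2$term == "habitat"],
               t1["habitat", "Sum Sq"], tolerance = 1e-6)

  # a response driven by height alone: height term strong, count term not
  n <- 120
  m2 <- tibble::tibble(
    habitat = rep(c("urban", "forest"), n / 2),
    pad_length_mm = exp(rnorm(n, 1.2, 0.12)),
    lamella_height_mm = exp(rnorm(n, -1.8, 0.15)),
    lamella_count = pmax(1, round(rnorm(n, 22, 1.4))),
    lm_polygon_area_mm2 = 6)
  m2$measured_pad_area_mm2 <- m2$lamella_height_mm^1.5 * exp(rnorm(n, 3, 0.05))
  t3 <- glm_anova_type2(m2, "area_lamellae")
  expect_lt(t3$p_value[t3$term == "ln_height"], 1e-6)
  expect_gt(t3$p_value[t3$term == "sqrt_count"], 0.01)

  # rank deficiency is reported with the aliased term
  m3 <- m2
  m3$lamella_count <- 22
  expect_error(glm_anova_type2(m3, ln_area ~ sqrt_count + sqrt_count),
               "aliased|deficient")
})

test_that("ICC matches the hand variance decomposition", {
  # hand-built 3 specimens x 2 replicates
  reps <- tibble::tibble(
    specimen_id = rep(c("a", "b", "c"), each = 2),
    value = c(1.0, 1.2, 2.0, 2.1, 3.3, 3.0))
  res <- icc_repeatability(reps)
  # hand one-way ANOVA decomposition
  gm <- tapply(reps$value, reps$specimen_id, mean)
  msb <- 2 * var(gm)
  ssw <- sum((reps$value - gm[reps$specimen_id])^2)
  msw <- ssw / 3
  among <- (msb - msw) / 2
  expect_equal(res$within_var, msw, tolerance = 1e-6)
  expect_equal(res$among_var, among, tolerance = 1e-6)
  expect_equal(res$icc, among / (among + msw), tolerance = 1e-6)

  # identical replicates: perfect repeatability
  perfect <- tibble::tibble(specimen_id = rep(c("a", "b"), each = 3),
                            value = rep(c(1, 2), each = 3))
  resp <- icc_repeatability(perfect)
  expect_equal(resp$icc, 1)
  expect_equal(resp$within_var, 0)

  # pure replicate noise with no specimen effect: ICC near zero
  set.seed(26)
  noise <- tibble::tibble(specimen_id = rep(sprintf("s%03d", 1:200), each = 3),
                          value = rnorm(600))
  expect_lt(icc_repeatability(noise)$icc, 0.15)

  expect_error(icc_repeatability(
    tibble::tibble(specimen_id = c("a", "b"), value = 1:2)), "replicated")
})
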