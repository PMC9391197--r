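# broom-style accessors for fitted result objects

#' @method tidy toe_anova
#' @export
tidy.toe_anova <- function(x, ...) x$table

#' @method glance toe_anova
#' @export
glance.toe_anova <- function(x, ...) {
  tibble(ss_type = x$ss_type, n_perm = x$n_perm,
         seed = x$seed %||% NA_integer_,
         total_SS = x$table$SS[x$table$term == "Total"])
}

#' @method tidy toe_disparity
#' @export
tidy.toe_disparity <- function(x, ...) x$pairs

#' @method glance toe_disparity
#' @export
glance.toe_disparity <- function(x, ...) {
  tibble(n_groups = nrow(x$pv), n_perm = x$n_perm,
         seed = x$seed %||% NA_integer_)
}

#' @method tidy toe_pca
#' @export
tidy.toe_pca <- function(x, ...) x$eig

#' @method tidy toe_bgpca
#' @export
tidy.toe_bgpca <- function(x, ...) x$eig

#' @method tidy toe_cva
#' @export
tidy.toe_cva <- function(x, ...) x$scores_tbl

#' @method glance toe_cva
#' @export
glance.toe_cva <- function(x, ...) {
  tibble(n_axes = ncol(x$scores), retained_dims = x$k,
         separation = x$separation,
         percent_variation = x$percent_variation)
}

#' @method tidy toe_cva_null
#' @export
tidy.toe_cva_null <- function(x, ...) {
  tibble(randomization = seq_along(x$separations),
         separation = x$separations)
}

#' @method glance toe_cva_null
#' @export
glance.toe_cva_null <- function(x, ...) {
  tibble(n_rand = x$n_rand, mean = x$mean, sd = x$sd, max = x$max,
         observed = x$observed, exceeds_max = x$exceeds_max)
}

#' @method tidy toe_allometry
#' @export
tidy.toe_allometry <- function(x, ...) x$anova$table

#' @method glance toe_allometry
#' @export
glance.toe_allometry <- function(x, ...) {
  tibble(size_type = x$size_type,
         pc1_r = x$pc_correlations$r[1L],
         pc2_r = x$pc_correlations$r[2L],
         pc3_r = x$pc_correlations$r[3L])
}
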