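# internal helpers shared across modules

# flatten a k x 2 coordinate matrix column-major (all x, then all y)
flat_coords <- function(m) as.vector(m)

unflat_coords <- function(v) matrix(v, ncol = 2L)

# stack every point of a configuration: fixed landmarks first, then curves
config_points <- function(config) {
  rbind(config$fixed, do.call(rbind, config$curves))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# rotation R minimizing ||X %*% R - target||_F over proper rotations
# (orthogonal matrices if allow_reflection)
fit_rotation <- function(x, target, allow_reflection = FALSE) {
  m <- crossprod(x, target)
  sv <- svd(m)
  r <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(r) < 0) {
    r <- sv$u %*% diag(c(1, -1)) %*% t(sv$v)
  }
  r
}

center_points <- function(m) sweep(m, 2L, colMeans(m))

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}

HABITATS <- c("urban", "forest")
MUNICIPALITIES <- c("San Juan", "Arecibo", "Aguadilla", "Mayagüez", "Ponce")
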