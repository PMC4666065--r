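# shared fixtures; everything is generated in code at test time

test_spacing <- 0.03442

# a small blob volume with a couple of landmarks, for IO and label tests
blob_volume <- function(d = c(16, 20, 16), spacing = rep(1, 3),
                        origin = c(0, 0, 0)) {
  gx <- seq_len(d[1]) - 1; gy <- seq_len(d[2]) - 1; gz <- seq_len(d[3]) - 1
  c0 <- (d - 1) / 2
  r <- (d - 1) / 3
  e <- outer(outer(((gx - c0[1]) / r[1])^2, ((gy - c0[2]) / r[2])^2, `+`),
             ((gz - c0[3]) / r[3])^2, `+`)
  volume(array(exp(-e), d), spacing, origin)
}

# small synthetic study, memoised across tests in one file run
.study_cache <- new.env(parent = emptyenv())
small_study <- function(n = 6, grid = c(32, 48, 32), seed = 11, ...) {
  key <- paste(n, paste(grid, collapse = "x"), seed, ...)
  if (is.null(.study_cache[[key]])) {
    spec <- synth_study_spec(n = n, grid = grid, ...)
    .study_cache[[key]] <- synth_study(spec, seed = seed)
  }
  .study_cache[[key]]
}

lm_err_vox <- function(a, b, spacing = test_spacing) {
  sqrt(rowSums((as.matrix(a[, c("x", "y", "z")]) -
                  as.matrix(b[, c("x", "y", "z")]))^2)) / spacing
}

expect_landmarks_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$name, b$name)
  expect_lt(max(abs(as.matrix(a[, c("x", "y", "z")]) -
                      as.matrix(b[, c("x", "y", "z")]))), tol)
}

# fast registration settings for small test grids
fast_reg <- function() registration_config(levels = 3,
                                           iterations = c(80, 40, 20))
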