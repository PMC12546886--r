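# Shared independent oracles and tiny fixtures for the test suite.

with_seed <- vibroseed:::with_seed

# O(n^2 m) brute-force nondominated front peeling, independent of the
# package's fast sort.
brute_fronts <- function(F) {
  n <- nrow(F)
  remaining <- seq_len(n)
  fronts <- list()
  while (length(remaining) > 0) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        i != j && all(F[j, ] <= F[i, ]) && any(F[j, ] < F[i, ])
      }, TRUE))
    }, TRUE)]
    fronts[[length(fronts) + 1]] <- sort(nd)
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# Monte-Carlo hypervolume estimate with standard error.
mc_hypervolume <- function(F, ref, n_samples = 20000) {
  lo <- apply(F, 2, min)
  vol <- prod(ref - lo)
  U <- sapply(seq_along(ref), function(j) runif(n_samples, lo[j], ref[j]))
  dominated <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(F))) {
    inside <- rep(TRUE, n_samples)
    for (j in seq_along(ref)) inside <- inside & U[, j] >= F[i, j]
    dominated <- dominated | inside
  }
  p <- mean(dominated)
  list(hv = p * vol, se = sqrt(p * (1 - p) / n_samples) * vol)
}

# Moment-based ellipse fit: major/minor axis lengths (in pixels) of the
# bright region of a rendered seed image.
fit_ellipse_axes <- function(img) {
  bright <- img[, , 1] + img[, , 2] + img[, , 3]
  mask <- bright > 0.5
  idx <- which(mask, arr.ind = TRUE)
  mu <- colMeans(idx)
  S <- stats::cov(sweep(idx, 2, mu)) * (nrow(idx) - 1) / nrow(idx)
  ev <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
  # uniform ellipse: variance along an axis = (semi-axis)^2 / 4
  c(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]))
}

# A small calibrated problem shared by optimizer tests.
test_problem <- function(variety = 1) {
  v <- default_varieties()
  make_problem(v[[variety]])
}

# A protocol safely inside all bounds.
mid_protocol <- function(...) {
  treatment_protocol(field_strength_mT = 2.5, frequency_Hz = 300,
                     duration_s = 120, ...)
}
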