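#' Sigmoid parameter sets for the pairwise-distance cost
#'
#' Six positive reals: `sigma_h, a_h, b_h` shape the sigmoid applied to
#' high-dimensional (fingerprint-space) distances, `sigma_l, a_l, b_l` the one
#' applied to low-dimensional (map-space) distances. `sigma` is the distance
#' at which the sigmoid reaches 1/2, i.e. the distance scale the embedding
#' focuses on; `a` and `b` set how sharply smaller and larger distances are
#' suppressed.
#'
#' Two presets are provided, tuned for a small fast-folding mini-protein
#' (20 residues; `sigma_h = 0.5`) and for a larger two-domain protein
#' (165 residues; `sigma_h = 1.0`).
#'
#' @param sigma_h,a_h,b_h high-dimensional sigmoid parameters
#' @param sigma_l,a_l,b_l low-dimensional sigmoid parameters
#' @return object of class `sigmoid_params`
#' @export
sigmoid_params <- function(sigma_h = 0.5, a_h = 6, b_h = 6,
                           sigma_l = 1, a_l = 2, b_l = 6) {
  p <- list(sigma_h = sigma_h, a_h = a_h, b_h = b_h,
            sigma_l = sigma_l, a_l = a_l, b_l = b_l)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1)))) {
    stop("input error: all six sigmoid parameters must be positive scalars")
  }
  structure(p, class = "sigmoid_params")
}

#' @rdname sigmoid_params
#' @param preset `"minipro"` (sigma_h 0.5, for ~20-residue systems) or
#'   `"twodomain"` (sigma_h 1.0, for larger multi-domain systems)
#' @export
sigmoid_preset <- function(preset = c("minipro", "twodomain")) {
  preset <- match.arg(preset)
  switch(preset,
         minipro   = sigmoid_params(0.5, 6, 6, 1, 2, 6),
         twodomain = sigmoid_params(1.0, 6, 6, 1, 2, 6))
}

#' Sigmoid transform of a pairwise distance
#'
#' `s(r) = 1 - (1 + (2^(a/b) - 1) * (r/sigma)^a)^(-b/a)`
#'
#' Monotonically non-decreasing in `r`, with `s(0) = 0`, `s(sigma) = 1/2`
#' (exactly, for any `a`, `b`) and `s(r) -> 1` as `r -> Inf`. Compresses very
#' small and very large distances so the embedding concentrates on
#' intermediate-scale structure (the Sketch-map idea).
#'
#' @param r non-negative distance (vectorized)
#' @param sigma,a,b positive parameters
#' @return values in `[0, 1)`
#' @export
sigmoid_transform <- function(r, sigma, a, b) {
  if (any(r < 0)) stop("input error: distances must be non-negative")
  if (sigma <= 0 || a <= 0 || b <= 0) {
    stop("input error: sigma, a, b must be positive")
  }
  k <- 2^(a / b) - 1
  1 - (1 + k * (r / sigma)^a)^(-b / a)
}

# derivative ds/dr, with the r = 0 limit handled (0 for a > 1, finite for a = 1)
sigmoid_transform_deriv <- function(r, sigma, a, b) {
  k <- 2^(a / b) - 1
  u <- (r / sigma)^a
  base <- (1 + k * u)^(-b / a - 1)
  # d/dr [k u] = k * a * r^(a-1) / sigma^a ; guard r = 0 for a < 1 not needed (a > 0)
  dr <- ifelse(r > 0, k * a * r^(a - 1) / sigma^a, if (a == 1) k / sigma else 0)
  (b / a) * base * dr
}
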