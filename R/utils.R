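# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("cannot normalize a (near-)zero vector", class = "waterkrig_degenerate_frame")
  v / n
}

# uniform random rotation matrix (quaternion method); uses the current RNG stream
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# derive a stream of well-separated 31-bit sub-seeds from one master seed
.sub_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

.assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "waterkrig_domain_error")
  }
  as.integer(x)
}
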