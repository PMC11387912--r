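# internal helpers shared across modules

hr_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "handrehab_error"),
                      call = call))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (n < tol) hr_stop("cannot normalize a near-zero vector", "handrehab_zero_vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# weight-normalized RMS distance in feature space:
# d(a, b) = sqrt(sum(w * (a - b)^2) / sum(w))
feature_dist <- function(a, b, w) {
  sqrt(sum(w * (a - b)^2) / sum(w))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1)
    hr_stop(sprintf("`%s` must be a single number in [0, 1]", name),
            "handrehab_bad_argument")
}
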