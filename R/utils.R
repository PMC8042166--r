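# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ftsz <- function(..., class) {
  stop(structure(class = c(class, "ftszdyn_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop_ftsz(name, " must be a single integer >= ", min,
              class = "invalid_spec_error")
  }
  as.integer(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_ftsz(name, " must be a single positive number",
              class = "invalid_spec_error")
  }
  as.numeric(x)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    stop_ftsz("degenerate (zero-length) axis vector", class = "geometry_error")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

centroid <- function(xyz) colMeans(xyz)

# flat xyz row (x1,y1,z1,x2,...) <-> N x 3 matrix
vec2mat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
mat2vec <- function(m) as.numeric(t(m))

# deterministic 32-bit seed stream for (seed, frame, stage) keys
derive_seed <- function(seed, frame = 0L, stage = 0L) {
  m <- 2147483647
  h <- (as.numeric(seed) %% m)
  h <- (h * 48271 + as.numeric(frame) * 1299721 +
          as.numeric(stage) * 7919 + 12345) %% m
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
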