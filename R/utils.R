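# Run code with a temporary RNG state so library functions stay pure.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Deterministic child seeds below 2^31, documented derivation: linear
# congruential fold of the root seed and a stream index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + 101 * as.numeric(index) + 17) %% 2147483647)
}

# Vectorized ray-casting point-in-polygon test (boundary counts as inside
# up to floating-point behaviour of the crossing rule).
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Shoelace polygon area.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

bbox_of <- function(poly) {
  c(xmin = min(poly[, 1]), xmax = max(poly[, 1]),
    ymin = min(poly[, 2]), ymax = max(poly[, 2]))
}
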