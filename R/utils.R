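## Internal helpers shared across modules.

# The 13 unique 3D direction offsets at distance 1 (one of each +/- pair),
# used for both co-occurrence and run-length texture features.
texture_directions <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  # keep one representative per +/- pair: first nonzero component positive
  keep <- apply(d, 1L, function(v) {
    nz <- v[v != 0]
    nz[1L] > 0
  })
  as.matrix(d[keep, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_integerish <- function(x, tol = 1e-8) {
  all(is.finite(x)) && max(abs(x - round(x))) < tol
}

# Quantize values into ng fixed-width bins spanning [min, max].
# A constant region maps every voxel to bin 1.
quantize_bins <- function(x, ng = 32L) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(rep.int(1L, length(x)))
  b <- floor((x - lo) / (hi - lo) * ng) + 1L
  b[b > ng] <- ng
  as.integer(b)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
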