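# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so simulation internals never perturb user code.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from a base seed; stays below 2^31 - 1.
derive_seed <- function(base, i) {
  as.integer((as.numeric(base) + 1000003 * as.numeric(i)) %% 2147483629L + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)

# 2D FFT pair with the unitary-in-round-trip normalization used throughout.
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Mean of the k largest values; the focus/peak statistic robust to hot pixels.
top_k_mean <- function(x, k = 9L) {
  k <- min(k, length(x))
  mean(sort.int(x, decreasing = TRUE)[seq_len(k)])
}

# Pad a matrix to (2*nr, 2*nc) with a constant fill, centered.
pad_matrix <- function(m, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, 2L * nr, 2L * nc)
  r0 <- floor(nr / 2); c0 <- floor(nc / 2)
  out[r0 + seq_len(nr), c0 + seq_len(nc)] <- m
  attr(out, "crop") <- c(r0, c0, nr, nc)
  out
}

crop_matrix <- function(m, crop) {
  m[crop[1] + seq_len(crop[3]), crop[2] + seq_len(crop[4])]
}
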