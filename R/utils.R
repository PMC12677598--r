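# internal helpers shared across modules

# run `code` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

rms <- function(x) sqrt(mean(x^2))

# central-difference derivative, same length as x; t must be uniform
finite_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d
}

# columnwise finite difference for samples x 3 matrices
finite_diff_cols <- function(m, dt) {
  apply(m, 2L, finite_diff, dt = dt)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 1

# zero-phase (forward-backward) IIR filtering of samples x channels data
# with odd-symmetric edge reflection to suppress boundary transients;
# `filt` is a single filter (list with b, a) or a list of cascaded sections
filtfilt_mat <- function(filt, X, npad = 500L) {
  sections <- if (!is.null(filt$b)) list(list(b = filt$b, a = filt$a))
              else lapply(filt, function(f) list(b = f$b, a = f$a))
  one_d <- is.null(dim(X))
  if (one_d) X <- matrix(X, ncol = 1L)
  Y <- cpp_filtfilt(X, sections, as.integer(npad))
  if (one_d) as.numeric(Y) else Y
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
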