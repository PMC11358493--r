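# Shared fixtures: built in code, cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

test_chain <- function() cached("chain", ac225_chain())

# default-voxel Ac-225 chain kernel (39 x 39 x 10 um)
test_kernel <- function() {
  cached("kernel", bin_kernel_to_voxels(
    generate_csda_kernel(test_chain(), radial_step = 0.5), c(39, 39, 10)))
}

# isotropic kernel for cubic-volume convolution tests
test_kernel_iso <- function() {
  cached("kernel_iso", bin_kernel_to_voxels(
    generate_csda_kernel(test_chain(), radial_step = 0.5), c(39, 39, 39)))
}

# Numerical two-nuclide Bateman oracle (parent activity Aa, daughter
# activity Ab): dAa/dt = -la Aa, dAb/dt = lb (Aa - Ab).
bateman_ode <- function(Aa0, Ab0, la, lb, times) {
  deSolve::ode(
    y = c(Aa = Aa0, Ab = Ab0), times = times,
    func = function(t, y, p) list(c(-la * y["Aa"], lb * (y["Aa"] - y["Ab"]))),
    rtol = 1e-10, atol = 1e-12
  )
}

# Smooth strictly positive random image (for gamma-index comparisons)
smooth_image <- function(n, seed, base = 10) {
  set.seed(seed)
  raw <- matrix(rnorm(n * n), n)
  k <- outer(dnorm(-3:3, sd = 1.5), dnorm(-3:3, sd = 1.5))
  k <- k / sum(k)
  sm <- matrix(0, n, n)
  pad <- matrix(0, n + 6, n + 6)
  pad[4:(n + 3), 4:(n + 3)] <- raw
  for (i in 1:7) for (j in 1:7) {
    sm <- sm + k[i, j] * pad[i:(i + n - 1), j:(j + n - 1)]
  }
  base + 3 * sm
}

# Direct double-sum 3D convolution (zero padding), independent of the FFT
# implementation.
conv3d_direct <- function(x, k) {
  dx <- dim(x); dk <- dim(k); ctr <- (dk + 1) / 2
  out <- array(0, dx)
  for (a in seq_len(dk[1])) for (b in seq_len(dk[2])) for (c in seq_len(dk[3])) {
    # out[i] = sum_j k[j] * x[i - (j - center)]
    sa <- a - ctr[1]; sb <- b - ctr[2]; sc <- c - ctr[3]
    xlo <- max(1, 1 + sa); xhi <- min(dx[1], dx[1] + sa)
    ylo <- max(1, 1 + sb); yhi <- min(dx[2], dx[2] + sb)
    zlo <- max(1, 1 + sc); zhi <- min(dx[3], dx[3] + sc)
    if (xlo > xhi || ylo > yhi || zlo > zhi) next
    xi <- xlo:xhi; yi <- ylo:yhi; zi <- zlo:zhi
    out[xi, yi, zi] <- out[xi, yi, zi] +
      k[a, b, c] * x[xi - sa, yi - sb, zi - sc]
  }
  out
}

# Exhaustive all-voxel gamma search, independent of the vectorised
# implementation.
gamma_direct <- function(ref, eval, dose_tol, dist_tol, pixel_size,
                         normalization = "local") {
  nr <- nrow(ref); nc <- ncol(ref)
  rmax <- max(ref)
  g <- matrix(NA_real_, nr, nc)
  coords <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      dn <- if (normalization == "local") ref[i, j] else rmax
      num <- (eval[cbind(coords$i, coords$j)] - ref[i, j])^2
      dterm <- if (dn == 0) ifelse(num == 0, 0, Inf) else num / (dose_tol * dn)^2
      dist2 <- (pixel_size^2) * ((coords$i - i)^2 + (coords$j - j)^2)
      g[i, j] <- sqrt(min(dterm + dist2 / dist_tol^2))
    }
  }
  g
}
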