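# Independent oracles used by the test suite.  These are deliberately
# coded by different routes than the package implementation: the Mie
# oracle uses Lentz's continued fraction for the logarithmic derivative
# and half-integer-order Bessel functions for the Riccati-Bessel
# functions, instead of downward/upward recurrences.

oracle_mie <- function(d, lam, m, nmed) {
  x <- pi * d * nmed / lam
  mrel <- m / nmed
  mx <- mrel * x
  N <- ceiling(x + 4 * x^(1 / 3) + 2)
  lentz_D <- function(n, z) {
    aterm <- function(k) (-1)^(k + 1) * 2 * (n + k - 0.5) / z
    f <- aterm(1); if (f == 0) f <- 1e-30 + 0i
    C <- f; D <- 0 + 0i
    for (k in 2:20000) {
      b <- aterm(k)
      D <- b + D; if (D == 0) D <- 1e-30 + 0i
      C <- b + 1 / C; if (C == 0) C <- 1e-30 + 0i
      D <- 1 / D
      delta <- C * D
      f <- f * delta
      if (Mod(delta - 1) < 1e-15) break
    }
    -n / z + f
  }
  psi <- sqrt(pi * x / 2) * besselJ(x, seq(0.5, N + 0.5))
  chi <- -sqrt(pi * x / 2) * besselY(x, seq(0.5, N + 0.5))
  xi <- complex(real = psi, imaginary = -chi)
  csum <- 0
  for (n in 1:N) {
    Dn <- lentz_D(n, mx)
    fa <- Dn / mrel + n / x
    fb <- Dn * mrel + n / x
    an <- (fa * psi[n + 1] - psi[n]) / (fa * xi[n + 1] - xi[n])
    bn <- (fb * psi[n + 1] - psi[n]) / (fb * xi[n + 1] - xi[n])
    csum <- csum + (2 * n + 1) * Re(an + bn)
  }
  k <- 2 * pi * nmed / lam
  (2 * pi / k^2) * csum * 1e-6
}

# Rayleigh (dipole) limit: absorption + scattering efficiencies
rayleigh_cext <- function(d, lam, m, nmed) {
  x <- pi * d * nmed / lam
  mrel <- m / nmed
  L <- (mrel^2 - 1) / (mrel^2 + 2)
  (4 * x * Im(L) + 8 / 3 * x^4 * Mod(L)^2) * pi * (d / 2)^2 * 1e-6
}

# Analytic Lorentz-oscillator susceptibility: a Kramers-Kronig pair.
# Frequency variable w = 1000/lambda (arbitrary units).
lorentz_pair <- function(lam, lam0, G, f) {
  w <- 1000 / lam
  w0 <- 1000 / lam0
  den <- (w0^2 - w^2)^2 + G^2 * w^2
  list(re = f * (w0^2 - w^2) / den, im = f * G * w / den)
}

# random interior point of the unit 2-simplex
random_fractions <- function() {
  u <- -log(stats::runif(3))
  u <- u / sum(u)
  hb_fractions(u[1], u[2], u[3])
}

# shared fixtures: synthetic optics and the reference-batch PSD
test_optics <- hb_default_optics()
test_psd <- lognormal_from_summary(760, 395)
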