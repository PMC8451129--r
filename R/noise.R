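#' Rician magnitude noise
#'
#' Corrupts a noise-free magnitude signal with Rician noise, modelled as the
#' modulus of a complex signal whose real and imaginary channels each carry
#' independent Gaussian noise: \code{sqrt((s + n1)^2 + n2^2)} with
#' \code{n1, n2 ~ Normal(0, sigma)}. In signal-free voxels this reduces to a
#' Rayleigh distribution with mean \code{sigma * sqrt(pi/2)}.
#'
#' @param signal numeric vector/array of noise-free magnitudes.
#' @param sigma Gaussian channel standard deviation (signal units).
#' @return Noisy magnitudes with the shape of \code{signal}.
#' @examples
#' x <- riceNoise(rep(0, 1000), sigma = 1)
#' mean(x) # close to sqrt(pi/2)
#' @export
riceNoise <- function(signal, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}
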