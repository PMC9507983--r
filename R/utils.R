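#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Used by the EEG simulator to draw
#' per-epoch phase offsets; the mean resultant length of the distribution is
#' \code{besselI(kappa, 1) / besselI(kappa, 0)}, which is what the inter-trial
#' phase coherence of a noise-free simulated signal converges to.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0); 0 gives the uniform circle, \code{Inf}
#'   a point mass at \code{mu}.
#' @return numeric vector of angles in radians.
#' @export
rVonMises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      out[i] <- sign(u[3L] - 0.5) * acos(max(min(f, 1), -1))
      i <- i + 1L
    }
  }
  mu + out
}

#' Power-law (1/f^alpha) Gaussian noise
#'
#' Spectrally shaped white Gaussian noise: the white spectrum is multiplied
#' by f^(-alpha/2) (DC removed) and inverted, then rescaled to the requested
#' standard deviation.
#'
#' @param n number of samples.
#' @param alpha spectral exponent (1 = pink noise; 0 = white).
#' @param sigma target standard deviation.
#' @return numeric vector of length \code{n}.
#' @export
pinkNoise <- function(n, alpha = 1, sigma = 1) {
  stopifnot(n >= 1, sigma >= 0)
  if (sigma == 0) return(numeric(n))
  if (n == 1L) return(stats::rnorm(1L, sd = sigma))
  if (alpha == 0) return(sigma * stats::rnorm(n))
  m <- 2^ceiling(log2(n))         # pad to a power of two for the FFT
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  k <- seq_len(m) - 1L
  fidx <- pmin(k, m - k)          # symmetric frequency index
  scale <- c(0, fidx[-1L]^(-alpha / 2))
  y <- Re(stats::fft(X * scale, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  sigma * y / s
}

#' Expected resultant length of a von Mises sample
#'
#' Population mean resultant length R(kappa) = I1(kappa)/I0(kappa); the
#' asymptotic ITC of phase-jittered but otherwise noise-free entrained
#' epochs.
#'
#' @param kappa concentration (>= 0, may be \code{Inf}).
#' @return value in [0, 1].
#' @export
vonMisesResultant <- function(kappa) {
  ifelse(is.infinite(kappa), 1,
         ifelse(kappa < 1e-12, 0, besselI(kappa, 1) / besselI(kappa, 0)))
}

#' Expected ITC under uniform phase
#'
#' Mean resultant length of N independent uniform unit phasors,
#' sqrt(pi) / (2 sqrt(N)): the noise floor of an ITC estimate from N epochs.
#'
#' @param n number of epochs.
#' @return expected resultant length.
#' @export
uniformPhaseITC <- function(n) sqrt(pi) / (2 * sqrt(n))

#' Standard recording montages
#'
#' Channel label sets used by the simulator and default analyses: a
#' 32-channel cap (children) and a 64-channel cap (adults), each
#' with a frontocentral region of interest where auditory entrainment is
#' maximal, plus left/right mastoid reference channels. Analyses never assume
#' a fixed montage; any recording's ROI can be overridden.
#'
#' @param nChannels 32 or 64 scalp channels.
#' @return list with \code{labels} (scalp + mastoids), \code{roi},
#'   \code{mastoids}.
#' @export
defaultMontage <- function(nChannels = 32) {
  if (nChannels == 32) {
    scalp <- c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3", "CP1",
               "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz", "O2", "PO4",
               "P4", "P8", "CP6", "CP2", "C4", "T8", "FC6", "FC2", "F4",
               "F8", "AF4", "Fp2", "Fz", "Cz")
    roi <- c("F7", "F3", "Fz", "F4", "F8", "AF3", "AF4", "FC5", "FC1",
             "FC2", "FC6", "C3", "Cz", "C4", "CP5", "CP1", "CP2", "CP6")
  } else if (nChannels == 64) {
    scalp <- c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5",
               "FC3", "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3",
               "CP1", "P1", "P3", "P5", "P7", "P9", "PO7", "PO3", "O1",
               "Iz", "Oz", "POz", "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4",
               "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6", "FC4",
               "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
               "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4",
               "O2")
    roi <- c("F1", "F3", "Fz", "F2", "F4", "FC5", "FC3", "FC1", "FCz",
             "FC2", "FC4", "FC6", "C1", "C3", "Cz", "C2", "C4", "CP1",
             "CPz", "CP2")
  } else {
    stop("defaultMontage supports 32 or 64 scalp channels")
  }
  list(labels = c(scalp, "M1", "M2"), roi = roi, mastoids = c("M1", "M2"))
}

# nearest-bin lookup with tie-to-lower rule; returns index
.nearestBin <- function(binFreqs, target) {
  d <- abs(binFreqs - target)
  idx <- which(d == min(d))
  idx[1L]                                    # ties resolve to lower frequency
}
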