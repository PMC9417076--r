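# Fixtures built in code: small recordings and cohorts used across tests.

identity_recording <- function(n = 3, activity = "squat") {
  sensor_recording("P01", "test", "sacrum", 1, activity,
                   quat = cbind(rep(1, n), 0, 0, 0),
                   free_acc = matrix(0, n, 3))
}

random_recording <- function(n = 50, seed = 42, activity = "squat") {
  set.seed(seed)
  e <- cbind(z = cumsum(rnorm(n, 0, 2)), x = 30 * sin(seq_len(n) / 5),
             y = cumsum(rnorm(n, 0, 1)))
  sensor_recording("P01", "criterion", "thigh", 2, activity,
                   quat = euler_zxy_to_quat(e),
                   free_acc = matrix(rnorm(3 * n), n, 3))
}

random_unit_quats <- function(n, seed = 1) {
  set.seed(seed)
  q <- matrix(rnorm(4 * n), ncol = 4)
  q / sqrt(rowSums(q^2))
}

# independent composition Rz(z) %*% Rx(x) %*% Ry(y) from angles in degrees
rotmat_from_zxy <- function(z, x, y) {
  r <- pi / 180
  Rz <- matrix(c(cos(z*r), -sin(z*r), 0, sin(z*r), cos(z*r), 0, 0, 0, 1), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(x*r), -sin(x*r), 0, sin(x*r), cos(x*r)), 3, byrow = TRUE)
  Ry <- matrix(c(cos(y*r), 0, sin(y*r), 0, 1, 0, -sin(y*r), 0, cos(y*r)), 3, byrow = TRUE)
  Rz %*% Rx %*% Ry
}

# steady-state amplitude of a sinusoid at frequency f in signal y (central
# third, least squares on a sin/cos basis)
fit_amplitude <- function(y, f, fs) {
  n <- length(y)
  idx <- seq(floor(n / 3), ceiling(2 * n / 3))
  t <- (idx - 1) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- stats::lm.fit(X, y[idx])$coefficients
  sqrt(sum(cf^2))
}

# dual-pass magnitude of the digital Butterworth design, evaluated from the
# transfer-function polynomials (independent of the time-domain filter path)
dualpass_gain <- function(f, fs, cutoff = 6, order = 2) {
  ba <- signal::butter(order, cutoff / (fs / 2), type = "low")
  zi <- exp(1i * 2 * pi * f / fs)
  num <- sum(ba$b * zi^-(seq_along(ba$b) - 1))
  den <- sum(ba$a * zi^-(seq_along(ba$a) - 1))
  Mod(num / den)^2
}
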