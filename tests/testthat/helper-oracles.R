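# Independent oracles used to validate the package implementations.

# Horn's closed-form quaternion absolute-orientation solution: an
# independent route to the optimal rigid superposition, used to check the
# SVD-based Kabsch implementation.
horn_superpose <- function(ref, mov) {
  cr <- colMeans(ref); cm <- colMeans(mov)
  A <- sweep(ref, 2, cr); B <- sweep(mov, 2, cm)
  S <- t(B) %*% A
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  moved <- B %*% t(R)
  list(rmsd = sqrt(mean(rowSums((moved - A)^2))))
}

# exhaustive all-windows PWM scan (the brute-force sequence-score oracle)
brute_pwm_scan <- function(seq, pwm) {
  res <- strsplit(seq, "")[[1]]
  w <- pwm$width
  n <- length(res)
  if (n < w) return(list(raw = -Inf, start = NA_integer_))
  best <- -Inf; best_at <- NA_integer_
  for (s in 1:(n - w + 1)) {
    sc <- 0
    for (j in 1:w) {
      a <- res[s + j - 1]
      if (a %in% colnames(pwm$weights)) sc <- sc + unname(pwm$weights[j, a])
    }
    if (sc > best) { best <- sc; best_at <- s }
  }
  list(raw = best, start = best_at)
}

# brute-force Kyte-Doolittle window means (per center position)
brute_kd_means <- function(seq, window) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2, X = 0)
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  half <- (window - 1) %/% 2
  centers <- (half + 1):(n - half)
  vapply(centers, function(c) mean(kd[res[(c - half):(c + half)]]),
         numeric(1))
}

# random test protein sequence
AA20_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
random_aa_seq <- function(n, alphabet = AA20_TEST) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
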