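# small in-code fixtures shared across tests

# centroids on a regular grid in general position (slight jitter avoids
# distance ties unless a test wants them)
grid_centroids <- function(nr, nc, spacing = 1, jitter = 0, seed = 42) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(nc), y = seq_len(nr))
  data.frame(unit_id = sprintf("U%03d", seq_len(nr * nc)),
             x_km = g$x * spacing + stats::runif(nr * nc, -jitter, jitter),
             y_km = g$y * spacing + stats::runif(nr * nc, -jitter, jitter),
             stringsAsFactors = FALSE)
}

# dense brute-force Moran's I (independent double-sum oracle)
moran_bruteforce <- function(z, W) {
  n <- length(z)
  zc <- z - mean(z)
  s0 <- sum(W)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * zc[i] * zc[j]
  (n / s0) * num / sum(zc^2)
}

# a small landscape + weights + SDM data bundle for estimator tests
make_sdm_data <- function(n = 100, rho = 0.4, beta = c(a = 0.8, b = -0.5),
                          theta = c(0.2, 0.1), sigma = 0.2, seed = 1,
                          jitter = 0.3) {
  cents <- grid_centroids(ceiling(sqrt(n)), ceiling(sqrt(n)),
                          jitter = jitter, seed = seed)[seq_len(n), ]
  w <- knn_weights(cents, 3)
  dgp <- dgp_config(rho = rho, beta = beta, theta = theta, sigma = sigma)
  set.seed(seed + 1000)
  X <- matrix(rnorm(n * length(beta)), n, length(beta),
              dimnames = list(NULL, names(beta)))
  y <- gen_outcome(X, w, dgp, seed = seed)
  list(w = w, X = X, y = y, dgp = dgp, centroids = cents)
}

# fabricate an sdm_fit-like object with chosen parameters (for impact tests)
fake_fit <- function(rho, beta, theta, iv_names = names(beta)) {
  coefs <- c("(Intercept)" = 0, beta, stats::setNames(theta, paste0("lag.", iv_names)))
  vcov <- matrix(0, length(coefs) + 1, length(coefs) + 1,
                 dimnames = list(c(names(coefs), "rho"), c(names(coefs), "rho")))
  structure(list(rho = rho, coefficients = coefs,
                 beta = c("(Intercept)" = 0, beta),
                 theta = stats::setNames(theta, paste0("lag.", iv_names)),
                 vcov = vcov, iv_names = iv_names, interval = c(-1, 1)),
            class = "sdm_fit")
}
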