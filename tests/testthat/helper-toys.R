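# Small fixture networks and series used across the test files.

toy_chain_net <- function() {
  parse_network(c(
    "r0: S -> A , a -> a ; irreversible",
    "r1: A -> B , a -> a ; irreversible",
    "r2: B -> C , a -> a ; irreversible",
    "r3: C -> X , a -> a ; irreversible"
  ))
}

# condensation/cleavage toy with <= 4 carbons, used for the isotopomer
# oracle comparison
toy_condense_net <- function() {
  parse_network(c(
    "fix: Cin + A2 -> B3 , a + bc -> abc ; irreversible",
    "spl: B3 -> A2 + C1 , abc -> bc + a ; irreversible",
    "oA: A2 -> XA , ab -> ab ; irreversible",
    "iA: A0 -> A2 , ab -> ab ; irreversible",
    "oC: C1 -> XC , a -> a ; irreversible"
  ))
}

sampling_grid <- c(0, 0.5, 1, 2, 2.5, 3, 5, 7, 10, 15, 30, 60, 90, 120)

polyexp_series <- function(A, k, C = 0, times_min = sampling_grid,
                           noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- drop(exp(outer(times_min / 60, -k)) %*% A) + C
  if (noise_sd > 0) u <- u + stats::rnorm(length(u), 0, noise_sd)
  tibble::tibble(time_min = times_min, pct_12c = u)
}

# a linear least-squares toy (straight-line fit) exercised through the
# generic fit interface used by the CI methods
linear_toy_fit <- function(beta = c(2, 0.5), sigma = 0.3, n = 30, seed = 42) {
  set.seed(seed)
  x <- seq(0, 3, length.out = n)
  X <- cbind(1, x)
  y <- drop(X %*% beta) + stats::rnorm(n, 0, sigma)
  fit <- cbclabel:::new_ls_fit(
    predict_num = function(par) drop(X %*% par),
    par0 = c(b0 = 0, b1 = 0),
    values = y, sds = rep(sigma, n),
    lower = c(-10, -10), upper = c(10, 10)
  )
  list(fit = fit, X = X, y = y, sigma = sigma)
}
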