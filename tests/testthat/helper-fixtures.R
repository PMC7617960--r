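# Shared fixtures, all built in code.

# random rank-r matrix with unit-ish conditioning
make_lowrank <- function(n, p, r, seed, scale = 1) {
  set.seed(seed)
  scale * (matrix(rnorm(n * r), n) %*% t(matrix(rnorm(p * r), p)))
}

# mask hiding `n_hide` uniformly random entries
random_mask <- function(n, p, n_hide, seed) {
  set.seed(seed)
  m <- matrix(TRUE, n, p)
  m[sample(n * p, n_hide)] <- FALSE
  m
}

# spectrum row from Gaussian components on a grid
gauss_row <- function(comps, freqs) {
  rowSums(vapply(comps, function(cp) gaussian_eval(cp, freqs),
                 numeric(length(freqs))))
}

# default analysis grid used throughout: 0-1 Hz at 1/256 Hz
full_grid <- function() seq(0, 1, by = 1 / 256)

rel_frob <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# independent quadrature oracle
trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
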