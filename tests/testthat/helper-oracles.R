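# independent oracles used across test files

# brute-force AUC: fraction of concordant positive/negative pairs,
# ties counted one half
brute_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

# term-by-term symmetric KL divergence on probability vectors
hand_sym_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p))
    s <- s + p[i] * log(p[i] / q[i]) + q[i] * log(q[i] / p[i])
  s
}

# hand-applied Benjamini-Hochberg step-up rule
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# residualize-then-correlate partial correlation oracle
hand_partial_corr <- function(x, y, covs) {
  rx <- resid(lm(x ~ covs))
  ry <- resid(lm(y ~ covs))
  cor(rx, ry)
}

# brute-force O(T^2) DFT sqrt-power average over band bins
brute_alff <- function(x, tr, band) {
  T_len <- length(x)
  k_all <- seq_len(floor(T_len / 2))
  f <- k_all / (T_len * tr)
  bins <- k_all[f >= band[1] & f < band[2]]
  vals <- vapply(bins, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(T_len - 1)) / T_len))
    im <- sum(x * sin(-2 * pi * k * (0:(T_len - 1)) / T_len))
    sqrt((re^2 + im^2) / T_len)
  }, numeric(1))
  mean(vals)
}

# small deterministic discrete pdf on an arbitrary grid (for sym_kl tests)
pdf_on_grid <- function(prob, grid = seq_along(prob)) {
  structure(list(support = grid, prob = prob / sum(prob), bandwidth = NA),
            class = "discrete_pdf")
}

# T x V matrix view of a bold_series (internal accessor)
.bold_matrix_for_test <- function(s) klscoupling:::.bold_matrix(s)

# quick small phantom for io/pipeline tests
tiny_phantom <- function(R = 5, shape = c(14, 14, 14), seed = 7,
                         affected = integer(0),
                         n_per_group = c(HC = 5, MDD_noanh = 5, MDD_anh = 5)) {
  atl <- make_phantom_atlas(shape, R = R, seed = seed)
  tru <- phantom_truth(R = R, affected_regions = affected)
  sim <- simulate_cohort(atl, tru, n_per_group = n_per_group,
                         seed = seed + 1)
  c(sim, list(atlas = atl))
}
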