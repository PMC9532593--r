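# Independent brute-force oracles and small fixture builders. These
# deliberately use naive loops / different code paths than the package.

random_profiles <- function(n, seed) {
  set.seed(seed)
  data.frame(site_id = sprintf("S%02d", seq_len(n)),
             bg = runif(n, 1, 1000), cbh = runif(n, 1, 500),
             nag = runif(n, 1, 300), lap = runif(n, 1, 100),
             ap = runif(n, 1, 500), stringsAsFactors = FALSE)
}

random_counts <- function(n_sites, n_taxa, seed, max_count = 50) {
  set.seed(seed)
  m <- matrix(sample(0:max_count, n_sites * n_taxa, replace = TRUE),
              n_sites, n_taxa,
              dimnames = list(sprintf("S%02d", 1:n_sites), sprintf("t%d", 1:n_taxa)))
  m
}

# naive per-pair Bray-Curtis from the defining formula
naive_bray_curtis <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- 1 - 2 * sum(pmin(m[i, ], m[j, ])) / (sum(m[i, ]) + sum(m[j, ]))
  }
  out
}

# naive pairwise Euclidean distance, double loop
naive_euclidean <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  }
  out
}

# all permutations of 1..n, built by a different construction than the
# package (incremental insertion rather than recursion over the first slot)
enumerate_permutations <- function(n) {
  perms <- list(1L)
  for (k in 2:n) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(seq_len(k), function(pos) append(p, k, after = pos - 1))
    }), recursive = FALSE)
  }
  perms
}

# exact Mantel p by full enumeration, counting ties like the implementation
naive_mantel_exact_p <- function(m1, m2, tol = 1e-12) {
  low <- lower.tri(m1)
  v1 <- m1[low]
  r_obs <- cor(v1, m2[low])
  r_perm <- vapply(enumerate_permutations(nrow(m1)),
                   function(p) cor(v1, m2[p, p][low]), numeric(1))
  list(r = r_obs, p = sum(r_perm >= r_obs - tol) / length(r_perm))
}

# enzyme sums with the desired vector angle (degrees), c_acq fixed at 1
sums_for_angle <- function(angle_deg, n_acq = 1) {
  # angle = atan(y/x); with c = 1: x = 1/(1+p), y = 1/(1+n)
  ratio <- tan(angle_deg * pi / 180)  # = (1+p)/(1+n)
  data.frame(c_acq = 1, n_acq = n_acq, p_acq = ratio * (1 + n_acq) - 1)
}
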