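.check_taxon_table <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || anyNA(m)) {
    .stop_field("taxon table must be numeric with no missing values")
  }
  if (any(m < 0)) .stop_field("taxon table contains negative counts")
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("t%d", seq_len(ncol(m)))
  m
}

#' Per-site taxon richness
#'
#' @param table site-by-taxon matrix (or data frame) of nonnegative counts,
#'   sites in rows.
#' @return named integer vector: number of taxa with count > 0 at each site.
#' @export
richness <- function(table) {
  m <- .check_taxon_table(table)
  setNames(as.integer(rowSums(m > 0)), rownames(m))
}

#' Bray-Curtis dissimilarity between sites
#'
#' Quantitative compositional distance
#' \deqn{BC_{ij} = 1 - \frac{2\sum_t \min(c_{it}, c_{jt})}{\sum_t c_{it} + \sum_t c_{jt}}}
#' in \[0, 1\]: 0 for identical abundance vectors, 1 for sites sharing no
#' taxa. Computed on counts as given by default; `mode = "relative"`
#' converts each row to relative abundances first, which removes library-size
#' differences between sites.
#'
#' @param table site-by-taxon count matrix, sites in rows; every site must
#'   have a positive total count.
#' @param mode `"counts"` (default) or `"relative"`.
#' @return a [stats::dist] object labelled by site.
#' @export
bray_curtis <- function(table, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  m <- .check_taxon_table(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    .stop_field("Bray-Curtis undefined for all-zero site(s): %s",
                paste(rownames(m)[totals == 0], collapse = ", "))
  }
  if (mode == "relative") m <- m / totals
  vegan::vegdist(m, method = "bray")
}

# all permutations of 1..n as an n! x n matrix (n small; used for exact Mantel)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row + seq_len(nrow(sub)), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

.as_dist_matrix <- function(d, arg) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) .stop_field("%s must be a square distance structure", arg)
  if (max(abs(m - t(m))) > 1e-8) .stop_field("%s is not symmetric", arg)
  m
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation r between the off-diagonal entries of two distance
#' matrices over the same sites, with significance from a permutation null:
#' rows and columns of the second matrix are jointly relabelled by the same
#' random permutation and r recomputed. The test is one-tailed for positive
#' association and uses the add-one convention
#' p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm), so p can never be 0 and
#' never falls below 1/(n_perm + 1). For small surveys (n <= 7 sites by
#' default) the null is enumerated exactly over all n! relabellings and
#' `n_perm` is ignored; the exact p is #\{r_perm >= r_obs\}/n! (the identity
#' relabelling counts, so p >= 1/n!).
#'
#' @param d1,d2 [stats::dist] objects or symmetric matrices over the same
#'   sites in the same order (labels are checked when both carry them).
#' @param n_perm number of random permutations (default 999).
#' @param seed optional integer seed making the permutation draw reproducible.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` enumerates when n <= 7.
#' @return object of class `mantel_result`: list with elements `r`,
#'   `p_value`, `n_perm` (number of null relabellings actually used),
#'   `method` (`"permutation"` or `"exact"`), `tail` (`"greater"`), `seed`
#'   and `n_sites`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL, exact = NULL) {
  m1 <- .as_dist_matrix(d1, "d1")
  m2 <- .as_dist_matrix(d2, "d2")
  n <- nrow(m1)
  if (nrow(m2) != n) .stop_field("d1 and d2 cover different numbers of sites")
  l1 <- rownames(m1); l2 <- rownames(m2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    .stop_field("site order mismatch between d1 and d2: %s",
                paste(utils::head(l1[l1 != l2], 3), collapse = ", "))
  }
  if (n < 4) .stop_field("Mantel test needs at least 4 sites")
  low <- lower.tri(m1)
  v1 <- m1[low]
  v2 <- m2[low]
  if (sd(v1) == 0 || sd(v2) == 0) {
    .stop_field("constant distance matrix: Mantel correlation undefined")
  }
  r_obs <- cor(v1, v2)
  if (is.null(exact)) exact <- n <= 7
  # ties between permuted statistics and r_obs are counted with a small
  # tolerance so that permutations equal to the observed labelling up to
  # floating-point summation order are not dropped
  tol <- 1e-12

  if (exact) {
    perms <- .permutations(n)
    r_perm <- vapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      cor(v1, m2[p, p][low])
    }, numeric(1))
    p_value <- sum(r_perm >= r_obs - tol) / nrow(perms)
    res <- list(r = r_obs, p_value = p_value, n_perm = nrow(perms),
                method = "exact", tail = "greater", seed = seed, n_sites = n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      cor(v1, m2[p, p][low])
    }, numeric(1))
    p_value <- (1 + sum(r_perm >= r_obs - tol)) / (1 + n_perm)
    res <- list(r = r_obs, p_value = p_value, n_perm = n_perm,
                method = "permutation", tail = "greater", seed = seed, n_sites = n)
  }
  class(res) <- "mantel_result"
  res
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, one-tailed greater): r = %.4f, p = %.4g (%d null relabellings, n = %d sites)\n",
              x$method, x$r, x$p_value, x$n_perm, x$n_sites))
  invisible(x)
}
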