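# Brute-force oracles, written with explicit loops and kept independent of
# the package's vectorized implementations.

rand_ct <- function(n_genes, n_samples, seed, base = 20, spread = 2) {
  set.seed(seed)
  ct <- matrix(base + runif(n_genes, -spread, spread) +
                 rnorm(n_genes * n_samples, sd = runif(1, 0.2, 1.5)),
               n_genes, n_samples)
  ct_matrix(ct, paste0("g", seq_len(n_genes)),
            paste0("s", seq_len(n_samples)))
}

quantity_of <- function(m, eff = 2) to_relative_quantity(m, eff)

# mean over partners of the SD of per-sample Ct differences
oracle_deltact <- function(ct) {
  n <- nrow(ct)
  out <- numeric(n)
  for (j in seq_len(n)) {
    sds <- c()
    for (k in seq_len(n)) if (k != j) sds <- c(sds, sd(ct[j, ] - ct[k, ]))
    out[j] <- mean(sds)
  }
  setNames(out, rownames(ct))
}

oracle_genorm_m <- function(q) {
  n <- nrow(q)
  out <- numeric(n)
  for (j in seq_len(n)) {
    vs <- c()
    for (k in seq_len(n)) if (k != j)
      vs <- c(vs, sd(log2(q[j, ] / q[k, ])))
    out[j] <- mean(vs)
  }
  setNames(out, rownames(q))
}

# stepwise elimination, recomputing M from scratch at every step
oracle_genorm_elimination <- function(q) {
  alive <- rownames(q)
  dropped <- character()
  while (length(alive) > 2L) {
    m <- oracle_genorm_m(q[alive, , drop = FALSE])
    worst <- alive[max(which(m == max(m)))]
    dropped <- c(dropped, worst)
    alive <- setdiff(alive, worst)
  }
  list(order_dropped = dropped, survivors = alive)
}

# ungrouped NormFinder: explicit residual loops + bias-corrected variance
oracle_normfinder <- function(q) {
  y <- log2(q)
  g <- nrow(y); n <- ncol(y)
  gm <- rowMeans(y); sm <- colMeans(y); mm <- mean(y)
  s <- numeric(g)
  for (i in seq_len(g)) {
    rss <- 0
    for (j in seq_len(n)) rss <- rss + (y[i, j] - gm[i] - sm[j] + mm)^2
    s[i] <- rss / (n - 1)
  }
  v <- numeric(g)
  for (i in seq_len(g))
    v[i] <- max(0, g / (g - 2) * (s[i] - sum(s) / (g * (g - 1))))
  setNames(sqrt(v), rownames(y))
}

oracle_normfinder_grouped <- function(q, groups) {
  y <- log2(q)
  g <- nrow(y)
  lev <- unique(groups)
  gamma2 <- d <- matrix(0, g, length(lev))
  for (k in seq_along(lev)) {
    yk <- y[, groups == lev[k], drop = FALSE]
    nk <- ncol(yk)
    gmk <- rowMeans(yk); smk <- colMeans(yk); mmk <- mean(yk)
    for (i in seq_len(g)) {
      rss <- 0
      for (j in seq_len(nk)) rss <- rss + (yk[i, j] - gmk[i] - smk[j] + mmk)^2
      d[i, k] <- gmk[i]
      gamma2[i, k] <- rss / (nk - 1)
    }
    s_raw <- gamma2[, k]
    for (i in seq_len(g))
      gamma2[i, k] <- max(0, g / (g - 2) *
                            (s_raw[i] - sum(s_raw) / (g * (g - 1))))
  }
  # center gene-by-group means for gene and group effects
  d <- d - rowMeans(d)
  for (k in seq_along(lev)) d[, k] <- d[, k] - mean(d[, k])
  rho <- matrix(0, g, length(lev))
  for (k in seq_along(lev)) {
    nk <- sum(groups == lev[k])
    for (i in seq_len(g)) {
      vd <- gamma2[i, k] / nk
      rho[i, k] <- sqrt(max(0, d[i, k]^2 - vd)) + sqrt(vd)
    }
  }
  setNames(rowMeans(rho), rownames(y))
}

oracle_bestkeeper <- function(ct) {
  n <- nrow(ct); s <- ncol(ct)
  index <- numeric(s)
  for (j in seq_len(s)) index[j] <- prod(ct[, j])^(1 / n)
  out <- data.frame(gene = rownames(ct), geo_mean_ct = NA_real_,
                    sd_ct = NA_real_, cv_pct = NA_real_, r = NA_real_)
  for (i in seq_len(n)) {
    v <- ct[i, ]
    out$geo_mean_ct[i] <- prod(v)^(1 / s)
    out$sd_ct[i] <- sd(v)
    out$cv_pct[i] <- 100 * sd(v) / mean(v)
    out$r[i] <- if (sd(v) == 0) NA_real_ else cor(v, index)
  }
  list(per_gene = out, index = index)
}

geomean <- function(x) exp(mean(log(x)))
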