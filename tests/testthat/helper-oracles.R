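# Independent oracles: each re-derives a quantity from first principles,
# sharing no code with the implementation it checks.

# Pearson r from the raw covariance formula, p from the t CDF.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  r <- sxy / sqrt(sxx * syy)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p)
}

# mid-ranks by explicit tie averaging, then the direct Pearson formula
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      below <- sum(v < v[i])
      ties <- sum(v == v[i])
      out[i] <- below + (ties + 1) / 2
    }
    out
  }
  res <- oracle_pearson(midrank(x), midrank(y))
  list(rho = res$r, p = res$p)
}

# brute-force BH step-up: adjusted_(k) = min_{j >= k} min(1, p_(j) * m / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m))
    adj[k] <- min(1, min(sorted[k:m] * m / (k:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# degree by explicit neighbour-set enumeration over an edge list
oracle_degree <- function(edges, nodes) {
  sapply(nodes, function(n) {
    nb <- character()
    for (i in seq_len(nrow(edges))) {
      if (edges$node_a[i] == n && edges$node_b[i] != n)
        nb <- union(nb, edges$node_b[i])
      if (edges$node_b[i] == n && edges$node_a[i] != n)
        nb <- union(nb, edges$node_a[i])
    }
    length(nb)
  })
}

# textbook sums-of-squares ANOVA
oracle_anova <- function(values) {
  all_v <- unlist(values)
  grand <- mean(all_v)
  sse <- 0; ssb <- 0
  for (g in values) {
    sse <- sse + sum((g - mean(g))^2)
    ssb <- ssb + length(g) * (mean(g) - grand)^2
  }
  df_error <- length(all_v) - length(values)
  list(mse = sse / df_error, df_error = df_error,
       f = (ssb / (length(values) - 1)) / (sse / df_error))
}

# Manual Duncan step-down: iterate spans largest-first; a window whose
# extreme gap does not exceed its critical range is homogeneous, and no
# window inside a homogeneous one is ever tested. Pair decision matrix.
oracle_duncan_decisions <- function(values, alpha = 0.05) {
  av <- oracle_anova(values)
  ord <- order(-sapply(values, mean), names(values))
  means <- sapply(values, mean)[ord]
  k <- length(means)
  n_h <- k / sum(1 / lengths(values)[ord])
  Rp <- sapply(2:k, function(p)
    qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, av$df_error) *
      sqrt(av$mse / n_h))
  homog <- list()
  inside_homog <- function(i, j)
    any(vapply(homog, function(h) h[1] <= i && j <= h[2], logical(1)))
  for (p in k:2) {
    for (i in seq_len(k - p + 1)) {
      j <- i + p - 1
      if (inside_homog(i, j)) next
      if (means[i] - means[j] <= Rp[p - 1])
        homog[[length(homog) + 1]] <- c(i, j)
    }
  }
  different <- matrix(FALSE, k, k,
                      dimnames = list(names(values)[ord], names(values)[ord]))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sig <- !inside_homog(i, j) && means[i] - means[j] > Rp[j - i]
    different[i, j] <- different[j, i] <- sig
  }
  different
}

# small study used across tests (two varieties, full design)
tiny_config <- function(seed = 1, ...) {
  sim_config(n_genes = 60, n_pathway_genes = 18, seed = seed, ...)
}

random_edge_df <- function(nodes, n_edges, seed) {
  set.seed(seed)
  a <- sample(nodes, n_edges, replace = TRUE)
  b <- sample(nodes, n_edges, replace = TRUE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  df <- data.frame(node_a = pmin(a, b), node_b = pmax(a, b),
                   pearson_r = runif(sum(keep), -1, 1),
                   stringsAsFactors = FALSE)
  df[!duplicated(paste(df$node_a, df$node_b)), , drop = FALSE]
}
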