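# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles (enumeration, closed form, brute force),
# never by calling the code path under test.

# two-sided Fisher exact p by direct hypergeometric enumeration with choose()
fisher_enum_p <- function(a, b, c, d) {
  m1 <- a + b # factor-positive margin
  m2 <- c + d
  k <- a + c  # case margin
  n <- m1 + m2
  xs <- max(0, k - m2):min(k, m1)
  probs <- choose(m1, xs) * choose(m2, k - xs) / choose(n, k)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the literal step-up definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- ranked * m / seq_len(m)
  # enforce step-up monotonicity from the largest rank down
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact central binomial 99% interval for a count
binom_bounds99 <- function(n, p) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p))
}

# brute-force maximal-run finder over one query/subject pair: enumerates
# every diagonal window, tests validity directly, and keeps windows not
# contained in a larger valid window on the same diagonal
brute_runs <- function(qres, sres, codes, k, min_len) {
  qch <- strsplit(qres, "")[[1]]
  sch <- strsplit(sres, "")[[1]]
  lq <- length(qch); ls <- length(sch)
  out <- list()
  for (off in (1 - lq):(ls - 1)) {
    qlo <- max(1, 1 - off); qhi <- min(lq, ls - off)
    L <- qhi - qlo + 1
    if (L < min_len) next
    st <- codes[cbind(match(qch[qlo:qhi], rownames(codes)),
                      match(sch[(qlo:qhi) + off], rownames(codes)))]
    nz <- st != 0
    Z <- cumsum(st == 0)
    valid <- matrix(FALSE, L, L)
    for (i in seq_len(L)) for (j in i:L) {
      if (j - i + 1 < min_len) next
      if (!nz[i] || !nz[j]) next
      zeros_inside <- Z[j] - Z[i]
      if (zeros_inside <= k) valid[i, j] <- TRUE
    }
    # count of valid windows in the containing region {i2 <= i, j2 >= j}
    colcum <- apply(valid, 2, cumsum)
    if (L == 1) colcum <- matrix(colcum, 1)
    region_count <- t(apply(colcum, 1, function(r) rev(cumsum(rev(r)))))
    for (i in seq_len(L)) for (j in seq_len(L)) {
      if (!valid[i, j]) next
      if (region_count[i, j] == 1) # only itself: maximal
        out[[length(out) + 1]] <- data.frame(
          query_start = qlo + i - 1, query_end = qlo + j - 1,
          subject_start = qlo + i - 1 + off)
    }
  }
  if (!length(out)) return(data.frame(query_start = integer(),
                                      query_end = integer(),
                                      subject_start = integer()))
  res <- do.call(rbind, out)
  res[order(res$subject_start, res$query_start), , drop = FALSE]
}

# a deliberately tiny deterministic scenario for fast unit tests
tiny_fox_config <- function(n = 100L, seed = 1L) {
  builtin_scenario("two_island_fox", n_per_stratum = n, seed = seed)
}
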