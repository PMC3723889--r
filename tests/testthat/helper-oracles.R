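# Independent oracles, deliberately implemented by different algorithms than
# the package code paths they check.

# Squared distance with missing-data rescaling: naive O(n^2 L) double loop.
oracle_distance <- function(x) {
  n <- nrow(x); L <- ncol(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- !is.na(x[i, ]) & !is.na(x[j, ])
      stopifnot(any(shared))
      d[i, j] <- (L / sum(shared)) * sum((x[i, shared] - x[j, shared])^2)
    }
  }
  d
}

# AMOVA sums of squares from explicit pair loops.
oracle_amova <- function(d, groups) {
  n <- nrow(d)
  groups <- factor(groups)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_along(idx)[-length(idx)]) {
        for (b in (a + 1):length(idx)) s <- s + d[idx[a], idx[b]]
      }
    }
    ss_within <- ss_within + s / length(idx)
  }
  k <- nlevels(groups)
  ng <- as.numeric(table(groups))
  ms_among <- (ss_total - ss_within) / (k - 1)
  ms_within <- ss_within / (n - k)
  n0 <- (n - sum(ng^2) / n) / (k - 1)
  s2a <- (ms_among - ms_within) / n0
  s2w <- ms_within
  list(ss_among = ss_total - ss_within, ss_within = ss_within,
       ss_total = ss_total, sigma2_among = s2a, sigma2_within = s2w,
       phi_st = s2a / (s2a + s2w))
}

# Two-sided Fisher exact p for a 2 x k table by complete enumeration of all
# margin-fixed tables (probability-ordering convention).
oracle_fisher <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2)
  cs <- colSums(tab)
  r1 <- sum(tab[1, ])
  k <- ncol(tab)
  logp_table <- function(a) sum(lchoose(cs, a)) - lchoose(sum(cs), r1)
  # enumerate first-row vectors summing to r1 within column bounds
  grids <- lapply(cs, function(cj) 0:cj)
  combos <- expand.grid(grids[-k])
  p_obs <- logp_table(tab[1, ])
  total <- 0
  for (r in seq_len(max(1, nrow(combos)))) {
    head <- if (k > 1) as.numeric(combos[r, ]) else numeric(0)
    last <- r1 - sum(head)
    if (last < 0 || last > cs[k]) next
    lp <- logp_table(c(head, last))
    if (lp <= p_obs + 1e-7) total <- total + exp(lp)
  }
  min(total, 1)
}

# Benjamini-Hochberg step-up, written directly (not via p.adjust).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# Kruskal-Wallis H with tie correction from explicitly constructed ranks.
oracle_kruskal <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exact dip by bisection over the band half-width d, using constructive
# greatest-convex-minorant / least-concave-majorant feasibility (a different
# algorithm than the triple-enumeration implementation).
oracle_dip <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  ux <- unique(x)
  cnt <- as.numeric(table(match(x, ux)))
  cum <- cumsum(cnt)
  m <- length(ux)
  ym <- c(0, cum[-m]) / n
  yp <- cum / n
  if (m == 1) return(1 / (2 * n))

  convex_feasible <- function(xs, lo, hi) {
    k <- length(xs)
    if (any(hi < lo)) return(FALSE)
    if (k <= 2) return(TRUE)
    hull <- 1L
    for (i in 2:k) {
      while (length(hull) >= 2) {
        a <- hull[length(hull) - 1]; b <- hull[length(hull)]
        if ((hi[b] - hi[a]) * (xs[i] - xs[a]) >=
            (hi[i] - hi[a]) * (xs[b] - xs[a])) {
          hull <- hull[-length(hull)]
        } else break
      }
      hull <- c(hull, i)
    }
    gcm <- approx(xs[hull], hi[hull], xout = xs)$y
    all(gcm >= lo - 1e-12)
  }
  concave_feasible <- function(xs, lo, hi) convex_feasible(xs, -hi, -lo)

  feasible <- function(d) {
    for (k in seq_len(m)) {
      lo_l <- c(yp[seq_len(k - 1)] - d, ym[k] - d)
      hi_l <- c(ym[seq_len(k - 1)] + d, ym[k] + d)
      if (!convex_feasible(ux[1:k], lo_l, hi_l)) next
      idx <- k:m
      lo_r <- c(yp[k] - d, yp[idx[-1]] - d)
      hi_r <- c(yp[k] + d, ym[idx[-1]] + d)
      if (concave_feasible(ux[idx], lo_r, hi_r)) return(TRUE)
    }
    FALSE
  }

  lo <- 0; hi <- 0.3
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  max(hi, 1 / (2 * n))
}
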