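# Independent brute-force oracles used to verify the package's vectorized
# implementations. These deliberately use naive loops and textbook
# formulas, never the code paths they check.

# Random label grid with all 9 codes present-ish; optionally some masked
# cells (simulating filtered patches).
random_grid <- function(seed, nr = 15, nc = 15, with_mask = FALSE) {
  set.seed(seed)
  g <- matrix(sample(0:8, nr * nc, replace = TRUE,
                     prob = c(0.3, rep(0.06, 6), 0.14, 0.2)), nr, nc)
  if (with_mask) {
    m <- matrix(runif(nr * nc) < 0.1, nr, nc)
    attr(g, "mask") <- m
  }
  g
}

oracle_tip <- function(grid) {
  mask <- attr(grid, "mask")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(grid), ncol(grid))
  counts <- numeric(8)
  total <- 0
  for (r in seq_len(nrow(grid))) for (c in seq_len(ncol(grid))) {
    if (mask[r, c] || grid[r, c] == 8) next
    counts[grid[r, c] + 1] <- counts[grid[r, c] + 1] + 1
    total <- total + 1
  }
  counts / total
}

# Per-tumor-patch neighbor enumeration; multiplicity counting.
oracle_tmec_counts <- function(grid) {
  mask <- attr(grid, "mask")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(grid), ncol(grid))
  b <- numeric(8)
  n_tumor <- 0
  for (r in seq_len(nrow(grid))) for (c in seq_len(ncol(grid))) {
    if (mask[r, c] || grid[r, c] != 0) next
    n_tumor <- n_tumor + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nrow(grid) || cc < 1 || cc > ncol(grid)) next
      lab <- grid[rr, cc]
      if (lab == 0 || lab == 8 || mask[rr, cc]) next
      b[lab + 1] <- b[lab + 1] + 1
    }
  }
  list(b = b, n_tumor = n_tumor)
}

# Standardized log-rank z for the split x > cut, via the per-event-time
# hypergeometric O-E / variance accumulation.
oracle_logrank_z <- function(x, times, events, cut) {
  hi <- x > cut
  oe <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at <- times >= t
    nk <- sum(at); n1 <- sum(at & hi)
    dk <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & hi)
    oe <- oe + d1 - dk * n1 / nk
    if (nk > 1) v <- v + dk * (n1 / nk) * (1 - n1 / nk) * (nk - dk) / (nk - 1)
  }
  if (v <= 0) 0 else oe / sqrt(v)
}

oracle_maxstat <- function(x, times, events, minprop = 0.1) {
  u <- sort(unique(x))
  cuts <- (u[-1] + u[-length(u)]) / 2
  n <- length(x)
  best <- -Inf; best_cut <- NA
  for (cc in cuts) {
    nh <- sum(x > cc)
    if (nh < minprop * n - 1e-9 || n - nh < minprop * n - 1e-9) next
    z <- abs(oracle_logrank_z(x, times, events, cc))
    if (z > best + 1e-12) { best <- z; best_cut <- cc }
  }
  list(cutoff = best_cut, statistic = best)
}

# Harrell c-index by exhaustive pair enumeration (no tied times in the
# fixtures that use this).
oracle_cindex <- function(risk, times, events) {
  conc <- 0; comp <- 0
  n <- length(risk)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    first <- if (times[i] < times[j]) i else j
    second <- if (times[i] < times[j]) j else i
    if (times[i] == times[j] || events[first] == 0) next
    comp <- comp + 1
    if (risk[first] > risk[second]) conc <- conc + 1
    else if (risk[first] == risk[second]) conc <- conc + 0.5
  }
  conc / comp
}

# BH step-up by explicit union over all qualifying thresholds.
oracle_bh <- function(p, q, m = length(p)) {
  ord <- order(p)
  reject <- logical(length(p))
  for (r in seq_along(p)) {
    if (p[ord[r]] <= r * q / m) reject[ord[seq_len(r)]] <- TRUE
  }
  reject
}

# Efron-tie Cox partial log-likelihood for a single covariate.
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    sr <- sum(exp(beta * x[R]))
    sd_ <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D])
    for (l in 0:(d - 1)) ll <- ll - log(sr - (l / d) * sd_)
  }
  ll
}

oracle_roc_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  s <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) s <- s + 1
    else if (scores[i] == scores[j]) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

# 4-connected component sizes of each non-background class region.
oracle_component_sizes <- function(grid) {
  seen <- matrix(FALSE, nrow(grid), ncol(grid))
  sizes <- integer(0)
  for (r in seq_len(nrow(grid))) for (c in seq_len(ncol(grid))) {
    if (seen[r, c] || grid[r, c] == 8) next
    lab <- grid[r, c]
    queue <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- cur[1] + d[1]; cc <- cur[2] + d[2]
        if (rr < 1 || rr > nrow(grid) || cc < 1 || cc > ncol(grid)) next
        if (!seen[rr, cc] && grid[rr, cc] == lab) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Per-pixel Reinhard forward transform (log10-LMS rotated axes), matching
# the published matrices, computed one pixel at a time.
oracle_lab_pixel <- function(rgb255) {
  rgb <- rgb255 / 255
  M <- matrix(c(0.3811, 0.5783, 0.0402,
                0.1967, 0.7244, 0.0782,
                0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
  lms <- as.numeric(M %*% rgb)
  loglms <- log10(pmax(lms, 1e-4))
  A <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
    matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
  as.numeric(A %*% loglms)
}

# Small survival fixture with no tied times.
toy_survival <- function(seed, n = 40, rate = 0.01, censor = 0.3) {
  set.seed(seed)
  t_event <- rexp(n, rate)
  cens <- runif(n, 0, quantile(t_event, 1 - censor) * 2)
  list(time = pmin(t_event, cens), event = as.integer(t_event <= cens))
}
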