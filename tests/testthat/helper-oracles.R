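# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, closed forms and textbook formulas.

# brute-force 8-connected component count via explicit-stack flood fill
flood_fill_count <- function(bw, min_area = 1) {
  nr <- nrow(bw); nc <- ncol(bw)
  seen <- matrix(FALSE, nr, nc)
  counts <- integer(0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!bw[i, j] || seen[i, j]) next
    size <- 0L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
            bw[a, b] && !seen[a, b]) {
          seen[a, b] <- TRUE
          stack[[length(stack) + 1]] <- c(a, b)
        }
      }
    }
    counts <- c(counts, size)
  }
  sum(counts >= min_area)
}

# one-way ANOVA F and p from the between/within sums-of-squares definitions
anova_ss <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g); N <- length(values)
  grand <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  Fst <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fst, p = stats::pf(Fst, k - 1, N - k, lower.tail = FALSE))
}

# analytic slab step response at the closed far face:
# u_t = D u_xx, u(0,t) = 0, u_x(L,t) = 0, u(x,0) = level0; value at x = L
slab_series_closed <- function(t, L, D, level0 = 19, nterms = 400) {
  k <- seq_len(nterms)
  lam <- (2 * k - 1) * pi / (2 * L)
  amp <- (-1)^(k + 1) * 4 / ((2 * k - 1) * pi)
  vapply(t, function(tt) level0 * sum(amp * exp(-D * lam^2 * tt)),
         numeric(1))
}

# brute-force disk mean over pixel centres (inclusive radius)
disk_mean_brute <- function(img, cx, cy, r) {
  acc <- 0; n <- 0L
  for (row in seq_len(nrow(img))) for (col in seq_len(ncol(img))) {
    if ((col - cx)^2 + (row - cy)^2 <= r^2) {
      acc <- acc + img[row, col]; n <- n + 1L
    }
  }
  acc / n
}

default_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- device_geometry()
      p <- transport_params(g)
      gr <- build_grid(g)
      cache <<- list(g = g, p = p, gr = gr, cells = cell_field(p, gr))
    }
    cache
  }
})
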