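# Independent numerical oracles used across the suite. These deliberately
# avoid the code paths they check: curvature by central finite differences
# on evaluated points, Ward by explicit within-cluster variance.

# finite-difference curvature on the evaluated curve (never the hodograph)
fd_curvature <- function(curve, t, h = 1e-4) {
  vapply(t, function(ti) {
    hh <- min(h, ti, 1 - ti)
    if (hh == 0) hh <- h
    p0 <- predict(curve, max(0, ti - hh))
    p1 <- predict(curve, ti)
    p2 <- predict(curve, min(1, ti + hh))
    d1 <- (p2 - p0) / (2 * hh)
    d2 <- (p2 - 2 * p1 + p0) / hh^2
    (d1[1] * d2[2] - d1[2] * d2[1]) / sum(d1^2)^1.5
  }, numeric(1))
}

# greedy Ward agglomeration computing every candidate merge's within-cluster
# sum-of-squares increase explicitly; heights on the ward.D2 distance scale
ward_oracle_heights <- function(m) {
  ess <- function(rows) {
    x <- m[rows, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (d < best[1]) best <- c(d, i, j)
    }
    heights <- c(heights, sqrt(2 * best[1]))
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# does a letter assignment encode exactly the given significance relation?
letters_match_relation <- function(letts, sig) {
  g <- names(letts)
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (j <= i) next
    share <- length(intersect(strsplit(letts[i], "")[[1]],
                              strsplit(letts[j], "")[[1]])) > 0
    if (share == sig[g[i], g[j]]) return(FALSE)
  }
  TRUE
}

random_bezier <- function(degree, scale = 100) {
  bezier(cbind(sort(stats::runif(degree + 1, 0, scale)),
               stats::runif(degree + 1, 0, scale / 2)))
}
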