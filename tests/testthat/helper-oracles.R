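# Independent brute-force oracles. These deliberately share no code
# with the package implementations they check.

# O(n^2) silhouette by direct looping over points.
brute_silhouette <- function(X, labels) {
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(X) - X[i, ])^2))
    same <- which(labels == labels[i])
    if (length(same) == 1L) { s[i] <- 0; next }
    a <- mean(di[setdiff(same, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(di[labels == k]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# ARI by explicit pair counting: loop over all unordered pairs.
brute_ari <- function(a, b) {
  n <- length(a)
  n11 <- na <- nb <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    n11 <- n11 + (sa && sb); na <- na + sa; nb <- nb + sb
  }
  N <- n * (n - 1) / 2
  expected <- na * nb / N
  maximum <- (na + nb) / 2
  if (maximum == expected) return(1)
  (n11 - expected) / (maximum - expected)
}

# Crossing-number point-in-polygon with inclusive boundary, written
# against the segment-parametric form rather than the edge-slope form.
oracle_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  for (i in seq_len(n)) {  # boundary: projection onto the segment
    p1 <- poly[i, ]; p2 <- poly[nxt[i], ]
    v <- p2 - p1; w <- c(x, y) - p1
    L2 <- sum(v^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum(w * v) / L2))
    if (sum((w - t * v)^2) < 1e-20) return(TRUE)
  }
  crossings <- 0
  for (i in seq_len(n)) {
    y1 <- poly[i, 2]; y2 <- poly[nxt[i], 2]
    x1 <- poly[i, 1]; x2 <- poly[nxt[i], 1]
    if ((y1 <= y) != (y2 <= y)) {
      xc <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      if (xc > x) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# A small typed table used across tests.
toy_table <- function() {
  build_contig_table(
    data.frame(
      id = c("c1", "c2", "c3", "c4", "c5"),
      length = c(100, 300, 2000, 5000, 1500),
      gc = c(40, 60, 55, 48, NA),
      genus = c("Escherichia", "Faecalibacterium", "Escherichia", NA, "Bacillus"),
      feats = c("K00001,K00001,K00002", "K00002", "", "dsrA,K00003", NA),
      note = c("a", "b", "c", "d", "e")
    ),
    rbind(column_spec("length", "numeric"), column_spec("gc", "numeric"),
          column_spec("genus", "categorical"), column_spec("feats", "feature_set"),
          column_spec("note", "descriptive"))
  )
}

random_polygon <- function(k, star = FALSE) {
  th <- sort(stats::runif(k, 0, 2 * pi))
  r <- if (star) stats::runif(k, 0.2, 1) else 1
  cbind(r * cos(th), r * sin(th))
}
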