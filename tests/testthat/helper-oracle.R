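# Independent brute-force TFCE oracle: explicit loops, flood fill by
# repeated queue expansion at every height level. Deliberately naive and
# written without reference to the package internals.

oracle_label_image4 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  nextlab <- 0L
  for (j in seq_len(m)) for (i in seq_len(n)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nextlab <- nextlab + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nextlab
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
        if (ni < 1 || ni > n || nj < 1 || nj > m) next
        if (mask[ni, nj] && lab[ni, nj] == 0) {
          lab[ni, nj] <- nextlab
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# edge-graph components: repeatedly merge edge groups sharing an ROI
oracle_label_edge_graph <- function(mask) {
  n <- nrow(mask)
  edges <- which(mask & upper.tri(mask), arr.ind = TRUE)
  lab <- matrix(0L, n, n)
  if (!nrow(edges)) return(lab)
  comp <- seq_len(nrow(edges))
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(edges))) for (b in seq_len(nrow(edges))) {
      if (comp[a] != comp[b] &&
          length(intersect(edges[a, ], edges[b, ])) > 0) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp <- as.integer(factor(comp, levels = unique(comp)))
  for (k in seq_len(nrow(edges))) {
    lab[edges[k, 1], edges[k, 2]] <- comp[k]
    lab[edges[k, 2], edges[k, 1]] <- comp[k]
  }
  lab
}

# full brute-force TFCE (signed, two tails handled by the caller's flag)
oracle_tfce <- function(stat, E = 0.5, H = 2, n_steps = 100, h0 = 0,
                        two_sided = TRUE,
                        neighborhood = c("matrix_image_4", "edge_graph")) {
  neighborhood <- match.arg(neighborhood)
  one_tail <- function(s) {
    n <- nrow(s)
    out <- matrix(0, n, n)
    hmax <- max(s)
    if (hmax <= h0) return(out)
    dh <- (hmax - h0) / n_steps
    for (step in seq_len(n_steps)) {
      h <- h0 + (step - 0.5) * dh
      mask <- s >= h
      lab <- if (neighborhood == "matrix_image_4") oracle_label_image4(mask)
             else oracle_label_edge_graph(mask)
      if (!any(lab > 0)) next
      for (k in seq_len(max(lab))) {
        cells <- lab == k
        extent <- if (neighborhood == "matrix_image_4") sum(cells)
                  else sum(cells & upper.tri(cells))
        out[cells] <- out[cells] + extent^E * h^H * dh
      }
    }
    out
  }
  res <- one_tail(pmax(stat, 0))
  if (two_sided) res <- res - one_tail(pmax(-stat, 0))
  res
}

# random symmetric zero-diagonal stat map
random_stat_map <- function(n, sd = 1.5) {
  m <- matrix(stats::rnorm(n * n, sd = sd), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
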