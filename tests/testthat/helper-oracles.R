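# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

make_labels <- function(n_resp, n_nonresp) {
  data.frame(sample_id = sprintf("S%03d", seq_len(n_resp + n_nonresp)),
             response = c(rep("responder", n_resp),
                          rep("nonresponder", n_nonresp)),
             stringsAsFactors = FALSE)
}

# textbook pooled-variance two-sample t-test
pooled_t_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  tt <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t = tt, p = 2 * pt(-abs(tt), df = n1 + n2 - 2))
}

# all-pairs Mann-Whitney AUC with ties counted 0.5
auc_oracle <- function(pos, neg) {
  tot <- 0
  for (x in pos) tot <- tot + sum(x > neg) + 0.5 * sum(x == neg)
  tot / (length(pos) * length(neg))
}

# trapezoidal area under a stepwise ROC given raw scores
trapezoid_auc <- function(pos, neg) {
  thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE), -Inf)
  fpr <- vapply(thr, function(t) mean(neg > t), 0)
  tpr <- vapply(thr, function(t) mean(pos > t), 0)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# exhaustive Youden search over every interval between distinct scores;
# counts kept on the integer scale so exact ties resolve deterministically
threshold_oracle <- function(scores, is_pos) {
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  best_t <- NA_real_; best_jn <- -Inf
  for (t in cand) {
    jn <- sum(scores[is_pos] > t) * n2 + sum(scores[!is_pos] <= t) * n1
    if (jn > best_jn) { best_jn <- jn; best_t <- t }
  }
  c(t = best_t, j = best_jn / (n1 * n2) - 1)
}

# grid sweep of unit vectors on the circle maximizing cov^2(Xw, y)
grid_weight_oracle <- function(X, y01, n_grid = 1e5) {
  Xs <- scale(X)
  yc <- y01 - mean(y01)
  cv <- drop(crossprod(Xs, yc)) / (nrow(X) - 1)
  theta <- seq(0, 2 * pi, length.out = n_grid)
  obj <- (cos(theta) * cv[1] + sin(theta) * cv[2])^2
  th <- theta[which.max(obj)]
  c(cos(th), sin(th))
}

# --- exhaustive shortest-path centralities for tiny graphs -----------------

# adjacency matrix of a simple undirected graph from an edge index matrix
adj_from_edges <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    A[edges] <- TRUE
    A[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  A
}

# all simple paths between s and t by DFS
all_simple_paths_dfs <- function(A, s, t) {
  n <- nrow(A); paths <- list()
  walk <- function(v, seen, path) {
    if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (w in seq_len(n)) if (A[v, w] && !seen[w]) {
      seen[w] <- TRUE
      walk(w, seen, c(path, w))
      seen[w] <- FALSE
    }
  }
  seen <- rep(FALSE, n); seen[s] <- TRUE
  walk(s, seen, s)
  paths
}

# betweenness (normalized) and harmonic closeness (normalized) by path
# enumeration; pair contributions follow sigma_st(v) / sigma_st
centrality_oracle <- function(A) {
  n <- nrow(A)
  btw <- numeric(n); harm <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_simple_paths_dfs(A, s, t)
    if (!length(paths)) next
    len <- vapply(paths, length, 0L)
    d <- min(len) - 1L
    sp <- paths[len == min(len)]
    harm[s] <- harm[s] + 1 / d
    harm[t] <- harm[t] + 1 / d
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(sp, function(p) v %in% p, TRUE))
      btw[v] <- btw[v] + through / length(sp)
    }
  }
  list(betweenness = if (n > 2) btw / ((n - 1) * (n - 2) / 2) else rep(0, n),
       closeness = harm / (n - 1))
}
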