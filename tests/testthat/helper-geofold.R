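# shared fixtures and a memoised store for the heavier simulation ensembles
# (computed once per test run, reused by several acceptance checks)

.geofold_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .geofold_cache)) {
    assign(key, force(expr), envir = .geofold_cache)
  }
  get(key, envir = .geofold_cache)
}

# path graph as a contact network
path_network <- function(n) {
  contact_network(n, cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

complete_network <- function(n) {
  contact_network(n, t(utils::combn(n, 2)))
}

cycle_network <- function(n) {
  contact_network(n, cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
}

# brute-force reference: distance-threshold adjacency by a double loop
brute_force_prn_edges <- function(coords, d_c) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= d_c) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# brute-force all-pairs BFS diameter
brute_force_diameter <- function(net) {
  n <- net$n_nodes
  adj <- vector("list", n)
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges[k, 1]; j <- net$edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  best <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    if (anyNA(dist)) return(NA_integer_)
    best <- max(best, max(dist))
  }
  best
}
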