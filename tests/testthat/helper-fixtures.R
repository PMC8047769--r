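# Shared fixtures and independent oracles, all built in code.

# A mixture assembled by hand (exact chemicals, no RNG), for hand-stepped
# traces.
manual_mixture <- function(chems, run_length) {
  chems$noise <- if (is.null(chems$noise)) FALSE else chems$noise
  structure(list(chemicals = chems, run_length = run_length, seed = NA_integer_),
            class = "dda_mixture")
}

two_chem_mixture <- function() {
  manual_mixture(data.frame(
    id = c("A", "B"), mz = c(100, 200), rt_apex = c(5, 6),
    max_intensity = c(1e6, 5e5), width_sigma = c(3, 3),
    stringsAsFactors = FALSE
  ), run_length = 8)
}

# An MS1 scan literal for the pure selection functions.
ms1_scan <- function(t, mz, intensity) {
  o <- order(mz)
  list(start_time = t, mz = mz[o], intensity = intensity[o])
}

# Brute-force maximum bipartite matching by exhaustive recursion over the
# left side: the independent oracle for hopcroft_karp() on small graphs.
bf_max_matching <- function(graph) {
  n_left <- graph$n_left
  adj <- lapply(seq_len(n_left), function(u)
    graph$edges$right[graph$edges$left == u])
  rec <- function(u, used) {
    if (u > n_left) return(0L)
    best <- rec(u + 1L, used)
    for (v in adj[[u]]) {
      if (!used[v]) {
        used[v] <- TRUE
        best <- max(best, 1L + rec(u + 1L, used))
        used[v] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, graph$n_right))
}

# Random bipartite graph with independent edge probability p.
random_bigraph <- function(n_left, n_right, p) {
  grid <- expand.grid(left = seq_len(n_left), right = seq_len(n_right))
  keep <- stats::runif(nrow(grid)) < p
  bipartite_graph(n_left, n_right, grid$left[keep], grid$right[keep])
}
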