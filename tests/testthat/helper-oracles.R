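# Independent brute-force oracles used by the tests.

# Plain O(V^2) Dijkstra over the mesh edge graph, no igraph involvement.
brute_dijkstra <- function(mesh, start) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], c(e[k, 2], w[k]))
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], w[k]))
  }
  dist <- rep(Inf, n)
  done <- logical(n)
  dist[start] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || done[u] || !is.finite(dist[u])) break
    done[u] <- TRUE
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]
      nd <- dist[u] + adj[[u]][r, 2]
      if (nd < dist[v]) dist[v] <- nd
    }
  }
  dist
}

# Magnetic scalar potential outside a spherically symmetric conductor;
# its negative gradient (by central differences) is the finite-difference
# oracle for the closed-form dipole field.
scalar_potential_U <- function(r, r0, Q) {
  a <- r - r0
  an <- sqrt(sum(a^2))
  R <- sqrt(sum(r^2))
  FF <- an * (R * an + R^2 - sum(r0 * r))
  Qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
            Q[3] * r0[1] - Q[1] * r0[3],
            Q[1] * r0[2] - Q[2] * r0[1])
  -1e-7 * sum(Qxr0 * r) / FF
}

fd_field_oracle <- function(r, r0, Q, h = 1e-6) {
  -vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (scalar_potential_U(r + e, r0, Q) -
       scalar_potential_U(r - e, r0, Q)) / (2 * h)
  }, numeric(1))
}
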