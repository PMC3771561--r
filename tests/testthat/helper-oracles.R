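# Independent oracles used to cross-check the circuit-breaking pipeline.
# They deliberately avoid the package's solvers: finite-difference Jacobians,
# plain multistart Newton, exhaustive graph searches.

# All fixed points of a model inside its bounds, by multistart Newton from
# quasi-uniform random starts with a finite-difference Jacobian.
oracle_fixed_points <- function(model, overrides = NULL, n_starts = 200L,
                                seed = 1L, tol = 1e-10) {
  set.seed(seed)
  n <- model$n
  lo <- model$bounds[, 1L]; hi <- model$bounds[, 2L]
  found <- list()
  for (s in seq_len(n_starts)) {
    x <- lo + runif(n) * (hi - lo)
    ok <- FALSE
    for (it in 1:80) {
      f <- tryCatch(eval_rhs(model, x, overrides), error = function(e) NULL)
      if (is.null(f) || any(!is.finite(f))) break
      if (max(abs(f)) < tol) { ok <- TRUE; break }
      J <- tryCatch(jacobian_fd(model, x, overrides), error = function(e) NULL)
      if (is.null(J)) break
      dx <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) break
      # step damping keeps iterates finite on steep Hill terms
      if (max(abs(dx)) > (max(hi) - min(lo))) dx <- dx * (max(hi) - min(lo)) / max(abs(dx))
      x <- x + dx
    }
    if (!ok) next
    if (any(x < lo - 1e-6 * (hi - lo) | x > hi + 1e-6 * (hi - lo))) next
    dup <- any(vapply(found, function(y)
      max(abs(y - x) / pmax(1, abs(y))) < 1e-5, logical(1L)))
    if (!dup) found[[length(found) + 1L]] <- x
  }
  if (!length(found)) return(matrix(numeric(0), 0L, n))
  pts <- do.call(rbind, found)
  pts[order(pts[, 1L], pts[, min(2L, n)]), , drop = FALSE]
}

# All elementary circuits of a digraph by brute force: for every vertex
# subset, every cyclic arrangement starting at the subset's minimum.
oracle_circuits <- function(n, edges) {
  has_edge <- matrix(FALSE, n, n)
  if (NROW(edges)) has_edge[as.matrix(edges[, 1:2])] <- TRUE
  out <- list()
  for (v in seq_len(n)) if (has_edge[v, v]) out[[length(out) + 1L]] <- v
  for (size in 2:max(2, n)) {
    if (size > n) break
    subs <- combn(n, size)
    for (ci in seq_len(ncol(subs))) {
      vs <- subs[, ci]
      first <- vs[1L]
      perms <- perms_of(vs[-1L])
      for (pi in seq_len(nrow(perms))) {
        cyc <- c(first, perms[pi, ])
        nxt <- c(cyc[-1L], first)
        if (all(has_edge[cbind(cyc, nxt)]))
          out[[length(out) + 1L]] <- cyc
      }
    }
  }
  out
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], perms_of(v[-i]))))
}

# Minimum hitting-set size by brute force over all vertex subsets.
oracle_min_cover_size <- function(circuits, n) {
  if (!length(circuits)) return(0L)
  for (size in 1:n) {
    subs <- combn(n, size)
    for (ci in seq_len(ncol(subs))) {
      S <- subs[, ci]
      if (all(vapply(circuits, function(cc) any(cc %in% S), logical(1L))))
        return(size)
    }
  }
  n
}

# Random digraph edge list (no self-loops unless asked).
random_digraph_edges <- function(n, p = 0.3, self_p = 0, seed = 1L) {
  set.seed(seed)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { if (runif(1) < self_p) { from <- c(from, i); to <- c(to, j) } }
    else if (runif(1) < p) { from <- c(from, i); to <- c(to, j) }
  }
  cbind(from, to)
}

canon_circuit_set <- function(circuits) {
  norm1 <- lapply(circuits, function(cc) {
    i <- which.min(cc)
    if (i > 1L) cc <- c(cc[i:length(cc)], cc[seq_len(i - 1L)])
    paste(cc, collapse = ",")
  })
  sort(unlist(norm1))
}
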