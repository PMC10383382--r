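# Brute-force oracles, independent of the package implementations
# (no igraph): plain recursive/matrix algorithms on small graphs, plus a
# generator of random connected molecular-like graphs.

# construct a mol_graph directly from an edge list (bypasses SMILES parsing)
fake_graph <- function(edges, n = max(edges), elements = rep("C", n),
                       order = rep(1, nrow(edges)), weights = NULL) {
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  bonds <- data.frame(i = edges[, 1], j = edges[, 2], order = order,
                      aromatic = FALSE)
  atoms <- data.frame(
    element = elements,
    mass = pfasqsar:::.element_prop(elements, "mass"),
    vdw_vol = pfasqsar:::.element_prop(elements, "vdw_vol"),
    degree = tabulate(c(edges[, 1], edges[, 2]), nbins = n),
    n_h = 0L,
    stringsAsFactors = FALSE
  )
  if (!is.null(weights)) atoms$mass <- atoms$vdw_vol <- weights
  structure(list(atoms = atoms, bonds = bonds, smiles = NA_character_),
            class = "mol_graph")
}

# random connected graph: random spanning tree plus extra edges
random_connected_graph <- function(n_max = 12) {
  n <- sample(2:n_max, 1)
  edges <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L),
                             integer(1)))
  extra <- sample(0:2, 1)
  for (k in seq_len(extra)) {
    cand <- sample.int(n, 2)
    e <- c(min(cand), max(cand))
    if (e[1] != e[2] &&
        !any(edges[, 1] == e[2] & edges[, 2] == e[1]) &&
        !any(pmin(edges[, 1], edges[, 2]) == e[1] &
             pmax(edges[, 1], edges[, 2]) == e[2])) {
      edges <- rbind(edges, e)
    }
  }
  els <- sample(c("C", "N", "O", "F", "S"), n, replace = TRUE)
  fake_graph(edges, n = n, elements = els)
}

# adjacency list of a mol_graph
adj_list <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b]; j <- g$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# exhaustive simple-path enumeration by recursive DFS
oracle_paths <- function(g, len) {
  adj <- adj_list(g)
  paths <- list()
  walk <- function(path) {
    if (length(path) == len + 1L) {
      if (path[1] < path[length(path)]) paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nb in adj[[path[length(path)]]]) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  for (v in seq_len(nrow(g$atoms))) walk(v)
  paths
}

oracle_avg_connectivity <- function(g, order) {
  deg <- g$atoms$degree
  if (order == 0) return(mean(deg[deg > 0]^(-0.5)))
  ps <- oracle_paths(g, order)
  if (length(ps) == 0L) return(0)
  mean(vapply(ps, function(p) 1 / sqrt(prod(deg[p])), numeric(1)))
}

# all-pairs shortest paths by iterated min-plus, no igraph
oracle_distances <- function(g) {
  n <- nrow(g$atoms)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (b in seq_len(nrow(g$bonds))) {
    d[g$bonds$i[b], g$bonds$j[b]] <- d[g$bonds$j[b], g$bonds$i[b]] <- 1
  }
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

oracle_eccentric_deviation <- function(g) {
  d <- oracle_distances(g)
  ecc <- apply(d, 1, max)
  mean(abs(ecc - mean(ecc)))
}

oracle_moran <- function(g, lag, w) {
  d <- oracle_distances(g)
  n <- length(w); wb <- mean(w)
  num <- 0; delta <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j]) && d[i, j] == lag) {
      num <- num + (w[i] - wb) * (w[j] - wb); delta <- delta + 1
    }
  }
  den <- sum((w - wb)^2) / n
  if (delta == 0 || den == 0) return(0)
  (num / delta) / den
}

oracle_geary <- function(g, lag, w) {
  d <- oracle_distances(g)
  n <- length(w); wb <- mean(w)
  num <- 0; delta <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j]) && d[i, j] == lag) {
      num <- num + (w[i] - w[j])^2; delta <- delta + 1
    }
  }
  den <- sum((w - wb)^2) / (n - 1)
  if (delta == 0 || den == 0) return(0)
  (num / (2 * delta)) / den
}

# carbon-scaled weights as used by the package's autocorrelation descriptors
scaled_weights <- function(g, what = c("mass", "vdw_volume")) {
  what <- match.arg(what)
  tab <- pfasqsar:::.element_table
  if (what == "mass") g$atoms$mass / tab["C", "mass"]
  else g$atoms$vdw_vol / tab["C", "vdw_vol"]
}

fixture_path <- function() {
  system.file("extdata", "pfas24.csv", package = "pfasqsar", mustWork = TRUE)
}
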