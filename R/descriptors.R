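#' Average path connectivity index
#'
#' Kier-Hall average connectivity index of a given path order: the sum over
#' all simple paths spanning `order + 1` vertices of the reciprocal square
#' root of the product of the vertex degrees along the path, divided by the
#' number of such paths. Order 4 of this index (`X4A`) is one of the three
#' descriptors of the study's discriminant model, where it carries the
#' largest weight: branched, compact structures score high and push a
#' compound towards the low-affinity class.
#'
#' @param g a [build_graph()] molecular graph.
#' @param order path order (number of edges in the path), non-negative.
#' @return The average connectivity index; 0 when the graph has no path of
#'   the requested order.
#' @examples
#' avg_connectivity_index(build_graph("CCCCC"), 4)  # 1/sqrt(8)
#' @export
avg_connectivity_index <- function(g, order) {
  stopifnot(inherits(g, "mol_graph"), order >= 0, order == round(order))
  deg <- g$atoms$degree
  if (order == 0) {
    if (nrow(g$atoms) == 0L || any(deg == 0 & nrow(g$atoms) > 1L)) {
      # isolated vertices have degree 0; chi term undefined, treat as no path
      deg <- deg[deg > 0]
      if (length(deg) == 0L) return(0)
    }
    return(mean(deg^(-0.5)))
  }
  paths <- .simple_paths(g, order)
  if (length(paths) == 0L) return(0)
  chi <- vapply(paths, function(p) 1 / sqrt(prod(deg[p])), numeric(1))
  sum(chi) / length(paths)
}

# all simple paths with `len` edges, each unordered path once
.simple_paths <- function(g, len) {
  if (nrow(g$bonds) == 0L) return(list())
  gr <- .igraph_of(g)
  out <- list()
  for (v in seq_len(nrow(g$atoms))) {
    ps <- igraph::all_simple_paths(gr, from = v, cutoff = len)
    for (p in ps) {
      p <- as.integer(p)
      if (length(p) == len + 1L && p[1] < p[length(p)]) {
        out[[length(out) + 1L]] <- p
      }
    }
  }
  out
}

#' Eccentricity dispersion index
#'
#' Mean absolute deviation of the vertex eccentricities of the
#' hydrogen-depleted graph (`DECC`): for each atom the eccentricity is the
#' longest topological distance to any other atom, and the index averages the
#' absolute deviations from their mean. Elongated molecules with
#' differentiated ends score high; perfectly symmetric graphs (cycles,
#' single atoms) score 0.
#'
#' @inheritParams avg_connectivity_index
#' @return Non-negative real; 0 for a single atom.
#' @export
eccentric_deviation <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  n <- nrow(g$atoms)
  if (n <= 1L) return(0)
  d <- .dist_matrix(g)
  if (any(!is.finite(d))) {
    stop("eccentric_deviation requires a connected molecular graph",
         call. = FALSE)
  }
  ecc <- apply(d, 1L, max)
  mean(abs(ecc - mean(ecc)))
}

#' Eigenvalues of the bond-order-augmented edge adjacency matrix
#'
#' Builds the symmetric edge adjacency matrix (entry 1 when two bonds share
#' an atom) with each diagonal entry set to the order of the corresponding
#' bond (aromatic = 1.5), and returns its k-th largest eigenvalue. The 12th
#' eigenvalue (`Eig12_AEA(bo)`) enters the study's discriminant model.
#' Molecules with fewer than `k` bonds return 0, a deterministic padding
#' convention that keeps the descriptor defined for small structures.
#'
#' @inheritParams avg_connectivity_index
#' @param k rank of the requested eigenvalue (1 = largest, by algebraic
#'   value, descending).
#' @export
augmented_edge_adjacency_eig <- function(g, k) {
  stopifnot(inherits(g, "mol_graph"), k >= 1, k == round(k))
  nb <- nrow(g$bonds)
  if (k > nb) return(0)
  E <- diag(g$bonds$order, nb)
  if (nb > 1L) {
    for (a in seq_len(nb - 1L)) {
      for (b in seq((a + 1L), nb)) {
        share <- length(intersect(c(g$bonds$i[a], g$bonds$j[a]),
                                  c(g$bonds$i[b], g$bonds$j[b]))) > 0L
        if (share) E[a, b] <- E[b, a] <- 1
      }
    }
  }
  sort(eigen(E, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)[k]
}

# atomic weights for the autocorrelation descriptors, carbon-scaled by default
.atom_weights <- function(g, weight = c("mass", "vdw_volume"), scaled = TRUE) {
  weight <- match.arg(weight)
  w <- switch(weight, mass = g$atoms$mass, vdw_volume = g$atoms$vdw_vol)
  if (scaled) {
    wc <- switch(weight,
                 mass = .element_table["C", "mass"],
                 vdw_volume = .element_table["C", "vdw_vol"])
    w <- w / wc
  }
  w
}

#' Moran spatial autocorrelation over the molecular graph
#'
#' Moran coefficient of an atomic property at a given topological lag:
#' \deqn{I(d) = \frac{\Delta^{-1} \sum\sum_{d(i,j)=d} (w_i-\bar w)(w_j-\bar w)}
#'              {A^{-1} \sum_i (w_i-\bar w)^2}}
#' with \eqn{\Delta} the number of ordered atom pairs at distance `lag` and
#' `A` the atom count. Weights are the atomic property scaled relative to
#' carbon (set `scaled = FALSE` for raw values). The mass-weighted lag-8
#' coefficient (`MATS8m`) is one of the four regression-model descriptors.
#'
#' Returns 0 when no atom pair sits at the requested lag or when the weight
#' variance is 0.
#'
#' @inheritParams avg_connectivity_index
#' @param lag topological distance (bond counts), >= 1.
#' @param weight atomic property: `"mass"` or `"vdw_volume"`.
#' @param scaled scale weights relative to carbon before centering?
#' @export
moran_autocorrelation <- function(g, lag, weight = "mass", scaled = TRUE) {
  stopifnot(inherits(g, "mol_graph"), lag >= 1)
  w <- .atom_weights(g, weight, scaled)
  n <- length(w)
  if (n < 2L) return(0)
  d <- .dist_matrix(g)
  at_lag <- is.finite(d) & d == lag
  delta <- sum(at_lag)           # ordered pairs
  dev <- w - mean(w)
  denom <- sum(dev^2) / n
  if (delta == 0L || denom == 0) return(0)
  num <- sum(outer(dev, dev)[at_lag]) / delta
  num / denom
}

#' Geary spatial autocorrelation over the molecular graph
#'
#' Geary coefficient of an atomic property at a given topological lag:
#' \deqn{c(d) = \frac{(2\Delta)^{-1} \sum\sum_{d(i,j)=d} (w_i-w_j)^2}
#'              {(A-1)^{-1} \sum_i (w_i-\bar w)^2}}
#' with the same pair-counting and zero conventions as
#' [moran_autocorrelation()]. The van-der-Waals-volume-weighted lag-8
#' coefficient (`GATS8v`) enters the regression model.
#'
#' @inheritParams moran_autocorrelation
#' @export
geary_autocorrelation <- function(g, lag, weight = "vdw_volume",
                                  scaled = TRUE) {
  stopifnot(inherits(g, "mol_graph"), lag >= 1)
  w <- .atom_weights(g, weight, scaled)
  n <- length(w)
  if (n < 2L) return(0)
  d <- .dist_matrix(g)
  at_lag <- is.finite(d) & d == lag
  delta <- sum(at_lag)
  denom <- sum((w - mean(w))^2) / (n - 1L)
  if (delta == 0L || denom == 0) return(0)
  num <- sum(outer(w, w, FUN = function(a, b) (a - b)^2)[at_lag]) / (2 * delta)
  num / denom
}

#' McGowan characteristic volume
#'
#' \eqn{V_x}: the sum of published elemental volume increments over all atoms
#' (hydrogens included) minus 6.56 per bond (bonds to hydrogen included),
#' divided by 100, in (cm^3/mol)/100. The numerator of the packing density
#' index.
#'
#' @inheritParams avg_connectivity_index
#' @export
mcgowan_volume <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  n_h <- sum(g$atoms$n_h)
  incr <- sum(.element_prop(g$atoms$element, "mcgowan")) +
    n_h * .element_table["H", "mcgowan"]
  n_bonds <- nrow(g$bonds) + n_h
  (incr - 6.56 * n_bonds) / 100
}

#' Total Van der Waals surface area (Labute-style)
#'
#' Sum over heavy atoms of approximate per-atom van der Waals surface-area
#' contributions, following Labute's pairwise sphere-capping approximation:
#' each atom starts from its full sphere surface \eqn{4\pi R_i^2} and loses a
#' spherical cap per bonded neighbour (implicit hydrogens included, one cap
#' per hydrogen), with the cap geometry set by the two bond radii and an
#' idealized bond length shortened by 0.1/0.2/0.3 for aromatic, double and
#' triple bonds. Strictly positive for any molecule with at least one atom.
#'
#' @inheritParams avg_connectivity_index
#' @param per_atom return the per-heavy-atom contributions instead of the sum?
#' @export
vsa_total <- function(g, per_atom = FALSE) {
  stopifnot(inherits(g, "mol_graph"))
  n <- nrow(g$atoms)
  rads <- .element_prop(g$atoms$element, "rb0")
  r_h <- .element_table["H", "rb0"]
  Vi <- numeric(n)
  scale_of <- function(order, aromatic) {
    if (aromatic) 0.1 else c(0, 0.2, 0.3)[order]
  }
  if (nrow(g$bonds) > 0L) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[b]; j <- g$bonds$j[b]
      Ri <- rads[i]; Rj <- rads[j]
      bij <- Ri + Rj - scale_of(if (g$bonds$aromatic[b]) 1L
                                else as.integer(round(g$bonds$order[b])),
                                g$bonds$aromatic[b])
      dij <- min(max(abs(Ri - Rj), bij), Ri + Rj)
      Vi[i] <- Vi[i] + Rj^2 - (Ri - dij)^2 / dij
      Vi[j] <- Vi[j] + Ri^2 - (Rj - dij)^2 / dij
    }
  }
  for (a in seq_len(n)) {
    if (g$atoms$n_h[a] > 0L) {
      Ri <- rads[a]
      dij <- Ri + r_h
      Vi[a] <- Vi[a] + g$atoms$n_h[a] * (r_h^2 - (Ri - dij)^2 / dij)
    }
  }
  contrib <- 4 * pi * rads^2 - pi * rads * Vi
  if (per_atom) contrib else sum(contrib)
}

#' Packing density index
#'
#' `PDI = Vx / SAtot`: McGowan characteristic volume over the total
#' Labute-style van der Waals surface area. A compactness measure; in the
#' study's regression model it carries a large negative coefficient, so
#' densely packed PFAS are predicted to bind albumin more strongly (lower
#' EC50).
#'
#' @inheritParams avg_connectivity_index
#' @export
packing_density_index <- function(g) {
  sa <- vsa_total(g)
  if (!is.finite(sa) || sa <= 0) {
    stop("packing_density_index undefined: non-positive surface area",
         call. = FALSE)
  }
  mcgowan_volume(g) / sa
}

#' Descriptor table for a dataset
#'
#' Computes the requested descriptors for every compound. Per-compound
#' failures (unparsable SMILES, degenerate structures) do not abort the
#' batch: the affected row is filled with `NA` and the error messages are
#' attached as the `"errors"` attribute.
#'
#' @param x a `qsar_dataset`, a character vector of SMILES (optionally
#'   named), or a list of `mol_graph` objects.
#' @param names descriptors to compute; any of
#'   `r paste0('"', c("X4A","DECC","Eig12_AEA_bo","PDI","MATS8m","GATS8v","QED","Vx","SAtot"), '"', collapse = ", ")`.
#' @param qed_weights weight set passed to [qed_score()].
#' @return data.frame, one row per compound, with an `id` column.
#' @export
descriptor_table <- function(x, names = c("X4A", "DECC", "Eig12_AEA_bo",
                                          "PDI", "MATS8m", "GATS8v", "QED"),
                             qed_weights = "unit") {
  valid <- c("X4A", "DECC", "Eig12_AEA_bo", "PDI", "MATS8m", "GATS8v", "QED",
             "Vx", "SAtot")
  bad <- setdiff(names, valid)
  if (length(bad) > 0L) {
    stop("unknown descriptor(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if (inherits(x, "qsar_dataset")) {
    smiles <- x$records$smiles
    ids <- x$records$id
  } else if (is.character(x)) {
    smiles <- x
    ids <- if (!is.null(base::names(x))) base::names(x) else
      paste0("M", seq_along(x))
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "mol_graph"))) {
    smiles <- NULL
    ids <- if (!is.null(base::names(x))) base::names(x) else
      paste0("M", seq_along(x))
  } else {
    stop("'x' must be a qsar_dataset, SMILES vector, or list of mol_graph",
         call. = FALSE)
  }
  n <- length(ids)
  out <- as.data.frame(matrix(NA_real_, n, length(names),
                              dimnames = list(NULL, names)))
  errors <- character(0)
  for (r in seq_len(n)) {
    res <- tryCatch({
      g <- if (is.null(smiles)) x[[r]] else build_graph(smiles[r])
      vapply(names, function(nm) .one_descriptor(g, nm, qed_weights),
             numeric(1))
    }, error = function(e) {
      errors[[ids[r]]] <<- conditionMessage(e)
      rep(NA_real_, length(names))
    })
    out[r, ] <- res
  }
  out <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), out)
  if (length(errors) > 0L) attr(out, "errors") <- errors
  out
}

.one_descriptor <- function(g, name, qed_weights = "unit") {
  switch(name,
    X4A = avg_connectivity_index(g, 4L),
    DECC = eccentric_deviation(g),
    Eig12_AEA_bo = augmented_edge_adjacency_eig(g, 12L),
    PDI = packing_density_index(g),
    MATS8m = moran_autocorrelation(g, 8L, "mass"),
    GATS8v = geary_autocorrelation(g, 8L, "vdw_volume"),
    QED = qed_score(g, weights = qed_weights),
    Vx = mcgowan_volume(g),
    SAtot = vsa_total(g),
    stop("unknown descriptor: ", name, call. = FALSE)
  )
}
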