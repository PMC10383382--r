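#' Build a hydrogen-depleted molecular graph from a SMILES string
#'
#' Parses a SMILES string (via OpenBabel through ChemmineR) into a labelled,
#' undirected molecular graph over the heavy atoms. Implicit hydrogen counts
#' are assigned from standard neutral-atom valences using the kekulized bond
#' orders; aromatic rings are perceived and their bonds flagged (bond order
#' 1.5 where a descriptor consumes aromatic bonds).
#'
#' @param smiles single SMILES string.
#' @return An object of class `mol_graph`: a list with components
#'   \describe{
#'     \item{atoms}{data.frame with one row per heavy atom: `element`, `mass`,
#'       `vdw_vol` (Bondi volume, cubic Angstrom), `degree` (heavy-atom
#'       degree), `n_h` (implicit hydrogens).}
#'     \item{bonds}{data.frame with columns `i`, `j` (1-based atom indices,
#'       `i < j`), `order` (1, 2, 3, or 1.5 for aromatic), `aromatic`.}
#'     \item{smiles}{the input string.}
#'   }
#' @examples
#' g <- build_graph("OC(=O)C(F)(F)F")  # trifluoroacetic acid
#' nrow(g$atoms)
#' @export
build_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("'smiles' must be a single non-empty string", call. = FALSE)
  }
  molblock <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
    error = function(e) {
      stop("failed to parse SMILES '", smiles, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  counts <- strsplit(trimws(strsplit(molblock, "\n")[[1]][4]), "\\s+")[[1]]
  if (length(counts) < 2L || is.na(suppressWarnings(as.integer(counts[1]))) ||
      as.integer(counts[1]) == 0L) {
    stop("failed to parse SMILES '", smiles, "': no atoms", call. = FALSE)
  }
  if (as.integer(counts[2]) == 0L) {
    # bond-free molecule; ChemmineR rejects these, read the molblock directly
    lines <- strsplit(molblock, "\n")[[1]]
    n <- as.integer(counts[1])
    elements <- vapply(lines[5:(4 + n)], function(l) {
      strsplit(trimws(l), "\\s+")[[1]][4]
    }, character(1), USE.NAMES = FALSE)
    atoms <- data.frame(
      element = elements,
      mass = .element_prop(elements, "mass"),
      vdw_vol = .element_prop(elements, "vdw_vol"),
      degree = 0L,
      n_h = vapply(elements, function(e) {
        v <- .element_valences[[e]]
        as.integer(if (is.null(v)) 0L else min(v))
      }, integer(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
    return(structure(
      list(atoms = atoms,
           bonds = data.frame(i = integer(), j = integer(), order = numeric(),
                              aromatic = logical()),
           smiles = smiles),
      class = "mol_graph"))
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      stop("failed to parse SMILES '", smiles, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0L) {
    stop("failed to parse SMILES '", smiles, "': no atoms", call. = FALSE)
  }
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)

  bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
  if (!is.null(bb) && (is.null(dim(bb)) || ncol(bb) < 3L)) bb <- NULL
  if (!is.null(bb) && nrow(bb) > 0L) {
    bonds <- data.frame(
      i = pmin(as.integer(bb[, 1]), as.integer(bb[, 2])),
      j = pmax(as.integer(bb[, 1]), as.integer(bb[, 2])),
      order = as.numeric(bb[, 3])
    )
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  if (nrow(bonds) > 0L &&
      (any(bonds$i < 1L) || any(bonds$j > n) || any(bonds$i == bonds$j))) {
    stop("malformed bond block for SMILES '", smiles, "'", call. = FALSE)
  }

  bonds$aromatic <- .aromatic_bonds(mol, bonds)
  # descriptor convention: aromatic bond order 1.5
  bonds$order[bonds$aromatic] <- 1.5

  degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
  # kekulized integer orders (pre aromatic-flagging) for valence accounting
  order_int <- if (nrow(bonds) > 0L) as.numeric(bb[, 3]) else numeric()
  val_used <- vapply(seq_len(n), function(a) {
    sum(order_int[bonds$i == a | bonds$j == a])
  }, numeric(1))
  n_h <- vapply(seq_len(n), function(a) {
    v <- .element_valences[[elements[a]]]
    if (is.null(v)) return(0)
    ok <- v[v >= val_used[a]]
    if (length(ok) == 0L) 0 else min(ok) - val_used[a]
  }, numeric(1))

  atoms <- data.frame(
    element = elements,
    mass = .element_prop(elements, "mass"),
    vdw_vol = .element_prop(elements, "vdw_vol"),
    degree = degree,
    n_h = as.integer(round(n_h)),
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds, smiles = smiles),
            class = "mol_graph")
}

# flag bonds that belong to an aromatic ring, using ChemmineR ring perception
.aromatic_bonds <- function(mol, bonds) {
  if (nrow(bonds) == 0L) return(logical(0))
  arom <- rep(FALSE, nrow(bonds))
  rings <- tryCatch(
    suppressWarnings(ChemmineR::rings(mol, type = "all", arom = TRUE,
                                      inner = FALSE)),
    error = function(e) NULL
  )
  if (is.null(rings) || length(rings$RINGS) == 0L) return(arom)
  aromatic_rings <- rings$RINGS[unlist(rings$AROMATIC)]
  for (ring in aromatic_rings) {
    idx <- as.integer(sub("^[^0-9]*", "", ring))
    m <- length(idx)
    for (k in seq_len(m)) {
      a <- idx[k]; b <- idx[if (k == m) 1L else k + 1L]
      arom[bonds$i == min(a, b) & bonds$j == max(a, b)] <- TRUE
    }
  }
  arom
}

#' @export
print.mol_graph <- function(x, ...) {
  comp <- table(c(x$atoms$element, rep("H", sum(x$atoms$n_h))))
  cat("mol_graph:", x$smiles, "\n")
  cat(" ", nrow(x$atoms), "heavy atoms,", nrow(x$bonds), "bonds; formula ~",
      paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = ""), "\n")
  invisible(x)
}

# igraph view of the heavy-atom skeleton
.igraph_of <- function(g) {
  n <- nrow(g$atoms)
  if (nrow(g$bonds) == 0L) {
    return(igraph::make_empty_graph(n, directed = FALSE))
  }
  igraph::add_vertices(
    igraph::graph_from_edgelist(cbind(g$bonds$i, g$bonds$j), directed = FALSE),
    max(0L, n - max(g$bonds$j))
  )
}

# topological distance matrix (bond counts)
.dist_matrix <- function(g) {
  igraph::distances(.igraph_of(g))
}
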