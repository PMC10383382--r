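# Synthetic data generators shaped like the study's inputs: small
# descriptor matrices with a known linear response, two-class descriptor
# clouds, and homologous PFAS-like molecular series.

#' Specification for a synthetic descriptor dataset
#'
#' Mirrors the shape of the study data: around two dozen compounds, a pool
#' of correlated descriptors, a handful of truly active descriptors with
#' known coefficients, and Gaussian response noise.
#'
#' @param n number of compounds.
#' @param pool descriptor-pool size.
#' @param true_idx indices of the descriptors that carry signal.
#' @param beta their coefficients.
#' @param sigma response noise standard deviation; the special value
#'   `"relative"` (with `sigma_rel`) sets it to a fraction of the noiseless
#'   response SD.
#' @param sigma_rel fraction used when `sigma = "relative"` (default 0.1).
#' @param rho common inter-descriptor correlation, `|rho| < 1`.
#' @param seed RNG seed.
#' @export
synthetic_spec <- function(n = 22, pool = 30, true_idx = 1:4,
                           beta = c(1.5, -2, 1, -1), sigma = "relative",
                           sigma_rel = 0.1, rho = 0.3, seed = 1) {
  stopifnot(all(true_idx >= 1), all(true_idx <= pool),
            length(beta) == length(true_idx), abs(rho) < 1)
  if (is.numeric(sigma)) stopifnot(sigma >= 0)
  structure(list(n = as.integer(n), pool = as.integer(pool),
                 true_idx = as.integer(true_idx), beta = beta,
                 sigma = sigma, sigma_rel = sigma_rel, rho = rho,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# equicorrelated Gaussian matrix via its closed-form square root
.correlated_gaussian <- function(n, p, rho) {
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho == 0) return(z)
  shared <- stats::rnorm(n)
  sqrt(rho) * shared + sqrt(1 - rho) * z
}

#' Generate a synthetic descriptor dataset with a known linear response
#'
#' `y = X[, true_idx] %*% beta + N(0, sigma^2)`; the truth record stores the
#' active indices and coefficients for recovery scoring.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `x` (n x pool matrix, columns `D1..Dpool`), `y`, and
#'   `truth` (`idx`, `names`, `beta`, `sigma`).
#' @export
make_descriptor_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    x <- .correlated_gaussian(spec$n, spec$pool, spec$rho)
    colnames(x) <- paste0("D", seq_len(spec$pool))
    signal <- drop(x[, spec$true_idx, drop = FALSE] %*% spec$beta)
    sigma <- if (identical(spec$sigma, "relative")) {
      spec$sigma_rel * stats::sd(signal)
    } else spec$sigma
    y <- signal + stats::rnorm(spec$n, sd = sigma)
    list(x = x, y = y,
         truth = list(idx = spec$true_idx,
                      names = colnames(x)[spec$true_idx],
                      beta = spec$beta, sigma = sigma))
  })
}

#' Generate a synthetic two-class descriptor dataset
#'
#' Two Gaussian classes separated by `delta` (in descriptor units) on the
#' true descriptors; all other pool columns are noise.
#'
#' @param spec a [synthetic_spec()].
#' @param delta mean separation on each true descriptor.
#' @param prop_positive exact fraction of `H` labels.
#' @return list with `x`, `labels` (`"H"`/`"L"`), `truth`.
#' @export
make_classification_dataset <- function(spec = synthetic_spec(),
                                        delta = 2, prop_positive = 0.5) {
  stopifnot(inherits(spec, "synthetic_spec"), delta >= 0)
  .with_seed(spec$seed, {
    n_pos <- round(spec$n * prop_positive)
    labels <- c(rep("H", n_pos), rep("L", spec$n - n_pos))
    x <- .correlated_gaussian(spec$n, spec$pool, spec$rho)
    colnames(x) <- paste0("D", seq_len(spec$pool))
    x[labels == "H", spec$true_idx] <-
      x[labels == "H", spec$true_idx] + delta / 2
    x[labels == "L", spec$true_idx] <-
      x[labels == "L", spec$true_idx] - delta / 2
    list(x = x, labels = labels,
         truth = list(idx = spec$true_idx, delta = delta))
  })
}

#' Construct a homologous PFAS series
#'
#' Programmatic SMILES for the chemical families of the study:
#' perfluoroalkyl carboxylic acids (`PFCA`, chain length = total carbons),
#' perfluoroalkyl sulfonic acids (`PFSA`, length = perfluorinated carbons),
#' fluorotelomer carboxylic acids (`FTCA`, n:3 telomers, length = n),
#' fluorotelomer sulfonic acids (`FTSA`, n:2) and fluorotelomer alcohols
#' (`FTOH`, n:2). Acids are produced in neutral form.
#'
#' @param family one of `"PFCA"`, `"PFSA"`, `"FTCA"`, `"FTSA"`, `"FTOH"`.
#' @param lengths integer vector of chain lengths (>= 2).
#' @return data.frame with `id`, `smiles`, `family`, `length`.
#' @export
make_pfas_series <- function(family = c("PFCA", "PFSA", "FTCA", "FTSA",
                                        "FTOH"),
                             lengths = 4:8) {
  family <- match.arg(family)
  stopifnot(all(lengths >= 2), all(lengths == round(lengths)))
  cf2 <- function(k) paste(rep("C(F)(F)", k), collapse = "")
  smi <- vapply(as.integer(lengths), function(n) {
    switch(family,
      PFCA = paste0("OC(=O)", cf2(n - 2), "C(F)(F)F"),
      PFSA = paste0("OS(=O)(=O)", cf2(n - 1), "C(F)(F)F"),
      FTCA = paste0("OC(=O)CC", cf2(n - 1), "C(F)(F)F"),
      FTSA = paste0("OS(=O)(=O)CC", cf2(n - 1), "C(F)(F)F"),
      FTOH = paste0("OCC", cf2(n - 1), "C(F)(F)F"))
  }, character(1))
  data.frame(id = paste0(family, "_", lengths), smiles = smi,
             family = family, length = as.integer(lengths),
             stringsAsFactors = FALSE)
}

#' Molecular formula of a molecular graph
#'
#' Hill-ordered formula string including implicit hydrogens; used to verify
#' programmatically constructed structures.
#'
#' @inheritParams avg_connectivity_index
#' @export
molecular_formula <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  counts <- table(g$atoms$element)
  nh <- sum(g$atoms$n_h)
  els <- names(counts)
  hill <- c(intersect("C", els), if (nh > 0) "H",
            sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(e) {
    k <- if (e == "H") nh else as.integer(counts[[e]])
    paste0(e, if (k > 1) k else "")
  }, character(1)), collapse = "")
}
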