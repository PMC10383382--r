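# Quantitative estimate of drug-likeness.
#
# QED maps eight physicochemical properties through asymmetric double
# sigmoidal (ADS) desirability functions fitted to the distributions of
# approved oral drugs, and aggregates them as a weighted geometric mean:
#   QED = exp( sum(w_i * ln d_i) / sum(w_i) ).
# The ADS parameters below are the published ones. Unit weights ("QEDw,u")
# are the default; the published mean- and max-information-gain weight sets
# are selectable.

.qed_ads_params <- local({
  p <- rbind(
    MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353,
               49.22325677, 65.37051707, 104.9805561),
    ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897,
               0.822739154, 0.576295591, 131.3186604),
    HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202,
               0.290141953, 1.300669958, 148.7763046),
    HBD    = c(1.618662227, 1010.051101, 0.985094388, 1e-09,
               0.713820843, 0.920922555, 258.1632616),
    PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614,
               12.01999824, 28.51324732, 104.5686167),
    ROTB   = c(0.01, 272.4121427, 2.55837997, 1.565547684,
               1.271567166, 2.758063707, 105.4420403),
    AROM   = c(3.21778897, 957.7374108, 2.274627939, 1e-09,
               1.317690384, 0.375760881, 312.337261),
    ALERTS = c(0.01, 1199.094025, -0.09002883, 1e-09,
               0.185904477, 0.875193782, 417.725314)
  )
  colnames(p) <- c("A", "B", "C", "D", "E", "F", "DMAX")
  p
})

.qed_weight_sets <- list(
  unit = c(MW = 1, ALOGP = 1, HBA = 1, HBD = 1, PSA = 1, ROTB = 1,
           AROM = 1, ALERTS = 1),
  mean = c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61, PSA = 0.06,
           ROTB = 0.65, AROM = 0.48, ALERTS = 0.95),
  max  = c(MW = 0.50, ALOGP = 0.25, HBA = 0.00, HBD = 0.50, PSA = 0.00,
           ROTB = 0.50, AROM = 0.25, ALERTS = 1.00)
)

# ADS desirability of property value x
.qed_ads <- function(x, p) {
  e1 <- 1 + exp(-(x - p["C"] + p["D"] / 2) / p["E"])
  e2 <- 1 + exp(-(x - p["C"] - p["D"] / 2) / p["F"])
  dx <- p["A"] + p["B"] / e1 * (1 - 1 / e2)
  unname(dx / p["DMAX"])
}

#' The eight QED property values of a molecule
#'
#' Computes molecular weight, Wildman-Crippen logP (via OpenBabel), hydrogen
#' bond acceptor count (N + O atoms), donor count (hydrogens on N or O),
#' topological polar surface area (Ertl, via OpenBabel), rotatable bond
#' count (non-ring single bonds between non-terminal heavy atoms, excluding
#' amide C-N and terminal CX3 / tert-butyl rotors), aromatic ring count, and
#' the number of structural-alert patterns matched.
#'
#' @inheritParams avg_connectivity_index
#' @return Named numeric vector `MW, ALOGP, HBA, HBD, PSA, ROTB, AROM,
#'   ALERTS`.
#' @export
qed_properties <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  sdf <- ChemmineR::smiles2sdf(g$smiles)
  ob <- ChemmineR::propOB(sdf)
  mw <- sum(g$atoms$mass) + sum(g$atoms$n_h) * .element_table["H", "mass"]
  hba <- sum(g$atoms$element %in% c("N", "O"))
  hbd <- sum(g$atoms$n_h[g$atoms$element %in% c("N", "O")])
  c(MW = mw,
    ALOGP = as.numeric(ob$logP),
    HBA = hba,
    HBD = hbd,
    PSA = as.numeric(ob$TPSA),
    ROTB = .rotatable_bonds(g),
    AROM = .aromatic_ring_count(g),
    ALERTS = .alert_count(sdf))
}

# strict rotatable-bond count on the heavy-atom graph
.rotatable_bonds <- function(g) {
  if (nrow(g$bonds) == 0L) return(0L)
  gr <- .igraph_of(g)
  bridges <- igraph::bridges(gr)
  in_ring <- rep(TRUE, nrow(g$bonds))
  in_ring[as.integer(bridges)] <- FALSE   # bridge = acyclic bond
  deg <- g$atoms$degree
  halide_hub <- function(a) {
    # CX3 (X = F, Cl, Br, I) or C(CH3)3-style terminal rotor
    if (g$atoms$element[a] != "C") return(FALSE)
    nb <- c(g$bonds$j[g$bonds$i == a], g$bonds$i[g$bonds$j == a])
    term <- nb[deg[nb] == 1L]
    halide <- sum(g$atoms$element[term] %in% c("F", "Cl", "Br", "I"))
    methyl <- sum(g$atoms$element[term] == "C" & g$atoms$n_h[term] == 3L)
    halide >= 3L || methyl >= 3L
  }
  amide <- function(i, j) {
    for (ord in list(c(i, j), c(j, i))) {
      cc <- ord[1]; nn <- ord[2]
      if (g$atoms$element[cc] == "C" && g$atoms$element[nn] == "N") {
        nb <- c(g$bonds$j[g$bonds$i == cc], g$bonds$i[g$bonds$j == cc])
        dbl_o <- any(g$atoms$element[nb] == "O" &
                       vapply(nb, function(b) {
                         any((g$bonds$i == min(cc, b) &
                              g$bonds$j == max(cc, b) &
                              g$bonds$order == 2))
                       }, logical(1)))
        if (dbl_o) return(TRUE)
      }
    }
    FALSE
  }
  count <- 0L
  for (b in seq_len(nrow(g$bonds))) {
    if (in_ring[b] || g$bonds$order[b] != 1) next
    i <- g$bonds$i[b]; j <- g$bonds$j[b]
    if (deg[i] < 2L || deg[j] < 2L) next
    if (halide_hub(i) || halide_hub(j)) next
    if (amide(i, j)) next
    count <- count + 1L
  }
  count
}

.aromatic_ring_count <- function(g) {
  if (!any(g$bonds$aromatic)) return(0L)
  rings <- tryCatch(
    suppressWarnings(ChemmineR::rings(ChemmineR::smiles2sdf(g$smiles)[[1]],
                                      type = "all", arom = TRUE,
                                      inner = FALSE)),
    error = function(e) NULL
  )
  if (is.null(rings)) return(0L)
  sum(unlist(rings$AROMATIC))
}

# number of structural-alert patterns with enough matches
.alert_count <- function(sdf) {
  pats <- .qed_alert_patterns
  fired <- 0L
  for (k in seq_len(nrow(pats))) {
    n <- tryCatch(
      suppressWarnings(as.numeric(
        ChemmineR::smartsSearchOB(sdf, pats$smarts[k], uniqueMatches = TRUE)
      )),
      error = function(e) 0
    )
    if (isTRUE(n >= pats$min_matches[k])) fired <- fired + 1L
  }
  fired
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of the eight ADS-mapped property desirabilities;
#' always in (0, 1]. Unit weights by default; `"mean"` and `"max"` select
#' the published information-gain weight sets.
#'
#' @inheritParams avg_connectivity_index
#' @param weights `"unit"`, `"mean"`, `"max"`, or a named numeric vector over
#'   the eight properties.
#' @param properties optional precomputed [qed_properties()] vector.
#' @export
qed_score <- function(g, weights = c("unit", "mean", "max"),
                      properties = NULL) {
  if (is.character(weights)) {
    weights <- .qed_weight_sets[[match.arg(weights)]]
  }
  props <- if (is.null(properties)) qed_properties(g) else properties
  stopifnot(all(rownames(.qed_ads_params) %in% names(props)),
            all(names(weights) %in% rownames(.qed_ads_params)))
  d <- vapply(rownames(.qed_ads_params), function(nm) {
    .qed_ads(props[[nm]], .qed_ads_params[nm, ])
  }, numeric(1))
  w <- weights[rownames(.qed_ads_params)]
  exp(sum(w * log(d)) / sum(w))
}
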