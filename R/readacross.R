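# Generic similarity-weighted read-across (GenRA-style) prediction of a
# binary toxicity outcome from structural analogues.

#' Jaccard (Tanimoto) similarity of two binary fingerprints
#'
#' @param fp_a,fp_b equal-length binary (0/1 or logical) vectors, not both
#'   all-zero.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(fp_a, fp_b) {
  fp_a <- as.logical(fp_a); fp_b <- as.logical(fp_b)
  if (length(fp_a) != length(fp_b)) {
    stop("fingerprints must have equal length", call. = FALSE)
  }
  union <- sum(fp_a | fp_b)
  if (union == 0L) {
    stop("both fingerprints are all-zero; similarity undefined",
         call. = FALSE)
  }
  sum(fp_a & fp_b) / union
}

#' Generic substructure-key fingerprint
#'
#' A pluggable default fingerprint for read-across when no external
#' chemotype keys are available: all linear atom paths of up to
#' `max_path` atoms are encoded as canonical element/bond-order strings and
#' hashed onto a fixed-length bit vector. Deterministic, and identical for
#' graph-isomorphic inputs of the same molecule.
#'
#' @param g a [build_graph()] molecular graph (or SMILES string).
#' @param n_bits fingerprint length.
#' @param max_path maximum path length in atoms.
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
substructure_fingerprint <- function(g, n_bits = 256, max_path = 4) {
  if (is.character(g)) g <- build_graph(g)
  stopifnot(inherits(g, "mol_graph"))
  frags <- character(0)
  el <- g$atoms$element
  # single atoms (with H count) and paths
  frags <- c(frags, paste0(el, "H", g$atoms$n_h))
  if (nrow(g$bonds) > 0L && max_path >= 2) {
    for (len in 1:(max_path - 1)) {
      for (p in .simple_paths(g, len)) {
        lab <- character(0)
        for (k in seq_along(p)) {
          lab <- c(lab, el[p[k]])
          if (k < length(p)) {
            a <- min(p[k], p[k + 1]); b <- max(p[k], p[k + 1])
            ord <- g$bonds$order[g$bonds$i == a & g$bonds$j == b]
            lab <- c(lab, as.character(ord))
          }
        }
        fwd <- paste(lab, collapse = "")
        rev_ <- paste(rev(lab), collapse = "")
        frags <- c(frags, min(fwd, rev_))
      }
    }
  }
  bits <- integer(n_bits)
  for (f in unique(frags)) {
    h <- sum(utf8ToInt(f) * (31^(seq_len(nchar(f)) %% 7))) %% n_bits
    bits[h + 1L] <- 1L
  }
  bits
}

#' Build an analogue set for read-across
#'
#' @param target_fp binary fingerprint of the target compound (may be `NULL`
#'   when similarities are supplied directly).
#' @param fingerprints list (or matrix rows) of analogue fingerprints, or
#'   `NULL` when `similarities` are given.
#' @param activities analogue activities: binary 0/1 effect flags, or
#'   continuous doses binarized by `dose_cutoff`.
#' @param similarities optional precomputed similarities in `[0, 1]`.
#' @param dose_cutoff when activities are doses, values at or below the
#'   cutoff are treated as active (1).
#' @return An `analogue_set`.
#' @export
analogue_set <- function(target_fp = NULL, fingerprints = NULL, activities,
                         similarities = NULL, dose_cutoff = NULL) {
  if (is.null(similarities)) {
    if (is.null(target_fp) || is.null(fingerprints)) {
      stop("supply either similarities or target_fp + fingerprints",
           call. = FALSE)
    }
    if (is.matrix(fingerprints)) {
      fingerprints <- asplit(fingerprints, 1)
    }
    similarities <- vapply(fingerprints, jaccard_similarity, numeric(1),
                           fp_b = target_fp)
  }
  if (length(similarities) != length(activities)) {
    stop("activities and similarities must have equal length", call. = FALSE)
  }
  if (length(activities) == 0L) stop("at least one analogue required",
                                     call. = FALSE)
  if (any(similarities < 0 | similarities > 1)) {
    stop("similarities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(dose_cutoff)) activities <- as.integer(activities <= dose_cutoff)
  if (!all(activities %in% c(0, 1))) {
    stop("activities must be binary (or supply dose_cutoff)", call. = FALSE)
  }
  structure(list(similarities = as.numeric(similarities),
                 activities = as.numeric(activities),
                 fingerprints = fingerprints, target_fp = target_fp),
            class = "analogue_set")
}

#' Similarity-weighted read-across activity score
#'
#' GenRA-style prediction: the similarity-weighted mean activity of the `k`
#' most similar analogues,
#' \eqn{ACT = \sum_i s_i a_i / \sum_i s_i}. A convex combination of the
#' neighbour activities, so always between their minimum and maximum, and
#' invariant to rescaling all similarities by a positive constant. Ties in
#' similarity are broken by input order (reported via the `"used"`
#' attribute).
#'
#' @param aset an [analogue_set()].
#' @param k number of analogues used (default 10).
#' @return Activity score in `[0, 1]` with attribute `"used"` (indices of
#'   the analogues entering the score).
#' @export
genra_predict <- function(aset, k = 10) {
  stopifnot(inherits(aset, "analogue_set"), k >= 1)
  ord <- order(-aset$similarities)        # stable: ties keep input order
  used <- ord[seq_len(min(k, length(ord)))]
  s <- aset$similarities[used]
  if (sum(s) == 0) {
    stop("all similarities of the selected analogues are zero",
         call. = FALSE)
  }
  structure(sum(s * aset$activities[used]) / sum(s), used = used)
}

#' Leave-one-out validation of a read-across neighbourhood
#'
#' Predicts each analogue from the remaining ones (similarities recomputed
#' from fingerprints when available, otherwise taken as given), computes the
#' AUROC of the scores against the true activities, and a seeded permutation
#' p-value (fraction of activity permutations whose AUROC is at least the
#' observed one). A single-class neighbourhood yields an undefined AUC,
#' flagged rather than reported as 0.
#'
#' @param aset an [analogue_set()] with fingerprints, or with similarities
#'   interpreted as analogue-analogue proxies.
#' @param k neighbours per leave-one-out prediction.
#' @param n_perm number of activity permutations.
#' @param seed RNG seed.
#' @return list with `auc`, `p_value`, `scores`, and `defined` (FALSE for a
#'   single-class neighbourhood, in which case `auc` and `p_value` are NA).
#' @export
genra_validate <- function(aset, k = 10, n_perm = 999, seed = 1) {
  stopifnot(inherits(aset, "analogue_set"))
  n <- length(aset$activities)
  if (n < 2L) stop("need at least two analogues", call. = FALSE)
  smat <- .analogue_similarity_matrix(aset)
  loo_scores <- function(act) {
    vapply(seq_len(n), function(i) {
      s <- smat[i, -i]; a <- act[-i]
      ord <- order(-s)
      used <- ord[seq_len(min(k, length(ord)))]
      if (sum(s[used]) == 0) return(NA_real_)
      sum(s[used] * a[used]) / sum(s[used])
    }, numeric(1))
  }
  scores <- loo_scores(aset$activities)
  if (length(unique(aset$activities)) < 2L) {
    return(list(auc = NA_real_, p_value = NA_real_, scores = scores,
                defined = FALSE,
                note = "single-class neighbourhood; AUC undefined"))
  }
  ok <- !is.na(scores)
  auc <- roc_auc(scores[ok], ifelse(aset$activities[ok] == 1, "H", "L"))$auc
  null_auc <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      act <- sample(aset$activities)
      if (length(unique(act[ok])) < 2L) return(NA_real_)
      sc <- loo_scores(act)
      roc_auc(sc[ok], ifelse(act[ok] == 1, "H", "L"))$auc
    }, numeric(1))
  })
  null_auc <- null_auc[!is.na(null_auc)]
  p <- (1 + sum(null_auc >= auc)) / (length(null_auc) + 1)
  list(auc = auc, p_value = p, scores = scores, defined = TRUE)
}

.analogue_similarity_matrix <- function(aset) {
  n <- length(aset$activities)
  if (!is.null(aset$fingerprints)) {
    fps <- aset$fingerprints
    smat <- diag(1, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        smat[i, j] <- smat[j, i] <- jaccard_similarity(fps[[i]], fps[[j]])
      }
    }
    smat
  } else {
    # proxy: product of target-similarities, a crude analogue-analogue guess
    outer(aset$similarities, aset$similarities)
  }
}
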