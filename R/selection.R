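# Descriptor-pool pretreatment, genetic-algorithm subset selection, and the
# exhaustive double cross-validation workflow for small datasets.

#' Descriptor-pool pretreatment
#'
#' Drops near-constant columns (variance below `var_tol`) and, from each
#' pair of descriptors correlated beyond `cor_tol` in absolute value, the
#' member less correlated with the response (when `y` is given; otherwise
#' the later column). The dropped names and reasons are attached as the
#' `"dropped"` attribute.
#'
#' @param x descriptor matrix or data.frame.
#' @param y optional response guiding correlated-pair resolution.
#' @param var_tol variance threshold for near-constant columns.
#' @param cor_tol absolute-correlation threshold for redundant pairs.
#' @return The reduced matrix.
#' @export
pretreat <- function(x, y = NULL, var_tol = 1e-4, cor_tol = 0.95) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  dropped <- data.frame(column = character(), reason = character(),
                        stringsAsFactors = FALSE)
  v <- apply(x, 2, stats::var)
  const <- v < var_tol
  if (any(const)) {
    dropped <- rbind(dropped, data.frame(column = colnames(x)[const],
                                         reason = "near-constant"))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) >= 2L) {
    repeat {
      cm <- abs(suppressWarnings(stats::cor(x)))
      diag(cm) <- 0
      if (all(cm <= cor_tol, na.rm = TRUE)) break
      idx <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
      a <- idx[1]; b <- idx[2]
      loser <- if (!is.null(y)) {
        ra <- abs(stats::cor(x[, a], y)); rb <- abs(stats::cor(x[, b], y))
        if (ra >= rb) b else a
      } else max(a, b)
      dropped <- rbind(dropped,
                       data.frame(column = colnames(x)[loser],
                                  reason = sprintf("|r| > %.2f with %s",
                                                   cor_tol,
                                                   colnames(x)[idx[idx != loser][1]])))
      x <- x[, -loser, drop = FALSE]
      if (ncol(x) < 2L) break
    }
  }
  attr(x, "dropped") <- dropped
  x
}

#' Genetic-algorithm configuration
#'
#' Standard small-pool settings: population 50, 100 generations, one-point
#' crossover at rate 0.8, per-gene mutation 0.05, elitism 1, fixed seed.
#'
#' @param population population size.
#' @param generations number of generations.
#' @param crossover_rate one-point crossover probability.
#' @param mutation_rate per-gene replacement probability.
#' @param elitism number of elite chromosomes copied unchanged.
#' @param seed RNG seed; fixes the run exactly.
#' @export
ga_config <- function(population = 50, generations = 100,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      elitism = 1, seed = 1) {
  stopifnot(population > 0, generations > 0, crossover_rate >= 0,
            mutation_rate >= 0, elitism >= 0)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# closed-form leave-one-out Q2 for OLS (PRESS via hat diagonal); used as the
# GA fitness for regression so selection stays cheap. q2_loo() is the naive
# oracle equivalent.
.q2_loo_ols <- function(x, y) {
  X1 <- cbind(1, x)
  qr_ <- qr(X1)
  if (qr_$rank < ncol(X1)) return(-Inf)
  res <- qr.resid(qr_, y)
  h <- rowSums(qr.Q(qr_)^2)
  press <- sum((res / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Genetic-algorithm descriptor-subset selection
#'
#' Seeded, reproducible GA over fixed-size descriptor subsets. Fitness is a
#' cross-validated quality metric: leave-one-out Q2 for regression
#' (`kind = "mlr"`), negative Wilks' lambda for classification
#' (`kind = "lda"`). Chromosomes are index sets; crossover recombines two
#' parents' pooled genes, mutation swaps a gene for a random non-member,
#' elitism preserves the best chromosome, so elite fitness is monotone
#' non-decreasing across generations.
#'
#' @param x_pool descriptor pool (matrix/data.frame).
#' @param y response or class labels.
#' @param size subset size to select.
#' @param kind `"mlr"` or `"lda"`.
#' @param cfg a [ga_config()].
#' @return data.frame of the distinct subsets visited, ranked by fitness
#'   (best first), with columns `subset` (list of column-name vectors) and
#'   `fitness`; the per-generation elite fitness trace is attached as
#'   attribute `"trace"`.
#' @export
ga_select <- function(x_pool, y, size, kind = c("mlr", "lda"),
                      cfg = ga_config()) {
  kind <- match.arg(kind)
  x_pool <- as.matrix(x_pool)
  if (is.null(colnames(x_pool)))
    colnames(x_pool) <- paste0("x", seq_len(ncol(x_pool)))
  p <- ncol(x_pool)
  if (size > p) stop("subset size exceeds pool size", call. = FALSE)
  fitness_of <- function(idx) {
    xs <- x_pool[, idx, drop = FALSE]
    if (kind == "mlr") {
      .q2_loo_ols(xs, y)
    } else {
      -tryCatch(wilks_lambda(xs, y)$lambda, error = function(e) 1)
    }
  }
  if (size == p) {
    out <- data.frame(fitness = fitness_of(seq_len(p)))
    out$subset <- list(colnames(x_pool))
    attr(out, "trace") <- out$fitness
    return(out)
  }
  .with_seed(cfg$seed, {
    pop <- replicate(cfg$population, sort(sample.int(p, size)),
                     simplify = FALSE)
    seen <- new.env(parent = emptyenv())
    note <- function(idx, fit) {
      key <- paste(idx, collapse = ",")
      if (is.null(seen[[key]])) seen[[key]] <- fit
    }
    fits <- vapply(pop, fitness_of, numeric(1))
    mapply(note, pop, fits)
    trace <- numeric(cfg$generations)
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fits, decreasing = TRUE)
      pop <- pop[ord]; fits <- fits[ord]
      trace[gen] <- fits[1]
      nxt <- pop[seq_len(min(cfg$elitism, length(pop)))]
      while (length(nxt) < cfg$population) {
        # binary tournament selection
        pick <- function() {
          cand <- sample.int(length(pop), 2L)
          pop[[cand[which.max(fits[cand])]]]
        }
        child <- if (stats::runif(1) < cfg$crossover_rate) {
          genes <- union(pick(), pick())
          sort(sample(genes, size))
        } else pick()
        mut <- stats::runif(size) < cfg$mutation_rate
        if (any(mut)) {
          outside <- setdiff(seq_len(p), child)
          for (gidx in which(mut)) {
            if (length(outside) == 0L) break
            swap_in <- outside[sample.int(length(outside), 1L)]
            outside <- c(setdiff(outside, swap_in), child[gidx])
            child[gidx] <- swap_in
          }
          child <- sort(child)
        }
        nxt[[length(nxt) + 1L]] <- child
      }
      pop <- nxt
      fits <- vapply(pop, fitness_of, numeric(1))
      mapply(note, pop, fits)
    }
    keys <- ls(seen)
    all_fits <- vapply(keys, function(k) seen[[k]], numeric(1))
    ord <- order(all_fits, decreasing = TRUE)
    out <- data.frame(fitness = unname(all_fits[ord]))
    out$subset <- lapply(keys[ord], function(k) {
      colnames(x_pool)[as.integer(strsplit(k, ",")[[1]])]
    })
    attr(out, "trace") <- trace
    out
  })
}

#' Double cross-validation configuration
#'
#' @param validation_size held-out compounds per split (study value: 3).
#' @param max_splits cap on the number of enumerated splits; above the cap a
#'   seeded subsample is drawn.
#' @param rule optimal-model selection rule: `"mae"` ranks splits by mean
#'   absolute error on the held-out compounds (ties broken by higher Q2).
#' @param seed RNG seed for subsampling above the cap.
#' @export
dcv_config <- function(validation_size = 3, max_splits = Inf,
                       rule = c("mae"), seed = 1) {
  structure(list(validation_size = as.integer(validation_size),
                 max_splits = max_splits, rule = match.arg(rule),
                 seed = as.integer(seed)),
            class = "dcv_config")
}

#' Exhaustive double cross-validation for small datasets
#'
#' Enumerates every validation subset of the configured size (all
#' `choose(n, v)` combinations by default; a seeded subsample above
#' `max_splits`), fits the model on the remaining compounds, and scores the
#' held-out ones. Splits are ranked by held-out MAE (ties by higher
#' training Q2); the best split's model is returned as the optimal model,
#' and the consensus prediction of each compound is the mean of its
#' held-out predictions across splits.
#'
#' @param x descriptor matrix (the already-selected descriptors).
#' @param y numeric response.
#' @param cfg a [dcv_config()].
#' @param fit fitting function `(x, y) -> qsar_model`.
#' @return A `qsar_dcv` object: list with `splits` (data.frame: held-out
#'   indices, MAE, Q2), `best` (refitted optimal model), `consensus`
#'   (per-compound mean held-out prediction), `coefficients` (per-split
#'   coefficient matrix), `n_splits`.
#' @export
double_cross_validate <- function(x, y, cfg = dcv_config(), fit = qsar_mlr) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  v <- cfg$validation_size
  if (v >= n) stop("validation size must be smaller than the dataset",
                   call. = FALSE)
  combos <- utils::combn(n, v)
  if (ncol(combos) > cfg$max_splits) {
    keep <- .with_seed(cfg$seed,
                       sample.int(ncol(combos), cfg$max_splits))
    combos <- combos[, keep, drop = FALSE]
  }
  ns <- ncol(combos)
  mae <- q2 <- numeric(ns)
  pred_sum <- pred_cnt <- numeric(n)
  coefs <- matrix(NA_real_, ns, ncol(x) + 1L,
                  dimnames = list(NULL, c("(Intercept)", colnames(x))))
  for (s in seq_len(ns)) {
    hold <- combos[, s]
    m <- fit(x[-hold, , drop = FALSE], y[-hold])
    pr <- predict(m, x[hold, , drop = FALSE])
    mae[s] <- mean(abs(y[hold] - pr))
    q2[s] <- .q2_loo_ols(x[-hold, , drop = FALSE], y[-hold])
    pred_sum[hold] <- pred_sum[hold] + pr
    pred_cnt[hold] <- pred_cnt[hold] + 1
    coefs[s, ] <- coef(m)[colnames(coefs)]
  }
  ord <- order(mae, -q2)
  best_split <- ord[1]
  hold <- combos[, best_split]
  best <- fit(x[-hold, , drop = FALSE], y[-hold])
  consensus <- ifelse(pred_cnt > 0, pred_sum / pred_cnt, NA_real_)
  structure(list(
    splits = data.frame(split = seq_len(ns),
                        held_out = apply(combos, 2, paste, collapse = ","),
                        mae = mae, q2 = q2)[ord, ],
    best = best, best_split = best_split,
    consensus = consensus, coefficients = coefs, n_splits = ns,
    config = cfg
  ), class = "qsar_dcv")
}

#' @export
print.qsar_dcv <- function(x, ...) {
  cat("double cross-validation:", x$n_splits, "splits, validation size",
      x$config$validation_size, "\n")
  cat("best split MAE:", format(x$splits$mae[1], digits = 4),
      " Q2:", format(x$splits$q2[1], digits = 4), "\n")
  cat("optimal model:\n")
  print(x$best)
  invisible(x)
}

#' Small-dataset QSAR workflow
#'
#' The full undivided-dataset pipeline: (i) descriptor-pool pretreatment,
#' (ii) genetic-algorithm subset selection with cross-validated fitness,
#' (iii) exhaustive double cross-validation of the selected subset, and
#' (iv) internal validation metrics of the optimal model.
#'
#' @param x_pool descriptor pool.
#' @param y numeric response.
#' @param n_desc number of descriptors in the final model.
#' @param ga_cfg a [ga_config()].
#' @param dcv_cfg a [dcv_config()].
#' @param fit fitting function for the final model.
#' @return list with `pool` (pretreated matrix), `ga` (ranked subsets),
#'   `selected` (descriptor names), `dcv` (the `qsar_dcv`), `model` (model
#'   refitted on all compounds with the selected descriptors), and
#'   `metrics` (R2, Q2, MAE, rm2 of the full-data fit).
#' @export
small_dataset_qsar <- function(x_pool, y, n_desc = 4,
                               ga_cfg = ga_config(),
                               dcv_cfg = dcv_config(), fit = qsar_mlr) {
  pool <- pretreat(x_pool, y)
  ga <- ga_select(pool, y, n_desc, kind = "mlr", cfg = ga_cfg)
  selected <- ga$subset[[1]]
  xs <- pool[, selected, drop = FALSE]
  dcv <- double_cross_validate(xs, y, cfg = dcv_cfg, fit = fit)
  model <- fit(xs, y)
  fitted <- predict(model, xs)
  reg <- regression_metrics(y, fitted)
  q2 <- q2_loo(xs, y, fit = fit)
  rm2 <- rm2_metrics(y, q2$loo_pred)
  list(pool = pool, ga = ga, selected = selected, dcv = dcv, model = model,
       metrics = list(r2 = reg$r2, mae = reg$mae, q2_loo = q2$q2,
                      rm2_bar = rm2$rm2_bar, delta_rm2 = rm2$delta_rm2))
}
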