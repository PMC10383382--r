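# Reproduction of the study's published summary statistics from the bundled
# dataset, and the docking-energy correlation.

#' Recompute the study's published summary statistics
#'
#' From the bundled 24-compound table this recomputes: (i) the H/L class
#' split obtained by thresholding the observed EC50 values, (ii) the full
#' training- and test-set classification metric battery from the published
#' observed and LDA-predicted class columns, and (iii) the regression R2
#' and MAE from the published observed and PLS-predicted EC50 values over
#' the 22 binding compounds. Each quantity is compared against its stored
#' published value and flagged pass/fail.
#'
#' @param threshold_mM EC50 class threshold (study value 1.45).
#' @param ds optional replacement dataset (defaults to the bundled fixture).
#' @return A `reproduction_report`: list of blocks `class_split`,
#'   `classification` (train/test), `regression`, each holding `computed`,
#'   `expected`, `pass`.
#' @export
reproduce_study <- function(threshold_mM = 1.45, ds = NULL) {
  if (is.null(ds)) ds <- pfas_hsa_data(classes = "printed")
  r <- ds$records
  need <- c("observed_class_printed", "predicted_class_lda",
            "predicted_ec50_pls")
  miss <- setdiff(need, names(r))
  if (length(miss) > 0L) {
    stop("dataset lacks published prediction column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  thr <- assign_classes(ds, threshold_mM)$records$observed_class
  split_counts <- c(H = sum(thr == "H"), L = sum(thr == "L"))

  blocks <- list()
  blocks$class_split <- list(
    computed = split_counts,
    expected = c(H = 11, L = 13),
    pass = identical(unname(split_counts), c(11L, 13L))
  )

  expected_cls <- list(
    train = c(sensitivity = 87.5, specificity = 100, precision = 100,
              accuracy = 93.75, f_measure = 93.33, mcc = 0.88, kappa = 0.88,
              g_means = 93.5),
    test = c(sensitivity = 100, specificity = 100, precision = 100,
             accuracy = 100, f_measure = 100, mcc = 1, kappa = 1,
             g_means = 100)
  )
  blocks$classification <- lapply(c(train = "train", test = "test"),
                                  function(sp) {
    rows <- r$split == sp
    cm <- confusion(r$observed_class_printed[rows],
                    r$predicted_class_lda[rows])
    met <- classification_metrics(cm)
    computed <- vapply(names(expected_cls[[sp]]), function(nm) met[[nm]],
                       numeric(1))
    rounded <- round(computed, 2)
    list(confusion = cm, computed = computed,
         expected = expected_cls[[sp]],
         pass = all(abs(rounded - expected_cls[[sp]]) < 1e-8 +
                      c(rep(0.005, 5), 0, 0, 0.05)))
  })

  both <- !is.na(r$ec50_mM) & !is.na(r$predicted_ec50_pls)
  reg <- regression_metrics(r$ec50_mM[both], r$predicted_ec50_pls[both])
  blocks$regression <- list(
    computed = c(r2 = reg$r2, mae = reg$mae, n = reg$n),
    expected = c(r2 = 0.802, mae = 0.205, n = 22),
    pass = abs(reg$r2 - 0.802) <= 0.002 && round(reg$mae, 3) == 0.205 &&
      reg$n == 22
  )

  structure(blocks, class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  flag <- function(p) if (isTRUE(p)) "PASS" else "FAIL"
  cat("class split at threshold:",
      paste(names(x$class_split$computed), x$class_split$computed,
            sep = "=", collapse = " / "),
      " [", flag(x$class_split$pass), "]\n")
  for (sp in names(x$classification)) {
    b <- x$classification[[sp]]
    cat(sp, "set metrics [", flag(b$pass), "]\n")
    print(round(rbind(computed = b$computed, expected = b$expected), 2))
  }
  cat("regression (published PLS predictions) [",
      flag(x$regression$pass), "]\n")
  print(round(rbind(computed = x$regression$computed,
                    expected = x$regression$expected), 4))
  invisible(x)
}

#' Correlate docking energies with observed binding affinity
#'
#' Pearson and Spearman correlations between the Glide docking energies
#' carried in the dataset and the observed EC50 values, over the compounds
#' holding both. Descriptive only; the docking computation itself is
#' outside this package's scope.
#'
#' @param ds a `qsar_dataset` with `glide_energy_kcal_mol` (defaults to the
#'   bundled study data).
#' @return list with `pearson`, `spearman` (each estimate + p-value), `n`;
#'   `defined = FALSE` when either column is constant.
#' @export
correlate_docking <- function(ds = pfas_hsa_data()) {
  r <- ds$records
  if (!"glide_energy_kcal_mol" %in% names(r)) {
    stop("dataset has no glide_energy_kcal_mol column", call. = FALSE)
  }
  both <- !is.na(r$ec50_mM) & !is.na(r$glide_energy_kcal_mol)
  e <- r$glide_energy_kcal_mol[both]; y <- r$ec50_mM[both]
  if (stats::sd(e) == 0 || stats::sd(y) == 0) {
    return(list(defined = FALSE, n = sum(both),
                note = "constant column; correlation undefined"))
  }
  pe <- stats::cor.test(e, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(e, y, method = "spearman"))
  list(defined = TRUE, n = sum(both),
       pearson = c(estimate = unname(pe$estimate), p_value = pe$p.value),
       spearman = c(estimate = unname(sp$estimate), p_value = sp$p.value))
}
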