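#' Read a QSAR dataset from CSV
#'
#' Loads and validates a compound table. Required columns: `id`, `cas`,
#' `name`, `smiles`, `ec50_mM`, `split`. Optional columns (carried through
#' when present): `observed_class_printed`, `predicted_class_lda`,
#' `predicted_ec50_pls`, `glide_energy_kcal_mol`, `smiles_provenance`,
#' `observed_class`. Malformed rows are reported with their line numbers;
#' unparsable SMILES are reported per record id.
#'
#' @param path CSV file (comma-separated, UTF-8, dot decimal, header row).
#' @param check_smiles validate every SMILES by parsing it? (default TRUE)
#' @return A `qsar_dataset`: list with `records` (data.frame) and
#'   `provenance`.
#' @export
read_qsar_dataset <- function(path, check_smiles = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("id", "cas", "name", "smiles", "ec50_mM", "split")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  line_of <- function(r) r + 1L  # header occupies line 1
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0L) {
    stop("schema error: duplicate id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  num_or_na <- function(x) {
    x[!nzchar(trimws(x))] <- NA
    suppressWarnings(as.numeric(x))
  }
  ec50 <- num_or_na(df$ec50_mM)
  bad_ec50 <- which(!is.na(df$ec50_mM) & nzchar(trimws(df$ec50_mM)) &
                      is.na(ec50))
  for (r in bad_ec50) {
    problems <- c(problems, sprintf("line %d (id %s): unparsable ec50_mM '%s'",
                                    line_of(r), df$id[r], df$ec50_mM[r]))
  }
  nonpos <- which(!is.na(ec50) & ec50 <= 0)
  for (r in nonpos) {
    problems <- c(problems, sprintf("line %d (id %s): ec50_mM must be > 0",
                                    line_of(r), df$id[r]))
  }
  bad_split <- which(!df$split %in% c("train", "test", "all"))
  for (r in bad_split) {
    problems <- c(problems, sprintf("line %d (id %s): split '%s' not in train/test/all",
                                    line_of(r), df$id[r], df$split[r]))
  }
  if (check_smiles && nrow(df) > 0L) {
    for (r in seq_len(nrow(df))) {
      err <- tryCatch({ build_graph(df$smiles[r]); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(err)) {
        problems <- c(problems, sprintf("line %d (id %s): %s",
                                        line_of(r), df$id[r], err))
      }
    }
  }
  if (length(problems) > 0L) {
    stop("invalid dataset:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  records <- data.frame(
    id = df$id, cas = df$cas, name = df$name, smiles = df$smiles,
    ec50_mM = ec50, split = df$split, stringsAsFactors = FALSE
  )
  char_opt <- c("observed_class_printed", "predicted_class_lda",
                "observed_class", "smiles_provenance")
  num_opt <- c("predicted_ec50_pls", "glide_energy_kcal_mol")
  for (opt in intersect(names(df), c(char_opt, num_opt))) {  # file order
    if (opt %in% num_opt) {
      records[[opt]] <- num_or_na(df[[opt]])
    } else {
      v <- df[[opt]]
      v[!nzchar(trimws(v))] <- NA
      records[[opt]] <- v
    }
  }
  structure(list(records = records, provenance = path), class = "qsar_dataset")
}

#' Assign binding-affinity classes by EC50 threshold
#'
#' Applies the study's class rule: compounds with `ec50_mM` at or below the
#' threshold are labelled `H` (high affinity), all others `L`; compounds
#' without an EC50 (declared non-binders) are always `L`. Idempotent, and
#' depends only on `ec50_mM` and the threshold.
#'
#' @param ds a `qsar_dataset`.
#' @param threshold_mM positive EC50 cutoff in mM (study value 1.45).
#' @return The dataset with an `observed_class` column.
#' @export
assign_classes <- function(ds, threshold_mM = 1.45) {
  stopifnot(inherits(ds, "qsar_dataset"), threshold_mM > 0)
  ec <- ds$records$ec50_mM
  ds$records$observed_class <- ifelse(!is.na(ec) & ec <= threshold_mM,
                                      "H", "L")
  ds
}

#' Write a QSAR dataset to CSV
#'
#' Round-trips losslessly through [read_qsar_dataset()]; absent EC50 values
#' are written as empty cells.
#'
#' @param ds a `qsar_dataset`.
#' @param path output file.
#' @export
write_qsar_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "qsar_dataset"))
  utils::write.csv(ds$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a plain SMILES file
#'
#' One `SMILES<tab>id` pair per line (id optional; sequential ids are
#' assigned when missing). Returns a named character vector of SMILES.
#'
#' @param path text file.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(k) {
    if (length(parts[[k]]) >= 2L) parts[[k]][2] else paste0("M", k)
  }, character(1))
  stats::setNames(smiles, ids)
}

#' The 24-compound PFAS / human serum albumin study dataset
#'
#' Loads the bundled dataset: 24 PFAS with CAS numbers, SMILES (written from
#' the printed CAS registry numbers and names, acids in neutral form),
#' observed EC50 (mM; absent for the two fluorotelomer alcohols that did not
#' bind), the published observed/predicted classifications and PLS-predicted
#' EC50, the train/test split, and docking energies. The `classes` argument
#' selects which observed class column populates `observed_class`:
#' `"printed"` keeps the published table's column (which disagrees with the
#' threshold rule for three compounds), `"threshold"` re-derives classes
#' from EC50 via [assign_classes()].
#'
#' @param classes `"printed"` or `"threshold"`.
#' @param threshold_mM cutoff used when `classes = "threshold"`.
#' @return a `qsar_dataset`.
#' @export
pfas_hsa_data <- function(classes = c("printed", "threshold"),
                          threshold_mM = 1.45) {
  classes <- match.arg(classes)
  path <- system.file("extdata", "pfas24.csv", package = "pfasqsar",
                      mustWork = TRUE)
  ds <- read_qsar_dataset(path, check_smiles = FALSE)
  if (classes == "printed") {
    ds$records$observed_class <- ds$records$observed_class_printed
  } else {
    ds <- assign_classes(ds, threshold_mM)
  }
  ds
}

#' @export
print.qsar_dataset <- function(x, ...) {
  r <- x$records
  cat("qsar_dataset:", nrow(r), "compounds")
  if ("split" %in% names(r)) {
    cat(" (", sum(r$split == "train"), "train /", sum(r$split == "test"),
        "test )")
  }
  cat("\n")
  if ("observed_class" %in% names(r) && !all(is.na(r$observed_class))) {
    cat("  classes:", sum(r$observed_class == "H", na.rm = TRUE), "H /",
        sum(r$observed_class == "L", na.rm = TRUE), "L\n")
  }
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
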