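#' Convert IC50 (nM) to pIC50
#'
#' Converts a half-maximal inhibitory concentration in nanomolar to the
#' negative base-10 logarithm of the molar concentration, the standard
#' medicinal-chemistry potency scale: `pIC50 = 9 - log10(IC50_nM)`.
#' A raw-nM variant (`-log10(IC50_nM)`, no unit conversion) is available
#' via `convention = "nM"`.
#'
#' @param ic50_nM Numeric vector of IC50 values in nanomolar; all > 0.
#' @param convention `"molar"` (default) or `"nM"`.
#' @return Numeric vector of pIC50 values (dimensionless log units).
#' @examples
#' ic50_to_pic50(c(1, 50, 1e9))
#' @export
ic50_to_pic50 <- function(ic50_nM, convention = c("molar", "nM")) {
  convention <- match.arg(convention)
  if (!is.numeric(ic50_nM)) abort("`ic50_nM` must be numeric.")
  bad <- which(!is.finite(ic50_nM) | ic50_nM <= 0)
  if (length(bad) > 0) {
    abort(sprintf("IC50 must be positive and finite; offending element(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (convention == "molar") 9 - log10(ic50_nM) else -log10(ic50_nM)
}

#' Convert pIC50 back to IC50 (nM)
#'
#' Inverse of [ic50_to_pic50()] under the molar convention.
#'
#' @param pic50 Numeric vector of pIC50 values.
#' @param convention `"molar"` (default) or `"nM"`.
#' @return IC50 in nanomolar.
#' @export
pic50_to_ic50 <- function(pic50, convention = c("molar", "nM")) {
  convention <- match.arg(convention)
  if (convention == "molar") 10^(9 - pic50) else 10^(-pic50)
}

#' Read a compound set with activities
#'
#' Joins a structure file (SMILES, one `smiles<whitespace>id` record per
#' line, or SDF) with an activity CSV (`compound_id, ic50_nM,
#' target_class`) into a compound table with pIC50 populated.
#'
#' @param structures_path Path to a SMILES (`.smi`/`.smiles`/`.txt`) or
#'   SDF (`.sdf`) file.
#' @param activity_path Path to a CSV with columns `compound_id`,
#'   `ic50_nM` and `target_class` (`wild` or `mutant`).
#' @param on_invalid_smiles `"abort"` (default) or `"skip"`: whether an
#'   unparseable structure is a hard error or dropped with a warning.
#' @param convention pIC50 unit convention, see [ic50_to_pic50()].
#' @return A tibble with columns `compound_id`, `smiles`, `ic50_nM`,
#'   `pic50`, `target_class`.
#' @export
read_compounds <- function(structures_path, activity_path,
                           on_invalid_smiles = c("abort", "skip"),
                           convention = "molar") {
  on_invalid_smiles <- match.arg(on_invalid_smiles)
  if (!file.exists(structures_path)) {
    abort(sprintf("Structure file not found: %s", structures_path))
  }
  if (!file.exists(activity_path)) {
    abort(sprintf("Activity file not found: %s", activity_path))
  }
  structures <- read_structure_table(structures_path)

  act <- readr::read_csv(activity_path, show_col_types = FALSE,
                         progress = FALSE)
  needed <- c("compound_id", "ic50_nM", "target_class")
  missing_cols <- setdiff(needed, names(act))
  if (length(missing_cols) > 0) {
    abort(sprintf("Activity table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  bad_ic50 <- which(!is.finite(act$ic50_nM) | act$ic50_nM <= 0)
  if (length(bad_ic50) > 0) {
    abort(sprintf(
      "Non-positive or missing ic50_nM in activity row(s) %s (compound_id %s)",
      paste(bad_ic50, collapse = ", "),
      paste(act$compound_id[bad_ic50], collapse = ", ")))
  }
  bad_class <- setdiff(unique(act$target_class), c("wild", "mutant"))
  if (length(bad_class) > 0) {
    abort(sprintf("Unknown target_class value(s): %s",
                  paste(bad_class, collapse = ", ")))
  }

  orphans <- c(setdiff(structures$compound_id, act$compound_id),
               setdiff(act$compound_id, structures$compound_id))
  if (length(orphans) > 0) {
    abort(sprintf(
      "Structure and activity tables do not join; orphan id(s): %s",
      paste(sort(orphans), collapse = ", ")))
  }
  if (anyDuplicated(structures$compound_id) || anyDuplicated(act$compound_id)) {
    abort("compound_id values must be unique within each input table.")
  }

  out <- structures |>
    inner_join(act, by = "compound_id") |>
    mutate(pic50 = ic50_to_pic50(.data$ic50_nM, convention = convention)) |>
    select("compound_id", "smiles", "ic50_nM", "pic50", "target_class")

  invalid <- !smiles_is_valid(out$smiles)
  if (any(invalid)) {
    msg <- sprintf("Invalid SMILES for compound(s): %s",
                   paste(out$compound_id[invalid], collapse = ", "))
    if (on_invalid_smiles == "abort") abort(msg)
    warn(paste0(msg, " (skipped)"))
    out <- out[!invalid, , drop = FALSE]
  }
  out
}

read_structure_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdf)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    return(tibble(compound_id = ids, smiles = unname(smi)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(trimws(lines), "\\s+", 2)
  if (any(!nzchar(parts[, 2]))) {
    abort("Each SMILES record must be `smiles<whitespace>compound_id`.")
  }
  tibble(compound_id = parts[, 2], smiles = parts[, 1])
}

#' Write a compound set to disk
#'
#' Emits the SMILES + activity CSV pair that [read_compounds()] reads, so
#' a dataset round-trips exactly.
#'
#' @param compounds Compound tibble as returned by [read_compounds()].
#' @param structures_path,activity_path Output paths.
#' @return `compounds`, invisibly.
#' @export
write_compounds <- function(compounds, structures_path, activity_path) {
  writeLines(paste(compounds$smiles, compounds$compound_id), structures_path)
  readr::write_csv(
    compounds |> select("compound_id", "ic50_nM", "target_class"),
    activity_path)
  invisible(compounds)
}

# Validity check via OpenBabel parse. Tries one batch parse first (an
# error there means at least one bad record), then falls back to
# per-molecule checks so offenders are identified.
smiles_is_valid <- function(smiles) {
  named <- setNames(smiles, sprintf("q%06d", seq_along(smiles)))
  batch <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(named))
    if (length(sdf) == length(smiles))
      unname(ChemmineR::validSDF(sdf)) else NULL
  }, error = function(e) NULL)
  if (!is.null(batch)) return(batch)
  vapply(seq_along(smiles), function(i) {
    isTRUE(tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(named[i]))
      length(sdf) == 1 && ChemmineR::validSDF(sdf)
    }, error = function(e) FALSE))
  }, logical(1))
}

#' Split a compound set into training and validation subsets
#'
#' Uniform random split without replacement, reproducible under `seed`.
#' The validation size is `floor(fraction_valid * n)` unless explicit
#' counts are given (some literature splits do not follow a single
#' rounding rule).
#'
#' @param compounds Compound tibble (or any data frame with
#'   `compound_id`).
#' @param fraction_valid Fraction held out for validation, in (0, 1).
#' @param seed Integer seed fixing the split.
#' @param explicit_counts Optional `c(n_train, n_valid)` overriding
#'   `fraction_valid`; must sum to `nrow(compounds)`.
#' @return A tibble with columns `compound_id` and `subset`
#'   (`"train"`/`"valid"`), carrying the seed as attribute `"seed"`.
#' @examples
#' cmp <- tibble::tibble(compound_id = paste0("c", 1:10))
#' split_dataset(cmp, fraction_valid = 0.2, seed = 1)
#' @export
split_dataset <- function(compounds, fraction_valid = 0.2, seed = 1,
                          explicit_counts = NULL) {
  n <- nrow(compounds)
  if (n < 2) abort("Need at least 2 compounds to split.")
  if (anyDuplicated(compounds$compound_id)) {
    abort("compound_id values must be unique.")
  }
  if (is.null(explicit_counts)) {
    if (!is.numeric(fraction_valid) || fraction_valid <= 0 || fraction_valid >= 1) {
      abort("`fraction_valid` must lie in (0, 1).")
    }
    n_valid <- floor(fraction_valid * n)
    if (n_valid < 1) n_valid <- 1L
  } else {
    if (length(explicit_counts) != 2 || sum(explicit_counts) != n) {
      abort(sprintf("`explicit_counts` must be c(n_train, n_valid) summing to %d.", n))
    }
    n_valid <- explicit_counts[[2]]
  }
  valid_idx <- withr::with_seed(derive_seed(seed, "split"),
                                sample.int(n, n_valid))
  out <- tibble(
    compound_id = compounds$compound_id,
    subset = ifelse(seq_len(n) %in% valid_idx, "valid", "train"))
  attr(out, "seed") <- seed
  out
}

#' Read a docking-energy descriptor table
#'
#' Reads a CSV of the seven per-compound docking energy terms (kcal/mol)
#' produced by a docking engine: estimated free energy of binding,
#' final intermolecular energy, vdW + H-bond + desolvation energy,
#' electrostatic energy, final total internal energy, torsional free
#' energy, and the unbound system's energy.
#'
#' @param path CSV with columns `compound_id`, `E_FreeBind`,
#'   `E_InterMol`, `E_VHD`, `E_Elec`, `E_FToT`, `E_Tors`, `E_Unb`.
#' @param on_missing `"abort"` (default) or `"drop"`: policy for rows
#'   with a missing/non-finite energy term.
#' @return A tibble, one row per compound, all seven terms finite.
#' @export
read_docking_energies <- function(path, on_missing = c("abort", "drop")) {
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) abort(sprintf("Energy file not found: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(docking_energy_terms(), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"compound_id" %in% names(x)) abort("missing column compound_id")
  if (anyDuplicated(x$compound_id)) {
    abort("Duplicate compound_id in energy table.")
  }
  x <- x |> select("compound_id", dplyr::all_of(docking_energy_terms()))
  ok <- apply(as.matrix(x[docking_energy_terms()]), 1,
              function(r) all(is.finite(r)))
  if (!all(ok)) {
    msg <- sprintf("Non-finite energy term(s) for compound(s): %s",
                   paste(x$compound_id[!ok], collapse = ", "))
    if (on_missing == "abort") abort(msg)
    warn(paste0(msg, " (dropped)"))
    x <- x[ok, , drop = FALSE]
  }
  x
}

#' The seven docking energy term names
#'
#' @return Character vector of the seven energy column names.
#' @export
docking_energy_terms <- function() {
  c("E_FreeBind", "E_InterMol", "E_VHD", "E_Elec", "E_FToT", "E_Tors", "E_Unb")
}
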