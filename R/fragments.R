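# Fragment class-frequency enrichment over binary fingerprint columns.
# "Fragment" means a binary substructure key / fingerprint bit; presence
# is per-molecule (multiple occurrences within one molecule count once).

binary_columns <- function(descriptors) {
  feats <- feature_names(descriptors)
  feats[vapply(descriptors[feats],
               function(v) all(v %in% c(0, 1)), logical(1))]
}

class_lookup <- function(descriptors, classes) {
  if (!all(c("compound_id", "target_class") %in% names(classes))) {
    abort("`classes` needs columns compound_id and target_class.")
  }
  cl <- classes$target_class[match(descriptors$compound_id,
                                   classes$compound_id)]
  if (anyNA(cl)) abort("Every compound needs a class label.")
  lv <- unique(cl)
  if (length(lv) != 2) abort("Exactly two classes are required.")
  cl
}

#' Class-frequency enrichment of one fragment
#'
#' The enrichment frequency of a fragment in a class is its class
#' prevalence normalized by its overall prevalence:
#' `frequency = (N_fragment_class / N_class) / (N_fragment_total /
#' N_total)`. A value of 1 means the fragment occurs in the class at
#' the background rate; values above 1 mean class enrichment; 0 means
#' the fragment is absent from the class. The class-weighted sum of
#' frequencies over both classes is exactly 1 for any fragment present
#' somewhere.
#'
#' @param descriptors Descriptor tibble containing the fragment as a
#'   binary column.
#' @param classes Tibble with `compound_id` and `target_class` (two
#'   classes).
#' @param fragment_id Name of the binary column.
#' @param class_label Which class to score.
#' @return One-row tibble: `fragment_id`, `class`, `N_fragment_class`,
#'   `N_class`, `N_fragment_total`, `N_total`, `frequency`.
#' @export
fragment_frequency <- function(descriptors, classes, fragment_id,
                               class_label) {
  if (!fragment_id %in% names(descriptors)) {
    abort(sprintf("No column `%s` in the descriptor table.", fragment_id))
  }
  v <- descriptors[[fragment_id]]
  if (!all(v %in% c(0, 1))) {
    abort(sprintf("`%s` is not a binary fragment column.", fragment_id))
  }
  cl <- class_lookup(descriptors, classes)
  if (!class_label %in% cl) {
    abort(sprintf("Class `%s` is empty or unknown.", class_label))
  }
  in_class <- cl == class_label
  n_fc <- sum(v[in_class])
  n_c <- sum(in_class)
  n_ft <- sum(v)
  n_t <- length(v)
  freq <- if (n_ft == 0) 0 else (n_fc / n_c) / (n_ft / n_t)
  tibble(fragment_id = fragment_id, class = class_label,
         N_fragment_class = n_fc, N_class = n_c,
         N_fragment_total = n_ft, N_total = n_t, frequency = freq)
}

#' Class-frequency enrichment of every fragment
#'
#' Applies [fragment_frequency()] to every binary column for both
#' classes.
#'
#' @inheritParams fragment_frequency
#' @return Tibble, one row per fragment x class.
#' @export
fragment_frequency_table <- function(descriptors, classes) {
  cl <- class_lookup(descriptors, classes)
  bits <- binary_columns(descriptors)
  if (length(bits) == 0) abort("No binary fragment columns found.")
  m <- as.matrix(descriptors[bits])
  n_t <- nrow(m)
  n_ft <- colSums(m)
  rows <- map(unique(cl), function(lab) {
    in_class <- cl == lab
    n_fc <- colSums(m[in_class, , drop = FALSE])
    freq <- ifelse(n_ft == 0, 0, (n_fc / sum(in_class)) / (n_ft / n_t))
    tibble(fragment_id = bits, class = lab,
           N_fragment_class = unname(n_fc), N_class = sum(in_class),
           N_fragment_total = unname(n_ft), N_total = n_t,
           frequency = unname(freq))
  })
  bind_rows(rows) |> arrange(.data$fragment_id, .data$class)
}

#' Find fragments exclusive to one inhibitor class
#'
#' Strict exclusives are present in every molecule of one class and
#' absent from every molecule of the other. A relaxed list admits
#' fragments with class prevalence at least `relaxed_in` in one class
#' and at most `relaxed_out` in the other.
#'
#' @inheritParams fragment_frequency
#' @param relaxed_in,relaxed_out Prevalence thresholds for the relaxed
#'   list (defaults 0.9 and 0.1).
#' @return Tibble: `fragment_id`, `class` (the enriched class),
#'   `rule` (`"strict"`/`"relaxed"`), `prevalence_in`,
#'   `prevalence_out`. Strict hits also appear in the relaxed rule's
#'   terms but are reported once, as strict.
#' @export
find_exclusive_fragments <- function(descriptors, classes,
                                     relaxed_in = 0.9, relaxed_out = 0.1) {
  cl <- class_lookup(descriptors, classes)
  bits <- binary_columns(descriptors)
  m <- as.matrix(descriptors[bits])
  labs <- unique(cl)
  rows <- map(labs, function(lab) {
    other <- setdiff(labs, lab)
    p_in <- colMeans(m[cl == lab, , drop = FALSE])
    p_out <- colMeans(m[cl == other, , drop = FALSE])
    strict <- p_in == 1 & p_out == 0
    relaxed <- !strict & p_in >= relaxed_in & p_out <= relaxed_out
    tibble(fragment_id = bits,
           class = lab,
           rule = ifelse(strict, "strict",
                         ifelse(relaxed, "relaxed", NA_character_)),
           prevalence_in = unname(p_in),
           prevalence_out = unname(p_out)) |>
      filter(!is.na(.data$rule))
  })
  bind_rows(rows) |> arrange(.data$class, .data$rule, .data$fragment_id)
}

#' Find fragments common to both inhibitor classes
#'
#' @inheritParams fragment_frequency
#' @param min_prevalence Minimum class prevalence required in BOTH
#'   classes, in (0, 1\].
#' @return Tibble: `fragment_id` plus one prevalence column per class.
#' @export
find_common_fragments <- function(descriptors, classes,
                                  min_prevalence = 0.9) {
  if (min_prevalence <= 0 || min_prevalence > 1) {
    abort("`min_prevalence` must lie in (0, 1].")
  }
  cl <- class_lookup(descriptors, classes)
  bits <- binary_columns(descriptors)
  m <- as.matrix(descriptors[bits])
  labs <- sort(unique(cl))
  prev <- vapply(labs, function(lab)
    colMeans(m[cl == lab, , drop = FALSE]), numeric(length(bits)))
  if (length(bits) == 1) prev <- matrix(prev, nrow = 1)
  keep <- apply(prev >= min_prevalence, 1, all)
  out <- tibble(fragment_id = bits[keep])
  for (j in seq_along(labs)) {
    out[[paste0("prevalence_", labs[j])]] <- prev[keep, j]
  }
  out
}
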