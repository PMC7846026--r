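#' @importFrom rlang .data abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Columns every repertoire tibble carries; extra metadata columns are allowed
# and preserved by read/write.
REP_CORE_COLS <- c(
  "sample_id", "subject_id", "group", "timepoint", "chain", "tissue",
  "junction", "junction_aa", "v_call", "j_call", "duplicate_count"
)

#' Build a validated repertoire tibble
#'
#' The central container of the package: one row per clone (clonotype), where
#' clone identity within a sample is the nucleotide junction alone. Rows with
#' identical `(sample_id, junction)` are merged with summed `duplicate_count`;
#' their V/J annotations are kept as a comma-joined set (a single CDR3 can
#' arise from several V-J pairings, so V/J is annotation, not identity).
#'
#' @param x A data frame with at least `junction`, `junction_aa` and
#'   `duplicate_count`. Missing metadata columns (`sample_id`, `subject_id`,
#'   `group`, `timepoint`, `chain`, `tissue`, `v_call`, `j_call`) are filled
#'   with defaults.
#' @param merge Merge duplicate `(sample_id, junction)` rows (default `TRUE`).
#' @return A tibble with the repertoire columns, one row per clone.
#' @export
as_repertoire <- function(x, merge = TRUE) {
  x <- as_tibble(x)
  need <- c("junction", "junction_aa", "duplicate_count")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
          class = "tcrshare_format_error")
  }
  defaults <- list(
    sample_id = "sample1", subject_id = "subject1", group = "control",
    timepoint = NA_integer_, chain = "beta", tissue = "blood",
    v_call = "", j_call = ""
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(x)) x[[nm]] <- defaults[[nm]]
  }
  x$duplicate_count <- as.integer(x$duplicate_count)
  if (any(x$duplicate_count < 1L)) {
    abort("duplicate_count must be >= 1 for every clone",
          class = "tcrshare_format_error")
  }
  if (merge) x <- merge_clones(x)
  relocate(x, all_of(REP_CORE_COLS))
}

# Merge rows sharing (sample_id, junction): counts summed, V/J joined as sets,
# other metadata taken from the first row. Order-independent by construction.
merge_clones <- function(x) {
  join_set <- function(v) {
    v <- unique(unlist(strsplit(v[v != "" & !is.na(v)], ",", fixed = TRUE)))
    paste(sort(v), collapse = ",")
  }
  x |>
    group_by(.data$sample_id, .data$junction) |>
    summarise(
      across(any_of(c("subject_id", "group", "timepoint", "chain", "tissue",
                      "junction_aa")), ~ .x[1]),
      v_call = join_set(.data$v_call),
      j_call = join_set(.data$j_call),
      duplicate_count = sum(.data$duplicate_count),
      across(!any_of(c(REP_CORE_COLS)), ~ .x[1]),
      .groups = "drop"
    ) |>
    arrange(.data$sample_id, .data$junction)
}

#' Total sequencing reads per sample
#'
#' @param x A repertoire tibble.
#' @return A tibble with `sample_id` and `total_reads`.
#' @export
total_reads <- function(x) {
  x |>
    group_by(.data$sample_id) |>
    summarise(total_reads = sum(.data$duplicate_count), .groups = "drop")
}

#' Study design: which timepoints count as young vs old
#'
#' Longitudinal samples are binned into two epochs for overlap and abundance
#' comparisons; the defaults follow the convention of calling monthly
#' timepoints 1-4 "young" and 5-8 "old".
#'
#' @param young,old Integer vectors of timepoints; must be disjoint.
#' @return An object of class `study_design`.
#' @export
study_design <- function(young = 1:4, old = 5:8) {
  young <- as.integer(young); old <- as.integer(old)
  if (length(intersect(young, old)) > 0) {
    abort("young and old timepoint sets must be disjoint",
          class = "tcrshare_config_error")
  }
  structure(list(young = young, old = old), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> young:", paste(x$young, collapse = ","),
      " old:", paste(x$old, collapse = ","), "\n")
  invisible(x)
}

# Map timepoints to epoch labels ("young"/"old"/NA).
epoch_of <- function(timepoint, design) {
  out <- rep(NA_character_, length(timepoint))
  out[timepoint %in% design$young] <- "young"
  out[timepoint %in% design$old] <- "old"
  out
}
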