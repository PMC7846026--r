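#' Classify amino-acid clones by publicness
#'
#' A CDR3 amino-acid sequence appearing in a single subject is *private*; one
#' appearing in at least two subjects is *public*. Public sequences found in
#' both study groups are *inclusive*; those shared only among case subjects
#' (or only among controls) are *exclusive*. Presence means a count of at
#' least `min_count` in the subject's (typically pooled and subsampled)
#' repertoire.
#'
#' @param pooled A repertoire tibble with one sample per subject (see
#'   [pool_subjects()]), covering both groups and a single chain.
#' @param min_count Minimum per-subject copy number to count as present
#'   (default 1).
#' @return A tibble of class `tcr_publicness`: `junction_aa`,
#'   `n_control_subjects`, `n_case_subjects`, `n_subjects_total`, `label`
#'   (one of `private`, `public_inclusive`, `public_exclusive_control`,
#'   `public_exclusive_case`).
#' @export
classify_publicness <- function(pooled, min_count = 1) {
  groups <- unique(pooled$group)
  if (!all(c("control", "case") %in% groups)) {
    abort("both groups (control, case) are required to define inclusiveness",
          class = "tcrshare_design_error")
  }
  pres <- pooled |>
    group_by(.data$subject_id, .data$group, .data$junction_aa) |>
    summarise(copies = sum(.data$duplicate_count), .groups = "drop") |>
    filter(.data$copies >= min_count)
  out <- pres |>
    group_by(.data$junction_aa) |>
    summarise(
      n_control_subjects = n_distinct(.data$subject_id[.data$group == "control"]),
      n_case_subjects = n_distinct(.data$subject_id[.data$group == "case"]),
      .groups = "drop"
    ) |>
    mutate(
      n_subjects_total = .data$n_control_subjects + .data$n_case_subjects,
      label = case_when(
        .data$n_subjects_total == 1L ~ "private",
        .data$n_control_subjects >= 1L & .data$n_case_subjects >= 1L ~
          "public_inclusive",
        .data$n_case_subjects >= 2L ~ "public_exclusive_case",
        TRUE ~ "public_exclusive_control"
      )
    )
  class(out) <- c("tcr_publicness", class(out))
  out
}

PUBLICNESS_LABELS <- c("private", "public_inclusive",
                       "public_exclusive_control", "public_exclusive_case")

#' Per-subject publicness fractions
#'
#' For each subject, the share of its repertoire in each publicness category.
#' With `weighting = "unique"` every amino-acid clone counts once; with
#' `"total_reads"` clones are weighted by copy number. Fractions sum to 1 per
#' subject.
#'
#' @param pooled Per-subject pooled repertoire tibble (as passed to
#'   [classify_publicness()]).
#' @param records Publicness records; computed from `pooled` when `NULL`.
#' @param weighting `"unique"` (default) or `"total_reads"`.
#' @return A tibble of class `tcr_publicness_fractions`: `subject_id`,
#'   `group`, `label`, `fraction`.
#' @export
publicness_fractions <- function(pooled, records = NULL,
                                 weighting = c("unique", "total_reads")) {
  weighting <- match.arg(weighting)
  if (is.null(records)) records <- classify_publicness(pooled)
  lab <- stats::setNames(records$label, records$junction_aa)
  if (!all(pooled$junction_aa %in% names(lab))) {
    abort("publicness records do not cover all amino-acid clones",
          class = "tcrshare_internal_error")
  }
  per_aa <- pooled |>
    group_by(.data$subject_id, .data$group, .data$junction_aa) |>
    summarise(copies = sum(.data$duplicate_count), .groups = "drop") |>
    mutate(
      label = unname(lab[.data$junction_aa]),
      w = if (weighting == "unique") 1 else .data$copies
    )
  frac <- per_aa |>
    group_by(.data$subject_id, .data$group) |>
    mutate(total_w = sum(.data$w)) |>
    group_by(.data$subject_id, .data$group, .data$label) |>
    summarise(fraction = sum(.data$w) / .data$total_w[1], .groups = "drop")
  out <- per_aa |>
    distinct(.data$subject_id, .data$group) |>
    tidyr::crossing(label = PUBLICNESS_LABELS) |>
    left_join(frac, by = c("subject_id", "group", "label")) |>
    mutate(fraction = tidyr::replace_na(.data$fraction, 0)) |>
    arrange(.data$subject_id, match(.data$label, PUBLICNESS_LABELS))
  class(out) <- c("tcr_publicness_fractions", class(out))
  out
}

#' Convergent-recombination level of each amino-acid clone
#'
#' The CR level of an amino-acid CDR3 is the number of distinct nucleotide
#' junctions encoding it within the given scope (a sample, a subject pool, or
#' a whole group pool). Summed over amino acids, CR levels equal the number
#' of distinct nucleotide junctions in scope.
#'
#' @param x A repertoire tibble (any scope).
#' @return A tibble: `junction_aa`, `cr_level`, `nt_set` (list-column of the
#'   distinct nucleotide junctions).
#' @export
cr_levels <- function(x) {
  if (any(is.na(x$junction) | x$junction == "")) {
    abort("junction (nucleotide) required for CR levels",
          class = "tcrshare_data_error")
  }
  x |>
    distinct(.data$junction_aa, .data$junction) |>
    group_by(.data$junction_aa) |>
    summarise(cr_level = n(), nt_set = list(sort(.data$junction)),
              .groups = "drop")
}

#' Association between convergent recombination and public sharing
#'
#' For each group, each amino-acid clone contributes a point (CR level
#' computed over the group's pooled clones, sharing level = number of the
#' group's subjects carrying it); points are averaged to mean sharing per CR
#' level. Nested Gaussian GLMs — `sharing ~ cr` versus
#' `sharing ~ cr + group + cr:group` — are compared by a likelihood-ratio
#' test ([lmtest::lrtest()]), asking whether the sharing-vs-CR curve differs
#' between groups.
#'
#' @param pooled Per-subject pooled repertoire tibble with both groups.
#' @return Object of class `cr_assoc`: list with `points` (per group x
#'   CR-level mean sharing), `fit0`, `fit1`, `lr` (tibble: statistic, df,
#'   p.value).
#' @export
cr_publicness_association <- function(pooled) {
  if (length(unique(pooled$group)) < 2) {
    abort("both groups required", class = "tcrshare_design_error")
  }
  per_group <- pooled |>
    group_by(.data$group) |>
    group_modify(function(df, key) {
      cr <- cr_levels(df)
      sharing <- df |>
        group_by(.data$junction_aa) |>
        summarise(sharing = n_distinct(.data$subject_id), .groups = "drop")
      left_join(cr, sharing, by = "junction_aa") |>
        select("junction_aa", "cr_level", "sharing")
    }) |>
    ungroup()
  points <- per_group |>
    group_by(.data$group, .data$cr_level) |>
    summarise(mean_sharing = mean(.data$sharing), n_aa = n(), .groups = "drop")
  fit0 <- stats::glm(mean_sharing ~ cr_level, data = points,
                     family = stats::gaussian())
  fit1 <- stats::glm(mean_sharing ~ cr_level * group, data = points,
                     family = stats::gaussian())
  lr <- lmtest::lrtest(fit0, fit1)
  out <- list(
    points = points, fit0 = fit0, fit1 = fit1,
    lr = tibble(statistic = lr$Chisq[2], df = lr$Df[2],
                p.value = lr$`Pr(>Chisq)`[2])
  )
  class(out) <- "cr_assoc"
  out
}

#' @export
print.cr_assoc <- function(x, ...) {
  cat("<cr_assoc> sharing ~ CR level, group comparison\n")
  cat(sprintf("  LR = %.3f, df = %d, p = %.3g\n",
              x$lr$statistic, x$lr$df, x$lr$p.value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname cr_publicness_association
#' @param x A `cr_assoc` object.
#' @param ... Unused.
#' @export
tidy.cr_assoc <- function(x, ...) x$points

#' @rdname cr_publicness_association
#' @export
glance.cr_assoc <- function(x, ...) x$lr

#' Morisita-Horn overlap between two samples
#'
#' Abundance-weighted community overlap in `[0, 1]`:
#' `2 * sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)` over the
#' clone union, with `X`, `Y` the total counts. 1 for identical relative
#' abundances, 0 for disjoint clone sets.
#'
#' @param a,b Named count vectors (names are clone identities), or
#'   single-sample repertoire tibbles (counts aggregated by `junction_aa`).
#' @return A number in `[0, 1]`.
#' @export
morisita_overlap <- function(a, b) {
  a <- as_named_counts(a); b <- as_named_counts(b)
  if (sum(a) == 0 || sum(b) == 0) {
    abort("overlap undefined for an empty sample",
          class = "tcrshare_empty_error")
  }
  u <- union(names(a), names(b))
  x <- stats::setNames(rep(0, length(u)), u); x[names(a)] <- a
  y <- stats::setNames(rep(0, length(u)), u); y[names(b)] <- b
  d <- vegan::vegdist(rbind(x, y), method = "horn")
  unname(1 - as.numeric(d))
}

as_named_counts <- function(x) {
  if (is.data.frame(x)) {
    agg <- x |>
      group_by(.data$junction_aa) |>
      summarise(n = sum(.data$duplicate_count), .groups = "drop")
    stats::setNames(agg$n, agg$junction_aa)
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' Mean pairwise overlap between group-epoch combinations
#'
#' Timepoint samples are binned into young/old epochs by the study design;
#' Morisita-Horn overlap is computed for every pair of samples, and pairs are
#' averaged within each unordered combination of `group:epoch` cells
#' (self-pairs excluded).
#'
#' @param x A repertoire tibble with `timepoint` set (one chain).
#' @param design A [study_design()].
#' @return Object of class `tcr_overlap_matrix`: list with `matrix`
#'   (symmetric mean-overlap matrix over the four cells) and `pairs` (tibble
#'   of all pairwise overlaps).
#' @export
grouped_overlap_matrix <- function(x, design = study_design()) {
  x <- mutate(x, epoch = epoch_of(.data$timepoint, design))
  x <- filter(x, !is.na(.data$epoch))
  cells <- x |>
    distinct(.data$sample_id, .data$group, .data$epoch) |>
    mutate(cell = paste(.data$group, .data$epoch, sep = ":"))
  if (any(table(cells$cell) < 1)) warn("a group-epoch cell has no samples")
  counts <- split(x, x$sample_id) |>
    lapply(as_named_counts)
  ids <- cells$sample_id
  pairs <- tidyr::expand_grid(i = seq_along(ids), j = seq_along(ids)) |>
    filter(.data$i < .data$j) |>
    mutate(
      sample_a = ids[.data$i], sample_b = ids[.data$j],
      cell_a = cells$cell[.data$i], cell_b = cells$cell[.data$j],
      overlap = purrr::map2_dbl(.data$sample_a, .data$sample_b,
                                ~ morisita_overlap(counts[[.x]], counts[[.y]]))
    ) |>
    select(-"i", -"j")
  lv <- sort(unique(cells$cell))
  m <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    sel <- (pairs$cell_a == lv[i] & pairs$cell_b == lv[j]) |
      (pairs$cell_a == lv[j] & pairs$cell_b == lv[i])
    if (any(sel)) m[i, j] <- mean(pairs$overlap[sel])
  }
  structure(list(matrix = m, pairs = pairs), class = "tcr_overlap_matrix")
}

#' Repertoire summary statistics
#'
#' Per sample: unique amino-acid clones, Shannon diversity (nats) over clone
#' read frequencies, clonality (1 minus Pielou evenness; 0 for a single
#' clone), and the CDR3 amino-acid length distribution.
#'
#' @param x A repertoire tibble.
#' @return A tibble with one row per sample: `sample_id`, `unique_clones`,
#'   `shannon_diversity`, `clonality`, `cdr3_length_histogram` (list-column
#'   of length/count tibbles).
#' @export
repertoire_summary <- function(x) {
  stopifnot(nrow(x) > 0)
  x |>
    group_by(.data$sample_id) |>
    group_modify(function(df, key) {
      agg <- df |>
        group_by(.data$junction_aa) |>
        summarise(n = sum(.data$duplicate_count), .groups = "drop")
      p <- agg$n / sum(agg$n)
      h <- -sum(p * log(p))
      k <- nrow(agg)
      tibble(
        unique_clones = k,
        shannon_diversity = h,
        clonality = if (k > 1) 1 - h / log(k) else 0,
        cdr3_length_histogram = list(
          count(agg, length = nchar(.data$junction_aa), name = "count"))
      )
    }) |>
    ungroup()
}

#' Welch two-sample t-test
#'
#' Two-sided, unequal-variance. When both groups have zero variance, p is 1
#' if the means are equal (no evidence of difference) and 0 otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A tibble: `statistic`, `df`, `p.value`.
#' @export
welch_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble(statistic = if (same) 0 else Inf * sign(mean(a) - mean(b)),
                  df = NA_real_, p.value = if (same) 1 else 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param a,b Numeric vectors.
#' @return A tibble: `statistic` (D, the sup distance between empirical
#'   CDFs) and `p.value`.
#' @export
ks_compare <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  kt <- suppressWarnings(stats::ks.test(a, b))
  tibble(statistic = unname(kt$statistic), p.value = kt$p.value)
}
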