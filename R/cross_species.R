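#' Presence quantifier for cross-species set construction
#'
#' @param min_mouse_samples Minimum number of mouse samples an amino-acid
#'   clone must appear in (default 1).
#' @param require_all_mouse_timepoints Require presence at every mouse
#'   timepoint (default `FALSE`).
#' @param human_requirement `"all"` (present in every human dataset, the
#'   default) or `"any"`.
#' @return A `cross_quantifier` list.
#' @export
cross_quantifier <- function(min_mouse_samples = 1,
                             require_all_mouse_timepoints = FALSE,
                             human_requirement = c("all", "any")) {
  structure(list(
    min_mouse_samples = as.integer(min_mouse_samples),
    require_all_mouse_timepoints = isTRUE(require_all_mouse_timepoints),
    human_requirement = match.arg(human_requirement)
  ), class = "cross_quantifier")
}

#' Build the cross-species clone set
#'
#' Amino-acid CDR3 sequences present in the mouse data (per the quantifier:
#' a minimum number of samples, optionally every timepoint) and in the human
#' datasets (all of them, or any). Provenance flags per dataset are returned
#' alongside the member set.
#'
#' @param mouse Mouse repertoire tibble (one chain).
#' @param humans Named list of human repertoire tibbles (one per dataset).
#' @param quantifier A [cross_quantifier()].
#' @return Object of class `cross_species_set`: list with `members`
#'   (character vector), `provenance` (tibble of per-dataset presence flags
#'   for every candidate), and `quantifier`.
#' @export
build_cross_species_set <- function(mouse, humans,
                                    quantifier = cross_quantifier()) {
  stopifnot(nrow(mouse) > 0, length(humans) >= 1)
  if (is.null(names(humans)) || any(names(humans) == "")) {
    abort("human datasets must be named", class = "tcrshare_config_error")
  }
  mouse_pres <- mouse |>
    group_by(.data$junction_aa) |>
    summarise(
      n_mouse_samples = n_distinct(.data$sample_id),
      n_mouse_timepoints = n_distinct(.data$timepoint[!is.na(.data$timepoint)]),
      .groups = "drop"
    )
  n_tp <- length(unique(mouse$timepoint[!is.na(mouse$timepoint)]))
  prov <- mouse_pres
  for (d in names(humans)) {
    prov[[paste0("in_", d)]] <- prov$junction_aa %in% humans[[d]]$junction_aa
  }
  human_flags <- as.matrix(prov[paste0("in_", names(humans))])
  human_ok <- if (quantifier$human_requirement == "all") {
    rowSums(human_flags) == length(humans)
  } else {
    rowSums(human_flags) >= 1
  }
  mouse_ok <- prov$n_mouse_samples >= quantifier$min_mouse_samples
  if (quantifier$require_all_mouse_timepoints) {
    mouse_ok <- mouse_ok & prov$n_mouse_timepoints == n_tp
  }
  structure(list(
    members = sort(prov$junction_aa[mouse_ok & human_ok]),
    provenance = prov,
    quantifier = quantifier
  ), class = "cross_species_set")
}

#' @export
print.cross_species_set <- function(x, ...) {
  cat("<cross_species_set>", length(x$members), "members\n")
  invisible(x)
}

#' Tumor-associated clone filter
#'
#' Keeps amino-acid clones present in at least one tumor-tissue sample and in
#' no normal-tissue sample.
#'
#' @param tumor,normal Repertoire tibbles of tumor and matched normal
#'   samples. An empty `normal` degenerates to tumor presence (warning).
#' @return Character vector of tumor-associated amino-acid sequences.
#' @export
tumor_associated_filter <- function(tumor, normal) {
  stopifnot(nrow(tumor) > 0)
  if (is.null(normal) || nrow(normal) == 0) {
    warn("no normal samples given; filter degenerates to tumor presence")
    return(sort(unique(tumor$junction_aa)))
  }
  sort(setdiff(unique(tumor$junction_aa), unique(normal$junction_aa)))
}

#' Rank clones by copy number
#'
#' Amino-acid clones are ranked by descending total copy number within the
#' sample: the most abundant clone is rank 1. Ties are broken by
#' lexicographic order of the amino-acid sequence, so the ranks are a dense
#' deterministic permutation `1..k`.
#'
#' @param x A single-sample repertoire tibble (counts aggregated by
#'   `junction_aa`), or a named count vector.
#' @return A tibble: `junction_aa`, `copies`, `rank`.
#' @export
rank_clones <- function(x) {
  cnt <- as_named_counts(x)
  stopifnot(length(cnt) > 0)
  ord <- order(-cnt, names(cnt))
  tibble(junction_aa = names(cnt)[ord], copies = unname(cnt[ord]),
         rank = seq_along(cnt))
}

#' Cross-species rank-area metric
#'
#' `1 / (rank_mouse * rank_human)`: the area a shared clone occupies is the
#' reciprocal of the product of its copy-number ranks in the two species, so
#' a clone ranked first in both has area 1 and a clone ranked last in both
#' (258th of 258, say) has area ~0.000015.
#'
#' @param rank_mouse,rank_human Integer ranks, both >= 1 (vectorized).
#' @return Numeric areas in `(0, 1]`.
#' @export
cross_rank_area <- function(rank_mouse, rank_human) {
  if (any(rank_mouse < 1) || any(rank_human < 1)) {
    abort("ranks must be >= 1", class = "tcrshare_domain_error")
  }
  1 / (rank_mouse * rank_human)
}

#' Rank-area profile of a cross-species set over mouse timepoints
#'
#' For each mouse timepoint, the member clones are ranked by abundance in the
#' pooled timepoint sample and in the human reference sample; each member's
#' area is `1/(rank_mouse * rank_human)` and its share is the area normalized
#' over members within the timepoint (the stacked-bar data).
#'
#' @param members Character vector of member amino-acid sequences (present in
#'   every timepoint pool and in the human reference, by construction).
#' @param mouse Repertoire tibble with `timepoint` set.
#' @param human_ref A human reference repertoire tibble.
#' @return A tibble of class `tcr_rank_area`: `timepoint`, `junction_aa`,
#'   `rank_mouse`, `rank_human`, `area`, `share`.
#' @export
rank_area_profile <- function(members, mouse, human_ref) {
  stopifnot(length(members) > 0)
  hcnt <- as_named_counts(human_ref)
  hcnt <- hcnt[names(hcnt) %in% members]
  missing_h <- setdiff(members, names(hcnt))
  if (length(missing_h) > 0) {
    abort(paste0("member absent from human reference: ", missing_h[1]),
          class = "tcrshare_coverage_error")
  }
  hr <- rank_clones(hcnt)
  hrank <- stats::setNames(hr$rank, hr$junction_aa)
  out <- mouse |>
    filter(!is.na(.data$timepoint)) |>
    group_by(timepoint = .data$timepoint) |>
    group_modify(function(df, key) {
      cnt <- as_named_counts(df)
      cnt <- cnt[names(cnt) %in% members]
      missing_m <- setdiff(members, names(cnt))
      if (length(missing_m) > 0) {
        abort(paste0("member absent at timepoint ", key$timepoint, ": ",
                     missing_m[1]),
              class = "tcrshare_coverage_error")
      }
      mr <- rank_clones(cnt)
      res <- tibble(
        junction_aa = mr$junction_aa,
        rank_mouse = mr$rank,
        rank_human = unname(hrank[mr$junction_aa])
      )
      res$area <- cross_rank_area(res$rank_mouse, res$rank_human)
      res$share <- res$area / sum(res$area)
      res
    }) |>
    ungroup()
  class(out) <- c("tcr_rank_area", class(out))
  out
}

#' Frequency-weighted (Ruzicka) Jaccard overlap
#'
#' `sum_i min(fA_i, fB_i) / sum_i max(fA_i, fB_i)` over the clone union — the
#' standard frequency-aware generalization of the Jaccard index.
#'
#' @param a,b Named non-negative frequency vectors, each with at least one
#'   positive entry.
#' @return A number in `[0, 1]`; 1 for identical vectors, 0 for disjoint
#'   supports.
#' @export
weighted_jaccard <- function(a, b) {
  stopifnot(!is.null(names(a)), !is.null(names(b)),
            all(a >= 0), all(b >= 0))
  if (sum(a) == 0 || sum(b) == 0) {
    abort("weighted Jaccard undefined for an all-zero side",
          class = "tcrshare_empty_error")
  }
  u <- union(names(a), names(b))
  x <- stats::setNames(rep(0, length(u)), u); x[names(a)] <- a
  y <- stats::setNames(rep(0, length(u)), u); y[names(b)] <- b
  sum(pmin(x, y)) / sum(pmax(x, y))
}

#' Overlap of group-exclusive clone sets with human cohorts
#'
#' All mouse and human samples are subsampled to a common read depth; for
#' every mouse-human sample pair, the weighted Jaccard overlap is computed on
#' frequencies restricted to a group-exclusive amino-acid set. Means per
#' (exclusive set, cohort) and Welch comparisons between the two exclusive
#' sets within each cohort are returned.
#'
#' @param mouse Mouse repertoire tibble (per-subject pools are used as the
#'   mouse samples).
#' @param exclusive_sets Named list of character vectors, typically
#'   `list(control = ..., case = ...)`.
#' @param cohorts Named list of human repertoire tibbles.
#' @param subsample_n Common read depth; must not exceed any sample's depth.
#' @param seed Seed for the subsampling.
#' @return List with `pairs` (per-pair overlaps), `summary` (mean overlap per
#'   set x cohort), `tests` (per cohort, Welch comparison of the exclusive
#'   sets' overlap distributions).
#' @export
exclusive_vs_cohort_overlap <- function(mouse, exclusive_sets, cohorts,
                                        subsample_n, seed = 1) {
  stopifnot(length(exclusive_sets) >= 1, length(cohorts) >= 1)
  set.seed(seed)
  mouse_s <- subsample_repertoire(mouse, subsample_n)
  freqs_of <- function(tbl) {
    lapply(split(tbl, tbl$sample_id), function(df) {
      cnt <- as_named_counts(df)
      cnt / sum(cnt)
    })
  }
  mfreq <- freqs_of(mouse_s)
  pairs <- list()
  for (cohort in names(cohorts)) {
    hfreq <- freqs_of(subsample_repertoire(cohorts[[cohort]], subsample_n))
    for (set_name in names(exclusive_sets)) {
      aa_set <- exclusive_sets[[set_name]]
      for (m in names(mfreq)) for (h in names(hfreq)) {
        fm <- mfreq[[m]][names(mfreq[[m]]) %in% aa_set]
        fh <- hfreq[[h]][names(hfreq[[h]]) %in% aa_set]
        ov <- if (length(aa_set) == 0 || sum(fm) == 0 || sum(fh) == 0) 0
              else weighted_jaccard(fm, fh)
        pairs[[length(pairs) + 1L]] <- tibble(
          set = set_name, cohort = cohort, mouse_sample = m,
          human_sample = h, overlap = ov)
      }
    }
  }
  pairs <- bind_rows(pairs)
  summary <- pairs |>
    group_by(.data$set, .data$cohort) |>
    summarise(mean_overlap = mean(.data$overlap), n_pairs = n(),
              .groups = "drop")
  tests <- NULL
  if (length(exclusive_sets) == 2) {
    sn <- names(exclusive_sets)
    tests <- pairs |>
      group_by(.data$cohort) |>
      group_modify(function(df, key) {
        welch_ttest(df$overlap[df$set == sn[1]], df$overlap[df$set == sn[2]])
      }) |>
      ungroup()
  }
  list(pairs = pairs, summary = summary, tests = tests)
}

#' Similarity between a sample and disease stages
#'
#' `(shared clones between sample and stage) /
#' (clones in the sample * total cases of the stage)`, where the stage pool
#' is the union of its cases' amino-acid clones.
#'
#' @param sample A single-sample repertoire tibble or character vector of
#'   amino-acid sequences.
#' @param staged Tibble with columns `stage`, `case_id`, `junction_aa`.
#' @return A tibble of class `tcr_stage_similarity`: `stage`, `shared_count`,
#'   `n_clones_sample`, `n_cases_stage`, `similarity`.
#' @export
stage_similarity <- function(sample, staged) {
  aa <- if (is.character(sample)) unique(sample) else unique(sample$junction_aa)
  stopifnot(length(aa) > 0, nrow(staged) > 0)
  out <- staged |>
    group_by(.data$stage) |>
    summarise(
      shared_count = length(intersect(unique(.data$junction_aa), aa)),
      n_cases_stage = n_distinct(.data$case_id),
      .groups = "drop"
    ) |>
    mutate(
      n_clones_sample = length(aa),
      similarity = .data$shared_count /
        (.data$n_clones_sample * .data$n_cases_stage)
    ) |>
    select("stage", "shared_count", "n_clones_sample", "n_cases_stage",
           "similarity")
  empty <- out$n_cases_stage == 0
  if (any(empty)) {
    warn("stage with zero cases excluded")
    out <- out[!empty, , drop = FALSE]
  }
  class(out) <- c("tcr_stage_similarity", class(out))
  out
}

#' Select highly abundant clones differing between epochs
#'
#' Candidates are amino-acid clones present in at least `min_samples` young
#' samples and at least `min_samples` old samples; among candidates, those
#' whose per-sample copy numbers differ between epochs (two-sided Welch test
#' at `alpha`) are called significant. Copy numbers are taken over every
#' sample of each epoch, zero when absent.
#'
#' @param x A repertoire tibble with `timepoint` set (one chain).
#' @param design A [study_design()].
#' @param min_samples Presence threshold per epoch (default 10).
#' @param alpha Significance level (default 0.05).
#' @return List with `candidates` and `significant` (character vectors) and
#'   `tests` (per-candidate tibble: `junction_aa`, `statistic`, `p.value`).
#' @export
select_highly_abundant <- function(x, design = study_design(),
                                   min_samples = 10, alpha = 0.05) {
  x <- mutate(x, epoch = epoch_of(.data$timepoint, design))
  x <- filter(x, !is.na(.data$epoch))
  n_y <- n_distinct(x$sample_id[x$epoch == "young"])
  n_o <- n_distinct(x$sample_id[x$epoch == "old"])
  if (min_samples > n_y || min_samples > n_o) {
    abort(paste0("min_samples (", min_samples, ") exceeds epoch size (young ",
                 n_y, ", old ", n_o, ")"),
          class = "tcrshare_config_error")
  }
  pres <- x |>
    group_by(.data$junction_aa, .data$epoch) |>
    summarise(n_samples = n_distinct(.data$sample_id), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "epoch", values_from = "n_samples",
                       values_fill = 0L)
  for (col in c("young", "old")) if (!col %in% names(pres)) pres[[col]] <- 0L
  candidates <- sort(pres$junction_aa[pres$young >= min_samples &
                                        pres$old >= min_samples])
  if (length(candidates) == 0) {
    return(list(candidates = character(0), significant = character(0),
                tests = tibble(junction_aa = character(0),
                               statistic = numeric(0), p.value = numeric(0))))
  }
  ids <- x |> distinct(.data$sample_id, .data$epoch)
  counts <- x |>
    filter(.data$junction_aa %in% candidates) |>
    group_by(.data$sample_id, .data$junction_aa) |>
    summarise(copies = sum(.data$duplicate_count), .groups = "drop") |>
    tidyr::complete(sample_id = ids$sample_id, junction_aa = candidates,
                    fill = list(copies = 0L)) |>
    left_join(ids, by = "sample_id")
  tests <- counts |>
    group_by(.data$junction_aa) |>
    group_modify(function(df, key) {
      welch_ttest(df$copies[df$epoch == "young"], df$copies[df$epoch == "old"])
    }) |>
    ungroup() |>
    select("junction_aa", "statistic", "p.value")
  list(
    candidates = candidates,
    significant = sort(tests$junction_aa[tests$p.value < alpha]),
    tests = tests
  )
}

#' Resampling null for a selected clone set's cohort frequency
#'
#' The observed statistic is the mean cohort frequency of the selected
#' amino-acid clones (per clone: summed copies across the cohort divided by
#' total cohort depth). The null resamples `|selected|` clones uniformly
#' without replacement from the candidate set `n_iter` times; the empirical p
#' uses the +1 correction, so it is never exactly zero.
#'
#' @param selected,candidates Character vectors, `selected` a subset size-wise
#'   of `candidates`.
#' @param cohort A repertoire tibble.
#' @param n_iter Null iterations (default 1000).
#' @param seed Seed.
#' @return List with `observed`, `null` (numeric vector of length `n_iter`),
#'   `p.value`.
#' @export
resampling_null <- function(selected, candidates, cohort, n_iter = 1000,
                            seed = 1) {
  if (nrow(cohort) == 0) abort("empty cohort", class = "tcrshare_data_error")
  stopifnot(length(selected) <= length(candidates), length(selected) >= 1)
  set.seed(seed)
  depth <- sum(cohort$duplicate_count)
  per_aa <- cohort |>
    group_by(.data$junction_aa) |>
    summarise(freq = sum(.data$duplicate_count) / depth, .groups = "drop")
  freq_of <- stats::setNames(per_aa$freq, per_aa$junction_aa)
  freq <- function(aa) {
    f <- freq_of[aa]
    f[is.na(f)] <- 0
    mean(f)
  }
  observed <- freq(selected)
  null <- vapply(seq_len(n_iter), function(i) {
    freq(sample(candidates, length(selected)))
  }, numeric(1))
  list(observed = observed, null = null,
       p.value = (1 + sum(null >= observed)) / (n_iter + 1))
}

#' Enumerate CDR3-peptide pairs
#'
#' Cartesian product of a CDR3 list and a peptide list, optionally scored by
#' a pluggable scorer: a function `f(cdr3, peptide)`, a pair score table
#' (columns `cdr3`, `peptide`, `score`), or a per-sequence table (`sequence`,
#' `score`, applied to the CDR3). Duplicated inputs are deduplicated with a
#' warning; missing lookups score `NA`.
#'
#' @param cdr3s,peptides Character vectors.
#' @param scorer Optional scorer (see above).
#' @return A tibble: `cdr3`, `peptide`, and `score` when a scorer is given.
#' @export
enumerate_peptide_pairs <- function(cdr3s, peptides, scorer = NULL) {
  if (anyDuplicated(cdr3s) || anyDuplicated(peptides)) {
    warn("duplicate entries deduplicated")
    cdr3s <- unique(cdr3s); peptides <- unique(peptides)
  }
  out <- tidyr::expand_grid(cdr3 = cdr3s, peptide = peptides)
  if (!is.null(scorer)) {
    if (is.function(scorer)) {
      out$score <- purrr::map2_dbl(out$cdr3, out$peptide, scorer)
    } else if (is.data.frame(scorer) && all(c("cdr3", "peptide", "score") %in%
                                            names(scorer))) {
      out <- left_join(out, select(scorer, "cdr3", "peptide", "score"),
                       by = c("cdr3", "peptide"))
    } else if (is.data.frame(scorer) && all(c("sequence", "score") %in%
                                            names(scorer))) {
      lk <- stats::setNames(scorer$score, scorer$sequence)
      out$score <- unname(lk[out$cdr3])
    } else {
      abort("unrecognized scorer", class = "tcrshare_config_error")
    }
  }
  out
}

#' V/J gene-usage correlation across samples
#'
#' Per sample, the read-weighted usage frequency of each V (or J) gene; genes
#' listed as comma-joined sets share the clone's weight equally. Pearson
#' correlations between gene-usage vectors across samples; genes used in
#' fewer than two samples (or with zero variance) are excluded with a
#' warning.
#'
#' @param x A repertoire tibble with `v_call`/`j_call` annotations.
#' @param gene `"v"` or `"j"`.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
vj_usage_correlation <- function(x, gene = c("v", "j")) {
  gene <- match.arg(gene)
  col <- paste0(gene, "_call")
  long <- x |>
    select(sample_id = "sample_id", call = all_of(col),
           duplicate_count = "duplicate_count") |>
    filter(!is.na(.data$call), .data$call != "") |>
    mutate(genes = strsplit(.data$call, ",", fixed = TRUE),
           w = .data$duplicate_count / lengths(.data$genes)) |>
    tidyr::unnest(cols = "genes") |>
    group_by(.data$sample_id) |>
    mutate(w = .data$w / sum(.data$w)) |>
    group_by(.data$sample_id, .data$genes) |>
    summarise(usage = sum(.data$w), .groups = "drop")
  wide <- tidyr::pivot_wider(long, names_from = "genes",
                             values_from = "usage", values_fill = 0)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample_id
  used_in <- colSums(m > 0)
  drop <- used_in < 2 | apply(m, 2, stats::sd) == 0
  if (any(drop)) {
    warn(paste0("excluding ", sum(drop),
                " gene(s) used in <2 samples or with constant usage"))
    m <- m[, !drop, drop = FALSE]
  }
  stats::cor(m)
}
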