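#' Assemble alpha-beta pairs from per-cell chain calls
#'
#' A cell yields a pair only when it carries exactly one alpha and exactly
#' one beta call. Cells with two or more calls of either chain are dropped as
#' `multichain` (checked first); cells missing a chain are dropped as
#' `incomplete`. Duplicate `(cell_id, chain, junction_aa)` rows are collapsed
#' before counting, with a warning.
#'
#' @param calls Tibble with columns `cell_id`, `chain` (`"alpha"`/`"beta"`),
#'   `junction_aa`.
#' @return List with `pairs` (tibble: `cell_id`, `alpha_aa`, `beta_aa`) and
#'   `dropped` (tibble: `reason`, `count`).
#' @export
assemble_pairs <- function(calls) {
  stopifnot(all(calls$chain %in% c("alpha", "beta")))
  n0 <- nrow(calls)
  calls <- distinct(calls, .data$cell_id, .data$chain, .data$junction_aa)
  if (nrow(calls) < n0) {
    warn(paste0("collapsed ", n0 - nrow(calls), " duplicate chain-call row(s)"))
  }
  per_cell <- calls |>
    group_by(.data$cell_id) |>
    summarise(
      n_alpha = sum(.data$chain == "alpha"),
      n_beta = sum(.data$chain == "beta"),
      alpha_aa = .data$junction_aa[.data$chain == "alpha"][1],
      beta_aa = .data$junction_aa[.data$chain == "beta"][1],
      .groups = "drop"
    ) |>
    mutate(status = case_when(
      .data$n_alpha >= 2 | .data$n_beta >= 2 ~ "multichain",
      .data$n_alpha == 0 | .data$n_beta == 0 ~ "incomplete",
      TRUE ~ "paired"
    ))
  list(
    pairs = per_cell |>
      filter(.data$status == "paired") |>
      select("cell_id", "alpha_aa", "beta_aa"),
    dropped = per_cell |>
      filter(.data$status != "paired") |>
      count(reason = .data$status, name = "count")
  )
}

#' Deduplicate alpha-beta pairs
#'
#' @param pairs Tibble with `alpha_aa`, `beta_aa` (e.g. from
#'   [assemble_pairs()]).
#' @return Tibble of distinct `(alpha_aa, beta_aa)` pairs.
#' @export
unique_pairs <- function(pairs) {
  distinct(as_tibble(pairs), .data$alpha_aa, .data$beta_aa)
}

#' Match alpha-beta pairs against bulk samples
#'
#' A pair is shared with a sample when its alpha chain appears in the
#' sample's alpha repertoire and its beta chain in its beta repertoire
#' (amino-acid level, typically after subsampling). Samples are keyed by
#' `subject_id`; subjects missing a chain are excluded with a warning.
#'
#' @param pairs Tibble of distinct pairs (`alpha_aa`, `beta_aa`).
#' @param alpha,beta Repertoire tibbles of the two chains (e.g. per-subject
#'   pools).
#' @return List with `matches` (tibble: `subject_id`, `group`, `alpha_aa`,
#'   `beta_aa`), `per_sample` (tibble: `subject_id`, `group`,
#'   `n_shared_pairs`), `occurrences` (total pair-sample matches),
#'   `n_unique_shared` (distinct pairs shared with any sample), and `test`
#'   (Welch comparison of per-sample counts, control vs case, when both
#'   groups have >= 2 subjects).
#' @export
match_pairs_to_samples <- function(pairs, alpha, beta) {
  pairs <- unique_pairs(pairs)
  subj_a <- unique(alpha$subject_id)
  subj_b <- unique(beta$subject_id)
  subjects <- intersect(subj_a, subj_b)
  half <- union(setdiff(subj_a, subj_b), setdiff(subj_b, subj_a))
  if (length(half) > 0) {
    warn(paste0("subject(s) missing one chain excluded: ",
                paste(half, collapse = ", ")))
  }
  groups <- bind_rows(alpha, beta) |> distinct(.data$subject_id, .data$group)
  matches <- list()
  for (s in subjects) {
    a_set <- unique(alpha$junction_aa[alpha$subject_id == s])
    b_set <- unique(beta$junction_aa[beta$subject_id == s])
    hit <- pairs$alpha_aa %in% a_set & pairs$beta_aa %in% b_set
    if (any(hit)) {
      matches[[s]] <- mutate(pairs[hit, ], subject_id = s, .before = 1)
    }
  }
  matches <- bind_rows(matches)
  if (nrow(matches) == 0) {
    matches <- tibble(subject_id = character(0), alpha_aa = character(0),
                      beta_aa = character(0))
  }
  matches <- left_join(matches, groups, by = "subject_id")
  per_sample <- tibble(subject_id = subjects) |>
    left_join(count(matches, .data$subject_id, name = "n_shared_pairs"),
              by = "subject_id") |>
    mutate(n_shared_pairs = tidyr::replace_na(.data$n_shared_pairs, 0L)) |>
    left_join(groups, by = "subject_id")
  test <- NULL
  ctl <- per_sample$n_shared_pairs[per_sample$group == "control"]
  cs <- per_sample$n_shared_pairs[per_sample$group == "case"]
  if (length(ctl) >= 2 && length(cs) >= 2) test <- welch_ttest(ctl, cs)
  list(
    matches = matches,
    per_sample = per_sample,
    occurrences = nrow(matches),
    n_unique_shared = nrow(distinct(matches, .data$alpha_aa, .data$beta_aa)),
    test = test
  )
}

#' Partition shared pairs by group occurrence and build their networks
#'
#' Each shared pair lands in exactly one of `control_only`, `case_only` or
#' `both`, by the groups of the samples it matched; each subset is turned
#' into an edit-distance network over pairs (summed-chain distance by
#' default, up to `d_max` differences).
#'
#' @param matches Match tibble from [match_pairs_to_samples()] (`subject_id`,
#'   `group`, `alpha_aa`, `beta_aa`).
#' @param d_max Maximum summed distance for network edges (default 3).
#' @param pair_distance Passed to [build_distance_network()].
#' @return List with `partition` (tibble: `alpha_aa`, `beta_aa`, `subset`)
#'   and `networks` (named list of `tcr_network`, empty subsets yield `NULL`).
#' @export
pair_group_partition <- function(matches, d_max = 3,
                                 pair_distance = "summed_chains") {
  partition <- matches |>
    group_by(.data$alpha_aa, .data$beta_aa) |>
    summarise(
      subset = case_when(
        all(.data$group == "control") ~ "control_only",
        all(.data$group == "case") ~ "case_only",
        TRUE ~ "both"
      ),
      .groups = "drop"
    )
  networks <- lapply(
    stats::setNames(nm = c("control_only", "case_only", "both")),
    function(ss) {
      sub <- filter(partition, .data$subset == ss)
      if (nrow(sub) == 0) return(NULL)
      build_distance_network(sub, d_max = d_max, pair_distance = pair_distance)
    }
  )
  list(partition = partition, networks = networks)
}
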