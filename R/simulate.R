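#' Simulation configuration
#'
#' Bundles the parameters of the synthetic repertoire study: two groups of
#' mice sampled monthly, power-law clone abundances, convergent recombination
#' realized through synonymous nucleotide variants, and planted public clones
#' that are exclusive to one group or inclusive of both.
#'
#' @param n_control,n_case Number of subjects per group (default 5 each).
#' @param timepoints Number of monthly samples per subject (default 8).
#' @param clones_per_subject Unique amino-acid clones per subject pool
#'   (default 500).
#' @param abundance_exponent Zipf exponent of the clone-size power law
#'   (default 1.2; heavy-tailed, as observed in blood repertoires).
#' @param planted_exclusive_case_frac,planted_exclusive_control_frac Fraction
#'   of each subject's clones drawn from the group-exclusive shared pools
#'   (defaults 0.10 and 0.02: the tumor group carries more exclusive publics).
#' @param planted_inclusive_frac Fraction shared across both groups
#'   (default 0.15).
#' @param cr_variants_mean Mean number of distinct synonymous nucleotide
#'   encodings per planted amino-acid clone; variants ~ 1 + Poisson(mean - 1)
#'   (default 1.5).
#' @param old_public_decay Factor by which public clone reads are down-
#'   weighted at old timepoints (5-8), so that young samples overlap more than
#'   old ones (default 2).
#' @param cross_species_frac Fraction of mouse public clones injected into the
#'   synthetic human cohorts with species-disjoint nucleotide encodings
#'   (default 0.25).
#' @param chains Chains to simulate (default both).
#' @param seed Master seed (default 42).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_control = 5, n_case = 5, timepoints = 8,
                       clones_per_subject = 500, abundance_exponent = 1.2,
                       planted_exclusive_case_frac = 0.10,
                       planted_exclusive_control_frac = 0.02,
                       planted_inclusive_frac = 0.15,
                       cr_variants_mean = 1.5,
                       old_public_decay = 2,
                       cross_species_frac = 0.25,
                       chains = c("alpha", "beta"),
                       seed = 42) {
  cfg <- list(
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    timepoints = as.integer(timepoints),
    clones_per_subject = as.integer(clones_per_subject),
    abundance_exponent = abundance_exponent,
    planted_exclusive_case_frac = planted_exclusive_case_frac,
    planted_exclusive_control_frac = planted_exclusive_control_frac,
    planted_inclusive_frac = planted_inclusive_frac,
    cr_variants_mean = cr_variants_mean,
    old_public_decay = old_public_decay,
    cross_species_frac = cross_species_frac,
    chains = match.arg(chains, c("alpha", "beta"), several.ok = TRUE),
    seed = as.integer(seed)
  )
  fr <- cfg$planted_exclusive_case_frac + cfg$planted_exclusive_control_frac +
    cfg$planted_inclusive_frac
  if (fr > 1) {
    abort("planted fractions must sum to at most 1",
          class = "tcrshare_config_error")
  }
  if (cfg$cr_variants_mean < 1) {
    abort("cr_variants_mean must be >= 1", class = "tcrshare_config_error")
  }
  stopifnot(cfg$n_control >= 0, cfg$n_case >= 0, cfg$timepoints >= 1,
            cfg$clones_per_subject >= 1, cfg$abundance_exponent > 0)
  structure(cfg, class = "sim_config")
}

AA20 <- c("A","R","N","D","Q","E","G","H","I","L",
          "K","M","F","P","S","T","W","Y","V","C")

# codon table keyed by amino acid (stop codons excluded)
codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
})

# Random CDR3-like AA sequences: conserved C...F, unique within the call.
random_cdr3_aa <- function(n, min_len = 8, max_len = 16) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(min_len:max_len, 2L * need + 10L, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste0("C", paste(sample(AA20, L - 2L, replace = TRUE), collapse = ""), "F")
    }, character(1))
    out <- unique(c(out, seqs))
  }
  out[seq_len(n)]
}

# One random NT encoding per AA sequence (random synonymous codon per site);
# vectorized over sequences.
encode_nt_batch <- function(aa_vec) {
  if (length(aa_vec) == 0) return(character(0))
  letters_all <- strsplit(aa_vec, "")
  lens <- lengths(letters_all)
  flat <- unlist(letters_all)
  cods <- codons_by_aa[flat]
  n <- lengths(cods)
  base <- cumsum(c(0L, n[-length(n)]))
  pick <- as.integer(ceiling(stats::runif(length(flat)) * n))
  chosen <- unlist(cods, use.names = FALSE)[base + pick]
  grp <- factor(rep(seq_along(aa_vec), lens), levels = seq_along(aa_vec))
  unname(tapply(chosen, grp, paste, collapse = ""))
}

encode_nt <- function(aa) encode_nt_batch(aa)

# k distinct synonymous NT variants of an AA sequence, avoiding `forbid`.
# Few-codon sequences may not admit k distinct encodings; returns what exists.
synonymous_variants <- function(aa, k, forbid = character(0)) {
  out <- character(0)
  for (round in 1:6) {
    cand <- unique(encode_nt_batch(rep(aa, max(4L * k, 8L))))
    out <- unique(c(out, setdiff(cand, forbid)))
    if (length(out) >= k) return(out[seq_len(k)])
  }
  out
}

# Assign each shared AA to a random subject subset. `min_per` per group.
assign_subjects <- function(n_aa, subjects_by_group, min_control, min_case) {
  lapply(seq_len(n_aa), function(i) {
    pick <- function(pool, k_min) {
      if (k_min == 0 && length(pool) == 0) return(character(0))
      k <- sample(k_min:length(pool), 1L)
      if (k == 0) character(0) else sample(pool, k)
    }
    c(pick(subjects_by_group$control, min_control),
      pick(subjects_by_group$case, min_case))
  })
}

#' Simulate the longitudinal mouse study
#'
#' Generates per subject x timepoint x chain repertoire samples with planted
#' ground truth. Group-exclusive public amino-acid clones are planted in at
#' least two subjects of one group and none of the other; inclusive publics in
#' at least one subject of each group; the remainder are subject-private.
#' Each planted clone is realized through one or more synonymous nucleotide
#' encodings (convergent recombination), and clone sizes follow a Zipf power
#' law. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `samples` (repertoire tibble over all subjects,
#'   timepoints and both chains) and `truth` (tibble: `chain`, `junction_aa`,
#'   `label`, `subjects` and `nt_variants` list-columns).
#' @export
simulate_mouse_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  subjects <- list(
    control = if (config$n_control > 0) paste0("C", seq_len(config$n_control)) else character(0),
    case = if (config$n_case > 0) paste0("T", seq_len(config$n_case)) else character(0)
  )
  all_truth <- list()
  all_rows <- list()
  for (chain in config$chains) {
    plan <- plan_chain(config, subjects)
    all_truth[[chain]] <- mutate(plan, chain = chain, .before = 1)
    rows <- realize_chain(plan, config, subjects, chain)
    all_rows[[chain]] <- rows
  }
  samples <- as_repertoire(bind_rows(all_rows))
  list(samples = samples, truth = bind_rows(all_truth))
}

# Decide the AA universe of one chain: labels, subject assignments, NT variants.
plan_chain <- function(config, subjects) {
  cl <- config$clones_per_subject
  n_ctl <- length(subjects$control); n_case <- length(subjects$case)
  n_subj <- n_ctl + n_case
  mean_sub <- function(kmin_c, kmin_t) {
    # expected subjects per AA when subset sizes are uniform on [kmin, n]
    ec <- if (n_ctl > 0) mean(kmin_c:n_ctl) else 0
    et <- if (n_case > 0) mean(kmin_t:n_case) else 0
    ec + et
  }
  n_ec <- if (n_case >= 2 && config$planted_exclusive_case_frac > 0) {
    max(1L, round(config$planted_exclusive_case_frac * cl * n_case /
                    mean(2:n_case)))
  } else 0L
  n_eo <- if (n_ctl >= 2 && config$planted_exclusive_control_frac > 0) {
    max(1L, round(config$planted_exclusive_control_frac * cl * n_ctl /
                    mean(2:n_ctl)))
  } else 0L
  n_inc <- if (n_ctl >= 1 && n_case >= 1 && config$planted_inclusive_frac > 0) {
    max(1L, round(config$planted_inclusive_frac * cl * n_subj /
                    mean_sub(1, 1)))
  } else 0L
  if (n_ec + n_eo + n_inc > cl * max(1L, n_subj)) {
    abort("more planted public clones than clones available",
          class = "tcrshare_config_error")
  }

  assigns_ec <- if (n_ec > 0) {
    assign_subjects(n_ec, list(control = character(0), case = subjects$case), 0, 2)
  } else list()
  assigns_eo <- if (n_eo > 0) {
    assign_subjects(n_eo, list(control = subjects$control, case = character(0)), 2, 0)
  } else list()
  assigns_inc <- if (n_inc > 0) {
    assign_subjects(n_inc, subjects, 1, 1)
  } else list()

  shared_aa <- random_cdr3_aa(n_ec + n_eo + n_inc)
  truth_shared <- tibble(
    junction_aa = shared_aa,
    label = rep(c("exclusive_case", "exclusive_control", "inclusive"),
                c(n_ec, n_eo, n_inc)),
    subjects = c(assigns_ec, assigns_eo, assigns_inc)
  )

  # top up each subject with private AAs to reach clones_per_subject
  assigned_per_subject <- table(factor(unlist(truth_shared$subjects),
                                       levels = unlist(subjects)))
  priv <- list()
  for (s in unlist(subjects)) {
    n_priv <- max(0L, cl - as.integer(assigned_per_subject[[s]]))
    priv[[s]] <- n_priv
  }
  n_priv_total <- sum(unlist(priv))
  priv_aa <- if (n_priv_total > 0) {
    pool <- random_cdr3_aa(n_priv_total + nrow(truth_shared) + 50L)
    setdiff(pool, truth_shared$junction_aa)[seq_len(n_priv_total)]
  } else character(0)
  truth_priv <- tibble(
    junction_aa = priv_aa,
    label = "private",
    subjects = as.list(rep(unlist(subjects), times = unlist(priv)))
  )
  truth <- bind_rows(truth_shared, truth_priv)

  # CR: number of NT encodings per AA ~ 1 + Poisson(mean - 1); encodings are
  # drawn in two big batches (singletons, then multi-variant AAs) for speed
  k <- 1L + stats::rpois(nrow(truth), config$cr_variants_mean - 1)
  nt <- vector("list", nrow(truth))
  ones <- which(k == 1L)
  if (length(ones) > 0) {
    nt[ones] <- as.list(encode_nt_batch(truth$junction_aa[ones]))
  }
  multi <- which(k > 1L)
  if (length(multi) > 0) {
    reps <- pmax(4L * k[multi], 8L)
    cand <- encode_nt_batch(rep(truth$junction_aa[multi], reps))
    by <- split(cand, rep(seq_along(multi), reps))
    nt[multi] <- mapply(function(cands, kk, aa) {
      u <- unique(cands)
      if (length(u) >= kk) u[seq_len(kk)] else synonymous_variants(aa, kk)
    }, by, k[multi], truth$junction_aa[multi], SIMPLIFY = FALSE)
  }
  truth$nt_variants <- nt
  truth
}

# Expand the chain plan into per-sample clone rows.
realize_chain <- function(plan, config, subjects, chain) {
  truth <- plan
  group_of <- c(
    stats::setNames(rep("control", length(subjects$control)), subjects$control),
    stats::setNames(rep("case", length(subjects$case)), subjects$case)
  )
  tp <- seq_len(config$timepoints)
  old_tp <- tp[tp > ceiling(config$timepoints / 2)]
  rows <- list()
  for (s in names(group_of)) {
    carries <- vapply(truth$subjects, function(v) s %in% v, logical(1))
    sub <- truth[carries, , drop = FALSE]
    if (nrow(sub) == 0) next
    nt <- unlist(sub$nt_variants)
    aa <- rep(sub$junction_aa, lengths(sub$nt_variants))
    lab <- rep(sub$label, lengths(sub$nt_variants))
    n_rows <- length(nt)
    # Zipf abundances over a random permutation of the subject's NT clones
    rank_perm <- sample.int(n_rows)
    counts <- pmax(1L, as.integer(round(
      n_rows / rank_perm^config$abundance_exponent)))
    # split counts over timepoints; public clones decay at old timepoints
    w_pub <- rep(1, config$timepoints)
    if (length(old_tp) > 0 && config$old_public_decay != 1) {
      w_pub[old_tp] <- 1 / config$old_public_decay
    }
    split_mat <- vapply(seq_len(n_rows), function(i) {
      w <- if (lab[i] == "private") rep(1, config$timepoints) else w_pub
      as.integer(stats::rmultinom(1, counts[i], prob = w))
    }, integer(config$timepoints))
    if (config$timepoints == 1L) split_mat <- matrix(split_mat, nrow = 1L)
    nz <- which(split_mat > 0L, arr.ind = TRUE)  # rows: (timepoint, clone)
    i_cl <- nz[, 2L]; i_tp <- nz[, 1L]
    rows[[length(rows) + 1L]] <- tibble(
      sample_id = paste0(s, ".", chain, ".tp", i_tp),
      subject_id = s, group = group_of[[s]], timepoint = as.integer(i_tp),
      chain = chain, tissue = "blood",
      junction = nt[i_cl], junction_aa = aa[i_cl],
      v_call = paste0("TRBV", 1L + (i_cl %% 20L)),
      j_call = paste0("TRBJ", 1L + (i_cl %% 2L), "-", 1L + (i_cl %% 7L)),
      duplicate_count = split_mat[nz]
    )
  }
  bind_rows(rows)
}

#' Simulate human cohorts sharing amino-acid clones with the mouse study
#'
#' Injects a fraction of the mouse public amino-acid clones into synthetic
#' human bulk datasets and a staged cohort, using freshly generated nucleotide
#' encodings rejected against the mouse encodings — so shared amino-acid
#' sequences never share a nucleotide origin across species. The staged
#' cohort carries stage labels `i`-`iv` with a sharing gradient enriched at
#' stage i.
#'
#' @param config A [sim_config()].
#' @param mouse Result of [simulate_mouse_study()] (uses its `truth`).
#' @param n_bulk_datasets Number of bulk human datasets (default 3).
#' @param samples_per_dataset Samples per bulk dataset (default 3).
#' @param clones_per_human_sample Background clones per human sample
#'   (default 300).
#' @param cases_per_stage Cases per stage in the staged cohort (default 5).
#' @param stage_share_prob Per-stage probability that a case carries an
#'   injected clone; default `c(i = .4, ii = .3, iii = .2, iv = .1)` (a
#'   fourfold stage-i over stage-iv gradient).
#' @param seed Seed (default `config$seed + 1`).
#' @return List with `bulk` (named list of repertoire tibbles), `staged`
#'   (tibble: `stage`, `case_id`, `junction_aa`), `scores` (list of `pgen` and
#'   `binding` score tibbles), and `truth_cross` (tibble: `junction_aa`,
#'   `mouse_nt`, `human_nt` list-columns; the sets are disjoint).
#' @export
simulate_human_cohorts <- function(config, mouse,
                                   n_bulk_datasets = 3,
                                   samples_per_dataset = 3,
                                   clones_per_human_sample = 300,
                                   cases_per_stage = 5,
                                   stage_share_prob = c(i = 0.4, ii = 0.3,
                                                        iii = 0.2, iv = 0.1),
                                   seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(mouse$truth)) {
    abort("mouse truth manifest required", class = "tcrshare_dependency_error")
  }
  set.seed(seed)
  truth_b <- filter(mouse$truth, .data$chain == "beta")
  publics <- filter(truth_b, .data$label != "private")
  n_cross <- round(config$cross_species_frac * nrow(publics))
  cross <- if (n_cross > 0) slice_sample(publics, n = n_cross) else publics[0, ]

  truth_cross <- tibble(
    junction_aa = cross$junction_aa,
    mouse_nt = cross$nt_variants,
    human_nt = purrr::map2(cross$junction_aa, cross$nt_variants, function(aa, forbid) {
      k <- 1L + stats::rpois(1, config$cr_variants_mean - 1)
      synonymous_variants(aa, k, forbid = forbid)
    })
  )
  # drop injected AAs whose codon space is too small for disjoint encodings
  ok <- lengths(truth_cross$human_nt) > 0
  truth_cross <- truth_cross[ok, , drop = FALSE]

  human_nt_of <- stats::setNames(truth_cross$human_nt, truth_cross$junction_aa)

  make_sample <- function(ds, sm, injected_aa) {
    bg_aa <- random_cdr3_aa(clones_per_human_sample)
    bg_aa <- setdiff(bg_aa, c(truth_b$junction_aa, injected_aa))
    aa <- c(injected_aa, bg_aa)
    nt <- c(
      vapply(injected_aa, function(a) sample(human_nt_of[[a]], 1L),
             character(1), USE.NAMES = FALSE),
      encode_nt_batch(bg_aa)
    )
    n <- length(aa)
    counts <- pmax(1L, as.integer(round(n / sample.int(n)^config$abundance_exponent)))
    tibble(
      sample_id = paste0(ds, ".", sm), subject_id = paste0(ds, ".", sm),
      group = "human", timepoint = NA_integer_, chain = "beta",
      tissue = "tumor", junction = nt, junction_aa = aa,
      v_call = paste0("TRBV", sample(1:30, n, replace = TRUE)),
      j_call = paste0("TRBJ2-", sample(1:7, n, replace = TRUE)),
      duplicate_count = counts
    )
  }

  bulk <- list()
  for (d in seq_len(n_bulk_datasets)) {
    ds <- paste0("bulk", letters[d])
    smp <- lapply(seq_len(samples_per_dataset), function(sm) {
      # every injected AA present in every bulk sample (presence quantifiers
      # over datasets are then exactly recoverable)
      make_sample(ds, paste0("s", sm), truth_cross$junction_aa)
    })
    bulk[[ds]] <- as_repertoire(bind_rows(smp))
  }

  stages <- names(stage_share_prob)
  staged <- list()
  for (st in stages) {
    for (cs in seq_len(cases_per_stage)) {
      carry <- truth_cross$junction_aa[
        stats::runif(nrow(truth_cross)) < stage_share_prob[[st]]]
      bg <- setdiff(random_cdr3_aa(clones_per_human_sample), truth_b$junction_aa)
      staged[[length(staged) + 1L]] <- tibble(
        stage = st, case_id = paste0("tcga.", st, ".", cs),
        junction_aa = c(carry, bg)
      )
    }
  }
  staged <- bind_rows(staged)

  all_aa <- unique(c(truth_b$junction_aa, staged$junction_aa,
                     unlist(lapply(bulk, function(b) b$junction_aa))))
  scores <- list(
    pgen = tibble(sequence = all_aa,
                  score = 10^stats::runif(length(all_aa), -12, -6)),
    binding = tibble(sequence = all_aa,
                     score = stats::runif(length(all_aa)))
  )
  list(bulk = bulk, staged = staged, scores = scores, truth_cross = truth_cross)
}

#' Simulate a single-cell chain-call table
#'
#' Emits per-cell alpha/beta CDR3 calls. A configurable fraction of cells
#' carry more than one alpha or beta chain (to exercise the multichain
#' filter), and a configurable fraction of clean cells carry a pair whose two
#' chains are both present in a designated mouse sample (a planted match).
#'
#' @param mouse Result of [simulate_mouse_study()].
#' @param n_cells Number of cells (default 100).
#' @param multichain_frac Fraction of cells with an extra chain (default 0.1).
#' @param matched_frac Fraction of cells whose pair is planted into a mouse
#'   sample (default 0.2).
#' @param seed Seed (default 7).
#' @return List with `calls` (tibble: `cell_id`, `chain`, `junction_aa`) and
#'   `truth` (tibble of planted matched cells: `cell_id`, `alpha_aa`,
#'   `beta_aa`, `sample_pair`).
#' @export
simulate_single_cell <- function(mouse, n_cells = 100, multichain_frac = 0.1,
                                 matched_frac = 0.2, seed = 7) {
  set.seed(seed)
  samp <- mouse$samples
  subjects <- unique(samp$subject_id)
  n_match <- round(matched_frac * n_cells)
  n_multi <- round(multichain_frac * n_cells)
  calls <- list(); truth <- list()
  fresh <- random_cdr3_aa(2L * n_cells + 10L)
  fresh <- setdiff(fresh, samp$junction_aa)
  fi <- 1L
  for (i in seq_len(n_cells)) {
    cell <- sprintf("cell%04d", i)
    if (i <= n_match) {
      s <- sample(subjects, 1L)
      a_pool <- samp$junction_aa[samp$subject_id == s & samp$chain == "alpha"]
      b_pool <- samp$junction_aa[samp$subject_id == s & samp$chain == "beta"]
      alpha <- sample(a_pool, 1L); beta <- sample(b_pool, 1L)
      truth[[length(truth) + 1L]] <- tibble(
        cell_id = cell, alpha_aa = alpha, beta_aa = beta, subject_id = s)
    } else {
      alpha <- fresh[fi]; beta <- fresh[fi + 1L]; fi <- fi + 2L
    }
    rows <- tibble(cell_id = cell, chain = c("alpha", "beta"),
                   junction_aa = c(alpha, beta))
    if (i > n_match && i <= n_match + n_multi) {
      extra_chain <- sample(c("alpha", "beta"), 1L)
      rows <- bind_rows(rows, tibble(cell_id = cell, chain = extra_chain,
                                     junction_aa = fresh[fi]))
      fi <- fi + 1L
    }
    calls[[i]] <- rows
  }
  list(calls = bind_rows(calls), truth = bind_rows(truth))
}
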