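#' Pipeline configuration
#'
#' Bundles paths, thresholds and the seed for [run_pipeline()]. When
#' `input_path` is `NULL` the pipeline simulates its inputs from
#' `sim` (a [sim_config()]).
#'
#' @param outdir Output directory for stage TSVs and the JSON summary.
#' @param input_path Optional AIRR TSV of mouse clonotypes; simulated when
#'   `NULL`.
#' @param sim A [sim_config()] used when simulating.
#' @param subsample_frac Fraction of the shallowest pooled subject used as
#'   the common per-chain subsampling depth (default 0.9).
#' @param min_samples,alpha,d_max,n_random,n_iter Stage thresholds (see the
#'   stage functions).
#' @param seed Master seed; every stochastic stage derives from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("tcrshare_run_"),
                            input_path = NULL,
                            sim = sim_config(),
                            subsample_frac = 0.9,
                            min_samples = 3, alpha = 0.05, d_max = 2,
                            n_random = 100, n_iter = 200, seed = 42) {
  stopifnot(alpha >= 0, alpha <= 1, d_max >= 0, n_random >= 1, n_iter >= 1,
            subsample_frac > 0, subsample_frac <= 1)
  structure(list(
    outdir = outdir, input_path = input_path, sim = sim,
    subsample_frac = subsample_frac, min_samples = min_samples,
    alpha = alpha, d_max = d_max, n_random = n_random, n_iter = n_iter,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full analysis chain
#'
#' Load (or simulate) -> pool subjects -> equal-depth subsample ->
#' publicness + convergent recombination + overlap matrix -> cross-species
#' set, rank-area profile, stage similarity, abundant-clone selection with
#' resampling null -> edit-distance networks -> single-cell pair matching ->
#' report. Every stage writes a TSV under `config$outdir` and the run ends
#' with a JSON summary and manifest; a rerun with the same config and seed is
#' bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return The report (named list of stage summaries), invisibly; also
#'   written to `summary.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), class = "tcrshare_pipeline_error")
    })
  }
  out <- function(name) file.path(config$outdir, name)

  # --- load / simulate -------------------------------------------------
  sim <- config$sim
  sim$seed <- config$seed
  sim <- do.call(sim_config, unclass(sim))
  mouse <- stage("load", {
    if (!is.null(config$input_path)) {
      samples <- read_airr(config$input_path)
      list(samples = samples, truth = NULL)
    } else {
      simulate_mouse_study(sim)
    }
  })
  humans <- stage("simulate_human", {
    if (is.null(mouse$truth)) NULL else simulate_human_cohorts(sim, mouse)
  })
  write_airr(mouse$samples, out("mouse_clones.tsv"))
  report$load <- list(
    n_samples = n_distinct(mouse$samples$sample_id),
    n_clones = nrow(mouse$samples),
    total_reads = sum(mouse$samples$duplicate_count)
  )

  # --- pool + subsample ------------------------------------------------
  subsampled <- stage("subsample", {
    res <- list()
    for (ch in unique(mouse$samples$chain)) {
      pooled <- pool_subjects(filter(mouse$samples, .data$chain == ch))
      depth <- floor(min(total_reads(pooled)$total_reads) *
                       config$subsample_frac)
      res[[ch]] <- subsample_repertoire(pooled, depth,
                                        seed = config$seed + 1L)
    }
    res
  })
  report$subsample <- lapply(subsampled, function(s)
    list(depth = unique(total_reads(s)$total_reads),
         n_subjects = n_distinct(s$subject_id)))

  # --- publicness + CR -------------------------------------------------
  pub <- stage("publicness", {
    lapply(subsampled, function(s) {
      recs <- classify_publicness(s)
      fr <- publicness_fractions(s, recs)
      list(records = recs, fractions = fr)
    })
  })
  for (ch in names(pub)) {
    readr::write_tsv(select(pub[[ch]]$records, -any_of("nt_set")),
                     out(paste0("publicness_", ch, ".tsv")), progress = FALSE)
    readr::write_tsv(pub[[ch]]$fractions,
                     out(paste0("publicness_fractions_", ch, ".tsv")),
                     progress = FALSE)
  }
  report$publicness <- lapply(pub, function(p) {
    as.list(table(p$records$label))
  })

  cr <- stage("cr", {
    lapply(subsampled, function(s) {
      lv <- cr_levels(s)
      readr::write_tsv(select(lv, -"nt_set"), out("cr_levels.tsv"),
                       progress = FALSE)
      lv
    })
  })
  report$cr <- lapply(cr, function(lv)
    list(n_aa = nrow(lv), mean_cr = mean(lv$cr_level),
         frac_convergent = mean(lv$cr_level > 1)))
  assoc <- stage("cr_association", {
    lapply(subsampled, cr_publicness_association)
  })
  report$cr_association <- lapply(assoc, function(a) as.list(glance(a)))

  ovl <- stage("overlap", {
    beta_tp <- filter(mouse$samples, .data$chain == "beta")
    grouped_overlap_matrix(beta_tp, study_design(
      young = seq_len(ceiling(sim$timepoints / 2)),
      old = setdiff(seq_len(sim$timepoints),
                    seq_len(ceiling(sim$timepoints / 2)))
    ))
  })
  readr::write_tsv(ovl$pairs, out("overlap_pairs.tsv"), progress = FALSE)
  report$overlap <- list(cells = rownames(ovl$matrix),
                         matrix = as.list(as.data.frame(ovl$matrix)))

  # --- cross-species ---------------------------------------------------
  if (!is.null(humans)) {
    cross <- stage("cross_species", {
      build_cross_species_set(subsampled$beta, humans$bulk,
                              cross_quantifier(human_requirement = "all"))
    })
    readr::write_tsv(cross$provenance, out("cross_species_provenance.tsv"),
                     progress = FALSE)
    report$cross_species <- list(n_members = length(cross$members))

    stage_sim <- stage("stage_similarity", {
      per_subject <- subsampled$beta |>
        group_by(.data$subject_id, .data$group) |>
        group_modify(~ stage_similarity(.x, humans$staged)) |>
        ungroup()
    })
    readr::write_tsv(stage_sim, out("stage_similarity.tsv"), progress = FALSE)
    report$stage_similarity <- stage_sim |>
      group_by(.data$stage) |>
      summarise(mean_similarity = mean(.data$similarity), .groups = "drop") |>
      (\(d) stats::setNames(as.list(d$mean_similarity), d$stage))()

    abundant <- stage("abundant", {
      beta_tp <- filter(mouse$samples, .data$chain == "beta",
                        .data$group == "case")
      design <- study_design(
        young = seq_len(ceiling(sim$timepoints / 2)),
        old = setdiff(seq_len(sim$timepoints),
                      seq_len(ceiling(sim$timepoints / 2))))
      sel <- select_highly_abundant(beta_tp, design,
                                    min_samples = config$min_samples,
                                    alpha = config$alpha)
      nullres <- if (length(sel$significant) >= 1 &&
                     length(sel$candidates) > length(sel$significant)) {
        resampling_null(sel$significant, sel$candidates,
                        bind_rows(humans$bulk), n_iter = config$n_iter,
                        seed = config$seed + 2L)
      } else NULL
      list(sel = sel, null = nullres)
    })
    report$abundant <- list(
      n_candidates = length(abundant$sel$candidates),
      n_significant = length(abundant$sel$significant),
      null_p = if (!is.null(abundant$null)) abundant$null$p.value else NA
    )

    # --- networks ------------------------------------------------------
    net <- stage("networks", {
      pool <- top_n_pool(filter(mouse$samples, .data$chain == "beta",
                                .data$group == "case"), n = 2000)
      focals <- utils::head(cross$members, 2)
      if (length(focals) == 0) focals <- pool[1]
      nb <- neighborhood_vs_random(focals, pool, n_random = config$n_random,
                                   d_max = config$d_max,
                                   seed = config$seed + 3L)
      list(pool_size = length(pool), neighborhoods = nb)
    })
    report$networks <- list(
      pool_size = net$pool_size,
      focal_counts = stats::setNames(as.list(net$neighborhoods$focal$count),
                                     net$neighborhoods$focal$junction_aa),
      baseline_mean = net$neighborhoods$baseline_mean
    )
  }

  # --- single cell -----------------------------------------------------
  if (is.null(config$input_path)) {
    sc <- stage("single_cell", {
      scd <- simulate_single_cell(mouse, seed = config$seed + 4L)
      asm <- assemble_pairs(scd$calls)
      mt <- match_pairs_to_samples(unique_pairs(asm$pairs),
                                   subsampled$alpha, subsampled$beta)
      part <- pair_group_partition(mt$matches, d_max = 3)
      list(asm = asm, matches = mt, partition = part)
    })
    readr::write_tsv(sc$matches$per_sample, out("sc_shared_pairs.tsv"),
                     progress = FALSE)
    report$single_cell <- list(
      n_pairs = nrow(sc$asm$pairs),
      dropped = stats::setNames(as.list(sc$asm$dropped$count),
                                sc$asm$dropped$reason),
      occurrences = sc$matches$occurrences,
      n_unique_shared = sc$matches$n_unique_shared,
      subset_sizes = lapply(sc$partition$networks,
                            function(n) if (is.null(n)) 0 else length(n$nodes))
    )
  }

  manifest <- list(seed = config$seed,
                   simulated = is.null(config$input_path),
                   parameters = unclass(config)[c("subsample_frac",
                                                  "min_samples", "alpha",
                                                  "d_max", "n_random",
                                                  "n_iter")])
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  jsonlite::write_json(report, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(report)
}
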