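mini_sample <- function(id, aa, counts = NULL, tissue = "tumor",
                        timepoint = NA_integer_) {
  tibble::tibble(
    sample_id = id, subject_id = id, group = "human",
    timepoint = timepoint, chain = "beta", tissue = tissue,
    junction = paste0(id, ".", seq_along(aa)), junction_aa = aa,
    v_call = "", j_call = "",
    duplicate_count = if (is.null(counts)) rep(1L, length(aa))
                      else as.integer(counts)
  )
}

test_that("cross-species set obeys the presence quantifier", {
  mouse <- bind_rows(
    mini_sample("m1", c("AAA", "BBB", "CCC"), timepoint = 1L),
    mini_sample("m2", c("AAA", "BBB"), timepoint = 2L)
  )
  humans <- list(
    d1 = mini_sample("h1", c("AAA", "BBB")),
    d2 = mini_sample("h2", c("AAA", "CCC"))
  )
  all_q <- build_cross_species_set(mouse, humans, cross_quantifier())
  expect_equal(all_q$members, "AAA")                    # in every dataset
  any_q <- build_cross_species_set(
    mouse, humans, cross_quantifier(human_requirement = "any"))
  expect_setequal(any_q$members, c("AAA", "BBB", "CCC"))
  tp_q <- build_cross_species_set(
    mouse, humans,
    cross_quantifier(require_all_mouse_timepoints = TRUE,
                     human_requirement = "any"))
  expect_setequal(tp_q$members, c("AAA", "BBB"))        # CCC only at tp 1
  # monotone: relaxing the quantifier never removes members
  expect_true(all(all_q$members %in% any_q$members))
  expect_true(all(tp_q$members %in% any_q$members))
  expect_error(build_cross_species_set(mouse, unname(humans)),
               class = "tcrshare_config_error")
})

test_that("cross-species membership equals a nested-loop oracle", {
  set.seed(41)
  for (rep in 1:10) {
    aa_pool <- paste0("AA", 1:30)
    mouse <- bind_rows(lapply(1:4, function(i) {
      mini_sample(paste0("m", i), sample(aa_pool, 10), timepoint = i)
    }))
    humans <- lapply(setNames(nm = c("d1", "d2", "d3")), function(d) {
      mini_sample(d, sample(aa_pool, 12))
    })
    got <- build_cross_species_set(mouse, humans,
                                   cross_quantifier(min_mouse_samples = 2))
    want <- character(0)
    for (aa in aa_pool) {
      n_m <- sum(vapply(split(mouse$junction_aa, mouse$sample_id),
                        function(v) aa %in% v, logical(1)))
      in_all <- all(vapply(humans, function(h) aa %in% h$junction_aa,
                           logical(1)))
      if (n_m >= 2 && in_all) want <- c(want, aa)
    }
    expect_setequal(got$members, want)
  }
})

test_that("tumor-associated filter keeps tumor-only clones", {
  tumor <- mini_sample("t1", c("AAA", "BBB"), tissue = "tumor")
  normal <- mini_sample("n1", c("BBB", "CCC"), tissue = "normal")
  expect_equal(tumor_associated_filter(tumor, normal), "AAA")
  expect_warning(all_t <- tumor_associated_filter(tumor, NULL),
                 "degenerates")
  expect_setequal(all_t, c("AAA", "BBB"))
})

test_that("clone ranking is dense with lexicographic tie-break", {
  r <- rank_clones(c(a = 10, b = 5, c = 1))
  expect_equal(setNames(r$rank, r$junction_aa), c(a = 1, b = 2, c = 3))
  tied <- rank_clones(c(b = 5, a = 5))
  expect_equal(setNames(tied$rank, tied$junction_aa), c(a = 1, b = 2))
  set.seed(42)
  for (i in 1:20) {
    cnt <- setNames(sample(1:50, 15, TRUE), paste0("s", sample(100, 15)))
    r <- rank_clones(cnt)
    ord <- order(-cnt, names(cnt))
    expect_equal(r$junction_aa, names(cnt)[ord])
    expect_equal(r$rank, 1:15)
  }
})

test_that("rank-area metric is the reciprocal rank product", {
  expect_equal(cross_rank_area(1, 1), 1)
  expect_equal(round(cross_rank_area(258, 258), 6), 0.000015)
  expect_equal(cross_rank_area(2, 3), 1 / 6)
  expect_error(cross_rank_area(0, 1), class = "tcrshare_domain_error")
  # strictly decreasing in each argument
  expect_true(all(diff(cross_rank_area(1:10, 5)) < 0))
  expect_true(all(diff(cross_rank_area(5, 1:10)) < 0))
})

test_that("rank-area profile normalizes shares per timepoint", {
  members <- c("AAA", "BBB")
  mouse <- bind_rows(
    mini_sample("m.tp1", c("AAA", "BBB", "XXX"), c(10, 5, 1), timepoint = 1L),
    mini_sample("m.tp2", c("AAA", "BBB", "YYY"), c(2, 8, 1), timepoint = 2L)
  )
  human <- mini_sample("h", c("AAA", "BBB", "ZZZ"), c(7, 3, 1))
  prof <- rank_area_profile(members, mouse, human)
  sums <- tapply(prof$share, prof$timepoint, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # concordant top clone takes > 0.5 of the stack (1 vs 1/4)
  tp1 <- prof[prof$timepoint == 1, ]
  expect_gt(tp1$share[tp1$junction_aa == "AAA"], 0.5)
  # brute recomputation from rank_clones
  for (tp in 1:2) {
    sm <- mouse[mouse$timepoint == tp, ]
    rm_ <- rank_clones(sm[sm$junction_aa %in% members, ])
    rh <- rank_clones(human[human$junction_aa %in% members, ])
    for (aa in members) {
      want <- 1 / (rm_$rank[rm_$junction_aa == aa] *
                     rh$rank[rh$junction_aa == aa])
      expect_equal(prof$area[prof$timepoint == tp & prof$junction_aa == aa],
                   want)
    }
  }
  expect_error(rank_area_profile(c("AAA", "QQQ"), mouse, human),
               class = "tcrshare_coverage_error")
})

test_that("weighted Jaccard is the min/max ratio over the union", {
  a <- c(a = 0.5, b = 0.5)
  b <- c(a = 0.25, c = 0.75)
  expect_equal(weighted_jaccard(a, b), 0.25 / 1.75)
  expect_equal(weighted_jaccard(a, a), 1)
  expect_equal(weighted_jaccard(a, c(x = 1)), 0)
  expect_error(weighted_jaccard(a, c(x = 0)), class = "tcrshare_empty_error")
  set.seed(43)
  for (i in 1:50) {
    u <- paste0("c", 1:10)
    x <- setNames(runif(10) * rbinom(10, 1, 0.6), u)
    y <- setNames(runif(10) * rbinom(10, 1, 0.6), u)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(weighted_jaccard(x, y), wj_oracle(x, y), tolerance = 1e-12)
    expect_equal(weighted_jaccard(x, y), weighted_jaccard(y, x))
    expect_gte(weighted_jaccard(x, y), 0)
    expect_lte(weighted_jaccard(x, y), 1)
  }
})

test_that("exclusive-set overlap recovers planted cohort enrichment", {
  set.seed(44)
  case_excl <- paste0("CE", 1:10)
  ctl_excl <- paste0("KE", 1:10)
  bg <- function(n) paste0("BG", sample(1e5, n))
  mouse <- bind_rows(lapply(1:4, function(i) {
    mini_sample(paste0("m", i), c(case_excl, bg(30)),
                counts = sample(1:10, 40, TRUE))
  }))
  breast <- bind_rows(lapply(1:3, function(i) {
    mini_sample(paste0("b", i), c(case_excl, bg(30)),
                counts = sample(1:10, 40, TRUE))
  }))
  res <- exclusive_vs_cohort_overlap(
    mouse, list(control = ctl_excl, case = case_excl),
    list(breast = breast), subsample_n = 50, seed = 1)
  m <- res$summary
  expect_gt(m$mean_overlap[m$set == "case"], m$mean_overlap[m$set == "control"])
  expect_true(all(m$mean_overlap[m$set == "control"] == 0))
  expect_lt(res$tests$p.value, 0.05)
})

test_that("stage similarity follows the shared/(clones x cases) formula", {
  samp <- mini_sample("s", paste0("AA", 1:10))
  staged <- tidyr::expand_grid(stage = "i", case_id = paste0("c", 1:5)) |>
    mutate(junction_aa = list(c("AA1", "AA2", "ZZZ"))) |>
    tidyr::unnest(cols = "junction_aa")
  ss <- stage_similarity(samp, staged)
  expect_equal(ss$similarity, 2 / (10 * 5))              # 0.04
  none <- stage_similarity(mini_sample("s", "QQQ"), staged)
  expect_equal(none$similarity, 0)
  # invariant under clone relabeling (only intersections and sizes matter)
  relab <- staged
  relab$junction_aa[relab$junction_aa == "ZZZ"] <- "WWW"
  expect_equal(stage_similarity(samp, relab)$similarity, ss$similarity)
})

test_that("highly abundant selection applies presence and Welch filters", {
  design <- study_design(young = 1:2, old = 3:4)
  mk <- function(aa, tp, counts) {
    bind_rows(lapply(seq_along(tp), function(i) {
      mini_sample(paste0("t", tp[i], ".", i), aa, counts[[i]],
                  timepoint = tp[i])
    }))
  }
  # AA1 in all samples, 5x higher when old; AA2 in young only
  x <- bind_rows(
    mini_sample("y1", c("AA1", "AA2"), c(2, 3), timepoint = 1L),
    mini_sample("y2", c("AA1", "AA2"), c(3, 2), timepoint = 2L),
    mini_sample("o1", "AA1", 14, timepoint = 3L),
    mini_sample("o2", "AA1", 16, timepoint = 4L)
  )
  sel <- select_highly_abundant(x, design, min_samples = 2, alpha = 0.05)
  expect_equal(sel$candidates, "AA1")                   # AA2 absent when old
  expect_equal(sel$significant, "AA1")
  sel0 <- select_highly_abundant(x, design, min_samples = 2, alpha = 0)
  expect_equal(sel0$significant, character(0))
  expect_error(select_highly_abundant(x, design, min_samples = 10),
               class = "tcrshare_config_error")
})

test_that("resampling null is reproducible and detects extreme selections", {
  set.seed(45)
  cohort <- mini_sample("h", paste0("AA", 1:20), counts = 20:1)
  candidates <- paste0("AA", 1:20)
  top <- paste0("AA", 1:3)                               # most frequent
  res <- resampling_null(top, candidates, cohort, n_iter = 200, seed = 9)
  expect_equal(res$p.value, 1 / 201)                     # minimal possible p
  res2 <- resampling_null(top, candidates, cohort, n_iter = 200, seed = 9)
  expect_identical(res$null, res2$null)                  # bit-reproducible
  expect_gte(res$p.value, 1 / 201)
  expect_lte(res$p.value, 1)
  expect_error(resampling_null(top, candidates, cohort[0, ], 10, 1),
               class = "tcrshare_data_error")
})

test_that("peptide-pair enumeration is the Cartesian product", {
  cdr3s <- random_aa_strings(258)
  peptides <- random_aa_strings(300)[1:257]
  pairs <- enumerate_peptide_pairs(cdr3s, peptides)
  expect_equal(nrow(pairs), 66306)                       # 258 x 257
  expect_equal(nrow(enumerate_peptide_pairs("A", "B")), 1)
  expect_equal(nrow(enumerate_peptide_pairs(c("A", "B", "C"),
                                            c("w", "x", "y", "z"))), 12)
  expect_warning(enumerate_peptide_pairs(c("A", "A"), "B"), "duplicate")
  scored <- enumerate_peptide_pairs(
    c("A", "B"), c("x", "y"),
    scorer = tibble::tibble(sequence = c("A", "B"), score = c(0.1, 0.9)))
  expect_equal(scored$score, c(0.1, 0.1, 0.9, 0.9))
  fn <- enumerate_peptide_pairs("AB", "CD",
                                scorer = function(c3, pep) nchar(c3) + nchar(pep))
  expect_equal(fn$score, 4)
})

test_that("V/J usage correlation matches direct Pearson computation", {
  x <- bind_rows(lapply(1:4, function(i) {
    s <- mini_sample(paste0("s", i), paste0("AA", 1:3),
                     counts = c(2 * i, 4 * i, 8))
    s$v_call <- c("TRBV1", "TRBV2", "TRBV3")
    s
  }))
  m <- vj_usage_correlation(x, "v")
  expect_equal(diag(m), setNames(rep(1, 3), colnames(m)))
  expect_equal(m, t(m))
  # TRBV1 and TRBV2 usage proportional across samples -> correlation 1
  expect_equal(m["TRBV1", "TRBV2"], 1, tolerance = 1e-12)
  # direct summation oracle
  usage <- sapply(paste0("TRBV", 1:3), function(g) {
    sapply(paste0("s", 1:4), function(s) {
      rows <- x[x$sample_id == s, ]
      sum(rows$duplicate_count[rows$v_call == g]) / sum(rows$duplicate_count)
    })
  })
  expect_equal(unclass(m), unclass(cor(usage)), tolerance = 1e-12)
  # gene in a single sample is excluded with a warning
  y <- x
  y$v_call[1] <- "TRBV9"
  expect_warning(m2 <- vj_usage_correlation(y, "v"), "excluding")
  expect_false("TRBV9" %in% colnames(m2))
})
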