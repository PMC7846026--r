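make_presence <- function(...) {
  # helper: list of subject -> AA vectors, group from subject prefix (C/T)
  lst <- list(...)
  df <- do.call(rbind, lapply(names(lst), function(s) {
    data.frame(subject_id = s,
               group = if (startsWith(s, "C")) "control" else "case",
               junction_aa = lst[[s]])
  }))
  pooled_from_presence(df)
}

test_that("publicness labels follow the subject-sharing rules", {
  pooled <- make_presence(
    C1 = c("AAA", "BBB", "DDD"), C2 = c("BBB", "EEE"),
    T1 = c("AAA", "CCC"), T2 = c("CCC")
  )
  rec <- classify_publicness(pooled)
  lab <- setNames(rec$label, rec$junction_aa)
  expect_equal(lab[["DDD"]], "private")                  # one subject
  expect_equal(lab[["AAA"]], "public_inclusive")         # C1 and T1
  expect_equal(lab[["BBB"]], "public_exclusive_control") # C1 and C2
  expect_equal(lab[["CCC"]], "public_exclusive_case")    # T1 and T2
  expect_error(classify_publicness(filter(pooled, group == "case")),
               class = "tcrshare_design_error")
})

test_that("publicness equals an exhaustive presence-tally oracle", {
  set.seed(21)
  for (rep in 1:20) {
    subjects <- c(paste0("C", 1:3), paste0("T", 1:3))
    presence <- do.call(rbind, lapply(subjects, function(s) {
      data.frame(subject_id = s,
                 group = if (startsWith(s, "C")) "control" else "case",
                 junction_aa = sample(paste0("AA", 1:50),
                                      sample(5:30, 1)))
    }))
    got <- classify_publicness(pooled_from_presence(presence))
    want <- publicness_oracle(presence)
    m <- merge(as.data.frame(got), want, by = "junction_aa")
    expect_equal(nrow(m), nrow(got))
    expect_equal(m$label.x, m$label.y)
    expect_equal(m$n_control_subjects, m$n_control)
    expect_equal(m$n_case_subjects, m$n_case)
  }
})

test_that("per-subject publicness fractions sum to one under both weightings", {
  set.seed(22)
  presence <- do.call(rbind, lapply(c("C1", "C2", "T1", "T2"), function(s) {
    data.frame(subject_id = s,
               group = if (startsWith(s, "C")) "control" else "case",
               junction_aa = sample(paste0("AA", 1:30), 15))
  }))
  pooled <- pooled_from_presence(presence,
                                 counts = sample(1:20, nrow(presence), TRUE))
  for (w in c("unique", "total_reads")) {
    fr <- publicness_fractions(pooled, weighting = w)
    sums <- tapply(fr$fraction, fr$subject_id, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
  # all-private input puts all mass on "private"
  solo <- make_presence(C1 = c("AAA", "BBB"), T1 = c("CCC"))
  fr <- publicness_fractions(solo)
  expect_equal(fr$fraction[fr$label == "private"], c(1, 1))
  expect_equal(sum(fr$fraction), 2)
})

test_that("CR level counts distinct nucleotide encodings per amino acid", {
  x <- as_repertoire(tibble::tibble(
    sample_id = "s",
    junction = c("TGTGCCAGCAGC", "TGCGCCAGCAGC", "GAAGAG"),
    junction_aa = c("CASS", "CASS", "EE"),
    duplicate_count = c(1L, 2L, 1L)
  ))
  lv <- cr_levels(x)
  expect_equal(lv$cr_level[lv$junction_aa == "CASS"], 2L)
  expect_equal(lv$cr_level[lv$junction_aa == "EE"], 1L)
  # conservation: sum of CR levels = distinct NT count
  expect_equal(sum(lv$cr_level), length(unique(x$junction)))
})

test_that("CR levels match a brute-force dictionary oracle on random pools", {
  for (seed in 1:10) {
    x <- as_repertoire(random_repertoire(250, n_samples = 1, seed = seed))
    lv <- cr_levels(x)
    oracle <- tapply(x$junction, x$junction_aa,
                     function(v) length(unique(v)))
    expect_equal(lv$cr_level, as.vector(oracle[lv$junction_aa]))
    expect_equal(sum(lv$cr_level), length(unique(x$junction)))
  }
})

test_that("CR-sharing association is null for exchangeable groups", {
  set.seed(23)
  # synonymous-rich universe so CR levels vary (codons for A and S only)
  cods <- c("GCT", "GCC", "GCA", "GCG", "AGC", "TCT", "TCC", "AGT")
  nts <- unique(replicate(120, paste(sample(cods, 3, TRUE), collapse = "")))
  half <- tibble::tibble(
    sample_id = "x",
    subject_id = sample(paste0("m", 1:4), length(nts), replace = TRUE),
    group = "control", timepoint = NA_integer_, chain = "beta",
    tissue = "blood", junction = nts,
    junction_aa = unname(vapply(nts, translate_oracle, character(1))),
    v_call = "", j_call = "",
    duplicate_count = sample(1:5, length(nts), replace = TRUE)
  )
  both <- rbind(transform(half, group = "control",
                          subject_id = paste0("C", subject_id)),
                transform(half, group = "case",
                          subject_id = paste0("T", subject_id)))
  both$sample_id <- both$subject_id
  a <- cr_publicness_association(as_repertoire(both))
  expect_gt(length(unique(tidy(a)$cr_level)), 1)
  expect_gt(glance(a)$p.value, 0.99)   # duplicated data: group adds nothing
  expect_lt(glance(a)$statistic, 1e-6)
})

test_that("LR statistic matches hand-computed Gaussian log-likelihoods", {
  pts <- tibble::tibble(
    group = rep(c("control", "case"), each = 3),
    cr_level = rep(1:3, 2),
    mean_sharing = c(1, 1.5, 2.5, 1, 2.2, 4.1)
  )
  fit0 <- stats::glm(mean_sharing ~ cr_level, data = pts)
  fit1 <- stats::glm(mean_sharing ~ cr_level * group, data = pts)
  # Gaussian profile log-likelihood: -n/2 (log(2*pi*RSS/n) + 1)
  ll <- function(fit) {
    rss <- sum(stats::residuals(fit)^2); n <- length(stats::residuals(fit))
    -n / 2 * (log(2 * pi * rss / n) + 1)
  }
  lr_hand <- 2 * (ll(fit1) - ll(fit0))
  got <- lmtest::lrtest(fit0, fit1)
  expect_equal(unname(got$Chisq[2]), lr_hand, tolerance = 1e-8)
})

test_that("Morisita-Horn overlap matches the direct formula", {
  a <- c(x = 2, y = 1)
  b <- c(x = 1, y = 1, z = 1)
  expect_equal(morisita_overlap(a, b), 0.75)   # hand: 6 / 8
  expect_equal(morisita_overlap(a, a), 1)
  expect_equal(morisita_overlap(a, c(q = 3, r = 1)), 0)
  expect_error(morisita_overlap(a, numeric(0)))
  set.seed(24)
  for (i in 1:50) {
    u <- paste0("c", 1:12)
    x <- setNames(sample(0:9, 12, TRUE), u); x <- x[x > 0]
    y <- setNames(sample(0:9, 12, TRUE), u); y <- y[y > 0]
    if (length(x) == 0 || length(y) == 0) next
    expect_equal(morisita_overlap(x, y), mh_oracle(x, y), tolerance = 1e-12)
    expect_equal(morisita_overlap(x, y), morisita_overlap(y, x))
    expect_gte(morisita_overlap(x, y), 0)
    expect_lte(morisita_overlap(x, y), 1 + 1e-12)
  }
})

test_that("grouped overlap matrix averages pairwise overlaps per cell", {
  base <- tibble::tibble(
    junction = paste0("NT", 1:5), junction_aa = paste0("AA", 1:5),
    duplicate_count = c(5L, 4L, 3L, 2L, 1L)
  )
  samples <- bind_rows(lapply(1:8, function(i) {
    mutate(base, sample_id = paste0("s", i),
           subject_id = paste0("m", i),
           group = if (i <= 4) "control" else "case",
           timepoint = if (i %% 2 == 1) 1L else 5L)
  }))
  ov <- grouped_overlap_matrix(as_repertoire(samples), study_design())
  expect_true(all(abs(ov$matrix - 1) < 1e-12))   # identical samples
  expect_equal(nrow(ov$pairs), choose(8, 2))     # no self-pairs
  # each cell equals the brute-force mean over enumerated pairs
  for (i in rownames(ov$matrix)) for (j in colnames(ov$matrix)) {
    sel <- (ov$pairs$cell_a == i & ov$pairs$cell_b == j) |
      (ov$pairs$cell_a == j & ov$pairs$cell_b == i)
    if (any(sel)) expect_equal(ov$matrix[i, j], mean(ov$pairs$overlap[sel]))
  }
  expect_equal(ov$matrix, t(ov$matrix))
})

test_that("repertoire summary computes Shannon diversity and clonality", {
  uni <- as_repertoire(tibble::tibble(
    sample_id = "u", junction = paste0("NT", 1:4),
    junction_aa = paste0("AA", 1:4), duplicate_count = rep(3L, 4)
  ))
  s <- repertoire_summary(uni)
  expect_equal(s$shannon_diversity, log(4), tolerance = 1e-12)
  expect_equal(s$clonality, 0, tolerance = 1e-12)
  solo <- as_repertoire(tibble::tibble(
    sample_id = "v", junction = "NT1", junction_aa = "AAA",
    duplicate_count = 10L))
  s1 <- repertoire_summary(solo)
  expect_equal(s1$shannon_diversity, 0)
  expect_equal(s1$clonality, 0)
  # random sample against direct summation
  x <- as_repertoire(random_repertoire(100, n_samples = 1, seed = 31))
  s2 <- repertoire_summary(x)
  cnt <- tapply(x$duplicate_count, x$junction_aa, sum)
  p <- cnt / sum(cnt)
  expect_equal(s2$shannon_diversity, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(s2$unique_clones, length(cnt))
  hist <- s2$cdr3_length_histogram[[1]]
  expect_equal(sum(hist$count), length(cnt))
})

test_that("Welch test handles separation and degenerate inputs", {
  same <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  sep <- welch_ttest(c(1, 2, 3), c(11, 12, 13))
  expect_lt(sep$p.value, 0.01)
  flat <- welch_ttest(c(2, 2), c(2, 2))
  expect_equal(flat$p.value, 1)
})

test_that("KS comparison matches a brute-force sup over pooled points", {
  expect_equal(ks_compare(1:10, 1:10)$statistic, 0)
  expect_equal(ks_compare(runif(20), runif(20, 2, 3))$statistic, 1)
  set.seed(25)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(25, 0.5)
    pooled <- sort(c(a, b))
    d_brute <- max(abs(ecdf(a)(pooled) - ecdf(b)(pooled)))
    expect_equal(ks_compare(a, b)$statistic, d_brute, tolerance = 1e-12)
  }
})
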