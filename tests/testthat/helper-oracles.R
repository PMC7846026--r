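# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

suppressPackageStartupMessages(library(dplyr))

# Full-matrix dynamic-programming Levenshtein distance.
lev_dp <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                           D[i, j] + (A[i] != B[j]))
  }
  D[n + 1, m + 1]
}

# Second codon-table translation (independent of Biostrings).
codon_table <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G"
)
translate_oracle <- function(nt) {
  if (nchar(nt) %% 3 != 0) return(NA_character_)
  cods <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  aa <- unname(codon_table[cods])
  if (any(aa == "*")) NA_character_ else paste(aa, collapse = "")
}

# Morisita-Horn by direct formula evaluation.
mh_oracle <- function(a, b) {
  u <- union(names(a), names(b))
  x <- setNames(rep(0, length(u)), u); x[names(a)] <- a
  y <- setNames(rep(0, length(u)), u); y[names(b)] <- b
  X <- sum(x); Y <- sum(y)
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

# Weighted Jaccard by direct summation.
wj_oracle <- function(a, b) {
  u <- union(names(a), names(b))
  x <- setNames(rep(0, length(u)), u); x[names(a)] <- a
  y <- setNames(rep(0, length(u)), u); y[names(b)] <- b
  sum(pmin(x, y)) / sum(pmax(x, y))
}

# Exhaustive per-AA presence tally for publicness labels.
publicness_oracle <- function(df) {
  # df: subject_id, group, junction_aa (presence rows)
  out <- list()
  for (aa in unique(df$junction_aa)) {
    rows <- df[df$junction_aa == aa, ]
    nc <- length(unique(rows$subject_id[rows$group == "control"]))
    nt <- length(unique(rows$subject_id[rows$group == "case"]))
    lab <- if (nc + nt == 1) "private"
      else if (nc >= 1 && nt >= 1) "public_inclusive"
      else if (nt >= 2) "public_exclusive_case"
      else "public_exclusive_control"
    out[[aa]] <- data.frame(junction_aa = aa, n_control = nc, n_case = nt,
                            label = lab)
  }
  do.call(rbind, unname(out))
}

# Random repertoire tibble over a small clone universe.
random_repertoire <- function(n_rows = 200, n_samples = 3, n_nt = 40,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  universe <- unique(replicate(n_nt, paste(
    sample(c("GCT","GCC","TGT","TGC","AGC","TCT","GAA","GAG","TTT","TAC"),
           sample(3:6, 1), replace = TRUE), collapse = "")))
  nt <- sample(universe, n_rows, replace = TRUE)
  tibble::tibble(
    sample_id = paste0("s", sample(seq_len(n_samples), n_rows, replace = TRUE)),
    subject_id = "x", group = "control", timepoint = 1L,
    chain = "beta", tissue = "blood",
    junction = nt,
    junction_aa = unname(vapply(nt, translate_oracle, character(1))),
    v_call = "TRBV1", j_call = "TRBJ1-1",
    duplicate_count = sample(1:9, n_rows, replace = TRUE)
  )
}

# Random AA-like strings for distance property tests.
random_aa_strings <- function(n, min_len = 3, max_len = 12) {
  lens <- if (min_len == max_len) rep(min_len, n)
          else sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(LETTERS[1:20], L, replace = TRUE), collapse = "")
  }, character(1))
}

# Small two-group pooled repertoire with known AA->subject placements.
pooled_from_presence <- function(presence, counts = NULL) {
  # presence: data.frame(subject_id, group, junction_aa)
  n <- nrow(presence)
  tibble::tibble(
    sample_id = presence$subject_id,
    subject_id = presence$subject_id,
    group = presence$group,
    timepoint = NA_integer_, chain = "beta", tissue = "blood",
    junction = paste0("NT", seq_len(n)),  # unique NT per row
    junction_aa = presence$junction_aa,
    v_call = "", j_call = "",
    duplicate_count = if (is.null(counts)) rep(1L, n) else counts
  )
}
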