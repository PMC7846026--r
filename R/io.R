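#' Translate a nucleotide junction to amino acids
#'
#' Standard genetic code. A junction translates only when its length is a
#' multiple of three and the frame contains no stop codon; otherwise `NA` is
#' returned (such rearrangements are non-productive and are dropped at load).
#'
#' @param junction_nt Character vector of DNA strings over `A`,`C`,`G`,`T`.
#' @return Character vector of amino-acid strings, `NA` where non-productive.
#' @examples
#' translate_junction("TGTGCCAGCAGC")  # "CASS"
#' translate_junction("TGA")           # NA: stop codon
#' @export
translate_junction <- function(junction_nt) {
  junction_nt <- toupper(as.character(junction_nt))
  bad <- grepl("[^ACGT]", junction_nt)
  if (any(bad)) {
    abort(paste0("junction_nt contains non-ACGT characters: ",
                 paste(utils::head(junction_nt[bad], 3), collapse = ", ")),
          class = "tcrshare_alphabet_error")
  }
  out <- rep(NA_character_, length(junction_nt))
  ok <- nchar(junction_nt) > 0 & nchar(junction_nt) %% 3L == 0L
  if (any(ok)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(junction_nt[ok]),
      no.init.codon = TRUE
    ))
    aa[grepl("*", aa, fixed = TRUE)] <- NA_character_
    out[ok] <- aa
  }
  out
}

#' Read an AIRR Rearrangement-style TSV into a repertoire tibble
#'
#' Expects a tab-separated file with a header and at least the columns
#' `junction`, `junction_aa` and `duplicate_count` (AIRR names); `v_call`,
#' `j_call` and the sample metadata columns (`sample_id`/`repertoire_id`,
#' `subject_id`, `group`, `timepoint`, `chain`, `tissue`) are used when
#' present. Non-productive rows (junction length not a multiple of three, or
#' an in-frame stop) are excluded; the number skipped per reason is attached
#' as the `skip_report` attribute and reported via a message. Rows sharing a
#' nucleotide junction within a sample are merged with summed counts.
#'
#' @param path Path to the TSV file.
#' @param metadata Optional named character vector mapping file column names
#'   to repertoire column names, e.g. `c(repertoire_id = "sample_id")`.
#' @return A repertoire tibble (see [as_repertoire()]).
#' @export
read_airr <- function(path, metadata = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tcrshare_io_error")
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0 && ncol(x) == 0) {
    abort("empty input file", class = "tcrshare_empty_error")
  }
  if (!is.null(metadata)) {
    for (from in names(metadata)) {
      if (from %in% names(x)) names(x)[names(x) == from] <- metadata[[from]]
    }
  }
  if ("repertoire_id" %in% names(x) && !"sample_id" %in% names(x)) {
    x <- rename(x, sample_id = "repertoire_id")
  }
  need <- c("junction", "junction_aa", "duplicate_count")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
          class = "tcrshare_format_error")
  }
  if (nrow(x) == 0) {
    abort("input file has a header but no rows", class = "tcrshare_empty_error")
  }

  # productivity filter on the nucleotide junction
  len_bad <- nchar(x$junction) %% 3L != 0L | nchar(x$junction) == 0L
  aa <- rep(NA_character_, nrow(x))
  aa[!len_bad] <- translate_junction(x$junction[!len_bad])
  stop_bad <- !len_bad & is.na(aa)
  skip <- tibble(
    reason = c("frame_length", "stop_codon"),
    count = c(sum(len_bad), sum(stop_bad))
  )
  keep <- !len_bad & !stop_bad
  if (any(!keep)) {
    inform(paste0("read_airr: skipped ", sum(!keep),
                  " non-productive row(s) (frame: ", sum(len_bad),
                  ", stop: ", sum(stop_bad), ")"))
  }
  x <- x[keep, , drop = FALSE]
  x$junction_aa <- aa[keep]
  out <- as_repertoire(x)
  attr(out, "skip_report") <- skip
  out
}

#' Write a repertoire tibble as an AIRR-style TSV
#'
#' Round-trips with [read_airr()]: clone multisets and metadata (including
#' unknown extra columns) are preserved.
#'
#' @param x A repertoire tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(x, path) {
  if (nrow(x) == 0) warn("writing a repertoire with no clones (header only)")
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Pool all timepoint samples of each subject
#'
#' Combines every sample of a subject (within a chain) into one pooled
#' repertoire: clone counts are summed over timepoints and `timepoint` is set
#' to `NA`. Pooling precedes equal-depth subsampling and publicness analysis.
#'
#' @param x A repertoire tibble covering one or more subjects.
#' @return A repertoire tibble with one sample per `(subject_id, chain)`,
#'   `sample_id` set to `"<subject_id>.<chain>"`.
#' @export
pool_subjects <- function(x) {
  stopifnot(nrow(x) > 0)
  per_subject <- distinct(x, .data$subject_id, .data$chain)
  x |>
    mutate(
      sample_id = paste(.data$subject_id, .data$chain, sep = "."),
      timepoint = NA_integer_
    ) |>
    as_repertoire()
}

#' Subsample each sample to a fixed read depth
#'
#' Draws `n` reads without replacement from each sample's read multiset (each
#' clone expanded to `duplicate_count` copies) — a multivariate hypergeometric
#' draw, the standard rarefaction scheme. The result has total reads exactly
#' `n` per sample; clones drawn zero times are dropped.
#'
#' @param x A repertoire tibble.
#' @param n Target read depth per sample; must not exceed any sample's depth.
#' @param seed Optional integer seed for reproducibility.
#' @return A repertoire tibble with `sum(duplicate_count) == n` per sample.
#' @export
subsample_repertoire <- function(x, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  depths <- total_reads(x)
  short <- depths[depths$total_reads < n, ]
  if (nrow(short) > 0) {
    abort(paste0("requested depth ", n, " exceeds sample depth: ",
                 paste0(short$sample_id, " (", short$total_reads, ")",
                        collapse = ", ")),
          class = "tcrshare_depth_error")
  }
  if (n == 0) return(x[0, , drop = FALSE])
  x |>
    group_by(.data$sample_id) |>
    group_modify(function(df, key) {
      reads <- rep.int(seq_len(nrow(df)), df$duplicate_count)
      drawn <- if (length(reads) == n) reads else sample(reads, n)
      cnt <- tabulate(drawn, nbins = nrow(df))
      df$duplicate_count <- cnt
      df[cnt > 0L, , drop = FALSE]
    }) |>
    ungroup() |>
    relocate(all_of(REP_CORE_COLS))
}
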