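#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' between two sequences. Vectorized elementwise with recycling.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @examples
#' levenshtein("CASSLGYEQYF", "CASSLSYEQYF")  # 1
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  as.integer(diag(utils::adist(a, b)))
}

# full cross distance matrix (C implementation in utils::adist)
levenshtein_matrix <- function(a, b = a) utils::adist(a, b)

#' Top-N pooled sequences at one timepoint
#'
#' Pools the given samples, then keeps the `n` amino-acid sequences with the
#' highest pooled copy number (ties broken lexicographically) — a fixed-size
#' pool that removes sample-size bias from neighborhood comparisons.
#'
#' @param x A repertoire tibble (e.g. all case-group samples of one
#'   timepoint).
#' @param n Pool size (default 10000); if fewer sequences exist, all are
#'   returned with a warning.
#' @return Character vector of amino-acid sequences, most abundant first.
#' @export
top_n_pool <- function(x, n = 10000) {
  agg <- x |>
    group_by(.data$junction_aa) |>
    summarise(copies = sum(.data$duplicate_count), .groups = "drop") |>
    arrange(desc(.data$copies), .data$junction_aa)
  if (nrow(agg) < n) {
    warn(paste0("pool has only ", nrow(agg), " sequences (requested ", n, ")"))
    n <- nrow(agg)
  }
  agg$junction_aa[seq_len(n)]
}

#' Count near-neighbors of a sequence in a pool
#'
#' Number of pool members, other than the focal sequence itself, within
#' Levenshtein distance `d_max` of it.
#'
#' @param focal An amino-acid sequence.
#' @param pool Character vector of sequences.
#' @param d_max Maximum edit distance (default 2).
#' @return Integer count.
#' @export
neighborhood_count <- function(focal, pool, d_max = 2) {
  stopifnot(length(focal) == 1, length(pool) > 0)
  pool <- pool[pool != focal]
  if (length(pool) == 0) return(0L)
  d <- utils::adist(focal, pool)
  sum(d <= d_max & d >= 1L)
}

#' Neighborhood counts versus a random baseline
#'
#' Counts near-neighbors for each focal sequence and for `n_random` sequences
#' drawn uniformly from the pool (excluding the focal set); per focal, the
#' empirical p (+1 corrected) is the probability a random sequence has at
#' least as many neighbors.
#'
#' @param focals Character vector of focal sequences.
#' @param pool Character vector (e.g. from [top_n_pool()]).
#' @param n_random Baseline draws (default 1000).
#' @param d_max Maximum edit distance (default 2).
#' @param seed Seed.
#' @return List with `focal` (tibble: `junction_aa`, `count`, `p.value`),
#'   `baseline_counts`, `baseline_mean`, `baseline_sd`.
#' @export
neighborhood_vs_random <- function(focals, pool, n_random = 1000, d_max = 2,
                                   seed = 1) {
  set.seed(seed)
  avail <- setdiff(pool, focals)
  if (length(avail) < 1) {
    abort("pool too small for baseline draws after excluding focal set",
          class = "tcrshare_config_error")
  }
  draws <- sample(avail, n_random, replace = n_random > length(avail))
  base_counts <- vapply(draws, neighborhood_count, integer(1),
                        pool = pool, d_max = d_max)
  focal_tbl <- tibble(
    junction_aa = focals,
    count = vapply(focals, neighborhood_count, integer(1),
                   pool = pool, d_max = d_max)
  )
  focal_tbl$p.value <- vapply(focal_tbl$count, function(k) {
    (1 + sum(base_counts >= k)) / (n_random + 1)
  }, numeric(1))
  list(focal = focal_tbl, baseline_counts = unname(base_counts),
       baseline_mean = mean(base_counts), baseline_sd = stats::sd(base_counts))
}

#' Build an edit-distance network
#'
#' Nodes are sequences (or alpha-beta pairs); an edge joins two nodes whose
#' distance lies in `[1, d_max]`. For pairs under `summed_chains`, the
#' distance is the sum of the alpha-alpha and beta-beta Levenshtein
#' distances; under `single_chain` each chain must be within `d_max` on its
#' own (edge weight = summed distance).
#'
#' @param x Character vector of sequences, or a data frame with `alpha_aa`
#'   and `beta_aa` columns.
#' @param d_max Maximum edge distance.
#' @param pair_distance `"summed_chains"` (default) or `"single_chain"`.
#' @return Object of class `tcr_network`: list with `nodes`, `edges`
#'   (tibble: `node_a`, `node_b`, `distance`), `components` (membership
#'   tibble), `component_sizes`, `d_max`.
#' @export
build_distance_network <- function(x, d_max = 2,
                                   pair_distance = c("summed_chains",
                                                     "single_chain")) {
  pair_distance <- match.arg(pair_distance)
  if (is.data.frame(x)) {
    stopifnot(all(c("alpha_aa", "beta_aa") %in% names(x)))
    x <- distinct(x, .data$alpha_aa, .data$beta_aa)
    nodes <- paste(x$alpha_aa, x$beta_aa, sep = "|")
    da <- levenshtein_matrix(x$alpha_aa)
    db <- levenshtein_matrix(x$beta_aa)
    d <- da + db
    ok <- if (pair_distance == "single_chain") da <= d_max & db <= d_max
          else d <= d_max
  } else {
    nodes <- unique(x)
    if (length(nodes) == 0) {
      abort("at least one node required", class = "tcrshare_empty_error")
    }
    d <- levenshtein_matrix(nodes)
    ok <- d <= d_max
  }
  ok <- ok & d >= 1
  ok[lower.tri(ok, diag = TRUE)] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  edges <- tibble(node_a = nodes[idx[, 1]], node_b = nodes[idx[, 2]],
                  distance = d[idx])
  g <- igraph::graph_from_data_frame(
    edges[c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  comp <- igraph::components(g)
  structure(list(
    nodes = nodes, edges = edges,
    components = tibble(node = names(comp$membership),
                        component = unname(comp$membership)),
    component_sizes = sort(unname(comp$csize), decreasing = TRUE),
    d_max = d_max
  ), class = "tcr_network")
}

#' @export
print.tcr_network <- function(x, ...) {
  cat("<tcr_network>", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (d_max =", x$d_max, "),",
      length(x$component_sizes), "components\n")
  invisible(x)
}

#' Nucleotide-origin bipartite graph of a shared amino-acid clone
#'
#' Collects the distinct nucleotide junctions encoding a focal amino-acid
#' sequence in the mouse data and in the human data. For the tumor-associated
#' cross-species clones the two sets do not overlap: the species converge on
#' the same amino-acid sequence through entirely different recombinations.
#'
#' @param focal_aa The amino-acid sequence.
#' @param mouse,human Repertoire tibbles.
#' @return List of class `nt_origin`: `focal_aa`, `mouse_nt`, `human_nt`,
#'   `overlap` (size of the intersection), `edges` (tibble: `junction`,
#'   `junction_aa`, `species`).
#' @export
nt_origin_bipartite <- function(focal_aa, mouse, human) {
  m_nt <- sort(unique(mouse$junction[mouse$junction_aa == focal_aa]))
  h_nt <- sort(unique(human$junction[human$junction_aa == focal_aa]))
  if (length(m_nt) == 0 || length(h_nt) == 0) {
    abort(paste0("focal sequence absent from ",
                 if (length(m_nt) == 0) "mouse" else "human", " data"),
          class = "tcrshare_presence_error")
  }
  structure(list(
    focal_aa = focal_aa, mouse_nt = m_nt, human_nt = h_nt,
    overlap = length(intersect(m_nt, h_nt)),
    edges = bind_rows(
      tibble(junction = m_nt, junction_aa = focal_aa, species = "mouse"),
      tibble(junction = h_nt, junction_aa = focal_aa, species = "human")
    )
  ), class = "nt_origin")
}

#' @export
print.nt_origin <- function(x, ...) {
  cat("<nt_origin>", x$focal_aa, "- mouse:", length(x$mouse_nt),
      "NT, human:", length(x$human_nt), "NT, overlap:", x$overlap, "\n")
  invisible(x)
}
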