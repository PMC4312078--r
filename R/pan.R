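# Cluster families by pairwise homology, within-strain deduplication,
# presence/absence matrices, core/auxiliary/specific partitioning and the
# pairwise conservation matrix.

#' Similarity between two gene clusters by chained anchor coverage
#'
#' Finds maximal unique match anchors between the two sequences
#' ([find_mums()], both strands), chains them ([chain_anchors()]), and
#' reports the fraction of the *shorter* sequence covered by the best
#' chain. This conservative metric approaches 1 for near-identical
#' clusters, stays high for a fragment against its full-length homolog,
#' and is effectively 0 for unrelated sequences.
#'
#' @param a,b Nucleotide sequences.
#' @param min_len Minimum anchor length in bp.
#' @return Similarity fraction in `[0, 1]`.
#' @export
cluster_similarity <- function(a, b, min_len = 20) {
  stopifnot(is.character(a), is.character(b))
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("cluster sequences must be non-empty", call. = FALSE)
  }
  if (nchar(a) <= nchar(b)) {
    q <- a
    r <- b
  } else {
    q <- b
    r <- a
  }
  ch <- best_chain(q, r, kmer_index(r, min_len), min_len)
  # N spacers (e.g. stitching junctions) never align, so do not count them
  eff_len <- nchar(gsub("N", "", q, fixed = TRUE))
  if (eff_len == 0) {
    return(0)
  }
  min(ch$covered_q / eff_len, 1)
}

# similarity on a pre-filtered pair list; pairs sharing no k-mer are 0
# without running the full anchor machinery
pair_similarities <- function(seqs, pairs, min_len) {
  ksets <- purrr::map(seqs, function(s) names(kmer_index(s, min_len)))
  vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]
    j <- pairs$j[r]
    if (length(intersect(ksets[[i]], ksets[[j]])) == 0) {
      return(0)
    }
    cluster_similarity(seqs[[i]], seqs[[j]], min_len)
  }, numeric(1))
}

#' Remove duplicate gene clusters within one strain
#'
#' Clusters of one strain with pairwise similarity at or above `threshold`
#' are collapsed (single linkage); the longest member of each group is
#' retained as representative. This mirrors self-versus-self homology
#' screening used to count duplicated clusters once.
#'
#' @param clusters Tibble with columns `cluster_id`, `sequence` (and
#'   optionally others, carried through); all rows must belong to one
#'   strain.
#' @param threshold Similarity threshold for collapsing, in `(0, 1]`.
#' @param min_len Minimum anchor length for [cluster_similarity()].
#' @return The retained rows, with an attribute `removed`: a tibble
#'   mapping each removed `cluster_id` to the `kept` representative.
#' @export
dedup_within_strain <- function(clusters, threshold = 0.9, min_len = 20) {
  stopifnot(is.data.frame(clusters),
            all(c("cluster_id", "sequence") %in% names(clusters)))
  if ("strain_id" %in% names(clusters) &&
      length(unique(clusters$strain_id)) > 1) {
    stop("dedup_within_strain expects clusters from a single strain",
         call. = FALSE)
  }
  n <- nrow(clusters)
  if (n <= 1) {
    attr(clusters, "removed") <- tibble::tibble(cluster_id = character(),
                                                kept = character())
    return(clusters)
  }
  pairs <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) |>
    dplyr::filter(.data$i < .data$j)
  sim <- pair_similarities(clusters$sequence, pairs, min_len)
  g <- igraph::graph_from_data_frame(
    pairs[sim >= threshold, c("i", "j")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  comp <- igraph::components(g)$membership
  keep <- vapply(split(seq_len(n), comp), function(idx) {
    idx[which.max(nchar(clusters$sequence[idx]))]
  }, integer(1))
  removed_idx <- setdiff(seq_len(n), keep)
  kept_of <- stats::setNames(
    clusters$cluster_id[keep][match(comp[removed_idx], comp[keep])],
    NULL
  )
  out <- clusters[sort(keep), , drop = FALSE]
  attr(out, "removed") <- tibble::tibble(
    cluster_id = clusters$cluster_id[removed_idx],
    kept = kept_of
  )
  out
}

#' Build cluster families across strains by single-linkage homology
#'
#' Computes pairwise similarities ([cluster_similarity()]) among all
#' clusters, draws an edge wherever similarity meets `threshold`, and
#' calls each connected component a family. The presence/absence matrix is
#' derived from the strains contributing members to each family
#' (duplicates within a strain collapse to a single presence).
#'
#' @param clusters Tibble with columns `strain_id`, `cluster_id`,
#'   `sequence`.
#' @param threshold Similarity threshold for a homology edge.
#' @param min_len Minimum anchor length.
#' @return A list of class `bgc_families`: `families` (tibble `family_id`,
#'   `cluster_id`, `strain_id`), `presence` (a [presence_matrix()] tibble).
#' @export
build_families <- function(clusters, threshold = 0.5, min_len = 20) {
  stopifnot(is.data.frame(clusters),
            all(c("strain_id", "cluster_id", "sequence") %in% names(clusters)))
  stopifnot(!anyDuplicated(clusters$cluster_id))
  n <- nrow(clusters)
  stopifnot(n >= 1)
  if (n == 1) {
    comp <- 1L
  } else {
    pairs <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) |>
      dplyr::filter(.data$i < .data$j)
    sim <- pair_similarities(clusters$sequence, pairs, min_len)
    g <- igraph::graph_from_data_frame(
      pairs[sim >= threshold, c("i", "j")],
      directed = FALSE,
      vertices = data.frame(name = seq_len(n))
    )
    comp <- igraph::components(g)$membership
  }
  # stable family ids: by first-seen cluster order
  fam_codes <- match(comp, unique(comp))
  fam_ids <- sprintf("FAM%03d", fam_codes)
  families <- tibble::tibble(
    family_id = fam_ids,
    cluster_id = clusters$cluster_id,
    strain_id = clusters$strain_id
  )
  strains <- unique(clusters$strain_id)
  pres <- tibble::tibble(family_id = unique(fam_ids))
  for (s in strains) {
    fams_s <- unique(fam_ids[clusters$strain_id == s])
    pres[[s]] <- pres$family_id %in% fams_s
  }
  out <- list(families = families, presence = presence_matrix(pres))
  class(out) <- "bgc_families"
  out
}

#' @export
print.bgc_families <- function(x, ...) {
  cat(sprintf("<bgc_families> %d clusters in %d families across %d strains\n",
              nrow(x$families), length(unique(x$families$family_id)),
              length(unique(x$families$strain_id))))
  invisible(x)
}

#' Construct a presence/absence matrix object
#'
#' @param tbl A tibble whose first column is `family_id` and whose
#'   remaining columns are one logical column per strain.
#' @return The validated tibble with class `bgc_presence`.
#' @export
presence_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), names(tbl)[1] == "family_id", ncol(tbl) >= 2)
  tbl <- tibble::as_tibble(tbl)
  for (s in names(tbl)[-1]) {
    if (!is.logical(tbl[[s]])) tbl[[s]] <- as.logical(tbl[[s]])
  }
  stopifnot(!anyDuplicated(tbl$family_id))
  if (any(rowSums(as.matrix(tbl[-1])) == 0)) {
    stop("every family must be present in at least one strain",
         call. = FALSE)
  }
  class(tbl) <- c("bgc_presence", class(tibble::tibble()))
  tbl
}

pa_strains <- function(pa) names(pa)[-1]

pa_mat <- function(pa) {
  m <- as.matrix(tibble::as_tibble(pa)[-1])
  rownames(m) <- pa$family_id
  m
}

#' Partition families into core, auxiliary and strain-specific sets
#'
#' A family is *core* when present in every strain, *strain-specific* when
#' present in exactly one, and *auxiliary* otherwise (at least 2 but fewer
#' than all strains).
#'
#' @param pa A [presence_matrix()] (or the `presence` element of
#'   [build_families()]).
#' @return A tibble of class `bgc_partition`: `family_id`, `n_strains`,
#'   `category`. Use [glance()] for the category counts.
#' @examples
#' pa <- presence_matrix(tibble::tibble(
#'   family_id = c("f1", "f2"), A = c(TRUE, TRUE), B = c(TRUE, FALSE)
#' ))
#' partition_families(pa)
#' @export
partition_families <- function(pa) {
  stopifnot(inherits(pa, "bgc_presence"))
  m <- pa_mat(pa)
  if (ncol(m) < 2) stop("partition needs >= 2 strains", call. = FALSE)
  k <- rowSums(m)
  if (any(k == 0)) {
    stop("family present in zero strains", call. = FALSE)
  }
  out <- tibble::tibble(
    family_id = rownames(m),
    n_strains = as.integer(k),
    category = dplyr::case_when(
      k == ncol(m) ~ "core",
      k == 1 ~ "specific",
      TRUE ~ "auxiliary"
    )
  )
  class(out) <- c("bgc_partition", class(tibble::tibble()))
  out
}

#' @export
glance.bgc_partition <- function(x, ...) {
  tibble::tibble(
    core = sum(x$category == "core"),
    auxiliary = sum(x$category == "auxiliary"),
    specific = sum(x$category == "specific"),
    n_families = nrow(x)
  )
}

#' Pairwise conservation matrix of cluster families
#'
#' For every strain pair, counts the families present in both. The
#' diagonal carries each strain's total family count; percentages are
#' *floor-truncated* integers with the row strain's total as denominator
#' (`percent[i, j] = floor(100 * shared[i, j] / totals[i])`), matching the
#' convention of published strain-comparison tables. Per-strain unique
#' counts are families present in that strain only.
#'
#' @param pa A [presence_matrix()].
#' @return A list of class `pan_matrix`: `strains`, `shared` (symmetric
#'   integer matrix, totals on the diagonal), `percent` (integer matrix),
#'   `totals`, `unique_counts`, `unique_percent`, `notes` (character
#'   vector of data-quality annotations, empty when none).
#' @export
pan_matrix <- function(pa) {
  stopifnot(inherits(pa, "bgc_presence"))
  m <- pa_mat(pa)
  if (ncol(m) < 2) stop("pan_matrix needs >= 2 strains", call. = FALSE)
  shared <- t(m) %*% m
  storage.mode(shared) <- "integer"
  totals <- diag(shared)
  percent <- matrix(
    as.integer(floor(100 * shared / rep(totals, ncol(shared)))),
    nrow = nrow(shared), dimnames = dimnames(shared)
  )
  uniq <- colSums(m[rowSums(m) == 1, , drop = FALSE])
  out <- list(
    strains = colnames(m),
    shared = shared,
    percent = percent,
    totals = totals,
    unique_counts = as.integer(uniq),
    unique_percent = as.integer(floor(100 * uniq / totals)),
    notes = character(0)
  )
  names(out$unique_counts) <- names(out$unique_percent) <- colnames(m)
  class(out) <- "pan_matrix"
  out
}

#' @export
print.pan_matrix <- function(x, ...) {
  cat("<pan_matrix>", length(x$strains), "strains,",
      sum(x$unique_counts), "strain-specific families\n")
  print(format_pan_matrix(x))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Format a pan matrix in the published table layout
#'
#' Upper-triangle cells read `shared (percent%)` with the row strain's
#' total as denominator; the final column holds each strain's unique
#' cluster count.
#'
#' @param pm A [pan_matrix()].
#' @return A tibble with one row per strain.
#' @export
format_pan_matrix <- function(pm) {
  stopifnot(inherits(pm, "pan_matrix"))
  n <- length(pm$strains)
  out <- tibble::tibble(strain = pm$strains)
  for (j in seq_len(n)) {
    col <- character(n)
    for (i in seq_len(n)) {
      col[i] <- if (j < i) "" else
        sprintf("%d (%d%%)", pm$shared[i, j], pm$percent[i, j])
    }
    out[[pm$strains[j]]] <- col
  }
  out$unique <- sprintf("%d (%d%%)", pm$unique_counts, pm$unique_percent)
  out
}

#' @export
tidy.pan_matrix <- function(x, ...) {
  n <- length(x$strains)
  tidyr::expand_grid(strain_a = x$strains, strain_b = x$strains) |>
    dplyr::mutate(
      shared = as.vector(t(x$shared)),
      percent = as.vector(t(x$percent))
    )
}

#' @export
glance.pan_matrix <- function(x, ...) {
  off <- x$shared[upper.tri(x$shared)]
  tibble::tibble(
    n_strains = length(x$strains),
    min_total = min(x$totals),
    max_total = max(x$totals),
    mean_shared = mean(off),
    n_specific = sum(x$unique_counts)
  )
}

#' Count families present in exactly a given strain subset
#'
#' @param pa A [presence_matrix()].
#' @param strain_subset Character vector of strain names (non-empty, all
#'   known).
#' @return Integer: the number of families whose presence pattern equals
#'   the subset exactly (present in every subset strain, absent from all
#'   others).
#' @examples
#' pa <- presence_matrix(tibble::tibble(
#'   family_id = c("f1", "f2"), A = c(TRUE, TRUE), B = c(TRUE, FALSE)
#' ))
#' exclusive_shared(pa, "B") # 0
#' @export
exclusive_shared <- function(pa, strain_subset) {
  stopifnot(inherits(pa, "bgc_presence"))
  strains <- pa_strains(pa)
  if (length(strain_subset) == 0) {
    stop("strain_subset must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(strain_subset, strains)
  if (length(unknown)) {
    stop("unknown strain id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- pa_mat(pa)
  target <- strains %in% strain_subset
  sum(apply(m, 1, function(row) all(row == target)))
}

#' @export
autoplot.bgc_presence <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"family_id",
                              names_to = "strain", values_to = "present")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strain, y = .data$family_id,
                                     fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "white")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.pan_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strain_b, y = .data$strain_a,
                                     fill = .data$shared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%d%%)", .data$shared, .data$percent)
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared") +
    ggplot2::theme_minimal()
}
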