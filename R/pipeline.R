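# End-to-end pan-metabolome pipeline: greedy reference selection,
# per-strain stitching of co-assigned fragments, within-strain
# deduplication, family building and partitioning.

#' Run the full cluster-repertoire analysis on per-strain cluster records
#'
#' Mirrors the reference-anchored survey workflow:
#'
#' 1. **Reference selection** — records are processed in decreasing length
#'    order; a record founds a new reference unless its best anchor chain
#'    covers at least `min_q_coverage` of it against an existing reference
#'    (greedy centroid selection, so each family's longest record becomes
#'    its exemplar).
#' 2. **Stitching** — within each strain, records co-assigned to the same
#'    reference with essentially disjoint reference intervals are fragments
#'    of one split cluster and are stitched ([stitch()]); records whose
#'    intervals overlap the same reference region are duplicate candidates
#'    and stay separate.
#' 3. **Deduplication** — [dedup_within_strain()] collapses near-identical
#'    clusters within each strain.
#' 4. **Families and partition** — [build_families()],
#'    [partition_families()] and [pan_matrix()].
#'
#' @param clusters Tibble of cluster records with columns `strain_id`, an
#'   id column (`record_id` or `cluster_id`) and `sequence` — e.g. the
#'   `clusters` element of [simulate_strains()], or rows read from
#'   per-strain FASTA files.
#' @param family_threshold Similarity threshold for family edges.
#' @param dedup_threshold Similarity threshold for within-strain
#'   duplicates.
#' @param min_len Minimum anchor length in bp.
#' @param min_q_coverage Coverage needed to assign a record to a reference.
#' @param ambiguity_margin Runner-up margin for flagging ambiguous
#'   assignments.
#' @param spacer_n `N`s inserted at stitch junctions.
#' @return A list of class `pan_analysis`: `references` (exemplar record
#'   ids), `assignments`, `clusters` (post-stitch, post-dedup tibble with a
#'   `members` list-column tracing each final cluster to its input
#'   records), `families`, `presence`, `partition`, `pan`.
#' @examples
#' sim <- simulate_strains(sim_config(
#'   n_strains = 3, n_core = 2, n_auxiliary = 1, n_specific = 1,
#'   family_length_range = c(1000, 1200),
#'   spacer_length_range = c(2000, 3000), seed = 11
#' ))
#' res <- pan_pipeline(sim$clusters)
#' glance(res$partition)
#' @export
pan_pipeline <- function(clusters, family_threshold = 0.5,
                         dedup_threshold = 0.9, min_len = 20,
                         min_q_coverage = 0.5, ambiguity_margin = 0.1,
                         spacer_n = 100) {
  stopifnot(is.data.frame(clusters), "strain_id" %in% names(clusters),
            "sequence" %in% names(clusters))
  id_col <- intersect(c("record_id", "cluster_id"), names(clusters))[1]
  if (is.na(id_col)) stop("clusters needs a record_id or cluster_id column",
                          call. = FALSE)
  recs <- tibble::tibble(
    strain_id = clusters$strain_id,
    record_id = as.character(clusters[[id_col]]),
    sequence = clusters$sequence
  )
  stopifnot(!anyDuplicated(recs$record_id))

  # 1. greedy reference selection + assignment
  ord <- order(-nchar(recs$sequence), recs$record_id)
  panel_idx <- integer(0)
  panel_ridx <- list()
  panel_kset <- list()
  asg <- vector("list", nrow(recs))
  ksets <- purrr::map(recs$sequence, function(s) names(kmer_index(s, min_len)))
  for (i in ord) {
    q <- recs$sequence[i]
    best <- NULL
    best_norm <- 0
    runner <- 0
    for (p in seq_along(panel_idx)) {
      if (length(intersect(ksets[[i]], panel_kset[[p]])) == 0) next
      ch <- best_chain(q, recs$sequence[panel_idx[p]], panel_ridx[[p]],
                       min_len)
      norm <- ch$score / nchar(q)
      if (norm > best_norm) {
        runner <- best_norm
        best_norm <- norm
        best <- list(p = p, chain = ch)
      } else if (norm > runner) {
        runner <- norm
      }
    }
    if (!is.null(best) &&
        chain_span_q(best$chain) / nchar(q) >= min_q_coverage) {
      ch <- best$chain
      asg[[i]] <- tibble::tibble(
        fragment_id = recs$record_id[i],
        reference_id = recs$record_id[panel_idx[best$p]],
        strand = ch$strand,
        q_coverage = chain_span_q(ch) / nchar(q),
        r_start = min(ch$anchors$r_start),
        r_end = max(ch$anchors$r_end),
        ambiguous = runner >= (1 - ambiguity_margin) * best_norm
      )
    } else {
      panel_idx <- c(panel_idx, i)
      panel_ridx[[length(panel_ridx) + 1]] <- kmer_index(q, min_len)
      panel_kset[[length(panel_kset) + 1]] <- ksets[[i]]
      asg[[i]] <- tibble::tibble(
        fragment_id = recs$record_id[i], reference_id = recs$record_id[i],
        strand = "+", q_coverage = 1, r_start = 1L,
        r_end = nchar(q), ambiguous = FALSE
      )
    }
  }
  assignments <- dplyr::bind_rows(asg)
  assignments$strain_id <- recs$strain_id[match(assignments$fragment_id,
                                                recs$record_id)]

  # 2. per strain/reference: split co-assigned records into
  # interval-disjoint subgroups (fragments) vs overlapping ones
  # (duplicate candidates), then stitch each multi-record subgroup
  final <- list()
  for (s in unique(recs$strain_id)) {
    a_s <- dplyr::filter(assignments, .data$strain_id == s)
    for (ref in unique(a_s$reference_id)) {
      g <- dplyr::arrange(dplyr::filter(a_s, .data$reference_id == ref),
                          .data$r_start, .data$fragment_id)
      # ambiguous assignments are not stitched; keep them as-is
      for (rid in g$fragment_id[g$ambiguous]) {
        final[[length(final) + 1]] <- tibble::tibble(
          strain_id = s, cluster_id = rid,
          sequence = recs$sequence[match(rid, recs$record_id)],
          stitched = FALSE, members = list(rid)
        )
      }
      g <- dplyr::filter(g, !.data$ambiguous)
      if (nrow(g) == 0) next
      groups <- list()
      for (k in seq_len(nrow(g))) {
        placed <- FALSE
        for (gi in seq_along(groups)) {
          rows <- groups[[gi]]
          ok <- all(vapply(rows, function(r) {
            ov <- min(g$r_end[r], g$r_end[k]) - max(g$r_start[r], g$r_start[k]) + 1L
            shorter <- min(g$r_end[r] - g$r_start[r],
                           g$r_end[k] - g$r_start[k]) + 1L
            ov <= 0.5 * shorter
          }, logical(1)))
          if (ok) {
            groups[[gi]] <- c(rows, k)
            placed <- TRUE
            break
          }
        }
        if (!placed) groups[[length(groups) + 1]] <- k
      }
      for (gi in seq_along(groups)) {
        rows <- groups[[gi]]
        sub <- g[rows, , drop = FALSE]
        if (nrow(sub) == 1) {
          rid <- sub$fragment_id[1]
          final[[length(final) + 1]] <- tibble::tibble(
            strain_id = s, cluster_id = rid,
            sequence = recs$sequence[match(rid, recs$record_id)],
            stitched = FALSE, members = list(rid)
          )
        } else {
          st <- stitch(sub, stats::setNames(recs$sequence, recs$record_id),
                       spacer_n = spacer_n)
          final[[length(final) + 1]] <- tibble::tibble(
            strain_id = s,
            cluster_id = sprintf("%s|%s|stitched%d", s, ref, gi),
            sequence = st$sequence[1],
            stitched = TRUE, members = st$fragment_ids
          )
        }
      }
    }
  }
  final <- dplyr::bind_rows(final)

  # 3. within-strain dedup
  deduped <- list()
  for (s in unique(final$strain_id)) {
    d <- dedup_within_strain(dplyr::filter(final, .data$strain_id == s),
                             threshold = dedup_threshold, min_len = min_len)
    deduped[[length(deduped) + 1]] <- d
  }
  deduped <- dplyr::bind_rows(deduped)

  # 4. families, partition, conservation matrix
  fams <- build_families(deduped, threshold = family_threshold,
                         min_len = min_len)
  part <- partition_families(fams$presence)
  pm <- pan_matrix(fams$presence)

  out <- list(
    references = recs$record_id[panel_idx],
    assignments = assignments,
    clusters = deduped,
    families = fams$families,
    presence = fams$presence,
    partition = part,
    pan = pm
  )
  class(out) <- "pan_analysis"
  out
}

#' @export
print.pan_analysis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<pan_analysis> %d strains, %d clusters -> %d families (core %d / auxiliary %d / specific %d)\n",
    length(unique(x$clusters$strain_id)), nrow(x$clusters), g$n_families,
    g$core, g$auxiliary, g$specific))
  invisible(x)
}

#' @export
glance.pan_analysis <- function(x, ...) glance(x$partition)

#' @export
tidy.pan_analysis <- function(x, ...) {
  dplyr::left_join(x$families, x$partition, by = "family_id")
}
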