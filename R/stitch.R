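# Reference-anchored stitching of contig-fragmented clusters: maximal
# unique match (MUM) anchors, sparse collinear chaining, fragment-to-
# reference assignment and ordered concatenation.

# -- k-mer machinery ----------------------------------------------------------

# positions of every k-mer (k-mers containing N are excluded)
kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) {
    return(list())
  }
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  split(starts[ok], kmers[ok])
}

# maximal exact matches >= k between q and r, given r's k-mer index.
# Returns q_start, r_start, length. Two positions belong to the same
# maximal match iff they sit on the same diagonal at consecutive offsets,
# so maximal matches are exactly the runs of seed hits per diagonal.
maximal_matches <- function(q, ridx, k) {
  qidx <- kmer_index(q, k)
  common <- intersect(names(qidx), names(ridx))
  if (length(common) == 0) {
    return(tibble::tibble(q_start = integer(), r_start = integer(),
                          length = integer()))
  }
  qp <- qidx[common]
  rp <- ridx[common]
  nq <- lengths(qp)
  nr <- lengths(rp)
  qv <- unlist(mapply(function(a, b) rep(a, each = length(b)), qp, rp,
                      SIMPLIFY = FALSE), use.names = FALSE)
  rv <- unlist(mapply(function(a, b) rep(b, times = length(a)), qp, rp,
                      SIMPLIFY = FALSE), use.names = FALSE)
  dg <- qv - rv
  o <- order(dg, qv)
  dg <- dg[o]
  qv <- qv[o]
  m <- length(qv)
  newrun <- c(TRUE, dg[-1] != dg[-m] | qv[-1] != qv[-m] + 1L)
  run <- cumsum(newrun)
  first <- which(newrun)
  last <- c(first[-1] - 1L, m)
  tibble::tibble(
    q_start = qv[first],
    r_start = qv[first] - dg[first],
    length = qv[last] - qv[first] + k
  )
}

count_occurrences <- function(pattern, subject_dna) {
  Biostrings::countPattern(pattern, subject_dna, fixed = TRUE)
}

#' Find maximal unique matches (MUMs) between two sequences
#'
#' Enumerates all exact matches of length at least `min_len` that are
#' maximal (extendable in neither direction) and whose matched substring
#' occurs exactly once in the query and once in the reference (strict MUM
#' semantics). Both strands are searched; a minus-strand anchor means the
#' reverse complement of the spanned query substring equals the spanned
#' reference substring. Matches never span an `N`.
#'
#' @param query,reference Nucleotide sequences (A/C/G/T/N, uppercase).
#' @param min_len Minimum match length in bp (>= 4; 20 is the customary
#'   anchor length for genome-scale comparisons and lengths below 8 are
#'   rarely informative outside toy examples).
#' @return A tibble of anchors: `q_start`, `q_end`, `r_start`, `r_end`
#'   (1-based inclusive, query coordinates always on the forward query),
#'   `length`, `strand` (`"+"`/`"-"`), sorted by `r_start`.
#' @examples
#' find_mums("GATTACA", "TTGATTACCA", min_len = 4)
#' @export
find_mums <- function(query, reference, min_len = 20) {
  stopifnot(is.character(query), is.character(reference))
  if (min_len < 4) stop("min_len must be >= 4", call. = FALSE)
  check_nucleotides(query, "query")
  check_nucleotides(reference, "reference")
  ridx <- kmer_index(reference, min_len)
  find_mums_indexed(query, reference, ridx, min_len)
}

empty_anchor_tbl <- function() {
  tibble::tibble(q_start = integer(), q_end = integer(),
                 r_start = integer(), r_end = integer(),
                 length = integer(), strand = character())
}

# shared engine: reference index computed once by the caller
find_mums_indexed <- function(query, reference, ridx, min_len) {
  rdna <- Biostrings::DNAString(if (nchar(reference)) reference else "A")
  one_strand <- function(q, strand) {
    mm <- maximal_matches(q, ridx, min_len)
    if (nrow(mm) == 0) {
      return(empty_anchor_tbl())
    }
    qdna <- Biostrings::DNAString(q)
    subs <- substring(q, mm$q_start, mm$q_start + mm$length - 1L)
    uniq <- vapply(seq_along(subs), function(i) {
      count_occurrences(subs[i], qdna) == 1L &&
        count_occurrences(subs[i], rdna) == 1L
    }, logical(1))
    mm <- mm[uniq, , drop = FALSE]
    tibble::tibble(
      q_start = mm$q_start, q_end = mm$q_start + mm$length - 1L,
      r_start = mm$r_start, r_end = mm$r_start + mm$length - 1L,
      length = mm$length, strand = strand
    )
  }
  fwd <- one_strand(query, "+")
  qrc <- revcomp(query)
  rev <- one_strand(qrc, "-")
  if (nrow(rev)) {
    n <- nchar(query)
    q_start <- n - rev$q_end + 1L
    q_end <- n - rev$q_start + 1L
    rev$q_start <- q_start
    rev$q_end <- q_end
  }
  out <- dplyr::bind_rows(fwd, rev)
  dplyr::arrange(out, .data$r_start, .data$q_start)
}

#' Chain anchors into the best collinear chain
#'
#' Sparse dynamic programming over anchors from one query/reference/strand
#' combination: the chain must be strictly increasing in both query and
#' reference coordinates (query direction reversed for minus-strand
#' anchors), overlap between adjacent anchors is trimmed from the score,
#' and ties are broken toward the chain whose first anchor has the smaller
#' `r_start`.
#'
#' @param anchors A tibble of anchors as returned by [find_mums()], all on
#'   one strand.
#' @return A list of class `bgc_chain`: `anchors` (chained subset, in chain
#'   order), `covered_q` and `covered_r` (non-overlapping covered bp),
#'   `score` (total anchor bp after overlap trimming), `strand`. An empty
#'   anchor set gives an empty chain with score 0.
#' @examples
#' a <- find_mums("GATTACA", "TTGATTACCA", min_len = 4)
#' chain_anchors(a)
#' @export
chain_anchors <- function(anchors) {
  empty <- list(anchors = tibble::tibble(
    q_start = integer(), q_end = integer(), r_start = integer(),
    r_end = integer(), length = integer(), strand = character()
  ), covered_q = 0L, covered_r = 0L, score = 0, strand = NA_character_)
  class(empty) <- "bgc_chain"
  if (is.null(anchors) || nrow(anchors) == 0) {
    return(empty)
  }
  if (length(unique(anchors$strand)) > 1) {
    stop("anchors must all be on one strand", call. = FALSE)
  }
  strand <- anchors$strand[1]
  # chain in (u, r) space where u is the query coordinate on the chain's
  # strand: for "-" the query runs backwards, so negate
  if (strand == "-") {
    u_start <- -anchors$q_end
    u_end <- -anchors$q_start
  } else {
    u_start <- anchors$q_start
    u_end <- anchors$q_end
  }
  n <- nrow(anchors)
  o <- order(u_start, anchors$r_start)
  us <- u_start[o]
  ue <- u_end[o]
  rs <- anchors$r_start[o]
  re <- anchors$r_end[o]
  len <- anchors$length[o]
  score <- as.numeric(len)
  prev <- rep(NA_integer_, n)
  start_r <- rs # r_start of the first anchor of the best chain ending here
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (us[j] < us[i] && rs[j] < rs[i]) {
        ov <- max(0L, ue[j] - us[i] + 1L, re[j] - rs[i] + 1L)
        gain <- len[i] - ov
        if (gain <= 0) next
        cand <- score[j] + gain
        if (cand > score[i] + 1e-9 ||
            (abs(cand - score[i]) <= 1e-9 && start_r[j] < start_r[i])) {
          score[i] <- cand
          prev[i] <- j
          start_r[i] <- start_r[j]
        }
      }
    }
  }
  best <- which(score == max(score))
  if (length(best) > 1) best <- best[which.min(start_r[best])]
  path <- integer(0)
  i <- best
  while (!is.na(i)) {
    path <- c(i, path)
    i <- prev[i]
  }
  chained <- anchors[o[path], , drop = FALSE]
  cov <- function(s, e) {
    o2 <- order(s)
    s <- s[o2]
    e <- e[o2]
    total <- 0L
    hi <- -Inf
    for (k in seq_along(s)) {
      lo <- max(s[k], hi + 1L)
      if (e[k] >= lo) total <- total + (e[k] - lo + 1L)
      hi <- max(hi, e[k])
    }
    as.integer(total)
  }
  out <- list(
    anchors = tibble::as_tibble(chained),
    covered_q = cov(chained$q_start, chained$q_end),
    covered_r = cov(chained$r_start, chained$r_end),
    score = score[best],
    strand = strand
  )
  class(out) <- "bgc_chain"
  out
}

#' @export
print.bgc_chain <- function(x, ...) {
  cat(sprintf("<bgc_chain> %d anchor(s), strand %s, score %.0f, covers %d bp (query) / %d bp (reference)\n",
              nrow(x$anchors), x$strand %||% "?", x$score,
              x$covered_q, x$covered_r))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# query / reference span of a chain (first to last anchor, gaps included)
chain_span_q <- function(ch) {
  if (nrow(ch$anchors) == 0) return(0L)
  max(ch$anchors$q_end) - min(ch$anchors$q_start) + 1L
}

chain_span_r <- function(ch) {
  if (nrow(ch$anchors) == 0) return(0L)
  max(ch$anchors$r_end) - min(ch$anchors$r_start) + 1L
}

# best chain between q and an indexed reference, over both strands
best_chain <- function(query, reference, ridx, min_len) {
  anchors <- find_mums_indexed(query, reference, ridx, min_len)
  if (nrow(anchors) == 0) {
    return(chain_anchors(anchors))
  }
  chains <- lapply(split(anchors, anchors$strand), chain_anchors)
  scores <- vapply(chains, function(c) c$score, numeric(1))
  chains[[which.max(scores)]]
}

#' Assign fragments to their best-matching reference cluster
#'
#' For each fragment, anchors are found against every reference
#' ([find_mums()]), chained ([chain_anchors()]), and the reference with the
#' highest chain score normalised by fragment length wins. The assignment
#' is accepted only if the chain *spans* at least `min_q_coverage` of the
#' fragment (first to last chained anchor, including the gaps between
#' anchors — the convention alignment-based contig assignment reports,
#' which stays robust for short fragments of diverged homologs where exact
#' anchors cover only part of the aligned region); it is flagged ambiguous
#' when the runner-up reference scores within `ambiguity_margin` of the
#' best.
#'
#' @param fragments Tibble with an id column (first) and `sequence`, or a
#'   named character vector.
#' @param references Tibble with an id column (first) and `sequence`, or a
#'   named character vector.
#' @param min_len Minimum anchor length in bp.
#' @param min_q_coverage Minimum fraction of the fragment spanned by the
#'   chain for an assignment.
#' @param ambiguity_margin Runner-up margin: ambiguous if second-best score
#'   >= `(1 - ambiguity_margin) * best`.
#' @return A tibble with one row per fragment: `fragment_id`,
#'   `reference_id` (`NA` if unassigned), `strand`, `q_coverage`,
#'   `ref_coverage`, `r_start`, `r_end` (chain span on the reference),
#'   `score`, `ambiguous`, and a `chain` list-column of [chain_anchors()]
#'   results.
#' @export
assign_fragments <- function(fragments, references, min_len = 20,
                             min_q_coverage = 0.5, ambiguity_margin = 0.1) {
  fragments <- as_seq_tbl(fragments, "fragments")
  references <- as_seq_tbl(references, "references")
  stopifnot(nrow(references) >= 1)
  ridx <- lapply(references$sequence, kmer_index, k = min_len)
  rlen <- nchar(references$sequence)
  out <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    q <- fragments$sequence[i]
    chains <- lapply(seq_len(nrow(references)), function(j) {
      best_chain(q, references$sequence[j], ridx[[j]], min_len)
    })
    norm <- vapply(chains, function(c) c$score, numeric(1)) / nchar(q)
    j <- which.max(norm)
    ch <- chains[[j]]
    q_cov <- chain_span_q(ch) / nchar(q)
    runner <- if (length(norm) > 1) max(norm[-j]) else 0
    amb <- norm[j] > 0 && runner >= (1 - ambiguity_margin) * norm[j]
    assigned <- q_cov >= min_q_coverage
    out[[i]] <- tibble::tibble(
      fragment_id = fragments$id[i],
      reference_id = if (assigned) references$id[j] else NA_character_,
      strand = if (assigned) ch$strand else NA_character_,
      q_coverage = q_cov,
      ref_coverage = if (assigned) chain_span_r(ch) / rlen[j] else 0,
      r_start = if (assigned && nrow(ch$anchors)) min(ch$anchors$r_start) else NA_integer_,
      r_end = if (assigned && nrow(ch$anchors)) max(ch$anchors$r_end) else NA_integer_,
      score = ch$score,
      ambiguous = assigned && amb,
      chain = list(ch)
    )
  }
  dplyr::bind_rows(out)
}

#' @rdname assign_fragments
#' @param fragment A single nucleotide sequence.
#' @export
assign_fragment <- function(fragment, references, min_len = 20,
                            min_q_coverage = 0.5, ambiguity_margin = 0.1) {
  assign_fragments(c(fragment_1 = fragment), references, min_len,
                   min_q_coverage, ambiguity_margin)
}

as_seq_tbl <- function(x, what) {
  if (is.character(x)) {
    if (is.null(names(x))) {
      stop(what, " must be a named character vector or a tibble with id ",
           "and sequence columns", call. = FALSE)
    }
    x <- tibble::tibble(id = names(x), sequence = unname(x))
  }
  stopifnot(is.data.frame(x), "sequence" %in% names(x))
  out <- tibble::tibble(id = as.character(x[[1]]), sequence = x$sequence)
  stopifnot(!anyDuplicated(out$id))
  out
}

#' Stitch co-assigned fragments into single clusters
#'
#' Fragments assigned to the same reference are ordered by the reference
#' start of their chain, reverse-complemented if on the minus strand (so
#' output is reference-oriented), and concatenated with a junction spacer
#' of `spacer_n` `N`s. Ambiguous assignments are excluded with a message.
#' When two fragments' reference intervals overlap by more than half of
#' the shorter interval the stitched record is flagged as a possible
#' duplicate or misassembly but still emitted.
#'
#' @param assignments Tibble from [assign_fragments()].
#' @param fragments Tibble with an id column (first) and `sequence`, or a
#'   named character vector; must cover every assigned fragment.
#' @param spacer_n Number of `N`s inserted at each junction.
#' @return A tibble with one row per reference that received at least one
#'   fragment: `cluster_id` (the reference id), `n_fragments`,
#'   `fragment_ids` (list), `sequence`, `overlap_flag`, and a `report`
#'   list-column of per-fragment reference intervals.
#' @export
stitch <- function(assignments, fragments, spacer_n = 100) {
  fragments <- as_seq_tbl(fragments, "fragments")
  seqs <- stats::setNames(fragments$sequence, fragments$id)
  asg <- dplyr::filter(assignments, !is.na(.data$reference_id))
  n_amb <- sum(asg$ambiguous)
  if (n_amb > 0) {
    message("excluding ", n_amb, " ambiguous assignment(s) from stitching")
    asg <- dplyr::filter(asg, !.data$ambiguous)
  }
  if (nrow(asg) == 0) {
    return(tibble::tibble(cluster_id = character(), n_fragments = integer(),
                          fragment_ids = list(), sequence = character(),
                          overlap_flag = logical(), report = list()))
  }
  missing <- setdiff(asg$fragment_id, names(seqs))
  if (length(missing)) {
    stop("fragment sequence(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  spacer <- strrep("N", spacer_n)
  out <- asg |>
    dplyr::group_by(.data$reference_id) |>
    dplyr::group_map(function(g, key) {
      g <- dplyr::arrange(g, .data$r_start)
      flag <- FALSE
      if (nrow(g) > 1) {
        for (a in seq_len(nrow(g) - 1)) {
          for (b in (a + 1):nrow(g)) {
            ov <- min(g$r_end[a], g$r_end[b]) - max(g$r_start[a], g$r_start[b]) + 1L
            shorter <- min(g$r_end[a] - g$r_start[a], g$r_end[b] - g$r_start[b]) + 1L
            if (ov > 0.5 * shorter) flag <- TRUE
          }
        }
      }
      pieces <- vapply(seq_len(nrow(g)), function(k) {
        s <- seqs[[g$fragment_id[k]]]
        if (identical(g$strand[k], "-")) revcomp(s) else s
      }, character(1))
      tibble::tibble(
        cluster_id = key$reference_id,
        n_fragments = nrow(g),
        fragment_ids = list(g$fragment_id),
        sequence = paste(pieces, collapse = spacer),
        overlap_flag = flag,
        report = list(dplyr::select(g, "fragment_id", "r_start", "r_end",
                                    "strand", "q_coverage"))
      )
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(out, .data$cluster_id)
}
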