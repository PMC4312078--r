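# Multilocus sequence analysis: marker concatenation, pairwise identity,
# Jukes-Cantor distances and greedy identity-threshold OTU binning.

#' Default marker locus order
#'
#' The five housekeeping loci used for the multilocus phylogeny, in
#' concatenation order. `locus_alias()` maps commonly seen alternative
#' spellings (`aptD` for `atpD`, `gyrB` for the gyrase locus) onto the
#' canonical names.
#'
#' @return Character vector of locus names.
#' @export
default_locus_order <- function() c("atpD", "gyrA", "recA", "rpoB", "trpB")

#' @rdname default_locus_order
#' @param locus Character vector of locus names to canonicalize.
#' @export
locus_alias <- function(locus) {
  dplyr::recode(locus, aptD = "atpD", gyrB = "gyrA")
}

#' Trim marker loci to a common length and concatenate them per strain
#'
#' Each locus is trimmed (from the 3' end) to the minimum length observed
#' for that locus across the retained strains, then the loci are
#' concatenated in `locus_order`. Strains missing one or more loci are
#' excluded with a warning, mirroring the practice of dropping genomes with
#' absent or unusable marker genes.
#'
#' @param markers Tibble with columns `strain_id`, `locus`, `sequence`
#'   (e.g. the `markers` element of [simulate_strains()]).
#' @param locus_order Character vector of locus names; alternative
#'   spellings are canonicalized via [locus_alias()].
#' @return A tibble of concatenated profiles: `strain_id`, `sequence`, and
#'   a `boundaries` list-column of tibbles (`locus`, `start`, `end`,
#'   1-based inclusive).
#' @examples
#' m <- tibble::tibble(
#'   strain_id = rep(c("A", "B"), each = 2),
#'   locus = rep(c("atpD", "recA"), 2),
#'   sequence = c("ACGTACGT", "GGGTTT", "ACGTAC", "GGGTTTAA")
#' )
#' trim_and_concatenate(m, c("atpD", "recA"))
#' @export
trim_and_concatenate <- function(markers, locus_order = default_locus_order()) {
  stopifnot(is.data.frame(markers),
            all(c("strain_id", "locus", "sequence") %in% names(markers)))
  markers <- dplyr::mutate(markers, locus = locus_alias(.data$locus))
  locus_order <- locus_alias(locus_order)
  unknown <- setdiff(markers$locus, locus_order)
  if (length(unknown)) {
    stop("unknown locus name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(markers$sequence) == 0)) {
    stop("empty marker sequence", call. = FALSE)
  }
  have <- markers |>
    dplyr::distinct(.data$strain_id, .data$locus) |>
    dplyr::count(.data$strain_id)
  complete <- have$strain_id[have$n == length(locus_order)]
  dropped <- setdiff(unique(markers$strain_id), complete)
  if (length(dropped)) {
    warning("excluding strain(s) missing loci: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(complete) == 0) {
    stop("no strain carries all loci in locus_order", call. = FALSE)
  }
  markers <- dplyr::filter(markers, .data$strain_id %in% complete)
  trim_len <- markers |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(len = min(nchar(.data$sequence)), .groups = "drop")
  lens <- stats::setNames(trim_len$len, trim_len$locus)[locus_order]
  starts <- cumsum(c(1, utils::head(lens, -1)))
  ends <- cumsum(lens)
  boundaries <- tibble::tibble(locus = locus_order,
                               start = as.integer(starts),
                               end = as.integer(ends))
  profiles <- lapply(sort(unique(markers$strain_id)), function(s) {
    rows <- dplyr::filter(markers, .data$strain_id == s)
    seqs <- stats::setNames(rows$sequence, rows$locus)[locus_order]
    tibble::tibble(
      strain_id = s,
      sequence = paste(substr(seqs, 1, lens), collapse = ""),
      boundaries = list(boundaries)
    )
  })
  dplyr::bind_rows(profiles)
}

#' Global-alignment nucleotide identity between two sequences
#'
#' Aligns the two sequences end to end (Needleman-Wunsch; match +1,
#' mismatch -1, gap open 5, gap extend 1) and reports the fraction of
#' identical columns among alignment columns, excluding terminal runs of
#' gap-containing columns so that incomplete fragment ends are not
#' penalized. `N` never counts as a match.
#'
#' @param a,b Nucleotide sequences (A/C/G/T/N).
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGT", "ACGA") # 0.75
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), nchar(a) > 0, nchar(b) > 0)
  check_nucleotides(a, "sequence 'a'")
  check_nucleotides(b, "sequence 'b'")
  if (a == b && !grepl("N", a, fixed = TRUE)) {
    return(1)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gapcol <- pa == "-" | pb == "-"
  # drop terminal runs of gap-containing columns
  keep <- rep(TRUE, length(pa))
  i <- 1L
  while (i <= length(pa) && gapcol[i]) {
    keep[i] <- FALSE
    i <- i + 1L
  }
  i <- length(pa)
  while (i >= 1 && gapcol[i]) {
    keep[i] <- FALSE
    i <- i - 1L
  }
  pa <- pa[keep]
  pb <- pb[keep]
  if (length(pa) == 0) {
    return(0)
  }
  matches <- sum(pa == pb & pa %in% c("A", "C", "G", "T"))
  matches / length(pa)
}

#' Jukes-Cantor distance from an observed proportion of differing sites
#'
#' Corrects the observed per-site difference `p` for multiple substitutions:
#' `d = -(3/4) log(1 - 4p/3)`. The correction saturates as `p` approaches
#' 3/4 (the expected difference between unrelated sequences); saturated
#' inputs raise an error rather than being silently capped, because capped
#' distances corrupt distance-based tree inference.
#'
#' @param p Observed fraction(s) of differing sites, each in `[0, 0.75)`.
#' @return Corrected distance(s) in substitutions per site.
#' @examples
#' jc_distance(0.03)
#' @export
jc_distance <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0)) stop("p must be >= 0", call. = FALSE)
  if (any(p >= 0.75)) {
    stop("saturated distance: p >= 0.75 is outside the Jukes-Cantor domain",
         call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise distance matrix for concatenated profiles
#'
#' Computes all pairwise identities with [pairwise_identity()] and returns
#' either the identity matrix, the observed-difference matrix (`p = 1 -
#' identity`) or the Jukes-Cantor-corrected distance matrix.
#'
#' @param profiles Tibble with an id column (first) and a `sequence`
#'   column, e.g. from [trim_and_concatenate()].
#' @param mode One of `"jc"`, `"p"`, `"identity"`.
#' @return A symmetric matrix with the profile ids as dimnames. Diagonal is
#'   0 in distance modes and 1 in identity mode.
#' @export
profile_distances <- function(profiles, mode = c("jc", "p", "identity")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(profiles), "sequence" %in% names(profiles),
            nrow(profiles) >= 2)
  ids <- as.character(profiles[[1]])
  stopifnot(!anyDuplicated(ids))
  n <- length(ids)
  m <- matrix(if (mode == "identity") 1 else 0, n, n,
              dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      id <- pairwise_identity(profiles$sequence[i], profiles$sequence[j])
      v <- switch(mode, identity = id, p = 1 - id, jc = jc_distance(1 - id))
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}

#' Greedy centroid OTU clustering at an identity threshold
#'
#' Processes sequences in order of decreasing length (ties broken by
#' lexicographic id). Each sequence joins the first existing centroid to
#' which its [pairwise_identity()] is at least `threshold`; otherwise it
#' founds a new OTU with itself as centroid. This is the greedy
#' centroid-list scheme used for species-level binning of concatenated
#' marker profiles (97% is the conventional species threshold).
#'
#' @param profiles Tibble with an id column (first) and a `sequence`
#'   column.
#' @param threshold Identity threshold in `(0, 1]`.
#' @return An `otu_assignment`: a tibble `id`, `otu`, `centroid_id`,
#'   `identity_to_centroid`, with the threshold stored as an attribute.
#' @examples
#' p <- tibble::tibble(id = c("a", "b"), sequence = c("ACGTACGT", "ACGTACGT"))
#' cluster_otus(p, 0.97)
#' @export
cluster_otus <- function(profiles, threshold = 0.97) {
  stopifnot(is.data.frame(profiles), "sequence" %in% names(profiles),
            nrow(profiles) >= 1)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  ids <- as.character(profiles[[1]])
  stopifnot(!anyDuplicated(ids))
  seqs <- stats::setNames(profiles$sequence, ids)
  ord <- order(-nchar(seqs), ids)
  centroids <- character(0)
  assignment <- list()
  for (i in ord) {
    id <- ids[i]
    hit <- NA_character_
    hit_id <- NA_real_
    for (c_id in centroids) {
      ident <- pairwise_identity(seqs[[id]], seqs[[c_id]])
      if (ident >= threshold) {
        hit <- c_id
        hit_id <- ident
        break
      }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, id)
      hit <- id
      hit_id <- 1
    }
    assignment[[length(assignment) + 1]] <- tibble::tibble(
      id = id, centroid_id = hit, identity_to_centroid = hit_id
    )
  }
  out <- dplyr::bind_rows(assignment) |>
    dplyr::mutate(otu = sprintf("OTU%03d", match(.data$centroid_id, centroids))) |>
    dplyr::select("id", "otu", "centroid_id", "identity_to_centroid")
  out <- out[match(ids, out$id), ]
  structure(tibble::as_tibble(out), threshold = threshold,
            class = c("otu_assignment", class(tibble::tibble())))
}

#' @export
tidy.otu_assignment <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.otu_assignment <- function(x, ...) {
  tibble::tibble(
    n_sequences = nrow(x),
    n_otus = length(unique(x$otu)),
    threshold = attr(x, "threshold")
  )
}
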