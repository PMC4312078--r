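# Synthetic strain sets with known core/auxiliary/specific family structure.
#
# The simulator emulates the inputs of a strain-level BGC survey: a set of
# cluster families shared by all / some / one of N strains, per-strain
# sequence divergence (substitutions + short indels), occasional duplicated
# clusters, and draft-assembly contig breaks that split clusters into
# fragments. Everything is driven by a single RNG stream so a given config
# always reproduces byte-identical output.

#' Configuration for a synthetic strain simulation
#'
#' Defaults describe a six-strain species with 18 core, 14 auxiliary and 16
#' strain-specific cluster families — the repertoire structure of the
#' *Streptomyces albus* clade — at within-species divergence, with
#' desk-scale cluster lengths.
#'
#' @param n_strains Number of strains (>= 2).
#' @param n_core,n_auxiliary,n_specific Family counts per category.
#'   Auxiliary families require `n_strains >= 3` (they must be present in at
#'   least 2 but fewer than all strains).
#' @param family_length_range Ancestor length range in bp (min >= 1000).
#' @param divergence Per-site substitution probability applied to each
#'   strain's copy relative to the family ancestor (so two strains' copies
#'   differ at roughly twice this rate). Must be < 0.75.
#' @param indel_rate Per-site probability of a short (1-10 bp) indel.
#' @param duplication_prob Probability that a strain carries a second,
#'   near-identical copy of a family it harbours.
#' @param fragmentation_prob Probability that a cluster copy is split by a
#'   contig breakpoint. When < 1, every family keeps at least one intact
#'   copy so the reference-anchored stitching workflow has an exemplar to
#'   anchor on (mirroring analyses anchored on a closed reference genome).
#' @param spacer_length_range Length range of intergenic spacer DNA between
#'   clusters on the simulated genome, in bp.
#' @param gc GC content of ancestors and spacers (0.72 mimics
#'   *Streptomyces*).
#' @param seed Integer RNG seed.
#' @return A `sim_config` list, validated.
#' @examples
#' sim_config(n_strains = 3, n_core = 2, n_auxiliary = 1, n_specific = 1)
#' @export
sim_config <- function(n_strains = 6, n_core = 18, n_auxiliary = 14,
                       n_specific = 16, family_length_range = c(1500, 3000),
                       divergence = 0.03, indel_rate = 5e-4,
                       duplication_prob = 0.05, fragmentation_prob = 0.1,
                       spacer_length_range = c(10000, 50000),
                       gc = 0.72, seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains), n_core = as.integer(n_core),
    n_auxiliary = as.integer(n_auxiliary), n_specific = as.integer(n_specific),
    family_length_range = as.integer(family_length_range),
    divergence = divergence, indel_rate = indel_rate,
    duplication_prob = duplication_prob,
    fragmentation_prob = fragmentation_prob,
    spacer_length_range = as.integer(spacer_length_range),
    gc = gc, seed = as.integer(seed)
  )
  if (cfg$n_strains < 2) stop("n_strains must be >= 2", call. = FALSE)
  if (any(c(cfg$n_core, cfg$n_auxiliary, cfg$n_specific) < 0)) {
    stop("family counts must be >= 0", call. = FALSE)
  }
  if (cfg$n_auxiliary > 0 && cfg$n_strains < 3) {
    stop("auxiliary families need n_strains >= 3 (presence in >= 2 but ",
         "fewer than all strains is impossible with 2 strains)",
         call. = FALSE)
  }
  if (cfg$divergence < 0 || cfg$divergence >= 0.75) {
    stop("divergence must be in [0, 0.75)", call. = FALSE)
  }
  if (cfg$indel_rate < 0 || cfg$indel_rate >= 1) {
    stop("indel_rate must be in [0, 1)", call. = FALSE)
  }
  if (length(cfg$family_length_range) != 2 ||
      cfg$family_length_range[1] < 1000 ||
      diff(cfg$family_length_range) < 0) {
    stop("family_length_range must be an increasing pair with min >= 1000",
         call. = FALSE)
  }
  for (p in c("duplication_prob", "fragmentation_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]",
                                           call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# uniform integer in [lo, hi], safe when lo == hi
rand_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# Substitutions then indels; returns the mutated sequence.
mutate_sequence <- function(seq, divergence, indel_rate = 0,
                            indel_len_range = c(1, 10)) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (divergence > 0) {
    hit <- which(stats::runif(n) < divergence)
    if (length(hit)) {
      alt <- c("A", "C", "G", "T")
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(alt, b), 1),
                        character(1))
    }
  }
  if (indel_rate > 0) {
    n_ev <- stats::rbinom(1, n, indel_rate)
    if (n_ev > 0) {
      # apply right-to-left so earlier positions stay valid
      pos <- sort(sample.int(n, n_ev), decreasing = TRUE)
      for (p in pos) {
        len <- rand_int(indel_len_range[1], indel_len_range[2])
        if (stats::runif(1) < 0.5) {
          ch <- ch[-(p:min(p + len - 1, length(ch)))]
        } else {
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          ch <- append(ch, ins, after = p)
        }
      }
    }
  }
  paste(ch, collapse = "")
}

#' Simulate strain cluster repertoires, draft assemblies and marker loci
#'
#' Draws one ancestor sequence per family, assigns families to strains
#' according to their category (core: all strains; auxiliary: a random
#' subset of 2 to `n_strains - 1`; specific: exactly one strain), mutates
#' each strain's copy at the configured divergence, optionally duplicates
#' copies within a strain, lays the clusters out on a genome with random
#' spacer DNA, and breaks the genome into contigs, splitting cluster copies
#' with probability `fragmentation_prob`. Marker loci are evolved along a
#' random coalescent tree over the strains.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `strain_simulation` with elements
#' \describe{
#'   \item{clusters}{tibble of emitted cluster records (one row per FASTA
#'     record): `strain_id`, `record_id`, `cluster_id` (the copy a fragment
#'     belongs to), `family_id`, `fragment` (logical), `contig_id`,
#'     `start`, `end` (1-based inclusive coordinates on the contig),
#'     `sequence`.}
#'   \item{contigs}{tibble `strain_id`, `contig_id`, `sequence`.}
#'   \item{markers}{tibble `strain_id`, `locus`, `sequence`.}
#'   \item{truth}{list with `family_of_cluster` (record_id -> family_id),
#'     `category_of_family`, `breakpoints` (cluster_id, position within the
#'     unsplit copy), `presence` (strain x family logical tibble),
#'     `ancestors` (family_id -> ancestor sequence), `marker_tree`
#'     (`ape::phylo`).}
#'   \item{config}{the input config.}
#' }
#' @examples
#' sim <- simulate_strains(sim_config(
#'   n_strains = 3, n_core = 2, n_auxiliary = 1, n_specific = 1,
#'   family_length_range = c(1000, 1200),
#'   spacer_length_range = c(2000, 3000), seed = 7
#' ))
#' dplyr::count(sim$clusters, strain_id)
#' @export
simulate_strains <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_strains_impl(config))
}

simulate_strains_impl <- function(cfg) {
  n <- cfg$n_strains
  strains <- sprintf("S%d", seq_len(n))
  n_fam <- cfg$n_core + cfg$n_auxiliary + cfg$n_specific
  fam_ids <- sprintf("F%02d", seq_len(max(n_fam, 1))[seq_len(n_fam)])
  category <- rep(c("core", "auxiliary", "specific"),
                  c(cfg$n_core, cfg$n_auxiliary, cfg$n_specific))

  ancestors <- vapply(fam_ids, function(f) {
    len <- rand_int(cfg$family_length_range[1], cfg$family_length_range[2])
    random_dna(len, cfg$gc)
  }, character(1))

  pick_one <- function(v) v[sample.int(length(v), 1)]
  membership <- lapply(seq_along(fam_ids), function(i) {
    switch(category[i],
      core = strains,
      auxiliary = sample(strains, pick_one(2:(n - 1))),
      specific = pick_one(strains)
    )
  })
  names(membership) <- fam_ids

  # one copy per (family, strain); duplicates are extra near-identical copies
  copies <- list()
  for (i in seq_along(fam_ids)) {
    f <- fam_ids[i]
    for (s in membership[[f]]) {
      seq <- mutate_sequence(ancestors[[f]], cfg$divergence, cfg$indel_rate)
      copies[[length(copies) + 1]] <- list(strain = s, family = f,
                                           sequence = seq, duplicate = FALSE)
      if (stats::runif(1) < cfg$duplication_prob) {
        dup <- mutate_sequence(seq, 0.005, 0)
        copies[[length(copies) + 1]] <- list(strain = s, family = f,
                                             sequence = dup, duplicate = TRUE)
      }
    }
  }
  copies <- dplyr::bind_rows(lapply(copies, tibble::as_tibble))
  copies <- copies |>
    dplyr::group_by(.data$strain) |>
    dplyr::mutate(cluster_id = sprintf("%s_c%02d", .data$strain,
                                       dplyr::row_number())) |>
    dplyr::ungroup()

  # fragmentation: per copy; unless fragmentation_prob == 1, guarantee each
  # family one intact copy (the stitching workflow's reference exemplar)
  split_flag <- stats::runif(nrow(copies)) < cfg$fragmentation_prob
  if (cfg$fragmentation_prob < 1) {
    for (f in unique(copies$family)) {
      idx <- which(copies$family == f)
      if (all(split_flag[idx])) {
        split_flag[idx[sample.int(length(idx), 1)]] <- FALSE
      }
    }
  }
  breakpoints <- vector("list", nrow(copies))
  for (i in which(split_flag)) {
    len <- nchar(copies$sequence[i])
    nb <- sample(1:2, 1, prob = c(0.8, 0.2))
    lo <- 200L
    hi <- len - 200L
    if (hi - lo < 200L * nb) { # too short to split cleanly
      split_flag[i] <- FALSE
      next
    }
    bp <- sort(sample(seq(lo, hi, by = 1), nb))
    while (nb == 2 && diff(bp) < 200) bp <- sort(sample(seq(lo, hi), nb))
    breakpoints[[i]] <- bp
  }

  # genome layout per strain: spacer, cluster, spacer, ..., spacer; contig
  # breaks at cluster breakpoints plus random breaks within half the spacers
  cluster_rows <- list()
  contig_rows <- list()
  for (s in strains) {
    idx <- which(copies$strain == s)
    idx <- idx[sample.int(length(idx))] # random order along the genome
    pieces <- character(0)       # genome pieces between contig breaks
    piece_meta <- list()         # cluster records carried by current piece
    cur <- random_dna(rand_int(cfg$spacer_length_range[1],
                               cfg$spacer_length_range[2]), cfg$gc)
    cur_meta <- list()
    flush <- function() {
      pieces[[length(pieces) + 1]] <<- cur
      piece_meta[[length(piece_meta) + 1]] <<- cur_meta
      cur <<- ""
      cur_meta <<- list()
    }
    for (i in idx) {
      seq <- copies$sequence[i]
      cid <- copies$cluster_id[i]
      bp <- breakpoints[[i]]
      if (is.null(bp)) {
        cur_meta[[length(cur_meta) + 1]] <- list(
          record_id = cid, cluster_id = cid, family = copies$family[i],
          fragment = FALSE, start = nchar(cur) + 1L,
          end = nchar(cur) + nchar(seq), sequence = seq
        )
        cur <- paste0(cur, seq)
      } else {
        starts <- c(1L, bp + 1L)
        ends <- c(bp, nchar(seq))
        for (k in seq_along(starts)) {
          frag <- substr(seq, starts[k], ends[k])
          cur_meta[[length(cur_meta) + 1]] <- list(
            record_id = sprintf("%s.f%d", cid, k), cluster_id = cid,
            family = copies$family[i], fragment = TRUE,
            start = nchar(cur) + 1L, end = nchar(cur) + nchar(frag),
            sequence = frag
          )
          cur <- paste0(cur, frag)
          if (k < length(starts)) flush() # contig break at the breakpoint
        }
      }
      spacer <- random_dna(rand_int(cfg$spacer_length_range[1],
                                    cfg$spacer_length_range[2]), cfg$gc)
      if (stats::runif(1) < 0.5) { # random break inside the spacer
        cut <- sample.int(nchar(spacer) - 1L, 1)
        cur <- paste0(cur, substr(spacer, 1, cut))
        flush()
        cur <- substr(spacer, cut + 1L, nchar(spacer))
      } else {
        cur <- paste0(cur, spacer)
      }
    }
    flush()
    for (j in seq_along(pieces)) {
      ctg <- sprintf("%s_ctg%03d", s, j)
      contig_rows[[length(contig_rows) + 1]] <- tibble::tibble(
        strain_id = s, contig_id = ctg, sequence = pieces[[j]]
      )
      for (m in piece_meta[[j]]) {
        cluster_rows[[length(cluster_rows) + 1]] <- tibble::tibble(
          strain_id = s, record_id = m$record_id, cluster_id = m$cluster_id,
          family_id = m$family, fragment = m$fragment, contig_id = ctg,
          start = m$start, end = m$end, sequence = m$sequence
        )
      }
    }
  }
  clusters <- dplyr::bind_rows(cluster_rows)
  contigs <- dplyr::bind_rows(contig_rows)

  # markers along a coalescent tree scaled to ~2% maximum depth
  marker_tree <- ape::rcoal(n, tip.label = strains)
  marker_tree$edge.length <- marker_tree$edge.length /
    max(ape::node.depth.edgelength(marker_tree)) * 0.01
  markers <- evolve_markers(marker_tree, seed = sample.int(2^30, 1))

  bp_tbl <- dplyr::bind_rows(lapply(which(split_flag), function(i) {
    tibble::tibble(cluster_id = copies$cluster_id[i],
                   position = breakpoints[[i]])
  }))
  if (nrow(bp_tbl) == 0) {
    bp_tbl <- tibble::tibble(cluster_id = character(), position = integer())
  }

  presence <- tibble::tibble(family_id = fam_ids)
  for (s in strains) {
    presence[[s]] <- vapply(fam_ids, function(f) s %in% membership[[f]],
                            logical(1))
  }

  truth <- list(
    family_of_cluster = dplyr::distinct(
      dplyr::select(clusters, "record_id", "cluster_id", "family_id")
    ),
    category_of_family = tibble::tibble(family_id = fam_ids,
                                        category = category),
    breakpoints = bp_tbl,
    presence = presence,
    ancestors = ancestors,
    marker_tree = marker_tree
  )
  structure(list(clusters = clusters, contigs = contigs, markers = markers,
                 truth = truth, config = cfg),
            class = "strain_simulation")
}

#' Evolve marker-locus sequences along a phylogeny
#'
#' Simulates independent-site nucleotide evolution under the Jukes-Cantor
#' model: along a branch of length `t` (substitutions/site, scaled by
#' `substitution_rate`) each site differs from its parent with probability
#' `(3/4)(1 - exp(-4t/3))`, and a differing site is replaced by one of the
#' three other bases uniformly.
#'
#' @param tree An `ape::phylo` with positive branch lengths and >= 2 leaves.
#' @param locus_lengths Named integer vector of locus lengths in bp. The
#'   default five housekeeping loci total 2566 nt.
#' @param substitution_rate Multiplier applied to branch lengths.
#' @param seed Integer RNG seed.
#' @return A tibble `strain_id`, `locus`, `sequence` (one row per leaf per
#'   locus).
#' @examples
#' tr <- ape::read.tree(text = "(A:0.01,B:0.01);")
#' evolve_markers(tr, c(atpD = 100, recA = 120), seed = 1)
#' @export
evolve_markers <- function(tree,
                           locus_lengths = c(atpD = 500, gyrA = 400,
                                             recA = 600, rpoB = 566,
                                             trpB = 500),
                           substitution_rate = 1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("tree needs >= 2 leaves", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have non-negative branch lengths", call. = FALSE)
  }
  if (any(locus_lengths <= 0)) stop("zero-length locus", call. = FALSE)
  if (is.null(names(locus_lengths))) {
    names(locus_lengths) <- sprintf("locus%d", seq_along(locus_lengths))
  }
  withr::with_seed(as.integer(seed), {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    out <- list()
    for (locus in names(locus_lengths)) {
      len <- locus_lengths[[locus]]
      seqs <- vector("list", ntip + tree$Nnode)
      seqs[[root]] <- strsplit(random_dna(len, 0.5), "", fixed = TRUE)[[1]]
      # preorder: parents before children
      ord <- ape::reorder.phylo(tree, "cladewise")
      for (r in seq_len(nrow(ord$edge))) {
        par <- ord$edge[r, 1]
        child <- ord$edge[r, 2]
        t <- ord$edge.length[r] * substitution_rate
        p_diff <- 0.75 * (1 - exp(-4 * t / 3))
        ch <- seqs[[par]]
        hit <- which(stats::runif(len) < p_diff)
        if (length(hit)) {
          ch[hit] <- vapply(ch[hit],
                            function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                            character(1))
        }
        seqs[[child]] <- ch
      }
      for (tip in seq_len(ntip)) {
        out[[length(out) + 1]] <- tibble::tibble(
          strain_id = tree$tip.label[tip], locus = locus,
          sequence = paste(seqs[[tip]], collapse = "")
        )
      }
    }
    dplyr::arrange(dplyr::bind_rows(out), .data$strain_id)
  })
}

#' Write a simulation to FASTA files and a JSON truth record
#'
#' Emits `{strain}.clusters.fasta`, `{strain}.contigs.fasta`,
#' `{strain}.markers.fasta` (marker ids `{strain}|{locus}`) and
#' `truth.json` under `dir`.
#'
#' @param sim A [simulate_strains()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "strain_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in unique(sim$clusters$strain_id)) {
    cl <- dplyr::filter(sim$clusters, .data$strain_id == s)
    write_fasta(dplyr::select(cl, "record_id", "sequence"),
                file.path(dir, paste0(s, ".clusters.fasta")))
    ct <- dplyr::filter(sim$contigs, .data$strain_id == s)
    write_fasta(dplyr::select(ct, "contig_id", "sequence"),
                file.path(dir, paste0(s, ".contigs.fasta")))
    mk <- dplyr::filter(sim$markers, .data$strain_id == s) |>
      dplyr::mutate(id = paste0(.data$strain_id, "|", .data$locus))
    write_fasta(dplyr::select(mk, "id", "sequence"),
                file.path(dir, paste0(s, ".markers.fasta")))
  }
  truth <- sim$truth
  write_json_stable(list(
    family_of_cluster = truth$family_of_cluster,
    category_of_family = truth$category_of_family,
    breakpoints = truth$breakpoints,
    presence = truth$presence,
    marker_tree = write_newick(truth$marker_tree),
    config = unclass(sim$config)
  ), file.path(dir, "truth.json"))
  invisible(dir)
}

#' @export
print.strain_simulation <- function(x, ...) {
  cat("<strain_simulation>\n")
  cat("  strains:  ", x$config$n_strains, "\n")
  cat("  families: ", nrow(x$truth$category_of_family), "(",
      paste(table(x$truth$category_of_family$category)[
        c("core", "auxiliary", "specific")], collapse = "/"), ")\n")
  cat("  cluster records:", nrow(x$clusters),
      sprintf("(%d fragments)", sum(x$clusters$fragment)), "\n")
  cat("  contigs:  ", nrow(x$contigs), "\n")
  invisible(x)
}
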