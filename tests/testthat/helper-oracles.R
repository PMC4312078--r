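# Independent oracles and fixture builders used across the test files.

rand_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# substitute exactly k sites (no two at the same position)
mutate_k_sites <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1))
  paste(ch, collapse = "")
}

# substitute each site independently with probability q
mutate_rate <- function(seq, q) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < q)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

# --- brute-force MUM oracle --------------------------------------------------
# Walks every diagonal of the character match matrix, takes maximal runs of
# matching A/C/G/T columns, then keeps runs whose matched substring occurs
# exactly once in the (strand-oriented) query and once in the reference,
# counting occurrences by direct sliding-window comparison.
oracle_mums <- function(query, reference, min_len) {
  count_occ <- function(pat, s) {
    pc <- strsplit(pat, "")[[1]]
    sc <- strsplit(s, "")[[1]]
    L <- length(pc)
    if (length(sc) < L) return(0L)
    sum(vapply(seq_len(length(sc) - L + 1),
               function(i) all(sc[i:(i + L - 1)] == pc), logical(1)))
  }
  one_strand <- function(q) {
    qc <- strsplit(q, "")[[1]]
    rcv <- strsplit(reference, "")[[1]]
    nq <- length(qc)
    nr <- length(rcv)
    hits <- list()
    for (d in seq(-(nr - 1), nq - 1)) {
      qs <- max(1L, 1L + d)
      rs <- qs - d
      len <- min(nq - qs, nr - rs) + 1L
      if (len < min_len) next
      eq <- qc[qs:(qs + len - 1)] == rcv[rs:(rs + len - 1)] &
        qc[qs:(qs + len - 1)] %in% c("A", "C", "G", "T")
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= min_len)) {
        a_qs <- qs + starts[k] - 1L
        a_rs <- rs + starts[k] - 1L
        pat <- substr(q, a_qs, a_qs + r$lengths[k] - 1L)
        if (count_occ(pat, q) == 1L && count_occ(pat, reference) == 1L) {
          hits[[length(hits) + 1]] <- data.frame(
            q_start = a_qs, r_start = a_rs, length = r$lengths[k]
          )
        }
      }
    }
    if (length(hits) == 0) {
      return(data.frame(q_start = integer(), r_start = integer(),
                        length = integer()))
    }
    do.call(rbind, hits)
  }
  fwd <- one_strand(query)
  fwd$strand <- rep("+", nrow(fwd))
  bwd <- one_strand(rc(query))
  if (nrow(bwd)) {
    n <- nchar(query)
    q_end_rc <- bwd$q_start + bwd$length - 1L
    bwd$q_start <- n - q_end_rc + 1L
  }
  bwd$strand <- rep("-", nrow(bwd))
  out <- rbind(fwd, bwd)
  out$q_end <- out$q_start + out$length - 1L
  out$r_end <- out$r_start + out$length - 1L
  out[order(out$r_start, out$q_start, out$strand),
      c("q_start", "q_end", "r_start", "r_end", "length", "strand")]
}

# --- exhaustive chain oracle -------------------------------------------------
# Enumerates every collinear anchor subset (<= 12 anchors) and returns the
# maximum score under the same trimmed-overlap scoring as the chainer.
oracle_chain_score <- function(anchors) {
  n <- nrow(anchors)
  stopifnot(n <= 12)
  if (n == 0) return(0)
  strand <- anchors$strand[1]
  if (strand == "-") {
    us <- -anchors$q_end
    ue <- -anchors$q_start
  } else {
    us <- anchors$q_start
    ue <- anchors$q_end
  }
  rs <- anchors$r_start
  re <- anchors$r_end
  len <- anchors$length
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0) next
    idx <- idx[order(us[idx])]
    ok <- TRUE
    score <- len[idx[1]]
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        a <- idx[k - 1]
        b <- idx[k]
        if (!(us[a] < us[b] && rs[a] < rs[b])) {
          ok <- FALSE
          break
        }
        gain <- len[b] - max(0, ue[a] - us[b] + 1, re[a] - rs[b] + 1)
        if (gain <= 0) {
          ok <- FALSE
          break
        }
        score <- score + gain
      }
    }
    if (ok) best <- max(best, score)
  }
  best
}

# --- misc --------------------------------------------------------------------

# connected components by repeated flood fill over a logical adjacency matrix
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- which(adj[f, ] & is.na(comp))
        comp[nb] <- cur
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  comp
}

# random additive tree with distinct branch lengths plus its path-distance
# matrix (from the tree itself, not from any NJ code)
random_additive_case <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.1, 1))
  tr$tip.label <- sprintf("t%02d", seq_len(ntaxa))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
  list(tree = tr, dm = dm)
}

# 120 concatenated profiles built as n_seed species plus satellites within
# sat_div of their seed; seeds are mutually unrelated random sequences
otu_test_profiles <- function(n_total = 120, n_seed = 82, len = 600,
                              sat_div = 0.008) {
  seeds <- vapply(seq_len(n_seed), function(i) rand_seq(len), character(1))
  ids <- sprintf("seed%03d", seq_len(n_seed))
  seqs <- seeds
  n_sat <- n_total - n_seed
  for (k in seq_len(n_sat)) {
    owner <- ((k - 1) %% n_seed) + 1
    ids <- c(ids, sprintf("sat%03d_of_%03d", k, owner))
    seqs <- c(seqs, mutate_rate(seeds[owner], sat_div))
  }
  tibble::tibble(id = ids, sequence = seqs)
}
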