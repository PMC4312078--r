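test_that("find_mums handles the canonical small examples", {
  a <- find_mums("GATTACA", "TTGATTACCA", min_len = 4)
  expect_equal(nrow(a), 1)
  expect_equal(a$q_start, 1)
  expect_equal(a$q_end, 6)
  expect_equal(a$r_start, 3)
  expect_equal(a$r_end, 8)
  expect_equal(a$length, 6)
  expect_equal(a$strand, "+")

  withr::local_seed(21)
  s <- rand_seq(500)
  # a sequence against itself: one full-length forward anchor (short
  # reverse-complement-palindromic anchors may additionally appear on the
  # minus strand and are genuine matches)
  self <- find_mums(s, s, min_len = 8)
  fwd <- self[self$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$q_start, 1)
  expect_equal(fwd$r_end, 500)
  expect_true(all(self$length[self$strand == "-"] < 500))

  flip <- find_mums(rc(s), s, min_len = 8)
  bwd <- flip[flip$strand == "-", ]
  expect_equal(nrow(bwd), 1)
  expect_equal(bwd$length, 500)
  expect_error(find_mums("ACGT", "ACGT", min_len = 2), "min_len")
})

test_that("matches never span N and uniqueness is enforced", {
  left <- "ACGTACGTCCGG"
  # same 12-mer twice in the reference: not unique, so no anchor
  ref2 <- paste0("TT", left, "AA", left, "TT")
  expect_equal(nrow(find_mums(left, ref2, min_len = 12)), 0)
  # an N in the query breaks the match
  q <- paste0(substr(left, 1, 6), "N", substr(left, 8, 12))
  a <- find_mums(q, paste0("TT", left, "GG"), min_len = 4)
  expect_true(all(a$length <= 6))
  expect_false(any(mapply(function(s, e) grepl("N", substr(q, s, e)),
                          a$q_start, a$q_end)))
})

test_that("find_mums agrees with the brute-force oracle", {
  withr::local_seed(22)
  n_cases <- 40
  for (k in seq_len(n_cases)) {
    nq <- sample(20:120, 1)
    nr <- sample(20:120, 1)
    q <- rand_seq(nq)
    r <- rand_seq(nr)
    style <- k %% 4
    if (style == 1) { # plant a shared forward segment
      seg <- rand_seq(sample(10:25, 1))
      q <- paste0(substr(q, 1, 10), seg, substr(q, 11, nq))
      r <- paste0(substr(r, 1, 5), seg, substr(r, 6, nr))
    } else if (style == 2) { # plant a reverse-complement segment
      seg <- rand_seq(sample(10:25, 1))
      q <- paste0(q, seg)
      r <- paste0(rc(seg), r)
    } else if (style == 3) { # diverged copy: many maximal matches
      r <- mutate_rate(q, 0.08)
    }
    ml <- sample(c(4L, 6L, 8L), 1)
    got <- find_mums(q, r, min_len = ml)
    want <- oracle_mums(q, r, min_len = ml)
    got <- got[order(got$r_start, got$q_start, got$strand), ]
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE,
                 info = sprintf("case %d (style %d, min_len %d)", k, style, ml))
  }
})

test_that("chain_anchors selects the optimal collinear chain", {
  one <- tibble::tibble(q_start = 5L, q_end = 14L, r_start = 3L, r_end = 12L,
                        length = 10L, strand = "+")
  ch <- chain_anchors(one)
  expect_equal(ch$score, 10)
  expect_equal(nrow(ch$anchors), 1)

  two <- tibble::tibble(
    q_start = c(1L, 21L), q_end = c(10L, 30L),
    r_start = c(1L, 21L), r_end = c(10L, 30L),
    length = c(10L, 10L), strand = "+"
  )
  expect_equal(chain_anchors(two)$score, 20)
  expect_equal(chain_anchors(two)$covered_q, 20)

  # crossing anchors: only one can be kept, the one with smaller r_start
  # wins the tie on score
  crossing <- tibble::tibble(
    q_start = c(1L, 21L), q_end = c(10L, 30L),
    r_start = c(51L, 1L), r_end = c(60L, 10L),
    length = c(10L, 10L), strand = "+"
  )
  ch <- chain_anchors(crossing)
  expect_equal(ch$score, 10)
  expect_equal(nrow(ch$anchors), 1)
  expect_equal(ch$anchors$r_start, 1L)

  expect_equal(chain_anchors(NULL)$score, 0)
  expect_error(chain_anchors(dplyr::mutate(two, strand = c("+", "-"))),
               "one strand")
})

test_that("chain scores match exhaustive enumeration on random anchor sets", {
  withr::local_seed(23)
  for (rep in 1:40) {
    n <- sample(1:8, 1)
    anchors <- tibble::tibble(
      q_start = sample(1:80, n),
      r_start = sample(1:80, n),
      length = sample(5:15, n, replace = TRUE),
      strand = sample(c("+", "-"), 1)
    )
    anchors$q_end <- anchors$q_start + anchors$length - 1L
    anchors$r_end <- anchors$r_start + anchors$length - 1L
    expect_equal(chain_anchors(anchors)$score, oracle_chain_score(anchors),
                 info = sprintf("rep %d", rep))
  }
})

test_that("chain score never decreases when anchors are added", {
  withr::local_seed(24)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    anchors <- tibble::tibble(
      q_start = sample(1:60, n), r_start = sample(1:60, n),
      length = sample(5:12, n, replace = TRUE), strand = "+"
    )
    anchors$q_end <- anchors$q_start + anchors$length - 1L
    anchors$r_end <- anchors$r_start + anchors$length - 1L
    sub <- anchors[seq_len(n - 1), ]
    expect_lte(chain_anchors(sub)$score, chain_anchors(anchors)$score)
  }
})

test_that("fragments are assigned to the right reference", {
  withr::local_seed(25)
  refs <- tibble::tibble(
    id = c("r1", "r2", "r3"),
    sequence = vapply(rep(3000, 3), rand_seq, character(1))
  )
  # exact substring: coverage 1, unambiguous
  frag <- substr(refs$sequence[2], 1001, 2500)
  a <- assign_fragment(frag, refs)
  expect_equal(a$reference_id, "r2")
  expect_equal(a$q_coverage, 1)
  expect_false(a$ambiguous)
  expect_equal(a$r_start, 1001L)
  expect_equal(a$r_end, 2500L)

  # random sequence: no assignment
  a0 <- assign_fragment(rand_seq(5000), refs)
  expect_true(is.na(a0$reference_id))

  # diverged fragment (2% pairwise) still finds its true reference
  frag2 <- mutate_rate(substr(refs$sequence[3], 501, 2300), 0.02)
  a2 <- assign_fragment(frag2, refs)
  expect_equal(a2$reference_id, "r3")
  expect_false(a2$ambiguous)

  # reverse-complement fragment: minus strand
  a3 <- assign_fragment(rc(frag), refs)
  expect_equal(a3$reference_id, "r2")
  expect_equal(a3$strand, "-")
})

test_that("assignment recovers >= 95% of 2-kb fragments at 5% divergence", {
  withr::local_seed(26)
  refs <- tibble::tibble(
    id = sprintf("ref%02d", 1:10),
    sequence = vapply(rep(4000, 10), rand_seq, character(1))
  )
  n_frag <- 40
  truth <- sample(10, n_frag, replace = TRUE)
  frags <- tibble::tibble(
    id = sprintf("f%02d", seq_len(n_frag)),
    sequence = vapply(truth, function(j) {
      start <- sample(1:1800, 1)
      mutate_rate(substr(refs$sequence[j], start, start + 2099), 0.05)
    }, character(1))
  )
  asg <- assign_fragments(frags, refs)
  correct <- asg$reference_id == refs$id[truth]
  expect_gte(mean(correct, na.rm = TRUE) * mean(!is.na(correct)), 0.95)
})

test_that("stitching reassembles split clusters in reference order", {
  withr::local_seed(27)
  ref <- rand_seq(3000)
  refs <- tibble::tibble(id = "anc", sequence = ref)
  pieces <- c(substr(ref, 1, 900), substr(ref, 901, 2100),
              substr(ref, 2101, 3000))
  frags <- tibble::tibble(id = c("p2", "p3", "p1"),
                          sequence = pieces[c(2, 3, 1)])
  st <- stitch(assign_fragments(frags, refs), frags, spacer_n = 100)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_fragments, 3)
  expect_equal(st$fragment_ids[[1]], c("p1", "p2", "p3")) # reference order
  expect_identical(gsub("N", "", st$sequence, fixed = TRUE), ref)
  expect_false(st$overlap_flag)

  # single fragment: stitched sequence is the fragment itself, no spacer
  one <- stitch(assign_fragments(frags[3, ], refs), frags[3, ])
  expect_identical(one$sequence, frags$sequence[3])

  # minus-strand fragments come out reference-oriented
  frc <- tibble::tibble(id = c("a", "b"),
                        sequence = c(rc(pieces[1]), pieces[2]))
  st2 <- stitch(assign_fragments(frc, refs), frc, spacer_n = 10)
  expect_identical(gsub("N", "", st2$sequence, fixed = TRUE),
                   substr(ref, 1, 2100))
})

test_that("stitching separates references and flags heavy overlaps", {
  withr::local_seed(28)
  r1 <- rand_seq(2500)
  r2 <- rand_seq(2500)
  refs <- tibble::tibble(id = c("r1", "r2"), sequence = c(r1, r2))
  frags <- tibble::tibble(
    id = c("x1", "x2", "y1"),
    sequence = c(substr(r1, 1, 1200), substr(r1, 1201, 2500),
                 substr(r2, 301, 1900))
  )
  st <- stitch(assign_fragments(frags, refs), frags)
  expect_equal(nrow(st), 2) # one stitched record per reference
  expect_setequal(st$cluster_id, c("r1", "r2"))

  # two fragments covering mostly the same reference interval: flagged but
  # still emitted
  dup <- tibble::tibble(
    id = c("d1", "d2"),
    sequence = c(substr(r1, 101, 1600), substr(r1, 201, 1700))
  )
  st_dup <- stitch(assign_fragments(dup, refs), dup)
  expect_equal(nrow(st_dup), 1)
  expect_true(st_dup$overlap_flag)

  # ambiguous assignments are excluded with a message
  asg <- assign_fragments(dup, refs)
  asg$ambiguous[1] <- TRUE
  expect_message(st_amb <- stitch(asg, dup), "ambiguous")
  expect_equal(st_amb$n_fragments, 1)
})
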