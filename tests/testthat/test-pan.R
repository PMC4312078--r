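test_that("cluster_similarity behaves at the extremes and mid-range", {
  withr::local_seed(31)
  s <- rand_seq(5000)
  expect_equal(cluster_similarity(s, s), 1)
  # unrelated sequences share essentially nothing
  expect_lt(cluster_similarity(rand_seq(10000), rand_seq(10000)), 0.05)
  # same-family pair at 3% pairwise divergence stays well above the
  # family threshold
  expect_gte(cluster_similarity(s, mutate_rate(s, 0.03)), 0.8)
  # a fragment against its full-length source scores on the fragment
  expect_equal(cluster_similarity(substr(s, 1001, 3000), s), 1)
  expect_error(cluster_similarity("", s), "non-empty")
})

test_that("within-strain dedup collapses duplicates, keeping the longest", {
  withr::local_seed(32)
  base <- rand_seq(2000)
  longer <- paste0(base, rand_seq(50))
  cl <- tibble::tibble(
    strain_id = "s1",
    cluster_id = c("c1", "c2", "c3"),
    sequence = c(base, longer, rand_seq(2000))
  )
  out <- dedup_within_strain(cl, threshold = 0.9)
  expect_setequal(out$cluster_id, c("c2", "c3")) # c2 is the longer copy
  rm <- attr(out, "removed")
  expect_equal(rm$cluster_id, "c1")
  expect_equal(rm$kept, "c2")

  # the duplicated-cluster pattern: a strain harbouring two near-identical
  # copies counts the family once
  dup_pair <- tibble::tibble(
    strain_id = "s1", cluster_id = c("nrps_a", "nrps_b"),
    sequence = c(base, mutate_rate(base, 0.005))
  )
  expect_equal(nrow(dedup_within_strain(dup_pair)), 1)

  # all-distinct input is unchanged
  distinct <- tibble::tibble(
    strain_id = "s1", cluster_id = c("a", "b"),
    sequence = c(rand_seq(1500), rand_seq(1500))
  )
  expect_equal(dedup_within_strain(distinct), distinct, ignore_attr = TRUE)
  expect_error(
    dedup_within_strain(dplyr::mutate(distinct, strain_id = c("s1", "s2"))),
    "single strain"
  )
})

test_that("family building matches brute-force graph components", {
  withr::local_seed(33)
  anc <- list(f1 = rand_seq(2000), f2 = rand_seq(2400), f3 = rand_seq(1800))
  rows <- list()
  for (s in c("A", "B", "C")) {
    for (f in names(anc)) {
      if (f == "f3" && s != "C") next # f3 only in strain C
      rows[[length(rows) + 1]] <- tibble::tibble(
        strain_id = s, cluster_id = paste(s, f, sep = "_"),
        sequence = mutate_rate(anc[[f]], 0.03)
      )
    }
  }
  cl <- dplyr::bind_rows(rows)
  fam <- build_families(cl, threshold = 0.5)
  expect_equal(length(unique(fam$families$family_id)), 3)
  # members group exactly by ancestor
  grp <- split(fam$families$cluster_id, fam$families$family_id)
  expect_setequal(
    vapply(grp, function(g) paste(sort(sub("^._", "", g)), collapse = "+"),
           character(1)),
    c("f1+f1+f1", "f2+f2+f2", "f3")
  )
  # brute-force single-linkage components over the similarity matrix
  n <- nrow(cl)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <-
        cluster_similarity(cl$sequence[i], cl$sequence[j]) >= 0.5
    }
  }
  comp <- oracle_components(adj)
  fam_code <- match(fam$families$family_id, unique(fam$families$family_id))
  expect_equal(outer(comp, comp, `==`), outer(fam_code, fam_code, `==`))

  # presence matrix: f3 in C only, others everywhere
  pa <- fam$presence
  k <- rowSums(as.matrix(tibble::as_tibble(pa)[-1]))
  expect_setequal(k, c(3, 3, 1))
})

test_that("families sharing no anchors are never merged", {
  withr::local_seed(34)
  cl <- tibble::tibble(
    strain_id = c("A", "B"),
    cluster_id = c("x", "y"),
    sequence = c(rand_seq(3000), rand_seq(3000))
  )
  fam <- build_families(cl, threshold = 0.5)
  expect_equal(length(unique(fam$families$family_id)), 2)
})

test_that("partitioning implements the core/auxiliary/specific rule", {
  fx <- read_presence_fixture()
  part <- partition_families(fx$presence)
  g <- glance(part)
  expect_equal(g$core, 18)
  expect_equal(g$auxiliary, 14)
  expect_equal(g$specific, 16)
  expect_equal(g$n_families, 48)
  expect_equal(g$core + g$auxiliary + g$specific, g$n_families)

  one_all <- presence_matrix(tibble::tibble(
    family_id = "f", A = TRUE, B = TRUE, C = TRUE
  ))
  expect_equal(partition_families(one_all)$category, "core")
  two_of_six <- presence_matrix(tibble::tibble(
    family_id = "f", a = TRUE, b = TRUE, c = FALSE, d = FALSE, e = FALSE,
    f = FALSE
  ))
  expect_equal(partition_families(two_of_six)$category, "auxiliary")
  expect_error(presence_matrix(tibble::tibble(
    family_id = "f", A = FALSE, B = FALSE
  )), "at least one")
})

test_that("pan_matrix reproduces counts, floor percentages and uniques", {
  fx <- read_presence_fixture()
  pm <- pan_matrix(fx$presence)
  expect_true(isSymmetric(pm$shared))
  expect_equal(unname(diag(pm$shared)), unname(pm$totals))
  expect_equal(sum(pm$unique_counts),
               sum(partition_families(fx$presence)$category == "specific"))
  # floor truncation, not rounding
  expect_equal(pm$percent["GBA-94-10", "SM8"], 65) # 19/29
  expect_equal(pm$percent["PVA-94-07", "SM8"], 66) # 20/30
  expect_equal(pm$percent["PVA-94-07", "GBA-94-10"], 93) # 28/30
  # identical repertoires degenerate correctly
  twin <- presence_matrix(tibble::tibble(
    family_id = c("f1", "f2"), A = c(TRUE, TRUE), B = c(TRUE, TRUE)
  ))
  pm2 <- pan_matrix(twin)
  expect_equal(unname(pm2$shared["A", "B"]), 2)
  expect_equal(unname(pm2$percent["A", "B"]), 100)
  expect_equal(unname(pm2$unique_counts), c(0, 0))
})

test_that("strain order does not affect pan matrix content", {
  fx <- read_presence_fixture()
  pm <- pan_matrix(fx$presence)
  perm <- c("S4", "J1074", "SM8", "GBA-94-10", "LaPpAH-202", "PVA-94-07")
  pa2 <- presence_matrix(
    dplyr::select(tibble::as_tibble(fx$presence),
                  "family_id", dplyr::all_of(perm))
  )
  pm2 <- pan_matrix(pa2)
  expect_equal(pm2$shared[perm, perm], pm$shared[perm, perm])
  expect_equal(pm2$percent[perm, perm], pm$percent[perm, perm])
  expect_equal(pm2$unique_counts[perm], pm$unique_counts[perm])
})

test_that("exclusive_shared counts exact presence patterns", {
  fx <- read_presence_fixture()
  expect_equal(exclusive_shared(fx$presence, c("PVA-94-07", "GBA-94-10")), 8)
  expect_equal(exclusive_shared(fx$presence, pa <- names(fx$presence)[-1]), 18)
  expect_equal(exclusive_shared(fx$presence, "J1074"), 2)
  expect_error(exclusive_shared(fx$presence, "nope"), "unknown strain")
  expect_error(exclusive_shared(fx$presence, character(0)), "non-empty")
})

test_that("the packaged fixture carries the published repertoires", {
  fx <- read_presence_fixture()
  pres <- tibble::as_tibble(fx$presence)
  lab <- fx$labels
  row_of <- function(prod) pres[match(prod, lab$product), ]
  cand <- row_of("Candicidin")
  expect_true(all(unlist(cand[-1])))
  indi <- row_of("Indigoidin")
  expect_equal(names(indi[-1])[unlist(indi[-1])], c("J1074", "LaPpAH-202"))
  paul <- row_of("Paulomycin")
  expect_equal(names(paul[-1])[unlist(paul[-1])], "J1074")
  # tampering is caught by the checksum
  tmp <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines(system.file("extdata", "albus_bgc_presence.tsv",
                                 package = "panbgc"))
  lines[2] <- sub("1", "0", lines[2])
  writeLines(lines, tmp)
  expect_error(read_presence_fixture(tmp), "checksum")
})

test_that("reproduce_table2 flags the inconsistent published SM8 total", {
  pm <- reproduce_table2()
  expect_equal(unname(pm$totals[["SM8"]]), 24)
  expect_match(pm$notes, "SM8", all = FALSE)
  ft <- format_pan_matrix(pm)
  expect_equal(ft[[2]][1], "25 (100%)")
})

test_that("the pipeline recovers a small known family structure", {
  sim <- simulate_strains(sim_config(
    n_strains = 4, n_core = 3, n_auxiliary = 2, n_specific = 2,
    family_length_range = c(1000, 1500),
    spacer_length_range = c(2000, 3000), seed = 35
  ))
  res <- pan_pipeline(sim$clusters)
  g <- glance(res)
  expect_equal(c(g$core, g$auxiliary, g$specific), c(3, 2, 2))
  expect_equal(g$n_families, 7)
})
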