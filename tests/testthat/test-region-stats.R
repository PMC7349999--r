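test_that("disorder content reproduces the dataset-level percentages", {
  ldr_row <- list(missing = 270656, observed = 1140513, unknown = 509174)
  expect_equal(round_half_up(100 * disorder_content(ldr_row)), 14.1)
  expect_equal(
    round_half_up(100 * disorder_content(ldr_row, exclude_unknown = TRUE)),
    19.2)

  structured_row <- list(missing = 28338, observed = 4242966,
                         unknown = 2485372)
  expect_equal(round_half_up(100 * disorder_content(structured_row)), 0.4)

  total_row <- list(missing = 602605, observed = 10108201,
                    unknown = 5782003)
  expect_equal(round_half_up(100 * disorder_content(total_row)), 3.7)

  expect_equal(disorder_content(list(missing = 0, observed = 10,
                                     unknown = 5)), 0)
  expect_error(disorder_content(list(missing = 0, observed = 0,
                                     unknown = 0)), "denominator")
})

make_track <- function(states, pid, rule = "majority") {
  structure(list(protein_id = pid, rule = rule, states = states,
                 coverage = as.integer(states != "U")),
            class = "consensus_track")
}

test_that("dataset summary tallies a hand-built three-protein fixture", {
  tracks <- list(
    PA = make_track(c(rep("D", 35), rep("S", 55), rep("U", 10)), "PA"),
    PB = make_track(c(rep("S", 20), rep("D", 10), rep("S", 50)), "PB"),
    PC = make_track(rep("S", 60), "PC"))
  regions <- data.frame(
    protein_id = c("PA", "PB"), rule = "majority",
    start = c(1L, 21L), end = c(35L, 30L), length = c(35L, 10L),
    class = c("LDR", "SDR"), stringsAsFactors = FALSE)
  classes <- data.frame(
    protein_id = c("PA", "PB", "PC"),
    category = c("LDR-protein", "SDR-protein", "structured"),
    fully_disordered = FALSE, stringsAsFactors = FALSE)

  summ <- summarize_dataset(classes, tracks, regions)
  expect_equal(summ$n_proteins, c(1L, 1L, 1L, 3L))
  expect_equal(summ$n_ldr, c(1L, 0L, 0L, 1L))
  expect_equal(summ$n_sdr, c(0L, 1L, 0L, 1L))
  expect_equal(summ$median_length, c(100, 80, 60, 80))
  expect_equal(summ$missing[summ$category == "LDR-protein"], 35L)
  expect_equal(summ$unknown[summ$category == "LDR-protein"], 10L)
  expect_equal(summ$missing_pct[summ$category == "LDR-protein"], 35.0)

  # total row is the column-wise sum of category rows
  total <- summ[summ$category == "total", ]
  cats <- summ[summ$category != "total", ]
  for (col in c("n_proteins", "n_sdr", "n_ldr", "missing", "observed",
                "unknown")) {
    expect_equal(total[[col]], sum(cats[[col]]))
  }
  # stored percentages recompute from raw counts to 1 d.p.
  tot_res <- summ$missing + summ$observed + summ$unknown
  expect_equal(summ$missing_pct, round_half_up(100 * summ$missing / tot_res))

  empty <- summarize_dataset(classes[0, ], list(), regions[0, ])
  expect_true(all(empty$n_proteins == 0L))
  expect_true(all(empty$missing == 0L))
})

test_that("length histogram bins by tens from the LDR threshold", {
  h <- length_histogram(c(30L, 39L, 40L))
  expect_equal(h$count[h$bin_start == 30], 2L)
  expect_equal(h$count[h$bin_start == 40], 1L)

  expect_equal(nrow(length_histogram(integer(0))), 0L)

  set.seed(41)
  lens <- sample(30:250, 1000, replace = TRUE)
  h2 <- length_histogram(lens)
  expect_equal(sum(h2$count), 1000L)
  # brute-force counter
  for (i in seq_len(nrow(h2))) {
    expect_equal(h2$count[i],
                 sum(lens >= h2$bin_start[i] & lens <= h2$bin_end[i]))
  }
  # permutation invariance
  expect_equal(length_histogram(sample(lens)), h2)

  expect_equal(fraction_in_length_range(c(30, 40, 44, 45, 200), 30, 44),
               3 / 5)
})

test_that("region localization uses 20% tails, full coverage, and the tie rule", {
  expect_equal(localize_region(1, 35, 100), "N-terminal")
  expect_equal(localize_region(1, 100, 100), "full")
  expect_equal(localize_region(40, 75, 100), "middle")
  expect_equal(localize_region(81, 100, 100), "C-terminal")
  # touches both tails without covering everything: larger overlap wins
  expect_equal(localize_region(2, 100, 100), "C-terminal")
  expect_equal(localize_region(1, 99, 100), "N-terminal")
  # equal overlap ties go N-terminal
  expect_equal(localize_region(2, 99, 100), "N-terminal")

  regs <- data.frame(protein_id = c("PA", "PA"), rule = "majority",
                     start = c(1L, 50L), end = c(30L, 70L),
                     length = c(30L, 21L), class = "LDR",
                     stringsAsFactors = FALSE)
  out <- localize_regions(regs, c(PA = 150L))
  expect_equal(out$localization, c("N-terminal", "middle"))
})

test_that("amino-acid enrichment folds against a background composition", {
  # identical composition -> fold 1 for every residue present
  seqs <- c("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSTVWY")
  enr <- aa_enrichment(seqs, seqs)
  expect_true(all(enr$fold == 1))

  # all-glycine target vs uniform background
  uniform <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")
  enr2 <- aa_enrichment("GGGGGGGG", uniform)
  expect_equal(enr2$fold[enr2$aa == "G"], 20)
  expect_true(all(enr2$fold[enr2$aa != "G"] == 0))

  # random sequences vs a direct counting oracle + frequency conservation
  set.seed(47)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  target <- paste(sample(aas, 500, replace = TRUE), collapse = "")
  background <- paste(sample(aas, 2000, replace = TRUE), collapse = "")
  enr3 <- aa_enrichment(target, background)
  tc <- table(factor(strsplit(target, "")[[1]], levels = sort(aas)))
  bc <- table(factor(strsplit(background, "")[[1]], levels = sort(aas)))
  present <- as.logical(bc > 0)
  expect_equal(enr3$fold[present],
               (as.numeric(tc)[present] / 500) /
                 (as.numeric(bc)[present] / 2000))
  expect_equal(sum(enr3$fold[present] * (as.numeric(bc)[present] / 2000)), 1)
})

test_that("LDR-per-protein distribution reports counts and percentages", {
  regs <- data.frame(
    protein_id = c("PA", "PB", "PC", "PC"), rule = "majority",
    start = 1L, end = 40L, length = 40L, class = "LDR",
    stringsAsFactors = FALSE)
  d <- count_regions_per_protein(regs)
  expect_equal(d$k, c(1L, 2L))
  expect_equal(d$n_proteins, c(2L, 1L))
  expect_equal(d$pct, c(66.7, 33.3))

  expect_equal(nrow(count_regions_per_protein(regs[0, ])), 0L)

  # SDRs are not counted
  regs$class <- "SDR"
  expect_equal(nrow(count_regions_per_protein(regs)), 0L)
})

test_that("region-set comparison performs protein-level set algebra", {
  a <- c("P1", "P2", "P3")
  same <- compare_region_sets(a, a)
  expect_equal(same$n_intersection, 3L)
  expect_equal(same$n_only_a, 0L)

  disj <- compare_region_sets(a, c("Q1", "Q2"))
  expect_equal(disj$n_intersection, 0L)
  expect_equal(disj$n_only_a, 3L)
  expect_equal(disj$n_only_b, 2L)

  set.seed(53)
  for (rep in 1:10) {
    x <- sample(sprintf("P%02d", 1:30), sample(5:20, 1))
    y <- sample(sprintf("P%02d", 1:30), sample(5:20, 1))
    cmp <- compare_region_sets(x, y)
    expect_setequal(cmp$intersection, intersect(x, y))
    expect_setequal(cmp$only_a, setdiff(x, y))
    expect_setequal(cmp$only_b, setdiff(y, x))
  }
})
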