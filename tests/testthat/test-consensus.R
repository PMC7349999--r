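cfg <- consensus_config()

test_that("majority rule: strict >50% of covering chains, uncovered is unknown", {
  # 5 chains, missing in 3 -> disordered
  m <- matrix(c("M", "M", "M", "O", "O"), ncol = 1)
  expect_equal(majority_consensus(stack_from_matrix(m), cfg)$states, "D")
  # 4 chains, missing in exactly 2 (50%) -> structured (strict majority)
  m <- matrix(c("M", "M", "O", "O"), ncol = 1)
  expect_equal(majority_consensus(stack_from_matrix(m), cfg)$states, "S")
  # not covered by any chain -> unknown
  m <- matrix(rep("N", 3), ncol = 1)
  trk <- majority_consensus(stack_from_matrix(m), cfg)
  expect_equal(trk$states, "U")
  expect_equal(trk$coverage, 0L)
})

test_that("zero rule: disordered only when missing in every covering chain", {
  m <- matrix(rep("M", 5), ncol = 1)
  expect_equal(zero_consensus(stack_from_matrix(m), cfg)$states, "D")
  # observed in one of five chains blocks the zero call
  m <- matrix(c("O", "M", "M", "M", "M"), ncol = 1)
  expect_equal(zero_consensus(stack_from_matrix(m), cfg)$states, "S")
})

test_that("single-track stacks: consensus equals the track with N -> U, both rules agree", {
  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(sample(c("O", "M", "N"), 20, replace = TRUE), nrow = 1)
    stack <- stack_from_matrix(m)
    maj <- majority_consensus(stack, cfg)
    zer <- zero_consensus(stack, cfg)
    expected <- c(O = "S", M = "D", N = "U")[m[1, ]]
    expect_equal(maj$states, unname(expected))
    expect_equal(zer$states, maj$states)
  }
})

test_that("every per-position vote pattern over <=4 chains matches the brute-force counter", {
  for (c in 1:4) {
    cols <- as.matrix(expand.grid(rep(list(c("O", "M", "N")), c),
                                  stringsAsFactors = FALSE))
    m <- t(cols)  # one position per enumerated pattern
    stack <- stack_from_matrix(m)
    expect_equal(majority_consensus(stack, cfg)$states,
                 bf_consensus(m, "majority"))
    expect_equal(zero_consensus(stack, cfg)$states,
                 bf_consensus(m, "zero"))
  }
})

test_that("random stacks up to 4 chains x 6 positions match the brute-force counter", {
  set.seed(17)
  for (rep in 1:200) {
    r <- sample(1:4, 1)
    p <- sample(1:6, 1)
    stack <- stack_from_matrix(
      matrix(sample(c("O", "M", "N"), r * p, replace = TRUE), nrow = r))
    expect_equal(majority_consensus(stack, cfg)$states,
                 bf_consensus(stack$tracks, "majority"))
    expect_equal(zero_consensus(stack, cfg)$states,
                 bf_consensus(stack$tracks, "zero"))
  }
})

test_that("consensus properties: zero subset of majority, permutation invariance, duplicate-track stability", {
  set.seed(23)
  for (rep in 1:50) {
    m <- matrix(sample(c("O", "M", "N"), 8 * 30, replace = TRUE), nrow = 8)
    stack <- stack_from_matrix(m)
    maj <- majority_consensus(stack, cfg)
    zer <- zero_consensus(stack, cfg)
    # covered all-missing implies strict majority missing
    expect_false(any(zer$states == "D" & maj$states != "D"))
    # permutation of tracks
    perm <- stack_from_matrix(m[sample(nrow(m)), , drop = FALSE])
    expect_equal(majority_consensus(perm, cfg)$states, maj$states)
    expect_equal(zero_consensus(perm, cfg)$states, zer$states)
    # duplicating a track never flips decisions at positions it covers
    # with vote margin >= 2
    t_idx <- sample(nrow(m), 1)
    dup <- stack_from_matrix(rbind(m, m[t_idx, ]))
    maj2 <- majority_consensus(dup, cfg)
    miss <- colSums(m == "M")
    cov <- colSums(m != "N")
    margin <- abs(2 * miss - cov)
    covered_by_t <- m[t_idx, ] != "N"
    idx <- which(covered_by_t & margin >= 2)
    expect_equal(maj2$states[idx], maj$states[idx])
  }
})

test_that("region extraction honours the 5/30-residue thresholds and splits on U", {
  trk <- function(states) {
    structure(list(protein_id = "P1", rule = "majority", states = states,
                   coverage = as.integer(states != "U")),
              class = "consensus_track")
  }
  r30 <- extract_regions(trk(c(rep("S", 3), rep("D", 30), "S")), cfg)
  expect_equal(r30$class, "LDR")
  expect_equal(r30$length, 30L)

  r29 <- extract_regions(trk(c(rep("D", 29), rep("S", 5))), cfg)
  expect_equal(r29$class, "SDR")

  expect_equal(nrow(extract_regions(trk(c(rep("D", 4), rep("S", 10))), cfg)), 0L)

  split <- extract_regions(trk(c(rep("D", 40), "U", rep("D", 40))), cfg)
  expect_equal(split$start, c(1L, 42L))
  expect_equal(split$length, c(40L, 40L))
  expect_equal(split$class, c("LDR", "LDR"))
})

test_that("region extraction matches a brute-force interval scanner on random tracks", {
  set.seed(31)
  for (rep in 1:30) {
    states <- sample(c("D", "S", "U"), 120, replace = TRUE,
                     prob = c(0.55, 0.3, 0.15))
    trk <- structure(list(protein_id = "P1", rule = "majority",
                          states = states,
                          coverage = as.integer(states != "U")),
                     class = "consensus_track")
    got <- extract_regions(trk, cfg)
    want <- bf_regions(states)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$class, want$class)
    # sum of region lengths never exceeds the number of D positions and
    # every D-run of length >= 5 is represented
    expect_lte(sum(got$length), sum(states == "D"))
  }
})

test_that("protein classification by best region class and disorder content", {
  trk <- function(states) {
    structure(list(protein_id = "P1", rule = "majority", states = states,
                   coverage = as.integer(states != "U")),
              class = "consensus_track")
  }
  regions <- data.frame(
    protein_id = "P1", rule = "majority",
    start = c(1L, 60L, 80L), end = c(40L, 69L, 89L),
    length = c(40L, 10L, 10L), class = c("LDR", "SDR", "SDR"),
    stringsAsFactors = FALSE)
  t1 <- trk(c(rep("D", 40), rep("S", 60)))
  expect_equal(classify_protein(regions, t1, cfg)$category, "LDR-protein")

  empty <- regions[0, ]
  t2 <- trk(c(rep("D", 4), rep("S", 96)))
  expect_equal(classify_protein(empty, t2, cfg)$category, "structured")

  # 70 of 100 disordered residues is exactly fully disordered
  t3 <- trk(c(rep("D", 70), rep("S", 30)))
  expect_true(classify_protein(regions, t3, cfg)$fully_disordered)
  t4 <- trk(c(rep("D", 69), rep("S", 31)))
  expect_false(classify_protein(regions, t4, cfg)$fully_disordered)
})

test_that("consensus difference subtracts the zero track from majority LDRs", {
  ztrk <- function(states) {
    structure(list(protein_id = "P1", rule = "zero", states = states,
                   coverage = rep(1L, length(states))),
              class = "consensus_track")
  }
  mreg <- function(start, end) {
    data.frame(protein_id = "P1", rule = "majority", start = start,
               end = end, length = end - start + 1L, class = "LDR",
               stringsAsFactors = FALSE)
  }
  # identical consensus -> empty difference, confirmed
  z1 <- ztrk(c(rep("D", 40), rep("S", 20)))
  d1 <- consensus_difference(mreg(1L, 40L), z1, cfg)
  expect_equal(nrow(d1$difference), 0L)
  expect_true(d1$ldr_confirmation$confirmed)

  # majority LDR 1-60, zero D only at 1-35 -> difference 36-60, confirmed
  z2 <- ztrk(c(rep("D", 35), rep("S", 25)))
  d2 <- consensus_difference(mreg(1L, 60L), z2, cfg)
  expect_equal(d2$difference$start, 36L)
  expect_equal(d2$difference$end, 60L)
  expect_true(d2$ldr_confirmation$confirmed)

  # majority LDR 1-40, zero D only at 1-20 -> difference 21-40, not confirmed
  z3 <- ztrk(c(rep("D", 20), rep("S", 20)))
  d3 <- consensus_difference(mreg(1L, 40L), z3, cfg)
  expect_equal(d3$difference$start, 21L)
  expect_equal(d3$difference$end, 40L)
  expect_false(d3$ldr_confirmation$confirmed)
})

test_that("consensus_config validates thresholds and reads key-value overrides", {
  expect_error(consensus_config(sdr_min_len = 0), "sdr_min_len")
  expect_error(consensus_config(majority_fraction = 1), "majority_fraction")
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("ldr_min_len = 20", "tail_fraction = 0.25"), path)
  over <- read_consensus_config(path)
  expect_equal(over$ldr_min_len, 20L)
  expect_equal(over$tail_fraction, 0.25)
  expect_equal(over$sdr_min_len, 5L)
  writeLines("no_such_key = 1", path)
  expect_error(read_consensus_config(path), "unknown")
})
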