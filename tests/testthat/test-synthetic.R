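test_that("generation is deterministic for a fixed seed and stable under n_proteins", {
  cfg <- sim_config(n_proteins = 6, seed = 19)
  s1 <- generate_ensemble(cfg)
  s2 <- generate_ensemble(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(s1$segments, s2$segments)
  expect_identical(lapply(s1$observations, `[[`, "states"),
                   lapply(s2$observations, `[[`, "states"))
  expect_identical(s1$quality, s2$quality)

  # per-protein substreams: growing the ensemble leaves early proteins alone
  s3 <- generate_ensemble(sim_config(n_proteins = 9, seed = 19))
  expect_identical(s3$ground_truth[names(s1$ground_truth)], s1$ground_truth)
  expect_identical(s3$sequences[names(s1$sequences)], s1$sequences)
})

test_that("noiseless generation recovers ground truth exactly on covered positions", {
  sim <- generate_ensemble(sim_config(
    n_proteins = 10, seed = 29, p_miss_disordered = 1,
    p_miss_structured = 0, trim_prob = 0))
  rec <- evaluate_recovery(sim)
  expect_equal(rec$covered_agreement, 1)
  expect_equal(rec$recovery, 1)
  expect_true(rec$zero_within_majority)

  # with untrimmed constructs the consensus equals the truth everywhere:
  # uncrystallized segments surface as U, and majority == zero
  stacks <- sim_stacks(sim)
  for (pid in names(stacks)) {
    maj <- majority_consensus(stacks[[pid]])
    zer <- zero_consensus(stacks[[pid]])
    expect_equal(maj$states, unname(truth_track(sim$ground_truth[[pid]])))
    expect_equal(zer$states, maj$states)
    # exact region recovery, including SDRs
    got <- extract_regions(maj)
    want <- sim$ground_truth[[pid]]$regions
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$class, want$class)
  }
})

test_that("noisy multi-chain ensembles keep zero regions inside majority regions", {
  sim <- generate_ensemble(sim_config(n_proteins = 10, n_chains = 7,
                                      seed = 37))
  rec <- evaluate_recovery(sim)
  expect_true(rec$zero_within_majority)
  regions <- rec$pipeline$regions
  zero_ldr <- regions[regions$rule == "zero" & regions$class == "LDR", ]
  maj <- regions[regions$rule == "majority", ]
  for (i in seq_len(nrow(zero_ldr))) {
    inside <- maj$protein_id == zero_ldr$protein_id[i] &
      maj$start <= zero_ldr$start[i] & maj$end >= zero_ldr$end[i]
    expect_true(any(inside))
  }
})

test_that("uncrystallized segments become unknown consensus positions", {
  segs <- data.frame(
    state = c("uncrystallized", "structured", "disordered", "structured",
              "uncrystallized"),
    length = c(20L, 60L, 40L, 60L, 30L), stringsAsFactors = FALSE)
  sim <- generate_ensemble(sim_config(n_proteins = 2, seed = 43,
                                      segments = segs, trim_prob = 0))
  stacks <- sim_stacks(sim)
  maj <- majority_consensus(stacks[[1]])
  expect_true(all(maj$states[1:20] == "U"))
  expect_true(all(maj$states[181:210] == "U"))
  expect_true(all(maj$coverage[21:180] > 0))
})

test_that("impossible architectures are rejected", {
  expect_error(sim_config(p_miss_disordered = 1.2), "probabilities")
  expect_error(sim_config(segments = data.frame(state = "disordered")),
               "segments")
  expect_error(sim_config(segments = data.frame(state = "weird",
                                                length = 10)), "state")
  all_unknown <- data.frame(state = "uncrystallized", length = 50L,
                            stringsAsFactors = FALSE)
  expect_error(generate_ensemble(sim_config(n_proteins = 1, seed = 1,
                                            segments = all_unknown)),
               "crystallizable")
})

test_that("fixture bundles round-trip through the ingest parsers", {
  sim <- generate_ensemble(sim_config(n_proteins = 4, n_chains = 3,
                                      seed = 47))
  dir <- withr::local_tempdir()
  manifest <- write_fixture_bundle(sim, dir)
  expect_equal(manifest$seed, 47L)
  expect_equal(manifest$n_structures, length(sim$observations))

  # tabular dialect
  back <- read_observations_tsv(file.path(dir, "observations.tsv"))
  expect_equal(back, sim$observations)

  # PDB files reproduce the in-memory observations exactly
  for (obs in sim$observations) {
    pdb <- parse_pdb_missing(
      file.path(dir, "pdb", paste0(obs$structure_id, ".pdb")),
      structure_id = obs$structure_id)
    expect_equal(pdb[[1]]$states, obs$states)
    expect_equal(pdb[[1]]$chain_id, obs$chain_id)
  }

  # mapping + fasta rebuild the same stacks
  segs <- read_mapping_tsv(file.path(dir, "mapping.tsv"))
  fasta <- seqinr::read.fasta(file.path(dir, "sequences.fasta"),
                              seqtype = "AA", as.string = TRUE)
  pid <- names(sim$ground_truth)[1]
  stack_mem <- sim_stacks(sim)[[pid]]
  stack_file <- build_stack(
    back, segs[segs$protein_id == pid, ], pid,
    toupper(as.character(fasta[[pid]])))
  expect_equal(stack_file$tracks, stack_mem$tracks)

  # OBO + GAF satisfy the enrichment preconditions
  ont <- load_ontology(file.path(dir, "ontology.obo"))
  ann <- read_gaf(file.path(dir, "annotations.gaf"))
  closed <- propagate_annotations(ann, ont)
  expect_true(all(names(closed) %in% names(sim$ground_truth)))
  expect_true(all(unlist(closed) %in% ont$terms$id))

  # quality csv readable
  q <- read_quality_csv(file.path(dir, "quality.csv"))
  expect_equal(nrow(q), length(sim$observations))
})

test_that("manifest hash changes iff the configuration changes", {
  sim_a <- generate_ensemble(sim_config(n_proteins = 2, seed = 53))
  sim_b <- generate_ensemble(sim_config(n_proteins = 2, seed = 53))
  sim_c <- generate_ensemble(sim_config(n_proteins = 2, seed = 54))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  h_a <- write_fixture_bundle(sim_a, d1)$config_hash
  h_b <- write_fixture_bundle(sim_b, d2)$config_hash
  h_c <- write_fixture_bundle(sim_c, d3)$config_hash
  expect_identical(h_a, h_b)
  expect_false(identical(h_a, h_c))
})

test_that("disordered segments show the expected compositional bias", {
  sim <- generate_ensemble(sim_config(n_proteins = 30, seed = 59))
  dis_seq <- character(0)
  str_seq <- character(0)
  for (pid in names(sim$ground_truth)) {
    states <- sim$ground_truth[[pid]]$states
    chars <- strsplit(sim$sequences[[pid]], "")[[1]]
    dis_seq <- c(dis_seq, chars[states == "disordered"])
    str_seq <- c(str_seq, chars[states == "structured"])
  }
  enr <- aa_enrichment(paste(dis_seq, collapse = ""),
                       paste(str_seq, collapse = ""))
  # disorder-promoting residues enriched, order-promoting depleted
  expect_gt(enr$fold[enr$aa == "P"], 1.5)
  expect_gt(enr$fold[enr$aa == "E"], 1.2)
  expect_lt(enr$fold[enr$aa == "I"], 0.7)
  expect_lt(enr$fold[enr$aa == "W"], 0.7)
})
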