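# Seeded generator of synthetic structure ensembles with ground-truth
# disorder architecture. Proteins carry disordered / structured /
# uncrystallized segments; each deposited chain observes the crystallized
# construct with state-conditional miss probabilities, emulating multiple
# X-ray experiments mapped to one protein sequence.

# Amino-acid sampling weights (alphabetical over the 20 standard residues).
# Disordered segments are enriched in disorder-promoting residues
# (P, E, S, Q, K, G, D, R, T, A) and depleted in order-promoting
# hydrophobics (W, C, F, I, Y, V, L); structured segments use a globular
# composition.
.AA_ALPHA <- sort(unname(.AA1))
.FREQ_DISORDERED <- c(
  A = 0.075, C = 0.005, D = 0.060, E = 0.105, F = 0.015, G = 0.080,
  H = 0.020, I = 0.020, K = 0.090, L = 0.035, M = 0.015, N = 0.035,
  P = 0.105, Q = 0.065, R = 0.060, S = 0.105, T = 0.060, V = 0.030,
  W = 0.005, Y = 0.015)
.FREQ_STRUCTURED <- c(
  A = 0.083, C = 0.017, D = 0.054, E = 0.062, F = 0.040, G = 0.072,
  H = 0.022, I = 0.057, K = 0.058, L = 0.092, M = 0.024, N = 0.044,
  P = 0.047, Q = 0.039, R = 0.051, S = 0.066, T = 0.055, V = 0.068,
  W = 0.013, Y = 0.036)

#' Synthetic-ensemble configuration
#'
#' Study conditions for the generator. Defaults describe a modest benchmark
#' ensemble: 50 proteins, half of which carry one or two long disordered
#' regions (30-80 aa), uncrystallized tails at either end emulating
#' construct design (the source of "unknown" residues), 5 chains per
#' protein, a 0.9 probability that a disordered residue is missing in any
#' given chain versus 0.05 for structured residues, and occasional
#' construct trimming of up to 10 residues per terminus.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Min/max structured core length used for proteins
#'   without disordered segments.
#' @param n_chains Chains (independent structures) per protein; a scalar or
#'   a \code{c(min, max)} range.
#' @param p_miss_disordered Probability a disordered residue is missing in
#'   a given chain.
#' @param p_miss_structured Probability a structured residue is missing.
#' @param p_ldr_protein Probability a protein carries LDR segment(s).
#' @param n_ldr_range Min/max number of LDR segments for LDR proteins.
#' @param ldr_len_range Min/max LDR segment length.
#' @param p_sdr Probability of an additional short disordered segment.
#' @param sdr_len_range Min/max SDR segment length.
#' @param p_tail_uncrystallized Probability of an uncrystallized tail at
#'   each terminus.
#' @param tail_len_range Min/max uncrystallized tail length.
#' @param trim_prob Probability a chain construct is trimmed at a terminus.
#' @param trim_max Maximum trim extent (residues) per terminus.
#' @param predictor_specs Named list of predictor error profiles, each
#'   \code{list(fn = , fp = )}: the false-negative rate on truly disordered
#'   residues and false-positive rate on other residues.
#' @param quality_coupling Linear coupling of resolution and R-free to a
#'   structure's disorder fraction (0 = independent).
#' @param quality_noise_sd Gaussian noise s.d. on the resolution.
#' @param plant_term Ontology term planted into annotations.
#' @param plant_prob_target Probability an LDR-carrying protein is
#'   annotated with the planted term.
#' @param plant_prob_background Probability a non-LDR protein is annotated
#'   with the planted term.
#' @param segments Optional explicit architecture applied to every protein:
#'   data.frame with columns \code{state} (\code{disordered},
#'   \code{structured}, \code{uncrystallized}) and \code{length}; overrides
#'   the random architecture.
#' @param seed Integer seed; all sampling derives from it through
#'   per-protein substreams, so protein \code{i} is stable under changes of
#'   \code{n_proteins}.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_proteins = 50L,
                       length_range = c(200L, 600L),
                       n_chains = 5L,
                       p_miss_disordered = 0.9,
                       p_miss_structured = 0.05,
                       p_ldr_protein = 0.5,
                       n_ldr_range = c(1L, 2L),
                       ldr_len_range = c(30L, 80L),
                       p_sdr = 0.3,
                       sdr_len_range = c(5L, 29L),
                       p_tail_uncrystallized = 0.5,
                       tail_len_range = c(20L, 60L),
                       trim_prob = 0.25,
                       trim_max = 10L,
                       predictor_specs = list(
                         strict = list(fn = 0.5, fp = 0.02),
                         balanced = list(fn = 0.25, fp = 0.10)),
                       quality_coupling = 0,
                       quality_noise_sd = 0.25,
                       plant_term = "GO:1000002",
                       plant_prob_target = 0.9,
                       plant_prob_background = 0.05,
                       segments = NULL,
                       seed = 1L) {
  probs <- c(p_miss_disordered, p_miss_structured, p_ldr_protein, p_sdr,
             p_tail_uncrystallized, trim_prob,
             plant_prob_target, plant_prob_background)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_proteins < 1L) stop("need at least one protein")
  if (!is.null(segments)) {
    if (!all(c("state", "length") %in% names(segments))) {
      stop("explicit segments need columns 'state' and 'length'")
    }
    if (!all(segments$state %in%
             c("disordered", "structured", "uncrystallized"))) {
      stop("unknown segment state")
    }
    if (any(segments$length < 1L)) stop("segment lengths must be positive")
  }
  cfg <- as.list(environment())
  cfg$probs <- NULL
  structure(cfg, class = "sim_config")
}

.substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1e6 * 1021 + index * 7919 + 13) %%
               2147483629)
}

.sample_range <- function(range) {
  range <- as.integer(range)
  if (length(range) == 1L) return(range)
  if (range[1L] == range[2L]) return(range[1L])
  sample(range[1L]:range[2L], 1L)
}

.random_partition <- function(total, n_parts, min_part) {
  # composition of `total` into n_parts parts, each >= min_part
  extra <- total - min_part * n_parts
  if (extra < 0L) stop("partition infeasible")
  if (n_parts == 1L) return(total)
  cuts <- sort(sample.int(extra + 1L, n_parts - 1L, replace = TRUE) - 1L)
  diff(c(0L, cuts, extra)) + min_part
}

.protein_architecture <- function(cfg) {
  if (!is.null(cfg$segments)) {
    return(data.frame(state = cfg$segments$state,
                      length = as.integer(cfg$segments$length),
                      stringsAsFactors = FALSE))
  }
  n_tail <- if (stats::runif(1) < cfg$p_tail_uncrystallized)
    .sample_range(cfg$tail_len_range) else 0L
  c_tail <- if (stats::runif(1) < cfg$p_tail_uncrystallized)
    .sample_range(cfg$tail_len_range) else 0L

  dis_lens <- integer(0)
  if (stats::runif(1) < cfg$p_ldr_protein) {
    k <- .sample_range(cfg$n_ldr_range)
    dis_lens <- vapply(seq_len(k), function(i)
      .sample_range(cfg$ldr_len_range), integer(1))
  }
  if (stats::runif(1) < cfg$p_sdr) {
    dis_lens <- c(dis_lens, .sample_range(cfg$sdr_len_range))
  }
  if (length(dis_lens) > 1L) dis_lens <- sample(dis_lens)

  min_gap <- 30L  # structured blocks separating disordered segments
  core_len <- .sample_range(cfg$length_range)
  needed <- sum(dis_lens) + min_gap * (length(dis_lens) + 1L)
  if (core_len < needed) core_len <- needed
  gaps <- .random_partition(core_len - sum(dis_lens),
                            length(dis_lens) + 1L, min_gap)

  states <- character(0)
  lens <- integer(0)
  if (n_tail > 0L) { states <- "uncrystallized"; lens <- n_tail }
  for (i in seq_along(dis_lens)) {
    states <- c(states, "structured", "disordered")
    lens <- c(lens, gaps[i], dis_lens[i])
  }
  states <- c(states, "structured")
  lens <- c(lens, gaps[length(gaps)])
  if (c_tail > 0L) {
    states <- c(states, "uncrystallized")
    lens <- c(lens, c_tail)
  }
  data.frame(state = states, length = lens, stringsAsFactors = FALSE)
}

.truth_regions <- function(states, cfg_cons = consensus_config()) {
  runs <- rle(states == "disordered")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= cfg_cons$sdr_min_len
  data.frame(start = starts[keep], end = ends[keep],
             length = runs$lengths[keep],
             class = as.character(
               ifelse(runs$lengths[keep] >= cfg_cons$ldr_min_len,
                      "LDR", "SDR")),
             stringsAsFactors = FALSE)
}

.sample_sequence <- function(states) {
  out <- character(length(states))
  dis <- states == "disordered"
  if (any(dis)) {
    out[dis] <- sample(.AA_ALPHA, sum(dis), replace = TRUE,
                       prob = .FREQ_DISORDERED[.AA_ALPHA])
  }
  if (any(!dis)) {
    out[!dis] <- sample(.AA_ALPHA, sum(!dis), replace = TRUE,
                        prob = .FREQ_STRUCTURED[.AA_ALPHA])
  }
  paste(out, collapse = "")
}

#' Generate a synthetic structure ensemble
#'
#' Deterministic for a fixed seed. Each protein receives a ground-truth
#' architecture; each chain covers the crystallized core (uncrystallized
#' segments are excluded from every construct and surface as unknown
#' residues downstream), optionally trimmed at the termini, and samples a
#' missing/observed state per covered position with the state-conditional
#' probability. Optional outputs: per-method predictor tracks obtained by
#' flipping the truth with the configured error rates, per-structure quality
#' records with configurable coupling to the disorder fraction, and GO
#' annotations planting an enriched term in LDR-carrying proteins.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List of class \code{sim_ensemble} with \code{config},
#'   \code{ground_truth} (per protein: \code{states}, \code{regions}),
#'   \code{sequences}, \code{observations}, \code{segments} (mapping
#'   data.frame), \code{predictions}, \code{quality}, \code{annotations}
#'   (data.frame \code{protein_id}, \code{term_id}), \code{ontology_obo}
#'   and the parsed \code{ontology}.
#' @export
generate_ensemble <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config")
  obo <- synthetic_ontology()
  ontology <- load_ontology(obo)
  noise_pool <- ontology$terms$id[
    ontology$terms$level >= 1L & ontology$terms$level <= 2L &
      ontology$terms$id != cfg$plant_term]

  ground_truth <- list()
  sequences <- character(0)
  observations <- list()
  segments_rows <- list()
  quality_rows <- list()
  ann_rows <- list()
  predictions <- stats::setNames(
    replicate(length(cfg$predictor_specs), list(), simplify = FALSE),
    names(cfg$predictor_specs))

  for (i in seq_len(cfg$n_proteins)) {
    set.seed(.substream_seed(cfg$seed, i))
    pid <- sprintf("PROT%04d", i)

    arch <- .protein_architecture(cfg)
    states <- rep(arch$state, arch$length)
    L <- length(states)
    seq_str <- .sample_sequence(states)
    regions <- .truth_regions(states)
    ground_truth[[pid]] <- list(protein_id = pid, states = states,
                                regions = regions)
    sequences[pid] <- seq_str

    # crystallizable runs: uncrystallized segments (tails or internal) are
    # excluded from every construct and may split it into several mapped
    # segments
    cryst_runs <- rle(states != "uncrystallized")
    run_ends <- cumsum(cryst_runs$lengths)
    run_starts <- run_ends - cryst_runs$lengths + 1L
    run_starts <- run_starts[cryst_runs$values]
    run_ends <- run_ends[cryst_runs$values]
    if (length(run_starts) == 0L) {
      stop("architecture leaves no crystallizable residues for ", pid)
    }

    n_chains <- .sample_range(cfg$n_chains)
    for (j in seq_len(n_chains)) {
      sid <- sprintf("S%04d%02d", i, j)
      tn <- if (stats::runif(1) < cfg$trim_prob)
        sample(0:cfg$trim_max, 1L) else 0L
      tc <- if (stats::runif(1) < cfg$trim_prob)
        sample(0:cfg$trim_max, 1L) else 0L
      rs <- run_starts
      re <- run_ends
      rs[1L] <- rs[1L] + tn
      re[length(re)] <- re[length(re)] - tc
      if (any(re - rs < 0L) || sum(re - rs + 1L) < 10L) {
        rs <- run_starts
        re <- run_ends
      }
      span <- unlist(Map(seq.int, rs, re), use.names = FALSE)
      p_miss <- ifelse(states[span] == "disordered",
                       cfg$p_miss_disordered, cfg$p_miss_structured)
      miss <- stats::runif(length(span)) < p_miss
      year <- sample(2000:2018, 1L)
      observations[[length(observations) + 1L]] <- chain_observation(
        sid, "A", ifelse(miss, "M", "O"), release_year = year)
      run_lens <- re - rs + 1L
      chain_ends <- cumsum(run_lens)
      chain_starts <- chain_ends - run_lens + 1L
      segments_rows[[length(segments_rows) + 1L]] <- data.frame(
        structure_id = sid, chain_id = "A",
        chain_start = chain_starts, chain_end = chain_ends,
        protein_id = pid, protein_start = rs, protein_end = re,
        stringsAsFactors = FALSE)
      frac <- mean(miss)
      quality_rows[[length(quality_rows) + 1L]] <- data.frame(
        structure_id = sid,
        resolution = max(0.8, 1.8 + cfg$quality_coupling * frac +
                           stats::rnorm(1, 0, cfg$quality_noise_sd)),
        r_free = min(0.45, max(0.10,
          0.22 + 0.05 * cfg$quality_coupling * frac +
            stats::rnorm(1, 0, 0.02))),
        clashscore = stats::rgamma(1, shape = 2, scale = 3),
        rama_outliers = stats::rgamma(1, shape = 2, scale = 0.4),
        rotamer_outliers = stats::rgamma(1, shape = 2, scale = 0.8),
        rsrz_outliers = stats::rgamma(1, shape = 2, scale = 1.5),
        year = year, stringsAsFactors = FALSE)
    }

    truly_dis <- states == "disordered"
    for (method in names(cfg$predictor_specs)) {
      spec <- cfg$predictor_specs[[method]]
      pred <- logical(L)
      pred[truly_dis] <- stats::runif(sum(truly_dis)) >= spec$fn
      pred[!truly_dis] <- stats::runif(sum(!truly_dis)) < spec$fp
      score <- numeric(L)
      score[pred] <- stats::runif(sum(pred), 0.5, 1)
      score[!pred] <- stats::runif(sum(!pred), 0, 0.5)
      attr(pred, "score") <- score
      predictions[[method]][[pid]] <- pred
    }

    has_ldr <- any(regions$class == "LDR")
    p_plant <- if (has_ldr) cfg$plant_prob_target else
      cfg$plant_prob_background
    terms <- character(0)
    if (stats::runif(1) < p_plant) terms <- cfg$plant_term
    terms <- c(terms, sample(noise_pool, sample(1:3, 1L)))
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      protein_id = pid, term_id = unique(terms), stringsAsFactors = FALSE)
  }

  structure(
    list(config = cfg,
         ground_truth = ground_truth,
         sequences = sequences,
         observations = observations,
         segments = do.call(rbind, segments_rows),
         predictions = predictions,
         quality = do.call(rbind, quality_rows),
         annotations = do.call(rbind, ann_rows),
         ontology_obo = obo,
         ontology = ontology),
    class = "sim_ensemble"
  )
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("<sim_ensemble> %d proteins, %d chains (seed %d)\n",
              length(x$ground_truth), length(x$observations),
              x$config$seed))
  invisible(x)
}

#' Build protein track stacks from a synthetic ensemble
#'
#' @param sim A \code{\link{generate_ensemble}} result.
#' @return Named list of \code{\link{build_stack}} results.
#' @export
sim_stacks <- function(sim) {
  ids <- names(sim$ground_truth)
  out <- lapply(ids, function(pid) {
    segs <- sim$segments[sim$segments$protein_id == pid, , drop = FALSE]
    build_stack(sim$observations, segs, pid, sim$sequences[[pid]])
  })
  names(out) <- ids
  out
}

#' Ground-truth consensus states of a synthetic protein
#'
#' @param gt One element of \code{sim$ground_truth}.
#' @return Character vector over \code{D}/\code{S}/\code{U}: disordered
#'   positions are \code{D}, structured \code{S}, uncrystallized \code{U}.
#' @export
truth_track <- function(gt) {
  c(disordered = "D", structured = "S",
    uncrystallized = "U")[gt$states]
}

#' Measure consensus recovery of the ground truth
#'
#' Runs both consensus rules over the ensemble and measures (i) the
#' fraction of true LDRs recovered with exact boundaries by the majority
#' rule, (ii) per-position agreement of the majority consensus with the
#' ground truth on covered positions, and (iii) whether every
#' zero-consensus disordered position is also majority-disordered.
#'
#' @param sim A \code{\link{generate_ensemble}} result.
#' @param cfg A \code{\link{consensus_config}}.
#' @return List with \code{n_true_ldr}, \code{n_recovered},
#'   \code{recovery} (fraction), \code{covered_agreement} (fraction),
#'   \code{zero_within_majority} (logical) and the
#'   \code{\link{consensus_pipeline}} result as \code{pipeline}.
#' @export
evaluate_recovery <- function(sim, cfg = consensus_config()) {
  stacks <- sim_stacks(sim)
  pipe <- consensus_pipeline(stacks, cfg)
  n_true <- 0L
  n_rec <- 0L
  agree <- 0L
  covered <- 0L
  zero_ok <- TRUE
  for (pid in names(sim$ground_truth)) {
    gt <- sim$ground_truth[[pid]]
    maj <- pipe$majority_tracks[[pid]]
    zer <- pipe$zero_tracks[[pid]]
    true_ldr <- gt$regions[gt$regions$class == "LDR", , drop = FALSE]
    found <- pipe$regions[pipe$regions$protein_id == pid &
                            pipe$regions$rule == "majority" &
                            pipe$regions$class == "LDR", , drop = FALSE]
    n_true <- n_true + nrow(true_ldr)
    for (r in seq_len(nrow(true_ldr))) {
      hit <- any(found$start == true_ldr$start[r] &
                   found$end == true_ldr$end[r])
      n_rec <- n_rec + as.integer(hit)
    }
    cov <- maj$coverage > 0L
    truth <- truth_track(gt)
    agree <- agree + sum(maj$states[cov] == truth[cov])
    covered <- covered + sum(cov)
    zero_ok <- zero_ok &&
      !any(zer$states == "D" & maj$states != "D")
  }
  list(n_true_ldr = n_true, n_recovered = n_rec,
       recovery = if (n_true) n_rec / n_true else NA_real_,
       covered_agreement = if (covered) agree / covered else NA_real_,
       zero_within_majority = zero_ok,
       pipeline = pipe)
}

#' Built-in synthetic ontology
#'
#' A small GO-like ontology (OBO 1.2, is_a edges only) with the three
#' standard namespaces, terms down to level 5 and one obsolete term, used
#' by the generator's annotation output. The term \code{GO:1000002}
#' (level 2, molecular function) is the generator's default planted term.
#'
#' @return OBO text as a single string.
#' @export
synthetic_ontology <- function() {
  paste(c(
    "format-version: 1.2",
    "ontology: synthetic-go",
    "",
    "[Term]", "id: GO:0003674", "name: molecular_function",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:1000001", "name: synthetic binding",
    "namespace: molecular_function", "is_a: GO:0003674 ! molecular_function", "",
    "[Term]", "id: GO:1000002", "name: disorder-associated binding",
    "namespace: molecular_function", "is_a: GO:1000001 ! synthetic binding", "",
    "[Term]", "id: GO:1000003", "name: peptide region binding",
    "namespace: molecular_function", "is_a: GO:1000002 ! disorder-associated binding", "",
    "[Term]", "id: GO:1000004", "name: linear motif binding",
    "namespace: molecular_function", "is_a: GO:1000003 ! peptide region binding", "",
    "[Term]", "id: GO:1000005", "name: deep motif binding",
    "namespace: molecular_function", "is_a: GO:1000004 ! linear motif binding", "",
    "[Term]", "id: GO:1000006", "name: catalytic-like activity",
    "namespace: molecular_function", "is_a: GO:0003674 ! molecular_function", "",
    "[Term]", "id: GO:1000007", "name: retired activity",
    "namespace: molecular_function", "is_obsolete: true", "",
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:2000001", "name: synthetic regulation",
    "namespace: biological_process", "is_a: GO:0008150 ! biological_process", "",
    "[Term]", "id: GO:2000002", "name: regulation of folding",
    "namespace: biological_process", "is_a: GO:2000001 ! synthetic regulation", "",
    "[Term]", "id: GO:2000003", "name: signal relay",
    "namespace: biological_process", "is_a: GO:0008150 ! biological_process", "",
    "[Term]", "id: GO:0005575", "name: cellular_component",
    "namespace: cellular_component", "",
    "[Term]", "id: GO:3000001", "name: synthetic complex",
    "namespace: cellular_component", "is_a: GO:0005575 ! cellular_component", "",
    "[Term]", "id: GO:3000002", "name: nuclear-like body",
    "namespace: cellular_component", "is_a: GO:3000001 ! synthetic complex", ""),
    collapse = "\n")
}

#' Write a synthetic ensemble as a fixture bundle
#'
#' Emits the exact file formats the pipeline ingests: one PDB file per
#' structure (SEQRES + REMARK 465), the tabular observation dialect, the
#' mapping TSV, FASTA sequences, per-method prediction TSVs, the quality
#' CSV, the OBO ontology, a GAF annotation file, and a key-value manifest
#' recording the seed and a hash of the configuration.
#'
#' @param sim A \code{\link{generate_ensemble}} result.
#' @param dir Output directory (created if needed).
#' @return The manifest as a named list, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdb_dir <- file.path(dir, "pdb")
  dir.create(pdb_dir, showWarnings = FALSE)

  seg_key <- paste(sim$segments$structure_id, sim$segments$chain_id,
                   sep = "\r")
  for (obs in sim$observations) {
    key <- paste(obs$structure_id, obs$chain_id, sep = "\r")
    segs <- sim$segments[seg_key == key, , drop = FALSE]
    chain_seq <- rep("X", obs$seqres_length)
    for (s in seq_len(nrow(segs))) {
      prot <- strsplit(sim$sequences[[segs$protein_id[s]]], "")[[1L]]
      chain_seq[segs$chain_start[s]:segs$chain_end[s]] <-
        prot[segs$protein_start[s]:segs$protein_end[s]]
    }
    write_pdb_observation(obs, paste(chain_seq, collapse = ""),
                          file.path(pdb_dir,
                                    paste0(obs$structure_id, ".pdb")))
  }

  write_observations_tsv(sim$observations,
                         file.path(dir, "observations.tsv"))
  utils::write.table(sim$segments, file.path(dir, "mapping.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seqinr::write.fasta(
    sequences = lapply(sim$sequences, function(s) strsplit(s, "")[[1L]]),
    names = names(sim$sequences),
    file.out = file.path(dir, "sequences.fasta"))

  for (method in names(sim$predictions)) {
    rows <- lapply(names(sim$predictions[[method]]), function(pid) {
      pred <- sim$predictions[[method]][[pid]]
      data.frame(protein_id = pid, position = seq_along(pred),
                 residue = strsplit(sim$sequences[[pid]], "")[[1L]],
                 score = round(attr(pred, "score"), 4),
                 state = ifelse(pred, "disordered", "ordered"),
                 stringsAsFactors = FALSE)
    })
    utils::write.table(do.call(rbind, rows),
                       file.path(dir, paste0("predictions_", method, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  utils::write.csv(sim$quality, file.path(dir, "quality.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(sim$ontology_obo, file.path(dir, "ontology.obo"))

  aspect <- c(MF = "F", BP = "P", CC = "C")[
    sim$ontology$terms$namespace[
      match(sim$annotations$term_id, sim$ontology$terms$id)]]
  gaf <- c("!gaf-version: 2.1",
           paste("SYNDB", sim$annotations$protein_id,
                 sim$annotations$protein_id, "", sim$annotations$term_id,
                 "SYN_REF:0000001", "IDA", "", aspect, "", "", "protein",
                 "taxon:32630", "20200101", "SYNDB", "", "", sep = "\t"))
  writeLines(gaf, file.path(dir, "annotations.gaf"))

  cfg_file <- tempfile()
  cfg_for_hash <- sim$config
  cfg_for_hash$predictor_specs <-
    cfg_for_hash$predictor_specs[order(names(cfg_for_hash$predictor_specs))]
  writeLines(deparse(cfg_for_hash[order(names(cfg_for_hash))]), cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  manifest <- list(seed = sim$config$seed,
                   n_proteins = sim$config$n_proteins,
                   n_structures = length(sim$observations),
                   config_hash = config_hash)
  writeLines(paste0(names(manifest), ": ", unlist(manifest)),
             file.path(dir, "manifest.txt"))
  invisible(manifest)
}
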