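# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (position-by-position loops, exhaustive sums) so they
# cannot share a defect with the vectorized implementations they check.

# Minimal stack wrapper around a tracks matrix (rows = chains, cells in
# O/M/N) for consensus tests that do not need real observations.
stack_from_matrix <- function(m, protein_id = "P1") {
  structure(
    list(protein_id = protein_id,
         sequence = strrep("A", ncol(m)),
         length = ncol(m),
         tracks = m,
         track_ids = data.frame(
           structure_id = sprintf("S%02d", seq_len(nrow(m))),
           chain_id = "A", stringsAsFactors = FALSE)),
    class = "protein_track_stack")
}

# Position-by-position consensus vote counter.
bf_consensus <- function(m, rule, majority_fraction = 0.5) {
  vapply(seq_len(ncol(m)), function(i) {
    col <- m[, i]
    covering <- col[col != "N"]
    if (length(covering) == 0L) return("U")
    miss <- sum(covering == "M")
    if (rule == "majority") {
      if (miss / length(covering) > majority_fraction) "D" else "S"
    } else {
      if (miss == length(covering)) "D" else "S"
    }
  }, character(1))
}

# Brute-force maximal all-D interval scanner.
bf_regions <- function(states, sdr_min = 5L, ldr_min = 30L) {
  n <- length(states)
  out <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(states[s:e] == "D") &&
          (s == 1L || states[s - 1L] != "D") &&
          (e == n || states[e + 1L] != "D") &&
          (e - s + 1L) >= sdr_min) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = e, length = e - s + 1L,
          class = if (e - s + 1L >= ldr_min) "LDR" else "SDR",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               class = character(0), stringsAsFactors = FALSE)
}

# Position-by-position chain-to-protein mapper.
bf_map_track <- function(obs, segs, L) {
  track <- rep("N", L)
  for (p in seq_len(L)) {
    for (s in seq_len(nrow(segs))) {
      if (p >= segs$protein_start[s] && p <= segs$protein_end[s]) {
        cpos <- segs$chain_start[s] + (p - segs$protein_start[s])
        track[p] <- obs$states[cpos]
      }
    }
  }
  track
}

# Exhaustive hypergeometric tail sum for the one-sided Fisher test.
bf_fisher_greater <- function(a, b, c, d) {
  k <- a + b          # draws (target size)
  K <- a + c          # successes in population (term carriers)
  N <- a + b + c + d  # population
  ks <- max(0L, k - (N - K)):min(k, K)
  probs <- exp(lchoose(K, ks) + lchoose(N - K, k - ks) - lchoose(N, k))
  sum(probs[ks >= a])
}

# Textbook covariance-formula Pearson r.
bf_pearson_r <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Hand-built PDB text, written independently of the package's writer.
make_pdb_text <- function(chains, structure_id = "1XYZ") {
  lines <- sprintf("%-50s%9s   %-4s", "HEADER    TEST PROTEIN",
                   "01-JAN-15", structure_id)
  for (ch in names(chains)) {
    miss <- chains[[ch]]$missing
    res3 <- chains[[ch]]$res3
    for (pos in miss) {
      lines <- c(lines, sprintf("REMARK 465     %-3s %s %5d",
                                res3[pos], ch, pos))
    }
  }
  for (ch in names(chains)) {
    res3 <- chains[[ch]]$res3
    n <- length(res3)
    ser <- 0L
    for (i in seq(1L, n, by = 13L)) {
      ser <- ser + 1L
      lines <- c(lines, sprintf(
        "SEQRES %3d %s %4d  %s", ser, ch, n,
        paste(sprintf("%-3s", res3[i:min(i + 12L, n)]), collapse = " ")))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# Hand-built mmCIF text with an explicit unobserved-residue category.
make_cif_text <- function(chains, structure_id = "1xyz",
                          with_unobs = TRUE, atom_site_observed = NULL) {
  out <- c(paste0("data_", structure_id), "#")
  out <- c(out, "loop_", "_struct_asym.id", "_struct_asym.entity_id",
           vapply(seq_along(chains), function(k)
             paste(names(chains)[k], k), character(1)), "#")
  out <- c(out, "loop_", "_entity_poly_seq.entity_id",
           "_entity_poly_seq.num", "_entity_poly_seq.mon_id")
  for (k in seq_along(chains)) {
    res3 <- chains[[k]]$res3
    out <- c(out, paste(k, seq_along(res3), res3))
  }
  out <- c(out, "#")
  if (with_unobs) {
    rows <- character(0)
    for (k in seq_along(chains)) {
      ch <- names(chains)[k]
      res3 <- chains[[k]]$res3
      for (pos in chains[[k]]$missing) {
        rows <- c(rows, paste("1", "Y", "1", ch, res3[pos], pos,
                              "?", ch, res3[pos], pos))
      }
    }
    if (length(rows)) {
      out <- c(out, "loop_",
               "_pdbx_unobs_or_zero_occ_residues.id",
               "_pdbx_unobs_or_zero_occ_residues.polymer_flag",
               "_pdbx_unobs_or_zero_occ_residues.PDB_model_num",
               "_pdbx_unobs_or_zero_occ_residues.auth_asym_id",
               "_pdbx_unobs_or_zero_occ_residues.auth_comp_id",
               "_pdbx_unobs_or_zero_occ_residues.auth_seq_id",
               "_pdbx_unobs_or_zero_occ_residues.PDB_ins_code",
               "_pdbx_unobs_or_zero_occ_residues.label_asym_id",
               "_pdbx_unobs_or_zero_occ_residues.label_comp_id",
               "_pdbx_unobs_or_zero_occ_residues.label_seq_id",
               rows, "#")
    }
  }
  if (!is.null(atom_site_observed)) {
    out <- c(out, "loop_", "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.label_asym_id", "_atom_site.label_entity_id",
             "_atom_site.label_seq_id", "_atom_site.label_comp_id")
    id <- 0L
    for (k in seq_along(chains)) {
      ch <- names(chains)[k]
      res3 <- chains[[k]]$res3
      for (pos in atom_site_observed[[ch]]) {
        id <- id + 1L
        out <- c(out, paste("ATOM", id, ch, k, pos, res3[pos]))
      }
    }
    out <- c(out, "#")
  }
  paste(out, collapse = "\n")
}

random_res3 <- function(n) {
  sample(c("ALA", "GLY", "SER", "LYS", "GLU", "PRO", "THR", "VAL",
           "LEU", "ASP"), n, replace = TRUE)
}
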