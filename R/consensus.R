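#' Consensus configuration
#'
#' Thresholds governing consensus calling and region extraction. Defaults
#' follow the standard long-disorder analysis conventions: long disordered
#' regions (LDRs) need at least 30 consecutive disordered residues, short
#' disordered regions (SDRs) 5 to 29; a position is majority-disordered when
#' missing in strictly more than 50% of the chains covering it; protein
#' tails span 20% of the sequence at each end; a protein is fully disordered
#' at 70% disorder content.
#'
#' @param ldr_min_len Minimum LDR length (residues).
#' @param sdr_min_len Minimum SDR length (residues).
#' @param majority_fraction Strict fraction threshold for the majority rule.
#' @param tail_fraction Fraction of the protein length counted as each tail
#'   for region localization.
#' @param fully_disordered_fraction Disorder-content threshold (inclusive)
#'   for calling a protein fully disordered.
#' @return A list of class \code{consensus_config}.
#' @export
consensus_config <- function(ldr_min_len = 30L, sdr_min_len = 5L,
                             majority_fraction = 0.5, tail_fraction = 0.2,
                             fully_disordered_fraction = 0.7) {
  ldr_min_len <- as.integer(ldr_min_len)
  sdr_min_len <- as.integer(sdr_min_len)
  if (!(sdr_min_len > 0L && sdr_min_len < ldr_min_len)) {
    stop("need 0 < sdr_min_len < ldr_min_len")
  }
  if (!(majority_fraction > 0 && majority_fraction < 1)) {
    stop("majority_fraction must lie in (0, 1)")
  }
  if (!(tail_fraction > 0 && tail_fraction < 0.5)) {
    stop("tail_fraction must lie in (0, 0.5)")
  }
  structure(list(ldr_min_len = ldr_min_len, sdr_min_len = sdr_min_len,
                 majority_fraction = majority_fraction,
                 tail_fraction = tail_fraction,
                 fully_disordered_fraction = fully_disordered_fraction),
            class = "consensus_config")
}

#' Read a consensus configuration from a key-value file
#'
#' Plain-text \code{key = value} (or \code{key<TAB>value}) lines overriding
#' the \code{\link{consensus_config}} defaults; unknown keys are an error.
#'
#' @param path Path to the key-value file.
#' @return A \code{consensus_config}.
#' @export
read_consensus_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*|\\t")
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- as.numeric(vapply(kv, `[[`, character(1), 2L))
  args <- as.list(vals)
  names(args) <- trimws(keys)
  known <- names(formals(consensus_config))
  if (!all(names(args) %in% known)) {
    stop("unknown consensus_config keys: ",
         paste(setdiff(names(args), known), collapse = ", "))
  }
  do.call(consensus_config, args)
}

.new_consensus_track <- function(protein_id, rule, states, coverage) {
  structure(list(protein_id = protein_id, rule = rule,
                 states = states, coverage = as.integer(coverage)),
            class = "consensus_track")
}

#' @export
print.consensus_track <- function(x, ...) {
  cat(sprintf("<consensus_track> %s [%s]: %d residues (D=%d, S=%d, U=%d)\n",
              x$protein_id, x$rule, length(x$states),
              sum(x$states == "D"), sum(x$states == "S"),
              sum(x$states == "U")))
  invisible(x)
}

#' Majority-rule disorder consensus
#'
#' For each protein position, chains not covering the position (state
#' \code{"N"}) are excluded and do not affect the decision. With \code{c}
#' covering chains of which \code{m} report the residue missing, the
#' consensus state is \code{"U"} (unknown) when \code{c == 0}, \code{"D"}
#' (disordered) when \code{m/c} strictly exceeds the majority fraction, and
#' \code{"S"} (structured) otherwise -- an exact 50% tie is structured.
#'
#' @param stack A \code{\link{build_stack}} result.
#' @param cfg A \code{\link{consensus_config}}.
#' @return A \code{consensus_track} with per-position states and coverage.
#' @export
majority_consensus <- function(stack, cfg = consensus_config()) {
  if (nrow(stack$tracks) < 1L) stop("stack must contain at least one track")
  m <- colSums(stack$tracks == "M")
  cov <- colSums(stack$tracks != "N")
  states <- ifelse(cov == 0L, "U",
                   ifelse(m > cfg$majority_fraction * cov, "D", "S"))
  .new_consensus_track(stack$protein_id, "majority", states, cov)
}

#' Zero-rule disorder consensus
#'
#' The conservative counterpart of \code{\link{majority_consensus}}: a
#' position is disordered only when it is missing in every chain that
#' covers it; uncovered positions are unknown.
#'
#' @inheritParams majority_consensus
#' @return A \code{consensus_track}.
#' @export
zero_consensus <- function(stack, cfg = consensus_config()) {
  if (nrow(stack$tracks) < 1L) stop("stack must contain at least one track")
  m <- colSums(stack$tracks == "M")
  cov <- colSums(stack$tracks != "N")
  states <- ifelse(cov == 0L, "U", ifelse(m == cov, "D", "S"))
  .new_consensus_track(stack$protein_id, "zero", states, cov)
}

#' Extract disordered regions from a consensus track
#'
#' Regions are maximal runs of consecutive \code{"D"} positions; both
#' structured (\code{"S"}) and unknown (\code{"U"}) positions break a run,
#' so a region never spans uncovered sequence. Runs of at least
#' \code{ldr_min_len} become LDRs, runs in \code{[sdr_min_len,
#' ldr_min_len)} become SDRs, shorter runs are discarded.
#'
#' @param track A \code{consensus_track}.
#' @param cfg A \code{\link{consensus_config}}.
#' @return Data.frame with columns \code{protein_id}, \code{rule},
#'   \code{start}, \code{end}, \code{length}, \code{class}, sorted by start.
#' @export
extract_regions <- function(track, cfg = consensus_config()) {
  runs <- rle(track$states == "D")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= cfg$sdr_min_len
  data.frame(
    protein_id = rep(track$protein_id, sum(keep)),
    rule = rep(track$rule, sum(keep)),
    start = starts[keep],
    end = ends[keep],
    length = runs$lengths[keep],
    class = as.character(ifelse(runs$lengths[keep] >= cfg$ldr_min_len,
                                "LDR", "SDR")),
    stringsAsFactors = FALSE
  )
}

#' Classify a protein by its disordered regions
#'
#' A protein is an LDR-protein if it carries at least one LDR, an
#' SDR-protein if its longest region is an SDR, and structured when no
#' disordered run reaches \code{sdr_min_len}. A protein is additionally
#' flagged fully disordered when its consensus disorder content (fraction
#' of \code{"D"} positions over the full length) reaches
#' \code{fully_disordered_fraction}.
#'
#' @param regions Region data.frame for the protein (one rule).
#' @param track The matching \code{consensus_track}.
#' @param cfg A \code{\link{consensus_config}}.
#' @return List with \code{protein_id}, \code{category} and
#'   \code{fully_disordered}.
#' @export
classify_protein <- function(regions, track, cfg = consensus_config()) {
  category <- if (any(regions$class == "LDR")) {
    "LDR-protein"
  } else if (any(regions$class == "SDR")) {
    "SDR-protein"
  } else {
    "structured"
  }
  content <- sum(track$states == "D") / length(track$states)
  list(protein_id = track$protein_id,
       category = category,
       fully_disordered = content >= cfg$fully_disordered_fraction)
}

#' Consensus-difference regions (majority minus zero)
#'
#' Positions inside a majority LDR that are structured under the zero rule
#' are disordered in more than half of the chains but ordered in at least
#' one -- candidate context-dependent or fold-upon-binding segments. For
#' each majority LDR the function returns the maximal sub-intervals of such
#' positions, and whether the LDR is confirmed by the zero rule, i.e.
#' contains a zero-consensus disordered run of at least \code{ldr_min_len}
#' within its span.
#'
#' @param majority_regions Region data.frame from the majority rule.
#' @param zero_track The protein's zero-rule \code{consensus_track}.
#' @param cfg A \code{\link{consensus_config}}.
#' @return List with \code{difference} (data.frame \code{protein_id},
#'   \code{start}, \code{end}, \code{length}) and \code{ldr_confirmation}
#'   (data.frame \code{protein_id}, \code{start}, \code{end},
#'   \code{confirmed}).
#' @export
consensus_difference <- function(majority_regions, zero_track,
                                 cfg = consensus_config()) {
  ldrs <- majority_regions[majority_regions$class == "LDR", , drop = FALSE]
  diffs <- list()
  confirmed <- logical(nrow(ldrs))
  for (i in seq_len(nrow(ldrs))) {
    span <- ldrs$start[i]:ldrs$end[i]
    z <- zero_track$states[span]
    runs <- rle(z == "S")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values
    if (any(keep)) {
      diffs[[length(diffs) + 1L]] <- data.frame(
        protein_id = zero_track$protein_id,
        start = ldrs$start[i] + starts[keep] - 1L,
        end = ldrs$start[i] + ends[keep] - 1L,
        length = runs$lengths[keep],
        stringsAsFactors = FALSE
      )
    }
    druns <- rle(z == "D")
    confirmed[i] <- any(druns$values & druns$lengths >= cfg$ldr_min_len)
  }
  difference <- if (length(diffs)) {
    do.call(rbind, diffs)
  } else {
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), length = integer(0),
               stringsAsFactors = FALSE)
  }
  list(
    difference = difference,
    ldr_confirmation = data.frame(
      protein_id = ldrs$protein_id, start = ldrs$start, end = ldrs$end,
      confirmed = confirmed, stringsAsFactors = FALSE)
  )
}

#' Write consensus tracks as a per-position TSV
#'
#' @param majority,zero Matching \code{consensus_track} objects for one
#'   protein.
#' @param sequence Protein sequence string.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_consensus_tsv <- function(majority, zero, sequence, path) {
  stopifnot(majority$protein_id == zero$protein_id,
            length(majority$states) == length(zero$states))
  df <- data.frame(
    protein_id = majority$protein_id,
    position = seq_along(majority$states),
    residue = strsplit(sequence, "")[[1L]],
    majority_state = majority$states,
    zero_state = zero$states,
    coverage = majority$coverage,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write regions as TSV
#'
#' @param regions Region data.frame (1-based inclusive coordinates).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run both consensus rules over a set of stacks
#'
#' Convenience driver: computes majority and zero tracks, extracts regions
#' under both rules and classifies each protein under the majority rule.
#'
#' @param stacks List of \code{\link{build_stack}} results.
#' @param cfg A \code{\link{consensus_config}}.
#' @return List with \code{majority_tracks}, \code{zero_tracks} (named by
#'   protein), \code{regions} (row-bound data.frame over both rules) and
#'   \code{classes} (data.frame \code{protein_id}, \code{category},
#'   \code{fully_disordered}).
#' @export
consensus_pipeline <- function(stacks, cfg = consensus_config()) {
  ids <- vapply(stacks, `[[`, character(1), "protein_id")
  maj <- lapply(stacks, majority_consensus, cfg = cfg)
  zer <- lapply(stacks, zero_consensus, cfg = cfg)
  names(maj) <- ids
  names(zer) <- ids
  reg_maj <- lapply(maj, extract_regions, cfg = cfg)
  reg_zer <- lapply(zer, extract_regions, cfg = cfg)
  regions <- do.call(rbind, c(reg_maj, reg_zer))
  rownames(regions) <- NULL
  cls <- lapply(ids, function(id)
    classify_protein(reg_maj[[id]], maj[[id]], cfg))
  classes <- data.frame(
    protein_id = ids,
    category = vapply(cls, `[[`, character(1), "category"),
    fully_disordered = vapply(cls, `[[`, logical(1), "fully_disordered"),
    stringsAsFactors = FALSE
  )
  list(majority_tracks = maj, zero_tracks = zer,
       regions = regions, classes = classes)
}
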