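# Dataset-level summaries of consensus tracks and regions.

#' Round half-up to a fixed number of decimals
#'
#' Table percentages use commercial (half-up) rounding rather than R's
#' banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Disorder content of a residue accounting
#'
#' Fraction of missing (disordered) residues, optionally excluding unknown
#' residues (those covered by no crystallized construct) from the
#' denominator.
#'
#' @param acc List or one-row data.frame with fields \code{missing},
#'   \code{observed}, \code{unknown}.
#' @param exclude_unknown Drop unknown residues from the denominator.
#' @return Fraction in \code{[0, 1]}.
#' @examples
#' disorder_content(list(missing = 10, observed = 70, unknown = 20))
#' @export
disorder_content <- function(acc, exclude_unknown = FALSE) {
  m <- as.numeric(acc$missing)
  denom <- m + as.numeric(acc$observed) +
    if (exclude_unknown) 0 else as.numeric(acc$unknown)
  if (any(c(m, denom) < 0)) stop("residue counts must be non-negative")
  if (denom == 0) stop("disorder content undefined: zero denominator")
  m / denom
}

.residue_accounting <- function(tracks) {
  states <- unlist(lapply(tracks, `[[`, "states"), use.names = FALSE)
  list(missing = sum(states == "D"), observed = sum(states == "S"),
       unknown = sum(states == "U"))
}

#' Dataset composition summary
#'
#' Per protein category (LDR-proteins, SDR-proteins, structured, and a
#' total row): protein count, median protein length, SDR and LDR counts,
#' and a residue accounting where consensus \code{D} counts as missing,
#' \code{S} as observed and \code{U} as unknown, with percentages of the
#' category's total residues (half-up, one decimal).
#'
#' @param classes Data.frame \code{protein_id}, \code{category} (from
#'   \code{\link{consensus_pipeline}} or \code{\link{classify_protein}}).
#' @param tracks Named list of majority \code{consensus_track}s.
#' @param regions Region data.frame (majority rule rows are counted).
#' @return Data.frame, one row per category plus \code{total}.
#' @export
summarize_dataset <- function(classes, tracks, regions) {
  cats <- c("LDR-protein", "SDR-protein", "structured")
  regions <- regions[regions$rule == "majority", , drop = FALSE]
  row_for <- function(ids, label) {
    trk <- tracks[ids]
    acc <- .residue_accounting(trk)
    tot <- acc$missing + acc$observed + acc$unknown
    reg <- regions[regions$protein_id %in% ids, , drop = FALSE]
    data.frame(
      category = label,
      n_proteins = length(ids),
      median_length = if (length(ids)) {
        stats::median(vapply(trk, function(t) length(t$states), numeric(1)))
      } else NA_real_,
      n_sdr = sum(reg$class == "SDR"),
      n_ldr = sum(reg$class == "LDR"),
      missing = acc$missing,
      observed = acc$observed,
      unknown = acc$unknown,
      missing_pct = if (tot) round_half_up(100 * acc$missing / tot) else 0,
      observed_pct = if (tot) round_half_up(100 * acc$observed / tot) else 0,
      unknown_pct = if (tot) round_half_up(100 * acc$unknown / tot) else 0,
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(cats, function(cat)
    row_for(classes$protein_id[classes$category == cat], cat))
  rows[[length(rows) + 1L]] <- row_for(classes$protein_id, "total")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram of region lengths
#'
#' Bins of \code{bin_width} residues starting at \code{origin} (by default
#' the LDR threshold, giving bins [30,39], [40,49], ...).
#'
#' @param lengths Integer vector of region lengths, or a region data.frame
#'   with a \code{length} column.
#' @param bin_width Bin width in residues.
#' @param origin Start of the first bin.
#' @return Data.frame \code{bin_start}, \code{bin_end}, \code{count};
#'   empty input gives zero rows.
#' @export
length_histogram <- function(lengths, bin_width = 10L, origin = 30L) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (length(lengths) == 0L) {
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0)))
  }
  if (any(lengths < origin)) {
    stop("region lengths below the first bin origin (", origin, ")")
  }
  idx <- (lengths - origin) %/% bin_width
  counts <- table(factor(idx, levels = 0:max(idx)))
  data.frame(
    bin_start = origin + bin_width * (0:max(idx)),
    bin_end = origin + bin_width * (1:(max(idx) + 1L)) - 1L,
    count = as.integer(counts)
  )
}

#' Fraction of regions within a length range
#'
#' @param lengths Region lengths (vector or region data.frame).
#' @param lo,hi Inclusive length bounds.
#' @return Fraction of regions with length in \code{[lo, hi]}.
#' @export
fraction_in_length_range <- function(lengths, lo, hi) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (length(lengths) == 0L) stop("no regions supplied")
  mean(lengths >= lo & lengths <= hi)
}

#' Localize a region within its protein
#'
#' A region covering the whole sequence is \code{"full"}. Tails span
#' \code{ceiling(tail_fraction * L)} positions at each end; a region
#' reaching into the N-tail is \code{"N-terminal"}, into the C-tail
#' \code{"C-terminal"}, otherwise \code{"middle"}. A non-full region
#' touching both tails is labelled by the tail holding its larger overlap,
#' with ties going N-terminal.
#'
#' @param start,end Region bounds (1-based inclusive).
#' @param protein_length Full protein length.
#' @param tail_fraction Tail size as a fraction of the protein length.
#' @return One of \code{"full"}, \code{"N-terminal"}, \code{"C-terminal"},
#'   \code{"middle"}.
#' @export
localize_region <- function(start, end, protein_length, tail_fraction = 0.2) {
  if (start < 1L || end > protein_length || end < start) {
    stop("region outside protein bounds")
  }
  if (start == 1L && end == protein_length) return("full")
  tail_len <- ceiling(tail_fraction * protein_length)
  n_tail_end <- tail_len
  c_tail_start <- protein_length - tail_len + 1L
  in_n <- start <= n_tail_end
  in_c <- end >= c_tail_start
  if (in_n && in_c) {
    n_overlap <- min(end, n_tail_end) - start + 1L
    c_overlap <- end - max(start, c_tail_start) + 1L
    return(if (n_overlap >= c_overlap) "N-terminal" else "C-terminal")
  }
  if (in_n) return("N-terminal")
  if (in_c) return("C-terminal")
  "middle"
}

#' Localize every region in a table
#'
#' @param regions Region data.frame.
#' @param protein_lengths Named integer vector of protein lengths.
#' @param tail_fraction Tail size as a fraction of the protein length.
#' @return \code{regions} with an added \code{localization} column.
#' @export
localize_regions <- function(regions, protein_lengths, tail_fraction = 0.2) {
  regions$localization <- vapply(seq_len(nrow(regions)), function(i) {
    localize_region(regions$start[i], regions$end[i],
                    protein_lengths[[regions$protein_id[i]]], tail_fraction)
  }, character(1))
  regions
}

#' Amino-acid enrichment of region sequences
#'
#' Fold change of each amino acid's frequency in the target sequences
#' relative to a background set (typically all SEQRES sequences). Amino
#' acids absent from the background have an undefined fold (NA).
#'
#' @param region_sequences Character vector of target sequences.
#' @param background_sequences Character vector of background sequences.
#' @return Data.frame \code{aa}, \code{target_freq}, \code{background_freq},
#'   \code{fold}, over the 20 standard amino acids.
#' @export
aa_enrichment <- function(region_sequences, background_sequences) {
  aas <- sort(unname(.AA1))
  freq <- function(seqs) {
    chars <- unlist(strsplit(paste(seqs, collapse = ""), ""), use.names = FALSE)
    chars <- chars[chars %in% aas]
    if (length(chars) == 0L) stop("no standard amino acids in sequences")
    tab <- table(factor(chars, levels = aas))
    as.numeric(tab) / length(chars)
  }
  tf <- freq(region_sequences)
  bf <- freq(background_sequences)
  data.frame(
    aa = aas,
    target_freq = tf,
    background_freq = bf,
    fold = ifelse(bf > 0, tf / bf, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Distribution of LDR counts per protein
#'
#' @param regions Region data.frame; only rows with class \code{"LDR"} are
#'   counted.
#' @return Data.frame \code{k} (number of LDRs), \code{n_proteins},
#'   \code{pct} (half-up, one decimal, of LDR-carrying proteins); zero rows
#'   when no protein carries an LDR.
#' @export
count_regions_per_protein <- function(regions) {
  ldr <- regions[regions$class == "LDR", , drop = FALSE]
  if (nrow(ldr) == 0L) {
    return(data.frame(k = integer(0), n_proteins = integer(0),
                      pct = numeric(0)))
  }
  per <- table(ldr$protein_id)
  dist <- table(as.integer(per))
  total <- sum(dist)
  data.frame(
    k = as.integer(names(dist)),
    n_proteins = as.integer(dist),
    pct = round_half_up(100 * as.integer(dist) / total)
  )
}

#' Protein-level overlap between two region sets
#'
#' Compares the proteins carrying regions in two externally supplied sets
#' (e.g. this pipeline's LDR proteins against a curated disorder database).
#'
#' @param set_a,set_b Character vectors of protein ids, or region
#'   data.frames with a \code{protein_id} column.
#' @return List with id vectors \code{intersection}, \code{only_a},
#'   \code{only_b} and the matching counts \code{n_intersection},
#'   \code{n_only_a}, \code{n_only_b}, \code{n_a}, \code{n_b}.
#' @export
compare_region_sets <- function(set_a, set_b) {
  if (is.data.frame(set_a)) set_a <- set_a$protein_id
  if (is.data.frame(set_b)) set_b <- set_b$protein_id
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  both <- intersect(a, b)
  list(intersection = both,
       only_a = setdiff(a, b),
       only_b = setdiff(b, a),
       n_intersection = length(both),
       n_only_a = length(setdiff(a, b)),
       n_only_b = length(setdiff(b, a)),
       n_a = length(a), n_b = length(b))
}
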