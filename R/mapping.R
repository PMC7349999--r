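#' Read chain-to-protein mapping segments
#'
#' SIFTS-like residue-level mapping between deposited chain constructs and
#' full protein sequences. Each row is an affine segment: chain SEQRES
#' positions \code{chain_start..chain_end} map one-to-one onto protein
#' positions \code{protein_start..protein_end} (all 1-based inclusive).
#'
#' @param path TSV file with columns \code{structure_id}, \code{chain_id},
#'   \code{chain_start}, \code{chain_end}, \code{protein_id},
#'   \code{protein_start}, \code{protein_end}.
#' @return A data.frame of validated mapping segments.
#' @export
read_mapping_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_mapping_segments(df)
}

#' Validate mapping segments
#'
#' Checks the affine-length invariant (chain span equals protein span) and
#' that segments of one (structure, chain, protein) triple do not overlap on
#' either axis.
#'
#' @param segments Mapping segment data.frame (see
#'   \code{\link{read_mapping_tsv}}).
#' @return The validated data.frame.
#' @export
validate_mapping_segments <- function(segments) {
  required <- c("structure_id", "chain_id", "chain_start", "chain_end",
                "protein_id", "protein_start", "protein_end")
  if (!all(required %in% names(segments))) {
    stop("mapping segments must have columns: ",
         paste(required, collapse = ", "))
  }
  for (col in c("chain_start", "chain_end", "protein_start", "protein_end")) {
    segments[[col]] <- as.integer(segments[[col]])
  }
  if (nrow(segments) == 0L) return(segments)
  if (any(segments$chain_start < 1L) || any(segments$protein_start < 1L) ||
      any(segments$chain_end < segments$chain_start) ||
      any(segments$protein_end < segments$protein_start)) {
    stop("mapping segments must be 1-based with end >= start")
  }
  if (any(segments$chain_end - segments$chain_start !=
          segments$protein_end - segments$protein_start)) {
    stop("mapping segment spans differ between chain and protein axes")
  }
  key <- interaction(segments$structure_id, segments$chain_id,
                     segments$protein_id, drop = TRUE)
  for (grp in split(seq_len(nrow(segments)), key)) {
    if (length(grp) < 2L) next
    s <- segments[grp, , drop = FALSE]
    s <- s[order(s$chain_start), , drop = FALSE]
    if (any(s$chain_start[-1L] <= s$chain_end[-nrow(s)])) {
      stop("overlapping chain intervals in mapping segments for ",
           s$structure_id[1L], " chain ", s$chain_id[1L])
    }
    s <- s[order(s$protein_start), , drop = FALSE]
    if (any(s$protein_start[-1L] <= s$protein_end[-nrow(s)])) {
      stop("overlapping protein intervals in mapping segments for ",
           s$structure_id[1L], " chain ", s$chain_id[1L])
    }
  }
  segments
}

#' Stack chain observation tracks in protein coordinates
#'
#' Projects every mapped (structure, chain) observation onto the protein
#' sequence. Inside a mapping segment a protein position inherits the
#' \code{"O"}/\code{"M"} state of the corresponding chain position; protein
#' positions outside all segments of a chain are \code{"N"} (not covered by
#' that crystallized construct). Each deposited chain contributes exactly
#' one track and counts as one independent vote in the consensus, even when
#' several chains belong to one structure.
#'
#' @param observations List of \code{\link{chain_observation}}.
#' @param segments Mapping segment data.frame (validated internally); all
#'   rows must reference \code{protein_id}.
#' @param protein_id Target protein identifier.
#' @param sequence Full protein amino-acid sequence (one-letter string).
#' @return An object of class \code{protein_track_stack}: list with
#'   \code{protein_id}, \code{sequence}, \code{length}, a character matrix
#'   \code{tracks} (rows = chains, columns = protein positions, cells in
#'   \code{O}/\code{M}/\code{N}) and a data.frame \code{track_ids}.
#' @export
build_stack <- function(observations, segments, protein_id, sequence) {
  segments <- validate_mapping_segments(segments)
  if (!all(segments$protein_id == protein_id)) {
    stop("all mapping segments must reference protein '", protein_id, "'")
  }
  L <- nchar(sequence)
  if (any(segments$protein_end > L)) {
    stop("mapping segment extends beyond protein length ", L)
  }

  obs_key <- vapply(observations, function(o)
    paste(o$structure_id, o$chain_id, sep = "\r"), character(1))
  seg_key <- paste(segments$structure_id, segments$chain_id, sep = "\r")
  track_keys <- unique(seg_key)
  if (length(track_keys) == 0L) {
    stop("no mapping segments for protein '", protein_id, "'")
  }

  tracks <- matrix("N", nrow = length(track_keys), ncol = L)
  ids <- data.frame(structure_id = character(length(track_keys)),
                    chain_id = character(length(track_keys)),
                    stringsAsFactors = FALSE)
  for (t in seq_along(track_keys)) {
    key <- track_keys[t]
    oi <- which(obs_key == key)
    segs <- segments[seg_key == key, , drop = FALSE]
    ids$structure_id[t] <- segs$structure_id[1L]
    ids$chain_id[t] <- segs$chain_id[1L]
    if (length(oi) == 0L) {
      stop("no observation for mapped chain ",
           segs$structure_id[1L], " ", segs$chain_id[1L])
    }
    obs <- observations[[oi[1L]]]
    if (any(segs$chain_end > obs$seqres_length)) {
      stop("mapping segment exceeds SEQRES length of chain ",
           obs$structure_id, " ", obs$chain_id)
    }
    for (s in seq_len(nrow(segs))) {
      ppos <- segs$protein_start[s]:segs$protein_end[s]
      cpos <- segs$chain_start[s]:segs$chain_end[s]
      tracks[t, ppos] <- obs$states[cpos]
    }
  }
  rownames(tracks) <- gsub("\r", "_", track_keys, fixed = TRUE)

  structure(
    list(protein_id = protein_id, sequence = sequence, length = L,
         tracks = tracks, track_ids = ids),
    class = "protein_track_stack"
  )
}

#' @export
print.protein_track_stack <- function(x, ...) {
  cat(sprintf("<protein_track_stack> %s: %d residues, %d chain tracks\n",
              x$protein_id, x$length, nrow(x$tracks)))
  invisible(x)
}
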