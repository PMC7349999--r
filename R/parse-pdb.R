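# Amino-acid code tables used by the PDB parser/writer. Non-standard
# residues stay as-is in 3-letter form; they map to "X" in 1-letter form.

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.AA3 <- structure(names(.AA1), names = unname(.AA1))

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (length(text) == 1L) {
    return(strsplit(text, "\n", fixed = TRUE)[[1L]])
  }
  text
}

#' Parse missing residues from a PDB file
#'
#' Reads SEQRES records to obtain the full deposited sequence of each polymer
#' chain and REMARK 465 records to flag unobserved (missing) residues. Each
#' chain becomes one \code{\link{chain_observation}}: every SEQRES position
#' listed in REMARK 465 is \code{"M"}, all others \code{"O"}. Chains with no
#' REMARK 465 entries are all-\code{"O"}.
#'
#' REMARK 465 residue numbers are interpreted as SEQRES positions and
#' validated against the SEQRES residue name at that position; records that
#' cannot be resolved (out of range, insertion codes, name mismatch, unknown
#' chain) are dropped with a warning. Only the first model is read. Modeled
#' residues with alternate conformations or zero occupancy are not missing.
#'
#' @param pdb_text PDB file content (single string, character vector of
#'   lines, or a file path).
#' @param structure_id Optional structure identifier; defaults to the HEADER
#'   idCode when present.
#' @return List of \code{\link{chain_observation}}, one per SEQRES chain.
#' @export
parse_pdb_missing <- function(pdb_text, structure_id = NULL) {
  lines <- .as_lines(pdb_text)

  seqres <- grep("^SEQRES", lines, value = TRUE)
  if (length(seqres) == 0L) {
    stop("no SEQRES records found: cannot establish chain sequences")
  }
  chain_ids <- substr(seqres, 12, 12)
  res_fields <- lapply(seqres, function(l) {
    toks <- strsplit(trimws(substr(l, 20, nchar(l))), "\\s+")[[1L]]
    toks[nzchar(toks)]
  })
  chains <- unique(chain_ids)
  seqres_by_chain <- lapply(chains, function(ch) {
    unlist(res_fields[chain_ids == ch], use.names = FALSE)
  })
  names(seqres_by_chain) <- chains

  year <- NA_integer_
  header <- grep("^HEADER", lines, value = TRUE)
  if (length(header) >= 1L) {
    date <- trimws(substr(header[1L], 51, 59))
    if (grepl("^\\d{2}-[A-Z]{3}-\\d{2}$", date)) {
      yy <- as.integer(substr(date, 8, 9))
      year <- if (yy >= 50L) 1900L + yy else 2000L + yy
    }
    if (is.null(structure_id)) {
      id <- trimws(substr(header[1L], 63, 66))
      if (nzchar(id)) structure_id <- id
    }
  }
  if (is.null(structure_id)) structure_id <- "UNKNOWN"

  missing_by_chain <- lapply(chains, function(ch) integer(0))
  names(missing_by_chain) <- chains

  r465 <- grep("^REMARK 465", lines, value = TRUE)
  for (line in r465) {
    toks <- strsplit(trimws(line), "\\s+")[[1L]]
    rest <- toks[-(1:2)]
    # data lines: [model] resname chain resseq; anything else is a header
    if (length(rest) == 4L && grepl("^\\d+$", rest[1L])) {
      if (rest[1L] != "1") next  # only the first model
      rest <- rest[-1L]
    }
    if (length(rest) != 3L) next
    resname <- rest[1L]
    ch <- rest[2L]
    if (!grepl("^[A-Z0-9]{1,3}$", resname) || nchar(ch) != 1L) next
    if (!grepl("^-?\\d+$", rest[3L])) {
      if (ch %in% chains) {
        warning(sprintf(
          "REMARK 465 residue %s %s %s not resolvable to a SEQRES position; record dropped",
          resname, ch, rest[3L]))
      }
      next
    }
    pos <- as.integer(rest[3L])
    if (!ch %in% chains) {
      warning(sprintf("REMARK 465 names unknown chain '%s'; record dropped", ch))
      next
    }
    sr <- seqres_by_chain[[ch]]
    if (pos < 1L || pos > length(sr) || sr[pos] != resname) {
      warning(sprintf(
        "REMARK 465 residue %s %s %d does not match SEQRES; record dropped",
        resname, ch, pos))
      next
    }
    missing_by_chain[[ch]] <- c(missing_by_chain[[ch]], pos)
  }

  lapply(chains, function(ch) {
    states <- rep("O", length(seqres_by_chain[[ch]]))
    states[unique(missing_by_chain[[ch]])] <- "M"
    chain_observation(structure_id, ch, states, release_year = year)
  })
}

#' Write a minimal PDB file carrying observation records
#'
#' Emits HEADER, SEQRES and REMARK 465 records for a single chain so that
#' \code{\link{parse_pdb_missing}} round-trips the observation exactly. The
#' residue numbering written to REMARK 465 equals the SEQRES position.
#'
#' @param obs A \code{\link{chain_observation}}.
#' @param sequence One-letter amino-acid string of the chain construct
#'   (length \code{obs$seqres_length}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb_observation <- function(obs, sequence, path) {
  aa1 <- strsplit(sequence, "")[[1L]]
  if (length(aa1) != obs$seqres_length) {
    stop("sequence length does not match seqres_length")
  }
  res3 <- unname(.AA3[aa1])
  res3[is.na(res3)] <- "UNK"

  yy <- obs$release_year
  date <- if (is.na(yy)) "01-JAN-00" else
    sprintf("01-JAN-%02d", yy %% 100L)
  id4 <- toupper(substr(sprintf("%-4s", obs$structure_id), 1, 4))
  lines <- sprintf("%-50s%9s   %4s", "HEADER    SYNTHETIC PROTEIN", date, id4)

  lines <- c(lines,
             "REMARK 465",
             "REMARK 465 MISSING RESIDUES",
             "REMARK 465 THE FOLLOWING RESIDUES WERE NOT LOCATED IN THE",
             "REMARK 465 EXPERIMENT. (M=MODEL NUMBER; RES=RESIDUE NAME;",
             "REMARK 465 C=CHAIN IDENTIFIER; SSSEQ=SEQUENCE NUMBER;)",
             "REMARK 465",
             "REMARK 465   M RES C SSSEQI")
  miss <- which(obs$states == "M")
  if (length(miss)) {
    lines <- c(lines, sprintf("REMARK 465     %-3s %s %5d",
                              res3[miss], obs$chain_id, miss))
  }

  n <- length(res3)
  ser <- 0L
  for (i in seq(1L, n, by = 13L)) {
    ser <- ser + 1L
    block <- res3[i:min(i + 12L, n)]
    lines <- c(lines, sprintf("SEQRES %3d %s %4d  %s",
                              ser, obs$chain_id, n,
                              paste(sprintf("%-3s", block), collapse = " ")))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
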