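#' Per-chain residue observation track
#'
#' A \code{chain_observation} records, for one deposited polymer chain, which
#' SEQRES positions were modeled in the crystal structure (\code{"O"},
#' observed) and which are missing from the model (\code{"M"}, no atomic
#' coordinates -- the crystallographic proxy for intrinsic disorder).
#' Positions are 1-based SEQRES indices over the full deposited construct
#' sequence, independent of which residues were actually modeled.
#'
#' @param structure_id Identifier of the deposited structure (e.g. a PDB id).
#' @param chain_id Single chain identifier within the structure.
#' @param states Character vector over \code{c("O", "M")}, one element per
#'   SEQRES position.
#' @param release_year Optional integer deposition/release year.
#' @return An object of class \code{chain_observation} with fields
#'   \code{structure_id}, \code{chain_id}, \code{seqres_length},
#'   \code{states} and \code{release_year}.
#' @examples
#' obs <- chain_observation("1ABC", "A", c("M", "M", "O", "O", "O"))
#' missing_fraction_per_chain(obs)
#' @export
chain_observation <- function(structure_id, chain_id, states,
                              release_year = NA_integer_) {
  if (!is.character(structure_id) || length(structure_id) != 1L ||
      is.na(structure_id) || !nzchar(structure_id)) {
    stop("'structure_id' must be a non-empty string")
  }
  if (length(chain_id) != 1L || is.na(chain_id) || !nzchar(chain_id)) {
    stop("'chain_id' must be a non-empty string")
  }
  states <- as.character(states)
  if (length(states) < 1L) {
    stop("'states' must have at least one position")
  }
  bad <- !states %in% c("O", "M")
  if (any(bad)) {
    stop("'states' may only contain \"O\" and \"M\"; offending value: ",
         states[which(bad)[1L]])
  }
  structure(
    list(structure_id = structure_id,
         chain_id = as.character(chain_id),
         seqres_length = length(states),
         states = states,
         release_year = as.integer(release_year)),
    class = "chain_observation"
  )
}

#' @export
print.chain_observation <- function(x, ...) {
  cat(sprintf("<chain_observation> %s chain %s: %d residues, %d missing\n",
              x$structure_id, x$chain_id, x$seqres_length,
              sum(x$states == "M")))
  invisible(x)
}

#' Write chain observations to the tabular dialect
#'
#' One row per chain: \code{structure_id}, \code{chain_id} and the state
#' string over \code{O}/\code{M} (one letter per SEQRES position).
#'
#' @param observations List of \code{\link{chain_observation}} objects.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_observations_tsv <- function(observations, path) {
  df <- data.frame(
    structure_id = vapply(observations, `[[`, character(1), "structure_id"),
    chain_id = vapply(observations, `[[`, character(1), "chain_id"),
    states = vapply(observations, function(o) paste(o$states, collapse = ""),
                    character(1)),
    release_year = vapply(observations, `[[`, integer(1), "release_year"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read chain observations from the tabular dialect
#'
#' @param path File written by \code{\link{write_observations_tsv}}.
#' @return List of \code{\link{chain_observation}} objects.
#' @export
read_observations_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("structure_id", "chain_id", "states")
  if (!all(required %in% names(df))) {
    stop("observation table must have columns: ",
         paste(required, collapse = ", "))
  }
  year <- if ("release_year" %in% names(df)) {
    suppressWarnings(as.integer(df$release_year))
  } else {
    rep(NA_integer_, nrow(df))
  }
  lapply(seq_len(nrow(df)), function(i) {
    chain_observation(df$structure_id[i], df$chain_id[i],
                      strsplit(df$states[i], "")[[1L]],
                      release_year = year[i])
  })
}
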