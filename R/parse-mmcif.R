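# Minimal mmCIF reader for the observation-related categories. Handles
# data_ blocks, loop_ tables and simple tag/value pairs with single- or
# double-quoted tokens; multi-line semicolon text fields are not needed for
# these categories and are rejected.

.cif_tokenize <- function(lines) {
  lines <- sub("^\\s*#.*$", "", lines)
  if (any(grepl("^;", lines))) {
    stop("semicolon text fields are not supported in this mmCIF dialect")
  }
  pat <- "'[^']*'|\"[^\"]*\"|\\S+"
  toks <- unlist(regmatches(lines, gregexpr(pat, lines)), use.names = FALSE)
  sub("^['\"]", "", sub("['\"]$", "", toks))
}

.cif_parse <- function(cif_text) {
  toks <- .cif_tokenize(.as_lines(cif_text))
  n <- length(toks)
  cats <- list()
  block_id <- NA_character_
  i <- 1L
  is_tag <- function(t) startsWith(t, "_")
  store <- function(cats, tags, vals) {
    cat_names <- sub("\\..*$", "", tags)
    item_names <- sub("^[^.]*\\.", "", tags)
    m <- matrix(vals, ncol = length(tags), byrow = TRUE)
    for (cn in unique(cat_names)) {
      sel <- cat_names == cn
      df <- as.data.frame(m[, sel, drop = FALSE], stringsAsFactors = FALSE)
      names(df) <- item_names[sel]
      cats[[cn]] <- df
    }
    cats
  }
  while (i <= n) {
    tok <- toks[i]
    if (startsWith(tok, "data_")) {
      block_id <- sub("^data_", "", tok)
      i <- i + 1L
    } else if (tok == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && is_tag(toks[i])) {
        tags <- c(tags, toks[i]); i <- i + 1L
      }
      j <- i
      while (j <= n && !is_tag(toks[j]) && toks[j] != "loop_" &&
             !startsWith(toks[j], "data_")) j <- j + 1L
      vals <- toks[seq_len(j - i) + i - 1L]
      if (length(tags) == 0L || length(vals) %% length(tags) != 0L) {
        stop("malformed mmCIF loop_ at token ", i)
      }
      cats <- store(cats, tags, vals)
      i <- j
    } else if (is_tag(tok)) {
      if (i + 1L > n) stop("dangling mmCIF tag ", tok)
      cats <- store(cats, tok, toks[i + 1L])
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  list(block_id = block_id, categories = cats)
}

.cif_col <- function(df, name) {
  if (!is.null(df) && name %in% names(df)) df[[name]] else NULL
}

#' Parse missing residues from an mmCIF file
#'
#' The mmCIF counterpart of \code{\link{parse_pdb_missing}}, with an
#' identical contract. Chain sequences come from \code{_entity_poly_seq}
#' (chains resolved through \code{_struct_asym}, or \code{_atom_site} when
#' absent); unobserved residues come from
#' \code{_pdbx_unobs_or_zero_occ_residues}. When that category is missing,
#' the fallback marks as missing every declared position with no
#' \code{_atom_site} record. Only model 1 rows are considered and
#' non-polymer rows are ignored.
#'
#' @param cif_text mmCIF content (single string, character vector of lines,
#'   or a file path).
#' @param structure_id Optional override for the data block id.
#' @return List of \code{\link{chain_observation}}, one per polymer chain.
#' @export
parse_mmcif_missing <- function(cif_text, structure_id = NULL) {
  parsed <- .cif_parse(cif_text)
  cats <- parsed$categories
  if (is.null(structure_id)) {
    structure_id <- if (!is.na(parsed$block_id) && nzchar(parsed$block_id)) {
      parsed$block_id
    } else "UNKNOWN"
  }

  eps <- cats[["_entity_poly_seq"]]
  if (is.null(eps) || nrow(eps) == 0L) {
    stop("no polymer entities declared (_entity_poly_seq absent or empty)")
  }
  eps$num <- as.integer(eps$num)
  if (anyNA(eps$num)) stop("non-integer _entity_poly_seq.num")

  atom <- cats[["_atom_site"]]
  asym <- cats[["_struct_asym"]]
  if (!is.null(asym)) {
    chain2entity <- structure(asym$entity_id, names = asym$id)
  } else if (!is.null(atom)) {
    u <- unique(data.frame(id = atom$label_asym_id,
                           entity_id = atom$label_entity_id,
                           stringsAsFactors = FALSE))
    chain2entity <- structure(u$entity_id, names = u$id)
  } else {
    stop("cannot resolve chains: neither _struct_asym nor _atom_site present")
  }

  seqres_by_chain <- lapply(names(chain2entity), function(ch) {
    rows <- eps[eps$entity_id == chain2entity[[ch]], , drop = FALSE]
    rows$mon_id[order(rows$num)]
  })
  names(seqres_by_chain) <- names(chain2entity)
  seqres_by_chain <- Filter(function(s) length(s) > 0L, seqres_by_chain)
  if (length(seqres_by_chain) == 0L) {
    stop("no polymer chains with declared sequence positions")
  }
  chains <- names(seqres_by_chain)

  unobs <- cats[["_pdbx_unobs_or_zero_occ_residues"]]
  missing_by_chain <- lapply(chains, function(ch) integer(0))
  names(missing_by_chain) <- chains

  if (!is.null(unobs) && nrow(unobs) > 0L) {
    keep <- rep(TRUE, nrow(unobs))
    pf <- .cif_col(unobs, "polymer_flag")
    if (!is.null(pf)) keep <- keep & pf %in% c("Y", "y", ".", "?")
    mod <- .cif_col(unobs, "PDB_model_num")
    if (!is.null(mod)) keep <- keep & mod %in% c("1", ".", "?")
    unobs <- unobs[keep, , drop = FALSE]

    ch_col <- .cif_col(unobs, "label_asym_id")
    seq_col <- .cif_col(unobs, "label_seq_id")
    use_label <- !is.null(ch_col) && !is.null(seq_col) &&
      !all(seq_col %in% c(".", "?"))
    if (!use_label) {
      ch_col <- .cif_col(unobs, "auth_asym_id")
      seq_col <- .cif_col(unobs, "auth_seq_id")
    }
    comp_col <- if (use_label) .cif_col(unobs, "label_comp_id") else
      .cif_col(unobs, "auth_comp_id")
    if (is.null(ch_col) || is.null(seq_col)) {
      stop("unobserved-residue category lacks chain/position columns")
    }
    for (k in seq_along(ch_col)) {
      ch <- ch_col[k]
      if (!ch %in% chains) {
        stop(sprintf("cannot reconcile numbering: unobserved residue names unknown chain '%s'", ch))
      }
      pos <- suppressWarnings(as.integer(seq_col[k]))
      sr <- seqres_by_chain[[ch]]
      if (is.na(pos) || pos < 1L || pos > length(sr) ||
          (!is.null(comp_col) && sr[pos] != comp_col[k])) {
        stop(sprintf("cannot reconcile label/auth numbering for chain '%s' at position '%s'",
                     ch, seq_col[k]))
      }
      missing_by_chain[[ch]] <- c(missing_by_chain[[ch]], pos)
    }
  } else {
    if (is.null(atom)) {
      stop("neither _pdbx_unobs_or_zero_occ_residues nor _atom_site present")
    }
    for (ch in chains) {
      rows <- atom$label_asym_id == ch
      modeled <- unique(suppressWarnings(
        as.integer(atom$label_seq_id[rows])))
      modeled <- modeled[!is.na(modeled)]
      L <- length(seqres_by_chain[[ch]])
      missing_by_chain[[ch]] <- setdiff(seq_len(L), modeled)
    }
  }

  lapply(chains, function(ch) {
    states <- rep("O", length(seqres_by_chain[[ch]]))
    states[unique(missing_by_chain[[ch]])] <- "M"
    chain_observation(structure_id, ch, states)
  })
}
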