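# Correlation of wwPDB structure-quality metrics with disorder content.

.QUALITY_METRICS <- c("resolution", "r_free", "clashscore", "rama_outliers",
                      "rotamer_outliers", "rsrz_outliers")

#' Read a structure-quality table
#'
#' Pre-computed per-structure validation metrics; never recomputed from
#' coordinates.
#'
#' @param path CSV with columns \code{structure_id}, \code{resolution},
#'   \code{r_free}, \code{clashscore}, \code{rama_outliers},
#'   \code{rotamer_outliers}, \code{rsrz_outliers} and optionally
#'   \code{year}.
#' @return Data.frame of quality records.
#' @export
read_quality_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("structure_id", .QUALITY_METRICS)
  if (!all(required %in% names(df))) {
    stop("quality table must have columns: ",
         paste(required, collapse = ", "))
  }
  if (any(df$resolution <= 0, na.rm = TRUE)) {
    stop("resolution must be positive")
  }
  df
}

#' Missing-residue fraction of a chain
#'
#' @param obs A \code{\link{chain_observation}}.
#' @return \code{count(M) / seqres_length}.
#' @export
missing_fraction_per_chain <- function(obs) {
  sum(obs$states == "M") / obs$seqres_length
}

#' Per-structure disorder fractions
#'
#' A structure's disorder fraction is the mean of its chains'
#' missing-residue fractions (each computed over the chain's SEQRES).
#'
#' @param observations List of \code{\link{chain_observation}}.
#' @return Data.frame \code{structure_id}, \code{disorder_fraction}.
#' @export
structure_disorder_fractions <- function(observations) {
  sid <- vapply(observations, `[[`, character(1), "structure_id")
  frac <- vapply(observations, missing_fraction_per_chain, numeric(1))
  agg <- tapply(frac, sid, mean)
  data.frame(structure_id = names(agg),
             disorder_fraction = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation with a t-test p-value
#'
#' Sample Pearson r with a two-sided p-value from the t distribution on
#' \code{n - 2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, \code{n >= 3}, both
#'   non-constant.
#' @return List \code{n}, \code{r}, \code{p}.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(n = n, r = r, p = p)
}

#' Correlate quality metrics with per-structure disorder measures
#'
#' Joins a quality table with per-structure values (disorder fractions or
#' LDR lengths) on \code{structure_id}; records missing either side, or
#' missing a given metric, are dropped pairwise for that metric.
#'
#' @param quality Data.frame from \code{\link{read_quality_csv}}.
#' @param values Data.frame with \code{structure_id} and one numeric value
#'   column (its name is taken as the x variable).
#' @param metrics Character vector of quality columns to correlate.
#' @return Data.frame \code{metric}, \code{n}, \code{r}, \code{p},
#'   \code{insufficient} (TRUE when fewer than 3 complete pairs, with
#'   \code{r}/\code{p} set to NA).
#' @export
correlate_quality <- function(quality, values,
                              metrics = .QUALITY_METRICS) {
  value_col <- setdiff(names(values), "structure_id")[1L]
  merged <- merge(quality, values, by = "structure_id")
  rows <- lapply(metrics, function(metric) {
    x <- merged[[value_col]]
    y <- merged[[metric]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      return(data.frame(metric = metric, n = sum(ok), r = NA_real_,
                        p = NA_real_, insufficient = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- pearson_cor(x[ok], y[ok])
    data.frame(metric = metric, n = ct$n, r = ct$r, p = ct$p,
               insufficient = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
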