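## Contact-scale amyloidogenicity screen: a peptide is predicted
## amyloidogenic if at least `min_run` consecutive residues have
## window-averaged scale values above the empirical threshold 21.4.

#' Amyloid screen parameters
#'
#' @param residue_scale named per-residue scale (default: the packaged
#'   expected-contacts scale, see \code{\link{expected_contacts_scale}}).
#' @param averaging_window odd window size (residues) for the centered
#'   moving average; terminal windows truncate.
#' @param threshold empirical amyloidogenicity threshold (default 21.4).
#' @param min_run minimum number of consecutive above-threshold residues
#'   for an amyloidogenic call (default 7).
#' @return object of class \code{amyloid_params}.
#' @export
amyloid_params <- function(residue_scale = expected_contacts_scale(),
                           averaging_window = 5, threshold = 21.4,
                           min_run = 7) {
  stopifnot(averaging_window >= 1, averaging_window %% 2 == 1,
            min_run >= 1)
  structure(list(residue_scale = residue_scale,
                 averaging_window = as.integer(averaging_window),
                 threshold = threshold, min_run = as.integer(min_run)),
            class = "amyloid_params")
}

longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Amyloidogenicity profile of a single peptide
#'
#' Computes the per-residue scale profile, its centered moving average
#' (windows truncated at the termini), the longest run of consecutive
#' residues whose averaged value exceeds the threshold, and the resulting
#' classification.
#'
#' @param seq peptide sequence (one-letter string).
#' @param params an \code{\link{amyloid_params}} object.
#' @return object of class \code{amyloid_profile} with fields \code{raw},
#'   \code{averaged}, \code{longest_run} and \code{classification}
#'   (\code{"amyloidogenic"} or \code{"nonamyloidogenic"}).
#' @examples
#' amyloid_profile("KKKVKVKVNTT")$classification
#' @export
amyloid_profile <- function(seq, params = amyloid_params()) {
  chars <- seq_chars(seq)
  miss <- setdiff(chars, names(params$residue_scale))
  if (length(miss)) {
    stop("residue scale missing entries for: ",
         paste(unique(miss), collapse = ", "))
  }
  raw <- as.numeric(params$residue_scale[chars])
  avg <- moving_average(raw, params$averaging_window)
  run <- longest_run(avg > params$threshold)
  structure(list(sequence = seq, raw = raw, averaged = avg,
                 longest_run = run,
                 classification = if (run >= params$min_run)
                   "amyloidogenic" else "nonamyloidogenic",
                 params = params),
            class = "amyloid_profile")
}

#' @export
print.amyloid_profile <- function(x, ...) {
  cat("Amyloidogenicity profile:", x$sequence, "\n")
  cat(sprintf("  longest run above %.1f: %d (min for amyloidogenic: %d)\n",
              x$params$threshold, x$longest_run, x$params$min_run))
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' Screen both chains of a peptide pair
#'
#' @param pair a \code{\link{peptide_pair}}.
#' @param params an \code{\link{amyloid_params}} object.
#' @return data.frame with columns chain, sequence, longest_run,
#'   classification.
#' @export
screen_pair <- function(pair, params = amyloid_params()) {
  pa <- amyloid_profile(pair$seq_A, params)
  pb <- amyloid_profile(pair$seq_B, params)
  data.frame(chain = c("A", "B"),
             sequence = c(pair$seq_A, pair$seq_B),
             longest_run = c(pa$longest_run, pb$longest_run),
             classification = c(pa$classification, pb$classification),
             stringsAsFactors = FALSE)
}

#' Screen all records of a FASTA file
#'
#' @param path FASTA file of peptide sequences.
#' @param params an \code{\link{amyloid_params}} object.
#' @return data.frame with columns id, sequence, longest_run,
#'   classification.
#' @export
screen_fasta <- function(path, params = amyloid_params()) {
  seqs <- read_fasta_sequences(path)
  rows <- lapply(seq_along(seqs), function(i) {
    p <- amyloid_profile(seqs[[i]], params)
    data.frame(id = names(seqs)[i], sequence = seqs[[i]],
               longest_run = p$longest_run,
               classification = p$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
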