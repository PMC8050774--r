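#' In-silico Lys-C/P digestion
#'
#' Cleaves a protein sequence strictly C-terminal of every lysine, including
#' lysines followed by proline (the "/P" rule), and enumerates all peptides
#' with up to `max_missed` retained internal cleavage sites.
#'
#' @param sequence amino-acid string over the 20 standard residues.
#' @param max_missed maximum number of missed cleavages (>= 0).
#' @return data.frame with columns `peptide`, `start` (1-based inclusive
#'   position of the peptide's first residue) and `n_missed`, ordered by
#'   `n_missed` then `start`.
#' @examples
#' lysc_digest("MKAK", 1)
#' @export
lysc_digest <- function(sequence, max_missed = 2) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  if (max_missed < 0) stop("max_missed must be >= 0")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), .AA20)
  if (length(bad))
    stop("non-standard residue(s) in sequence: ", paste(bad, collapse = ", "))
  n <- length(chars)
  seg_end <- sort(unique(c(which(chars == "K"), n)))
  seg_start <- c(1L, utils::head(seg_end, -1L) + 1L)
  nseg <- length(seg_end)
  res <- list()
  for (m in 0:min(max_missed, nseg - 1L)) {
    i <- seq_len(nseg - m)
    res[[m + 1L]] <- data.frame(
      peptide = substring(sequence, seg_start[i], seg_end[i + m]),
      start = seg_start[i],
      n_missed = m,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}
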