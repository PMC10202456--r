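#' Write a simulated recording to a portable directory container
#'
#' Stores counts (one TSV per trial, units x bins), ground-truth latents
#' (TSV), and attributes (JSON: bin width, seed, dimensions). A stimulus
#' label CSV can be attached with [write_labels()] into the same directory.
#'
#' @param rec a `sim_recording` from [simulate_response()].
#' @param dir output directory (created if needed).
#' @param labels optional label data frame, written to `labels.csv`.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir, labels = NULL) {
  stopifnot(inherits(rec, "sim_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(rec$counts)
  for (tr in seq_len(d[1])) {
    utils::write.table(rec$counts[tr, , , drop = TRUE],
                       file.path(dir, sprintf("counts_trial%02d.tsv", tr)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(rec$true_latents, file.path(dir, "latents.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  attrs <- list(bin_s = rec$bin_s, seed = rec$seed, n_trials = d[1],
                n_units = d[2], n_bins = d[3],
                signal_dim = nrow(rec$true_latents))
  jsonlite::write_json(attrs, file.path(dir, "attrs.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(labels)) write_labels(labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Read a recording container written by [write_recording()]
#'
#' @param dir container directory.
#' @return a `sim_recording` (without the generating `pop`).
#' @export
read_recording <- function(dir) {
  attrs <- jsonlite::read_json(file.path(dir, "attrs.json"),
                               simplifyVector = TRUE)
  counts <- array(0L, dim = c(attrs$n_trials, attrs$n_units, attrs$n_bins))
  for (tr in seq_len(attrs$n_trials)) {
    m <- as.matrix(utils::read.table(
      file.path(dir, sprintf("counts_trial%02d.tsv", tr)), sep = "\t"))
    counts[tr, , ] <- as.integer(m)
  }
  latents <- as.matrix(utils::read.table(file.path(dir, "latents.tsv"),
                                         sep = "\t"))
  dimnames(latents) <- NULL
  structure(list(counts = counts, true_latents = latents,
                 bin_s = attrs$bin_s, rates = NULL, pop = NULL,
                 seed = attrs$seed),
            class = "sim_recording")
}
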