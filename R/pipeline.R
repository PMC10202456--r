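#' Experiment configuration
#'
#' A fully serializable description of an end-to-end run: stimulus class,
#' hearing profile, optional hearing-aid processing, synthetic population,
#' analyses, and a root seed from which all named random substreams derive.
#'
#' @param stimulus list with `class` (one of `"tones"`, `"sam_freq"`,
#'   `"sam_depth"`, `"consonants"`) and optional generator arguments (e.g.
#'   `levels`).
#' @param hearing `NULL` for normal hearing, or a numeric vector of 5
#'   threshold shifts (dB at 500-8000 Hz), or a [hearing_profile].
#' @param wdrc `FALSE`, `TRUE` (fit from the audiogram), or a [wdrc_config].
#' @param population list of [make_population()] arguments.
#' @param analyses character subset of `"signal_noise"`, `"manifold"`,
#'   `"rsa"`.
#' @param seed root integer seed.
#' @param outdir output directory for the result bundle.
#' @return an `experiment_config` object.
#' @export
experiment_config <- function(stimulus = list(class = "tones"),
                              hearing = NULL, wdrc = FALSE,
                              population = list(), analyses = c("manifold"),
                              seed = 1, outdir = tempfile("icdyn_run")) {
  structure(list(stimulus = stimulus, hearing = hearing, wdrc = wdrc,
                 population = population, analyses = analyses, seed = seed,
                 outdir = outdir),
            class = "experiment_config")
}

config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$outdir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

resolve_profile <- function(hearing) {
  if (is.null(hearing)) return(hearing_profile())
  if (inherits(hearing, "hearing_profile")) return(hearing)
  hearing_profile(as.numeric(hearing))
}

generate_stimulus <- function(stim, seed) {
  args <- stim[setdiff(names(stim), "class")]
  args$seed <- seed
  switch(stim$class,
    tones = do.call(make_tone_stream, args),
    sam_freq = do.call(make_sam_stream, c(list(mode = "freq_sweep"), args)),
    sam_depth = do.call(make_sam_stream, c(list(mode = "depth_sweep"), args)),
    consonants = do.call(make_consonant_tokens, args),
    stop("unknown stimulus class: ", stim$class))
}

read_manifest <- function(outdir) {
  p <- file.path(outdir, "manifest.json")
  if (!file.exists(p)) return(NULL)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

write_manifest <- function(outdir, manifest) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Run an end-to-end experiment
#'
#' Stimulus synthesis, optional hearing-aid processing, synthetic population
#' simulation (three repeats: one training and two test trials), and the
#' requested analyses, written to a result bundle with a manifest recording
#' the configuration hash, seed, and completed stages. Re-running an
#' identical configuration reproduces identical outputs; completed stages of
#' a partial run are skipped on resume.
#'
#' @param cfg an [experiment_config()].
#' @return the bundle directory, invisibly.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  manifest <- read_manifest(cfg$outdir)
  if (is.null(manifest) || !identical(manifest$config_hash, hash)) {
    manifest <- list(config_hash = hash, seed = cfg$seed,
                     package_version = as.character(utils::packageVersion("icdyn")),
                     stages = character())
  }
  done <- function(stage) stage %in% manifest$stages
  mark <- function(stage) {
    manifest$stages <<- union(manifest$stages, stage)
    write_manifest(cfg$outdir, manifest)
  }

  stim <- generate_stimulus(cfg$stimulus, substream_seed(cfg$seed, "stimuli"))
  if (!done("stimulus")) {
    write_labels(stim$labels, file.path(cfg$outdir, "labels.csv"))
    mark("stimulus")
  }
  wave <- stim$wave
  if (!isFALSE(cfg$wdrc)) {
    aid <- if (inherits(cfg$wdrc, "wdrc_config")) cfg$wdrc else
      fit_from_audiogram(resolve_profile(cfg$hearing))
    wave <- wdrc_process(wave, aid)
  }

  pop_args <- cfg$population
  pop_args$hearing <- resolve_profile(cfg$hearing)
  pop_args$seed <- substream_seed(cfg$seed, "population")
  pop <- do.call(make_population, pop_args)
  rec <- simulate_response(wave, pop, n_trials = 3,
                           seed = substream_seed(cfg$seed, "trials"))
  if (!done("recording")) {
    write_recording(rec, file.path(cfg$outdir, "recording"),
                    labels = stim$labels)
    mark("recording")
  }

  Rtrain <- rec$counts[1, , ]
  R1 <- rec$counts[2, , ]
  R2 <- rec$counts[3, , ]
  basis <- fit_pcs(Rtrain)

  if ("signal_noise" %in% cfg$analyses && !done("signal_noise")) {
    st <- signal_noise_stats(R1, R2)
    utils::write.csv(data.frame(unit = seq_along(st$total_var),
                                total_var = st$total_var,
                                signal_var = st$signal_var,
                                noise_var = st$noise_var),
                     file.path(cfg$outdir, "signal_noise.csv"),
                     row.names = FALSE)
    mark("signal_noise")
  }
  if ("manifold" %in% cfg$analyses && !done("manifold")) {
    Ds <- seq_len(min(24, nrow(basis$Z)))
    curves <- variance_explained_curves(R1, R2, basis, Ds)
    curves$metric_dim <- signal_dimensionality(curves$signal_ve)
    utils::write.csv(curves, file.path(cfg$outdir, "manifold_curves.csv"),
                     row.names = FALSE)
    mark("manifold")
  }
  # latent trajectories on the identified manifold (for report/RSA)
  Dstar <- max(pop$signal_dim, 2)
  X <- project_latents(R1, basis, Dstar)
  attr(X, "rate_hz") <- 1 / rec$bin_s
  if (!done("latents")) {
    utils::write.table(X, file.path(cfg$outdir, "latents_pca.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    mark("latents")
  }
  if ("rsa" %in% cfg$analyses && !done("rsa")) {
    traj <- sound_trajectories(X, stim$labels, rate_hz = 1 / rec$bin_s)
    rdm <- compute_rdm(traj)
    utils::write.csv(as.data.frame(unclass(rdm)),
                     file.path(cfg$outdir, "rdm.csv"), row.names = FALSE)
    mark("rsa")
  }
  invisible(cfg$outdir)
}

#' Summarize one or more experiment bundles
#'
#' Aggregates pairwise representational (RDM) and CCA similarities of the
#' bundles' latent dynamics. Bundles must come from runs over the same
#' stimulus configuration (matching label sets).
#'
#' @param dirs character vector of bundle directories.
#' @return list with `pairs` (data frame: bundle_a, bundle_b,
#'   rdm_similarity, cca_similarity) and `manifests`.
#' @export
report_bundles <- function(dirs) {
  stopifnot(length(dirs) >= 1)
  load_one <- function(d) {
    X <- as.matrix(utils::read.table(file.path(d, "latents_pca.tsv"),
                                     sep = "\t"))
    dimnames(X) <- NULL
    labels <- utils::read.csv(file.path(d, "labels.csv"))
    attrs <- jsonlite::read_json(file.path(d, "recording", "attrs.json"),
                                 simplifyVector = TRUE)
    list(X = X, labels = labels, bin_s = attrs$bin_s,
         manifest = read_manifest(d))
  }
  bundles <- lapply(dirs, load_one)
  lab0 <- bundles[[1]]$labels
  for (b in bundles)
    if (nrow(b$labels) != nrow(lab0)) stop("mismatched label sets")
  idx <- expand.grid(a = seq_along(dirs), b = seq_along(dirs))
  idx <- idx[idx$a <= idx$b, ]
  pairs <- do.call(rbind, lapply(seq_len(nrow(idx)), function(i) {
    a <- bundles[[idx$a[i]]]; b <- bundles[[idx$b[i]]]
    ta <- sound_trajectories(a$X, a$labels, rate_hz = 1 / a$bin_s)
    tb <- sound_trajectories(b$X, b$labels, rate_hz = 1 / b$bin_s)
    data.frame(bundle_a = dirs[idx$a[i]], bundle_b = dirs[idx$b[i]],
               rdm_similarity = rdm_similarity(compute_rdm(ta),
                                               compute_rdm(tb)),
               cca_similarity = cca_similarity(a$X, b$X))
  }))
  list(pairs = pairs, manifests = lapply(bundles, `[[`, "manifest"))
}
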