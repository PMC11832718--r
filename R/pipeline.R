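#' Analyse one subject's epochs
#'
#' The per-subject analysis chain: region selection, RESS spatial
#' filtering, complex demodulation, AM/ITPC profiles, MCGF fits and
#' average band power. Input epochs are assumed preprocessed (filtered,
#' baseline-corrected).
#'
#' @param epochs an `"assr_epochs"` object (all channels).
#' @param region region name passed to [region_selection()].
#' @param ress_settings a [ress_settings()].
#' @param demod_settings a [demod_settings()].
#' @param fit_window MCGF fit window, seconds.
#' @return list with `ress` (a `"ress_result"`), `profile`
#'   (`"assr_modprofile"` with AM and ITPC), `fit_am`, `fit_itpc`
#'   (`"mcgf_fit"`), `power` (scalar) and `topography`
#'   (`"assr_topography"`, all input channels).
#' @export
analyze_subject <- function(epochs, region = "mixed",
                            ress_settings = assrpipe::ress_settings(),
                            demod_settings = assrpipe::demod_settings(),
                            fit_window = c(0, 5)) {
  stopifnot(inherits(epochs, "assr_epochs"))
  reg <- region_selection(region, available = epochs$channel_labels)
  sub <- select_channels(epochs, intersect(reg$channels, epochs$channel_labels))
  rr <- ress(sub, ress_settings)
  dm <- complex_demodulate(rr$component, demod_settings)
  prof <- modulation_profile(dm)
  list(ress = rr,
       profile = prof,
       fit_am = fit_mcgf(prof, "am", fit_window),
       fit_itpc = fit_mcgf(prof, "itpc", fit_window),
       power = assr_bandpower(rr$component, demod_settings$f),
       topography = topography_40hz(epochs))
}

#' Extract one feature row from a subject analysis
#'
#' @param res result of [analyze_subject()].
#' @param id subject id.
#' @param group group label.
#' @return one-row data frame matching the GLM feature contract.
#' @export
subject_features <- function(res, id, group) {
  pa <- res$fit_am$params
  pi_ <- res$fit_itpc$params
  data.frame(id = id, group = group,
             A_am = pa$A, mu_am = pa$mu, sigma_am = pa$sigma,
             alpha_am = pa$alpha,
             A_itpc = pi_$A, mu_itpc = pi_$mu, sigma_itpc = pi_$sigma,
             alpha_itpc = pi_$alpha,
             power = res$power)
}

#' Run the synthetic-cohort pipeline end to end
#'
#' Simulates a two-group cohort (seeded), runs the per-subject analysis
#' chain on every simulated recording, assembles the feature table,
#' generates cognition scores from the configured GLM truth, fits the
#' three cognition GLMs, runs the group comparisons (t test on the IQ
#' indices, rank-sum tests on the SOC outcomes) and the channel-wise
#' permutation test on the 40 Hz topographies. Identical configurations
#' produce identical bundles.
#'
#' @param config list with elements (all optional): `n_high`, `n_low`
#'   (subjects per group, default 12 each; the full interaction design
#'   has 21 columns, so cohorts need more than 21 subjects for the GLM
#'   stage), `seed` (default 1),
#'   `region` (default "mixed"), `n_trials` (default 40), `n_perm`
#'   (default 500), `glm_truth` (see [simulate_cognition()]; a default
#'   truth with group-dependent magnitude/latency effects is used if
#'   absent), `cognition_noise_sd` (default 0.05), and `out_dir` (if
#'   given, CSV/JSON artifacts are written there).
#' @return object of class `"assr_bundle"`: list with `features`,
#'   `cognition`, `subjects` (per-subject fit summaries), `glm` (list
#'   IQ/SOCmove/SOCprob of `"assr_glm"`), `tests`, `topo_p`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    n_high = 12L, n_low = 12L, seed = 1L, region = "mixed",
    n_trials = 40L, n_perm = 500L, cognition_noise_sd = 0.05,
    glm_truth = default_glm_truth(), out_dir = NULL), config)
  timeline <- make_session_timeline(cfg$n_trials, 6, 5)
  groups <- rep(c("highCog", "lowCog"), c(cfg$n_high, cfg$n_low))
  ids <- sprintf("S%03d", seq_along(groups))

  subjects <- vector("list", length(groups))
  feats <- vector("list", length(groups))
  topo <- matrix(0, nrow = length(groups), ncol = 0)
  for (i in seq_along(groups)) {
    scfg <- group_synth_config(groups[i], seed = cfg$seed * 10000L + i)
    ep <- simulate_assr_epochs(scfg, timeline)
    res <- analyze_subject(ep, region = cfg$region)
    if (ncol(topo) == 0)
      topo <- matrix(0, nrow = length(groups),
                     ncol = length(res$topography$value),
                     dimnames = list(ids, names(res$topography$value)))
    topo[i, ] <- res$topography$value
    feats[[i]] <- subject_features(res, ids[i], groups[i])
    subjects[[i]] <- list(id = ids[i], group = groups[i],
                          fit_am = res$fit_am, fit_itpc = res$fit_itpc,
                          power = res$power, snr = as.numeric(res$ress$snr),
                          eigenvalues = res$ress$eigenvalues)
  }
  features <- do.call(rbind, feats)
  features$group <- factor(features$group, levels = c("highCog", "lowCog"))

  cognition <- simulate_cognition(cfg$glm_truth, features,
                                  noise_sd = cfg$cognition_noise_sd,
                                  seed = cfg$seed + 7L)

  glms <- list()
  for (rid in c("IQ", "SOCmove", "SOCprob")) {
    y <- transform_response(cognition, rid)
    glms[[rid]] <- fit_glm(build_design(features, rid), as.numeric(y))
  }

  hi <- cognition$group == "highCog"
  tests <- list(
    IST60 = two_sample_tests(cognition$IST60[hi], cognition$IST60[!hi], "t"),
    SOC_moves_4 = two_sample_tests(cognition$SOC_moves_4[hi],
                                   cognition$SOC_moves_4[!hi], "ranksum"),
    SOC_prob_min = two_sample_tests(cognition$SOC_prob_min[hi],
                                    cognition$SOC_prob_min[!hi], "ranksum"))

  topo_p <- permutation_topography(topo[groups == "highCog", , drop = FALSE],
                                   topo[groups == "lowCog", , drop = FALSE],
                                   n_perm = cfg$n_perm, seed = cfg$seed)

  provenance <- list(config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]),
                     seed = cfg$seed,
                     version = as.character(utils::packageVersion("assrpipe")))
  bundle <- structure(list(features = features, cognition = cognition,
                           subjects = subjects, glm = glms, tests = tests,
                           topography = topo, topo_p = topo_p,
                           provenance = provenance),
                      class = "assr_bundle")
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

#' Default GLM coefficient truth for the synthetic cohort
#'
#' A minimal set of group-dependent effects in the directions the
#' analysis expects (larger AM magnitude with higher cognition scores,
#' higher band power and later latency with poorer executive function),
#' expressed over the [build_design()] columns.
#'
#' @return named list with `IQ`, `SOCmove`, `SOCprob` coefficient
#'   vectors.
#' @export
default_glm_truth <- function() {
  list(
    IQ = c("(Intercept)" = -2.0, "grouphighCog" = 2.9,
           "A_am:lowCog" = 2.5, "power:lowCog" = -8.0),
    SOCmove = c("(Intercept)" = 0.17, "grouphighCog" = 0.05,
                "A_am:lowCog" = 0.05, "power:lowCog" = -0.2),
    SOCprob = c("(Intercept)" = 1.35, "mu_am:highCog" = -0.8,
                "mu_am:lowCog" = 0.4))
}

#' @export
print.assr_bundle <- function(x, ...) {
  cat(sprintf("<assr_bundle> %d subjects (%s), %d GLMs, hash %s\n",
              nrow(x$features),
              paste(table(x$features$group), collapse = "+"),
              length(x$glm), x$provenance$config_hash))
  invisible(x)
}

#' Write the result bundle to disk
#'
#' CSV for tables (features, cognition, GLM coefficient tables,
#' topography values) and JSON for fit summaries, test results and
#' provenance. Every file name embeds the config hash.
#'
#' @param bundle an `"assr_bundle"`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- bundle$provenance$config_hash
  pre <- function(name) file.path(out_dir, sprintf("%s_%s", name, h))
  write.csv(bundle$features, paste0(pre("features"), ".csv"), row.names = FALSE)
  write_cognition_csv(bundle$cognition, paste0(pre("cognition"), ".csv"))
  for (rid in names(bundle$glm))
    write.csv(bundle$glm[[rid]]$terms,
              paste0(pre(paste0("glm_", rid)), ".csv"), row.names = FALSE)
  write.csv(as.data.frame(bundle$topography),
            paste0(pre("topography"), ".csv"))
  jsonlite::write_json(
    list(tests = bundle$tests,
         topo_p = as.list(bundle$topo_p),
         glm_summaries = lapply(bundle$glm, function(g)
           g[c("r2", "loglik", "fstat", "f_p", "chi2", "chi2_p", "n")]),
         provenance = bundle$provenance),
    paste0(pre("summary"), ".json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(out_dir)
}

#' Load a pipeline configuration from YAML
#'
#' Thin wrapper for the command-line entry point: reads a YAML file of
#' [run_pipeline()] keys and merges command-line overrides on top.
#'
#' @param path YAML file path (optional).
#' @param overrides named list of overrides.
#' @return configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  utils::modifyList(cfg, overrides)
}
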