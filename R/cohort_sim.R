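#' Configuration for the synthetic maltreatment-exposure cohort generator
#'
#' Defines the generative model for a synthetic cohort of maltreated
#' children: per-subject annual 0/1 exposure bins from birth onward, a
#' prenatal domestic-violence flag, four maltreatment-type indicators
#' (physical, emotional, sexual, neglect), and a continuous regional
#' gray-matter signal whose depressive effect is concentrated in a
#' configurable age window.
#'
#' Exposure histories are single contiguous episodes: an onset age is drawn
#' from `onset_distribution`, the onset year is exposed, and each following
#' year remains exposed with probability `episode_persistence` until the
#' first gap or the last bin.  Type indicators are drawn independently from
#' `type_prevalence`; a subject with at least one type receives an episode,
#' a subject with no type has an all-zero annual history.  The default
#' prevalences are the observed cohort rates 7/21, 11/21, 2/21 and 16/21
#' for physical, emotional, sexual abuse and neglect, and the default
#' persistence 0.98 with a uniform onset reproduces a mean exposure
#' duration of about 7.7 years over 16 annual bins.
#'
#' @param n_subjects number of subjects (default 21, the study cohort size).
#' @param max_age_bin number of annual age bins, `[0,1) ... [max-1,max)`.
#' @param prenatal_prevalence probability of prenatal domestic-violence
#'   exposure.
#' @param type_prevalence named probabilities for `physical`, `emotional`,
#'   `sexual`, `neglect`.
#' @param episode_persistence probability that an exposed year is followed
#'   by another exposed year.
#' @param onset_distribution probability weights over the age bins for the
#'   episode onset; default uniform.
#' @param effect_window integer age-bin indices (0-based ages) in which an
#'   exposed year depresses the signal; default bins 5 and 6, i.e. ages
#'   5-7.
#' @param effect_size signal reduction per exposed year inside the window,
#'   in units of `noise_sd` = 1 by default.
#' @param type_effect signal change per count of maltreatment types
#'   (negative values depress the signal with multiplicity).
#' @param noise_sd standard deviation of the Gaussian residual signal.
#' @param tscc if `TRUE`, also simulate the six TSCC symptom subscales;
#'   subscales named in `tscc_affected` share the timing effect, the rest
#'   are pure noise.
#' @param tscc_affected subscale columns that carry the window effect.
#' @param seed integer seed; identical configurations generate identical
#'   cohorts.
#' @return an object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_subjects = 21,
                       max_age_bin = 16,
                       prenatal_prevalence = 0.2,
                       type_prevalence = c(physical = 7 / 21,
                                           emotional = 11 / 21,
                                           sexual = 2 / 21,
                                           neglect = 16 / 21),
                       episode_persistence = 0.98,
                       onset_distribution = NULL,
                       effect_window = c(5L, 6L),
                       effect_size = 1,
                       type_effect = 0,
                       noise_sd = 1,
                       tscc = FALSE,
                       tscc_affected = c("tscc_anx", "tscc_pts", "tscc_dis"),
                       seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be at least 2", call. = FALSE)
  if (max_age_bin < 1) stop("max_age_bin must be positive", call. = FALSE)
  probs <- c(prenatal_prevalence, episode_persistence, type_prevalence)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  req <- c("physical", "emotional", "sexual", "neglect")
  if (!all(req %in% names(type_prevalence)))
    stop("type_prevalence must name physical, emotional, sexual, neglect",
         call. = FALSE)
  if (is.null(onset_distribution))
    onset_distribution <- rep(1 / max_age_bin, max_age_bin)
  if (length(onset_distribution) != max_age_bin || any(onset_distribution < 0) ||
      sum(onset_distribution) <= 0)
    stop("onset_distribution must be non-negative weights over the age bins",
         call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  effect_window <- as.integer(effect_window)
  if (length(effect_window) &&
      (any(effect_window < 0) || any(effect_window >= max_age_bin)))
    stop("effect_window must be inside 0 .. max_age_bin - 1", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    max_age_bin = as.integer(max_age_bin),
    prenatal_prevalence = prenatal_prevalence,
    type_prevalence = type_prevalence[req],
    episode_persistence = episode_persistence,
    onset_distribution = onset_distribution / sum(onset_distribution),
    effect_window = effect_window,
    effect_size = effect_size,
    type_effect = type_effect,
    noise_sd = noise_sd,
    tscc = isTRUE(tscc),
    tscc_affected = tscc_affected,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Age-bin column names of a cohort
#'
#' @param max_age_bin number of annual bins.
#' @return character vector `age_0_1 ... age_<k-1>_<k>`.
#' @export
age_bin_names <- function(max_age_bin = 16) {
  paste0("age_", seq_len(max_age_bin) - 1L, "_", seq_len(max_age_bin))
}

#' Predictor sets of the two regression designs
#'
#' The timing design uses the prenatal flag, the annual exposure bins and
#' total duration; the type design uses the four maltreatment-type
#' indicators plus the number of types.
#'
#' @param max_age_bin number of annual bins in the cohort.
#' @return named character vector of predictor columns, names giving the
#'   predictor category.
#' @export
timing_predictors <- function(max_age_bin = 16) {
  cols <- c("prenatal_dv", age_bin_names(max_age_bin), "duration_years")
  names(cols) <- c("prenatal", rep("age-bin", max_age_bin), "duration")
  cols
}

#' @rdname timing_predictors
#' @export
type_predictors <- function() {
  cols <- c("physical", "emotional", "sexual", "neglect", "n_types")
  names(cols) <- c(rep("type", 4), "n_types")
  cols
}

#' Draw one subject's exposure history
#'
#' Uses the current R random-number stream; [simulate_cohort()] seeds it
#' once per cohort.
#'
#' @param config a [sim_config()].
#' @return list with elements `prenatal_dv`, `annual` (0/1 vector of length
#'   `max_age_bin`), `types` (named 0/1 vector), `n_types`,
#'   `duration_years`.
#' @export
sample_exposure_history <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  types <- stats::rbinom(4L, 1L, config$type_prevalence)
  names(types) <- names(config$type_prevalence)
  prenatal <- stats::rbinom(1L, 1L, config$prenatal_prevalence)
  annual <- integer(config$max_age_bin)
  if (sum(types) > 0L) {
    onset <- sample.int(config$max_age_bin, 1L,
                        prob = config$onset_distribution) - 1L
    annual[onset + 1L] <- 1L
    a <- onset + 1L
    while (a < config$max_age_bin) {
      if (stats::runif(1) >= config$episode_persistence) break
      annual[a + 1L] <- 1L
      a <- a + 1L
    }
  }
  list(prenatal_dv = prenatal,
       annual = annual,
       types = types,
       n_types = sum(types),
       duration_years = sum(annual))
}

#' Synthetic regional signal for a cohort
#'
#' The raw signal analogue is
#' `y = -effect_size * (exposed years inside the effect window)
#'    + type_effect * n_types + N(0, noise_sd)`,
#' mirroring a regional gray-matter eigenvariate depressed by exposure
#' during a sensitive period.  Returned unscaled; the analysis pipeline
#' applies the mean-100/SD-10 transform.
#'
#' @param cohort a cohort data frame containing the age-bin columns of the
#'   effect window and `n_types`.
#' @param config a [sim_config()].
#' @return numeric vector, one value per cohort row.
#' @export
generate_response <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  win_cols <- age_bin_names(config$max_age_bin)[config$effect_window + 1L]
  missing_cols <- setdiff(c(win_cols, "n_types"), names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  window_years <- if (length(win_cols))
    rowSums(cohort[, win_cols, drop = FALSE]) else rep(0, nrow(cohort))
  -config$effect_size * window_years +
    config$type_effect * cohort$n_types +
    stats::rnorm(nrow(cohort), 0, config$noise_sd)
}

#' Simulate a full synthetic cohort
#'
#' Draws `n_subjects` exposure histories and the synthetic regional signal
#' (`gm_signal`), laid out with the columns both regression designs need.
#' Deterministic: the same configuration (including its seed) always
#' returns an identical cohort.
#'
#' @param config a [sim_config()].
#' @return a data frame of class `cohort` with columns `subject_id`,
#'   `prenatal_dv`, the annual `age_*` bins, the four type indicators,
#'   `n_types`, `duration_years`, `gm_signal`, and the six `tscc_*`
#'   subscales when `config$tscc` is `TRUE`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 21, seed = 7))
#' mean(cohort$duration_years)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  histories <- lapply(seq_len(config$n_subjects),
                      function(i) sample_exposure_history(config))
  annual <- do.call(rbind, lapply(histories, `[[`, "annual"))
  colnames(annual) <- age_bin_names(config$max_age_bin)
  types <- do.call(rbind, lapply(histories, `[[`, "types"))
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(config$n_subjects)),
    prenatal_dv = vapply(histories, `[[`, integer(1), "prenatal_dv"),
    annual,
    types,
    n_types = vapply(histories, `[[`, integer(1), "n_types"),
    duration_years = vapply(histories, `[[`, integer(1), "duration_years"),
    check.names = FALSE
  )
  cohort$gm_signal <- generate_response(cohort, config)
  if (config$tscc) {
    subscales <- c("tscc_anx", "tscc_dep", "tscc_ang",
                   "tscc_pts", "tscc_dis", "tscc_sc")
    for (sc in subscales) {
      cfg_sc <- config
      if (!sc %in% config$tscc_affected) cfg_sc$effect_size <- 0
      cfg_sc$type_effect <- 0
      cohort[[sc]] <- generate_response(cohort, cfg_sc)
    }
  }
  class(cohort) <- c("cohort", "data.frame")
  attr(cohort, "sim_config") <- config
  cohort
}

#' Read and write cohort tables
#'
#' Plain UTF-8 comma-separated tables, one header row, no row names.
#' `read_cohort` validates the schema and rejects missing values.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `read_cohort` returns a `cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, check.names = FALSE)
  if (anyNA(cohort))
    stop("cohort file contains missing values; imputation is not supported",
         call. = FALSE)
  age_cols <- grep("^age_\\d+_\\d+$", names(cohort), value = TRUE)
  required <- c("subject_id", "prenatal_dv", "physical", "emotional",
                "sexual", "neglect", "n_types", "duration_years")
  absent <- setdiff(required, names(cohort))
  if (length(absent))
    stop("cohort file lacks required columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (!length(age_cols))
    stop("cohort file has no age-bin (age_a_b) columns", call. = FALSE)
  class(cohort) <- c("cohort", "data.frame")
  cohort
}
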