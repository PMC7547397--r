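# threshold vectors from cumulative category proportions
thr <- function(cum) stats::qnorm(cum)

# marginal category proportions of the MIRROR items in the study population
# (items 1-4 PTSD, 5 functioning on ten categories, 6-8 resilience)
default_mirror_thresholds <- function() {
  list(
    mirror_q1 = thr(c(.027, .084, .250, .635)),
    mirror_q2 = thr(c(.051, .136, .329, .603)),
    mirror_q3 = thr(c(.093, .231, .500, .729)),
    mirror_q4 = thr(c(.085, .199, .466, .734)),
    mirror_functioning = thr(c(.049, .118, .222, .380, .578, .787, .908,
                               .971, .987)),
    mirror_q6 = thr(c(.053, .138, .355, .708)),
    mirror_q7 = thr(c(.073, .229, .581, .886)),
    mirror_q8 = thr(c(.052, .203, .659, .940)))
}

default_context_frequencies <- function() {
  list(
    event_type = c(
      another_very_stressful_event = .326,
      transportation_accident = .174,
      physical_assault = .165,
      sudden_accidental_death = .057,
      serious_accident = .050,
      sexual_assault = .050,
      assault_with_weapon = .045,
      other_unwanted_sexual_experience = .045,
      sudden_violent_death = .036,
      severe_human_suffering = .021,
      life_threatening_illness_or_injury = .015,
      fire_or_explosion = .014,
      combat_or_war_zone = .002,
      captivity = 0,
      serious_injury_or_death_caused_by_you = 0,
      natural_disaster = 0,
      toxic_substance_exposure = 0),
    relation = c(happened_to_me = .640, witnessed = .172, learned_about = .056,
                 work_related = .116, other_specified = .016),
    time_phase = c(under_1_week = .363, one_to_4_weeks = .217,
                   over_4_weeks = .323, recurring = .097))
}

#' Synthetic-cohort simulation configuration
#'
#' Parameters of the seeded respondent generator. Respondents are drawn from
#' a bivariate-normal latent model: a "PTSD complaints" factor behind the four
#' PTSD items and a "psychosocial resources" factor behind the functioning
#' rating and the three resilience items, with a negative factor correlation.
#' Ordinal items arise by thresholding \code{loading * latent +
#' sqrt(1 - loading^2) * noise}; the default thresholds reproduce the study
#' population's printed item-category margins. Reference batteries (PCL-5,
#' DASS-21, RES, MHC-SF) are generated from instrument-level factors that mix
#' the two latents with weights calibrated so the scale-level correlations
#' approximate the published validity matrix. Event context is drawn i.i.d.
#' from the published category frequencies.
#'
#' @param n Cohort size.
#' @param seed Integer seed; the same configuration and seed always yield a
#'   byte-identical cohort.
#' @param factor_correlation Correlation between the complaints and resources
#'   latents (default -0.45).
#' @param mirror_loadings Named loadings of the 8 MIRROR items on their design
#'   factor (default 0.6 for the PTSD and resilience items, 0.4 for the
#'   functioning rating, whose published loading on the resources factor is
#'   markedly weaker than the resilience items').
#' @param functioning_cross_loading Loading of the functioning rating on the
#'   complaints factor (default -0.25): functioning is impaired by complaints
#'   beyond what the factor correlation carries, mirroring its published
#'   negative cross-loading.
#' @param mirror_thresholds Named list of strictly increasing threshold
#'   vectors (4 per 5-category item, 9 for functioning).
#' @param reference_weights Named list per instrument of
#'   \code{c(complaints, resources)} weights of the instrument factor.
#' @param reference_item_loadings Named loading of each instrument's items on
#'   its instrument factor.
#' @param reference_thresholds Named list of threshold vectors shared by an
#'   instrument's items.
#' @param context_frequencies Named list of categorical weights for
#'   \code{event_type}, \code{relation} and \code{time_phase}.
#' @param battery_rate Fraction of respondents who complete the reference
#'   battery (the rest get \code{NA} battery columns), default 1.
#' @return Object of class \code{simulation_config}.
#' @export
simulation_config <- function(n, seed,
                              factor_correlation = -0.45,
                              mirror_loadings = NULL,
                              functioning_cross_loading = -0.25,
                              mirror_thresholds = default_mirror_thresholds(),
                              reference_weights = list(
                                pcl5 = c(0.70, -0.36),
                                dass = c(0.36, -0.60),
                                res  = c(0.04, 0.87),
                                mhc  = c(0.04, 0.86)),
                              reference_item_loadings = c(
                                pcl5 = 0.75, dass = 0.75, res = 0.75,
                                mhc = 0.75),
                              reference_thresholds = list(
                                pcl5 = thr(c(.15, .35, .60, .82)),
                                dass = thr(c(.30, .60, .85)),
                                res  = thr(c(.10, .30, .55, .80)),
                                mhc  = thr(c(.10, .25, .45, .65, .85))),
                              context_frequencies = default_context_frequencies(),
                              battery_rate = 1) {
  if (is.null(mirror_loadings)) {
    mirror_loadings <- stats::setNames(rep(0.6, 8), names(mirror_thresholds))
    mirror_loadings["mirror_functioning"] <- 0.4
  }
  stopifnot(n >= 0, n == round(n), length(seed) == 1, seed == round(seed))
  if (abs(factor_correlation) >= 1)
    stop("configuration error: factor_correlation must lie in (-1, 1)")
  if (any(abs(mirror_loadings) > 1) ||
      any(abs(reference_item_loadings) > 1) ||
      abs(functioning_cross_loading) > 1)
    stop("configuration error: loadings must not exceed 1 in absolute value")
  fl <- mirror_loadings[["mirror_functioning"]]
  if (fl^2 + functioning_cross_loading^2 +
      2 * fl * functioning_cross_loading * factor_correlation > 1)
    stop("configuration error: functioning loadings imply latent variance > 1")
  for (nm in names(mirror_thresholds))
    if (is.unsorted(mirror_thresholds[[nm]], strictly = TRUE))
      stop("configuration error: non-monotone thresholds for ", nm)
  for (nm in names(reference_thresholds))
    if (is.unsorted(reference_thresholds[[nm]], strictly = TRUE))
      stop("configuration error: non-monotone thresholds for ", nm)
  for (nm in names(context_frequencies)) {
    f <- context_frequencies[[nm]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-6)
      stop("configuration error: ", nm,
           " frequencies must be non-negative and sum to 1")
  }
  for (nm in names(reference_weights)) {
    w <- reference_weights[[nm]]
    v <- w[1]^2 + w[2]^2 + 2 * w[1] * w[2] * factor_correlation
    if (v > 1)
      stop("configuration error: reference weights for ", nm,
           " imply latent variance > 1")
  }
  if (battery_rate < 0 || battery_rate > 1)
    stop("configuration error: battery_rate must lie in [0, 1]")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 factor_correlation = factor_correlation,
                 mirror_loadings = mirror_loadings,
                 functioning_cross_loading = functioning_cross_loading,
                 mirror_thresholds = mirror_thresholds,
                 reference_weights = reference_weights,
                 reference_item_loadings = reference_item_loadings,
                 reference_thresholds = reference_thresholds,
                 context_frequencies = context_frequencies,
                 battery_rate = battery_rate),
            class = "simulation_config")
}

#' Threshold ordinal items from latent scores
#'
#' Each item value is \code{1 + } the number of thresholds lying below
#' \code{loading * latent + sqrt(1 - loading^2) * noise}, with standard normal
#' unique noise per item.
#'
#' @param latents Numeric vector of latent scores (one per respondent).
#' @param loadings Numeric vector, one loading per item.
#' @param thresholds List of strictly increasing threshold vectors, one per
#'   item (a single vector is recycled across items).
#' @param seed Optional integer seed for the unique noise.
#' @return Integer matrix, respondents by items, categories starting at 1.
#' @export
simulate_ordinal_items <- function(latents, loadings, thresholds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(thresholds)) thresholds <- rep(list(thresholds), length(loadings))
  stopifnot(length(thresholds) == length(loadings))
  n <- length(latents)
  out <- matrix(NA_integer_, n, length(loadings))
  for (j in seq_along(loadings)) {
    tj <- thresholds[[j]]
    if (is.unsorted(tj, strictly = TRUE))
      stop("configuration error: non-monotone thresholds for item ", j)
    lam <- loadings[[j]]
    y <- lam * latents + sqrt(1 - lam^2) * stats::rnorm(n)
    out[, j] <- 1L + findInterval(y, tj)
  }
  colnames(out) <- names(loadings)
  out
}

#' Draw event contexts from categorical frequency weights
#'
#' Event type, relation and time phase are i.i.d. categorical draws; the week
#' count is uniform within the drawn phase's band (0-1, 1-4, or 4-52 weeks;
#' recurring respondents get a uniform 0-52 week count and the recurring
#' flag).
#'
#' @param n Number of respondents.
#' @param frequencies Named list as in \code{\link{simulation_config}}.
#' @param seed Optional integer seed.
#' @return Data frame with \code{event_type}, \code{relation},
#'   \code{weeks_since_event}, \code{recurring}.
#' @export
simulate_event_context <- function(n, frequencies = default_context_frequencies(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(f) if (n == 0) character(0)
    else sample(names(f), n, replace = TRUE, prob = f)
  event_type <- draw(frequencies$event_type)
  relation <- draw(frequencies$relation)
  phase <- draw(frequencies$time_phase)
  weeks <- numeric(n)
  weeks[phase == "under_1_week"] <- stats::runif(sum(phase == "under_1_week"), 0, 1)
  weeks[phase == "one_to_4_weeks"] <- stats::runif(sum(phase == "one_to_4_weeks"), 1, 4)
  weeks[phase == "over_4_weeks"] <- stats::runif(sum(phase == "over_4_weeks"), 4.001, 52)
  weeks[phase == "recurring"] <- stats::runif(sum(phase == "recurring"), 0, 52)
  data.frame(event_type = event_type, relation = relation,
             weeks_since_event = round(weeks, 2),
             recurring = phase == "recurring",
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic respondent cohort
#'
#' Generates \code{cfg$n} respondents in the canonical cohort schema: the 8
#' MIRROR items, event context, bookkeeping flags, and (for a
#' \code{battery_rate} fraction) the 64 reference-battery items.
#'
#' @param cfg A \code{\link{simulation_config}}.
#' @return Data frame, one respondent per row.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  rho <- cfg$factor_correlation
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  complaints <- z1
  resources <- rho * z1 + sqrt(1 - rho^2) * z2
  item_names <- names(cfg$mirror_thresholds)
  on_resources <- c("mirror_functioning", "mirror_q6", "mirror_q7", "mirror_q8")
  mirror <- matrix(NA_integer_, n, length(item_names),
                   dimnames = list(NULL, item_names))
  for (j in seq_along(item_names)) {
    nm <- item_names[[j]]
    lam <- cfg$mirror_loadings[nm]
    lat <- if (nm %in% on_resources) resources else complaints
    if (nm == "mirror_functioning" && cfg$functioning_cross_loading != 0) {
      # fold the cross-loading into a unit-variance composite latent
      cl <- cfg$functioning_cross_loading
      v <- lam^2 + cl^2 + 2 * lam * cl * rho
      lat <- (lam * resources + cl * complaints) / sqrt(v)
      lam <- sqrt(v)
    }
    mirror[, j] <- simulate_ordinal_items(
      lat, lam, cfg$mirror_thresholds[nm])
  }
  ctx <- simulate_event_context(n, cfg$context_frequencies)
  out <- data.frame(respondent_id = if (n) sprintf("S%05d", seq_len(n)) else character(0),
                    as.data.frame(mirror), ctx,
                    is_repeat = logical(n), is_proxy = logical(n),
                    flagged_invalid = logical(n),
                    stringsAsFactors = FALSE)
  # reference batteries
  sizes <- c(pcl5 = 20L, dass = 21L, res = 9L, mhc = 14L)
  prefix <- c(pcl5 = "pcl5_q", dass = "dass_q", res = "res_q", mhc = "mhc_q")
  has_battery <- if (n) stats::runif(n) <= cfg$battery_rate else logical(0)
  for (inst in names(sizes)) {
    w <- cfg$reference_weights[[inst]]
    u <- sqrt(max(1 - (w[1]^2 + w[2]^2 + 2 * w[1] * w[2] * rho), 0))
    ti <- w[1] * complaints + w[2] * resources + u * stats::rnorm(n)
    k <- sizes[[inst]]
    items <- simulate_ordinal_items(
      ti, rep(cfg$reference_item_loadings[[inst]], k),
      cfg$reference_thresholds[[inst]]) - 1L   # published scales start at 0
    items[!has_battery, ] <- NA_integer_
    colnames(items) <- paste0(prefix[[inst]], seq_len(k))
    out <- cbind(out, as.data.frame(items))
  }
  out
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: n = %d, seed = %d, factor correlation %.2f, battery rate %.2f\n",
              x$n, x$seed, x$factor_correlation, x$battery_rate))
  invisible(x)
}
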